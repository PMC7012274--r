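// Ant-colony clustering engine.
//
// Objects (embedded event signals) live on a toroidal square grid, at most
// one per cell. Ants pick up objects with probability (k1/(k1+f))^2 and drop
// them with probability min(2f, 1) reached at f >= k2, where f is the local
// similarity of the object to its s x s grid neighbourhood measured by
// Euclidean distance in the (normalized) embedding space:
//   f = max(0, (1/s^2) * sum_nb [1 - d(obj, nb) / (alpha * (1+(v-1)/vmax))]).
// All randomness goes through R's RNG so runs are reproducible via set.seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline int wrap(int a, int side) {
  int r = a % side;
  return r < 0 ? r + side : r;
}

static inline int cell_index(int x, int y, int side) {
  return wrap(x, side) + wrap(y, side) * side;
}

static inline int rand_int(int k) {
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

static double obj_dist(const NumericMatrix& coords, int a, int b) {
  double dx = coords(a, 0) - coords(b, 0);
  double dy = coords(a, 1) - coords(b, 1);
  return std::sqrt(dx * dx + dy * dy);
}

// Local similarity f of object `obj` evaluated at site (cx, cy). Any cell in
// the s x s block occupied by `obj` itself is excluded from the sum.
static double local_f(const IntegerVector& occ, int side,
                      const NumericMatrix& coords, int cx, int cy, int obj,
                      double alpha, int vmax, int s, int v) {
  int h = (s - 1) / 2;
  double scale = alpha * (1.0 + (double)(v - 1) / (double)vmax);
  double sum = 0.0;
  for (int dy = -h; dy <= h; ++dy) {
    for (int dx = -h; dx <= h; ++dx) {
      int nb = occ[cell_index(cx + dx, cy + dy, side)];
      if (nb < 0 || nb == obj) continue;
      sum += 1.0 - obj_dist(coords, obj, nb) / scale;
    }
  }
  double f = sum / (double)(s * s);
  return f > 0.0 ? f : 0.0;
}

// Nearest empty cell to (cx, cy): rings of increasing Chebyshev radius,
// lexicographic (dx, then dy) within a ring. With `torus` the search wraps
// around the grid edges (used for in-run drops, matching the movement
// topology); without it the search stays in bounds (used for initial
// placement, so point sets mapped to opposite grid corners are not
// interleaved across the wrap). Writes the cell into (ox, oy); returns
// false only if no empty cell is reachable.
static bool nearest_empty(const IntegerVector& occ, int side, int cx, int cy,
                          int& ox, int& oy, bool torus) {
  int max_rad = torus ? side / 2 + 1 : side;
  for (int rad = 0; rad <= max_rad; ++rad) {
    for (int dx = -rad; dx <= rad; ++dx) {
      for (int dy = -rad; dy <= rad; ++dy) {
        if (std::max(std::abs(dx), std::abs(dy)) != rad) continue;
        int x = cx + dx, y = cy + dy;
        if (torus) { x = wrap(x, side); y = wrap(y, side); }
        else if (x < 0 || x >= side || y < 0 || y >= side) continue;
        if (occ[x + y * side] < 0) { ox = x; oy = y; return true; }
      }
    }
  }
  return false;
}

static void check_state(const IntegerVector& occ, const IntegerMatrix& cells,
                        const IntegerVector& carrying, int side) {
  int n = cells.nrow();
  int on_grid = 0;
  for (int c = 0; c < side * side; ++c) {
    int o = occ[c];
    if (o < 0) continue;
    ++on_grid;
    if (o >= n || cells(o, 0) + cells(o, 1) * side != c)
      stop("ant engine invariant violated: occupancy/coordinate mismatch");
  }
  int carried = 0;
  for (int a = 0; a < carrying.size(); ++a) {
    int o = carrying[a];
    if (o < 0) continue;
    ++carried;
    if (cells(o, 0) != -1 || cells(o, 1) != -1)
      stop("ant engine invariant violated: carried object still on grid");
  }
  if (on_grid + carried != n)
    stop("ant engine invariant violated: object count not conserved");
}

// [[Rcpp::export]]
List cpp_place_on_grid(IntegerMatrix desired, int side) {
  int n = desired.nrow();
  if ((double)side * (double)side < n) stop("grid too small for objects");
  IntegerVector occ(side * side, -1);
  IntegerMatrix cells(n, 2);
  for (int i = 0; i < n; ++i) {
    int x, y;
    if (!nearest_empty(occ, side, desired(i, 0), desired(i, 1), x, y, false))
      stop("no empty cell available");
    occ[x + y * side] = i;
    cells(i, 0) = x;
    cells(i, 1) = y;
  }
  return List::create(_["cells"] = cells, _["occupancy"] = occ);
}

// [[Rcpp::export]]
double cpp_local_similarity(IntegerVector occupancy, int side,
                            NumericMatrix coords, int cx, int cy, int obj,
                            double alpha, int vmax, int s, int v) {
  return local_f(occupancy, side, coords, cx, cy, obj, alpha, vmax, s, v);
}

// [[Rcpp::export]]
List cpp_ant_steps(int side, IntegerVector occupancy, IntegerMatrix cells,
                   IntegerVector ant_x, IntegerVector ant_y,
                   IntegerVector ant_v, IntegerVector carrying,
                   NumericMatrix coords, double alpha, double k1, double k2,
                   int vmax, int s, int n_steps, bool check,
                   bool allow_pick) {
  IntegerVector occ = clone(occupancy);
  IntegerMatrix cel = clone(cells);
  IntegerVector ax = clone(ant_x), ay = clone(ant_y), car = clone(carrying);
  const int dirx[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int diry[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int n_ants = ax.size();
  for (int step = 0; step < n_steps; ++step) {
    for (int a = 0; a < n_ants; ++a) {
      int v = ant_v[a];
      if (car[a] >= 0) {
        // laden: move v cells in a random direction, then try to drop
        int d = rand_int(8);
        ax[a] = wrap(ax[a] + v * dirx[d], side);
        ay[a] = wrap(ay[a] + v * diry[d], side);
        int obj = car[a];
        double f = local_f(occ, side, coords, ax[a], ay[a], obj,
                           alpha, vmax, s, v);
        double pd = f >= k2 ? 1.0 : 2.0 * f;
        if (unif_rand() < pd) {
          int x, y;
          if (nearest_empty(occ, side, ax[a], ay[a], x, y, true)) {
            occ[x + y * side] = obj;
            cel(obj, 0) = x;
            cel(obj, 1) = y;
            car[a] = -1;
          }
        }
      } else {
        // unladen: maybe pick up the object at the current cell, then move
        int here = allow_pick ? occ[ax[a] + ay[a] * side] : -1;
        if (here >= 0) {
          double f = local_f(occ, side, coords, ax[a], ay[a], here,
                             alpha, vmax, s, v);
          double pp = (k1 / (k1 + f)) * (k1 / (k1 + f));
          if (unif_rand() < pp) {
            occ[ax[a] + ay[a] * side] = -1;
            cel(here, 0) = -1;
            cel(here, 1) = -1;
            car[a] = here;
          }
        }
        int d = rand_int(8);
        ax[a] = wrap(ax[a] + v * dirx[d], side);
        ay[a] = wrap(ay[a] + v * diry[d], side);
      }
    }
    if (check) check_state(occ, cel, car, side);
  }
  return List::create(_["occupancy"] = occ, _["cells"] = cel,
                      _["ant_x"] = ax, _["ant_y"] = ay,
                      _["carrying"] = car);
}

// [[Rcpp::export]]
List cpp_force_drop(int side, IntegerVector occupancy, IntegerMatrix cells,
                    IntegerVector ant_x, IntegerVector ant_y,
                    IntegerVector carrying) {
  IntegerVector occ = clone(occupancy);
  IntegerMatrix cel = clone(cells);
  IntegerVector car = clone(carrying);
  for (int a = 0; a < car.size(); ++a) {
    if (car[a] < 0) continue;
    int x, y;
    if (!nearest_empty(occ, side, ant_x[a], ant_y[a], x, y, true))
      stop("no empty cell available for forced drop");
    occ[x + y * side] = car[a];
    cel(car[a], 0) = x;
    cel(car[a], 1) = y;
    car[a] = -1;
  }
  return List::create(_["occupancy"] = occ, _["cells"] = cel,
                      _["carrying"] = car);
}
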