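#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

// Overlapping-spheres mechanics. Cells are rigid 10-um-diameter spheres.
// Contact at centre distance 10 um (sum of radii); repulsion proportional to
// overlap; bond attraction while the surface gap is in (0, 5] um; one-sided
// spring walls and floor. Damped relaxation: each sweep sums forces and moves
// every cell by mobility * force, until the largest per-cell displacement
// drops below tol or max_sweeps is reached.

static const double RADIUS = 5.0;
static const double CONTACT = 2.0 * RADIUS;

struct Grid {
  double cs, x0, y0, z0;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  Grid(const std::vector<double> &x, const std::vector<double> &y,
       const std::vector<double> &z, double cutoff) {
    const int n = (int)x.size();
    cs = cutoff;
    x0 = y0 = z0 = 0.0;
    double x1 = 1, y1 = 1, z1 = 1;
    if (n > 0) {
      x0 = x1 = x[0]; y0 = y1 = y[0]; z0 = z1 = z[0];
      for (int i = 1; i < n; i++) {
        x0 = std::min(x0, x[i]); x1 = std::max(x1, x[i]);
        y0 = std::min(y0, y[i]); y1 = std::max(y1, y[i]);
        z0 = std::min(z0, z[i]); z1 = std::max(z1, z[i]);
      }
    }
    nx = std::max(1, (int)((x1 - x0) / cs) + 1);
    ny = std::max(1, (int)((y1 - y0) / cs) + 1);
    nz = std::max(1, (int)((z1 - z0) / cs) + 1);
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int i = 0; i < n; i++) cells[index(x[i], y[i], z[i])].push_back(i);
  }
  size_t index(double x, double y, double z) const {
    int ix = std::min(nx - 1, std::max(0, (int)((x - x0) / cs)));
    int iy = std::min(ny - 1, std::max(0, (int)((y - y0) / cs)));
    int iz = std::min(nz - 1, std::max(0, (int)((z - z0) / cs)));
    return ((size_t)iz * ny + iy) * nx + ix;
  }
  template <class F> void for_pairs(F f) const {
    for (int iz = 0; iz < nz; iz++)
      for (int iy = 0; iy < ny; iy++)
        for (int ix = 0; ix < nx; ix++) {
          const std::vector<int> &a = cells[((size_t)iz * ny + iy) * nx + ix];
          if (a.empty()) continue;
          for (int dz = 0; dz <= 1; dz++)
            for (int dy = (dz == 0 ? 0 : -1); dy <= 1; dy++)
              for (int dx = (dz == 0 && dy == 0 ? 0 : -1); dx <= 1; dx++) {
                int jx = ix + dx, jy = iy + dy, jz = iz + dz;
                if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz >= nz) continue;
                const std::vector<int> &b =
                    cells[((size_t)jz * ny + jy) * nx + jx];
                bool same = (dx == 0 && dy == 0 && dz == 0);
                for (size_t u = 0; u < a.size(); u++) {
                  size_t v0 = same ? u + 1 : 0;
                  for (size_t v = v0; v < b.size(); v++) f(a[u], b[v]);
                }
              }
        }
  }
};

// All unordered pairs with centre distance <= cutoff. Returns a 3-column
// matrix (i, j, d) with 1-based indices.
// [[Rcpp::export]]
NumericMatrix neighbor_pairs_cpp(NumericVector x, NumericVector y,
                                 NumericVector z, double cutoff) {
  const int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end()),
      vz(z.begin(), z.end());
  std::vector<double> oi, oj, od;
  if (n > 1) {
    Grid g(vx, vy, vz, cutoff);
    const double c2 = cutoff * cutoff;
    g.for_pairs([&](int i, int j) {
      double dx = vx[i] - vx[j], dy = vy[i] - vy[j], dz = vz[i] - vz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        oi.push_back(i + 1);
        oj.push_back(j + 1);
        od.push_back(std::sqrt(d2));
      }
    });
  }
  NumericMatrix out((int)oi.size(), 3);
  for (size_t k = 0; k < oi.size(); k++) {
    out(k, 0) = oi[k]; out(k, 1) = oj[k]; out(k, 2) = od[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "d");
  return out;
}

// For each row of (ax, ay, az), distance to the nearest point in (bx, by, bz).
// Inf when the second set is empty.
// [[Rcpp::export]]
NumericVector nearest_dist_cpp(NumericVector ax, NumericVector ay,
                               NumericVector az, NumericVector bx,
                               NumericVector by, NumericVector bz) {
  const int na = ax.size(), nb = bx.size();
  NumericVector out(na, R_PosInf);
  for (int i = 0; i < na; i++) {
    double best = R_PosInf;
    for (int j = 0; j < nb; j++) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j], dz = az[i] - bz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
List resolve_cpp(NumericMatrix pos, NumericVector ccb, NumericVector csb,
                 NumericVector anchor, double k_rep, double k_att,
                 double mobility, double tol, int max_sweeps,
                 double bond_range, double k_settle, double lx, double ly,
                 double wall_height, int seed, bool trace) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  const double cutoff = CONTACT + bond_range;
  const double pad = 3.0;  // Verlet-list skin; rebuild when drift > pad/2
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<char> supported(n);
  std::vector<double> overlap_trace;
  std::vector<int> li, lj;
  double drift = pad;  // force an initial build
  int sweep = 0;
  bool converged = (n == 0);
  double max_overlap = 0.0;
  double e_hist[10];
  for (int k = 0; k < 10; k++) e_hist[k] = -1.0;
  for (sweep = 0; sweep < max_sweeps && n > 0; sweep++) {
    if (2.0 * drift > pad) {
      li.clear(); lj.clear();
      Grid g(x, y, z, cutoff + pad);
      const double b2 = (cutoff + pad) * (cutoff + pad);
      g.for_pairs([&](int i, int j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz <= b2) { li.push_back(i); lj.push_back(j); }
      });
      drift = 0.0;
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(supported.begin(), supported.end(), 0);
    max_overlap = 0.0;
    double energy = 0.0;
    const double c2 = cutoff * cutoff;
    for (size_t k = 0; k < li.size(); k++) {
      const int i = li[k], j = lj[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > c2) continue;
      double d = std::sqrt(d2);
      double ux, uy, uz;
      if (d < 1e-9) {  // coincident centres: seeded random separation axis
        double rx = unif(rng), ry = unif(rng), rz = unif(rng);
        double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (rn < 1e-12) { rx = 1; ry = 0; rz = 0; rn = 1; }
        ux = rx / rn; uy = ry / rn; uz = rz / rn;
        d = 0.0;
      } else {
        ux = dx / d; uy = dy / d; uz = dz / d;
      }
      double f = 0.0;
      if (d < CONTACT) {
        double ov = CONTACT - d;
        if (ov > max_overlap) max_overlap = ov;
        energy += ov * ov;
        f = k_rep * ov;                       // push i away from j
      } else {
        double gap = d - CONTACT;
        if (gap > 0 && gap <= bond_range) {
          double cb = 0.5 * (ccb[i] + ccb[j]);
          f = -k_att * cb * gap / bond_range; // pull i toward j
        }
      }
      fx[i] += f * ux; fy[i] += f * uy; fz[i] += f * uz;
      fx[j] -= f * ux; fy[j] -= f * uy; fz[j] -= f * uz;
      // a neighbour clearly below within interaction range counts as
      // support (bond cohesion handles the final approach)
      if (z[i] - z[j] > 2.5) supported[i] = 1;
      if (z[j] - z[i] > 2.5) supported[j] = 1;
    }
    bool any_settle = false;
    for (int i = 0; i < n; i++) {
      // floor: hard below z = RADIUS, substrate bond just above it
      double bottom = z[i] - RADIUS;
      if (bottom < 0) {
        fz[i] += k_rep * (-bottom);
      } else if (bottom <= bond_range) {
        fz[i] -= k_att * csb[i] * anchor[i] * bottom / bond_range;
      } else if (!supported[i]) {
        fz[i] -= k_settle;  // unsupported cells settle toward support
        any_settle = true;
      }
      // walls as one-sided springs keeping whole sphere in the column
      if (x[i] < RADIUS) fx[i] += k_rep * (RADIUS - x[i]);
      if (x[i] > lx - RADIUS) fx[i] -= k_rep * (x[i] - (lx - RADIUS));
      if (y[i] < RADIUS) fy[i] += k_rep * (RADIUS - y[i]);
      if (y[i] > ly - RADIUS) fy[i] -= k_rep * (y[i] - (ly - RADIUS));
      if (z[i] > wall_height - RADIUS)
        fz[i] -= k_rep * (z[i] - (wall_height - RADIUS));
    }
    double max_disp = 0.0;
    for (int i = 0; i < n; i++) {
      double sx = mobility * fx[i], sy = mobility * fy[i], sz = mobility * fz[i];
      x[i] += sx; y[i] += sy; z[i] += sz;
      // hard projection: centres stay inside the walled column even under
      // compressive load that the one-sided springs cannot balance
      if (x[i] < RADIUS) x[i] = RADIUS;
      if (x[i] > lx - RADIUS) x[i] = lx - RADIUS;
      if (y[i] < RADIUS) y[i] = RADIUS;
      if (y[i] > ly - RADIUS) y[i] = ly - RADIUS;
      if (z[i] < RADIUS) z[i] = RADIUS;
      if (z[i] > wall_height - RADIUS) z[i] = wall_height - RADIUS;
      double disp = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (disp > max_disp) max_disp = disp;
    }
    drift += max_disp;
    if (trace) {
      // residual overlap energy (sum of squared overlaps) after the move
      double en = 0.0;
      Grid g2(x, y, z, CONTACT);
      g2.for_pairs([&](int i, int j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < CONTACT) en += (CONTACT - d) * (CONTACT - d);
      });
      overlap_trace.push_back(en);
    }
    if (max_disp < tol) { converged = true; sweep++; break; }
    // stagnation exit: in a jammed force balance the relaxation oscillates
    // and the overlap energy stops improving long before the displacement
    // criterion can fire; compare against the energy ten sweeps back
    // (settling cells suppress the exit so they keep falling)
    double e_old = e_hist[sweep % 10];
    e_hist[sweep % 10] = energy;
    if (!any_settle && sweep >= 40 && e_old >= 0.0 &&
        std::fabs(e_old - energy) <= 1e-2 * std::max(energy, 1e-12)) {
      sweep++;
      break;
    }
  }
  // final residual overlap
  max_overlap = 0.0;
  if (n > 1) {
    Grid g(x, y, z, CONTACT);
    g.for_pairs([&](int i, int j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < CONTACT) max_overlap = std::max(max_overlap, CONTACT - d);
    });
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return List::create(_["pos"] = out, _["sweeps"] = sweep,
                      _["converged"] = converged,
                      _["max_overlap"] = max_overlap,
                      _["overlap_trace"] = NumericVector(overlap_trace.begin(),
                                                         overlap_trace.end()));
}
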