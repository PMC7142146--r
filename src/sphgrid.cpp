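// Scattered-to-regular interpolation of a radial surface function on the
// sphere. Mesh vertices give samples r(direction); the kernel evaluates the
// radius on an N x N equiangular grid (theta_i = pi*(i+0.5)/N, phi_j =
// 2*pi*j/N) by local weighted linear least squares in the tangent plane of
// each grid direction (gnomonic projection), using the k nearest vertex
// directions. The angular metric is computed from 3D dot products, so the
// scheme is pole-safe and rotation-symmetric; it is exact for constant
// radii and second-order accurate for smooth radial functions.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Candidate {
  int idx;
  double ang;
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix sph_grid_interp_cpp(NumericMatrix dirs, NumericVector radii,
                                  int grid_size, int k_neighbors) {
  int n = dirs.nrow();
  int N = grid_size;
  if (n < 3) stop("need at least 3 vertex directions");
  const double* dx = &dirs(0, 0);
  const double* dy = &dirs(0, 1);
  const double* dz = &dirs(0, 2);

  // bin vertices on a coarse (theta, phi) raster
  int Bt = std::max(4, std::min(64, (int)std::floor(std::sqrt(n / 8.0))));
  int Bp = 2 * Bt;
  // irrational bin offset: keeps vertices of symmetric meshes (axis-aligned
  // azimuths like pi/2) safely inside a bin, so that infinitesimal input
  // perturbations cannot flip bin membership and change neighbour pools
  const double OFF = 0.218281828;
  std::vector<std::vector<int>> bins((size_t)Bt * Bp);
  for (int i = 0; i < n; ++i) {
    double th = std::acos(std::max(-1.0, std::min(1.0, dz[i])));
    double ph = std::atan2(dy[i], dx[i]);
    if (ph < 0) ph += 2.0 * M_PI;
    int bt = std::min(Bt - 1, (int)(th / M_PI * Bt));
    int bp = ((int)std::floor(ph / (2.0 * M_PI) * Bp + OFF)) % Bp;
    bins[(size_t)bt * Bp + bp].push_back(i);
  }

  NumericMatrix out(N, N);
  std::vector<Candidate> cand;
  int kmin = std::min(k_neighbors, n);

  for (int gi = 0; gi < N; ++gi) {
    double th = M_PI * (gi + 0.5) / N;
    double st = std::sin(th), ct = std::cos(th);
    int bt0 = std::min(Bt - 1, (int)(th / M_PI * Bt));
    for (int gj = 0; gj < N; ++gj) {
      double ph = 2.0 * M_PI * gj / N;
      double gx = st * std::cos(ph), gy = st * std::sin(ph), gz = ct;
      int bp0 = ((int)std::floor(ph / (2.0 * M_PI) * Bp + OFF)) % Bp;

      // expanding ring search over bins; one extra ring once enough found.
      // The polar bin rows (bt = 0 and Bt - 1) are scanned as whole caps:
      // the azimuth of near-polar directions is numerically meaningless, so
      // assigning/searching them by phi bin would be unstable.
      cand.clear();
      bool cap_done[2] = {false, false};
      int maxring = std::max(Bt, Bp);
      auto add_bin = [&](int bt, int bp) {
        for (int idx : bins[(size_t)bt * Bp + bp]) {
          double dp = gx * dx[idx] + gy * dy[idx] + gz * dz[idx];
          dp = std::max(-1.0, std::min(1.0, dp));
          cand.push_back({idx, std::acos(dp)});
        }
      };
      for (int ring = 0, extra = -1; ring <= maxring; ++ring) {
        for (int bt = bt0 - ring; bt <= bt0 + ring; ++bt) {
          if (bt < 0 || bt >= Bt) continue;
          if (bt == 0 || bt == Bt - 1) {
            bool& done = cap_done[bt == 0 ? 0 : 1];
            if (!done) {
              for (int bp = 0; bp < Bp; ++bp) add_bin(bt, bp);
              done = true;
            }
            continue;
          }
          for (int dbp = -ring; dbp <= ring; ++dbp) {
            if (std::abs(bt - bt0) != ring && std::abs(dbp) != ring) continue;
            int bp = ((bp0 + dbp) % Bp + Bp) % Bp;
            add_bin(bt, bp);
          }
        }
        if ((int)cand.size() >= kmin) {
          if (extra < 0) extra = ring + 1;      // schedule one extra ring
          if (ring >= extra) break;
        }
      }

      int k = std::min((int)cand.size(), kmin);
      std::sort(cand.begin(), cand.end(),
                [](const Candidate& a, const Candidate& b) {
                  return a.ang < b.ang;
                });
      double angmax = cand[k - 1].ang;
      double h0 = std::max(angmax, 1e-6);
      // tie-inclusive cutoff: candidates at (numerically) the same angle as
      // the k-th neighbour all enter the fit, so the result is stable when
      // symmetric vertex pairs are equidistant from a grid direction
      while (k < (int)cand.size() && cand[k].ang <= angmax + 1e-9) ++k;

      // tangent basis at the grid direction
      double hx, hy, hz;
      if (std::fabs(gz) < 0.9) { hx = 0; hy = 0; hz = 1; }
      else { hx = 1; hy = 0; hz = 0; }
      double e1x = hy * gz - hz * gy, e1y = hz * gx - hx * gz,
             e1z = hx * gy - hy * gx;
      double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= e1n; e1y /= e1n; e1z /= e1n;
      double e2x = gy * e1z - gz * e1y, e2y = gz * e1x - gx * e1z,
             e2z = gx * e1y - gy * e1x;

      // weighted least squares r ~ a + b*u + c*v (gnomonic u, v)
      double A[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      double rhs[3] = {0, 0, 0};
      double wsum = 0.0, wrsum = 0.0;
      int used = 0;
      for (int m = 0; m < k; ++m) {
        int idx = cand[m].idx;
        double dot = gx * dx[idx] + gy * dy[idx] + gz * dz[idx];
        if (dot < 0.2) continue;  // > ~78 deg away: unusable in this chart
        double u = (dx[idx] * e1x + dy[idx] * e1y + dz[idx] * e1z) / dot;
        double v = (dx[idx] * e2x + dy[idx] * e2y + dz[idx] * e2z) / dot;
        double w = std::exp(-(cand[m].ang * cand[m].ang) / (h0 * h0));
        double r = radii[idx];
        A[0] += w;         A[1] += w * u;     A[2] += w * v;
        A[4] += w * u * u; A[5] += w * u * v; A[8] += w * v * v;
        rhs[0] += w * r; rhs[1] += w * u * r; rhs[2] += w * v * r;
        wsum += w; wrsum += w * r;
        ++used;
      }
      double value;
      if (used >= 3) {
        A[3] = A[1]; A[6] = A[2]; A[7] = A[5];
        double lam = 1e-10 * (A[0] + A[4] + A[8]);
        A[0] += lam; A[4] += lam; A[8] += lam;
        // solve 3x3 by Cramer
        double det = A[0] * (A[4] * A[8] - A[5] * A[7]) -
                     A[1] * (A[3] * A[8] - A[5] * A[6]) +
                     A[2] * (A[3] * A[7] - A[4] * A[6]);
        if (std::fabs(det) > 1e-14 * (A[0] * A[4] * A[8] + 1e-300)) {
          double a = (rhs[0] * (A[4] * A[8] - A[5] * A[7]) -
                      A[1] * (rhs[1] * A[8] - A[5] * rhs[2]) +
                      A[2] * (rhs[1] * A[7] - A[4] * rhs[2])) / det;
          value = a;
        } else {
          value = wrsum / wsum;  // degenerate design: weighted mean
        }
      } else if (wsum > 0) {
        value = wrsum / wsum;
      } else {
        value = radii[cand[0].idx];  // nearest-neighbour fallback
      }
      out(gi, gj) = value;
    }
  }
  return out;
}
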