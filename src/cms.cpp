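// Lattice Monte-Carlo cell-migration kernel.
//
// A cell is a set of occupied integer lattice sites (spatial units, SU).
// Each iteration moves exactly one SU from the rear surface to a free site
// at the front, chosen by acceptance-rejection sampling on the scores
//   S_r = |P|^pw * (6 - N)^nw * D^dw   (rear, removal)
//   S_f = |P|^pw * N^nw                (front, insertion)
// where P is the relative position along the migration axis, N the number
// of occupied 6-neighbours and D the distance to the centre of mass.
//
// Occupancy is kept in a dense re-centred grid so neighbour lookups are O(1)
// regardless of how far the cell drifts.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct Coord {
  int x, y, z;
};

class DenseGrid {
 public:
  // pos grid: -1 empty, otherwise index into the cell list
  std::vector<int> pos;
  int ox, oy, oz, nx, ny, nz;

  void rebuild(const std::vector<Coord>& cells, int margin) {
    int lo[3] = {cells[0].x, cells[0].y, cells[0].z};
    int hi[3] = {cells[0].x, cells[0].y, cells[0].z};
    for (const Coord& c : cells) {
      lo[0] = std::min(lo[0], c.x); hi[0] = std::max(hi[0], c.x);
      lo[1] = std::min(lo[1], c.y); hi[1] = std::max(hi[1], c.y);
      lo[2] = std::min(lo[2], c.z); hi[2] = std::max(hi[2], c.z);
    }
    ox = lo[0] - margin; oy = lo[1] - margin; oz = lo[2] - margin;
    nx = hi[0] - lo[0] + 2 * margin + 1;
    ny = hi[1] - lo[1] + 2 * margin + 1;
    nz = hi[2] - lo[2] + 2 * margin + 1;
    pos.assign((size_t)nx * ny * nz, -1);
    for (size_t i = 0; i < cells.size(); ++i)
      pos[idx(cells[i].x, cells[i].y, cells[i].z)] = (int)i;
  }

  inline size_t idx(int x, int y, int z) const {
    return ((size_t)(x - ox) * ny + (size_t)(y - oy)) * nz + (size_t)(z - oz);
  }
  inline bool inside(int x, int y, int z, int slack) const {
    return x - ox >= slack && y - oy >= slack && z - oz >= slack &&
           ox + nx - 1 - x >= slack && oy + ny - 1 - y >= slack &&
           oz + nz - 1 - z >= slack;
  }
  inline int at(int x, int y, int z) const { return pos[idx(x, y, z)]; }
};

const int NB[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                      {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};

inline double rel_pos(double x, double y, double z, const double com[3],
                      const double vD[3]) {
  double vx = x - com[0], vy = y - com[1], vz = z - com[2];
  double n = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (n == 0.0) return 0.0;
  return (vx * vD[0] + vy * vD[1] + vz * vD[2]) / n;
}

// Uniform draw from 0..(k-1) using R's RNG
inline int runif_int(int k) {
  int i;
  do {
    i = (int)std::floor(unif_rand() * k);
  } while (i >= k);  // guards against unif_rand() == 1.0
  return i;
}

// Acceptance-rejection draw: uniform candidate, accept with prob S/Smax.
// If all scores are zero the draw degenerates to uniform.
inline int accept_reject(const std::vector<double>& s) {
  double smax = 0.0;
  for (double v : s) smax = std::max(smax, v);
  int k = (int)s.size();
  if (smax <= 0.0) return runif_int(k);
  for (;;) {
    int i = runif_int(k);
    if (unif_rand() * smax <= s[i]) return i;
  }
}

}  // namespace

// Run the simulator for `n_iter` iterations from the given state, saving
// occupancy snapshots after the iterations listed in `save_at` (1-based
// offsets into this run, strictly increasing). Returns the snapshots, the
// final state and the last move.
// [[Rcpp::export]]
List cms_run_cpp(IntegerMatrix occ, NumericVector com0, NumericVector vD0,
                 double fr, double nw, double pw, double dw, int n_iter,
                 IntegerVector save_at) {
  int n = occ.nrow();
  if (n < 1) stop("empty occupancy");
  std::vector<Coord> cells(n);
  for (int i = 0; i < n; ++i) cells[i] = {occ(i, 0), occ(i, 1), occ(i, 2)};
  double com[3] = {com0[0], com0[1], com0[2]};
  double vD[3] = {vD0[0], vD0[1], vD0[2]};

  DenseGrid g;
  const int margin = 40;
  g.rebuild(cells, margin);

  std::vector<int> rear_idx;           // indices into cells
  std::vector<double> rear_score;
  std::vector<Coord> front_sites;
  std::vector<double> front_score;
  std::vector<size_t> front_seen;      // dense indices to clear the seen mask
  std::vector<uint8_t> seen(g.pos.size(), 0);

  List frames;
  int save_ptr = 0;
  int last_rem[3] = {0, 0, 0}, last_add[3] = {0, 0, 0};

  for (int iter = 1; iter <= n_iter; ++iter) {
    rear_idx.clear(); rear_score.clear();
    front_sites.clear(); front_score.clear();
    if (seen.size() != g.pos.size()) seen.assign(g.pos.size(), 0);
    for (size_t s : front_seen) seen[s] = 0;
    front_seen.clear();

    // scan occupancy: rear candidates and free front sites
    for (int i = 0; i < n; ++i) {
      const Coord& c = cells[i];
      int nocc = 0;
      for (int k = 0; k < 6; ++k) {
        int xx = c.x + NB[k][0], yy = c.y + NB[k][1], zz = c.z + NB[k][2];
        if (g.at(xx, yy, zz) >= 0) {
          ++nocc;
        } else {
          size_t di = g.idx(xx, yy, zz);
          if (!seen[di]) {
            seen[di] = 1;
            front_seen.push_back(di);
            double p = rel_pos(xx, yy, zz, com, vD);
            if (p > fr) {
              // count occupied neighbours of the free site
              int nf = 0;
              for (int k2 = 0; k2 < 6; ++k2)
                if (g.at(xx + NB[k2][0], yy + NB[k2][1], zz + NB[k2][2]) >= 0)
                  ++nf;
              front_sites.push_back({xx, yy, zz});
              front_score.push_back(std::pow(std::fabs(p), pw) *
                                    std::pow((double)nf, nw));
            }
          }
        }
      }
      if (nocc < 6) {  // surface SU
        double p = rel_pos(c.x, c.y, c.z, com, vD);
        if (p <= fr) {
          double dx = c.x - com[0], dy = c.y - com[1], dz = c.z - com[2];
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          rear_idx.push_back(i);
          rear_score.push_back(std::pow(std::fabs(p), pw) *
                               std::pow(6.0 - nocc, nw) * std::pow(d, dw));
        }
      }
    }

    if (rear_idx.empty())
      stop("simulation stalled at iteration %d: no rear-surface candidates (all surface sites have P > FR)", iter);
    if (front_sites.empty())
      stop("simulation stalled at iteration %d: no free front sites (all adjacent free sites have P <= FR)", iter);

    int ri = rear_idx[accept_reject(rear_score)];
    Coord add = front_sites[accept_reject(front_score)];
    Coord rem = cells[ri];

    // move SU: swap-remove from list, insert the front site
    g.pos[g.idx(rem.x, rem.y, rem.z)] = -1;
    cells[ri] = add;
    g.pos[g.idx(add.x, add.y, add.z)] = ri;
    com[0] += (add.x - rem.x) / (double)n;
    com[1] += (add.y - rem.y) / (double)n;
    com[2] += (add.z - rem.z) / (double)n;
    last_rem[0] = rem.x; last_rem[1] = rem.y; last_rem[2] = rem.z;
    last_add[0] = add.x; last_add[1] = add.y; last_add[2] = add.z;

    // re-centre the dense grid if the cell gets near its border
    if (!g.inside(add.x, add.y, add.z, 3)) {
      g.rebuild(cells, margin);
      seen.assign(g.pos.size(), 0);
      front_seen.clear();
    }

    if (save_ptr < save_at.size() && iter == save_at[save_ptr]) {
      IntegerMatrix snap(n, 3);
      for (int i = 0; i < n; ++i) {
        snap(i, 0) = cells[i].x;
        snap(i, 1) = cells[i].y;
        snap(i, 2) = cells[i].z;
      }
      frames.push_back(snap);
      ++save_ptr;
    }
    if ((iter & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix occ_out(n, 3);
  for (int i = 0; i < n; ++i) {
    occ_out(i, 0) = cells[i].x;
    occ_out(i, 1) = cells[i].y;
    occ_out(i, 2) = cells[i].z;
  }
  return List::create(
      _["frames"] = frames,
      _["occupancy"] = occ_out,
      _["center_of_mass"] = NumericVector::create(com[0], com[1], com[2]),
      _["last_removed"] = IntegerVector::create(last_rem[0], last_rem[1], last_rem[2]),
      _["last_added"] = IntegerVector::create(last_add[0], last_add[1], last_add[2]));
}
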