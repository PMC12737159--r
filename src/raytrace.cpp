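#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <limits>
using namespace Rcpp;

// Regular 1-mm-class voxel grid; lo = coordinate of the low corner.
struct Grid {
  double lo[3];
  int n[3];
  double vox;
};

static const double INF_T = std::numeric_limits<double>::infinity();

// Amanatides-Woo traversal of segment A->B clipped to the grid.
// Appends (1-based column-major linear voxel index, chord length in mm).
static void trace_segment(const double *A, const double *B, const Grid &g,
                          std::vector<int> &out_idx, std::vector<double> &out_len) {
  double d[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return;

  double t0 = 0.0, t1 = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    double hi = g.lo[ax] + g.n[ax] * g.vox;
    if (std::fabs(d[ax]) < 1e-12) {
      if (A[ax] <= g.lo[ax] || A[ax] >= hi) return;
    } else {
      double ta = (g.lo[ax] - A[ax]) / d[ax];
      double tb = (hi - A[ax]) / d[ax];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return;

  // Voxel of entry, probed slightly inside to dodge boundary ambiguity.
  double tm = t0 + (t1 - t0) * 1e-9;
  int ijk[3], stp[3];
  double tMax[3], tDelta[3];
  for (int ax = 0; ax < 3; ++ax) {
    double p = A[ax] + tm * d[ax];
    int i = (int)std::floor((p - g.lo[ax]) / g.vox);
    if (i < 0) i = 0;
    if (i >= g.n[ax]) i = g.n[ax] - 1;
    ijk[ax] = i;
    if (std::fabs(d[ax]) < 1e-12) {
      stp[ax] = 0; tMax[ax] = INF_T; tDelta[ax] = INF_T;
    } else {
      stp[ax] = d[ax] > 0 ? 1 : -1;
      int next = d[ax] > 0 ? i + 1 : i;
      tMax[ax] = (g.lo[ax] + next * g.vox - A[ax]) / d[ax];
      tDelta[ax] = g.vox / std::fabs(d[ax]);
    }
  }

  double tcur = t0;
  while (true) {
    double tnext = t1;
    if (tMax[0] < tnext) tnext = tMax[0];
    if (tMax[1] < tnext) tnext = tMax[1];
    if (tMax[2] < tnext) tnext = tMax[2];
    double seg = (tnext - tcur) * L;
    if (seg > 0.0) {
      out_idx.push_back(ijk[0] + g.n[0] * (ijk[1] + g.n[1] * ijk[2]) + 1);
      out_len.push_back(seg);
    }
    if (tnext >= t1) break;
    bool exited = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (tMax[ax] <= tnext + 1e-15) {
        ijk[ax] += stp[ax];
        tMax[ax] += tDelta[ax];
        if (ijk[ax] < 0 || ijk[ax] >= g.n[ax]) exited = true;
      }
    }
    tcur = tnext;
    if (exited) break;
  }
}

static Grid make_grid(NumericVector lo, IntegerVector dims, double vox) {
  Grid g;
  for (int ax = 0; ax < 3; ++ax) {
    g.lo[ax] = lo[ax];
    g.n[ax] = dims[ax];
  }
  g.vox = vox;
  return g;
}

// [[Rcpp::export]]
List cpp_siddon(NumericVector p1, NumericVector p2, NumericVector lo,
                IntegerVector dims, double vox) {
  Grid g = make_grid(lo, dims, vox);
  std::vector<int> idx;
  std::vector<double> len;
  double A[3] = {p1[0], p1[1], p1[2]};
  double B[3] = {p2[0], p2[1], p2[2]};
  trace_segment(A, B, g, idx, len);
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len));
}

// Accumulate Siddon weights of (optionally Bernoulli-thinned) crystal-pair LORs.
// cryst: (total crystals) x 3 positions, panel-major; offsets: start row (0-based)
// of each panel's block; per_panel: crystals per panel; pairs: m x 2 panel ids;
// tangent: n_panels x 3 in-plane tangential unit vectors. With jitter_mm > 0
// each endpoint is displaced uniformly within its crystal face (tangential and
// axial), integrating the system response over the face instead of sampling it
// at the center - this suppresses crystal-grid aliasing in the denominator.
// [[Rcpp::export]]
NumericVector cpp_sensitivity(NumericMatrix cryst, IntegerVector offsets,
                              int per_panel, IntegerMatrix pairs,
                              NumericMatrix tangent, double jitter_mm,
                              int n_rays, NumericVector lo, IntegerVector dims,
                              double vox, double keep_prob, int seed) {
  Grid g = make_grid(lo, dims, vox);
  int nvox = g.n[0] * g.n[1] * g.n[2];
  NumericVector sens(nvox);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_real_distribution<double> jit(-0.5 * jitter_mm, 0.5 * jitter_mm);
  std::vector<int> idx;
  std::vector<double> len;
  idx.reserve(256);
  len.reserve(256);
  bool thin = keep_prob < 1.0;
  bool jitter = jitter_mm > 0.0;
  if (!jitter || n_rays < 1) n_rays = 1;
  double wray = 1.0 / n_rays;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int pa = pairs(p, 0), pb = pairs(p, 1);
    int oa = offsets[pa], ob = offsets[pb];
    double ta[3] = {tangent(pa, 0), tangent(pa, 1), tangent(pa, 2)};
    double tb[3] = {tangent(pb, 0), tangent(pb, 1), tangent(pb, 2)};
    for (int a = 0; a < per_panel; ++a) {
      for (int b = 0; b < per_panel; ++b) {
        if (thin && unif(rng) >= keep_prob) continue;
        for (int rr = 0; rr < n_rays; ++rr) {
          double A[3] = {cryst(oa + a, 0), cryst(oa + a, 1), cryst(oa + a, 2)};
          double B[3] = {cryst(ob + b, 0), cryst(ob + b, 1), cryst(ob + b, 2)};
          if (jitter) {
            double ua = jit(rng), va = jit(rng);
            double ub = jit(rng), vb = jit(rng);
            for (int ax = 0; ax < 3; ++ax) {
              A[ax] += ua * ta[ax];
              B[ax] += ub * tb[ax];
            }
            A[2] += va;
            B[2] += vb;
          }
          idx.clear();
          len.clear();
          trace_segment(A, B, g, idx, len);
          for (size_t k = 0; k < idx.size(); ++k)
            sens[idx[k] - 1] += len[k] * wray;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return sens;
}

// List-mode MLEM. pa, pb: event LOR endpoints (E x 3). sens: voxel sensitivity.
// With jitter_mm > 0, endpoints are displaced uniformly within their crystal
// faces (panel_a/panel_b give the panels, tangent the in-plane face axes)
// when the event rows are built, matching the face-integrated system model of
// the sensitivity image. Rows are restricted to voxels with positive
// sensitivity; events with empty rows are dropped (counted). Returns image,
// per-iteration log-likelihood of the pre-update iterate, and accounting.
// [[Rcpp::export]]
List cpp_mlem(NumericMatrix pa, NumericMatrix pb, IntegerVector panel_a,
              IntegerVector panel_b, NumericMatrix tangent, double jitter_mm,
              int n_rays, NumericVector lo, IntegerVector dims, double vox,
              int n_iter, NumericVector sens, int seed) {
  Grid g = make_grid(lo, dims, vox);
  int nvox = g.n[0] * g.n[1] * g.n[2];
  int nev = pa.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> jit(-0.5 * jitter_mm, 0.5 * jitter_mm);
  bool jitter = jitter_mm > 0.0;
  if (!jitter || n_rays < 1) n_rays = 1;

  std::vector<int> row_idx;
  std::vector<double> row_len;
  std::vector<size_t> row_ptr;
  row_ptr.push_back(0);
  std::vector<int> idx;
  std::vector<double> len;
  double wray = 1.0 / n_rays;
  int dropped = 0;
  for (int e = 0; e < nev; ++e) {
    size_t kept = 0;
    for (int rr = 0; rr < n_rays; ++rr) {
      double A[3] = {pa(e, 0), pa(e, 1), pa(e, 2)};
      double B[3] = {pb(e, 0), pb(e, 1), pb(e, 2)};
      if (jitter) {
        int qa = panel_a[e], qb = panel_b[e];
        double ua = jit(rng), va = jit(rng), ub = jit(rng), vb = jit(rng);
        for (int ax = 0; ax < 3; ++ax) {
          A[ax] += ua * tangent(qa, ax);
          B[ax] += ub * tangent(qb, ax);
        }
        A[2] += va;
        B[2] += vb;
      }
      idx.clear();
      len.clear();
      trace_segment(A, B, g, idx, len);
      for (size_t k = 0; k < idx.size(); ++k) {
        if (sens[idx[k] - 1] > 0.0) {
          row_idx.push_back(idx[k] - 1);
          row_len.push_back(len[k] * wray);
          ++kept;
        }
      }
    }
    if (kept == 0) ++dropped;
    row_ptr.push_back(row_idx.size());
  }

  NumericVector x(nvox);
  for (int j = 0; j < nvox; ++j) x[j] = sens[j] > 0.0 ? 1.0 : 0.0;
  NumericVector loglik(n_iter);
  std::vector<double> back(nvox);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(back.begin(), back.end(), 0.0);
    double ll = 0.0;
    for (int e = 0; e < nev; ++e) {
      size_t a = row_ptr[e], b = row_ptr[e + 1];
      if (a == b) continue;
      double fwd = 0.0;
      for (size_t k = a; k < b; ++k) fwd += row_len[k] * x[row_idx[k]];
      if (fwd <= 0.0) continue;
      ll += std::log(fwd);
      double w = 1.0 / fwd;
      for (size_t k = a; k < b; ++k) back[row_idx[k]] += row_len[k] * w;
    }
    double sx = 0.0;
    for (int j = 0; j < nvox; ++j) sx += sens[j] * x[j];
    loglik[it] = ll - sx;
    for (int j = 0; j < nvox; ++j)
      if (sens[j] > 0.0) x[j] = x[j] / sens[j] * back[j];
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["image"] = x, _["loglik"] = loglik,
                      _["n_dropped"] = dropped, _["n_events"] = nev);
}

// Non-paralyzable per-panel-pair dead time on a time-sorted singles stream.
// ppair: n_panels x K matrix of 0-based pair ids each panel belongs to
// (-1 padding). Each pair processor accepts coincidence *frames*: a single
// opens a frame if the pair has been idle for >= dead_ns since the last
// frame start (inclusive); singles within window_ns of the last accepted
// single on that pair belong to the open frame and pass without resetting
// the frame clock. A single is kept iff every pair of its panel accepts it;
// kept singles update those pairs' clocks.
// [[Rcpp::export]]
LogicalVector cpp_deadtime(NumericVector t, IntegerVector panel,
                           IntegerMatrix ppair, int n_pairs, double dead_ns,
                           double window_ns) {
  int n = t.size();
  LogicalVector keep(n);
  std::vector<double> frame(n_pairs, -INF_T);  // frame start
  std::vector<double> last(n_pairs, -INF_T);   // last accepted single
  int K = ppair.ncol();
  for (int i = 0; i < n; ++i) {
    int p = panel[i];
    bool ok = true;
    for (int k = 0; k < K; ++k) {
      int pr = ppair(p, k);
      if (pr < 0) continue;
      bool in_frame = t[i] - last[pr] <= window_ns;
      bool idle = t[i] - frame[pr] >= dead_ns;
      if (!in_frame && !idle) { ok = false; break; }
    }
    keep[i] = ok;
    if (ok) {
      for (int k = 0; k < K; ++k) {
        int pr = ppair(p, k);
        if (pr < 0) continue;
        if (t[i] - last[pr] <= window_ns) {
          last[pr] = t[i];               // extend open frame
        } else {
          frame[pr] = t[i];              // open a new frame
          last[pr] = t[i];
        }
      }
    }
  }
  return keep;
}
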