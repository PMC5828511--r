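#include <Rcpp.h>
using namespace Rcpp;

// Fast inner loop for lattice infotaxis. Semantics identical to the R
// reference implementation (belief_update / choose_move / the exploitation
// fallback in run_infotaxis): per decision step
//   1. deterministic observation: hit iff the agent's cell is inside the
//      discretized laminar plume,
//   2. Bayes update of the belief over source cells with the per-step hit
//      probability field (precomputed over displacements; p = 1 at zero
//      displacement, the "found" likelihood),
//   3. early stop when the agent-cell posterior exceeds found_threshold,
//   4. greedy move minimizing expected posterior entropy with tie order
//      stay, -x, +x, -y, +y, -z, +z; when the belief is degenerate (no
//      move offers information gain) the agent instead steps toward the
//      belief mode, axis sampled proportional to the remaining displacement
//      (one uniform draw via R's RNG).
//
// Entropies use precomputed log tables: for posterior w_i = b_i * p_i,
// S = log W - (1/W) sum_i w_i (log b_i + log p_i), W = sum_i w_i.

struct Gather {
  // displacement-array strides for agent cell (ai, aj, ak), 1-based
  int nx, ny, nz, d1, d2;
};

// [[Rcpp::export]]
List run_infotaxis_cpp(IntegerVector start, int n_steps,
                       NumericVector pf, NumericVector lpf,
                       NumericVector l1pf,
                       IntegerVector dims,          // nx, ny, nz
                       LogicalVector in_plume,      // per cell
                       double found_threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncell = nx * ny * nz;
  const int d1 = 2 * nx - 1, d2 = 2 * ny - 1;

  std::vector<double> belief(ncell, 1.0 / ncell);
  std::vector<double> lb(ncell);

  IntegerMatrix path(n_steps + 1, 3);
  LogicalVector hits(n_steps);
  NumericVector entropy(n_steps);

  int ai = start[0], aj = start[1], ak = start[2];
  path(0, 0) = ai; path(0, 1) = aj; path(0, 2) = ak;
  bool found = false;
  int used = n_steps;

  // candidate offsets in tie-break order
  const int OFF[7][3] = {{0, 0, 0}, {-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                         {0, 1, 0}, {0, 0, -1}, {0, 0, 1}};

  for (int s = 0; s < n_steps; ++s) {
    int acell = (ai - 1) + nx * ((aj - 1) + ny * (ak - 1));
    bool hit = in_plume[acell];
    hits[s] = hit;

    // Bayes update at the agent cell
    {
      double W = 0.0;
      for (int c = 0; c < ncell; ++c) {
        int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
        int di = (ai - 1 - ci) + nx - 1;
        int dj = (aj - 1 - cj) + ny - 1;
        int dk = (ak - 1 - ck) + nz - 1;
        double p = pf[di + d1 * (dj + d2 * dk)];
        double w = hit ? belief[c] * p : belief[c] * (1.0 - p);
        belief[c] = w;
        W += w;
      }
      if (W <= 0.0)
        stop("numerically degenerate belief: observation has zero likelihood");
      for (int c = 0; c < ncell; ++c) belief[c] /= W;
    }

    // entropy and log-belief table
    double S = 0.0;
    for (int c = 0; c < ncell; ++c) {
      if (belief[c] > 0.0) {
        lb[c] = std::log(belief[c]);
        S -= belief[c] * lb[c];
      } else lb[c] = 0.0;
    }
    entropy[s] = S;

    acell = (ai - 1) + nx * ((aj - 1) + ny * (ak - 1));
    if (belief[acell] > found_threshold) { found = true; used = s + 1; break; }

    // greedy move: expected posterior entropy per candidate
    double bestE = R_PosInf;
    int bestm = -1;
    double ee[7], pfd[7];
    for (int m = 0; m < 7; ++m) {
      ee[m] = NA_REAL;
      pfd[m] = -1.0;
      int ci = ai + OFF[m][0], cj = aj + OFF[m][1], ck = ak + OFF[m][2];
      if (ci < 1 || ci > nx || cj < 1 || cj > ny || ck < 1 || ck > nz)
        continue;
      double Wh = 0.0, Ah = 0.0, Wm = 0.0, Am = 0.0;
      for (int c = 0; c < ncell; ++c) {
        int si = c % nx, sj = (c / nx) % ny, sk = c / (nx * ny);
        int di = (ci - 1 - si) + nx - 1;
        int dj = (cj - 1 - sj) + ny - 1;
        int dk = (ck - 1 - sk) + nz - 1;
        int off = di + d1 * (dj + d2 * dk);
        double p = pf[off];
        double b = belief[c];
        if (b <= 0.0) continue;
        double wh = b * p;
        if (wh > 0.0) { Wh += wh; Ah += wh * (lb[c] + lpf[off]); }
        double wm = b * (1.0 - p);
        if (wm > 0.0) { Wm += wm; Am += wm * (lb[c] + l1pf[off]); }
      }
      double s_hit = (Wh > 0.0) ? std::log(Wh) - Ah / Wh : 0.0;
      double s_miss = (Wm > 0.0) ? std::log(Wm) - Am / Wm : 0.0;
      int ccell = (ci - 1) + nx * ((cj - 1) + ny * (ck - 1));
      double pfound = belief[ccell];
      double E = (1.0 - pfound) * (Wh * s_hit + Wm * s_miss);
      ee[m] = E;
      pfd[m] = pfound;
      if (E < bestE) { bestE = E; bestm = m; }
    }
    // among candidates tied with the minimum: larger posterior source mass
    // wins, then the fixed preference order
    {
      double bestp = -2.0;
      for (int m = 0; m < 7; ++m) {
        if (!ISNA(ee[m]) && ee[m] <= bestE + 1e-12 && pfd[m] > bestp) {
          bestp = pfd[m]; bestm = m;
        }
      }
    }

    double gain = S - bestE;
    if (bestm == 0 && gain < 1e-10) {
      // degenerate belief: exploitation step toward the belief mode
      int mode = 0;
      double bmax = -1.0;
      for (int c = 0; c < ncell; ++c)
        if (belief[c] > bmax) { bmax = belief[c]; mode = c; }
      int mi = mode % nx + 1, mj = (mode / nx) % ny + 1,
          mk = mode / (nx * ny) + 1;
      double dd[3] = {double(mi - ai), double(mj - aj), double(mk - ak)};
      double tot = std::abs(dd[0]) + std::abs(dd[1]) + std::abs(dd[2]);
      if (tot > 0.0) {
        double u = unif_rand() * tot;
        int ax = 0;
        double acc = std::abs(dd[0]);
        while (ax < 2 && u >= acc) { ++ax; acc += std::abs(dd[ax]); }
        if (ax == 0) ai += (dd[0] > 0) ? 1 : -1;
        else if (ax == 1) aj += (dd[1] > 0) ? 1 : -1;
        else ak += (dd[2] > 0) ? 1 : -1;
      }
    } else {
      ai += OFF[bestm][0]; aj += OFF[bestm][1]; ak += OFF[bestm][2];
    }
    path(s + 1, 0) = ai; path(s + 1, 1) = aj; path(s + 1, 2) = ak;
  }

  return List::create(_["path"] = path, _["hits"] = hits,
                      _["entropy"] = entropy, _["used"] = used,
                      _["found"] = found);
}
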