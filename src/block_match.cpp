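#include <Rcpp.h>
using namespace Rcpp;

// Normalized cross-correlation block matching.
//
// a, b: consecutive frames (matrices, column-major). r0, c0: 0-based
// top-left corners of the square template patches in `a`. ps: patch side
// in pixels. radius: integer search radius in `b`. Shifts whose window
// leaves the frame are skipped (border patches search a restricted
// window). Ties in the NCC maximum break toward the smallest displacement
// magnitude; the integer optimum is refined to sub-pixel precision by
// independent 1-D parabolic fits along each axis.
//
// Returns an n x 5 matrix: dr, dc (px/frame), score (best NCC),
// valid (0/1), var (template variance). Patches whose template variance
// is below var_floor or whose best score is below min_ncc are invalid.
// [[Rcpp::export]]
NumericMatrix ncc_block_match(NumericMatrix a, NumericMatrix b,
                              IntegerVector r0, IntegerVector c0,
                              int ps, int radius,
                              double min_ncc, double var_floor) {
  const int nr = a.nrow(), nc = a.ncol(), n = r0.size();
  const int side = 2 * radius + 1;
  const double npx = (double)ps * ps;
  const double *A = a.begin(), *B = b.begin();
  NumericMatrix out(n, 5);
  std::vector<double> scores(side * side);

  for (int k = 0; k < n; ++k) {
    const int pr = r0[k], pc = c0[k];
    out(k, 3) = 0.0;
    if (pr < 0 || pc < 0 || pr + ps > nr || pc + ps > nc) continue;

    double st = 0.0, st2 = 0.0;
    for (int j = 0; j < ps; ++j) {
      const double *pa = A + (size_t)(pc + j) * nr + pr;
      for (int i = 0; i < ps; ++i) {
        const double v = pa[i];
        st += v; st2 += v * v;
      }
    }
    const double var_t = st2 - st * st / npx;  // n * variance
    out(k, 4) = var_t / npx;
    if (var_t / npx < var_floor || var_t <= 0) continue;

    double best = -2.0; int bu = 0, bv = 0; double bmag = 1e30;
    std::fill(scores.begin(), scores.end(), NA_REAL);

    for (int v = -radius; v <= radius; ++v) {
      for (int u = -radius; u <= radius; ++u) {
        const int qr = pr + u, qc = pc + v;
        if (qr < 0 || qc < 0 || qr + ps > nr || qc + ps > nc) continue;
        double ss = 0.0, ss2 = 0.0, sts = 0.0;
        for (int j = 0; j < ps; ++j) {
          const double *pa = A + (size_t)(pc + j) * nr + pr;
          const double *pb = B + (size_t)(qc + j) * nr + qr;
          for (int i = 0; i < ps; ++i) {
            const double w = pb[i];
            ss += w; ss2 += w * w; sts += pa[i] * w;
          }
        }
        const double var_s = ss2 - ss * ss / npx;
        double score;
        if (var_s <= 1e-300) score = 0.0;
        else score = (sts - st * ss / npx) / std::sqrt(var_t * var_s);
        scores[(v + radius) * side + (u + radius)] = score;
        const double mag = (double)u * u + (double)v * v;
        if (score > best + 1e-12 ||
            (score > best - 1e-12 && mag < bmag)) {
          best = score; bu = u; bv = v; bmag = mag;
        }
      }
    }
    if (best < -1.5 || best < min_ncc) { out(k, 2) = best; continue; }

    // parabolic sub-pixel refinement along each axis; a perfect match
    // (NCC == 1) is already exact and refinement would only add the
    // asymmetry of its neighbours
    double du = 0.0, dv = 0.0;
    if (best >= 1.0 - 1e-12) {
      out(k, 0) = bu; out(k, 1) = bv; out(k, 2) = best; out(k, 3) = 1.0;
      continue;
    }
    const int iu = bu + radius, iv = bv + radius;
    if (iu > 0 && iu < side - 1) {
      const double cm = scores[iv * side + iu - 1];
      const double cp = scores[iv * side + iu + 1];
      const double c0s = scores[iv * side + iu];
      if (R_finite(cm) && R_finite(cp)) {
        const double den = cm - 2.0 * c0s + cp;
        if (den < -1e-12) du = 0.5 * (cm - cp) / den;
        du = std::max(-0.5, std::min(0.5, du));
      }
    }
    if (iv > 0 && iv < side - 1) {
      const double cm = scores[(iv - 1) * side + iu];
      const double cp = scores[(iv + 1) * side + iu];
      const double c0s = scores[iv * side + iu];
      if (R_finite(cm) && R_finite(cp)) {
        const double den = cm - 2.0 * c0s + cp;
        if (den < -1e-12) dv = 0.5 * (cm - cp) / den;
        dv = std::max(-0.5, std::min(0.5, dv));
      }
    }
    out(k, 0) = bu + du;
    out(k, 1) = bv + dv;
    out(k, 2) = best;
    out(k, 3) = 1.0;
  }
  return out;
}
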