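#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cone-beam projector with Joseph-style ray integration: each ray is stepped
// along its dominant axis in voxel-index space, sampling the volume by
// bilinear interpolation in the plane perpendicular to that axis; the
// contribution of each sample is weighted by the world-space path length per
// step. mode 0 computes line integrals (forward, A x); mode 1 scatters
// projection values back into the volume with the transposed weights
// (backprojection, A' y), making the pair a matched adjoint by construction.
//
// Layout: volume is an R array dim (nx, ny, nz), x fastest; projections are
// an R array dim (rows, cols, n_proj) with row = vertical detector index.

// [[Rcpp::export(name = ".cb_project")]]
NumericVector cb_project(NumericVector vol,
                         IntegerVector vshape, NumericVector vsize,
                         NumericVector vorigin,
                         NumericMatrix src, NumericMatrix det,
                         NumericMatrix uax, NumericMatrix vax,
                         IntegerVector dshape, NumericVector pitch,
                         NumericVector proj, int mode) {
  const int nx = vshape[0], ny = vshape[1], nz = vshape[2];
  const double sx = vsize[0], sy = vsize[1], sz = vsize[2];
  const double ox = vorigin[0], oy = vorigin[1], oz = vorigin[2];
  const int rows = dshape[0], cols = dshape[1];
  const double pu = pitch[0], pv = pitch[1];
  const int np = src.nrow();
  const R_xlen_t nproj_len = (R_xlen_t)rows * cols * np;
  const R_xlen_t nvol_len = (R_xlen_t)nx * ny * nz;

  NumericVector out(mode == 0 ? nproj_len : nvol_len);
  double *outp = REAL(out);
  const double *volp = (mode == 0) ? REAL(vol) : nullptr;
  const double *projp = (mode == 1) ? REAL(proj) : nullptr;

  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int p = 0; p < np; ++p) {
    const double S[3] = {src(p, 0), src(p, 1), src(p, 2)};
    const double D0[3] = {det(p, 0), det(p, 1), det(p, 2)};
    const double U[3] = {uax(p, 0), uax(p, 1), uax(p, 2)};
    const double V[3] = {vax(p, 0), vax(p, 1), vax(p, 2)};
    // source in index coordinates
    const double Si[3] = {(S[0] - ox) / sx, (S[1] - oy) / sy,
                          (S[2] - oz) / sz};
    const R_xlen_t pbase = (R_xlen_t)rows * cols * p;

    for (int c = 0; c < cols; ++c) {
      const double uc = (c - (cols - 1) * 0.5) * pu;
      for (int r = 0; r < rows; ++r) {
        const double vc = (r - (rows - 1) * 0.5) * pv;
        const double P[3] = {D0[0] + uc * U[0] + vc * V[0],
                             D0[1] + uc * U[1] + vc * V[1],
                             D0[2] + uc * U[2] + vc * V[2]};
        const double Dw[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        const double Di[3] = {Dw[0] / sx, Dw[1] / sy, Dw[2] / sz};
        // dominant axis in index space
        int a = 0;
        double am = std::fabs(Di[0]);
        if (std::fabs(Di[1]) > am) { a = 1; am = std::fabs(Di[1]); }
        if (std::fabs(Di[2]) > am) { a = 2; am = std::fabs(Di[2]); }
        if (am <= 0) continue;
        const int b = (a + 1) % 3, cc = (a + 2) % 3;
        // world path length per unit index step along the dominant axis
        const double wnorm = std::sqrt(Dw[0] * Dw[0] + Dw[1] * Dw[1] +
                                       Dw[2] * Dw[2]);
        const double step = wnorm / am;
        // t-parameter (0 at source, 1 at pixel) per k-plane: t = (k-Si[a])/Di[a]
        // restrict k to planes whose perpendicular position can touch the
        // bilinear support [-1, n] on both other axes
        double t0 = 0.0, t1 = 1.0;
        for (int axi = 0; axi < 3; ++axi) {
          const double lo = -1.0, hi = dims[axi];
          if (std::fabs(Di[axi]) < 1e-12) {
            if (Si[axi] < lo || Si[axi] > hi) { t0 = 1.0; t1 = 0.0; }
          } else {
            double ta = (lo - Si[axi]) / Di[axi];
            double tb = (hi - Si[axi]) / Di[axi];
            if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
          }
        }
        if (t1 <= t0) continue;
        // k-plane range along dominant axis
        double ka = Si[a] + t0 * Di[a], kb = Si[a] + t1 * Di[a];
        if (ka > kb) { double tmp = ka; ka = kb; kb = tmp; }
        int k0 = (int)std::ceil(ka);
        int k1 = (int)std::floor(kb);
        if (k0 < 0) k0 = 0;
        if (k1 > dims[a] - 1) k1 = dims[a] - 1;
        if (k0 > k1) continue;
        const double inv_da = 1.0 / Di[a];
        // positions on the other two axes at plane k, and their increments
        const double dirsgn = (Di[a] > 0) ? 1.0 : -1.0;
        const double tb0 = (k0 - Si[a]) * inv_da;
        double pb = Si[b] + tb0 * Di[b];
        double pc = Si[cc] + tb0 * Di[cc];
        const double ib_inc = Di[b] * inv_da;  // per +1 k-plane
        const double ic_inc = Di[cc] * inv_da;
        const R_xlen_t sa = strides[a], sb = strides[b], sc = strides[cc];
        const int nb = dims[b], ncc = dims[cc];
        const R_xlen_t pix = pbase + (R_xlen_t)rows * c + r;
        double acc = 0.0;
        const double pval = (mode == 1) ? projp[pix] * step : 0.0;
        (void)dirsgn;
        // fast path: whole segment strictly interior on both in-plane axes
        const double pb_end = pb + ib_inc * (k1 - k0);
        const double pc_end = pc + ic_inc * (k1 - k0);
        const bool interior =
          std::min(pb, pb_end) >= 0.0 && std::max(pb, pb_end) < nb - 1 &&
          std::min(pc, pc_end) >= 0.0 && std::max(pc, pc_end) < ncc - 1;
        if (interior) {
          if (mode == 0) {
            for (int k = k0; k <= k1; ++k) {
              const int jb = (int)pb, jc = (int)pc;
              const double fb = pb - jb, fc = pc - jc;
              const double *v00 = volp + (R_xlen_t)k * sa + jb * sb + jc * sc;
              acc += (1 - fc) * ((1 - fb) * v00[0] + fb * v00[sb]) +
                     fc * ((1 - fb) * v00[sc] + fb * v00[sb + sc]);
              pb += ib_inc;
              pc += ic_inc;
            }
            outp[pix] = acc * step;
          } else {
            for (int k = k0; k <= k1; ++k) {
              const int jb = (int)pb, jc = (int)pc;
              const double fb = pb - jb, fc = pc - jc;
              double *o00 = outp + (R_xlen_t)k * sa + jb * sb + jc * sc;
              o00[0] += (1 - fb) * (1 - fc) * pval;
              o00[sb] += fb * (1 - fc) * pval;
              o00[sc] += (1 - fb) * fc * pval;
              o00[sb + sc] += fb * fc * pval;
              pb += ib_inc;
              pc += ic_inc;
            }
          }
          continue;
        }
        for (int k = k0; k <= k1; ++k) {
          const int jb = (int)std::floor(pb);
          const int jc = (int)std::floor(pc);
          const double fb = pb - jb, fc = pc - jc;
          const double w00 = (1 - fb) * (1 - fc), w10 = fb * (1 - fc);
          const double w01 = (1 - fb) * fc, w11 = fb * fc;
          const bool b0 = jb >= 0 && jb < nb, b1 = jb + 1 >= 0 && jb + 1 < nb;
          const bool c0 = jc >= 0 && jc < ncc, c1 = jc + 1 >= 0 && jc + 1 < ncc;
          const R_xlen_t base = (R_xlen_t)k * sa;
          if (mode == 0) {
            double s = 0.0;
            if (b0 && c0) s += w00 * volp[base + jb * sb + jc * sc];
            if (b1 && c0) s += w10 * volp[base + (jb + 1) * sb + jc * sc];
            if (b0 && c1) s += w01 * volp[base + jb * sb + (jc + 1) * sc];
            if (b1 && c1) s += w11 * volp[base + (jb + 1) * sb + (jc + 1) * sc];
            acc += s;
          } else {
            if (b0 && c0) outp[base + jb * sb + jc * sc] += w00 * pval;
            if (b1 && c0) outp[base + (jb + 1) * sb + jc * sc] += w10 * pval;
            if (b0 && c1) outp[base + jb * sb + (jc + 1) * sc] += w01 * pval;
            if (b1 && c1) outp[base + (jb + 1) * sb + (jc + 1) * sc] += w11 * pval;
          }
          pb += ib_inc;
          pc += ic_inc;
        }
        if (mode == 0) outp[pix] = acc * step;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
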