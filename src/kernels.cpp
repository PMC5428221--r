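#include <Rcpp.h>
using namespace Rcpp;

// Polychromatic Beer-Lambert detector counts.
//
// thick : n_px x n_el areal thicknesses in cm
// mu    : n_E x n_el linear attenuation coefficients in 1/cm
// w     : n_E per-bin detected weights (filtered spectrum x detector response)
//
// out[p] = sum_E w[E] * exp(-sum_el mu[E,el] * thick[p,el])
// [[Rcpp::export]]
NumericVector beer_lambert_counts(NumericMatrix thick, NumericMatrix mu,
                                  NumericVector w) {
  const int npx = thick.nrow(), nel = thick.ncol(), nE = mu.nrow();
  if (mu.ncol() != nel) stop("mu and thick disagree on element count");
  if (w.size() != nE) stop("weights and mu disagree on energy grid");
  NumericVector out(npx);
  for (int p = 0; p < npx; ++p) {
    double acc = 0.0;
    for (int e = 0; e < nE; ++e) {
      if (w[e] == 0.0) continue;
      double tau = 0.0;
      for (int el = 0; el < nel; ++el) tau += mu(e, el) * thick(p, el);
      acc += w[e] * std::exp(-tau);
    }
    out[p] = acc;
  }
  return out;
}

// Bilinear sampling of a stack of images at rotated coordinates.
//
// stack : (ny*nx) x nz matrix, images stored column-major per slice with
//         row index = y + ny*x (0-based)
// xs,ys : n_out source coordinates (0-based, fractional); out-of-range -> 0
//
// Returns n_out x nz matrix.
// [[Rcpp::export]]
NumericMatrix bilinear_gather(NumericMatrix stack, NumericVector xs,
                              NumericVector ys, int ny, int nx) {
  const int nout = xs.size(), nz = stack.ncol();
  if (stack.nrow() != ny * nx) stop("stack rows != ny*nx");
  NumericMatrix out(nout, nz);
  for (int i = 0; i < nout; ++i) {
    double x = xs[i], y = ys[i];
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
    // neighbour weights, zero outside the grid
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wgt = wy * (dx ? fx : 1.0 - fx);
        if (wgt == 0.0) continue;
        int src = yy + ny * xx;
        for (int z = 0; z < nz; ++z) out(i, z) += wgt * stack(src, z);
      }
    }
  }
  return out;
}

// Back-projection of one angle's filtered projections into a stack of slices.
//
// q       : n_det x nz filtered projections (detector samples, one column per
//           slice)
// svals   : (ny*nx) detector coordinate (0-based, fractional) of every output
//           pixel for this angle
// accum   : (ny*nx) x nz accumulator, modified in place
// [[Rcpp::export]]
void backproject_accum(NumericMatrix accum, NumericMatrix q,
                       NumericVector svals) {
  const int npx = svals.size(), ndet = q.nrow(), nz = q.ncol();
  if (accum.nrow() != npx || accum.ncol() != nz) stop("accumulator shape mismatch");
  for (int i = 0; i < npx; ++i) {
    double s = svals[i];
    int s0 = (int)std::floor(s);
    double fs = s - s0;
    if (s0 < -1 || s0 > ndet - 1) continue;
    bool has0 = s0 >= 0 && s0 < ndet, has1 = s0 + 1 >= 0 && s0 + 1 < ndet;
    for (int z = 0; z < nz; ++z) {
      double v = 0.0;
      if (has0) v += (1.0 - fs) * q(s0, z);
      if (has1) v += fs * q(s0 + 1, z);
      accum(i, z) += v;
    }
  }
}
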