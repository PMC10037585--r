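// [[Rcpp::depends(RcppArmadillo)]]
#include "nn.h"
#if defined(__GLIBC__)
#include <malloc.h>
// The conv layers allocate and free many multi-MB im2col buffers per
// iteration; serving these from the heap instead of fresh mmaps avoids
// continual page-fault + zeroing overhead.
__attribute__((constructor)) static void tibiasegTuneMalloc() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
}
#endif
using namespace Rcpp;

// R array of dim (H, W, C, N) -> fcube(H*W, C, N); layouts are
// bit-compatible (first index fastest), only the float cast is applied.
static fcube asCube(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d(x.attr("dim"));
  if (d.size() == 3) { H = d[0]; W = d[1]; C = 1; N = d[2]; }
  else if (d.size() == 4) { H = d[0]; W = d[1]; C = d[2]; N = d[3]; }
  else stop("expected a 3D or 4D array");
  fcube out(H * W, C, N);
  const double* src = x.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = (float)src[i];
  return out;
}

static NumericVector cubeToR(const fcube& X, int H, int W) {
  NumericVector out(X.n_elem);
  for (arma::uword i = 0; i < X.n_elem; ++i) out[i] = X(i);
  out.attr("dim") = IntegerVector::create(H, W, (int)X.n_cols, (int)X.n_slices);
  return out;
}

static Conv convFromR(const NumericVector& Wk, const NumericVector& b,
                      int stride, int pad) {
  IntegerVector d(Wk.attr("dim"));
  if (d.size() != 4) stop("kernel must be a 4D array (k, k, Cin, Cout)");
  if (d[0] != d[1]) stop("only square kernels are supported");
  Conv L;
  L.k = d[0]; L.stride = stride; L.pad = pad; L.Cin = d[2]; L.Cout = d[3];
  L.A.set_size(L.k * L.k * L.Cin, L.Cout);
  for (arma::uword i = 0; i < L.A.n_elem; ++i) L.A(i) = (float)Wk[i];
  L.b.set_size(L.Cout);
  if (b.size() != L.Cout) stop("bias length must equal Cout");
  for (int i = 0; i < L.Cout; ++i) L.b(i) = (float)b[i];
  return L;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector kernel,
                         NumericVector bias, int stride, int pad) {
  int H, W, C, N;
  fcube X = asCube(x, H, W, C, N);
  Conv L = convFromR(kernel, bias, stride, pad);
  if (L.Cin != C) stop("kernel Cin does not match input channels");
  int Ho, Wo;
  fcube Y = convFwd(L, X, H, W, Ho, Wo);
  return cubeToR(Y, Ho, Wo);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2(NumericVector x) {
  int H, W, C, N;
  fcube X = asCube(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  arma::ucube am;
  fcube Y = pool2Fwd(X, H, W, am);
  return cubeToR(Y, H / 2, W / 2);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  int H, W, C, N;
  fcube X = asCube(x, H, W, C, N);
  fcube Y = up2Fwd(X, H, W);
  return cubeToR(Y, 2 * H, 2 * W);
}

// Standalone attention gate:
//   xg = conv1x1_s2(x); gg = conv1x1(g); q = relu(xg+gg);
//   a  = sigmoid(conv1x1(q) -> 1 channel); alpha = bilinear_x2(a);
//   out = alpha (*) x   (broadcast over channels)
// [[Rcpp::export]]
List cpp_attention_gate(NumericVector x, NumericVector g,
                        NumericVector Wx, NumericVector bx,
                        NumericVector Wg, NumericVector bg,
                        NumericVector Wpsi, NumericVector bpsi) {
  int H2, W2, Cx, N, Hg, Wg_, Cg, Ng;
  fcube X = asCube(x, H2, W2, Cx, N);
  fcube G = asCube(g, Hg, Wg_, Cg, Ng);
  if (N != Ng)
    stop("batch size mismatch between input and gating signal");
  if (H2 != 2 * Hg || W2 != 2 * Wg_)
    stop("attention gate shape error: input signal is (" +
         std::to_string(H2) + "," + std::to_string(W2) + ") but gating is (" +
         std::to_string(Hg) + "," + std::to_string(Wg_) +
         "); input spatial dims must be exactly twice the gating dims");
  Conv Lx = convFromR(Wx, bx, 2, 0);
  Conv Lg = convFromR(Wg, bg, 1, 0);
  Conv Lp = convFromR(Wpsi, bpsi, 1, 0);
  if (Lx.k != 1 || Lg.k != 1 || Lp.k != 1) stop("gate convolutions must be 1x1");
  if (Lx.Cin != Cx) stop("Wx Cin must match input channels");
  if (Lg.Cin != Cg) stop("Wg Cin must match gating channels");
  if (Lx.Cout != Lg.Cout || Lp.Cin != Lx.Cout || Lp.Cout != 1)
    stop("gate channel contract: Wx/Wg out = F, Wpsi F -> 1");
  int Ho, Wo;
  fcube XG = convFwd(Lx, X, H2, W2, Ho, Wo);
  int h2, w2;
  fcube GG = convFwd(Lg, G, Hg, Wg_, h2, w2);
  if (Ho != Hg || Wo != Wg_) stop("internal gate shape mismatch");
  fcube Q = XG + GG;
  reluInplace(Q);
  fcube A = convFwd(Lp, Q, Hg, Wg_, h2, w2);
  sigmoidInplace(A);
  fcube Alpha = up2Fwd(A, Hg, Wg_);
  fcube Out(arma::size(X));
  for (int n = 0; n < N; ++n)
    Out.slice(n) = X.slice(n).each_col() % Alpha.slice(n).col(0);
  return List::create(_["output"] = cubeToR(Out, H2, W2),
                      _["alpha"] = cubeToR(Alpha, H2, W2));
}

// Symmetric Hausdorff distance between two point clouds (rows = points,
// physical coordinates).  Brute force with the classical early-break.
static double directedHD(const arma::mat& A, const arma::mat& B) {
  double cmax = 0.0;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double cmin = std::numeric_limits<double>::infinity();
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < cmin) {
        cmin = d;
        if (cmin <= cmax) break;   // cannot raise the max
      }
    }
    if (cmin > cmax && std::isfinite(cmin)) cmax = cmin;
  }
  return std::sqrt(cmax);
}

// [[Rcpp::export]]
double cpp_hausdorff(arma::mat a, arma::mat b) {
  if (a.n_rows == 0 || b.n_rows == 0) stop("empty point set");
  if (a.n_cols != 3 || b.n_cols != 3) stop("points must be n x 3");
  return std::max(directedHD(a, b), directedHD(b, a));
}

// Number of 26-connected foreground components of a 3D mask.
// [[Rcpp::export]]
int cpp_label26(IntegerVector mask, IntegerVector dims) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const R_xlen_t n = (R_xlen_t)dx * dy * dz;
  std::vector<int> lab(n, 0);
  int ncomp = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s]) continue;
    ++ncomp;
    lab[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      const int z = cur / ((R_xlen_t)dx * dy);
      const int rem = cur - (R_xlen_t)z * dx * dy;
      const int y = rem / dx, x = rem % dx;
      for (int ddz = -1; ddz <= 1; ++ddz)
        for (int ddy = -1; ddy <= 1; ++ddy)
          for (int ddx = -1; ddx <= 1; ++ddx) {
            if (!ddx && !ddy && !ddz) continue;
            const int nx = x + ddx, ny = y + ddy, nz = z + ddz;
            if (nx < 0 || nx >= dx || ny < 0 || ny >= dy || nz < 0 || nz >= dz)
              continue;
            const R_xlen_t q = nx + (R_xlen_t)dx * ny + (R_xlen_t)dx * dy * nz;
            if (mask[q] != 0 && !lab[q]) { lab[q] = ncomp; stack.push_back(q); }
          }
    }
  }
  return ncomp;
}
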