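// [[Rcpp::depends(RcppArmadillo)]]
// Attention-gated 2D U-Net: four-stage contracting path (2x2 max-pool,
// double 3x3 conv + batch-norm + ReLU blocks, filter count doubling per
// stage), a bottleneck block, and an expanding path with one attention
// gate per skip connection and bilinear x2 upsampling.  Forward,
// backprop and Adam are implemented here in single precision.
#include "nn.h"
using namespace Rcpp;

struct DC { Conv c1; BN n1; Conv c2; BN n2; };
struct GateL { Conv cx, cg, psi; };

struct Net {
  int F = 16, depth = 4, inCh = 1;
  std::vector<DC> enc;
  DC bott;
  std::vector<DC> dec;     // dec[q] operates at the resolution of skip j = depth-1-q
  std::vector<GateL> gate;
  Conv out;
};

static void initDC(DC& d, int ci, int co, std::mt19937& rng) {
  d.c1.init(3, 1, 1, ci, co, rng); d.n1.init(co);
  d.c2.init(3, 1, 1, co, co, rng); d.n2.init(co);
}

static Net makeNet(int F, int depth, int inCh, int seed) {
  Net net; net.F = F; net.depth = depth; net.inCh = inCh;
  std::mt19937 rng((unsigned)seed);
  net.enc.resize(depth); net.dec.resize(depth); net.gate.resize(depth);
  for (int i = 0; i < depth; ++i)
    initDC(net.enc[i], i == 0 ? inCh : (F << (i - 1)), F << i, rng);
  initDC(net.bott, F << (depth - 1), F << depth, rng);
  for (int q = 0; q < depth; ++q) {
    const int j = depth - 1 - q;
    const int Cs = F << j, Cg = F << (j + 1);
    net.gate[q].cx.init(1, 2, 0, Cs, Cg, rng);
    net.gate[q].cg.init(1, 1, 0, Cg, Cg, rng);
    net.gate[q].psi.init(1, 1, 0, Cg, 1, rng);
    initDC(net.dec[q], Cg + Cs, Cs, rng);
  }
  net.out.init(1, 1, 0, F, 1, rng);
  return net;
}

// ---- params list <-> Net -------------------------------------------------

static NumericVector matToR(const fmat& A, IntegerVector dim) {
  NumericVector out(A.n_elem);
  for (arma::uword i = 0; i < A.n_elem; ++i) out[i] = A(i);
  out.attr("dim") = dim;
  return out;
}
static NumericVector vecToR(const frowvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}
static void matFromR(fmat& A, const NumericVector& x) {
  if ((arma::uword)x.size() != A.n_elem) stop("parameter size mismatch");
  for (arma::uword i = 0; i < A.n_elem; ++i) A(i) = (float)x[i];
}
static void vecFromR(frowvec& v, const NumericVector& x) {
  if ((arma::uword)x.size() != v.n_elem) stop("parameter size mismatch");
  for (arma::uword i = 0; i < v.n_elem; ++i) v(i) = (float)x[i];
}

static List convToR(const Conv& c) {
  IntegerVector d = IntegerVector::create(c.k, c.k, c.Cin, c.Cout);
  return List::create(_["W"] = matToR(c.A, d), _["b"] = vecToR(c.b),
                      _["mW"] = matToR(c.mA, d), _["vW"] = matToR(c.vA, d),
                      _["mb"] = vecToR(c.mb), _["vb"] = vecToR(c.vb),
                      _["stride"] = c.stride, _["pad"] = c.pad);
}
static void convFromR(Conv& c, List l) {
  NumericVector W(l["W"]);
  IntegerVector d(W.attr("dim"));
  c.k = d[0]; c.Cin = d[2]; c.Cout = d[3];
  c.stride = as<int>(l["stride"]); c.pad = as<int>(l["pad"]);
  c.A.set_size(c.k * c.k * c.Cin, c.Cout); matFromR(c.A, W);
  c.b.set_size(c.Cout); vecFromR(c.b, l["b"]);
  c.mA.set_size(arma::size(c.A)); matFromR(c.mA, l["mW"]);
  c.vA.set_size(arma::size(c.A)); matFromR(c.vA, l["vW"]);
  c.mb.set_size(c.Cout); vecFromR(c.mb, l["mb"]);
  c.vb.set_size(c.Cout); vecFromR(c.vb, l["vb"]);
}
static List bnToR(const BN& n) {
  return List::create(_["gamma"] = vecToR(n.g), _["beta"] = vecToR(n.b),
                      _["rmean"] = vecToR(n.rm), _["rvar"] = vecToR(n.rv),
                      _["mg"] = vecToR(n.mg), _["vg"] = vecToR(n.vg),
                      _["mb"] = vecToR(n.mb), _["vb"] = vecToR(n.vb));
}
static void bnFromR(BN& n, List l) {
  NumericVector g(l["gamma"]);
  const int C = g.size();
  n.init(C);
  vecFromR(n.g, l["gamma"]); vecFromR(n.b, l["beta"]);
  vecFromR(n.rm, l["rmean"]); vecFromR(n.rv, l["rvar"]);
  vecFromR(n.mg, l["mg"]); vecFromR(n.vg, l["vg"]);
  vecFromR(n.mb, l["mb"]); vecFromR(n.vb, l["vb"]);
}
static List dcToR(const DC& d) {
  return List::create(_["c1"] = convToR(d.c1), _["bn1"] = bnToR(d.n1),
                      _["c2"] = convToR(d.c2), _["bn2"] = bnToR(d.n2));
}
static void dcFromR(DC& d, List l) {
  convFromR(d.c1, l["c1"]); bnFromR(d.n1, l["bn1"]);
  convFromR(d.c2, l["c2"]); bnFromR(d.n2, l["bn2"]);
}

static List netToR(const Net& net, int step) {
  List enc(net.depth), dec(net.depth), gate(net.depth);
  for (int i = 0; i < net.depth; ++i) enc[i] = dcToR(net.enc[i]);
  for (int q = 0; q < net.depth; ++q) {
    dec[q] = dcToR(net.dec[q]);
    gate[q] = List::create(_["cx"] = convToR(net.gate[q].cx),
                           _["cg"] = convToR(net.gate[q].cg),
                           _["psi"] = convToR(net.gate[q].psi));
  }
  return List::create(
    _["meta"] = IntegerVector::create(_["baseFilters"] = net.F,
                                      _["depth"] = net.depth,
                                      _["inChannels"] = net.inCh,
                                      _["step"] = step),
    _["enc"] = enc, _["bott"] = dcToR(net.bott), _["dec"] = dec,
    _["gate"] = gate, _["outc"] = convToR(net.out));
}

static Net netFromR(List params, int& step) {
  IntegerVector meta(params["meta"]);
  Net net;
  net.F = meta[0]; net.depth = meta[1]; net.inCh = meta[2];
  step = meta[3];
  net.enc.resize(net.depth); net.dec.resize(net.depth); net.gate.resize(net.depth);
  List enc(params["enc"]), dec(params["dec"]), gate(params["gate"]);
  for (int i = 0; i < net.depth; ++i) dcFromR(net.enc[i], enc[i]);
  dcFromR(net.bott, params["bott"]);
  for (int q = 0; q < net.depth; ++q) {
    dcFromR(net.dec[q], dec[q]);
    List gl = gate[q];
    convFromR(net.gate[q].cx, gl["cx"]);
    convFromR(net.gate[q].cg, gl["cg"]);
    convFromR(net.gate[q].psi, gl["psi"]);
  }
  convFromR(net.out, params["outc"]);
  return net;
}

// ---- forward/backward ----------------------------------------------------

struct DCCache { fcube in, z1, a1, z2, out; int H = 0, W = 0; };

static void dcFwd(DC& d, DCCache& c, const fcube& X, int H, int W, bool train,
                  bool keep) {
  int ho, wo;
  c.H = H; c.W = W;
  fcube z1 = convFwd(d.c1, X, H, W, ho, wo);
  fcube a1 = bnFwd(d.n1, z1, train);
  reluInplace(a1);
  fcube z2 = convFwd(d.c2, a1, H, W, ho, wo);
  fcube o = bnFwd(d.n2, z2, train);
  reluInplace(o);
  if (keep) { c.in = X; c.z1 = std::move(z1); c.a1 = std::move(a1); c.z2 = std::move(z2); }
  c.out = std::move(o);
}

static fcube dcBwd(DC& d, DCCache& c, const fcube& dOut, bool wantDX) {
  fcube g = reluBwd(c.out, dOut);
  g = bnBwd(d.n2, c.z2, g);
  g = convBwd(d.c2, c.a1, g, c.H, c.W, true);
  g = reluBwd(c.a1, g);
  g = bnBwd(d.n1, c.z1, g);
  return convBwd(d.c1, c.in, g, c.H, c.W, wantDX);
}

struct GateCache { fcube x, g, q, s, alpha; int Hs = 0, Ws = 0; };

static fcube gateFwd(GateL& gl, GateCache& c, const fcube& x, const fcube& g,
                     int Hs, int Ws, double alphaOverride, bool keep) {
  // x: skip at (Hs, Ws); g: gating at (Hs/2, Ws/2)
  int ho, wo;
  c.Hs = Hs; c.Ws = Ws;
  fcube xg = convFwd(gl.cx, x, Hs, Ws, ho, wo);
  fcube gg = convFwd(gl.cg, g, Hs / 2, Ws / 2, ho, wo);
  fcube q = xg + gg;
  reluInplace(q);
  fcube s = convFwd(gl.psi, q, Hs / 2, Ws / 2, ho, wo);
  sigmoidInplace(s);
  fcube alpha = up2Fwd(s, Hs / 2, Ws / 2);
  if (!ISNA(alphaOverride)) alpha.fill((float)alphaOverride);
  fcube out(arma::size(x));
  for (arma::uword n = 0; n < x.n_slices; ++n)
    out.slice(n) = x.slice(n).each_col() % alpha.slice(n).col(0);
  c.alpha = std::move(alpha);   // kept unconditionally (1 channel, cheap; also reported)
  if (keep) { c.x = x; c.g = g; c.q = std::move(q); c.s = std::move(s); }
  return out;
}

static void gateBwd(GateL& gl, GateCache& c, const fcube& dOut,
                    fcube& dX, fcube& dG) {
  const arma::uword N = dOut.n_slices;
  dX.set_size(arma::size(c.x));
  fcube dAlpha(c.alpha.n_rows, 1, N);
  for (arma::uword n = 0; n < N; ++n) {
    dX.slice(n) = dOut.slice(n).each_col() % c.alpha.slice(n).col(0);
    dAlpha.slice(n).col(0) = arma::sum(dOut.slice(n) % c.x.slice(n), 1);
  }
  fcube dS = up2Bwd(dAlpha, c.Hs / 2, c.Ws / 2);
  dS %= c.s % (1.0f - c.s);                      // sigmoid'
  fcube dQ = convBwd(gl.psi, c.q, dS, c.Hs / 2, c.Ws / 2, true);
  dQ = reluBwd(c.q, dQ);
  dX += convBwd(gl.cx, c.x, dQ, c.Hs, c.Ws, true);
  dG = convBwd(gl.cg, c.g, dQ, c.Hs / 2, c.Ws / 2, true);
}

struct FwdCache {
  std::vector<DCCache> enc, dec;
  std::vector<arma::ucube> amax;
  DCCache bott;
  std::vector<GateCache> gate;
  std::vector<fcube> catIn;    // concatenated decoder inputs (for split sizes)
  fcube probs;                  // sigmoid output
  fcube lastOut;                // decoder top output (input to out conv)
};

static fcube netFwd(Net& net, FwdCache& fc, const fcube& X, int H, int W,
                    bool train, bool gatesOn, double alphaOverride, bool keep,
                    List* alphasOut) {
  const int d = net.depth;
  if (H % (1 << d) || W % (1 << d))
    stop("input spatial dims (" + std::to_string(H) + "," + std::to_string(W) +
         ") must be divisible by 2^depth = " + std::to_string(1 << d));
  fc.enc.resize(d); fc.dec.resize(d); fc.amax.resize(d); fc.gate.resize(d);
  if (alphasOut) *alphasOut = List(d);
  fcube cur = X;
  int h = H, w = W;
  std::vector<int> hs(d), ws(d);
  for (int i = 0; i < d; ++i) {
    hs[i] = h; ws[i] = w;
    dcFwd(net.enc[i], fc.enc[i], cur, h, w, train, keep);
    cur = pool2Fwd(fc.enc[i].out, h, w, fc.amax[i]);
    h /= 2; w /= 2;
  }
  dcFwd(net.bott, fc.bott, cur, h, w, train, keep);
  fcube g = fc.bott.out;
  for (int q = 0; q < d; ++q) {
    const int j = d - 1 - q;
    fcube xg;
    if (gatesOn) {
      xg = gateFwd(net.gate[q], fc.gate[q], fc.enc[j].out, g, hs[j], ws[j],
                   alphaOverride, keep);
      if (alphasOut) {
        NumericVector al(fc.gate[q].alpha.n_elem);
        const fcube& a = fc.gate[q].alpha;
        for (arma::uword i = 0; i < a.n_elem; ++i) al[i] = a(i);
        al.attr("dim") = IntegerVector::create(hs[j], ws[j], 1, (int)a.n_slices);
        (*alphasOut)[q] = al;
      }
    } else {
      xg = fc.enc[j].out;
    }
    fcube gup = up2Fwd(g, hs[j] / 2, ws[j] / 2);
    fcube cat(gup.n_rows, gup.n_cols + xg.n_cols, gup.n_slices);
    cat.cols(0, gup.n_cols - 1) = gup;
    cat.cols(gup.n_cols, cat.n_cols - 1) = xg;
    dcFwd(net.dec[q], fc.dec[q], cat, hs[j], ws[j], train, keep);
    g = fc.dec[q].out;
  }
  int ho, wo;
  fcube z = convFwd(net.out, g, H, W, ho, wo);
  if (keep) fc.lastOut = g;
  fcube p = z;
  sigmoidInplace(p);
  fc.probs = p;
  return z;   // logits
}

static void zeroGrads(Net& net) {
  auto zdc = [](DC& d) { d.c1.zeroGrad(); d.n1.zeroGrad(); d.c2.zeroGrad(); d.n2.zeroGrad(); };
  for (auto& e : net.enc) zdc(e);
  zdc(net.bott);
  for (auto& e : net.dec) zdc(e);
  for (auto& g : net.gate) { g.cx.zeroGrad(); g.cg.zeroGrad(); g.psi.zeroGrad(); }
  net.out.zeroGrad();
}

static void netBwd(Net& net, FwdCache& fc, const fcube& dZ, int H, int W,
                   bool gatesOn) {
  const int d = net.depth;
  std::vector<int> hs(d), ws(d);
  int h = H, w = W;
  for (int i = 0; i < d; ++i) { hs[i] = h; ws[i] = w; h /= 2; w /= 2; }
  fcube dg = convBwd(net.out, fc.lastOut, dZ, H, W, true);
  std::vector<fcube> dEnc(d);   // gradients flowing into encoder outputs
  for (int q = d - 1; q >= 0; --q) {
    const int j = d - 1 - q;
    fcube dCat = dcBwd(net.dec[q], fc.dec[q], dg, true);
    const int Cg = net.F << (j + 1), Cs = net.F << j;
    fcube dGup = dCat.cols(0, Cg - 1);
    fcube dXg = dCat.cols(Cg, Cg + Cs - 1);
    fcube dgPrev = up2Bwd(dGup, hs[j] / 2, ws[j] / 2);
    if (gatesOn) {
      fcube dSkip, dGgate;
      gateBwd(net.gate[q], fc.gate[q], dXg, dSkip, dGgate);
      dEnc[j] = std::move(dSkip);
      dgPrev += dGgate;
    } else {
      dEnc[j] = std::move(dXg);
    }
    dg = std::move(dgPrev);
  }
  // dg now reaches the bottleneck output
  fcube dPool = dcBwd(net.bott, fc.bott, dg, true);
  for (int i = d - 1; i >= 0; --i) {
    fcube dOut = pool2Bwd(dPool, fc.amax[i], hs[i], ws[i]);
    dOut += dEnc[i];
    dPool = dcBwd(net.enc[i], fc.enc[i], dOut, i > 0);
  }
}

static void adamOne(fmat& w, const fmat& g, fmat& m, fmat& v,
                    double lr, double b1, double b2, double eps, int t) {
  m = (float)b1 * m + (float)(1 - b1) * g;
  v = (float)b2 * v + (float)(1 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  w -= (float)(lr / c1) * (m / (arma::sqrt(v / (float)c2) + (float)eps));
}
static void adamOneV(frowvec& w, const frowvec& g, frowvec& m, frowvec& v,
                     double lr, double b1, double b2, double eps, int t) {
  m = (float)b1 * m + (float)(1 - b1) * g;
  v = (float)b2 * v + (float)(1 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  w -= (float)(lr / c1) * (m / (arma::sqrt(v / (float)c2) + (float)eps));
}

static void adamStep(Net& net, double lr, double b1, double b2, double eps, int t) {
  auto upc = [&](Conv& c) {
    adamOne(c.A, c.gA, c.mA, c.vA, lr, b1, b2, eps, t);
    adamOneV(c.b, c.gb, c.mb, c.vb, lr, b1, b2, eps, t);
  };
  auto upn = [&](BN& n) {
    adamOneV(n.g, n.gg, n.mg, n.vg, lr, b1, b2, eps, t);
    adamOneV(n.b, n.gb, n.mb, n.vb, lr, b1, b2, eps, t);
  };
  auto updc = [&](DC& d) { upc(d.c1); upn(d.n1); upc(d.c2); upn(d.n2); };
  for (auto& e : net.enc) updc(e);
  updc(net.bott);
  for (auto& e : net.dec) updc(e);
  for (auto& g : net.gate) { upc(g.cx); upc(g.cg); upc(g.psi); }
  upc(net.out);
}

// ---- exports -------------------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_init(int baseFilters, int depth, int inChannels, int seed) {
  Net net = makeNet(baseFilters, depth, inChannels, seed);
  return netToR(net, 0);
}

static fcube rToCube3(const NumericVector& x, int& H, int& W, int& N) {
  IntegerVector d(x.attr("dim"));
  if (d.size() != 3) stop("expected array of dim (H, W, N)");
  H = d[0]; W = d[1]; N = d[2];
  fcube out(H * W, 1, N);
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = (float)x[i];
  return out;
}

// [[Rcpp::export]]
List cpp_unet_forward(List params, NumericVector x, bool gatesOn = true,
                      bool returnAlphas = false, double alphaOverride = NA_REAL) {
  int step; Net net = netFromR(params, step);
  int H, W, N;
  fcube X = rToCube3(x, H, W, N);
  FwdCache fc;
  List alphas;
  netFwd(net, fc, X, H, W, false, gatesOn, alphaOverride,
         false, returnAlphas ? &alphas : nullptr);
  NumericVector p(fc.probs.n_elem);
  for (arma::uword i = 0; i < fc.probs.n_elem; ++i) p[i] = fc.probs(i);
  p.attr("dim") = IntegerVector::create(H, W, N);
  if (returnAlphas) return List::create(_["probs"] = p, _["alphas"] = alphas);
  return List::create(_["probs"] = p);
}

// One pass over the supplied batches (an epoch): forward in training
// mode, binary cross-entropy on the sigmoid head, backprop, Adam update.
// `batches` is a (batchSize x nIter) matrix of 1-based slice indices.
// [[Rcpp::export]]
List cpp_unet_train_epoch(List params, NumericVector x, NumericVector y,
                          IntegerMatrix batches, double lr,
                          double beta1 = 0.9, double beta2 = 0.999,
                          double eps = 1e-8) {
  int step; Net net = netFromR(params, step);
  int H, W, N;
  fcube X = rToCube3(x, H, W, N);
  int Hy, Wy, Ny;
  fcube Y = rToCube3(y, Hy, Wy, Ny);
  if (Hy != H || Wy != W || Ny != N) stop("image/label array shape mismatch");
  const int B = batches.nrow(), nIter = batches.ncol();
  NumericVector losses(nIter);
  for (int it = 0; it < nIter; ++it) {
    fcube Xb(H * W, 1, B), Yb(H * W, 1, B);
    for (int b = 0; b < B; ++b) {
      const int s = batches(b, it) - 1;
      if (s < 0 || s >= N) stop("batch index out of range");
      Xb.slice(b) = X.slice(s);
      Yb.slice(b) = Y.slice(s);
    }
    FwdCache fc;
    fcube z = netFwd(net, fc, Xb, H, W, true, true, NA_REAL, true, nullptr);
    // BCE from logits: softplus(-z) + (1-y) z, averaged
    double loss = 0;
    for (arma::uword i = 0; i < z.n_elem; ++i) {
      const double zi = z(i), yi = Yb(i);
      const double sp = zi > 0 ? std::log1p(std::exp(-zi))
                               : -zi + std::log1p(std::exp(zi));
      loss += sp + (1.0 - yi) * zi;
    }
    const double scale = 1.0 / z.n_elem;
    loss *= scale;
    if (!std::isfinite(loss))
      stop("non-finite training loss at iteration " + std::to_string(it + 1));
    losses[it] = loss;
    fcube dZ = (fc.probs - Yb) * (float)scale;
    zeroGrads(net);
    netBwd(net, fc, dZ, H, W, true);
    ++step;
    adamStep(net, lr, beta1, beta2, eps, step);
  }
  return List::create(_["params"] = netToR(net, step), _["losses"] = losses);
}
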