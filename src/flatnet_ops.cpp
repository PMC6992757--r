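// Core numerical kernels: fp32 im2col/col2im convolution stack for the
// pooling-free dilated-bank network, its backward pass under the MAE loss,
// and the Gaussian-profile curve rasterizer used by the phantom generator.
//
// Layout conventions (must match the R side):
//  * images/feature maps are HW x C matrices, pixel index p = row + col*H
//    (column-major within the frame), 0-based rows/cols;
//  * im2col column order: (channel c, kernel col j, kernel row i) ->
//    column (c*k + j)*k + i; weight matrices follow the same row order;
//  * per-subnet weight list order:
//      for each branch b: W1_b, b1_b, W2_b, b2_b
//      then W4, b4, W5, b5, W6, b6, W7, b7.
//
// All large intermediates live in a persistent workspace reused across
// calls: fresh multi-hundred-MB allocations per training step would cost
// more in page faults than the GEMMs themselves.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

static void im2col(const fmat& X, int H, int W, int k, int d, fmat& P) {
  const int C = X.n_cols, R = k / 2;
  P.zeros(static_cast<arma::uword>(H) * W, static_cast<arma::uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    for (int j = 0; j < k; ++j) {
      const int dx = (j - R) * d;
      for (int i = 0; i < k; ++i) {
        const int dy = (i - R) * d;
        float* pc = P.colptr((static_cast<arma::uword>(c) * k + j) * k + i);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        if (r1 <= r0) continue;
        for (int cc = 0; cc < W; ++cc) {
          const int cs = cc + dx;
          if (cs < 0 || cs >= W) continue;
          std::memcpy(pc + static_cast<size_t>(cc) * H + r0,
                      xc + static_cast<size_t>(cs) * H + r0 + dy,
                      static_cast<size_t>(r1 - r0) * sizeof(float));
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add patch gradients back onto the input grid
static void col2im_add(const fmat& dP, int H, int W, int k, int d, fmat& dX) {
  const int C = dX.n_cols, R = k / 2;
  for (int c = 0; c < C; ++c) {
    float* xc = dX.colptr(c);
    for (int j = 0; j < k; ++j) {
      const int dx = (j - R) * d;
      for (int i = 0; i < k; ++i) {
        const int dy = (i - R) * d;
        const float* pc = dP.colptr((static_cast<arma::uword>(c) * k + j) * k + i);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        if (r1 <= r0) continue;
        for (int cc = 0; cc < W; ++cc) {
          const int cs = cc + dx;
          if (cs < 0 || cs >= W) continue;
          const float* src = pc + static_cast<size_t>(cc) * H + r0;
          float* dst = xc + static_cast<size_t>(cs) * H + r0 + dy;
          const int n = r1 - r0;
          for (int r = 0; r < n; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

static void relu_inplace(fmat& A) {
  float* p = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = p[i] > 0.f ? p[i] : 0.f;
}

// zero entries of G where the forward ReLU output A was inactive
static void relu_mask(fmat& G, const fmat& A) {
  float* g = G.memptr();
  const float* a = A.memptr();
  const size_t n = G.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0.f) g[i] = 0.f;
}

static void as_fmat_into(SEXP m, fmat& out) {
  NumericMatrix nm(m);
  out.set_size(nm.nrow(), nm.ncol());
  const double* src = REAL(nm);
  float* dst = out.memptr();
  const size_t n = static_cast<size_t>(nm.nrow()) * nm.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

static fmat as_fmat(SEXP m) {
  fmat out;
  as_fmat_into(m, out);
  return out;
}

static NumericMatrix as_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  double* dst = REAL(out);
  const float* src = m.memptr();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<double>(src[i]);
  return out;
}

struct NetWeights {
  int nb;
  std::vector<fmat> W1, W2;
  std::vector<frowvec> b1, b2;
  fmat W4, W5, W6, W7;
  frowvec b4, b5, b6, b7;
};

static frowvec as_frow(SEXP m) {
  fmat f = as_fmat(m);
  return frowvec(f.memptr(), f.n_elem);
}

static NetWeights unpack_weights(List weights, int nb) {
  NetWeights nw;
  nw.nb = nb;
  int idx = 0;
  for (int b = 0; b < nb; ++b) {
    nw.W1.push_back(as_fmat(weights[idx++]));
    nw.b1.push_back(as_frow(weights[idx++]));
    nw.W2.push_back(as_fmat(weights[idx++]));
    nw.b2.push_back(as_frow(weights[idx++]));
  }
  nw.W4 = as_fmat(weights[idx++]); nw.b4 = as_frow(weights[idx++]);
  nw.W5 = as_fmat(weights[idx++]); nw.b5 = as_frow(weights[idx++]);
  nw.W6 = as_fmat(weights[idx++]); nw.b6 = as_frow(weights[idx++]);
  nw.W7 = as_fmat(weights[idx++]); nw.b7 = as_frow(weights[idx++]);
  return nw;
}

// persistent buffers; reused across calls (shapes adjust via set_size)
struct Workspace {
  fmat X, T;
  std::vector<fmat> P1, A1, P2, A2, dP2, dA1;
  fmat A3, P4, A4, A5, A6, Out;
  fmat dZ7, dA6, dA5, dA4, dP4, dA3, dA2;
  void branches(int nb) {
    if (static_cast<int>(P1.size()) != nb) {
      P1.assign(nb, fmat()); A1.assign(nb, fmat());
      P2.assign(nb, fmat()); A2.assign(nb, fmat());
      dP2.assign(nb, fmat()); dA1.assign(nb, fmat());
    }
  }
};
static Workspace ws;

// forward pass into the workspace; patch matrices kept only when training
static void forward_net(const fmat& X, int H, int W, const NetWeights& nw,
                        const std::vector<int>& dil, int k1, int k4,
                        bool keep) {
  const int nb = nw.nb;
  const arma::uword HW = static_cast<arma::uword>(H) * W;
  ws.branches(nb);
  arma::uword f2tot = 0;
  for (int b = 0; b < nb; ++b) {
    im2col(X, H, W, k1, dil[b], ws.P1[b]);
    ws.A1[b] = ws.P1[b] * nw.W1[b];
    ws.A1[b].each_row() += nw.b1[b];
    relu_inplace(ws.A1[b]);
    im2col(ws.A1[b], H, W, k1, dil[b], ws.P2[b]);
    ws.A2[b] = ws.P2[b] * nw.W2[b];
    ws.A2[b].each_row() += nw.b2[b];
    relu_inplace(ws.A2[b]);
    f2tot += ws.A2[b].n_cols;
  }
  ws.A3.set_size(HW, f2tot);
  arma::uword off = 0;
  for (int b = 0; b < nb; ++b) {
    ws.A3.cols(off, off + ws.A2[b].n_cols - 1) = ws.A2[b];
    off += ws.A2[b].n_cols;
  }
  im2col(ws.A3, H, W, k4, 1, ws.P4);
  ws.A4 = ws.P4 * nw.W4; ws.A4.each_row() += nw.b4; relu_inplace(ws.A4);
  ws.A5 = ws.A4 * nw.W5; ws.A5.each_row() += nw.b5; relu_inplace(ws.A5);
  ws.A6 = ws.A5 * nw.W6; ws.A6.each_row() += nw.b6; relu_inplace(ws.A6);
  ws.Out = ws.A6 * nw.W7; ws.Out.each_row() += nw.b7;
  ws.Out = arma::tanh(ws.Out);
  (void)keep;
}

// [[Rcpp::export]]
NumericMatrix fn_forward(List weights, NumericMatrix image, int H, int W,
                         IntegerVector dilations, int k1 = 9, int k4 = 5) {
  std::vector<int> dil(dilations.begin(), dilations.end());
  NetWeights nw = unpack_weights(weights, dil.size());
  as_fmat_into(image, ws.X);
  forward_net(ws.X, H, W, nw, dil, k1, k4, false);
  return as_rmat(ws.Out);
}

// One optimisation step's worth of gradients for a mini-batch, under the
// mean-absolute-error loss between tanh outputs and target heat-maps.
// Returns the mean loss and gradients (averaged over the batch) in the
// same order as `weights`.
// [[Rcpp::export]]
List fn_step(List weights, List images, List targets, int H, int W,
             IntegerVector dilations, int k1 = 9, int k4 = 5) {
  std::vector<int> dil(dilations.begin(), dilations.end());
  const int nb = dil.size();
  NetWeights nw = unpack_weights(weights, nb);
  const int nbatch = images.size();

  std::vector<fmat> gW1(nb), gW2(nb);
  std::vector<frowvec> gb1(nb), gb2(nb);
  for (int b = 0; b < nb; ++b) {
    gW1[b].zeros(nw.W1[b].n_rows, nw.W1[b].n_cols);
    gW2[b].zeros(nw.W2[b].n_rows, nw.W2[b].n_cols);
    gb1[b].zeros(nw.b1[b].n_elem);
    gb2[b].zeros(nw.b2[b].n_elem);
  }
  fmat gW4(arma::size(nw.W4), arma::fill::zeros), gW5(arma::size(nw.W5), arma::fill::zeros),
       gW6(arma::size(nw.W6), arma::fill::zeros), gW7(arma::size(nw.W7), arma::fill::zeros);
  frowvec gb4(nw.b4.n_elem, arma::fill::zeros), gb5(nw.b5.n_elem, arma::fill::zeros),
          gb6(nw.b6.n_elem, arma::fill::zeros), gb7(nw.b7.n_elem, arma::fill::zeros);

  double loss = 0.0;
  const float scale = 1.0f / nbatch;

  for (int s = 0; s < nbatch; ++s) {
    as_fmat_into(images[s], ws.X);
    as_fmat_into(targets[s], ws.T);
    forward_net(ws.X, H, W, nw, dil, k1, k4, true);

    // loss and dL/dZ7 = sign(Out - T) * (1 - Out^2) / n, fused elementwise
    {
      const size_t n = ws.Out.n_elem;
      ws.dZ7.set_size(ws.Out.n_rows, ws.Out.n_cols);
      const float* o = ws.Out.memptr();
      const float* t = ws.T.memptr();
      float* dz = ws.dZ7.memptr();
      double acc = 0.0;
      const float g = scale / n;
      for (size_t i = 0; i < n; ++i) {
        const float e = o[i] - t[i];
        acc += std::fabs(e);
        const float sgn = (e > 0.f) - (e < 0.f);
        dz[i] = sgn * (1.f - o[i] * o[i]) * g;
      }
      loss += acc / n;
    }

    gW7 += ws.A6.t() * ws.dZ7;        gb7 += arma::sum(ws.dZ7, 0);
    ws.dA6 = ws.dZ7 * nw.W7.t();      relu_mask(ws.dA6, ws.A6);
    gW6 += ws.A5.t() * ws.dA6;        gb6 += arma::sum(ws.dA6, 0);
    ws.dA5 = ws.dA6 * nw.W6.t();      relu_mask(ws.dA5, ws.A5);
    gW5 += ws.A4.t() * ws.dA5;        gb5 += arma::sum(ws.dA5, 0);
    ws.dA4 = ws.dA5 * nw.W5.t();      relu_mask(ws.dA4, ws.A4);
    gW4 += ws.P4.t() * ws.dA4;        gb4 += arma::sum(ws.dA4, 0);
    ws.dP4 = ws.dA4 * nw.W4.t();
    ws.dA3.zeros(arma::size(ws.A3));
    col2im_add(ws.dP4, H, W, k4, 1, ws.dA3);

    arma::uword off = 0;
    for (int b = 0; b < nb; ++b) {
      const arma::uword f2 = ws.A2[b].n_cols;
      ws.dA2 = ws.dA3.cols(off, off + f2 - 1);
      off += f2;
      relu_mask(ws.dA2, ws.A2[b]);
      gW2[b] += ws.P2[b].t() * ws.dA2;  gb2[b] += arma::sum(ws.dA2, 0);
      ws.dP2[b] = ws.dA2 * nw.W2[b].t();
      ws.dA1[b].zeros(arma::size(ws.A1[b]));
      col2im_add(ws.dP2[b], H, W, k1, dil[b], ws.dA1[b]);
      relu_mask(ws.dA1[b], ws.A1[b]);
      gW1[b] += ws.P1[b].t() * ws.dA1[b]; gb1[b] += arma::sum(ws.dA1[b], 0);
      // input gradient not needed (first layer)
    }
  }

  List grads(4 * nb + 8);
  int idx = 0;
  for (int b = 0; b < nb; ++b) {
    grads[idx++] = as_rmat(gW1[b]);
    grads[idx++] = as_rmat(fmat(gb1[b]));
    grads[idx++] = as_rmat(gW2[b]);
    grads[idx++] = as_rmat(fmat(gb2[b]));
  }
  grads[idx++] = as_rmat(gW4); grads[idx++] = as_rmat(fmat(gb4));
  grads[idx++] = as_rmat(gW5); grads[idx++] = as_rmat(fmat(gb5));
  grads[idx++] = as_rmat(gW6); grads[idx++] = as_rmat(fmat(gb6));
  grads[idx++] = as_rmat(gW7); grads[idx++] = as_rmat(fmat(gb7));
  return List::create(_["loss"] = loss / nbatch, _["grads"] = grads);
}

// Release the persistent numerical workspace (e.g. after training).
// [[Rcpp::export]]
void fn_release_workspace() {
  ws = Workspace();
}

// Rasterize sampled curve points as bright Gaussian-profile strokes:
// canvas <- max(canvas, peak * exp(-d^2 / (2 width^2))) over all samples,
// evaluated within a 3.5*width window around each sample. Coordinates are
// 0-based (x = column, y = row).
// [[Rcpp::export]]
NumericMatrix render_curves(NumericMatrix canvas, NumericVector x, NumericVector y,
                            double width, double peak) {
  NumericMatrix out = clone(canvas);
  const int H = out.nrow(), W = out.ncol();
  const int rad = static_cast<int>(std::ceil(3.5 * width));
  const double inv2w2 = 1.0 / (2.0 * width * width);
  for (int s = 0; s < x.size(); ++s) {
    const double xs = x[s], ys = y[s];
    const int c0 = std::max(0, static_cast<int>(std::floor(xs)) - rad);
    const int c1 = std::min(W - 1, static_cast<int>(std::ceil(xs)) + rad);
    const int r0 = std::max(0, static_cast<int>(std::floor(ys)) - rad);
    const int r1 = std::min(H - 1, static_cast<int>(std::ceil(ys)) + rad);
    for (int c = c0; c <= c1; ++c) {
      const double dx2 = (c - xs) * (c - xs);
      for (int r = r0; r <= r1; ++r) {
        const double d2 = dx2 + (r - ys) * (r - ys);
        const double v = peak * std::exp(-d2 * inv2w2);
        if (v > out(r, c)) out(r, c) = v;
      }
    }
  }
  return out;
}
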