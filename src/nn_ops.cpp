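// Minimal sequential CNN engine: forward/backward passes for the layer
// types used by the reconstruction autoencoder and the WGAN-GP / izif
// networks.  Images are vectorized column-major as H x W x C (R array
// layout); a batch is a matrix with one sample per column.
//
// Layer descriptors (R lists): type one of conv|relu|lrelu|sigmoid|pool|
// dense|tconv, with dims h, w, cin, cout (conv/pool/tconv) or din, dout
// (dense).  conv = 3x3, stride 1, zero pad 1 (same size); pool = 2x2 max,
// stride 2; tconv = 2x2 transposed conv, stride 2 (doubles h and w).
// Parameters live in one flat vector, laid out layer by layer
// (weights then bias), so a truncated prefix of a network's parameter
// vector parameterizes its truncated layer list (used for the
// discriminator-feature subnetwork).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Layer {
  std::string type;
  int H = 0, W = 0, Cin = 0, Cout = 0, Din = 0, Dout = 0;
};

static int geti(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) return 0;
  return as<int>(l[nm]);
}

static std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> out;
  out.reserve(layers.size());
  for (R_xlen_t i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    Layer L;
    L.type = as<std::string>(l["type"]);
    L.H = geti(l, "h"); L.W = geti(l, "w");
    L.Cin = geti(l, "cin"); L.Cout = geti(l, "cout");
    L.Din = geti(l, "din"); L.Dout = geti(l, "dout");
    out.push_back(L);
  }
  return out;
}

static void layer_param_sizes(const Layer& L, size_t& nw, size_t& nb, size_t& fan_in) {
  nw = 0; nb = 0; fan_in = 0;
  if (L.type == "conv") {
    nw = (size_t)L.Cout * L.Cin * 9; nb = L.Cout; fan_in = (size_t)L.Cin * 9;
  } else if (L.type == "dense") {
    nw = (size_t)L.Dout * L.Din; nb = L.Dout; fan_in = L.Din;
  } else if (L.type == "tconv") {
    nw = (size_t)L.Cout * L.Cin * 4; nb = L.Cout; fan_in = L.Cin;
  }
}

// cols: (H*W) x (Cin*9); column r = c*9 + ki*3 + kj holds input pixel
// (i + ki - 1, j + kj - 1) for output pixel q = i + H*j.
static void im2col3(const double* x, int H, int W, int C, mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    for (int ki = 0; ki < 3; ++ki) {
      int i0 = std::max(0, 1 - ki), i1 = std::min(H, H + 1 - ki);
      if (i1 <= i0) continue;
      for (int kj = 0; kj < 3; ++kj) {
        int r = c * 9 + ki * 3 + kj;
        double* dst0 = cols.colptr(r);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          const double* src = plane + (size_t)H * jj + (i0 + ki - 1);
          std::copy(src, src + (i1 - i0), dst0 + (size_t)H * j + i0);
        }
      }
    }
  }
}

static void col2im3(const mat& dcols, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* plane = dx + (size_t)c * H * W;
    for (int ki = 0; ki < 3; ++ki) {
      int i0 = std::max(0, 1 - ki), i1 = std::min(H, H + 1 - ki);
      if (i1 <= i0) continue;
      for (int kj = 0; kj < 3; ++kj) {
        int r = c * 9 + ki * 3 + kj;
        const double* src0 = dcols.colptr(r);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          double* dst = plane + (size_t)H * jj + (i0 + ki - 1);
          const double* src = src0 + (size_t)H * j + i0;
          for (int t = 0; t < i1 - i0; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List nn_param_info_cpp(List layerspec) {
  std::vector<Layer> Ls = parse_layers(layerspec);
  int n = Ls.size();
  IntegerVector off(n), wsize(n), bsize(n), fanin(n);
  size_t cur = 0;
  for (int i = 0; i < n; ++i) {
    size_t nw, nb, fi;
    layer_param_sizes(Ls[i], nw, nb, fi);
    off[i] = (int)cur; wsize[i] = (int)nw; bsize[i] = (int)nb; fanin[i] = (int)fi;
    cur += nw + nb;
  }
  return List::create(_["offset"] = off, _["wsize"] = wsize,
                      _["bsize"] = bsize, _["fan_in"] = fanin,
                      _["n_params"] = (double)cur);
}

// [[Rcpp::export]]
List nn_forward_cpp(List layerspec, const arma::vec& params, const arma::mat& X,
                    bool keep_cache = true) {
  std::vector<Layer> Ls = parse_layers(layerspec);
  int nl = Ls.size(), B = X.n_cols;
  List caches(nl), poolidx(nl);
  mat cur = X;
  size_t off = 0;
  for (int li = 0; li < nl; ++li) {
    const Layer& L = Ls[li];
    size_t nw, nb, fi;
    layer_param_sizes(L, nw, nb, fi);
    if (L.type == "conv") {
      if (keep_cache) caches[li] = cur;
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Cout, (size_t)L.Cin * 9, false, true);
      const vec bv(const_cast<double*>(params.memptr()) + off + nw, nb, false, true);
      size_t HW = (size_t)L.H * L.W;
      mat out(HW * L.Cout, B);
      mat cols(HW, (size_t)L.Cin * 9);
      for (int s = 0; s < B; ++s) {
        im2col3(cur.colptr(s), L.H, L.W, L.Cin, cols);
        mat o = cols * Wm.t();            // HW x Cout
        o.each_row() += bv.t();
        std::copy(o.memptr(), o.memptr() + o.n_elem, out.colptr(s));
      }
      cur = std::move(out);
    } else if (L.type == "dense") {
      if (keep_cache) caches[li] = cur;
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Dout, L.Din, false, true);
      const vec bv(const_cast<double*>(params.memptr()) + off + nw, nb, false, true);
      mat out = Wm * cur;
      out.each_col() += bv;
      cur = std::move(out);
    } else if (L.type == "tconv") {
      if (keep_cache) caches[li] = cur;
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Cout, (size_t)L.Cin * 4, false, true);
      const vec bv(const_cast<double*>(params.memptr()) + off + nw, nb, false, true);
      int H = L.H, W = L.W, H2 = 2 * H, W2 = 2 * W;
      size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
      mat out(HW2 * L.Cout, B);
      for (int s = 0; s < B; ++s) {
        const mat inm(const_cast<double*>(cur.colptr(s)), HW, L.Cin, false, true);
        double* op = out.colptr(s);
        for (size_t k = 0; k < HW2 * (size_t)L.Cout; ++k) op[k] = 0.0;
        for (int t = 0; t < 4; ++t) {
          int a = t % 2, b = t / 2;   // row / col offsets
          mat Yt = inm * Wm.cols((size_t)t * L.Cin, (size_t)t * L.Cin + L.Cin - 1).t(); // HW x Cout
          for (int c = 0; c < L.Cout; ++c) {
            const double* yc = Yt.colptr(c);
            double* oc = op + (size_t)c * HW2;
            for (int j = 0; j < W; ++j) {
              const double* ycol = yc + (size_t)H * j;
              double* ocol = oc + (size_t)H2 * (2 * j + b) + a;
              for (int i = 0; i < H; ++i) ocol[2 * i] += ycol[i];
            }
          }
        }
        for (int c = 0; c < L.Cout; ++c) {
          double* oc = op + (size_t)c * HW2;
          for (size_t k = 0; k < HW2; ++k) oc[k] += bv[c];
        }
      }
      cur = std::move(out);
    } else if (L.type == "pool") {
      int H = L.H, W = L.W, C = L.Cin, H2 = H / 2, W2 = W / 2;
      size_t osz = (size_t)H2 * W2 * C;
      mat out(osz, B);
      umat idx(osz, B);
      for (int s = 0; s < B; ++s) {
        const double* xp = cur.colptr(s);
        double* op = out.colptr(s);
        uword* ip = idx.colptr(s);
        size_t q = 0;
        for (int c = 0; c < C; ++c) {
          const double* plane = xp + (size_t)c * H * W;
          size_t poff = (size_t)c * H * W;
          for (int j2 = 0; j2 < W2; ++j2) {
            for (int i2 = 0; i2 < H2; ++i2) {
              size_t k00 = (size_t)(2 * j2) * H + 2 * i2;
              size_t cand[4] = {k00, k00 + 1, k00 + (size_t)H, k00 + (size_t)H + 1};
              size_t best = cand[0];
              double bv_ = plane[cand[0]];
              for (int u = 1; u < 4; ++u)
                if (plane[cand[u]] > bv_) { bv_ = plane[cand[u]]; best = cand[u]; }
              // output layout: i2 + H2*j2 + H2*W2*c
              size_t oq = (size_t)i2 + (size_t)H2 * j2 + (size_t)H2 * W2 * c;
              op[oq] = bv_;
              ip[oq] = (uword)(poff + best);
              ++q;
            }
          }
        }
        (void)q;
      }
      poolidx[li] = idx;
      cur = std::move(out);
    } else if (L.type == "relu") {
      if (keep_cache) caches[li] = cur;
      cur.transform([](double v) { return v > 0 ? v : 0.0; });
    } else if (L.type == "lrelu") {
      if (keep_cache) caches[li] = cur;
      cur.transform([](double v) { return v > 0 ? v : 0.2 * v; });
    } else if (L.type == "sigmoid") {
      cur.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      if (keep_cache) caches[li] = cur;  // cache output
    } else {
      stop("unknown layer type: %s", L.type.c_str());
    }
    off += nw + nb;
  }
  return List::create(_["out"] = cur, _["caches"] = caches, _["poolidx"] = poolidx);
}

// [[Rcpp::export]]
List nn_backward_cpp(List layerspec, const arma::vec& params, List caches,
                     List poolidx, const arma::mat& dOut, bool want_dx = true) {
  std::vector<Layer> Ls = parse_layers(layerspec);
  int nl = Ls.size(), B = dOut.n_cols;
  std::vector<size_t> offs(nl), nws(nl), nbs(nl);
  size_t total = 0;
  for (int i = 0; i < nl; ++i) {
    size_t nw, nb, fi;
    layer_param_sizes(Ls[i], nw, nb, fi);
    offs[i] = total; nws[i] = nw; nbs[i] = nb;
    total += nw + nb;
  }
  vec dparams(total, fill::zeros);
  mat dcur = dOut;
  for (int li = nl - 1; li >= 0; --li) {
    const Layer& L = Ls[li];
    size_t off = offs[li], nw = nws[li];
    bool need_dx = want_dx || li > 0;
    if (L.type == "conv") {
      mat X = caches[li];
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Cout, (size_t)L.Cin * 9, false, true);
      size_t HW = (size_t)L.H * L.W;
      mat dW(L.Cout, (size_t)L.Cin * 9, fill::zeros);
      vec db(L.Cout, fill::zeros);
      mat dX;
      if (need_dx) dX.zeros((size_t)L.H * L.W * L.Cin, B);
      mat cols(HW, (size_t)L.Cin * 9);
      for (int s = 0; s < B; ++s) {
        const mat dM(const_cast<double*>(dcur.colptr(s)), HW, L.Cout, false, true);
        im2col3(X.colptr(s), L.H, L.W, L.Cin, cols);
        dW += dM.t() * cols;
        db += sum(dM, 0).t();
        if (need_dx) {
          mat dcols = dM * Wm;  // HW x Cin*9
          col2im3(dcols, L.H, L.W, L.Cin, dX.colptr(s));
        }
      }
      std::copy(dW.memptr(), dW.memptr() + nw, dparams.memptr() + off);
      std::copy(db.memptr(), db.memptr() + nbs[li], dparams.memptr() + off + nw);
      if (need_dx) dcur = std::move(dX); else dcur.reset();
    } else if (L.type == "dense") {
      mat X = caches[li];
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Dout, L.Din, false, true);
      mat dW = dcur * X.t();
      vec db = sum(dcur, 1);
      std::copy(dW.memptr(), dW.memptr() + nw, dparams.memptr() + off);
      std::copy(db.memptr(), db.memptr() + nbs[li], dparams.memptr() + off + nw);
      if (need_dx) dcur = Wm.t() * dcur; else dcur.reset();
    } else if (L.type == "tconv") {
      mat X = caches[li];
      const mat Wm(const_cast<double*>(params.memptr()) + off, L.Cout, (size_t)L.Cin * 4, false, true);
      int H = L.H, W = L.W, H2 = 2 * H, W2 = 2 * W;
      size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
      mat dW(L.Cout, (size_t)L.Cin * 4, fill::zeros);
      vec db(L.Cout, fill::zeros);
      mat dX;
      if (need_dx) dX.zeros(HW * L.Cin, B);
      mat dYt(HW, L.Cout);
      for (int s = 0; s < B; ++s) {
        const double* dp = dcur.colptr(s);
        const mat inm(const_cast<double*>(X.colptr(s)), HW, L.Cin, false, true);
        // bias gradient: sum over all output pixels
        for (int c = 0; c < L.Cout; ++c) {
          const double* oc = dp + (size_t)c * HW2;
          double acc = 0;
          for (size_t k = 0; k < HW2; ++k) acc += oc[k];
          db[c] += acc;
        }
        mat dinm;
        if (need_dx) dinm.zeros(HW, L.Cin);
        for (int t = 0; t < 4; ++t) {
          int a = t % 2, b = t / 2;
          for (int c = 0; c < L.Cout; ++c) {
            const double* oc = dp + (size_t)c * HW2;
            double* yc = dYt.colptr(c);
            for (int j = 0; j < W; ++j) {
              const double* ocol = oc + (size_t)H2 * (2 * j + b) + a;
              double* ycol = yc + (size_t)H * j;
              for (int i = 0; i < H; ++i) ycol[i] = ocol[2 * i];
            }
          }
          dW.cols((size_t)t * L.Cin, (size_t)t * L.Cin + L.Cin - 1) += dYt.t() * inm;
          if (need_dx) dinm += dYt * Wm.cols((size_t)t * L.Cin, (size_t)t * L.Cin + L.Cin - 1);
        }
        if (need_dx) std::copy(dinm.memptr(), dinm.memptr() + dinm.n_elem, dX.colptr(s));
      }
      std::copy(dW.memptr(), dW.memptr() + nw, dparams.memptr() + off);
      std::copy(db.memptr(), db.memptr() + nbs[li], dparams.memptr() + off + nw);
      if (need_dx) dcur = std::move(dX); else dcur.reset();
    } else if (L.type == "pool") {
      umat idx = poolidx[li];
      int H = L.H, W = L.W, C = L.Cin;
      mat dX(( size_t)H * W * C, B, fill::zeros);
      for (int s = 0; s < B; ++s) {
        const double* dp = dcur.colptr(s);
        const uword* ip = idx.colptr(s);
        double* xp = dX.colptr(s);
        size_t n = idx.n_rows;
        for (size_t k = 0; k < n; ++k) xp[ip[k]] += dp[k];
      }
      dcur = std::move(dX);
    } else if (L.type == "relu") {
      mat X = caches[li];
      dcur %= conv_to<mat>::from(X > 0);
    } else if (L.type == "lrelu") {
      mat X = caches[li];
      mat m = conv_to<mat>::from(X > 0);
      dcur %= (m + 0.2 * (1.0 - m));
    } else if (L.type == "sigmoid") {
      mat Y = caches[li];  // cached output
      dcur %= Y % (1.0 - Y);
    }
  }
  return List::create(_["dparams"] = dparams, _["dx"] = dcur);
}
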