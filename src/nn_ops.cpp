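// Forward inference and backpropagation for the position-classifier
// architectures: stacks of valid convolutions (full or per-map channel
// connectivity), 2x2 max-pooling, ReLU dense layers and a softmax output.
// Feature maps are arma::cube (rows = image rows, cols = image columns,
// slices = maps); flattening order (column-major within slice, slices last)
// matches R's array order, so weights round-trip unchanged.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

enum LayerKind { INPUT, CONV, POOL, DENSE, SOFTMAX };

struct LayerDef {
  LayerKind kind;
  int kh = 0, kw = 0, maps = 0;
  bool permap = false;
  int n = 0;      // dense/softmax width
  int h = 0, w = 0; // input only
};

struct LayerPar {
  // conv: W as cube; full connectivity uses slice index c + cin*m,
  // per-map uses slice index m. dense/softmax: Wd (n_out x n_in).
  cube W;
  mat Wd;
  vec b;
  int cin = 1;
};

std::vector<LayerDef> parse_spec(const List& spec) {
  std::vector<LayerDef> defs;
  for (int i = 0; i < spec.size(); ++i) {
    List ly = spec[i];
    std::string ty = as<std::string>(ly["type"]);
    LayerDef d;
    if (ty == "input") {
      d.kind = INPUT;
      d.h = as<int>(ly["h"]);
      d.w = as<int>(ly["w"]);
    } else if (ty == "conv") {
      d.kind = CONV;
      d.kh = as<int>(ly["kh"]);
      d.kw = as<int>(ly["kw"]);
      d.maps = as<int>(ly["maps"]);
      d.permap = as<std::string>(ly["connectivity"]) == "per_map";
    } else if (ty == "maxpool") {
      d.kind = POOL;
    } else if (ty == "dense") {
      d.kind = DENSE;
      d.n = as<int>(ly["n"]);
    } else if (ty == "softmax") {
      d.kind = SOFTMAX;
      d.n = as<int>(ly["n"]);
    } else {
      stop("unknown layer type: %s", ty);
    }
    defs.push_back(d);
  }
  return defs;
}

// params is a list with one element per trainable layer, in network order;
// trainable layers are conv/dense/softmax. Each element has $W and $b.
std::vector<LayerPar> parse_params(const std::vector<LayerDef>& defs,
                                   const List& params) {
  std::vector<LayerPar> pars(defs.size());
  int pi = 0;
  for (size_t i = 0; i < defs.size(); ++i) {
    const LayerDef& d = defs[i];
    if (d.kind == CONV) {
      List lp = params[pi++];
      NumericVector wv = lp["W"];
      NumericVector bv = lp["b"];
      IntegerVector dim = wv.attr("dim");
      int nsl;
      if (d.permap) {
        nsl = d.maps;
        pars[i].cin = d.maps;
      } else {
        // R array (kh, kw, cin, maps)
        pars[i].cin = dim[2];
        nsl = pars[i].cin * d.maps;
      }
      pars[i].W = cube(wv.begin(), d.kh, d.kw, nsl);
      pars[i].b = vec(bv.begin(), bv.size());
    } else if (d.kind == DENSE || d.kind == SOFTMAX) {
      List lp = params[pi++];
      NumericMatrix wm = lp["W"];
      NumericVector bv = lp["b"];
      pars[i].Wd = mat(wm.begin(), wm.nrow(), wm.ncol());
      pars[i].b = vec(bv.begin(), bv.size());
    }
  }
  return pars;
}

struct Cache {
  cube in;          // layer input (conv, pool)
  cube pre;         // conv pre-activation (for ReLU mask)
  Cube<uword> idx;  // pool argmax (linear index within input slice)
  vec din;          // dense input
  vec dpre;         // dense pre-activation
  uword in_h = 0, in_w = 0, in_c = 0;
};

// Forward pass; fills caches when `keep` is true. Returns softmax probs.
vec forward_net(const std::vector<LayerDef>& defs,
                const std::vector<LayerPar>& pars, const mat& img,
                std::vector<Cache>& caches, bool keep) {
  cube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  bool is_vec = false;
  vec curv;
  if (defs.empty() || defs[0].kind != INPUT)
    stop("spec must start with an input layer");
  if ((int)img.n_rows != defs[0].h || (int)img.n_cols != defs[0].w)
    stop("image is %dx%d but the network expects %dx%d (rows x cols)",
         (int)img.n_rows, (int)img.n_cols, defs[0].h, defs[0].w);
  for (size_t i = 1; i < defs.size(); ++i) {
    const LayerDef& d = defs[i];
    Cache& C = caches[i];
    if (d.kind == CONV) {
      int hin = cur.n_rows, win = cur.n_cols;
      int ho = hin - d.kh + 1, wo = win - d.kw + 1;
      if (ho < 1 || wo < 1) stop("conv kernel larger than its feature map");
      cube z(ho, wo, d.maps, fill::zeros);
      const LayerPar& p = pars[i];
      for (int m = 0; m < d.maps; ++m) {
        if (d.permap) {
          if ((int)cur.n_slices != d.maps)
            stop("per-map conv needs as many input maps as feature maps");
          const mat& K = p.W.slice(m);
          for (int a = 0; a < d.kh; ++a)
            for (int b = 0; b < d.kw; ++b)
              z.slice(m) += K(a, b) *
                cur.slice(m).submat(a, b, a + ho - 1, b + wo - 1);
        } else {
          for (uword c = 0; c < cur.n_slices; ++c) {
            const mat& K = p.W.slice(c + cur.n_slices * m);
            for (int a = 0; a < d.kh; ++a)
              for (int b = 0; b < d.kw; ++b)
                z.slice(m) += K(a, b) *
                  cur.slice(c).submat(a, b, a + ho - 1, b + wo - 1);
          }
        }
        z.slice(m) += p.b(m);
      }
      if (keep) { C.in = cur; C.pre = z; }
      cur = clamp(z, 0.0, datum::inf); // ReLU
    } else if (d.kind == POOL) {
      int hin = cur.n_rows, win = cur.n_cols, cs = cur.n_slices;
      if (hin % 2 || win % 2) stop("2x2 pooling needs even feature-map sides");
      int ho = hin / 2, wo = win / 2;
      cube out(ho, wo, cs);
      Cube<uword> idx(ho, wo, cs);
      for (int s = 0; s < cs; ++s) {
        const mat& S = cur.slice(s);
        for (int j = 0; j < wo; ++j) {
          for (int i2 = 0; i2 < ho; ++i2) {
            uword r = 2 * i2, c0 = 2 * j;
            double v = S(r, c0); uword best = r + hin * c0;
            if (S(r + 1, c0) > v)     { v = S(r + 1, c0);     best = r + 1 + hin * c0; }
            if (S(r, c0 + 1) > v)     { v = S(r, c0 + 1);     best = r + hin * (c0 + 1); }
            if (S(r + 1, c0 + 1) > v) { v = S(r + 1, c0 + 1); best = r + 1 + hin * (c0 + 1); }
            out(i2, j, s) = v;
            idx(i2, j, s) = best;
          }
        }
      }
      if (keep) {
        C.idx = idx;
        C.in_h = hin; C.in_w = win; C.in_c = cs;
      }
      cur = out;
    } else if (d.kind == DENSE || d.kind == SOFTMAX) {
      vec x = is_vec ? curv : vectorise(cur);
      const LayerPar& p = pars[i];
      if (p.Wd.n_cols != x.n_elem)
        stop("dense layer expects %d inputs, got %d", (int)p.Wd.n_cols,
             (int)x.n_elem);
      vec z = p.Wd * x + p.b;
      if (keep) { C.din = x; C.dpre = z; }
      if (d.kind == DENSE) {
        curv = clamp(z, 0.0, datum::inf);
      } else {
        double m = z.max();
        vec e = exp(z - m);
        curv = e / accu(e);
      }
      is_vec = true;
    }
  }
  return curv;
}

// Backward pass for one sample; accumulates parameter gradients.
void backward_net(const std::vector<LayerDef>& defs,
                  const std::vector<LayerPar>& pars,
                  const std::vector<Cache>& caches, const vec& probs,
                  int target0, std::vector<LayerPar>& grads) {
  vec d = probs;
  d(target0) -= 1.0; // d loss / d softmax-preactivation
  bool d_is_vec = true;
  cube dc;
  for (int i = (int)defs.size() - 1; i >= 1; --i) {
    const LayerDef& def = defs[i];
    const Cache& C = caches[i];
    if (def.kind == SOFTMAX || def.kind == DENSE) {
      if (def.kind == DENSE) d = d % (C.dpre > 0); // ReLU mask
      grads[i].Wd += d * C.din.t();
      grads[i].b += d;
      d = pars[i].Wd.t() * d;
      d_is_vec = true;
    } else if (def.kind == POOL) {
      uword ho = C.idx.n_rows, wo = C.idx.n_cols, cs = C.idx.n_slices;
      cube dout;
      if (d_is_vec) {
        dout = cube(d.memptr(), ho, wo, cs);
        d_is_vec = false;
      } else {
        dout = dc;
      }
      cube din(C.in_h, C.in_w, C.in_c, fill::zeros);
      for (uword s = 0; s < cs; ++s) {
        mat& DS = din.slice(s);
        for (uword j = 0; j < wo; ++j)
          for (uword i2 = 0; i2 < ho; ++i2)
            DS(C.idx(i2, j, s)) += dout(i2, j, s);
      }
      dc = din;
    } else if (def.kind == CONV) {
      uword ho = C.pre.n_rows, wo = C.pre.n_cols;
      cube dout;
      if (d_is_vec) {
        dout = cube(d.memptr(), ho, wo, def.maps);
        d_is_vec = false;
      } else {
        dout = dc;
      }
      uword cin = C.in.n_slices;
      cube din(C.in.n_rows, C.in.n_cols, cin, fill::zeros);
      for (int m = 0; m < def.maps; ++m) {
        mat D = dout.slice(m) % (C.pre.slice(m) > 0); // ReLU mask
        grads[i].b(m) += accu(D);
        if (def.permap) {
          mat& gK = grads[i].W.slice(m);
          const mat& K = pars[i].W.slice(m);
          for (int a = 0; a < def.kh; ++a)
            for (int b = 0; b < def.kw; ++b) {
              gK(a, b) += accu(
                C.in.slice(m).submat(a, b, a + ho - 1, b + wo - 1) % D);
              din.slice(m).submat(a, b, a + ho - 1, b + wo - 1) += K(a, b) * D;
            }
        } else {
          for (uword c = 0; c < cin; ++c) {
            mat& gK = grads[i].W.slice(c + cin * m);
            const mat& K = pars[i].W.slice(c + cin * m);
            for (int a = 0; a < def.kh; ++a)
              for (int b = 0; b < def.kw; ++b) {
                gK(a, b) += accu(
                  C.in.slice(c).submat(a, b, a + ho - 1, b + wo - 1) % D);
                din.slice(c).submat(a, b, a + ho - 1, b + wo - 1) += K(a, b) * D;
              }
          }
        }
      }
      dc = din;
    }
  }
}

std::vector<LayerPar> zero_like(const std::vector<LayerDef>& defs,
                                const std::vector<LayerPar>& pars) {
  std::vector<LayerPar> g(defs.size());
  for (size_t i = 0; i < defs.size(); ++i) {
    if (defs[i].kind == CONV) {
      g[i].W = cube(size(pars[i].W), fill::zeros);
      g[i].b = vec(size(pars[i].b), fill::zeros);
    } else if (defs[i].kind == DENSE || defs[i].kind == SOFTMAX) {
      g[i].Wd = mat(size(pars[i].Wd), fill::zeros);
      g[i].b = vec(size(pars[i].b), fill::zeros);
    }
  }
  return g;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".nn_forward_cpp")]]
NumericVector nn_forward_cpp(List spec, List params, NumericMatrix image) {
  std::vector<LayerDef> defs = parse_spec(spec);
  std::vector<LayerPar> pars = parse_params(defs, params);
  mat img(image.begin(), image.nrow(), image.ncol());
  std::vector<Cache> caches(defs.size());
  vec p = forward_net(defs, pars, img, caches, false);
  return NumericVector(p.begin(), p.end());
}

//' @noRd
// [[Rcpp::export(name = ".nn_predict_cpp")]]
IntegerVector nn_predict_cpp(List spec, List params, List images) {
  std::vector<LayerDef> defs = parse_spec(spec);
  std::vector<LayerPar> pars = parse_params(defs, params);
  int n = images.size();
  IntegerVector out(n);
  std::vector<Cache> caches(defs.size());
  for (int i = 0; i < n; ++i) {
    NumericMatrix im = images[i];
    mat img(im.begin(), im.nrow(), im.ncol());
    vec p = forward_net(defs, pars, img, caches, false);
    out[i] = (int)p.index_max() + 1; // 1-based class; first max wins ties
  }
  return out;
}

// Mean cross-entropy loss, batch-averaged gradients and exact-class hits
// over a mini-batch. `targets` are 1-based class indices.
//' @noRd
// [[Rcpp::export(name = ".nn_batch_grad_cpp")]]
List nn_batch_grad_cpp(List spec, List params, List images,
                       IntegerVector targets, bool compute_grad = true) {
  std::vector<LayerDef> defs = parse_spec(spec);
  std::vector<LayerPar> pars = parse_params(defs, params);
  int n = images.size();
  if (n == 0) stop("empty mini-batch");
  if (targets.size() != n) stop("targets must match the number of images");
  std::vector<LayerPar> grads;
  if (compute_grad) grads = zero_like(defs, pars);
  double loss = 0.0;
  int hits = 0;
  for (int s = 0; s < n; ++s) {
    NumericMatrix im = images[s];
    mat img(im.begin(), im.nrow(), im.ncol());
    std::vector<Cache> caches(defs.size());
    vec p = forward_net(defs, pars, img, caches, compute_grad);
    int t0 = targets[s] - 1;
    if (t0 < 0 || t0 >= (int)p.n_elem) stop("target class out of range");
    loss += -std::log(std::max(p(t0), 1e-12));
    if ((int)p.index_max() == t0) ++hits;
    if (compute_grad) backward_net(defs, pars, caches, p, t0, grads);
  }
  loss /= n;
  List gout;
  if (compute_grad) {
    // divide by n and serialize back in trainable-layer order, with the
    // same array shapes the R side supplied
    List glist;
    int pi = 0;
    for (size_t i = 0; i < defs.size(); ++i) {
      if (defs[i].kind == CONV) {
        List lp = params[pi++];
        NumericVector wv = clone(as<NumericVector>(lp["W"]));
        NumericVector bv = clone(as<NumericVector>(lp["b"]));
        grads[i].W /= n; grads[i].b /= n;
        std::copy(grads[i].W.begin(), grads[i].W.end(), wv.begin());
        std::copy(grads[i].b.begin(), grads[i].b.end(), bv.begin());
        glist.push_back(List::create(_["W"] = wv, _["b"] = bv));
      } else if (defs[i].kind == DENSE || defs[i].kind == SOFTMAX) {
        List lp = params[pi++];
        NumericVector wv = clone(as<NumericVector>(lp["W"]));
        NumericVector bv = clone(as<NumericVector>(lp["b"]));
        grads[i].Wd /= n; grads[i].b /= n;
        std::copy(grads[i].Wd.begin(), grads[i].Wd.end(), wv.begin());
        std::copy(grads[i].b.begin(), grads[i].b.end(), bv.begin());
        glist.push_back(List::create(_["W"] = wv, _["b"] = bv));
      }
    }
    gout = glist;
  }
  return List::create(_["loss"] = loss, _["hits"] = hits,
                      _["grads"] = gout);
}
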