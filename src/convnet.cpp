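// Small residual convolutional regression backbone with multi-stage
// supervision: the terminal activation of every residual stage is globally
// average-pooled and concatenated into the flattened feature vector feeding
// the linear regression head. All convolutions are 3x3 with zero padding 1;
// the stem and each stage entry convolution use stride 2.
//
// Parameters live in one flat numeric vector in a fixed canonical order
// (stem, then per stage: downsample / conv1 / conv2, then head); the R side
// obtains the layout from cpp_param_info() and owns initialization and the
// Adam update, so checkpoints are plain numeric vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline int conv_out_dim(int n, int stride) {
  // kernel 3, pad 1: floor((n + 2 - 3) / stride) + 1
  return (n - 1) / stride + 1;
}

// im2col for a 3x3 kernel, pad 1. Row index = ox * Ho + oy (column-major
// over the output map); column index = c * 9 + ky * 3 + kx.
static mat im2col3(const cube& x, int stride, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(static_cast<size_t>(Ho) * Wo, 9 * static_cast<size_t>(C),
          arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int col = c * 9 + ky * 3 + kx;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride + kx - 1;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ky - 1;
            if (iy < 0 || iy >= H) continue;
            out(static_cast<size_t>(ox) * Ho + oy, col) = x(iy, ix, c);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back onto the input.
static cube col2im3(const mat& gcols, int H, int W, int C, int stride,
                    int Ho, int Wo) {
  cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int col = c * 9 + ky * 3 + kx;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride + kx - 1;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ky - 1;
            if (iy < 0 || iy >= H) continue;
            gx(iy, ix, c) += gcols(static_cast<size_t>(ox) * Ho + oy, col);
          }
        }
      }
    }
  }
  return gx;
}

// Wt: (9*Cin) x Cout. Returns Ho x Wo x Cout; stores the im2col matrix.
static cube conv3(const cube& x, const mat& Wt, const vec& b, int stride,
                  mat& cols) {
  const int Ho = conv_out_dim(x.n_rows, stride);
  const int Wo = conv_out_dim(x.n_cols, stride);
  cols = im2col3(x, stride, Ho, Wo);
  mat o = cols * Wt;  // (Ho*Wo) x Cout
  o.each_row() += b.t();
  cube out(Ho, Wo, Wt.n_cols);
  for (arma::uword oc = 0; oc < Wt.n_cols; ++oc)
    out.slice(oc) = arma::reshape(o.col(oc), Ho, Wo);
  return out;
}

// Backward through conv3. gout: Ho x Wo x Cout. Accumulates gW, gb;
// returns gradient w.r.t. the conv input (dims H, W, Cin).
static cube conv3_back(const cube& gout, const mat& cols, const mat& Wt,
                       mat& gW, vec& gb, int H, int W, int Cin, int stride) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat gm(static_cast<size_t>(Ho) * Wo, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    gm.col(oc) = arma::vectorise(gout.slice(oc));
  gW += cols.t() * gm;
  gb += arma::sum(gm, 0).t();
  mat gcols = gm * Wt.t();
  return col2im3(gcols, H, W, Cin, stride, Ho, Wo);
}

static inline cube relu(const cube& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct NetShape {
  int stem_ch;
  std::vector<int> stage_ch;
  int n_out;
};

static NetShape parse_cfg(const List& cfg) {
  NetShape s;
  s.stem_ch = as<int>(cfg["stem_ch"]);
  IntegerVector sc = cfg["stage_ch"];
  s.stage_ch = std::vector<int>(sc.begin(), sc.end());
  s.n_out = as<int>(cfg["n_out"]);
  if (s.stem_ch < 1 || s.stage_ch.empty() || s.n_out < 1)
    stop("invalid network configuration");
  return s;
}

struct LayerDim { int r, c; std::string name; };

static std::vector<LayerDim> layer_dims(const NetShape& s) {
  std::vector<LayerDim> d;
  d.push_back({9, s.stem_ch, "stem_W"});
  d.push_back({s.stem_ch, 1, "stem_b"});
  int prev = s.stem_ch, feat = 0;
  for (size_t i = 0; i < s.stage_ch.size(); ++i) {
    const int c = s.stage_ch[i];
    const std::string tag = "stage" + std::to_string(i + 1);
    d.push_back({9 * prev, c, tag + "_down_W"});
    d.push_back({c, 1, tag + "_down_b"});
    d.push_back({9 * c, c, tag + "_c1_W"});
    d.push_back({c, 1, tag + "_c1_b"});
    d.push_back({9 * c, c, tag + "_c2_W"});
    d.push_back({c, 1, tag + "_c2_b"});
    prev = c;
    feat += c;
  }
  d.push_back({feat, s.n_out, "head_W"});
  d.push_back({s.n_out, 1, "head_b"});
  return d;
}

// Non-owning views into the flat parameter (or gradient) vector.
struct ParamRefs {
  mat stemW; vec stemb;
  std::vector<mat> downW; std::vector<vec> downb;
  std::vector<mat> c1W;  std::vector<vec> c1b;
  std::vector<mat> c2W;  std::vector<vec> c2b;
  mat headW; vec headb;
};

static ParamRefs bind_params(double* p, const NetShape& s, size_t len) {
  std::vector<LayerDim> dims = layer_dims(s);
  size_t need = 0;
  for (auto& d : dims) need += static_cast<size_t>(d.r) * d.c;
  if (len != need)
    stop("parameter vector has length %d, expected %d", (int)len, (int)need);
  ParamRefs P;
  size_t off = 0;
  auto take_mat = [&](int r, int c) {
    mat m(p + off, r, c, false, true);
    off += static_cast<size_t>(r) * c;
    return m;
  };
  auto take_vec = [&](int r) {
    vec v(p + off, r, false, true);
    off += r;
    return v;
  };
  // reserve up front: vector reallocation would deep-copy the aliased
  // matrices and detach them from the flat buffer
  const size_t S = s.stage_ch.size();
  P.downW.reserve(S); P.downb.reserve(S);
  P.c1W.reserve(S); P.c1b.reserve(S);
  P.c2W.reserve(S); P.c2b.reserve(S);
  P.stemW = take_mat(9, s.stem_ch);
  P.stemb = take_vec(s.stem_ch);
  int prev = s.stem_ch;
  for (size_t i = 0; i < s.stage_ch.size(); ++i) {
    const int c = s.stage_ch[i];
    P.downW.push_back(take_mat(9 * prev, c));
    P.downb.push_back(take_vec(c));
    P.c1W.push_back(take_mat(9 * c, c));
    P.c1b.push_back(take_vec(c));
    P.c2W.push_back(take_mat(9 * c, c));
    P.c2b.push_back(take_vec(c));
    prev = c;
  }
  int feat = 0;
  for (int c : s.stage_ch) feat += c;
  P.headW = take_mat(feat, s.n_out);
  P.headb = take_vec(s.n_out);
  return P;
}

struct Acts {
  cube a0;
  mat cols0;
  std::vector<cube> d, r1, r2pre, so;
  std::vector<mat> colsD, cols1, cols2;
  vec feats;
  vec out;
};

static void net_forward_one(const ParamRefs& P, const NetShape& s,
                            const mat& img, Acts& A) {
  const int S = static_cast<int>(s.stage_ch.size());
  cube x0(img.n_rows, img.n_cols, 1);
  x0.slice(0) = img;
  A.a0 = relu(conv3(x0, P.stemW, P.stemb, 2, A.cols0));
  A.d.resize(S); A.r1.resize(S); A.r2pre.resize(S); A.so.resize(S);
  A.colsD.resize(S); A.cols1.resize(S); A.cols2.resize(S);
  const cube* cur = &A.a0;
  int feat = 0;
  for (int i = 0; i < S; ++i) feat += s.stage_ch[i];
  A.feats.set_size(feat);
  int fo = 0;
  for (int i = 0; i < S; ++i) {
    A.d[i] = relu(conv3(*cur, P.downW[i], P.downb[i], 2, A.colsD[i]));
    A.r1[i] = relu(conv3(A.d[i], P.c1W[i], P.c1b[i], 1, A.cols1[i]));
    A.r2pre[i] = conv3(A.r1[i], P.c2W[i], P.c2b[i], 1, A.cols2[i]);
    A.so[i] = relu(A.r2pre[i] + A.d[i]);
    for (int c = 0; c < s.stage_ch[i]; ++c)
      A.feats(fo + c) = arma::accu(A.so[i].slice(c)) /
        (A.so[i].n_rows * A.so[i].n_cols);
    fo += s.stage_ch[i];
    cur = &A.so[i];
  }
  A.out = P.headW.t() * A.feats + P.headb;
}

// Backward from (dout, dfeats_extra). Accumulates into G.
static void net_backward_one(const ParamRefs& P, ParamRefs& G,
                             const NetShape& s, const mat& img,
                             const Acts& A, const vec& dout,
                             const vec& dfeats_extra) {
  const int S = static_cast<int>(s.stage_ch.size());
  vec dfeats = dfeats_extra;
  if (arma::any(arma::abs(dout) > 0)) {
    G.headW += A.feats * dout.t();
    G.headb += dout;
    dfeats += P.headW * dout;
  }
  // Split pooled-feature gradient per stage.
  std::vector<vec> dgap(S);
  int fo = 0;
  for (int i = 0; i < S; ++i) {
    dgap[i] = dfeats.subvec(fo, fo + s.stage_ch[i] - 1);
    fo += s.stage_ch[i];
  }
  cube dcur;  // gradient flowing into stage i's output from stage i+1
  for (int i = S - 1; i >= 0; --i) {
    const cube& so = A.so[i];
    cube dso(so.n_rows, so.n_cols, so.n_slices, arma::fill::zeros);
    if (i < S - 1) dso = dcur;
    const double inv_area = 1.0 / (so.n_rows * so.n_cols);
    for (arma::uword c = 0; c < so.n_slices; ++c)
      dso.slice(c) += dgap[i](c) * inv_area;
    cube dsum = dso % arma::conv_to<cube>::from(so > 0);
    // r2pre branch
    cube dr1 = conv3_back(dsum, A.cols2[i], P.c2W[i], G.c2W[i], G.c2b[i],
                          A.r1[i].n_rows, A.r1[i].n_cols, s.stage_ch[i], 1);
    dr1 %= arma::conv_to<cube>::from(A.r1[i] > 0);
    cube dd = conv3_back(dr1, A.cols1[i], P.c1W[i], G.c1W[i], G.c1b[i],
                         A.d[i].n_rows, A.d[i].n_cols, s.stage_ch[i], 1);
    dd += dsum;  // skip connection
    dd %= arma::conv_to<cube>::from(A.d[i] > 0);
    const cube& prev = (i == 0) ? A.a0 : A.so[i - 1];
    const int prev_c = (i == 0) ? s.stem_ch : s.stage_ch[i - 1];
    dcur = conv3_back(dd, A.colsD[i], P.downW[i], G.downW[i], G.downb[i],
                      prev.n_rows, prev.n_cols, prev_c, 2);
  }
  cube da0 = dcur % arma::conv_to<cube>::from(A.a0 > 0);
  mat dummyW(9, s.stem_ch, arma::fill::zeros);
  conv3_back(da0, A.cols0, P.stemW, G.stemW, G.stemb,
             img.n_rows, img.n_cols, 1, 2);
}

// [[Rcpp::export]]
List cpp_param_info(List cfg) {
  NetShape s = parse_cfg(cfg);
  std::vector<LayerDim> dims = layer_dims(s);
  const int n = static_cast<int>(dims.size());
  CharacterVector name(n);
  IntegerVector nr(n), nc(n);
  size_t total = 0;
  int feat = 0;
  for (int c : s.stage_ch) feat += c;
  for (int i = 0; i < n; ++i) {
    name[i] = dims[i].name;
    nr[i] = dims[i].r;
    nc[i] = dims[i].c;
    total += static_cast<size_t>(dims[i].r) * dims[i].c;
  }
  return List::create(_["name"] = name, _["nrow"] = nr, _["ncol"] = nc,
                      _["n_params"] = static_cast<double>(total),
                      _["feat_dim"] = feat);
}

// [[Rcpp::export]]
List cpp_net_forward(NumericVector params, List cfg, arma::cube xb) {
  NetShape s = parse_cfg(cfg);
  ParamRefs P = bind_params(params.begin(), s, params.size());
  const int N = xb.n_slices;
  int feat = 0;
  for (int c : s.stage_ch) feat += c;
  mat out(N, s.n_out), feats(N, feat);
  Acts A;
  for (int i = 0; i < N; ++i) {
    net_forward_one(P, s, xb.slice(i), A);
    out.row(i) = A.out.t();
    feats.row(i) = A.feats.t();
  }
  return List::create(_["out"] = out, _["feats"] = feats);
}

// Mean squared error over all outputs and samples; returns loss and the
// gradient of the mean loss w.r.t. the flat parameter vector.
// [[Rcpp::export]]
List cpp_net_grad_mse(NumericVector params, List cfg, arma::cube xb,
                      arma::mat targets) {
  NetShape s = parse_cfg(cfg);
  ParamRefs P = bind_params(params.begin(), s, params.size());
  const int N = xb.n_slices;
  if ((int)targets.n_rows != N || (int)targets.n_cols != s.n_out)
    stop("targets must be n_samples x n_out");
  NumericVector gflat(params.size());
  ParamRefs G = bind_params(gflat.begin(), s, gflat.size());
  double loss = 0.0;
  Acts A;
  const double scale = 1.0 / (static_cast<double>(N) * s.n_out);
  for (int i = 0; i < N; ++i) {
    net_forward_one(P, s, xb.slice(i), A);
    vec resid = A.out - targets.row(i).t();
    loss += arma::dot(resid, resid) * scale;
    vec dout = 2.0 * resid * scale;
    vec zf(A.feats.n_elem, arma::fill::zeros);
    net_backward_one(P, G, s, xb.slice(i), A, dout, zf);
  }
  return List::create(_["loss"] = loss, _["grad"] = gflat);
}

// Backprop an externally supplied gradient on the pooled multi-stage
// features (used by the contrastive pretraining head, which lives in R).
// [[Rcpp::export]]
NumericVector cpp_net_grad_feats(NumericVector params, List cfg,
                                 arma::cube xb, arma::mat featgrad) {
  NetShape s = parse_cfg(cfg);
  ParamRefs P = bind_params(params.begin(), s, params.size());
  const int N = xb.n_slices;
  int feat = 0;
  for (int c : s.stage_ch) feat += c;
  if ((int)featgrad.n_rows != N || (int)featgrad.n_cols != feat)
    stop("featgrad must be n_samples x feat_dim");
  NumericVector gflat(params.size());
  ParamRefs G = bind_params(gflat.begin(), s, gflat.size());
  Acts A;
  vec zout(s.n_out, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    net_forward_one(P, s, xb.slice(i), A);
    net_backward_one(P, G, s, xb.slice(i), A, zout, featgrad.row(i).t());
  }
  return gflat;
}
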