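// Capsule-network core: convolutional motif detectors -> (global max pool)
// -> primary capsules -> squash -> affine transform -> dynamic routing ->
// two digit capsules.  Trained by backprop through the unrolled routing
// iterations with a margin loss and Adam.
//
// Sequences arrive as integer code matrices (one row per fragment):
// 0=A, 1=T, 2=C, 3=G (the one-hot column order), 4=N.  N rows are all-zero
// in the one-hot picture, so the convolution simply skips them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::vec;
using arma::mat;
using arma::cube;


struct Config {
  int L, h, K, dIn, dOut, nClass, T;
  bool maxpool;
  double mPlus, mMinus, lambda;
  int P;  // feature-map length L - h + 1
  int n;  // number of primary capsules
  // 0: coupling softmax over the n input capsules, per output capsule
  //    (the default reading); 1: softmax over the output capsules per
  //    input capsule (the Sabour et al. convention)
  int softmaxAxis;
};

static int cfgList_has_axis(const List& cfg) {
  if (!cfg.containsElementNamed("softmaxAxis")) return 0;
  RObject v = cfg["softmaxAxis"];
  if (is<CharacterVector>(v))
    return as<std::string>(v) == "outputs" ? 1 : 0;
  return as<int>(v);
}

static Config parse_config(const List& cfg) {
  Config c;
  c.L = as<int>(cfg["L"]);
  c.h = as<int>(cfg["h"]);
  c.K = as<int>(cfg["K"]);
  c.dIn = as<int>(cfg["dIn"]);
  c.dOut = as<int>(cfg["dOut"]);
  c.nClass = as<int>(cfg["nClass"]);
  c.T = as<int>(cfg["T"]);
  c.maxpool = as<bool>(cfg["maxpool"]);
  c.mPlus = as<double>(cfg["mPlus"]);
  c.mMinus = as<double>(cfg["mMinus"]);
  c.lambda = as<double>(cfg["lambda"]);
  if (c.L < c.h) stop("fragment length L is smaller than the kernel size h");
  if (c.K % c.dIn != 0) stop("filter count K must be a multiple of the capsule dimension");
  if (c.T < 1) stop("routing iterations T must be >= 1");
  c.softmaxAxis = cfgList_has_axis(cfg);
  c.P = c.L - c.h + 1;
  c.n = c.maxpool ? (c.K / c.dIn) : (c.K / c.dIn) * c.P;
  return c;
}

struct Model {
  cube convW;  // h x 4 x K
  vec convB;   // K
  cube capsW;  // dOut x dIn x (n * nClass), slice = class*n + i
};

static Model parse_model(const List& w, const Config& c) {
  Model m;
  NumericVector cw = w["convW"];
  IntegerVector cwd = cw.attr("dim");
  if (cwd[0] != c.h || cwd[1] != 4 || cwd[2] != c.K)
    stop("convW dimensions do not match the model configuration");
  m.convW = cube(cw.begin(), c.h, 4, c.K);
  m.convB = as<vec>(w["convB"]);
  if ((int)m.convB.n_elem != c.K) stop("convB length mismatch");
  NumericVector aw = w["capsW"];
  IntegerVector awd = aw.attr("dim");
  if (awd[0] != c.dOut || awd[1] != c.dIn || awd[2] != c.n * c.nClass)
    stop("capsW dimensions do not match the model configuration (check maxpool/L)");
  m.capsW = cube(aw.begin(), c.dOut, c.dIn, c.n * c.nClass);
  return m;
}

static List model_to_list(const Model& m) {
  NumericVector cw(m.convW.begin(), m.convW.end());
  cw.attr("dim") = IntegerVector::create(m.convW.n_rows, m.convW.n_cols, m.convW.n_slices);
  NumericVector aw(m.capsW.begin(), m.capsW.end());
  aw.attr("dim") = IntegerVector::create(m.capsW.n_rows, m.capsW.n_cols, m.capsW.n_slices);
  return List::create(_["convW"] = cw,
                      _["convB"] = NumericVector(m.convB.begin(), m.convB.end()),
                      _["capsW"] = aw);
}

// ---- squash -------------------------------------------------------------

// v_out = (r^2/(1+r^2)) a/r written as a * r/(1+r^2): exact, no division
// by the norm, and the zero vector maps to the zero vector
static vec squash_fwd(const vec& a) {
  double r2 = arma::dot(a, a);
  return a * (std::sqrt(r2) / (1.0 + r2));
}

static vec squash_bwd(const vec& a, const vec& gv) {
  double r2 = arma::dot(a, a);
  double r = std::sqrt(r2);
  if (r < 1e-12) return arma::zeros<vec>(a.n_elem);
  double s = r / (1.0 + r2);
  double sp = (1.0 - r2) / ((1.0 + r2) * (1.0 + r2));
  return s * gv + (sp / r) * arma::dot(a, gv) * a;
}

// ---- dynamic routing ----------------------------------------------------

struct RouteCache {
  mat C;  // n x T couplings per round
  mat A;  // dOut x T weighted aggregates
  mat V;  // dOut x T squashed outputs
};

static void route_fwd(const mat& U, int T, RouteCache& rc) {
  int n = U.n_cols;
  rc.C.set_size(n, T);
  rc.A.set_size(U.n_rows, T);
  rc.V.set_size(U.n_rows, T);
  vec b = arma::zeros<vec>(n);
  for (int t = 0; t < T; ++t) {
    vec e = arma::exp(b - b.max());
    vec c = e / arma::accu(e);
    vec a = U * c;
    vec v = squash_fwd(a);
    rc.C.col(t) = c;
    rc.A.col(t) = a;
    rc.V.col(t) = v;
    b += U.t() * v;
  }
}

// Reverse pass through the unrolled routing rounds.  gvT is dLoss/d v^T.
static mat route_bwd(const mat& U, const RouteCache& rc, const vec& gvT, int T) {
  int n = U.n_cols;
  mat gU(U.n_rows, n, arma::fill::zeros);
  vec gb = arma::zeros<vec>(n);  // grad wrt b_t (b_T is never used downstream)
  for (int t = T - 1; t >= 0; --t) {
    vec gvt = (t == T - 1) ? gvT : arma::zeros<vec>(U.n_rows);
    // b_t = b_{t-1} + U' v^t
    gvt += U * gb;
    gU += rc.V.col(t) * gb.t();
    vec ga = squash_bwd(rc.A.col(t), gvt);
    // a^t = U c^t
    vec gc = U.t() * ga;
    gU += ga * rc.C.col(t).t();
    // c^t = softmax(b_{t-1}); identity pass-through of gb plus softmax term
    gb += rc.C.col(t) % (gc - arma::dot(rc.C.col(t), gc));
  }
  return gU;
}

// ---- joint routing (softmax over output capsules) -----------------------
//
// The alternative coupling convention: each input capsule's logits are
// softmaxed across the J output capsules, so the classes compete for each
// input's vote.  U holds u_{ij} as column j*n + i.

struct JointCache {
  std::vector<mat> C;  // per round: n x J couplings
  std::vector<mat> Av; // per round: dOut x J aggregates
  std::vector<mat> Vv; // per round: dOut x J outputs
};

static void route_joint_fwd(const mat& U, int n, int J, int T, JointCache& jc) {
  jc.C.resize(T); jc.Av.resize(T); jc.Vv.resize(T);
  mat B(n, J, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat C(n, J);
    for (int i = 0; i < n; ++i) {
      arma::rowvec e = arma::exp(B.row(i) - B.row(i).max());
      C.row(i) = e / arma::accu(e);
    }
    mat A(U.n_rows, J, arma::fill::zeros), V(U.n_rows, J);
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < n; ++i) A.col(j) += C(i, j) * U.col(j * n + i);
      V.col(j) = squash_fwd(A.col(j));
    }
    jc.C[t] = C; jc.Av[t] = A; jc.Vv[t] = V;
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < n; ++i)
        B(i, j) += arma::dot(V.col(j), U.col(j * n + i));
  }
}

static mat route_joint_bwd(const mat& U, int n, int J, int T,
                           const JointCache& jc, const mat& gvT) {
  mat gU(U.n_rows, U.n_cols, arma::fill::zeros);
  mat gB(n, J, arma::fill::zeros);  // B_T is unused downstream
  for (int t = T - 1; t >= 0; --t) {
    const mat& C = jc.C[t];
    mat gV = (t == T - 1) ? gvT : mat(U.n_rows, J, arma::fill::zeros);
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < n; ++i) {
        gV.col(j) += gB(i, j) * U.col(j * n + i);
        gU.col(j * n + i) += gB(i, j) * jc.Vv[t].col(j);
      }
    mat gC(n, J);
    for (int j = 0; j < J; ++j) {
      vec ga = squash_bwd(jc.Av[t].col(j), gV.col(j));
      for (int i = 0; i < n; ++i) {
        gC(i, j) = arma::dot(ga, U.col(j * n + i));
        gU.col(j * n + i) += C(i, j) * ga;
      }
    }
    for (int i = 0; i < n; ++i) {
      double dotcg = arma::dot(C.row(i), gC.row(i));
      gB.row(i) += C.row(i) % (gC.row(i) - dotcg);
    }
  }
  return gU;
}

// ---- margin loss --------------------------------------------------------

static double margin_loss(const vec& s, int label, const Config& c, vec& gs) {
  double L = 0.0;
  gs.set_size(s.n_elem);
  for (arma::uword k = 0; k < s.n_elem; ++k) {
    double Tc = (label == (int)k) ? 1.0 : 0.0;
    double pos = std::max(0.0, c.mPlus - s(k));
    double neg = std::max(0.0, s(k) - c.mMinus);
    L += Tc * pos * pos + c.lambda * (1.0 - Tc) * neg * neg;
    gs(k) = -2.0 * Tc * pos + 2.0 * c.lambda * (1.0 - Tc) * neg;
  }
  return L;
}

// ---- per-sample forward (+ optional backward) ---------------------------

struct Grads {
  cube convW;
  vec convB;
  cube capsW;
  void zero_like(const Model& m) {
    convW.zeros(m.convW.n_rows, m.convW.n_cols, m.convW.n_slices);
    convB.zeros(m.convB.n_elem);
    capsW.zeros(m.capsW.n_rows, m.capsW.n_cols, m.capsW.n_slices);
  }
};

static double sample_pass(const Model& M, const Config& c, const int* codes,
                          int label, bool doGrad, Grads* G, vec* scoresOut) {
  const int P = c.P, K = c.K, h = c.h, dIn = c.dIn, n = c.n, nC = c.nClass;

  // convolution + ReLU
  mat conf(P, K);
  for (int k = 0; k < K; ++k) {
    const double b = M.convB(k);
    for (int p = 0; p < P; ++p) {
      double z = b;
      for (int j = 0; j < h; ++j) {
        int cc = codes[p + j];
        if (cc < 4) z += M.convW(j, cc, k);
      }
      conf(p, k) = z > 0.0 ? z : 0.0;
    }
  }

  // primary capsule pre-squash vectors
  mat S(dIn, n, arma::fill::zeros);
  arma::ivec argp(K, arma::fill::zeros);
  if (c.maxpool) {
    for (int k = 0; k < K; ++k) {
      double best = conf(0, k);
      int bp = 0;
      for (int p = 1; p < P; ++p)
        if (conf(p, k) > best) { best = conf(p, k); bp = p; }  // leftmost tie
      argp(k) = bp;
      S(k % dIn, k / dIn) = best;
    }
  } else {
    for (int k = 0; k < K; ++k) {
      int g = k / dIn, r = k % dIn;
      for (int p = 0; p < P; ++p) S(r, g * P + p) = conf(p, k);
    }
  }

  mat Pc(dIn, n);
  for (int i = 0; i < n; ++i) Pc.col(i) = squash_fwd(S.col(i));

  // affine transform to digit-capsule space
  mat U(c.dOut, n * nC);
  for (int j = 0; j < nC; ++j)
    for (int i = 0; i < n; ++i)
      U.col(j * n + i) = M.capsW.slice(j * n + i) * Pc.col(i);

  // dynamic routing into the digit capsules
  std::vector<RouteCache> rc(nC);
  JointCache jc;
  vec s(nC);
  if (c.softmaxAxis == 0) {
    for (int j = 0; j < nC; ++j) {
      route_fwd(U.cols(j * n, j * n + n - 1), c.T, rc[j]);
      s(j) = arma::norm(rc[j].V.col(c.T - 1));
    }
  } else {
    route_joint_fwd(U, n, nC, c.T, jc);
    for (int j = 0; j < nC; ++j) s(j) = arma::norm(jc.Vv[c.T - 1].col(j));
  }
  if (scoresOut) *scoresOut = s;

  vec gs;
  double loss = margin_loss(s, label, c, gs);
  if (!doGrad) return loss;

  // backward
  mat gPc(dIn, n, arma::fill::zeros);
  if (c.softmaxAxis == 0) {
    for (int j = 0; j < nC; ++j) {
      vec vT = rc[j].V.col(c.T - 1);
      vec gv = (s(j) > 1e-12) ? vec((gs(j) / s(j)) * vT)
                              : arma::zeros<vec>(c.dOut);
      mat Uj = U.cols(j * n, j * n + n - 1);
      mat gU = route_bwd(Uj, rc[j], gv, c.T);
      for (int i = 0; i < n; ++i) {
        G->capsW.slice(j * n + i) += gU.col(i) * Pc.col(i).t();
        gPc.col(i) += M.capsW.slice(j * n + i).t() * gU.col(i);
      }
    }
  } else {
    mat gvT(c.dOut, nC, arma::fill::zeros);
    for (int j = 0; j < nC; ++j)
      if (s(j) > 1e-12) gvT.col(j) = (gs(j) / s(j)) * jc.Vv[c.T - 1].col(j);
    mat gU = route_joint_bwd(U, n, nC, c.T, jc, gvT);
    for (int j = 0; j < nC; ++j)
      for (int i = 0; i < n; ++i) {
        G->capsW.slice(j * n + i) += gU.col(j * n + i) * Pc.col(i).t();
        gPc.col(i) += M.capsW.slice(j * n + i).t() * gU.col(j * n + i);
      }
  }

  mat gS(dIn, n);
  for (int i = 0; i < n; ++i) gS.col(i) = squash_bwd(S.col(i), gPc.col(i));

  // back through pooling + ReLU into the convolution weights
  if (c.maxpool) {
    for (int k = 0; k < K; ++k) {
      int bp = argp(k);
      if (conf(bp, k) <= 0.0) continue;  // ReLU gate (all-zero map)
      double g = gS(k % dIn, k / dIn);
      if (g == 0.0) continue;
      G->convB(k) += g;
      for (int j = 0; j < h; ++j) {
        int cc = codes[bp + j];
        if (cc < 4) G->convW(j, cc, k) += g;
      }
    }
  } else {
    for (int k = 0; k < K; ++k) {
      int gcap = k / dIn, r = k % dIn;
      for (int p = 0; p < P; ++p) {
        if (conf(p, k) <= 0.0) continue;
        double g = gS(r, gcap * P + p);
        if (g == 0.0) continue;
        G->convB(k) += g;
        for (int j = 0; j < h; ++j) {
          int cc = codes[p + j];
          if (cc < 4) G->convW(j, cc, k) += g;
        }
      }
    }
  }
  return loss;
}

static std::vector<int> row_codes(const IntegerMatrix& codes, int i) {
  std::vector<int> out(codes.ncol());
  for (int j = 0; j < codes.ncol(); ++j) out[j] = codes(i, j);
  return out;
}

// ---- exported entry points ----------------------------------------------

// [[Rcpp::export(name = ".capsForwardCpp")]]
NumericMatrix caps_forward_cpp(IntegerMatrix codes, List weights, List cfgList) {
  Config c = parse_config(cfgList);
  if (codes.ncol() != c.L) stop("sequence length does not match the model's fragment length");
  Model m = parse_model(weights, c);
  int N = codes.nrow();
  NumericMatrix out(N, c.nClass);
  vec s;
  for (int i = 0; i < N; ++i) {
    std::vector<int> cd = row_codes(codes, i);
    sample_pass(m, c, cd.data(), 0, false, nullptr, &s);
    for (int j = 0; j < c.nClass; ++j) out(i, j) = s(j);
  }
  return out;
}

// [[Rcpp::export(name = ".capsLossGradCpp")]]
List caps_lossgrad_cpp(IntegerMatrix codes, IntegerVector labels, List weights,
                       List cfgList) {
  Config c = parse_config(cfgList);
  Model m = parse_model(weights, c);
  int N = codes.nrow();
  Grads G;
  G.zero_like(m);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    std::vector<int> cd = row_codes(codes, i);
    loss += sample_pass(m, c, cd.data(), labels[i], true, &G, nullptr);
  }
  loss /= N;
  G.convW /= N;
  G.convB /= N;
  G.capsW /= N;
  Model gm;
  gm.convW = G.convW; gm.convB = G.convB; gm.capsW = G.capsW;
  return List::create(_["loss"] = loss, _["grads"] = model_to_list(gm));
}

// [[Rcpp::export(name = ".convScanCpp")]]
List conv_scan_cpp(IntegerMatrix codes, List weights, List cfgList) {
  Config c = parse_config(cfgList);
  Model m = parse_model(weights, c);
  int N = codes.nrow();
  NumericMatrix maxv(N, c.K);
  IntegerMatrix argm(N, c.K);
  for (int i = 0; i < N; ++i) {
    std::vector<int> cd = row_codes(codes, i);
    for (int k = 0; k < c.K; ++k) {
      double best = -1.0;
      int bp = 0;
      for (int p = 0; p < c.P; ++p) {
        double z = m.convB(k);
        for (int j = 0; j < c.h; ++j) {
          int cc = cd[p + j];
          if (cc < 4) z += m.convW(j, cc, k);
        }
        if (z < 0.0) z = 0.0;
        if (z > best) { best = z; bp = p; }
      }
      maxv(i, k) = best;
      argm(i, k) = bp + 1;  // 1-based
    }
  }
  return List::create(_["max"] = maxv, _["argmax"] = argm);
}

// [[Rcpp::export(name = ".convMapsCpp")]]
NumericMatrix conv_maps_cpp(IntegerVector codes, List weights, List cfgList) {
  Config c = parse_config(cfgList);
  Model m = parse_model(weights, c);
  if ((int)codes.size() != c.L) stop("sequence length mismatch");
  NumericMatrix maps(c.P, c.K);
  for (int k = 0; k < c.K; ++k)
    for (int p = 0; p < c.P; ++p) {
      double z = m.convB(k);
      for (int j = 0; j < c.h; ++j) {
        int cc = codes[p + j];
        if (cc < 4) z += m.convW(j, cc, k);
      }
      maps(p, k) = z > 0.0 ? z : 0.0;
    }
  return maps;
}

// [[Rcpp::export(name = ".routeCpp")]]
List route_cpp(NumericMatrix U, int T) {
  if (T < 1) stop("routing iterations T must be >= 1");
  mat Um(U.begin(), U.nrow(), U.ncol());
  RouteCache rc;
  route_fwd(Um, T, rc);
  return List::create(_["v"] = NumericVector(rc.V.col(T - 1).begin(), rc.V.col(T - 1).end()),
                      _["couplings"] = wrap(rc.C),
                      _["aggregates"] = wrap(rc.A),
                      _["outputs"] = wrap(rc.V));
}

// ---- Adam training loop -------------------------------------------------

struct AdamState {
  cube mW, vW;
  vec mB, vB;
  cube mA, vA;
  long t = 0;
  void init(const Model& m) {
    mW.zeros(arma::size(m.convW)); vW.zeros(arma::size(m.convW));
    mB.zeros(m.convB.n_elem); vB.zeros(m.convB.n_elem);
    mA.zeros(arma::size(m.capsW)); vA.zeros(arma::size(m.capsW));
  }
};

template <typename T>
static void adam_update(T& w, const T& g, T& mm, T& vv, double lr,
                        double b1, double b2, double eps, double bc1, double bc2) {
  mm = b1 * mm + (1.0 - b1) * g;
  vv = b2 * vv + (1.0 - b2) * (g % g);
  w -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
}

// [[Rcpp::export(name = ".capsTrainCpp")]]
List caps_train_cpp(IntegerMatrix codes, IntegerVector labels,
                    IntegerMatrix vcodes, IntegerVector vlabels,
                    List weights, List cfgList, List optList) {
  Config c = parse_config(cfgList);
  Model m = parse_model(weights, c);
  const double lr = as<double>(optList["lr"]);
  const double b1 = as<double>(optList["beta1"]);
  const double b2 = as<double>(optList["beta2"]);
  const double eps = as<double>(optList["eps"]);
  const int epochs = as<int>(optList["epochs"]);
  const int batch = as<int>(optList["batch"]);
  const int patience = as<int>(optList["patience"]);
  if (batch < 1 || epochs < 1) stop("batch size and epoch count must be >= 1");

  const int N = codes.nrow(), NV = vcodes.nrow();
  AdamState opt;
  opt.init(m);
  Grads G;
  Model best = m;
  double bestVal = R_PosInf;
  int bestEpoch = 0, wait = 0;
  std::vector<double> trainHist, valHist;

  for (int ep = 0; ep < epochs; ++ep) {
    // epoch shuffle drawn from R's RNG stream for reproducibility
    IntegerVector perm = Rcpp::sample(N, N, false);
    double epLoss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int end = std::min(start + batch, N);
      G.zero_like(m);
      double bl = 0.0;
      for (int q = start; q < end; ++q) {
        int i = perm[q] - 1;
        std::vector<int> cd = row_codes(codes, i);
        bl += sample_pass(m, c, cd.data(), labels[i], true, &G, nullptr);
      }
      int bn = end - start;
      epLoss += bl;
      G.convW /= bn; G.convB /= bn; G.capsW /= bn;
      opt.t += 1;
      double bc1 = 1.0 - std::pow(b1, (double)opt.t);
      double bc2 = 1.0 - std::pow(b2, (double)opt.t);
      adam_update(m.convW, G.convW, opt.mW, opt.vW, lr, b1, b2, eps, bc1, bc2);
      adam_update(m.convB, G.convB, opt.mB, opt.vB, lr, b1, b2, eps, bc1, bc2);
      adam_update(m.capsW, G.capsW, opt.mA, opt.vA, lr, b1, b2, eps, bc1, bc2);
    }
    epLoss /= N;
    if (!std::isfinite(epLoss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
    double valLoss = 0.0;
    for (int i = 0; i < NV; ++i) {
      std::vector<int> cd = row_codes(vcodes, i);
      valLoss += sample_pass(m, c, cd.data(), vlabels[i], false, nullptr, nullptr);
    }
    valLoss /= std::max(NV, 1);
    if (!std::isfinite(valLoss)) stop("training diverged: non-finite validation loss at epoch %d", ep + 1);
    trainHist.push_back(epLoss);
    valHist.push_back(valLoss);
    if (valLoss < bestVal - 1e-9) {
      bestVal = valLoss;
      best = m;
      bestEpoch = ep + 1;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = model_to_list(best),
                      _["trainLoss"] = wrap(trainHist),
                      _["valLoss"] = wrap(valHist),
                      _["bestEpoch"] = bestEpoch,
                      _["bestValLoss"] = bestVal);
}
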