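// Compiled core of the multi-task VGAE: one training/evaluation step on a
// single (cell, chromosome) graph, operating on the concatenated
// parameter vector without copying (zero-copy Armadillo views). The
// semantics mirror the pure-R reference implementation (graphStepR) used
// as the gradient oracle in the tests; all randomness (the
// reparameterization draw, dropout masks) comes from R's RNG stream so
// seeded runs are reproducible and identical between the two paths.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Parameter layout: names -> (offset, nrow, ncol) built in R
// (adamLayout) and passed as parallel vectors. Vectors have ncol = 0.
struct Layout {
  std::map<std::string, arma::uword> off, nr, nc;
  Layout(const CharacterVector& names, const IntegerVector& offs,
         const IntegerVector& nrow, const IntegerVector& ncol) {
    for (int i = 0; i < names.size(); ++i) {
      std::string nm = as<std::string>(names[i]);
      off[nm] = offs[i]; nr[nm] = nrow[i]; nc[nm] = ncol[i];
    }
  }
  arma::mat matOf(double* base, const std::string& nm) const {
    return arma::mat(base + off.at(nm), nr.at(nm), nc.at(nm), false, true);
  }
  arma::rowvec rowOf(double* base, const std::string& nm) const {
    return arma::rowvec(base + off.at(nm), nr.at(nm), false, true);
  }
};

struct DecCache {
  std::vector<arma::mat> pres, acts, masks;
  arma::vec p;
  arma::mat In;
};

static void mlpForwardC(double* w, const Layout& L, const std::string& pre,
                        const arma::mat& In, bool train, double dropout,
                        int nH, DecCache& c) {
  c.In = In;
  arma::mat cur = In;
  c.pres.resize(nH); c.acts.resize(nH); c.masks.resize(nH);
  for (int i = 0; i < nH; ++i) {
    arma::mat W = L.matOf(w, pre + ".W" + std::to_string(i + 1));
    arma::rowvec b = L.rowOf(w, pre + ".b" + std::to_string(i + 1));
    arma::mat prei = cur * W;
    prei.each_row() += b;
    arma::mat act = arma::clamp(prei, 0.0, arma::datum::inf);
    if (train && dropout > 0) {
      NumericVector u = runif(act.n_elem);
      arma::mat m(act.n_rows, act.n_cols);
      std::copy(u.begin(), u.end(), m.memptr());
      m.transform([dropout](double x) { return x >= dropout ? 1.0 : 0.0; });
      act = act % m / (1.0 - dropout);
      c.masks[i] = m;
    }
    c.pres[i] = prei; c.acts[i] = act;
    cur = act;
  }
  arma::mat WF = L.matOf(w, pre + ".W" + std::to_string(nH + 1));
  arma::rowvec bF = L.rowOf(w, pre + ".b" + std::to_string(nH + 1));
  arma::mat logit = cur * WF;
  logit.each_row() += bF;
  c.p = 1.0 / (1.0 + arma::exp(-logit.col(0)));
}

static arma::mat mlpBackwardC(double* w, double* g, const Layout& L,
                              const std::string& pre, const DecCache& c,
                              const arma::vec& dlogit, bool train,
                              double dropout, int nH) {
  arma::mat last = nH > 0 ? c.acts[nH - 1] : c.In;
  L.matOf(g, pre + ".W" + std::to_string(nH + 1)) = last.t() * dlogit;
  L.rowOf(g, pre + ".b" + std::to_string(nH + 1)) =
    arma::rowvec{arma::accu(dlogit)};
  arma::mat WF = L.matOf(w, pre + ".W" + std::to_string(nH + 1));
  arma::mat dcur = dlogit * WF.t();
  for (int i = nH - 1; i >= 0; --i) {
    if (train && dropout > 0)
      dcur = dcur % c.masks[i] / (1.0 - dropout);
    arma::mat dpre = dcur % arma::conv_to<arma::mat>::from(c.pres[i] > 0);
    arma::mat below = i > 0 ? c.acts[i - 1] : c.In;
    L.matOf(g, pre + ".W" + std::to_string(i + 1)) = below.t() * dpre;
    L.rowOf(g, pre + ".b" + std::to_string(i + 1)) = arma::sum(dpre, 0);
    arma::mat W = L.matOf(w, pre + ".W" + std::to_string(i + 1));
    dcur = dpre * W.t();
  }
  return dcur;
}

static double bceC(const arma::vec& p, const arma::vec& y) {
  arma::vec pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// [[Rcpp::export]]
List cppGraphStepVec(NumericVector wvecR, const CharacterVector& names,
                     const IntegerVector& offs, const IntegerVector& nrows,
                     const IntegerVector& ncols, const arma::mat& X,
                     const arma::sp_mat& A, const arma::mat& AX,
                     const arma::uvec& ru, const arma::uvec& rv,
                     const arma::vec& ry, const arma::uvec& lu,
                     const arma::uvec& lv, const arma::vec& ly,
                     double dropout, double klWeight, bool train,
                     int nHidden) {
  Layout L(names, offs, nrows, ncols);
  double* w = wvecR.begin();
  const int N = X.n_rows;

  arma::mat H1pre = X * L.matOf(w, "enc1Ws") + AX * L.matOf(w, "enc1Wn");
  H1pre.each_row() += L.rowOf(w, "enc1b");
  arma::mat H1 = arma::clamp(H1pre, 0.0, arma::datum::inf);
  arma::mat AH1 = arma::mat(A * H1);
  arma::mat Mu = H1 * L.matOf(w, "muWs") + AH1 * L.matOf(w, "muWn");
  Mu.each_row() += L.rowOf(w, "mub");
  arma::mat LS = H1 * L.matOf(w, "lsWs") + AH1 * L.matOf(w, "lsWn");
  LS.each_row() += L.rowOf(w, "lsb");
  if (!Mu.is_finite() || !LS.is_finite())
    stop("NaN/Inf in encoder activations; aborting");

  arma::mat eps, Z;
  if (train) {
    NumericVector e = rnorm(Mu.n_elem);
    eps.set_size(Mu.n_rows, Mu.n_cols);
    std::copy(e.begin(), e.end(), eps.memptr());
    Z = Mu + arma::exp(LS) % eps;
  } else {
    Z = Mu;
  }

  DecCache cPhi, cTheta;
  mlpForwardC(w, L, "phi",
              arma::join_rows(Z.rows(ru), Z.rows(rv)), train, dropout,
              nHidden, cPhi);
  mlpForwardC(w, L, "theta",
              arma::join_rows(Z.rows(lu), Z.rows(lv)), train, dropout,
              nHidden, cTheta);

  const double br = bceC(cPhi.p, ry);
  const double bl = bceC(cTheta.p, ly);
  const double kl = -0.5 *
    arma::accu(1.0 + 2.0 * LS - arma::square(Mu) - arma::exp(2.0 * LS)) / N;
  List loss = List::create(_["total"] = br + bl + klWeight * kl,
                           _["bceRecon"] = br, _["bceLoop"] = bl,
                           _["kl"] = kl);
  if (!train)
    return List::create(_["loss"] = loss);

  NumericVector gvecR(wvecR.size());
  double* g = gvecR.begin();

  arma::vec dlPhi = (arma::clamp(cPhi.p, 1e-7, 1.0 - 1e-7) - ry) /
    (double)ry.n_elem;
  arma::mat dInPhi = mlpBackwardC(w, g, L, "phi", cPhi, dlPhi, train,
                                  dropout, nHidden);
  arma::vec dlTheta = (arma::clamp(cTheta.p, 1e-7, 1.0 - 1e-7) - ly) /
    (double)ly.n_elem;
  arma::mat dInTheta = mlpBackwardC(w, g, L, "theta", cTheta, dlTheta,
                                    train, dropout, nHidden);

  const int D = Mu.n_cols;
  // accumulate pair gradients into dZ via transposed (contiguous) columns
  arma::mat dZt(D, N, arma::fill::zeros);
  arma::mat dInPhiT = dInPhi.t();
  for (arma::uword r = 0; r < ru.n_elem; ++r) {
    dZt.col(ru[r]) += dInPhiT.submat(0, r, D - 1, r);
    dZt.col(rv[r]) += dInPhiT.submat(D, r, 2 * D - 1, r);
  }
  arma::mat dInThetaT = dInTheta.t();
  for (arma::uword r = 0; r < lu.n_elem; ++r) {
    dZt.col(lu[r]) += dInThetaT.submat(0, r, D - 1, r);
    dZt.col(lv[r]) += dInThetaT.submat(D, r, 2 * D - 1, r);
  }
  arma::mat dZ = dZt.t();

  arma::mat dMu = dZ + klWeight * Mu / N;
  arma::mat dLS = dZ % eps % arma::exp(LS) +
    klWeight * (arma::exp(2.0 * LS) - 1.0) / N;

  L.matOf(g, "muWs") = H1.t() * dMu;
  L.matOf(g, "muWn") = AH1.t() * dMu;
  L.rowOf(g, "mub") = arma::sum(dMu, 0);
  L.matOf(g, "lsWs") = H1.t() * dLS;
  L.matOf(g, "lsWn") = AH1.t() * dLS;
  L.rowOf(g, "lsb") = arma::sum(dLS, 0);

  arma::mat dH1 = dMu * L.matOf(w, "muWs").t() +
    arma::mat(A.t() * dMu) * L.matOf(w, "muWn").t() +
    dLS * L.matOf(w, "lsWs").t() +
    arma::mat(A.t() * dLS) * L.matOf(w, "lsWn").t();
  arma::mat dpre1 = dH1 % arma::conv_to<arma::mat>::from(H1pre > 0);
  L.matOf(g, "enc1Ws") = X.t() * dpre1;
  L.matOf(g, "enc1Wn") = AX.t() * dpre1;
  L.rowOf(g, "enc1b") = arma::sum(dpre1, 0);

  return List::create(_["loss"] = loss, _["grads"] = gvecR);
}

// Vectorized Adam on the concatenated parameter vector; updates the
// freshly allocated copies it returns, leaving the inputs untouched.
// [[Rcpp::export]]
List cppAdamStep(const NumericVector& w0, const NumericVector& g0,
                 const NumericVector& m0, const NumericVector& v0, int t,
                 double lr, double weightDecay) {
  const double b1 = 0.9, b2 = 0.999, epsilon = 1e-8;
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  int n = w0.size();
  NumericVector w(n), m(n), v(n);
  for (int j = 0; j < n; ++j) {
    double g = g0[j] + weightDecay * w0[j];
    m[j] = b1 * m0[j] + (1.0 - b1) * g;
    v[j] = b2 * v0[j] + (1.0 - b2) * g * g;
    w[j] = w0[j] - lr * (m[j] / c1) / (std::sqrt(v[j] / c2) + epsilon);
  }
  return List::create(_["w"] = w, _["m"] = m, _["v"] = v);
}
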