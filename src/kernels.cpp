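// Hot loops of the variational EM: the labeled per-token coordinate sweep
// and the class-coefficient (softmax response) objective/gradient. Both
// mirror the R formulas one-to-one; everything else stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// One full labeled sweep over tokens. base is K x N (log pi + log beta +
// E[log theta]); eta is C x K; w are token weights summing to W; label is
// 1-based. Returns the updated phi (N x K) and the per-token log response
// factors A (C x N), both consistent with the final phi.
// [[Rcpp::export]]
List cpp_sweep_phi_labeled(NumericMatrix phi_in, NumericMatrix base,
                           NumericMatrix eta, NumericVector w, double W,
                           int label) {
  const int N = phi_in.nrow(), K = phi_in.ncol(), C = eta.nrow();
  NumericMatrix phi(clone(phi_in));
  NumericMatrix A(C, N);
  std::vector<double> srow(C, 0.0);

  const bool uniform = [&] {
    for (int n = 1; n < N; ++n) if (w[n] != w[0]) return false;
    return true;
  }();

  // En = exp(eta * w_n / W); shared across tokens when weights are uniform
  NumericMatrix En(C, K);
  auto fill_En = [&](double wn) {
    for (int l = 0; l < C; ++l)
      for (int i = 0; i < K; ++i)
        En(l, i) = std::exp(eta(l, i) * wn);
  };
  if (uniform && N > 0) fill_En(w[0] / W);

  for (int n = 0; n < N; ++n) {
    if (!uniform) fill_En(w[n] / W);
    for (int l = 0; l < C; ++l) {
      double m = 0.0;
      for (int i = 0; i < K; ++i) m += En(l, i) * phi(n, i);
      A(l, n) = std::log(m);
      srow[l] += A(l, n);
    }
  }

  std::vector<double> s(C), h(K), lp(K);
  for (int n = 0; n < N; ++n) {
    const double wn = w[n] / W;
    if (!uniform) fill_En(wn);
    double Ms = R_NegInf;
    for (int l = 0; l < C; ++l) {
      s[l] = srow[l] - A(l, n);
      if (s[l] > Ms) Ms = s[l];
    }
    std::fill(h.begin(), h.end(), 0.0);
    for (int l = 0; l < C; ++l) {
      const double es = std::exp(s[l] - Ms);
      for (int i = 0; i < K; ++i) h[i] += es * En(l, i);
    }
    double hphi = 0.0;
    for (int i = 0; i < K; ++i) hphi += h[i] * phi(n, i);
    double Mlp = R_NegInf;
    for (int i = 0; i < K; ++i) {
      lp[i] = base(i, n) + eta(label - 1, i) * wn - h[i] / (hphi * w[n]);
      if (lp[i] > Mlp) Mlp = lp[i];
    }
    double tot = 0.0;
    for (int i = 0; i < K; ++i) {
      lp[i] = std::exp(lp[i] - Mlp);
      tot += lp[i];
    }
    for (int i = 0; i < K; ++i) phi(n, i) = lp[i] / tot;
    for (int l = 0; l < C; ++l) {
      double m = 0.0;
      for (int i = 0; i < K; ++i) m += En(l, i) * phi(n, i);
      const double Anew = std::log(m);
      srow[l] += Anew - A(l, n);
      A(l, n) = Anew;
    }
  }
  return List::create(_["phi"] = phi, _["A"] = A);
}

// Penalized response objective and gradient for the class coefficients.
// docs is a list of per-document lists with elements phi (N x K), w, W,
// y (1-based class), phi_bar (K). Returns the objective value and its
// C x K gradient.
// [[Rcpp::export]]
List cpp_eta_objective(NumericMatrix eta, List docs, double lambda) {
  const int C = eta.nrow(), K = eta.ncol();
  double val = 0.0;
  NumericMatrix grad(C, K);

  NumericMatrix En(C, K);
  std::vector<double> s(C), p(C);
  NumericMatrix G(C, K);

  for (int d = 0; d < docs.size(); ++d) {
    List dd = docs[d];
    NumericMatrix phi = dd["phi"];
    NumericVector w = dd["w"];
    const double W = dd["W"];
    const int y = as<int>(dd["y"]) - 1;
    NumericVector phi_bar = dd["phi_bar"];
    const int N = phi.nrow();
    if (N == 0) continue;

    bool uniform = true;
    for (int n = 1; n < N; ++n) if (w[n] != w[0]) { uniform = false; break; }
    auto fill_En = [&](double r) {
      for (int l = 0; l < C; ++l)
        for (int i = 0; i < K; ++i)
          En(l, i) = std::exp(eta(l, i) * r);
    };
    if (uniform) fill_En(w[0] / W);

    std::fill(s.begin(), s.end(), 0.0);
    std::fill(G.begin(), G.end(), 0.0);
    for (int n = 0; n < N; ++n) {
      const double r = w[n] / W;
      if (!uniform) fill_En(r);
      for (int l = 0; l < C; ++l) {
        double m = 0.0;
        for (int i = 0; i < K; ++i) m += En(l, i) * phi(n, i);
        s[l] += std::log(m);
        const double rm = r / m;
        for (int i = 0; i < K; ++i) G(l, i) += rm * En(l, i) * phi(n, i);
      }
    }
    double Ms = *std::max_element(s.begin(), s.end());
    double lse = 0.0;
    for (int l = 0; l < C; ++l) lse += std::exp(s[l] - Ms);
    lse = Ms + std::log(lse);
    for (int l = 0; l < C; ++l) p[l] = std::exp(s[l] - lse);

    for (int i = 0; i < K; ++i) val += eta(y, i) * phi_bar[i];
    val -= lse;
    for (int i = 0; i < K; ++i) grad(y, i) += phi_bar[i];
    for (int l = 0; l < C; ++l)
      for (int i = 0; i < K; ++i) grad(l, i) -= p[l] * G(l, i);
  }

  for (int l = 0; l < C; ++l)
    for (int i = 0; i < K; ++i) {
      val -= lambda * eta(l, i) * eta(l, i);
      grad(l, i) -= 2.0 * lambda * eta(l, i);
    }
  return List::create(_["value"] = val, _["gradient"] = grad);
}
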