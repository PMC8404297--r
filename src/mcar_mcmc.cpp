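// Metropolis-within-Gibbs sampler for the multivariate Poisson model with
// coregionalized Leroux-CAR area effects:
//
//   Y[i,j] ~ Poisson(E[i,j] * exp(beta[j] + phi[i,j])),
//   phi = u %*% t(A),  A = lower Cholesky factor of Sigma,
//   u[,j] ~ N(0, Q(rho_j)^{-1}),  Q(rho) = rho (D - W) + (1 - rho) I,
//
// with priors: beta_j ~ N(0, 1/betaPrec), sd_j ~ U(0, sdUpper),
// corr_m ~ U(corrLo, corrHi) (Sigma kept positive definite by rejection),
// rho ~ U(0, 1) (shared for M2, per-disease for M1).
//
// Updates per sweep: single-site random walk on each u[i,j]; random walk
// on each beta_j; log-scale random walk on each sd_j; logit-scale random
// walks on each corr_m and on rho, all with Jacobians. Step sizes adapt
// towards 0.44 acceptance during burn-in only. The chain uses its own
// mt19937_64 stream, so output is a pure function of the seed.
//
// A Gaussian likelihood (Y[i,j] ~ N(beta[j] + phi[i,j], gaussSd^2),
// ignoring E) is available as a test harness: with hyperparameters held
// fixed the (beta, u) posterior is then exactly Gaussian and the
// sampler's long-run moments can be checked against the closed form.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Walker {
  double step;
  int acc = 0, att = 0;
  explicit Walker(double s) : step(s) {}
  void tally(bool a) { att++; if (a) acc++; }
  void adapt(double target) {
    if (att == 0) return;
    double r = double(acc) / att;
    step *= std::exp(1.5 * (r - target));
    if (step < 1e-5) step = 1e-5;
    if (step > 50.0) step = 50.0;
    acc = 0; att = 0;
  }
};

// lower Cholesky of Sigma(sd, corr); false if not positive definite
bool cholSdCorr(const std::vector<double>& sd, const std::vector<double>& corr,
                int J, std::vector<double>& A) {
  std::vector<double> S(J * J);
  for (int a = 0; a < J; a++) S[a * J + a] = sd[a] * sd[a];
  int m = 0;
  for (int a = 0; a < J; a++)
    for (int b = a + 1; b < J; b++, m++) {
      double v = corr[m] * sd[a] * sd[b];
      S[a * J + b] = v; S[b * J + a] = v;
    }
  std::fill(A.begin(), A.end(), 0.0);
  for (int i = 0; i < J; i++) {
    for (int j = 0; j <= i; j++) {
      double s = S[i * J + j];
      for (int k = 0; k < j; k++) s -= A[i * J + k] * A[j * J + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        A[i * J + i] = std::sqrt(s);
      } else {
        A[i * J + j] = s / A[j * J + j];
      }
    }
  }
  return true;
}

inline double logit(double p) { return std::log(p / (1.0 - p)); }
inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

}  // namespace

// [[Rcpp::export]]
List mcarChainCpp(NumericMatrix Y, NumericMatrix E, List nbList,
                  NumericVector degrees, NumericVector eigDW,
                  bool sharedRho, int likelihood, double gaussSd,
                  double sdUpper, double betaPrec,
                  double corrLo, double corrHi,
                  NumericVector betaInit, NumericMatrix uInit,
                  NumericVector sdInit, NumericVector corrInit,
                  NumericVector rhoInit,
                  int iterations, int burnIn, int thin,
                  bool updateHyper, int adaptInterval, double seedD) {
  const int n = Y.nrow(), J = Y.ncol();
  const int nc = J * (J - 1) / 2;
  const int nRho = sharedRho ? 1 : J;
  const bool pois = (likelihood == 0);
  const double g2 = gaussSd * gaussSd;

  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; i++) {
    IntegerVector v = nbList[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }

  std::mt19937_64 gen(static_cast<uint64_t>(seedD));
  std::normal_distribution<double> rn(0.0, 1.0);
  std::uniform_real_distribution<double> ru(0.0, 1.0);

  // state
  std::vector<double> beta(betaInit.begin(), betaInit.end());
  std::vector<double> sd(sdInit.begin(), sdInit.end());
  std::vector<double> corr(corrInit.begin(), corrInit.end());
  std::vector<double> rho(rhoInit.begin(), rhoInit.end());
  std::vector<double> u(n * J);
  for (int j = 0; j < J; j++)
    for (int i = 0; i < n; i++) u[j * n + i] = uInit(i, j);

  std::vector<double> A(J * J), Aprop(J * J);
  if (!cholSdCorr(sd, corr, J, A))
    stop("initial sd/corr do not give a positive-definite Sigma");

  std::vector<double> phi(n * J), phiProp(n * J);
  auto recomputePhi = [&](const std::vector<double>& AA,
                          std::vector<double>& out) {
    for (int l = 0; l < J; l++)
      for (int i = 0; i < n; i++) {
        double s = 0.0;
        for (int m = 0; m <= l; m++) s += AA[l * J + m] * u[m * n + i];
        out[l * n + i] = s;
      }
  };
  recomputePhi(A, phi);

  std::vector<char> use(n * J);
  for (int l = 0; l < J; l++)
    for (int i = 0; i < n; i++)
      use[l * n + i] = !(E(i, l) == 0.0 && Y(i, l) == 0.0);

  std::vector<double> eb(J);
  for (int j = 0; j < J; j++) eb[j] = std::exp(beta[j]);

  // full-surface likelihood difference between phiNew and phiOld
  auto dllPhi = [&](const std::vector<double>& phiNew) {
    double d = 0.0;
    for (int l = 0; l < J; l++)
      for (int i = 0; i < n; i++) {
        int idx = l * n + i;
        if (!use[idx]) continue;
        if (pois)
          d += Y(i, l) * (phiNew[idx] - phi[idx]) -
               E(i, l) * eb[l] * (std::exp(phiNew[idx]) - std::exp(phi[idx]));
        else {
          double r0 = Y(i, l) - beta[l] - phi[idx];
          double r1 = Y(i, l) - beta[l] - phiNew[idx];
          d += 0.5 * (r0 * r0 - r1 * r1) / g2;
        }
      }
    return d;
  };

  auto logdetQ = [&](double r) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += std::log(r * eigDW[i] + 1.0 - r);
    return s;
  };

  // quadratic forms q1 = u' (D - W) u, q0 = u' u for disease j
  auto quadForms = [&](int j, double& q1, double& q0) {
    q1 = 0.0; q0 = 0.0;
    const double* uj = &u[j * n];
    for (int i = 0; i < n; i++) {
      double nbsum = 0.0;
      for (int k : nb[i]) nbsum += uj[k];
      q1 += uj[i] * (degrees[i] * uj[i] - nbsum);
      q0 += uj[i] * uj[i];
    }
  };

  std::vector<Walker> wU, wBeta, wSd, wCorr, wRho;
  for (int j = 0; j < J; j++) wU.emplace_back(0.5);
  for (int j = 0; j < J; j++) wBeta.emplace_back(0.1);
  for (int j = 0; j < J; j++) wSd.emplace_back(0.4);
  for (int m = 0; m < nc; m++) wCorr.emplace_back(0.6);
  for (int r = 0; r < nRho; r++) wRho.emplace_back(0.8);

  const int S = (iterations - burnIn) / thin;
  if (S <= 0) stop("no retained draws: check iterations/burnIn/thin");
  NumericMatrix betaDraws(S, J), sdDraws(S, J), rhoDraws(S, nRho);
  NumericMatrix corrDraws(S, std::max(nc, 1));
  NumericVector devDraws(S);
  R_xlen_t totLen = (R_xlen_t)S * n * J;
  NumericVector uDraws(totLen), muDraws(totLen);
  int s = 0;

  for (int it = 1; it <= iterations; it++) {
    // --- latent fields, single-site random walk ---
    for (int j = 0; j < J; j++) {
      double rj = sharedRho ? rho[0] : rho[j];
      double* uj = &u[j * n];
      for (int i = 0; i < n; i++) {
        double old = uj[i];
        double prop = old + wU[j].step * rn(gen);
        double Qii = rj * degrees[i] + 1.0 - rj;
        double nbsum = 0.0;
        for (int k : nb[i]) nbsum += uj[k];
        double dlp = -0.5 * Qii * (prop * prop - old * old) +
                     (prop - old) * rj * nbsum;
        double du = prop - old;
        for (int l = j; l < J; l++) {
          double a = A[l * J + j];
          int idx = l * n + i;
          if (!use[idx]) continue;
          double p0 = phi[idx], p1 = p0 + a * du;
          if (pois)
            dlp += Y(i, l) * (p1 - p0) -
                   E(i, l) * eb[l] * (std::exp(p1) - std::exp(p0));
          else {
            double r0 = Y(i, l) - beta[l] - p0;
            double r1 = Y(i, l) - beta[l] - p1;
            dlp += 0.5 * (r0 * r0 - r1 * r1) / g2;
          }
        }
        bool acc = std::log(ru(gen)) < dlp;
        if (acc) {
          uj[i] = prop;
          for (int l = j; l < J; l++) phi[l * n + i] += A[l * J + j] * du;
        }
        wU[j].tally(acc);
      }
    }

    // --- intercepts ---
    for (int j = 0; j < J; j++) {
      double old = beta[j];
      double prop = old + wBeta[j].step * rn(gen);
      double dlp = -0.5 * betaPrec * (prop * prop - old * old);
      if (pois) {
        double sy = 0.0, se = 0.0;
        for (int i = 0; i < n; i++) {
          int idx = j * n + i;
          if (!use[idx]) continue;
          sy += Y(i, j);
          se += E(i, j) * std::exp(phi[idx]);
        }
        dlp += sy * (prop - old) - se * (std::exp(prop) - std::exp(old));
      } else {
        for (int i = 0; i < n; i++) {
          int idx = j * n + i;
          double r0 = Y(i, j) - old - phi[idx];
          double r1 = Y(i, j) - prop - phi[idx];
          dlp += 0.5 * (r0 * r0 - r1 * r1) / g2;
        }
      }
      bool acc = std::log(ru(gen)) < dlp;
      if (acc) { beta[j] = prop; eb[j] = std::exp(prop); }
      wBeta[j].tally(acc);
    }

    if (updateHyper) {
      // --- sd parameters, log-scale walk; prior U(0, sdUpper) ---
      for (int j = 0; j < J; j++) {
        double old = sd[j];
        double prop = old * std::exp(wSd[j].step * rn(gen));
        bool acc = false;
        if (prop < sdUpper) {
          std::vector<double> sdProp = sd;
          sdProp[j] = prop;
          if (cholSdCorr(sdProp, corr, J, Aprop)) {
            recomputePhi(Aprop, phiProp);
            double dlp = dllPhi(phiProp) + std::log(prop) - std::log(old);
            if (std::log(ru(gen)) < dlp) {
              acc = true; sd[j] = prop; A = Aprop; phi = phiProp;
            }
          }
        }
        wSd[j].tally(acc);
      }

      // --- correlation parameters, logit-scale walk on (corrLo, corrHi) ---
      for (int m = 0; m < nc; m++) {
        double old = corr[m];
        double t0 = logit((old - corrLo) / (corrHi - corrLo));
        double t1 = t0 + wCorr[m].step * rn(gen);
        double prop = corrLo + (corrHi - corrLo) * invlogit(t1);
        bool acc = false;
        std::vector<double> corrProp = corr;
        corrProp[m] = prop;
        if (cholSdCorr(sd, corrProp, J, Aprop)) {
          recomputePhi(Aprop, phiProp);
          double jac = std::log((prop - corrLo) * (corrHi - prop)) -
                       std::log((old - corrLo) * (corrHi - old));
          double dlp = dllPhi(phiProp) + jac;
          if (std::log(ru(gen)) < dlp) {
            acc = true; corr[m] = prop; A = Aprop; phi = phiProp;
          }
        }
        wCorr[m].tally(acc);
      }

      // --- spatial correlation, logit-scale walk on (0, 1) ---
      for (int r = 0; r < nRho; r++) {
        double old = rho[r];
        double t1 = logit(old) + wRho[r].step * rn(gen);
        double prop = invlogit(t1);
        double dlp = std::log(prop * (1.0 - prop)) -
                     std::log(old * (1.0 - old));
        int j0 = sharedRho ? 0 : r, j1 = sharedRho ? J - 1 : r;
        double dLogdet = logdetQ(prop) - logdetQ(old);
        for (int j = j0; j <= j1; j++) {
          double q1, q0;
          quadForms(j, q1, q0);
          dlp += 0.5 * dLogdet - 0.5 * (prop - old) * (q1 - q0);
        }
        bool acc = std::log(ru(gen)) < dlp;
        if (acc) rho[r] = prop;
        wRho[r].tally(acc);
      }
    }

    if (it <= burnIn && it % adaptInterval == 0) {
      for (auto& w : wU) w.adapt(0.44);
      for (auto& w : wBeta) w.adapt(0.44);
      for (auto& w : wSd) w.adapt(0.44);
      for (auto& w : wCorr) w.adapt(0.44);
      for (auto& w : wRho) w.adapt(0.44);
    }

    if (it > burnIn && (it - burnIn) % thin == 0 && s < S) {
      for (int j = 0; j < J; j++) {
        betaDraws(s, j) = beta[j];
        sdDraws(s, j) = sd[j];
      }
      for (int m = 0; m < nc; m++) corrDraws(s, m) = corr[m];
      for (int r = 0; r < nRho; r++) rhoDraws(s, r) = rho[r];
      double dev = 0.0;
      for (int l = 0; l < J; l++)
        for (int i = 0; i < n; i++) {
          int idx = l * n + i;
          double mu;
          if (!use[idx]) {
            mu = 0.0;
          } else if (pois) {
            mu = E(i, l) * std::exp(beta[l] + phi[idx]);
            dev += -2.0 * (Y(i, l) * std::log(mu) - mu - std::lgamma(Y(i, l) + 1.0));
          } else {
            mu = beta[l] + phi[idx];
            double r0 = Y(i, l) - mu;
            dev += r0 * r0 / g2 + std::log(2.0 * M_PI * g2);
          }
          R_xlen_t off = (R_xlen_t)s + (R_xlen_t)S * idx;
          uDraws[off] = u[l * n + i];
          muDraws[off] = mu;
        }
      devDraws[s] = dev;
      s++;
    }

    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  uDraws.attr("dim") = IntegerVector::create(S, n, J);
  muDraws.attr("dim") = IntegerVector::create(S, n, J);

  auto rate = [](const std::vector<Walker>& ws) {
    NumericVector out(ws.size());
    for (size_t i = 0; i < ws.size(); i++)
      out[i] = ws[i].att > 0 ? double(ws[i].acc) / ws[i].att : NA_REAL;
    return out;
  };

  return List::create(
    _["beta"] = betaDraws, _["sd"] = sdDraws,
    _["corr"] = (nc > 0 ? corrDraws : NumericMatrix(S, 0)),
    _["rho"] = rhoDraws, _["u"] = uDraws, _["mu"] = muDraws,
    _["deviance"] = devDraws,
    _["accept"] = List::create(_["u"] = rate(wU), _["beta"] = rate(wBeta),
                               _["sd"] = rate(wSd), _["corr"] = rate(wCorr),
                               _["rho"] = rate(wRho)));
}
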