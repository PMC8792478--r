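#include <Rcpp.h>
using namespace Rcpp;

// Beta-binomial log-likelihood of x alt alleles out of n, with mean pi and
// precision theta (theta = (1-F)/F, F = logistic(alpha_i + beta_j)).
static inline double bbll(double x, double n, double pi, double theta) {
  if (n <= 0) return 0.0;
  double a = theta * pi, b = theta * (1.0 - pi);
  return R::lgammafn(theta) - R::lgammafn(theta + n) +
         R::lgammafn(a + x) - R::lgammafn(a) +
         R::lgammafn(b + n - x) - R::lgammafn(b);
}

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// log-lik of locus i across groups
static double locusLL(int i, const NumericMatrix& X, const NumericMatrix& N,
                      double pi, double alpha, const NumericVector& beta) {
  double ll = 0.0;
  for (int j = 0; j < beta.size(); ++j) {
    double F = logistic(alpha + beta[j]);
    if (F < 1e-12) F = 1e-12;
    if (F > 1.0 - 1e-12) F = 1.0 - 1e-12;
    double theta = (1.0 - F) / F;
    ll += bbll(X(i, j), N(i, j), pi, theta);
  }
  return ll;
}

// Reversible-jump MCMC for the per-locus selection term alpha_i.
// Prior: alpha ~ N(0,1) when included, P(excluded)/P(included) = priorOdds;
// beta_j ~ N(-1,1); pi_i uniform on (0,1), updated on the logit scale.
// Birth proposals draw alpha from its prior, so the prior density cancels
// and the acceptance ratio is the likelihood ratio over the prior odds.
// [[Rcpp::export(name = ".bayescanMcmc")]]
List bayescanMcmc(NumericMatrix X, NumericMatrix N, double priorOdds,
                  int nPilot, int pilotLen, int burnin, int nOut, int thin) {
  RNGScope scope;
  const int L = X.nrow(), J = X.ncol();
  NumericVector pi(L, 0.5), alpha(L, 0.0), beta(J, -1.0);
  LogicalVector delta(L, false);
  NumericVector sdPi(L, 0.5), sdAlpha(L, 0.5), sdBeta(J, 0.2);
  IntegerVector accPi(L), tryPi(L), accAl(L), tryAl(L), accBe(J), tryBe(J);

  // cached per-locus log-likelihood
  NumericVector ll(L);
  for (int i = 0; i < L; ++i)
    ll[i] = locusLL(i, X, N, pi[i], delta[i] ? alpha[i] : 0.0, beta);

  NumericVector postDelta(L, 0.0), postAlpha(L, 0.0), postFst(L, 0.0);
  int kept = 0;

  auto sweep = [&](bool record) {
    // pi updates (logit random walk; Jacobian pi(1-pi))
    for (int i = 0; i < L; ++i) {
      double lo = std::log(pi[i] / (1.0 - pi[i]));
      double lp = lo + norm_rand() * sdPi[i];
      double pnew = logistic(lp);
      double a = delta[i] ? alpha[i] : 0.0;
      double llNew = locusLL(i, X, N, pnew, a, beta);
      double lr = llNew - ll[i] +
        std::log(pnew * (1.0 - pnew)) - std::log(pi[i] * (1.0 - pi[i]));
      ++tryPi[i];
      if (std::log(unif_rand()) < lr) { pi[i] = pnew; ll[i] = llNew; ++accPi[i]; }
    }
    // beta updates
    for (int j = 0; j < J; ++j) {
      double bnew = beta[j] + norm_rand() * sdBeta[j];
      NumericVector betaNew = clone(beta);
      betaNew[j] = bnew;
      double llTotNew = 0.0, llTotOld = 0.0;
      NumericVector llNew(L);
      for (int i = 0; i < L; ++i) {
        llNew[i] = locusLL(i, X, N, pi[i], delta[i] ? alpha[i] : 0.0, betaNew);
        llTotNew += llNew[i];
        llTotOld += ll[i];
      }
      double lr = llTotNew - llTotOld +
        R::dnorm(bnew, -1.0, 1.0, 1) - R::dnorm(beta[j], -1.0, 1.0, 1);
      ++tryBe[j];
      if (std::log(unif_rand()) < lr) { beta = betaNew; ll = llNew; ++accBe[j]; }
    }
    // alpha random-walk updates (included loci)
    for (int i = 0; i < L; ++i) {
      if (!delta[i]) continue;
      double anew = alpha[i] + norm_rand() * sdAlpha[i];
      double llNew = locusLL(i, X, N, pi[i], anew, beta);
      double lr = llNew - ll[i] +
        R::dnorm(anew, 0.0, 1.0, 1) - R::dnorm(alpha[i], 0.0, 1.0, 1);
      ++tryAl[i];
      if (std::log(unif_rand()) < lr) { alpha[i] = anew; ll[i] = llNew; ++accAl[i]; }
    }
    // reversible-jump birth/death of the selection term
    for (int i = 0; i < L; ++i) {
      if (!delta[i]) {
        double anew = norm_rand();  // draw from the N(0,1) prior
        double llNew = locusLL(i, X, N, pi[i], anew, beta);
        double lr = llNew - ll[i] - std::log(priorOdds);
        if (std::log(unif_rand()) < lr) {
          delta[i] = true; alpha[i] = anew; ll[i] = llNew;
        }
      } else {
        double llNew = locusLL(i, X, N, pi[i], 0.0, beta);
        double lr = llNew - ll[i] + std::log(priorOdds);
        if (std::log(unif_rand()) < lr) {
          delta[i] = false; alpha[i] = 0.0; ll[i] = llNew;
        }
      }
    }
    if (record) {
      for (int i = 0; i < L; ++i) {
        if (delta[i]) { postDelta[i] += 1.0; postAlpha[i] += alpha[i]; }
        double f = 0.0;
        for (int j = 0; j < J; ++j)
          f += logistic((delta[i] ? alpha[i] : 0.0) + beta[j]);
        postFst[i] += f / J;
      }
      ++kept;
    }
  };

  // pilot runs: adapt random-walk SDs toward 25-45% acceptance
  for (int p = 0; p < nPilot; ++p) {
    std::fill(accPi.begin(), accPi.end(), 0); std::fill(tryPi.begin(), tryPi.end(), 0);
    std::fill(accAl.begin(), accAl.end(), 0); std::fill(tryAl.begin(), tryAl.end(), 0);
    std::fill(accBe.begin(), accBe.end(), 0); std::fill(tryBe.begin(), tryBe.end(), 0);
    for (int t = 0; t < pilotLen; ++t) sweep(false);
    for (int i = 0; i < L; ++i) {
      if (tryPi[i] > 0) {
        double r = (double)accPi[i] / tryPi[i];
        if (r > 0.45) sdPi[i] *= 1.2; else if (r < 0.25) sdPi[i] /= 1.2;
      }
      if (tryAl[i] > 0) {
        double r = (double)accAl[i] / tryAl[i];
        if (r > 0.45) sdAlpha[i] *= 1.2; else if (r < 0.25) sdAlpha[i] /= 1.2;
      }
    }
    for (int j = 0; j < J; ++j) {
      if (tryBe[j] > 0) {
        double r = (double)accBe[j] / tryBe[j];
        if (r > 0.45) sdBeta[j] *= 1.2; else if (r < 0.25) sdBeta[j] /= 1.2;
      }
    }
  }

  std::fill(accPi.begin(), accPi.end(), 0); std::fill(tryPi.begin(), tryPi.end(), 0);
  for (int t = 0; t < burnin; ++t) sweep(false);
  for (int s = 0; s < nOut; ++s) {
    for (int t = 0; t < thin; ++t) sweep(false);
    sweep(true);
  }

  double accRatePi = 0.0;
  long tot = 0, acc = 0;
  for (int i = 0; i < L; ++i) { tot += tryPi[i]; acc += accPi[i]; }
  if (tot > 0) accRatePi = (double)acc / tot;

  for (int i = 0; i < L; ++i) {
    postAlpha[i] = postDelta[i] > 0 ? postAlpha[i] / postDelta[i] : 0.0;
    postDelta[i] /= kept;
    postFst[i] /= kept;
  }
  return List::create(_["pip"] = postDelta, _["alpha"] = postAlpha,
                      _["fst"] = postFst, _["beta"] = beta,
                      _["accRatePi"] = accRatePi, _["kept"] = kept);
}
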