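// Gibbs sampler for the admixture model with either independent or
// correlated (F-model) allele frequencies.
//
// Data: n diploid individuals x L loci, alleles recoded 1..A_l, 0 missing.
// State: Q (n x K ancestry proportions), P (per-locus K x A_l frequencies),
// alpha (symmetric Dirichlet parameter of Q), and under the correlated
// model an ancestral frequency vector pA_l per locus plus per-population
// drift parameters F_k. Allele-copy origins Z are sampled, P and Q have
// conjugate Dirichlet updates, alpha / pA / F_k move by Metropolis.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rgamma_pos(double shape) {
  double g = R::rgamma(shape, 1.0);
  return (g > 1e-300) ? g : 1e-300;
}

static void dirichlet_draw(std::vector<double>& out, const std::vector<double>& par) {
  double s = 0.0;
  for (size_t a = 0; a < par.size(); ++a) { out[a] = rgamma_pos(par[a]); s += out[a]; }
  for (size_t a = 0; a < par.size(); ++a) out[a] /= s;
}

static double log_dirichlet_pdf(const std::vector<double>& x, const std::vector<double>& par) {
  double s = 0.0, lp = 0.0;
  for (size_t a = 0; a < par.size(); ++a) {
    s += par[a];
    lp += (par[a] - 1.0) * std::log(std::max(x[a], 1e-300)) - R::lgammafn(par[a]);
  }
  return lp + R::lgammafn(s);
}

// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix geno, IntegerVector nAlleles, int K,
                     int burnin, int iters, double lambda, double alpha0,
                     double alpha_max, double alpha_sd, bool correlated,
                     double f_init, double f_sd, double pa_conc) {
  RNGScope scope;
  const int n = geno.nrow();
  const int L = nAlleles.size();
  const int total = burnin + iters;

  // state
  std::vector<std::vector<double> > P(L), pA(L);   // P[l]: K*A_l row-major
  for (int l = 0; l < L; ++l) {
    P[l].assign((size_t)K * nAlleles[l], 1.0 / nAlleles[l]);
    pA[l].assign(nAlleles[l], 1.0 / nAlleles[l]);
  }
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  std::vector<double> Fk(K, f_init);
  double alpha = alpha0;

  // accumulators
  NumericMatrix Qsum(n, K);
  std::vector<std::vector<double> > Psum(L);
  for (int l = 0; l < L; ++l) Psum[l].assign((size_t)K * nAlleles[l], 0.0);
  NumericVector loglik(iters), alpha_trace(total);
  int alpha_acc = 0, alpha_try = 0;

  // scratch
  std::vector<std::vector<double> > counts(L);
  for (int l = 0; l < L; ++l) counts[l].assign((size_t)K * nAlleles[l], 0.0);
  std::vector<double> r((size_t)n * K), w(K), par, prop, cur;

  for (int sweep = 0; sweep < total; ++sweep) {
    // ---- Z step: sample allele-copy origins, accumulate counts, loglik ----
    double ll = 0.0;
    for (int l = 0; l < L; ++l) std::fill(counts[l].begin(), counts[l].end(), 0.0);
    std::fill(r.begin(), r.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[l][(size_t)k * nAlleles[l] + (a - 1)];
            s += w[k];
          }
          ll += std::log(std::max(s, 1e-300));
          double u = unif_rand() * s;
          int k = 0;
          for (; k < K - 1; ++k) { u -= w[k]; if (u <= 0) break; }
          counts[l][(size_t)k * nAlleles[l] + (a - 1)] += 1.0;
          r[(size_t)i * K + k] += 1.0;
        }
      }
    }

    // ---- Q update ----
    par.resize(K); cur.resize(K);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) par[k] = alpha + r[(size_t)i * K + k];
      dirichlet_draw(cur, par);
      for (int k = 0; k < K; ++k) Q(i, k) = cur[k];
    }

    // ---- P update (conjugate given prior parameters) ----
    for (int l = 0; l < L; ++l) {
      int A = nAlleles[l];
      par.resize(A); cur.resize(A);
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a) {
          double prior = correlated ? pA[l][a] * (1.0 - Fk[k]) / Fk[k] : lambda;
          par[a] = std::max(prior, 1e-6) + counts[l][(size_t)k * A + a];
        }
        dirichlet_draw(cur, par);
        for (int a = 0; a < A; ++a) P[l][(size_t)k * A + a] = cur[a];
      }
    }

    if (correlated) {
      // ---- pA update: Metropolis with Dirichlet(pa_conc * pA) proposal ----
      for (int l = 0; l < L; ++l) {
        int A = nAlleles[l];
        par.resize(A); prop.resize(A);
        for (int a = 0; a < A; ++a) par[a] = std::max(pa_conc * pA[l][a], 1e-2);
        dirichlet_draw(prop, par);
        double lr = 0.0;
        std::vector<double> prow(A), prior_new(A), prior_old(A);
        for (int k = 0; k < K; ++k) {
          double c = (1.0 - Fk[k]) / Fk[k];
          for (int a = 0; a < A; ++a) {
            prow[a] = P[l][(size_t)k * A + a];
            prior_new[a] = std::max(prop[a] * c, 1e-6);
            prior_old[a] = std::max(pA[l][a] * c, 1e-6);
          }
          lr += log_dirichlet_pdf(prow, prior_new) - log_dirichlet_pdf(prow, prior_old);
        }
        // Hastings correction for the asymmetric proposal (uniform prior on pA)
        std::vector<double> par_back(A);
        for (int a = 0; a < A; ++a) par_back[a] = std::max(pa_conc * prop[a], 1e-2);
        lr += log_dirichlet_pdf(pA[l], par_back) - log_dirichlet_pdf(prop, par);
        if (std::log(unif_rand()) < lr) pA[l] = prop;
      }
      // ---- F_k update: random walk on logit(F), uniform(0,1) prior ----
      for (int k = 0; k < K; ++k) {
        double x = std::log(Fk[k] / (1.0 - Fk[k]));
        double xn = x + norm_rand() * f_sd;
        double fn = 1.0 / (1.0 + std::exp(-xn));
        double lr = 0.0;
        for (int l = 0; l < L; ++l) {
          int A = nAlleles[l];
          std::vector<double> prow(A), prior_new(A), prior_old(A);
          double cn = (1.0 - fn) / fn, co = (1.0 - Fk[k]) / Fk[k];
          for (int a = 0; a < A; ++a) {
            prow[a] = P[l][(size_t)k * A + a];
            prior_new[a] = std::max(pA[l][a] * cn, 1e-6);
            prior_old[a] = std::max(pA[l][a] * co, 1e-6);
          }
          lr += log_dirichlet_pdf(prow, prior_new) - log_dirichlet_pdf(prow, prior_old);
        }
        // Jacobian of the logit transform
        lr += std::log(fn * (1.0 - fn)) - std::log(Fk[k] * (1.0 - Fk[k]));
        if (std::log(unif_rand()) < lr) Fk[k] = fn;
      }
    }

    // ---- alpha update (Metropolis, uniform prior on (0, alpha_max]) ----
    if (K > 1) {
      double an = alpha + norm_rand() * alpha_sd;
      ++alpha_try;
      if (an > 0.0 && an <= alpha_max) {
        double lr = n * (R::lgammafn(K * an) - K * R::lgammafn(an)
                       - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(Q(i, k), 1e-300));
        lr += (an - alpha) * slq;
        if (std::log(unif_rand()) < lr) { alpha = an; ++alpha_acc; }
      }
    }
    alpha_trace[sweep] = alpha;

    // ---- accumulate ----
    if (sweep >= burnin) {
      int t = sweep - burnin;
      loglik[t] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (size_t z = 0; z < Psum[l].size(); ++z) Psum[l][z] += P[l][z];
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= iters;
  List Pmean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix M(K, nAlleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < nAlleles[l]; ++a)
        M(k, a) = Psum[l][(size_t)k * nAlleles[l] + a] / iters;
    Pmean[l] = M;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pmean, _["loglik"] = loglik,
                      _["alpha_trace"] = alpha_trace,
                      _["alpha_accept"] = alpha_try ? (double)alpha_acc / alpha_try : NA_REAL,
                      _["F"] = NumericVector(Fk.begin(), Fk.end()));
}
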