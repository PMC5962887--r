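// Hamiltonian Monte Carlo sampler for the hierarchical plurality model.
//
// Posterior over: beta_p, beta_f, a (N(0,5) priors); rater biases r_i
// (N(0,sigma_R)); language and concept effects alpha_L, alpha_C (N(0,sigma));
// latent plurality p_c (U(0,1)); scale parameters sigma_{Q,R,L,C} (Exp(1/5)).
// Likelihood: ratings R_{c,i} ~ N(1 + 6 p_c + r_i, sigma_Q); outcomes
// S_{c,l} ~ Bernoulli(logit^{-1}(beta_p p_c + beta_f f_c + alpha_L + alpha_C + a)).
//
// Sampling happens on an unconstrained scale: non-centred z-scores for the
// hierarchical effects (r = sigma_R z_r etc.), logit for p_c, log for the
// sigmas, with the matching Jacobian terms. Warmup adapts the step size by
// dual averaging (target acceptance 0.8) and a diagonal mass matrix from the
// middle warmup window. The number of leapfrog steps is jittered uniformly in
// 1..max_leapfrog each iteration. All randomness comes from a private
// xorshift-free mt19937_64 with Box-Muller normals, so chains are bit
// reproducible for a given seed on a given platform.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { // (0,1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Box-Muller, deterministic
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int unif_int(int lo, int hi) { // inclusive
    return lo + static_cast<int>(unif() * (hi - lo + 1 - 1e-12));
  }
};

struct Model {
  int C, I, L;                       // concepts, raters, languages
  std::vector<int> rc, ri;           // rating indices (0-based)
  std::vector<double> Rv;            // rating values
  std::vector<int> oc, ol;           // outcome indices
  std::vector<double> Sv;            // outcomes 0/1
  std::vector<double> f;             // frequencies, length C
  int D;                             // unconstrained dimension

  // layout: [beta_p, beta_f, a | z_r(I) | z_L(L) | z_C(C) | u_p(C) | tQ,tR,tL,tC]
  int off_zr() const { return 3; }
  int off_zL() const { return 3 + I; }
  int off_zC() const { return 3 + I + L; }
  int off_up() const { return 3 + I + L + C; }
  int off_t()  const { return 3 + I + L + 2 * C; }

  // log posterior density (unconstrained scale) and its gradient
  double logp_grad(const std::vector<double>& th, std::vector<double>& g) const {
    const double LOG_SQRT_2PI = 0.9189385332046727;
    std::fill(g.begin(), g.end(), 0.0);
    const double bp = th[0], bf = th[1], a = th[2];
    const double tQ = th[off_t()], tR = th[off_t() + 1],
                 tL = th[off_t() + 2], tC = th[off_t() + 3];
    const double sQ = std::exp(tQ), sR = std::exp(tR),
                 sL = std::exp(tL), sC = std::exp(tC);

    std::vector<double> p(C), dpdu(C);
    for (int c = 0; c < C; ++c) {
      double u = th[off_up() + c];
      double pc = 1.0 / (1.0 + std::exp(-u));
      p[c] = pc; dpdu[c] = pc * (1.0 - pc);
    }

    double lp = 0.0;
    const double inv_sQ2 = 1.0 / (sQ * sQ);

    // ratings likelihood
    double sum_e2 = 0.0;
    for (size_t k = 0; k < Rv.size(); ++k) {
      int c = rc[k], i = ri[k];
      double r_i = sR * th[off_zr() + i];
      double e = Rv[k] - 1.0 - 6.0 * p[c] - r_i;
      sum_e2 += e * e;
      double w = e * inv_sQ2;
      g[off_up() + c] += 6.0 * w * dpdu[c];
      g[off_zr() + i] += w * sR;
      g[off_t() + 1]  += w * r_i;            // d/d tR via r = sR z
    }
    lp += -0.5 * sum_e2 * inv_sQ2
          - static_cast<double>(Rv.size()) * (tQ + LOG_SQRT_2PI);
    g[off_t()] += sum_e2 * inv_sQ2 - static_cast<double>(Rv.size());

    // outcomes likelihood
    for (size_t k = 0; k < Sv.size(); ++k) {
      int c = oc[k], l = ol[k];
      double aL = sL * th[off_zL() + l];
      double aC = sC * th[off_zC() + c];
      double eta = bp * p[c] + bf * f[c] + aL + aC + a;
      double m = eta > 0 ? eta : 0.0;
      lp += Sv[k] * eta - (m + std::log1p(std::exp(eta > 0 ? -eta : eta)));
      double gg = Sv[k] - 1.0 / (1.0 + std::exp(-eta));
      g[0] += gg * p[c];
      g[1] += gg * f[c];
      g[2] += gg;
      g[off_zL() + l] += gg * sL;
      g[off_zC() + c] += gg * sC;
      g[off_up() + c] += gg * bp * dpdu[c];
      g[off_t() + 2]  += gg * aL;
      g[off_t() + 3]  += gg * aC;
    }

    // priors: coefficients N(0,5)
    for (int j = 0; j < 3; ++j) {
      lp += -0.5 * th[j] * th[j] / 25.0 - std::log(5.0) - LOG_SQRT_2PI;
      g[j] += -th[j] / 25.0;
    }
    // standard-normal z blocks
    for (int j = off_zr(); j < off_up(); ++j) {
      lp += -0.5 * th[j] * th[j] - LOG_SQRT_2PI;
      g[j] += -th[j];
    }
    // p_c ~ U(0,1): prior constant, logit Jacobian log p(1-p)
    for (int c = 0; c < C; ++c) {
      lp += std::log(dpdu[c]);
      g[off_up() + c] += 1.0 - 2.0 * p[c];
    }
    // sigmas ~ Exp(rate 0.2), log Jacobian
    const double lam = 0.2;
    const double s[4] = {sQ, sR, sL, sC};
    for (int j = 0; j < 4; ++j) {
      lp += std::log(lam) - lam * s[j] + th[off_t() + j];
      g[off_t() + j] += -lam * s[j] + 1.0;
    }
    return lp;
  }
};

} // namespace

// [[Rcpp::export]]
List hmc_plurality_chain(List data, int warmup, int iters,
                         double target_accept, int max_leapfrog,
                         double init_step, int seed, int chain_id) {
  Model m;
  m.C = as<int>(data["n_concepts"]);
  m.I = as<int>(data["n_raters"]);
  m.L = as<int>(data["n_languages"]);
  m.rc = as<std::vector<int>>(data["rating_concept"]);
  m.ri = as<std::vector<int>>(data["rating_rater"]);
  m.Rv = as<std::vector<double>>(data["rating_value"]);
  m.oc = as<std::vector<int>>(data["outcome_concept"]);
  m.ol = as<std::vector<int>>(data["outcome_language"]);
  m.Sv = as<std::vector<double>>(data["outcome_value"]);
  m.f  = as<std::vector<double>>(data["frequency"]);
  m.D  = 3 + m.I + m.L + 2 * m.C + 4;
  const int D = m.D;

  Rng rng(static_cast<uint64_t>(seed) * 1000003ULL + 7919ULL * chain_id);

  std::vector<double> th(D), g(D), g_new(D), inv_mass(D, 1.0);
  for (int j = 0; j < D; ++j) th[j] = 0.5 * rng.norm() * 0.5;
  double lp = m.logp_grad(th, g);

  // dual averaging state
  double eps = init_step, log_eps_bar = std::log(eps);
  double mu = std::log(10.0 * eps), Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;

  // mass adaptation window (early, so step size re-adapts on the new metric)
  const int w1 = static_cast<int>(0.15 * warmup);
  const int w2 = static_cast<int>(0.60 * warmup);
  std::vector<double> acc_m(D, 0.0), acc_s(D, 0.0);
  long n_acc = 0;

  NumericMatrix draws(iters, D);
  NumericVector lp_out(iters);
  double accept_sum = 0.0;
  std::vector<double> p_mom(D), th_prop(D);

  int total = warmup + iters;
  int da_iter = 0;
  for (int it = 0; it < total; ++it) {
    // momentum ~ N(0, M), M = 1/inv_mass
    for (int j = 0; j < D; ++j) p_mom[j] = rng.norm() / std::sqrt(inv_mass[j]);
    double H0 = -lp;
    for (int j = 0; j < D; ++j) H0 += 0.5 * p_mom[j] * p_mom[j] * inv_mass[j];

    th_prop = th;
    g_new = g;
    int Lsteps = rng.unif_int(std::max(1, max_leapfrog / 2), max_leapfrog);
    bool diverged = false;
    double lp_prop = lp;
    for (int s = 0; s < Lsteps; ++s) {
      for (int j = 0; j < D; ++j) p_mom[j] += 0.5 * eps * g_new[j];
      for (int j = 0; j < D; ++j) th_prop[j] += eps * inv_mass[j] * p_mom[j];
      lp_prop = m.logp_grad(th_prop, g_new);
      if (!std::isfinite(lp_prop)) { diverged = true; break; }
      for (int j = 0; j < D; ++j) p_mom[j] += 0.5 * eps * g_new[j];
    }
    double alpha = 0.0;
    if (!diverged) {
      double H1 = -lp_prop;
      for (int j = 0; j < D; ++j) H1 += 0.5 * p_mom[j] * p_mom[j] * inv_mass[j];
      double dH = H0 - H1;
      alpha = dH > 0 ? 1.0 : std::exp(dH);
      if (rng.unif() < alpha) { th = th_prop; lp = lp_prop; g = g_new; }
      else { m.logp_grad(th, g); } // restore gradient at current point
    } else {
      m.logp_grad(th, g);
    }

    if (it < warmup) {
      // dual averaging step-size adaptation
      da_iter++;
      double w = 1.0 / (da_iter + t0);
      Hbar = (1.0 - w) * Hbar + w * (target_accept - alpha);
      double log_eps = mu - std::sqrt(static_cast<double>(da_iter)) / gamma * Hbar;
      double pw = std::pow(static_cast<double>(da_iter), -kappa);
      log_eps_bar = pw * log_eps + (1.0 - pw) * log_eps_bar;
      eps = std::exp(log_eps);

      if (it >= w1 && it < w2) { // Welford accumulation for mass matrix
        n_acc++;
        for (int j = 0; j < D; ++j) {
          double d = th[j] - acc_m[j];
          acc_m[j] += d / n_acc;
          acc_s[j] += d * (th[j] - acc_m[j]);
        }
      }
      if (it == w2 - 1 && n_acc > 10) {
        for (int j = 0; j < D; ++j) {
          double v = acc_s[j] / (n_acc - 1);
          inv_mass[j] = v * n_acc / (n_acc + 5.0) + 1e-3 * 5.0 / (n_acc + 5.0);
        }
        // restart step-size adaptation around the current step
        mu = std::log(10.0 * eps);
        Hbar = 0.0; da_iter = 0; log_eps_bar = std::log(eps);
      }
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      accept_sum += alpha;
      int row = it - warmup;
      // store constrained, centred parameters:
      // [beta_p, beta_f, a | r(I) | alpha_L(L) | alpha_C(C) | p(C) | sigmas(4)]
      double sQ = std::exp(th[m.off_t()]), sR = std::exp(th[m.off_t() + 1]),
             sL = std::exp(th[m.off_t() + 2]), sC = std::exp(th[m.off_t() + 3]);
      draws(row, 0) = th[0]; draws(row, 1) = th[1]; draws(row, 2) = th[2];
      for (int i = 0; i < m.I; ++i) draws(row, 3 + i) = sR * th[m.off_zr() + i];
      for (int l = 0; l < m.L; ++l) draws(row, 3 + m.I + l) = sL * th[m.off_zL() + l];
      for (int c = 0; c < m.C; ++c) draws(row, 3 + m.I + m.L + c) = sC * th[m.off_zC() + c];
      for (int c = 0; c < m.C; ++c)
        draws(row, 3 + m.I + m.L + m.C + c) = 1.0 / (1.0 + std::exp(-th[m.off_up() + c]));
      draws(row, D - 4) = sQ; draws(row, D - 3) = sR;
      draws(row, D - 2) = sL; draws(row, D - 1) = sC;
      lp_out[row] = lp;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["step_size"] = eps,
                      _["mean_accept"] = accept_sum / iters);
}
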