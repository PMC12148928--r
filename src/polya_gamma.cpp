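#include <Rcpp.h>
using namespace Rcpp;

// Sampler for the Polya-Gamma distribution PG(1, c), via the identity
// PG(1, c) = J*(1, c/2) / 4 and Devroye's alternating-series rejection
// sampler for the tilted Jacobi distribution J*(1, z).  All randomness
// comes from R's RNG (unif_rand / exp_rand / norm_rand), so draws are
// reproducible under set.seed().

static const double TRUNC = 0.64;  // series crossover point

// piecewise coefficients a_n(x) of the Jacobi density series
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC) {
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  }
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at x (z >= 0; z = 0 is the
// limiting one-sided stable case)
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double p = R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 0);
  double q = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0);
  return q + std::exp(2.0 * z) * p;
}

// inverse-Gaussian(1/z, 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mean beyond the truncation point: chi-based proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one draw from J*(1, z), z >= 0
static double sample_jstar(double z) {
  double k = z * z / 2.0 + M_PI * M_PI / 8.0;
  double p = (M_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() * (p + q) <= p) {
      x = TRUNC + exp_rand() / k;   // exponential right tail
    } else {
      x = rtigauss(z, TRUNC);       // truncated inverse-Gaussian body
    }
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject, draw a new proposal
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, c) variates
//'
//' @param c numeric vector of tilting parameters (any sign).
//' @return numeric vector of PG(1, c) draws, same length as `c`.
//' @keywords internal
// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector c) {
  R_xlen_t n = c.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = sample_jstar(std::fabs(c[i]) / 2.0) / 4.0;
  }
  return out;
}
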