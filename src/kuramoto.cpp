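#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Phase velocity dtheta_j = omega_j + K * sum_h C_jh * sin(theta_h - theta_j)
// via sin(b - a) = cos(a)(C sin)(a) - sin(a)(C cos)(a); all buffers
// preallocated by the caller.
static inline void phase_velocity(const arma::mat& C, const arma::vec& omega,
                                  double K, const arma::vec& theta,
                                  arma::vec& s, arma::vec& c, arma::vec& Cs,
                                  arma::vec& Cc, arma::vec& out) {
  const arma::uword n = theta.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    s[i] = std::sin(theta[i]);
    c[i] = std::cos(theta[i]);
  }
  Cs = C * s;
  Cc = C * c;
  for (arma::uword i = 0; i < n; ++i)
    out[i] = omega[i] + K * (c[i] * Cs[i] - s[i] * Cc[i]);
}

// Classical RK4 integration of the Kuramoto model, recording the order
// parameter r(t) and mean phase phi(t) every `record_stride` steps (step 0
// included). Returns final phases as well.
// [[Rcpp::export]]
List km_integrate(const arma::mat& C, const arma::vec& omega,
                  const arma::vec& theta0, double K, int n_steps, double dt,
                  int record_stride) {
  const int n_rec = n_steps / record_stride + 1;
  const arma::uword n = theta0.n_elem;
  arma::vec t_out(n_rec), r_out(n_rec), phi_out(n_rec);
  arma::vec theta = theta0;
  arma::vec s(n), c(n), Cs(n), Cc(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  const double N = static_cast<double>(n);

  int rec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % record_stride == 0) {
      double re = 0.0, im = 0.0;
      for (arma::uword i = 0; i < n; ++i) {
        re += std::cos(theta[i]);
        im += std::sin(theta[i]);
      }
      re /= N;
      im /= N;
      t_out(rec) = step * dt;
      r_out(rec) = std::min(1.0, std::sqrt(re * re + im * im));
      phi_out(rec) = std::atan2(im, re);
      ++rec;
    }
    if (step == n_steps) break;
    phase_velocity(C, omega, K, theta, s, c, Cs, Cc, k1);
    tmp = theta + (0.5 * dt) * k1;
    phase_velocity(C, omega, K, tmp, s, c, Cs, Cc, k2);
    tmp = theta + (0.5 * dt) * k2;
    phase_velocity(C, omega, K, tmp, s, c, Cs, Cc, k3);
    tmp = theta + dt * k3;
    phase_velocity(C, omega, K, tmp, s, c, Cs, Cc, k4);
    theta += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return List::create(_["t"] = t_out, _["r"] = r_out, _["phi"] = phi_out,
                      _["theta_final"] = theta);
}
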