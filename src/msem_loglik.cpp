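// Marginal log-likelihood of the two-level latent-factor ordinal probit
// model, integrated by nested Gauss-Hermite quadrature:
//   outer integral over the household residual u_j ~ N(0, psi_hh),
//   inner integrals (one per member) over e_ij ~ N(0, psi_ind),
//   eta_ij = x_ij'beta + z_j'gamma + u_j + e_ij,
//   P(Y_pij = c | eta) = Phi((tau_{p,c}-lambda_p eta)/sd_p)
//                      - Phi((tau_{p,c-1}-lambda_p eta)/sd_p).
// Gradients are analytic in beta, gamma, log psi_ind, log psi_hh and
// (optionally) lambda_2..lambda_K; thresholds and theta stay fixed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double phi_cdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}
static inline double phi_pdf(double z) {
  return std::exp(-0.5 * z * z) * 0.3989422804014327;
}

// [[Rcpp::export]]
List msem_loglik_cpp(IntegerMatrix Y, NumericMatrix X, NumericMatrix Z,
                     IntegerVector hh_start, IntegerVector hh_len,
                     NumericVector lambda, List tau, NumericVector theta,
                     NumericVector beta, NumericVector gamma,
                     double psi_ind, double psi_hh,
                     NumericVector gh_x, NumericVector gh_w,
                     bool want_grad, bool grad_lambda) {
  const int N = Y.nrow(), K = Y.ncol();
  const int J = hh_start.size();
  const int px = X.ncol(), pz = Z.ncol();
  const int Q = gh_x.size();
  const double s_hh = std::sqrt(psi_hh), s_in = std::sqrt(psi_ind);

  // unpack cutpoints
  std::vector< std::vector<double> > cuts(K);
  std::vector<double> sd(K), lam(K);
  for (int p = 0; p < K; ++p) {
    NumericVector t = tau[p];
    cuts[p] = std::vector<double>(t.begin(), t.end());
    sd[p] = std::sqrt(theta[p]);
    lam[p] = lambda[p];
  }

  // linear predictor m_i = x_i'beta + z_{j(i)}'gamma
  std::vector<double> m(N, 0.0);
  for (int j = 0; j < J; ++j) {
    double zg = 0.0;
    for (int r = 0; r < pz; ++r) zg += Z(j, r) * gamma[r];
    for (int i = hh_start[j]; i < hh_start[j] + hh_len[j]; ++i) {
      double xb = zg;
      for (int k = 0; k < px; ++k) xb += X(i, k) * beta[k];
      m[i] = xb;
    }
  }

  const int npar = px + pz + 2 + (grad_lambda ? K : 0);
  NumericVector grad(want_grad ? npar : 0);
  NumericVector hh_ll(J);
  double ll = 0.0;

  // scratch, sized for the largest household
  int max_ni = 0;
  for (int j = 0; j < J; ++j) if (hh_len[j] > max_ni) max_ni = hh_len[j];
  std::vector<double> logA(max_ni * Q), rm(max_ni * Q), rse(max_ni * Q);
  std::vector<double> rlam(grad_lambda ? (size_t)max_ni * Q * K : 0);
  std::vector<double> S(Q), Qw(Q);
  std::vector<double> dlog_dlam(K);

  for (int j = 0; j < J; ++j) {
    const int i0 = hh_start[j], ni = hh_len[j];
    for (int ii = 0; ii < ni; ++ii) {
      const int i = i0 + ii;
      for (int a = 0; a < Q; ++a) {
        const double u = s_hh * gh_x[a];
        double A = 0.0, dAm = 0.0, dAse = 0.0;
        std::vector<double> dAlam(grad_lambda ? K : 0, 0.0);
        for (int b = 0; b < Q; ++b) {
          const double eta = m[i] + u + s_in * gh_x[b];
          double logg = 0.0, dsum = 0.0;
          if (grad_lambda)
            std::fill(dlog_dlam.begin(), dlog_dlam.end(), 0.0);
          for (int p = 0; p < K; ++p) {
            const int c = Y(i, p);           // 1-based category
            const int nc = (int)cuts[p].size() + 1;
            const double le = lam[p] * eta;
            double Pu, Pl, fu = 0.0, fl = 0.0;
            if (c < nc) {
              const double zu = (cuts[p][c - 1] - le) / sd[p];
              Pu = phi_cdf(zu); fu = phi_pdf(zu);
            } else Pu = 1.0;
            if (c > 1) {
              const double zl = (cuts[p][c - 2] - le) / sd[p];
              Pl = phi_cdf(zl); fl = phi_pdf(zl);
            } else Pl = 0.0;
            double P = Pu - Pl;
            if (P < 1e-300) P = 1e-300;
            logg += std::log(P);
            if (want_grad) {
              const double dP = (fu - fl) / (sd[p] * P);
              dsum += -lam[p] * dP;
              if (grad_lambda) dlog_dlam[p] = -eta * dP;
            }
          }
          const double g = gh_w[b] * std::exp(logg);
          A += g;
          if (want_grad) {
            dAm += g * dsum;
            dAse += g * dsum * gh_x[b];
            if (grad_lambda)
              for (int p = 0; p < K; ++p) dAlam[p] += g * dlog_dlam[p];
          }
        }
        if (A < 1e-300) A = 1e-300;
        logA[ii * Q + a] = std::log(A);
        if (want_grad) {
          rm[ii * Q + a] = dAm / A;
          rse[ii * Q + a] = dAse / A;
          if (grad_lambda)
            for (int p = 0; p < K; ++p)
              rlam[((size_t)ii * Q + a) * K + p] = dAlam[p] / A;
        }
      }
    }
    double Smax = -1e308;
    for (int a = 0; a < Q; ++a) {
      double s = 0.0;
      for (int ii = 0; ii < ni; ++ii) s += logA[ii * Q + a];
      S[a] = s;
      if (s > Smax) Smax = s;
    }
    double den = 0.0;
    for (int a = 0; a < Q; ++a) {
      Qw[a] = gh_w[a] * std::exp(S[a] - Smax);
      den += Qw[a];
    }
    const double llj = Smax + std::log(den);
    if (!std::isfinite(llj))
      stop("non-finite log-likelihood at household %d", j + 1);
    hh_ll[j] = llj;
    ll += llj;

    if (want_grad) {
      double g_sh = 0.0, g_se = 0.0, g_z = 0.0;
      for (int a = 0; a < Q; ++a) {
        const double qa = Qw[a] / den;
        double sum_rm = 0.0, sum_rse = 0.0;
        for (int ii = 0; ii < ni; ++ii) {
          sum_rm += rm[ii * Q + a];
          sum_rse += rse[ii * Q + a];
        }
        g_sh += qa * gh_x[a] * sum_rm;
        g_se += qa * sum_rse;
        g_z += qa * sum_rm;
      }
      for (int ii = 0; ii < ni; ++ii) {
        const int i = i0 + ii;
        double dmi = 0.0;
        for (int a = 0; a < Q; ++a) dmi += (Qw[a] / den) * rm[ii * Q + a];
        for (int k = 0; k < px; ++k) grad[k] += X(i, k) * dmi;
      }
      for (int r = 0; r < pz; ++r) grad[px + r] += Z(j, r) * g_z;
      // d/d log psi = (s/2) d/d s
      grad[px + pz] += 0.5 * s_in * g_se;
      grad[px + pz + 1] += 0.5 * s_hh * g_sh;
      if (grad_lambda) {
        for (int p = 0; p < K; ++p) {
          double gl = 0.0;
          for (int a = 0; a < Q; ++a) {
            const double qa = Qw[a] / den;
            double s = 0.0;
            for (int ii = 0; ii < ni; ++ii)
              s += rlam[((size_t)ii * Q + a) * K + p];
            gl += qa * s;
          }
          grad[px + pz + 2 + p] += gl;
        }
      }
    }
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad,
                      _["hh_loglik"] = hh_ll);
}
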