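#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs samplers for Poisson-likelihood image restoration
// with homogeneous (Laplace / Gaussian) MRF priors and the locally adaptive
// Laplace+Gaussian mixture prior.  The system matrix arrives in CSC form
// (column j = detector rows touched by pixel j), so per-pixel likelihood
// deltas only visit the rows the pixel can influence.

namespace {

struct Csc {
  const int *p;       // column pointers, length m + 1
  const int *i;       // row indices (0-based)
  const double *x;    // values
};

// Change in Poisson log-likelihood when pixel j moves by delta.
// Rows with y = 0 contribute only -a_ij * delta (folded into colsum).
inline double dll_pixel(int j, double delta, const Csc &A,
                        const std::vector<double> &lambda,
                        const int *y, double colsum_j) {
  double s = -delta * colsum_j;
  for (int k = A.p[j]; k < A.p[j + 1]; ++k) {
    int row = A.i[k];
    if (y[row] > 0) {
      double lam = lambda[row];
      double lam2 = lam + A.x[k] * delta;
      if (lam2 <= 0.0) return R_NegInf;
      s += y[row] * (std::log(lam2) - std::log(lam));
    }
  }
  return s;
}

inline void apply_pixel(int j, double delta, const Csc &A,
                        std::vector<double> &lambda) {
  for (int k = A.p[j]; k < A.p[j + 1]; ++k)
    lambda[A.i[k]] += A.x[k] * delta;
}

inline int n_neighbours(int r, int c, int rows, int cols) {
  return (r > 0) + (r < rows - 1) + (c > 0) + (c < cols - 1);
}

// Fill nb with row-major neighbour indices of pixel (r, c); returns count.
inline int neighbours(int j, int rows, int cols, int nb[4]) {
  int r = j / cols, c = j % cols, n = 0;
  if (r > 0) nb[n++] = j - cols;
  if (r < rows - 1) nb[n++] = j + cols;
  if (c > 0) nb[n++] = j - 1;
  if (c < cols - 1) nb[n++] = j + 1;
  return n;
}

// Global MRF energy, each unordered pair once.
double energy(const std::vector<double> &x, int rows, int cols, bool quad) {
  double e = 0.0;
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < cols; ++c) {
      int j = r * cols + c;
      if (c + 1 < cols) {
        double d = x[j] - x[j + 1];
        e += quad ? d * d : std::fabs(d);
      }
      if (r + 1 < rows) {
        double d = x[j] - x[j + cols];
        e += quad ? d * d : std::fabs(d);
      }
    }
  return e;
}

// Local energies Phi_j (pair weight 0.5) at pixel j.
inline void local_energy(const std::vector<double> &x, int j, int rows,
                         int cols, double &ea, double &eq) {
  int nb[4];
  int n = neighbours(j, rows, cols, nb);
  ea = 0.0; eq = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = x[j] - x[nb[k]];
    ea += 0.5 * std::fabs(d);
    eq += 0.5 * d * d;
  }
}

inline double adapt(double scale, double acc, double att, double target) {
  double r = att > 0 ? acc / att : 0.0;
  return 0.5 * scale * (1.0 + r / target);
}

inline double sq(double z) { return z * z; }

}  // namespace

// One homogeneous-model Metropolis sweep over all pixels in raster order.
// potential: 0 = absolute (Laplace), 1 = quadratic (Gaussian).
static int sweep_homog(std::vector<double> &x, std::vector<double> &lambda,
                       const Csc &A, const int *y, const double *colsum,
                       int rows, int cols, int potential, double tau,
                       double sd) {
  int m = rows * cols, acc = 0, nb[4];
  for (int j = 0; j < m; ++j) {
    double xp = x[j] + norm_rand() * sd;
    if (xp < 0.0) continue;  // positivity constraint: reject outright
    double delta = xp - x[j];
    double dpr = 0.0;
    int n = neighbours(j, rows, cols, nb);
    for (int k = 0; k < n; ++k) {
      double dn = xp - x[nb[k]], dold = x[j] - x[nb[k]];
      dpr += potential ? (dn * dn - dold * dold)
                       : (std::fabs(dn) - std::fabs(dold));
    }
    double lr = dll_pixel(j, delta, A, lambda, y, colsum[j]);
    lr -= potential ? dpr / (2.0 * tau * tau) : dpr / tau;
    if (std::log(unif_rand()) < lr) {
      apply_pixel(j, delta, A, lambda);
      x[j] = xp;
      ++acc;
    }
  }
  return acc;
}

// One mixture-model Metropolis sweep over all pixels.
static int sweep_mix(std::vector<double> &x, std::vector<double> &lambda,
                     const Csc &A, const int *y, const double *colsum,
                     int rows, int cols, const std::vector<int> &theta,
                     double tau_l, double tau_g, double sd) {
  int m = rows * cols, acc = 0, nb[4];
  for (int j = 0; j < m; ++j) {
    double xp = x[j] + norm_rand() * sd;
    if (xp < 0.0) continue;
    double delta = xp - x[j];
    double dpl = 0.0, dpg = 0.0;
    int n = neighbours(j, rows, cols, nb);
    for (int k = 0; k < n; ++k) {
      int t = nb[k];
      double dn = xp - x[t], dold = x[j] - x[t];
      double wl = 0.5 * (theta[j] + theta[t]);
      double wg = 0.5 * ((1 - theta[j]) + (1 - theta[t]));
      if (wl > 0.0) dpl += wl * (std::fabs(dn) - std::fabs(dold));
      if (wg > 0.0) dpg += wg * (dn * dn - dold * dold);
    }
    double lr = dll_pixel(j, delta, A, lambda, y, colsum[j]) -
                dpl / tau_l - dpg / (2.0 * tau_g * tau_g);
    if (std::log(unif_rand()) < lr) {
      apply_pixel(j, delta, A, lambda);
      x[j] = xp;
      ++acc;
    }
  }
  return acc;
}

// [[Rcpp::export]]
List run_homogeneous_cpp(IntegerVector y, IntegerVector Ap, IntegerVector Ai,
                         NumericVector Ax, int rows, int cols, int potential,
                         bool estimate_tau, double tau0, NumericVector x0,
                         int iterations, int burn_in, int adapt_interval,
                         double target_rate, double sd_pixel0, double sd_tau0,
                         int thin, bool store_x) {
  RNGScope scope;
  int m = rows * cols, n = y.size();
  Csc A{Ap.begin(), Ai.begin(), Ax.begin()};
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> lambda(n, 0.0);
  std::vector<double> colsum(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) {
      lambda[A.i[k]] += A.x[k] * x[j];
      colsum[j] += A.x[k];
    }
  // Initial state must have finite log-posterior.
  for (int i = 0; i < n; ++i)
    if (y[i] > 0 && lambda[i] <= 0.0)
      stop("non-finite initial log-posterior: lambda = 0 where y > 0");

  double tau = tau0, sd_pixel = sd_pixel0, sd_tau = sd_tau0;
  bool quad = potential == 1;

  NumericVector tau_tr(iterations), acc_pix_tr(iterations),
      acc_tau_tr(iterations), sd_pix_tr(iterations), sd_tau_tr(iterations);
  int n_keep = store_x ? (iterations + thin - 1) / thin : 0;
  NumericMatrix xs(n_keep, store_x ? m : 0);
  IntegerVector kept(n_keep);
  std::vector<double> xsum(m, 0.0), x2sum(m, 0.0);
  int n_post = 0, keep_row = 0;
  double pix_acc = 0, pix_att = 0, tau_acc = 0, tau_att = 0;

  for (int k = 1; k <= iterations; ++k) {
    int acc = sweep_homog(x, lambda, A, y.begin(), colsum.data(), rows, cols,
                          potential, tau, sd_pixel);
    acc_pix_tr[k - 1] = static_cast<double>(acc) / m;
    pix_acc += acc; pix_att += m;

    if (estimate_tau) {
      double e = energy(x, rows, cols, quad);
      double taup = tau + norm_rand() * sd_tau;
      double a = 0;
      if (taup <= 0.0) {
        a = 0;
      } else {
        double lo, ln;
        if (quad) {
          lo = -e / (2.0 * tau * tau) - m * std::log(std::sqrt(2.0 * M_PI) * tau);
          ln = -e / (2.0 * taup * taup) - m * std::log(std::sqrt(2.0 * M_PI) * taup);
        } else {
          lo = -e / tau - m * std::log(2.0 * tau);
          ln = -e / taup - m * std::log(2.0 * taup);
        }
        double lr = (ln - std::log(taup)) - (lo - std::log(tau));
        if (std::log(unif_rand()) < lr) { tau = taup; a = 1; }
      }
      acc_tau_tr[k - 1] = a;
      tau_acc += a; tau_att += 1;
    } else {
      acc_tau_tr[k - 1] = NA_REAL;
    }
    tau_tr[k - 1] = tau;
    sd_pix_tr[k - 1] = sd_pixel; sd_tau_tr[k - 1] = sd_tau;

    if (k <= burn_in && k % adapt_interval == 0) {
      sd_pixel = adapt(sd_pixel, pix_acc, pix_att, target_rate);
      if (estimate_tau) sd_tau = adapt(sd_tau, tau_acc, tau_att, target_rate);
      pix_acc = pix_att = tau_acc = tau_att = 0;
    }
    if (k > burn_in) {
      ++n_post;
      for (int j = 0; j < m; ++j) { xsum[j] += x[j]; x2sum[j] += x[j] * x[j]; }
    }
    if (store_x && (k - 1) % thin == 0) {
      for (int j = 0; j < m; ++j) xs(keep_row, j) = x[j];
      kept[keep_row] = k;
      ++keep_row;
    }
  }

  NumericVector xm(m), xv(m);
  for (int j = 0; j < m; ++j) {
    xm[j] = n_post > 0 ? xsum[j] / n_post : NA_REAL;
    xv[j] = n_post > 1
      ? std::max(0.0, (x2sum[j] - n_post * xm[j] * xm[j]) / (n_post - 1))
      : NA_REAL;
  }
  return List::create(
      _["x_mean"] = xm, _["x_var"] = xv, _["tau"] = tau_tr,
      _["accept_pixel"] = acc_pix_tr, _["accept_tau"] = acc_tau_tr,
      _["sd_pixel"] = sd_pix_tr, _["sd_tau"] = sd_tau_tr,
      _["x_samples"] = store_x ? (SEXP)xs : R_NilValue,
      _["kept_iterations"] = store_x ? (SEXP)kept : R_NilValue,
      _["x_last"] = NumericVector(x.begin(), x.end()));
}

// [[Rcpp::export]]
List run_mixture_cpp(IntegerVector y, IntegerVector Ap, IntegerVector Ai,
                     NumericVector Ax, int rows, int cols, NumericVector x0,
                     IntegerVector theta0, double tau_l0, double tau_g0,
                     double rho0, NumericVector hyper, bool estimate_scales,
                     bool estimate_rho, int theta_mode, int rho_mode,
                     int iterations, int burn_in, int adapt_interval,
                     double target_rate, double sd_pixel0, double sd_tau_l0,
                     double sd_tau_g0, double sd_rho0, int thin, bool store_x,
                     bool store_theta) {
  RNGScope scope;
  int m = rows * cols, n = y.size();
  Csc A{Ap.begin(), Ai.begin(), Ax.begin()};
  double mean_l = hyper[0], mean_g = hyper[1], sd_hl = hyper[2],
         sd_hg = hyper[3], alpha = hyper[4], beta = hyper[5];
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<int> theta(theta0.begin(), theta0.end());
  std::vector<double> lambda(n, 0.0), colsum(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) {
      lambda[A.i[k]] += A.x[k] * x[j];
      colsum[j] += A.x[k];
    }
  for (int i = 0; i < n; ++i)
    if (y[i] > 0 && lambda[i] <= 0.0)
      stop("non-finite initial log-posterior: lambda = 0 where y > 0");

  double tau_l = tau_l0, tau_g = tau_g0, rho = rho0;
  double sd_pixel = sd_pixel0, sd_tl = sd_tau_l0, sd_tg = sd_tau_g0,
         sd_rho = sd_rho0;

  NumericVector tl_tr(iterations), tg_tr(iterations), rho_tr(iterations),
      acc_pix_tr(iterations), acc_th_tr(iterations), acc_tl_tr(iterations),
      acc_tg_tr(iterations), acc_rho_tr(iterations), sd_pix_tr(iterations);
  int n_keep = (store_x || store_theta) ? (iterations + thin - 1) / thin : 0;
  NumericMatrix xs(store_x ? n_keep : 0, store_x ? m : 0);
  IntegerMatrix ths(store_theta ? n_keep : 0, store_theta ? m : 0);
  IntegerVector kept(n_keep);
  std::vector<double> xsum(m, 0.0), x2sum(m, 0.0), thsum(m, 0.0);
  int n_post = 0, keep_row = 0;
  double pix_acc = 0, pix_att = 0, th_acc = 0, th_att = 0, tl_acc = 0,
         tl_att = 0, tg_acc = 0, tg_att = 0, rho_acc = 0, rho_att = 0;
  const double eps = 1e-12;

  for (int k = 1; k <= iterations; ++k) {
    // 1. image sweep under the current labels and scales
    int acc = sweep_mix(x, lambda, A, y.begin(), colsum.data(), rows, cols,
                        theta, tau_l, tau_g, sd_pixel);
    acc_pix_tr[k - 1] = static_cast<double>(acc) / m;
    pix_acc += acc; pix_att += m;

    // 2. spatial factor: exact-conditional (Gibbs) or Metropolis flips.
    //    Given x the labels are conditionally independent.
    double rho_c = std::min(1.0 - eps, std::max(eps, rho));
    double logit_rho = std::log(rho_c) - std::log1p(-rho_c);
    int th_acc_k = 0;
    for (int j = 0; j < m; ++j) {
      double ea, eq;
      local_energy(x, j, rows, cols, ea, eq);
      double log_l = -ea / tau_l - std::log(2.0 * tau_l);
      double log_g = -eq / (2.0 * tau_g * tau_g) -
                     std::log(std::sqrt(2.0 * M_PI) * tau_g);
      double z = logit_rho + log_l - log_g;  // log odds of theta_j = 1
      if (theta_mode == 0) {
        double p = 1.0 / (1.0 + std::exp(-z));
        theta[j] = unif_rand() < p ? 1 : 0;
      } else {
        double lr = theta[j] == 1 ? -z : z;  // propose a flip
        if (std::log(unif_rand()) < lr) { theta[j] = 1 - theta[j]; ++th_acc_k; }
        ++th_att;
      }
    }
    th_acc += th_acc_k;
    acc_th_tr[k - 1] = theta_mode == 1 ? static_cast<double>(th_acc_k) / m
                                       : NA_REAL;

    // 3. scales: two conditionally independent Metropolis updates on the
    //    pixel subsets selected by theta, plus their Gaussian hyperpriors.
    double a_tl = NA_REAL, a_tg = NA_REAL;
    if (estimate_scales) {
      double S_l = 0.0, S_g = 0.0;
      int n_l = 0, n_g = 0;
      for (int j = 0; j < m; ++j) {
        double ea, eq;
        local_energy(x, j, rows, cols, ea, eq);
        if (theta[j] == 1) { S_l += ea; ++n_l; }
        else               { S_g += eq; ++n_g; }
      }
      double tp = tau_l + norm_rand() * sd_tl;
      a_tl = 0;
      if (tp > 0.0) {
        double lr = (-S_l / tp - n_l * std::log(2.0 * tp) -
                     0.5 * sq((tp - mean_l) / sd_hl)) -
                    (-S_l / tau_l - n_l * std::log(2.0 * tau_l) -
                     0.5 * sq((tau_l - mean_l) / sd_hl));
        if (std::log(unif_rand()) < lr) { tau_l = tp; a_tl = 1; }
      }
      tl_acc += a_tl; tl_att += 1;
      tp = tau_g + norm_rand() * sd_tg;
      a_tg = 0;
      if (tp > 0.0) {
        double lr = (-S_g / (2.0 * tp * tp) -
                     n_g * std::log(std::sqrt(2.0 * M_PI) * tp) -
                     0.5 * sq((tp - mean_g) / sd_hg)) -
                    (-S_g / (2.0 * tau_g * tau_g) -
                     n_g * std::log(std::sqrt(2.0 * M_PI) * tau_g) -
                     0.5 * sq((tau_g - mean_g) / sd_hg));
        if (std::log(unif_rand()) < lr) { tau_g = tp; a_tg = 1; }
      }
      tg_acc += a_tg; tg_att += 1;
    }
    acc_tl_tr[k - 1] = a_tl; acc_tg_tr[k - 1] = a_tg;

    // 4. edge probability: conjugate Beta draw or Metropolis step
    double a_rho = NA_REAL;
    if (estimate_rho) {
      int s = 0;
      for (int j = 0; j < m; ++j) s += theta[j];
      if (rho_mode == 0) {
        rho = R::rbeta(alpha + s, beta + m - s);
      } else {
        double rp = rho + norm_rand() * sd_rho;
        a_rho = 0;
        if (rp > 0.0 && rp < 1.0) {
          double lr = ((alpha - 1 + s) * std::log(rp) +
                       (beta - 1 + m - s) * std::log1p(-rp)) -
                      ((alpha - 1 + s) * std::log(rho_c) +
                       (beta - 1 + m - s) * std::log1p(-rho_c));
          if (std::log(unif_rand()) < lr) { rho = rp; a_rho = 1; }
        }
        rho_acc += a_rho; rho_att += 1;
      }
    }
    acc_rho_tr[k - 1] = a_rho;

    tl_tr[k - 1] = tau_l; tg_tr[k - 1] = tau_g; rho_tr[k - 1] = rho;
    sd_pix_tr[k - 1] = sd_pixel;

    if (k <= burn_in && k % adapt_interval == 0) {
      sd_pixel = adapt(sd_pixel, pix_acc, pix_att, target_rate);
      if (estimate_scales) {
        sd_tl = adapt(sd_tl, tl_acc, tl_att, target_rate);
        sd_tg = adapt(sd_tg, tg_acc, tg_att, target_rate);
      }
      if (estimate_rho && rho_mode == 1)
        sd_rho = adapt(sd_rho, rho_acc, rho_att, target_rate);
      pix_acc = pix_att = th_acc = th_att = tl_acc = tl_att = 0;
      tg_acc = tg_att = rho_acc = rho_att = 0;
    }
    if (k > burn_in) {
      ++n_post;
      for (int j = 0; j < m; ++j) {
        xsum[j] += x[j]; x2sum[j] += x[j] * x[j]; thsum[j] += theta[j];
      }
    }
    if ((store_x || store_theta) && (k - 1) % thin == 0) {
      if (store_x)
        for (int j = 0; j < m; ++j) xs(keep_row, j) = x[j];
      if (store_theta)
        for (int j = 0; j < m; ++j) ths(keep_row, j) = theta[j];
      kept[keep_row] = k;
      ++keep_row;
    }
  }

  NumericVector xm(m), xv(m), thf(m);
  for (int j = 0; j < m; ++j) {
    xm[j] = n_post > 0 ? xsum[j] / n_post : NA_REAL;
    xv[j] = n_post > 1
      ? std::max(0.0, (x2sum[j] - n_post * xm[j] * xm[j]) / (n_post - 1))
      : NA_REAL;
    thf[j] = n_post > 0 ? thsum[j] / n_post : NA_REAL;
  }
  return List::create(
      _["x_mean"] = xm, _["x_var"] = xv, _["theta_freq"] = thf,
      _["tau_l"] = tl_tr, _["tau_g"] = tg_tr, _["rho"] = rho_tr,
      _["accept_pixel"] = acc_pix_tr, _["accept_theta"] = acc_th_tr,
      _["accept_tau_l"] = acc_tl_tr, _["accept_tau_g"] = acc_tg_tr,
      _["accept_rho"] = acc_rho_tr, _["sd_pixel"] = sd_pix_tr,
      _["x_samples"] = store_x ? (SEXP)xs : R_NilValue,
      _["theta_samples"] = store_theta ? (SEXP)ths : R_NilValue,
      _["kept_iterations"] = (store_x || store_theta) ? (SEXP)kept : R_NilValue,
      _["x_last"] = NumericVector(x.begin(), x.end()),
      _["theta_last"] = IntegerVector(theta.begin(), theta.end()));
}
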