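#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Numerical kernels for the state-space model: the per-step observation
// log-likelihood (two-component von Mises mixture whose mixing
// probability is a logistic function of the latent state), the recursive
// filter, a bootstrap particle filter used as an independent likelihood
// oracle, and samplers for the generative model. All RNG goes through
// R's generator so results are reproducible under set.seed().
//
// The filter propagates the one-dimensional filtering density by
// sequential quadrature on an adaptive point set: prediction is the
// exact Gaussian convolution of the previous step's (compressed)
// point-mass representation; the update multiplies in the pooled
// observation likelihood, with local grid refinement around posterior
// peaks so that posteriors much narrower than the predictive scale stay
// resolved, and edge extension when mass approaches the grid boundary.
// Gaussian moment summaries (mean/variance) are reported per step for
// smoothing and latent-path estimation.

static const double LOG2PI = std::log(2.0 * M_PI);

// pooled observation log-likelihood at latent state z:
//   l(z) = sum_j log[ p_j(z) e^{la_j} + (1 - p_j(z)) e^{lb_j} ],
//   p_j(z) = logistic(sgn * (beta_j + z)) = u_j t / (1 + u_j t)
// with u_j = exp(sgn beta_j) and t = exp(sgn z), so the inner loop is
// free of transcendentals: A/B hold exp(la - c), exp(lb - c) per trial,
// cmax_sum the summed per-trial maxima, all precomputed per time step.
static inline double obs_loglik(const double z,
                                const std::vector<double>& expb,
                                const std::vector<double>& A,
                                const std::vector<double>& B,
                                const double cmax_sum,
                                const double sgn) {
  const int J = (int)expb.size();
  const double e = std::max(-350.0, std::min(350.0, sgn * z));
  const double t = std::exp(e);
  double out = cmax_sum, prod = 1.0;
  for (int j = 0; j < J; ++j) {
    const double u = expb[j] * t;
    const double p = u / (1.0 + u);
    prod *= p * A[j] + (1.0 - p) * B[j];
    if (prod < 1e-280) {
      out += std::log(prod);
      prod = 1.0;
      if (!std::isfinite(out)) return -INFINITY;
    }
  }
  return out + std::log(prod);
}

static inline void step_logdens(const NumericMatrix& Y, const int n,
                                const double mu1, const double mu2,
                                const double kappa1, const double kappa2,
                                const double logI01, const double logI02,
                                std::vector<double>& la,
                                std::vector<double>& lb) {
  const int J = Y.nrow();
  for (int j = 0; j < J; ++j) {
    const double y = Y(j, n);
    la[j] = kappa1 * std::cos(y - mu1) - LOG2PI - logI01;
    lb[j] = kappa2 * std::cos(y - mu2) - LOG2PI - logI02;
  }
}

// log predictive density at z: either an analytic Gaussian or the
// convolution of the stored point masses with a Gaussian kernel of
// standard deviation `sigma` (the accumulated transition scale since the
// masses were formed)
static inline double log_pred_at(const double z, const bool analytic,
                                 const double m0, const double v0,
                                 const std::vector<double>& src_z,
                                 const std::vector<double>& src_lm,
                                 const double sigma) {
  if (analytic)
    return -0.5 * (z - m0) * (z - m0) / v0 - 0.5 * std::log(2.0 * M_PI * v0);
  // log sum_b exp(src_lm[b] + log phi(z - src_z[b]; sigma)); sources are
  // sorted in z, so the sum is restricted to the kernel's 8.2-sd band
  const double lnorm = -std::log(sigma) - 0.5 * LOG2PI;
  const double band = 8.2 * sigma;
  const size_t S = src_z.size();
  const size_t lo = std::lower_bound(src_z.begin(), src_z.end(),
                                     z - band) - src_z.begin();
  const size_t hi = std::upper_bound(src_z.begin(), src_z.end(),
                                     z + band) - src_z.begin();
  if (lo >= hi) return -745.0; // effectively zero density
  double mx = -INFINITY;
  std::vector<double> t(hi - lo);
  for (size_t b = lo; b < hi; ++b) {
    const double d = (z - src_z[b]) / sigma;
    t[b - lo] = src_lm[b] - 0.5 * d * d;
    if (t[b - lo] > mx) mx = t[b - lo];
  }
  if (!std::isfinite(mx)) return -745.0;
  double acc = 0.0;
  for (size_t b = lo; b < hi; ++b) acc += std::exp(t[b - lo] - mx);
  return mx + std::log(acc) + lnorm;
}

struct QPoint { double z, lpred, lobs; };

// Adaptive-grid sequential quadrature filter for one subject.
// Y: J x (N+1) matrix of angles (J = 0: pure prior recursion, loglik 0).
// [[Rcpp::export]]
List ga_filter_cpp(NumericMatrix Y, NumericVector beta_in,
                   double mu1, double mu2,
                   double kappa1, double kappa2,
                   double logI01, double logI02,
                   double sigma, double z0_mean, double z0_var,
                   double sgn, int n_base, int n_refine,
                   int max_refine) {
  const int J = Y.nrow();
  const int n_steps = Y.ncol();
  if (J != beta_in.size()) stop("beta length must equal the number of trials");
  std::vector<double> beta(beta_in.begin(), beta_in.end());

  NumericVector m_filt(n_steps), P_filt(n_steps);
  NumericVector m_pred_v(n_steps), P_pred_v(n_steps);
  double loglik = 0.0;
  const double s2 = sigma * sigma;

  std::vector<double> la(J), lb(J);
  std::vector<double> expb(J); // exp(sgn * beta_j), fixed across steps
  for (int j = 0; j < J; ++j) {
    const double e = std::max(-350.0, std::min(350.0, sgn * beta[j]));
    expb[j] = std::exp(e);
  }
  std::vector<double> src_z, src_lm; // posterior point masses (log)
  bool analytic = true;   // filtering density still exactly Gaussian
  double conv_var = 0.0;  // kernel variance accumulated since src formed
  double m_prev = 0.0, P_prev = 0.0;

  for (int n = 0; n < n_steps; ++n) {
    const double m_pred = (n == 0) ? z0_mean : m_prev;
    const double P_pred = (n == 0) ? z0_var : P_prev + s2;
    m_pred_v[n] = m_pred;
    P_pred_v[n] = P_pred;

    if (J == 0) { // no observations: moments follow the prior recursion
      m_filt[n] = m_pred; P_filt[n] = P_pred;
      m_prev = m_pred; P_prev = P_pred;
      continue;
    }

    step_logdens(Y, n, mu1, mu2, kappa1, kappa2, logI01, logI02, la, lb);

    // uninformative step (identical component densities at every trial):
    // the update is the identity and the increment is available in
    // closed form, so the prior recursion stays exact
    double dmax = 0.0;
    for (int j = 0; j < J; ++j)
      dmax = std::max(dmax, std::fabs(la[j] - lb[j]));
    if (dmax < 1e-12) {
      double inc = 0.0;
      for (int j = 0; j < J; ++j) inc += la[j];
      loglik += inc;
      m_filt[n] = m_pred; P_filt[n] = P_pred;
      m_prev = m_pred; P_prev = P_pred;
      if (!analytic) conv_var += s2;
      continue;
    }

    const double sd = std::sqrt(P_pred);
    // spacing must resolve both the predictive scale and the transition
    // kernel: trapezoidal Gaussian convolution has aliasing error
    // ~exp(-2 pi^2 (kernel sd / h)^2), so h <= 0.8 sigma keeps it below
    // 1e-13
    double h = std::min(17.0 * sd / std::max(n_base - 1, 8),
                        0.8 * sigma);
    int G = 2 * (int)std::ceil(8.5 * sd / h) + 1;
    if (G > 4001) { G = 4001; h = 17.0 * sd / (G - 1); }

    // per-trial mixture constants for this step
    std::vector<double> A(J), B(J);
    double cmax_sum = 0.0;
    for (int j = 0; j < J; ++j) {
      const double cj = std::max(la[j], lb[j]);
      cmax_sum += cj;
      A[j] = std::exp(la[j] - cj);
      B[j] = std::exp(lb[j] - cj);
    }

    const double ksd = analytic ? 0.0 : std::sqrt(conv_var);
    std::vector<QPoint> pts;
    std::vector<double> zs; // sorted z values of evaluated points
    pts.reserve(G + 4 * (max_refine + 1) * n_refine + 64);
    zs.reserve(pts.capacity());
    auto add_point = [&](double z, double spac) {
      // skip candidates with an existing point well inside their own
      // intended spacing (refinement passes re-propose similar windows)
      auto it = std::lower_bound(zs.begin(), zs.end(), z);
      double near = INFINITY;
      if (it != zs.end()) near = std::min(near, *it - z);
      if (it != zs.begin()) near = std::min(near, z - *(it - 1));
      if (near < 0.4 * spac) return;
      QPoint q;
      q.z = z;
      q.lpred = analytic
        ? log_pred_at(z, true, m_pred, P_pred, src_z, src_lm, 1.0)
        : log_pred_at(z, false, 0.0, 0.0, src_z, src_lm, ksd);
      q.lobs = obs_loglik(z, expb, A, B, cmax_sum, sgn);
      pts.push_back(q);
      zs.insert(it, z);
    };
    const int c = (G - 1) / 2;
    for (int i = 0; i < G; ++i) add_point(m_pred + (i - c) * h, h);

    // edge extension: grow the grid while the unnormalized posterior
    // density at a boundary is non-negligible
    for (int ext = 0; ext < 6; ++ext) {
      double qmax = -INFINITY;
      double zlo = INFINITY, zhi = -INFINITY;
      double qlo = 0, qhi = 0;
      for (const QPoint& q : pts) {
        const double v = q.lpred + q.lobs;
        if (v > qmax) qmax = v;
        if (q.z < zlo) { zlo = q.z; qlo = v; }
        if (q.z > zhi) { zhi = q.z; qhi = v; }
      }
      bool grew = false;
      if (qhi > qmax - 35.0) {
        for (int i = 1; i <= 16; ++i) add_point(zhi + i * h, h);
        grew = true;
      }
      if (qlo > qmax - 35.0) {
        for (int i = 1; i <= 16; ++i) add_point(zlo - i * h, h);
        grew = true;
      }
      if (!grew) break;
    }

    // local refinement around posterior peaks narrower than the grid
    for (int pass = 0; pass <= max_refine; ++pass) {
      std::sort(pts.begin(), pts.end(),
                [](const QPoint& a, const QPoint& b) { return a.z < b.z; });
      double qmax = -INFINITY;
      for (const QPoint& q : pts) qmax = std::max(qmax, q.lpred + q.lobs);
      // collect local maxima above qmax - 15
      struct Peak { double z, sdloc, hloc; };
      std::vector<Peak> peaks;
      for (size_t i = 1; i + 1 < pts.size(); ++i) {
        const double qm = pts[i - 1].lpred + pts[i - 1].lobs;
        const double q0 = pts[i].lpred + pts[i].lobs;
        const double qp = pts[i + 1].lpred + pts[i + 1].lobs;
        if (q0 >= qm && q0 >= qp && q0 > qmax - 15.0) {
          const double dl = pts[i].z - pts[i - 1].z;
          const double dr = pts[i + 1].z - pts[i].z;
          const double hl = std::max(dl, dr);
          // three-point second derivative on an unequal grid
          const double c2 = 2.0 * (qm / (dl * (dl + dr)) -
                                   q0 / (dl * dr) +
                                   qp / (dr * (dl + dr)));
          double sdloc = (c2 < -1e-12) ? 1.0 / std::sqrt(-c2) : hl;
          sdloc = std::max(sdloc, 1e-8 * sd);
          // refine only while the local spacing under-resolves the peak
          // (spacing ~ sdloc already gives ~1e-9 trapezoid accuracy)
          if (hl > sdloc && hl > 1e-7 * sd)
            peaks.push_back({pts[i].z, sdloc, hl});
          if (peaks.size() >= 4) break;
        }
      }
      if (peaks.empty()) break;
      for (const Peak& pk : peaks) {
        const double half = 6.0 * pk.sdloc;
        const double hr = 2.0 * half / (n_refine - 1);
        for (int i = 0; i < n_refine; ++i)
          add_point(pk.z - half + i * hr, hr);
      }
    }

    // assemble: sort, dedupe, trapezoid weights, increment, moments
    std::sort(pts.begin(), pts.end(),
              [](const QPoint& a, const QPoint& b) { return a.z < b.z; });
    std::vector<QPoint> u;
    u.reserve(pts.size());
    for (const QPoint& q : pts)
      if (u.empty() || q.z - u.back().z > 1e-9 * sd) u.push_back(q);
    const size_t M = u.size();
    if (M < 3) stop("degenerate quadrature grid at step %d", n);
    std::vector<double> lw(M);
    for (size_t i = 0; i < M; ++i) {
      const double left = (i == 0) ? u[1].z - u[0].z
        : u[i].z - u[i - 1].z;
      const double right = (i + 1 == M) ? u[M - 1].z - u[M - 2].z
        : u[i + 1].z - u[i].z;
      lw[i] = std::log(0.5 * (left + right));
    }
    double mx = -INFINITY;
    for (size_t i = 0; i < M; ++i)
      mx = std::max(mx, u[i].lpred + u[i].lobs + lw[i]);
    if (!std::isfinite(mx))
      stop("vanishing posterior mass at step %d", n);
    double Zs = 0.0;
    for (size_t i = 0; i < M; ++i)
      Zs += std::exp(u[i].lpred + u[i].lobs + lw[i] - mx);
    const double inc = mx + std::log(Zs);
    loglik += inc;

    double m1 = 0.0, m2 = 0.0;
    src_z.clear(); src_lm.clear();
    src_z.reserve(M); src_lm.reserve(M);
    for (size_t i = 0; i < M; ++i) {
      const double lp = u[i].lpred + u[i].lobs + lw[i] - inc; // log mass
      const double p = std::exp(lp);
      m1 += p * u[i].z;
      m2 += p * u[i].z * u[i].z;
      if (lp > -34.0) { // compress: drop negligible mass
        src_z.push_back(u[i].z);
        src_lm.push_back(lp);
      }
    }
    const double Pf = std::max(m2 - m1 * m1, 1e-10);
    m_filt[n] = m1;
    P_filt[n] = Pf;
    m_prev = m1; P_prev = Pf;
    analytic = false;
    conv_var = s2;
  }

  return List::create(_["m_filt"] = m_filt, _["P_filt"] = P_filt,
                      _["m_pred"] = m_pred_v, _["P_pred"] = P_pred_v,
                      _["loglik"] = loglik);
}

// helper for the particle filter and simulator
static inline double obs_loglik_nv(const double z,
                                   const NumericVector& beta,
                                   const std::vector<double>& la,
                                   const std::vector<double>& lb,
                                   const double sgn) {
  double out = 0.0;
  const int J = beta.size();
  for (int j = 0; j < J; ++j) {
    const double e = sgn * (beta[j] + z);
    double p;
    if (e >= 0) p = 1.0 / (1.0 + std::exp(-e));
    else { const double q = std::exp(e); p = q / (1.0 + q); }
    const double c = std::max(la[j], lb[j]);
    const double M = p * std::exp(la[j] - c) +
      (1.0 - p) * std::exp(lb[j] - c);
    out += c + std::log(M);
  }
  return out;
}

// Bootstrap particle filter with systematic resampling for one subject.
// Unbiased estimator of the marginal likelihood; the reported standard
// error treats the per-step relative weight variances as independent.
// [[Rcpp::export]]
List pf_loglik_cpp(NumericMatrix Y, NumericVector beta,
                   double mu1, double mu2,
                   double kappa1, double kappa2,
                   double logI01, double logI02,
                   double sigma, double z0_mean, double z0_var,
                   int n_particles, double sgn) {
  const int J = Y.nrow();
  const int n_steps = Y.ncol();
  const int Np = n_particles;
  std::vector<double> z(Np), z_new(Np), lw(Np), u(Np);
  std::vector<double> la(J), lb(J);
  double loglik = 0.0, var_sum = 0.0;

  const double sd0 = std::sqrt(z0_var);
  for (int p = 0; p < Np; ++p) z[p] = z0_mean + sd0 * norm_rand();

  for (int n = 0; n < n_steps; ++n) {
    if (n > 0)
      for (int p = 0; p < Np; ++p) z[p] += sigma * norm_rand();

    step_logdens(Y, n, mu1, mu2, kappa1, kappa2, logI01, logI02, la, lb);
    double lmax = -INFINITY;
    for (int p = 0; p < Np; ++p) {
      lw[p] = obs_loglik_nv(z[p], beta, la, lb, sgn);
      if (lw[p] > lmax) lmax = lw[p];
    }
    if (!std::isfinite(lmax))
      stop("particle degeneracy: all weights zero at step %d", n);
    double s1 = 0.0, s2 = 0.0;
    for (int p = 0; p < Np; ++p) {
      u[p] = std::exp(lw[p] - lmax);
      s1 += u[p]; s2 += u[p] * u[p];
    }
    if (s1 <= 0.0)
      stop("particle degeneracy: all weights zero at step %d", n);
    loglik += lmax + std::log(s1 / Np);
    const double mu_u = s1 / Np;
    const double cv2 = (s2 / Np) / (mu_u * mu_u) - 1.0;
    var_sum += std::max(cv2, 0.0) / Np;

    // systematic resampling
    const double u0 = unif_rand() / Np;
    double csum = u[0] / s1;
    int idx = 0;
    for (int p = 0; p < Np; ++p) {
      const double target = u0 + (double)p / Np;
      while (csum < target && idx < Np - 1) { ++idx; csum += u[idx] / s1; }
      z_new[p] = z[idx];
    }
    std::swap(z, z_new);
  }
  return List::create(_["loglik"] = loglik, _["se"] = std::sqrt(var_sum));
}

// Best-Fisher envelope-rejection sampler for the von Mises distribution.
// Returns angles in (-pi, pi] around mu. kappa = 0 falls back to uniform.
static inline double rvm1(const double mu, const double kappa) {
  if (kappa < 1e-12) return -M_PI + 2.0 * M_PI * unif_rand();
  const double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  const double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  const double r = (1.0 + b * b) / (2.0 * b);
  double theta;
  for (;;) {
    const double u1 = unif_rand();
    const double zc = std::cos(M_PI * u1);
    const double f = (1.0 + r * zc) / (r + zc);
    const double c = kappa * (r - f);
    const double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      const double u3 = unif_rand();
      theta = (u3 < 0.5 ? -1.0 : 1.0) * std::acos(f);
      break;
    }
  }
  double ang = mu + theta;
  while (ang > M_PI) ang -= 2.0 * M_PI;
  while (ang <= -M_PI) ang += 2.0 * M_PI;
  return ang;
}

// [[Rcpp::export]]
NumericVector rvonmises_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu, kappa);
  return out;
}

// Generate the observed angle array given latent paths and the trial-level
// linear predictor: component 1 is chosen with probability
// logistic(sgn * (beta_j + z_in)); draws are folded into [0, pi] by
// absolute value, matching the preprocessing convention.
// [[Rcpp::export]]
NumericVector simulate_angles_cpp(NumericMatrix Z, NumericVector beta,
                                  double mu1, double mu2,
                                  double kappa1, double kappa2,
                                  double sgn, bool fold) {
  const int I = Z.nrow();
  const int N1 = Z.ncol();
  const int J = beta.size();
  NumericVector out(I * J * N1);
  out.attr("dim") = IntegerVector::create(I, J, N1);
  for (int n = 0; n < N1; ++n)
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        const double e = sgn * (beta[j] + Z(i, n));
        double p;
        if (e >= 0) p = 1.0 / (1.0 + std::exp(-e));
        else { const double q = std::exp(e); p = q / (1.0 + q); }
        const bool first = (unif_rand() < p);
        const double ang = first ? rvm1(mu1, kappa1) : rvm1(mu2, kappa2);
        out[i + I * (j + J * n)] = fold ? std::fabs(ang) : ang;
      }
  return out;
}
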