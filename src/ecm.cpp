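// Core numerical routines for constrained parsimonious Gaussian mixtures:
// the weighted optimal-truncation operator, the nested shape/volume/rotation
// covariance update, and the full ECM iteration for one random start.
// Rotation regimes are encoded as integers: 0 = I, 1 = E, 2 = V.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::uvec;
using arma::uword;
using arma::vec;

static const double FLOOR_REL = 1e-12; // relative floor for degenerate eigen/volume values

// ---------------------------------------------------------------------------
// optimal truncation
// ---------------------------------------------------------------------------

// f(t) = sum_i w_i [ log m_t(v_i) + v_i / m_t(v_i) ],  m_t(v) = clamp(v; t, c t)
static double trunc_obj_core(const vec& v, const vec& w, double t, double c) {
  double ct = std::isfinite(c) ? c * t : arma::datum::inf;
  double s = 0.0;
  for (uword i = 0; i < v.n_elem; ++i) {
    if (w[i] <= 0.0) continue;
    double m = std::min(std::max(v[i], t), ct);
    s += w[i] * (std::log(m) + v[i] / m);
  }
  return s;
}

// Exact minimiser: t* lies either at a point where the clamping pattern
// changes (v_i or v_i / c) or at the stationary value of f inside an
// interval with a fixed pattern.
static vec opt_trunc_core(const vec& v, const vec& w, double c) {
  uvec pos = arma::find(w > 0.0);
  if (pos.n_elem == 0) Rcpp::stop("opt_trunc: all weights are zero");
  vec vp = v(pos), wp = w(pos);
  if (vp.min() < 0.0) Rcpp::stop("opt_trunc: negative values are not allowed");
  if (vp.max() <= 0.0) Rcpp::stop("degenerate-scatter: all positive-weight values are zero");
  if (!std::isfinite(c)) return v;
  if (c < 1.0) Rcpp::stop("opt_trunc: c must be >= 1");

  double vmin = vp.min(), vmax = vp.max();
  if (vmin > 0.0 && vmax / vmin <= c) return v; // already feasible

  // candidate pattern-change points
  std::vector<double> cand;
  for (uword i = 0; i < vp.n_elem; ++i) {
    if (vp[i] > 0.0) {
      cand.push_back(vp[i]);
      cand.push_back(vp[i] / c);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  double best_t = cand.front(), best_f = trunc_obj_core(vp, wp, best_t, c);
  for (size_t i = 1; i < cand.size(); ++i) {
    double f = trunc_obj_core(vp, wp, cand[i], c);
    if (f < best_f) { best_f = f; best_t = cand[i]; }
  }
  // stationary points inside each inter-candidate interval (including the
  // intervals below the smallest and above the largest candidate); the
  // clamping pattern is constant on each, so the stationary t has closed form
  for (size_t i = 0; i <= cand.size(); ++i) {
    double lo = (i == 0) ? 0.0 : cand[i - 1];
    double hi = (i == cand.size()) ? cand.back() * 2.0 : cand[i];
    double tm = (i == 0) ? hi / 2.0 : 0.5 * (lo + hi);
    if (tm <= 0.0) continue;
    double swv_L = 0.0, swv_U = 0.0, sw = 0.0;
    for (uword j = 0; j < vp.n_elem; ++j) {
      if (vp[j] < tm) { swv_L += wp[j] * vp[j]; sw += wp[j]; }
      else if (vp[j] > c * tm) { swv_U += wp[j] * vp[j]; sw += wp[j]; }
    }
    if (sw <= 0.0) continue;
    double t_st = (swv_L + swv_U / c) / sw;
    bool inside = (i == cand.size()) ? (t_st > lo) : (t_st > lo && t_st < hi);
    if (inside) {
      double f = trunc_obj_core(vp, wp, t_st, c);
      if (f < best_f) { best_f = f; best_t = t_st; }
    }
  }

  vec out(v.n_elem);
  double ct = c * best_t;
  for (uword i = 0; i < v.n_elem; ++i)
    out[i] = std::min(std::max(v[i], best_t), ct);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_opt_trunc(const arma::vec& values, const arma::vec& weights, double c) {
  return opt_trunc_core(values, weights, c);
}

// [[Rcpp::export]]
double cpp_trunc_objective(const arma::vec& values, const arma::vec& weights,
                           double t, double c) {
  if (t <= 0.0) Rcpp::stop("trunc_objective: t must be > 0");
  return trunc_obj_core(values, weights, t, c);
}

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------

static double rel_change_vec(const vec& prev, const vec& curr) {
  double np = arma::norm(prev);
  if (np == 0.0) return arma::norm(curr) == 0.0 ? 0.0 : arma::datum::inf;
  return arma::norm(curr - prev) / np;
}

// max_j ||vec(b_j) - vec(b_j_prev)|| / ||vec(b_j_prev)|| for matrix columns
static double rel_change_cols(const mat& prev, const mat& curr) {
  double d = 0.0;
  for (uword j = 0; j < prev.n_cols; ++j)
    d = std::max(d, rel_change_vec(prev.col(j), curr.col(j)));
  return d;
}

static double rel_change_scalars(const vec& prev, const vec& curr) {
  double d = 0.0;
  for (uword j = 0; j < prev.n_elem; ++j) {
    if (prev[j] == 0.0) { if (curr[j] != 0.0) return arma::datum::inf; }
    else d = std::max(d, std::fabs(curr[j] - prev[j]) / std::fabs(prev[j]));
  }
  return d;
}

// |p - trace[ ((R'R0)' (R R0') ]| / p  -- the rotation monitor
static double rot_change_core(const mat& R_prev, const mat& R_curr) {
  double p = (double)R_curr.n_rows;
  mat A = R_curr.t() * R_prev;
  mat B = R_curr * R_prev.t();
  return std::fabs(p - arma::trace(A.t() * B)) / p;
}

// [[Rcpp::export]]
double cpp_rotation_change(const arma::mat& R_prev, const arma::mat& R_curr) {
  return rot_change_core(R_prev, R_curr);
}

// eigenvectors with eigenvalues in decreasing order, sign-canonicalised
// (first entry of largest magnitude made positive) for determinism
static void eigen_desc(const mat& S, vec& eval, mat& evec) {
  vec ev; mat V;
  if (!arma::eig_sym(ev, V, arma::symmatu(S)))
    Rcpp::stop("eigendecomposition failed");
  eval = arma::reverse(ev);
  evec = arma::fliplr(V);
  for (uword j = 0; j < evec.n_cols; ++j) {
    uword imax = arma::index_max(arma::abs(evec.col(j)));
    if (evec(imax, j) < 0.0) evec.col(j) *= -1.0;
  }
}

// ---------------------------------------------------------------------------
// M-step covariance updates
// ---------------------------------------------------------------------------

// one inner shape iteration: within-truncation, (rot=V) decreasing sort,
// between-truncation, unsort, and per-component unit-determinant
// normalisation. `normalize_first` reproduces the alternative ordering in
// which shapes are normalised before the between-truncation; it is used as
// a feasibility-restoring pass (it is the identity at the limit cases) --
// the default order applies both truncations to the raw scaled diagonals,
// which is the exact coordinate-wise conditional optimum.
static void shapes_pass(mat& E, const vec& nj, double c_shw, double c_shb,
                        int rot, bool normalize_first, int* floors) {
  uword p = E.n_rows, k = E.n_cols;
  vec ones_p(p, arma::fill::ones);
  arma::umat perm(p, k);
  for (uword j = 0; j < k; ++j) {
    vec e = opt_trunc_core(E.col(j), ones_p, c_shw);
    double emax = e.max();
    for (uword l = 0; l < p; ++l)
      if (e[l] < FLOOR_REL * emax) { e[l] = FLOOR_REL * emax; ++(*floors); }
    if (normalize_first) e /= std::exp(arma::mean(arma::log(e)));
    E.col(j) = e;
  }
  if (rot == 2) { // sort each component's shape decreasing, remember order
    for (uword j = 0; j < k; ++j) {
      uvec o = arma::sort_index(E.col(j), "descend");
      perm.col(j) = o;
      E.col(j) = vec(E.col(j)).elem(o);
    }
  }
  for (uword l = 0; l < p; ++l) { // between constraint, coordinate-wise
    vec row = E.row(l).t();
    E.row(l) = opt_trunc_core(row, nj, c_shb).t();
  }
  if (rot == 2) { // undo the sort
    for (uword j = 0; j < k; ++j) {
      vec e = E.col(j);
      for (uword l = 0; l < p; ++l) E(perm(l, j), j) = e[l];
    }
  }
  for (uword j = 0; j < k; ++j)
    E.col(j) /= std::exp(arma::mean(arma::log(E.col(j))));
}

// largest between-component ratio, coordinate-wise on the (rot=V: sorted)
// shape elements
static double max_between_ratio(const mat& E, int rot) {
  mat Es = E;
  if (rot == 2)
    for (uword j = 0; j < Es.n_cols; ++j)
      Es.col(j) = arma::sort(Es.col(j), "descend");
  double r = 1.0;
  for (uword l = 0; l < Es.n_rows; ++l)
    r = std::max(r, Es.row(l).max() / Es.row(l).min());
  return r;
}

static mat shapes_core(const cube& S, const vec& nj, const vec& d, const cube& R,
                       double c_shw, double c_shb, int rot,
                       int iter_max, double tol, int* floors) {
  uword p = S.n_rows, k = S.n_slices;
  mat E(p, k);
  for (uword j = 0; j < k; ++j) {
    double dj = d[j] > 0.0 ? d[j] : 1.0;
    vec e = arma::diagvec(R.slice(j).t() * S.slice(j) * R.slice(j)) / dj;
    E.col(j) = arma::clamp(e, 0.0, arma::datum::inf); // shed rounding noise
  }
  mat Eprev;
  for (int s = 1; s <= iter_max; ++s) {
    Eprev = E;
    shapes_pass(E, nj, c_shw, c_shb, rot, false, floors);
    if (rel_change_cols(Eprev, E) <= tol) break;
  }
  // the final renormalisation can leave a between-ratio slightly above
  // c_shb for intermediate constants; restore exact feasibility with
  // normalise-first passes (a no-op whenever already feasible)
  if (std::isfinite(c_shb) && max_between_ratio(E, rot) > c_shb * (1.0 + 1e-10)) {
    for (int s = 1; s <= iter_max; ++s) {
      Eprev = E;
      shapes_pass(E, nj, c_shw, c_shb, rot, true, floors);
      if (rel_change_cols(Eprev, E) <= tol &&
          max_between_ratio(E, rot) <= c_shb * (1.0 + 1e-10)) break;
    }
  }
  return E;
}

// [[Rcpp::export]]
arma::mat cpp_update_shapes(const arma::cube& S, const arma::vec& nj,
                            const arma::vec& d, const arma::cube& R,
                            double c_shw, double c_shb, int rot,
                            int iter_max, double tol) {
  int floors = 0;
  return shapes_core(S, nj, d, R, c_shw, c_shb, rot, iter_max, tol, &floors);
}

// volume update: nu_j = trace(D_j^{-1} R_j' S_j R_j)/p, then truncation at
// c_det^{1/p}; zero volumes floored only when the constraint cannot fix them
static vec volumes_core(const cube& S, const vec& nj, const mat& D, const cube& R,
                        double c_det, int* floors) {
  uword p = S.n_rows, k = S.n_slices;
  vec nu(k);
  for (uword j = 0; j < k; ++j) {
    vec diagv = arma::diagvec(R.slice(j).t() * S.slice(j) * R.slice(j));
    nu[j] = std::max(arma::sum(diagv / D.col(j)) / (double)p, 0.0);
  }
  double c_root = std::isfinite(c_det) ? std::pow(c_det, 1.0 / (double)p)
                                       : arma::datum::inf;
  vec d = opt_trunc_core(nu, nj, c_root);
  double dmax = d.max();
  for (uword j = 0; j < k; ++j)
    if (d[j] < FLOOR_REL * dmax) { d[j] = FLOOR_REL * dmax; ++(*floors); }
  return d;
}

// [[Rcpp::export]]
arma::vec cpp_update_volumes(const arma::cube& S, const arma::vec& nj,
                             const arma::mat& D, const arma::cube& R,
                             double c_det) {
  int floors = 0;
  return volumes_core(S, nj, D, R, c_det, &floors);
}

// complete-data objective term that depends on the common rotation
// (to be minimised): sum_j n_j/(n d_j) trace(D_j^{-1} R' S_j R)
static double rot_objective(const cube& S, const vec& nj, const vec& d,
                            const mat& D, const mat& R, double n) {
  double g = 0.0;
  for (uword j = 0; j < S.n_slices; ++j) {
    vec diagv = arma::diagvec(R.t() * S.slice(j) * R);
    g += nj[j] / (n * d[j]) * arma::sum(diagv / D.col(j));
  }
  return g;
}

// common-rotation (rot=E) update by majorisation-minimisation; each accepted
// iterate does not increase the complete-data objective
static mat rotation_core(const cube& S, const vec& nj, const vec& d,
                         const mat& D, const mat& R0, int iter_max, double tol,
                         int* iters, bool* conv) {
  uword p = S.n_rows, k = S.n_slices;
  double n = arma::sum(nj);
  cube W(p, p, k);
  vec omega(k);
  for (uword j = 0; j < k; ++j) {
    W.slice(j) = (nj[j] / n) * S.slice(j);
    vec ev = arma::eig_sym(arma::symmatu(W.slice(j)));
    // strictly above the largest eigenvalue: keeps the majorisation valid
    // while making (omega I - W_j) positive definite, so the Procrustes
    // solution is unique and the optimum is an exact fixed point
    omega[j] = ev.max() + 0.01 * (ev.max() - ev.min()) + 1e-12;
  }
  mat R = R0;
  double g = rot_objective(S, nj, d, D, R, n);
  *conv = false;
  int r = 0;
  for (r = 1; r <= iter_max; ++r) {
    mat G(p, p, arma::fill::zeros);
    for (uword j = 0; j < k; ++j) {
      mat M = omega[j] * arma::eye(p, p) - W.slice(j);
      G += (1.0 / d[j]) * M * R * arma::diagmat(1.0 / D.col(j));
    }
    mat U, V; vec sv;
    if (!arma::svd(U, sv, V, G)) break;
    mat R_new = U * V.t();
    double g_new = rot_objective(S, nj, d, D, R_new, n);
    if (g_new > g + 1e-10 * (1.0 + std::fabs(g))) break; // guard: never worsen
    double dR = rot_change_core(R, R_new);
    R = R_new;
    g = g_new;
    if (dR <= tol) { *conv = true; break; }
  }
  *iters = r;
  return R;
}

// [[Rcpp::export]]
Rcpp::List cpp_update_rotation(const arma::cube& S, const arma::vec& nj,
                               const arma::vec& d, const arma::mat& D,
                               const arma::mat& R0, int iter_max, double tol) {
  int iters = 0; bool conv = false;
  mat R = rotation_core(S, nj, d, D, R0, iter_max, tol, &iters, &conv);
  return List::create(_["R"] = R, _["iterations"] = iters, _["converged"] = conv);
}

// full constrained covariance update: initialise d_j and R_j from the
// weighted covariances, then cycle shape -> volume -> rotation
static void scatters_core(const cube& S, const vec& nj,
                          double c_det, double c_shw, double c_shb, int rot,
                          int im_ddr, double tol_ddr, int im_D, double tol_D,
                          int im_R, double tol_R,
                          vec& d, mat& D, cube& R, cube& Sigma,
                          int* iters, bool* conv, int* floors) {
  uword p = S.n_rows, k = S.n_slices;
  double n = arma::sum(nj);
  d.set_size(k); D.set_size(p, k); R.set_size(p, p, k); Sigma.set_size(p, p, k);

  for (uword j = 0; j < k; ++j) {
    double det_j = arma::det(arma::symmatu(S.slice(j)));
    d[j] = det_j > 0.0 ? std::pow(det_j, 1.0 / (double)p) : 0.0;
  }
  double dtr = 0.0;
  for (uword j = 0; j < k; ++j) dtr = std::max(dtr, arma::trace(S.slice(j)) / p);
  if (dtr <= 0.0) Rcpp::stop("degenerate-scatter: all weighted covariances are zero");
  for (uword j = 0; j < k; ++j)
    if (d[j] < FLOOR_REL * dtr) { d[j] = FLOOR_REL * dtr; ++(*floors); }

  if (rot == 2) {
    for (uword j = 0; j < k; ++j) {
      vec ev; mat V;
      eigen_desc(S.slice(j), ev, V);
      R.slice(j) = V;
    }
  } else if (rot == 0) {
    for (uword j = 0; j < k; ++j) R.slice(j) = arma::eye(p, p);
  } else {
    mat pooled(p, p, arma::fill::zeros);
    for (uword j = 0; j < k; ++j)
      pooled += (nj[j] / n) * (1.0 / d[j]) * S.slice(j);
    vec ev; mat V;
    eigen_desc(pooled, ev, V);
    for (uword j = 0; j < k; ++j) R.slice(j) = V;
  }

  vec d_prev; mat D_prev; mat Rcommon_prev;
  *conv = false;
  int u = 0;
  for (u = 1; u <= im_ddr; ++u) {
    d_prev = d; D_prev = D;
    if (rot == 1) Rcommon_prev = R.slice(0);
    D = shapes_core(S, nj, d, R, c_shw, c_shb, rot, im_D, tol_D, floors);
    d = volumes_core(S, nj, D, R, c_det, floors);
    double dR = 0.0;
    if (rot == 1) {
      int rit = 0; bool rconv = false;
      mat Rnew = rotation_core(S, nj, d, D, R.slice(0), im_R, tol_R, &rit, &rconv);
      dR = rot_change_core(Rcommon_prev, Rnew);
      for (uword j = 0; j < k; ++j) R.slice(j) = Rnew;
    }
    double dd = rel_change_scalars(d_prev, d);
    double dD = (u == 1) ? arma::datum::inf : rel_change_cols(D_prev, D);
    if (u > 1 && std::max(std::max(dd, dD), dR) <= tol_ddr) { *conv = true; break; }
  }
  *iters = std::min(u, im_ddr);
  for (uword j = 0; j < k; ++j)
    Sigma.slice(j) = arma::symmatu(d[j] * R.slice(j) * arma::diagmat(D.col(j)) * R.slice(j).t());
}

// [[Rcpp::export]]
Rcpp::List cpp_update_scatters(const arma::cube& S, const arma::vec& nj,
                               double c_det, double c_shw, double c_shb, int rot,
                               int iter_max_ddr, double tol_ddr,
                               int iter_max_D, double tol_D,
                               int iter_max_R, double tol_R) {
  vec d; mat D; cube R, Sigma;
  int iters = 0, floors = 0; bool conv = false;
  scatters_core(S, nj, c_det, c_shw, c_shb, rot, iter_max_ddr, tol_ddr,
                iter_max_D, tol_D, iter_max_R, tol_R,
                d, D, R, Sigma, &iters, &conv, &floors);
  return List::create(_["d"] = d, _["D"] = D, _["R"] = R, _["Sigma"] = Sigma,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["floors"] = floors);
}

// ---------------------------------------------------------------------------
// densities and the E-step
// ---------------------------------------------------------------------------

// log(pi_j phi(x_i; mu_j, Sigma_j)) via the Cholesky factor of Sigma_j;
// returns an n x k matrix, or throws if some Sigma_j is not SPD
static mat log_weights_core(const mat& X, const vec& pi, const mat& mu,
                            const cube& Sigma) {
  uword n = X.n_rows, p = X.n_cols, k = pi.n_elem;
  mat logW(n, k);
  const double cst = -0.5 * (double)p * std::log(2.0 * arma::datum::pi);
  for (uword j = 0; j < k; ++j) {
    mat L;
    if (!arma::chol(L, arma::symmatu(Sigma.slice(j)), "lower"))
      Rcpp::stop("singular or non-positive-definite component covariance");
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    mat Xc = X.each_row() - mu.row(j);
    mat Z = arma::solve(arma::trimatl(L), Xc.t());
    vec q = arma::sum(arma::square(Z), 0).t();
    logW.col(j) = cst - 0.5 * logdet - 0.5 * q + std::log(pi[j]);
  }
  return logW;
}

// [[Rcpp::export]]
arma::mat cpp_log_weights(const arma::mat& X, const arma::vec& pi,
                          const arma::mat& mu, const arma::cube& Sigma) {
  return log_weights_core(X, pi, mu, Sigma);
}

// complete-data covariance objective sum_j n_j [log|Sigma_j| + tr(Sigma_j^{-1} S_j)]
// (the part of the Q-function the scatter update must not worsen)
static double cov_obj_core(const cube& Sigma, const cube& S, const vec& nj) {
  double f = 0.0;
  for (uword j = 0; j < Sigma.n_slices; ++j) {
    mat L;
    if (!arma::chol(L, arma::symmatu(Sigma.slice(j)), "lower"))
      return arma::datum::inf;
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    mat Z = arma::solve(arma::trimatl(L), S.slice(j));
    mat T = arma::solve(arma::trimatl(L), Z.t());
    f += nj[j] * (logdet + arma::trace(T));
  }
  return f;
}

// ---------------------------------------------------------------------------
// one full ECM run from a given initial parameter set
// ---------------------------------------------------------------------------

// status codes: 0 = ok, 1 = empty component (hard assignment), 2 = singular
// covariance encountered when evaluating densities
// [[Rcpp::export]]
Rcpp::List cpp_ecm_run(const arma::mat& X, const arma::vec& pi0,
                       const arma::mat& mu0, const arma::cube& Sigma0,
                       double c_det, double c_shw, double c_shb, int rot,
                       bool cem,
                       int iter_max_theta, double tol_theta,
                       int iter_max_ddr, double tol_ddr,
                       int iter_max_D, double tol_D,
                       int iter_max_R, double tol_R) {
  uword n = X.n_rows, p = X.n_cols, k = pi0.n_elem;
  vec pi = pi0;
  mat mu = mu0;
  cube Sigma = Sigma0;
  vec d(k); mat D(p, k); cube R(p, p, k);
  vec d_prev_acc; mat D_prev_acc; cube R_prev_acc;
  mat tau(n, k);
  arma::uvec labels(n);
  std::vector<double> trace;
  bool conv = false;
  int t = 0, floors = 0, status = 0;
  double target = -arma::datum::inf;

  for (t = 1; t <= iter_max_theta; ++t) {
    mat logW;
    try {
      logW = log_weights_core(X, pi, mu, Sigma);
    } catch (...) {
      status = 2;
      break;
    }
    // E-step (and the target value at the current parameters)
    vec rowmax = arma::max(logW, 1);
    if (cem) {
      double tgt = 0.0;
      for (uword i = 0; i < n; ++i) {
        labels[i] = arma::index_max(logW.row(i)); // first max wins ties
        tgt += logW(i, labels[i]);
      }
      tau.zeros();
      for (uword i = 0; i < n; ++i) tau(i, labels[i]) = 1.0;
      target = tgt;
    } else {
      vec lse = rowmax + arma::log(arma::sum(arma::exp(logW.each_col() - rowmax), 1));
      tau = arma::exp(logW.each_col() - lse);
      target = arma::sum(lse);
    }
    trace.push_back(target);

    vec nj = arma::sum(tau, 0).t();
    if (cem && nj.min() <= 0.0) { status = 1; break; }

    vec pi_prev = pi; mat mu_prev = mu; cube Sigma_prev = Sigma;

    // M-step: weights, means, weighted covariances
    pi = nj / (double)n;
    mu = (tau.t() * X);
    mu.each_col() /= nj;
    cube S(p, p, k);
    for (uword j = 0; j < k; ++j) {
      mat Xc = X.each_row() - mu.row(j);
      S.slice(j) = arma::symmatu((Xc.each_col() % tau.col(j)).t() * Xc / nj[j]);
    }
    int sc_it = 0; bool sc_conv = false;
    try {
      scatters_core(S, nj, c_det, c_shw, c_shb, rot, iter_max_ddr, tol_ddr,
                    iter_max_D, tol_D, iter_max_R, tol_R,
                    d, D, R, Sigma, &sc_it, &sc_conv, &floors);
    } catch (...) {
      status = 2;
      break;
    }
    // ECM safeguard: the nested truncation update is not guaranteed to beat
    // the previous (still feasible) scatter set under the new weights; keep
    // whichever achieves the better complete-data objective, so the target
    // likelihood never decreases
    if (t > 1) {
      double f_new = cov_obj_core(Sigma, S, nj);
      double f_old = cov_obj_core(Sigma_prev, S, nj);
      if (f_old < f_new) {
        Sigma = Sigma_prev;
        d = d_prev_acc; D = D_prev_acc; R = R_prev_acc;
      }
    }
    d_prev_acc = d; D_prev_acc = D; R_prev_acc = R;

    // relative parameter change (max over weights, means, scatters)
    double dpi = rel_change_vec(pi_prev, pi);
    double dmu = rel_change_cols(mu_prev.t(), mu.t());
    double dSig = 0.0;
    for (uword j = 0; j < k; ++j)
      dSig = std::max(dSig, rel_change_vec(arma::vectorise(Sigma_prev.slice(j)),
                                           arma::vectorise(Sigma.slice(j))));
    if (std::max(std::max(dpi, dmu), dSig) <= tol_theta) { conv = true; break; }
  }

  if (status == 0) {
    // evaluate the target at the final parameters
    mat logW = log_weights_core(X, pi, mu, Sigma);
    vec rowmax = arma::max(logW, 1);
    if (cem) {
      double tgt = 0.0;
      for (uword i = 0; i < n; ++i) {
        labels[i] = arma::index_max(logW.row(i));
        tgt += logW(i, labels[i]);
      }
      tau.zeros();
      for (uword i = 0; i < n; ++i) tau(i, labels[i]) = 1.0;
      target = tgt;
    } else {
      vec lse = rowmax + arma::log(arma::sum(arma::exp(logW.each_col() - rowmax), 1));
      tau = arma::exp(logW.each_col() - lse);
      target = arma::sum(lse);
      for (uword i = 0; i < n; ++i) labels[i] = arma::index_max(logW.row(i));
    }
    trace.push_back(target);
  }

  return List::create(
      _["pi"] = pi, _["mu"] = mu, _["Sigma"] = Sigma,
      _["d"] = d, _["D"] = D, _["R"] = R,
      _["tau"] = tau, _["labels"] = arma::conv_to<arma::ivec>::from(labels) + 1,
      _["target"] = target, _["trace"] = trace,
      _["iterations"] = std::min(t, iter_max_theta),
      _["converged"] = conv, _["status"] = status, _["floors"] = floors);
}
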