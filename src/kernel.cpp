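#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Term encoding shared with R/terms.R:
//   0 = edges, 1 = gwidegree(decay), 2 = gwesp(decay, OTP shared partners),
//   3 = absdiff(attr), 4 = nodematch(attr)
// attr: n x nterms matrix; only the column of an absdiff/nodematch term is read.

static inline double gw_weight(double tau, int s) {
  // geometric weighting e^tau * (1 - (1 - e^-tau)^s); 0 for s <= 0
  if (s <= 0) return 0.0;
  return std::exp(tau) * (1.0 - std::pow(1.0 - std::exp(-tau), (double)s));
}

// full statistic vector g(A)
static void stats_full(const IntegerMatrix &A, const IntegerVector &type,
                       const NumericVector &decay, const NumericMatrix &attr,
                       std::vector<double> &g) {
  int n = A.nrow(), p = type.size();
  std::vector<int> indeg(n, 0);
  int nedges = 0;
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++)
      if (A(i, j)) { indeg[j]++; nedges++; }
  for (int t = 0; t < p; t++) {
    double s = 0.0;
    switch (type[t]) {
    case 0:
      s = nedges; break;
    case 1:
      for (int j = 0; j < n; j++) s += gw_weight(decay[t], indeg[j]);
      break;
    case 2:
      for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
          if (A(i, j)) {
            int sp = 0;
            for (int k = 0; k < n; k++)
              if (A(i, k) && A(k, j)) sp++;   // transitive (OTP) shared partner
            s += gw_weight(decay[t], sp);
          }
      break;
    case 3:
      for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
          if (A(i, j)) s += std::fabs(attr(i, t) - attr(j, t));
      break;
    case 4:
      for (int i = 0; i < n; i++)
        for (int j = 0; j < n; j++)
          if (A(i, j) && attr(i, t) == attr(j, t)) s += 1.0;
      break;
    }
    g[t] = s;
  }
}

// change in g from toggling dyad (i, j), evaluated at the current A (before toggle)
static void delta_stats(const IntegerMatrix &A, const std::vector<int> &indeg,
                        int i, int j, const IntegerVector &type,
                        const NumericVector &decay, const NumericMatrix &attr,
                        double *d) {
  int n = A.nrow(), p = type.size();
  bool present = A(i, j) != 0;
  double sgn = present ? -1.0 : 1.0;
  for (int t = 0; t < p; t++) {
    double tau = decay[t];
    switch (type[t]) {
    case 0:
      d[t] = sgn; break;
    case 1: {
      int k = indeg[j];
      int k2 = present ? k - 1 : k + 1;
      d[t] = gw_weight(tau, k2) - gw_weight(tau, k);
      break;
    }
    case 2: {
      double dd = 0.0;
      // weight of the toggled edge itself (its own shared partners are unaffected)
      int sp = 0;
      for (int k = 0; k < n; k++)
        if (A(i, k) && A(k, j)) sp++;
      dd += sgn * gw_weight(tau, sp);
      // existing edges whose shared-partner count changes:
      //  (i, v): path i -> j -> v appears/disappears when A(j, v)
      //  (u, j): path u -> i -> j appears/disappears when A(u, i)
      for (int v = 0; v < n; v++) {
        if (v == i || v == j) continue;
        if (A(i, v) && A(j, v)) {
          int spv = 0;
          for (int k = 0; k < n; k++)
            if (A(i, k) && A(k, v)) spv++;
          int after = present ? spv - 1 : spv + 1;
          dd += gw_weight(tau, after) - gw_weight(tau, spv);
        }
        if (A(v, j) && A(v, i)) {
          int spu = 0;
          for (int k = 0; k < n; k++)
            if (A(v, k) && A(k, j)) spu++;
          int after = present ? spu - 1 : spu + 1;
          dd += gw_weight(tau, after) - gw_weight(tau, spu);
        }
      }
      d[t] = dd;
      break;
    }
    case 3:
      d[t] = sgn * std::fabs(attr(i, t) - attr(j, t)); break;
    case 4:
      d[t] = sgn * (attr(i, t) == attr(j, t) ? 1.0 : 0.0); break;
    }
  }
}

// [[Rcpp::export(name = ".cpp_stats")]]
NumericVector cpp_stats(IntegerMatrix A, IntegerVector type, NumericVector decay,
                        NumericMatrix attr) {
  std::vector<double> g(type.size());
  stats_full(A, type, decay, attr, g);
  return NumericVector(g.begin(), g.end());
}

// change statistics for setting each free dyad ON, evaluated with that dyad OFF
// (the conditional-logit / MPLE design matrix)
// [[Rcpp::export(name = ".cpp_mple_design")]]
NumericMatrix cpp_mple_design(IntegerMatrix A0, IntegerVector free_i, IntegerVector free_j,
                              IntegerVector type, NumericVector decay, NumericMatrix attr) {
  IntegerMatrix A = clone(A0);
  int n = A.nrow(), p = type.size(), f = free_i.size();
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++)
      if (A(i, j)) indeg[j]++;
  NumericMatrix D(f, p);
  std::vector<double> d(p);
  for (int r = 0; r < f; r++) {
    int i = free_i[r], j = free_j[r];
    bool present = A(i, j) != 0;
    if (present) { A(i, j) = 0; indeg[j]--; }
    delta_stats(A, indeg, i, j, type, decay, attr, d.data());
    if (present) { A(i, j) = 1; indeg[j]++; }
    for (int t = 0; t < p; t++) D(r, t) = d[t];
  }
  return D;
}

// Metropolis sampler over single-dyad toggles restricted to the free dyads.
// Uses R's RNG (seed governed by set.seed in R).
// [[Rcpp::export(name = ".cpp_sample")]]
List cpp_sample(IntegerMatrix A_init, IntegerVector free_i, IntegerVector free_j,
                NumericVector theta, IntegerVector type, NumericVector decay,
                NumericMatrix attr, int burnin, int interval, int nsamp,
                bool keep_networks) {
  IntegerMatrix A = clone(A_init);
  int n = A.nrow(), p = type.size(), f = free_i.size();
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++)
      if (A(i, j)) indeg[j]++;
  std::vector<double> g(p), d(p);
  stats_full(A, type, decay, attr, g);
  NumericMatrix G(nsamp, p);
  List nets(keep_networks ? nsamp : 0);
  long accepted = 0, total = 0;

  auto toggles = [&](int nt) {
    for (int s = 0; s < nt; s++) {
      int r = (int)(unif_rand() * f);
      if (r >= f) r = f - 1;
      int i = free_i[r], j = free_j[r];
      delta_stats(A, indeg, i, j, type, decay, attr, d.data());
      double lr = 0.0;
      for (int t = 0; t < p; t++) lr += theta[t] * d[t];
      total++;
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
        if (A(i, j)) { A(i, j) = 0; indeg[j]--; }
        else         { A(i, j) = 1; indeg[j]++; }
        for (int t = 0; t < p; t++) g[t] += d[t];
        accepted++;
      }
    }
  };

  if (f > 0) toggles(burnin);
  for (int s = 0; s < nsamp; s++) {
    if (f > 0) toggles(interval);
    for (int t = 0; t < p; t++) G(s, t) = g[t];
    if (keep_networks) nets[s] = clone(A);
  }
  return List::create(_["stats"] = G,
                      _["accept_rate"] = total > 0 ? (double)accepted / (double)total : NA_REAL,
                      _["final"] = A,
                      _["networks"] = nets);
}

// Gray-code enumeration of all 2^f configurations of the free dyads;
// returns the 2^f x p matrix of statistic vectors (row 0 = A_init).
// [[Rcpp::export(name = ".cpp_enumerate")]]
NumericMatrix cpp_enumerate(IntegerMatrix A_init, IntegerVector free_i, IntegerVector free_j,
                            IntegerVector type, NumericVector decay, NumericMatrix attr) {
  int f = free_i.size(), p = type.size();
  if (f > 20) stop("free-dyad count exceeds enumeration limit (20)");
  IntegerMatrix A = clone(A_init);
  int n = A.nrow();
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++)
      if (A(i, j)) indeg[j]++;
  std::vector<double> g(p), d(p);
  stats_full(A, type, decay, attr, g);
  unsigned long total = 1UL << f;
  NumericMatrix G(total, p);
  for (int t = 0; t < p; t++) G(0, t) = g[t];
  for (unsigned long s = 1; s < total; s++) {
    // bit toggled between gray(s-1) and gray(s) is the lowest set bit of s
    int b = 0;
    while (!((s >> b) & 1UL)) b++;
    int i = free_i[b], j = free_j[b];
    delta_stats(A, indeg, i, j, type, decay, attr, d.data());
    if (A(i, j)) { A(i, j) = 0; indeg[j]--; }
    else         { A(i, j) = 1; indeg[j]++; }
    for (int t = 0; t < p; t++) g[t] += d[t];
    for (int t = 0; t < p; t++) G(s, t) = g[t];
  }
  return G;
}

// ---------- logistic regression (Newton-Raphson) ----------

// solve symmetric positive-definite system in place (Gaussian elimination with
// partial pivoting; p is small). Returns false if singular.
static bool solve_sys(std::vector<double> &H, std::vector<double> &b, int p) {
  for (int c = 0; c < p; c++) {
    int piv = c;
    for (int r = c + 1; r < p; r++)
      if (std::fabs(H[r * p + c]) > std::fabs(H[piv * p + c])) piv = r;
    if (std::fabs(H[piv * p + c]) < 1e-12) return false;
    if (piv != c) {
      for (int k = 0; k < p; k++) std::swap(H[c * p + k], H[piv * p + k]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < p; r++) {
      double m = H[r * p + c] / H[c * p + c];
      for (int k = c; k < p; k++) H[r * p + k] -= m * H[c * p + k];
      b[r] -= m * b[c];
    }
  }
  for (int c = p - 1; c >= 0; c--) {
    double s = b[c];
    for (int k = c + 1; k < p; k++) s -= H[c * p + k] * b[k];
    b[c] = s / H[c * p + c];
  }
  return true;
}

static bool logit_nr(const double *X, const int *y, int m, int p,
                     double tol, int maxit, double sep_bound,
                     std::vector<double> &beta, bool &separated, double &loglik) {
  std::fill(beta.begin(), beta.end(), 0.0);
  separated = false;
  std::vector<double> mu(m), grad(p), H(p * p);
  for (int it = 0; it < maxit; it++) {
    for (int r = 0; r < m; r++) {
      double eta = 0.0;
      for (int c = 0; c < p; c++) eta += X[r + (size_t)m * c] * beta[c];
      mu[r] = 1.0 / (1.0 + std::exp(-eta));
    }
    std::fill(grad.begin(), grad.end(), 0.0);
    std::fill(H.begin(), H.end(), 0.0);
    for (int r = 0; r < m; r++) {
      double res = y[r] - mu[r];
      double w = mu[r] * (1.0 - mu[r]);
      for (int c = 0; c < p; c++) {
        double x = X[r + (size_t)m * c];
        grad[c] += x * res;
        for (int c2 = c; c2 < p; c2++)
          H[c * p + c2] += w * x * X[r + (size_t)m * c2];
      }
    }
    for (int c = 0; c < p; c++)
      for (int c2 = 0; c2 < c; c2++)
        H[c * p + c2] = H[c2 * p + c];
    double gmax = 0.0;
    for (int c = 0; c < p; c++) gmax = std::max(gmax, std::fabs(grad[c]));
    if (gmax < tol) {
      loglik = 0.0;
      for (int r = 0; r < m; r++) {
        double eta = 0.0;
        for (int c = 0; c < p; c++) eta += X[r + (size_t)m * c] * beta[c];
        loglik += y[r] * eta - std::log1p(std::exp(eta));
      }
      return true;
    }
    std::vector<double> step(grad);
    if (!solve_sys(H, step, p)) { separated = true; return false; }
    for (int c = 0; c < p; c++) beta[c] += step[c];
    for (int c = 0; c < p; c++)
      if (std::fabs(beta[c]) > sep_bound) { separated = true; return false; }
  }
  return false;
}

// [[Rcpp::export(name = ".cpp_logit")]]
List cpp_logit(NumericMatrix X, IntegerVector y, double tol = 1e-8,
               int maxit = 100, double sep_bound = 25.0) {
  int m = X.nrow(), p = X.ncol();
  std::vector<double> beta(p);
  bool separated = false;
  double ll = NA_REAL;
  bool conv = logit_nr(REAL(SEXP(X)), INTEGER(SEXP(y)), m, p, tol, maxit,
                       sep_bound, beta, separated, ll);
  return List::create(_["coef"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = conv,
                      _["separated"] = separated,
                      _["loglik"] = ll);
}

// QAP Y-permutation null: relabel nodes of A uniformly at random (rows and
// columns simultaneously), rebuild the dyadic response, refit the logistic
// model on the fixed design X. Failed fits are redrawn.
// [[Rcpp::export(name = ".cpp_qap_perm")]]
List cpp_qap_perm(IntegerMatrix A, NumericMatrix X, IntegerVector di, IntegerVector dj,
                  int n_perm, double tol = 1e-8, int maxit = 100,
                  double sep_bound = 25.0) {
  int n = A.nrow(), m = X.nrow(), p = X.ncol();
  NumericMatrix C(n_perm, p);
  std::vector<int> perm(n), yv(m);
  std::vector<double> beta(p);
  int redrawn = 0;
  long max_attempts = (long)n_perm * 100L;
  long attempts = 0;
  for (int s = 0; s < n_perm; s++) {
    bool ok = false;
    while (!ok) {
      if (++attempts > max_attempts)
        stop("QAP: too many failed permutation fits");
      for (int i = 0; i < n; i++) perm[i] = i;
      for (int i = n - 1; i > 0; i--) {
        int k = (int)(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(perm[i], perm[k]);
      }
      for (int r = 0; r < m; r++) yv[r] = A(perm[di[r]], perm[dj[r]]);
      bool separated = false;
      double ll;
      ok = logit_nr(REAL(SEXP(X)), yv.data(), m, p, tol, maxit, sep_bound,
                    beta, separated, ll);
      if (!ok) redrawn++;
    }
    for (int c = 0; c < p; c++) C(s, c) = beta[c];
  }
  return List::create(_["coef"] = C, _["n_redrawn"] = redrawn);
}
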