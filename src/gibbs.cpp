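// Gibbs sampler for the threshold (liability) animal model.
//
// Liability: l = X beta + Z a + e, e ~ N(0, I) (residual variance fixed at
// 1 for identifiability, threshold at 0). y_i = 1 iff l_i > 0. Breeding
// values a ~ N(0, sigma2_a * A). Updates per round:
//   (i)   l_i from its truncated-normal full conditional,
//   (ii)  beta jointly from N((X'X)^-1 X'(l - Za), (X'X)^-1),
//   (iii) a_j single-site in pedigree code order using the sparse A-inverse
//         neighbourhood,
//   (iv)  sigma2_a from a scaled inverse chi-square whose quadratic form
//         runs over the parental subset: (a_P' (A_PP)^-1 a_P + nu*S2) /
//         chisq(n_P + nu); with the all-animals option the form is
//         a' A^-1 a over all q animals.
// Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// One-sided truncated standard-normal-around-mu draw by inverse CDF.
// positive = true -> l > 0, else l <= 0. Plain probability space for
// moderate means; log-space complementary CDF when |mu| > 6 so that deep
// tails neither underflow nor return infinities.
static inline double rtrunc_norm(double mu, bool positive) {
  double u = unif_rand();
  if (u <= 0.0) u = DBL_MIN;
  if (mu > -6.0 && mu < 6.0) {
    if (positive) {
      // z = l - mu > -mu; upper-tail prob of z is u * Phi(mu)
      double q = u * R::pnorm(mu, 0.0, 1.0, 1, 0);
      return mu + R::qnorm(q, 0.0, 1.0, 0, 0);
    } else {
      double q = u * R::pnorm(-mu, 0.0, 1.0, 1, 0);
      return mu + R::qnorm(q, 0.0, 1.0, 1, 0);
    }
  }
  if (positive) {
    double logq = std::log(u) + R::pnorm(mu, 0.0, 1.0, 1, 1);
    return mu + R::qnorm(logq, 0.0, 1.0, 0, 1);
  }
  double logq = std::log(u) + R::pnorm(-mu, 0.0, 1.0, 1, 1);
  return mu + R::qnorm(logq, 0.0, 1.0, 1, 1);
}

// [[Rcpp::export(name = ".gibbs_threshold_cpp")]]
List gibbs_threshold_cpp(IntegerVector y,          // 0/1 per record
                         NumericMatrix X,          // n x p, full rank
                         IntegerVector rec_animal, // 0-based animal index
                         IntegerVector Ai_p,       // A^-1 CSR row pointers
                         IntegerVector Ai_j,       // column indices (0-based)
                         NumericVector Ai_x,       // values (full symmetric)
                         NumericMatrix XtX_inv_chol, // upper chol of (X'X)^-1
                         NumericMatrix U_pp,       // upper chol of (A_PP)^-1
                         IntegerVector parent_idx, // 0-based animal indices
                         bool parents_only,
                         int n_rounds, int burn_in, int thin,
                         double nu, double S2,
                         double start_sigma2a) {
  const int n = y.size();
  const int p = X.ncol();
  const int q = Ai_p.size() - 1;
  const int nP = parent_idx.size();

  std::vector<double> l(n), a(q, 0.0), beta(p, 0.0), xb(n, 0.0);
  // per-animal record lists (post-cleaning there is one record per animal,
  // but multiple records stay correct)
  std::vector<int> rec_ptr(q + 1, 0), rec_idx(n);
  for (int i = 0; i < n; ++i) rec_ptr[rec_animal[i] + 1]++;
  for (int j = 0; j < q; ++j) rec_ptr[j + 1] += rec_ptr[j];
  {
    std::vector<int> fill(rec_ptr.begin(), rec_ptr.end() - 1);
    for (int i = 0; i < n; ++i) rec_idx[fill[rec_animal[i]]++] = i;
  }

  const int *aip = Ai_p.begin();
  const int *aij = Ai_j.begin();
  const double *aix = Ai_x.begin();
  const double *xm = X.begin();              // column-major
  const double *ucm = XtX_inv_chol.begin();  // p x p, upper
  const double *upp = U_pp.begin();          // nP x nP, upper
  const int *pidx = parent_idx.begin();
  const int *ry = y.begin();
  const int *ra = rec_animal.begin();

  double s2a = start_sigma2a;
  const int n_store = (n_rounds - burn_in) / thin;
  NumericVector st_s2a(n_store), st_h2(n_store);
  IntegerVector st_round(n_store);
  NumericVector ebv_sum(q), beta_sum(p);
  int stored = 0;

  std::vector<double> work_p(p), zr(p), aP(nP), yP(nP);

  GetRNGstate();
  for (int round = 1; round <= n_rounds; ++round) {
    // (i) liabilities given current location xb + a
    for (int i = 0; i < n; ++i)
      l[i] = rtrunc_norm(xb[i] + a[ra[i]], ry[i] == 1);

    // (ii) beta | l, a ~ N(V X'r, V), V = (X'X)^-1 = Uc'Uc (Uc upper)
    for (int k = 0; k < p; ++k) zr[k] = 0.0;
    for (int k = 0; k < p; ++k) {
      const double *xc = xm + (size_t)n * k;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xc[i] * (l[i] - a[ra[i]]);
      zr[k] = s;
    }
    // work_p = Uc zr ; beta = Uc' work_p + Uc' eps
    for (int k = 0; k < p; ++k) {
      double s = 0.0;
      for (int m = k; m < p; ++m) s += ucm[k + p * m] * zr[m];
      work_p[k] = s + norm_rand();
    }
    // note: mean part requires Uc' (Uc zr); adding eps before the second
    // triangular product gives beta = Uc'(Uc zr) + Uc' eps as required
    for (int k = 0; k < p; ++k) {
      double s = 0.0;
      for (int m = 0; m <= k; ++m) s += ucm[m + p * k] * work_p[m];
      beta[k] = s;
    }
    for (int i = 0; i < n; ++i) xb[i] = 0.0;
    for (int k = 0; k < p; ++k) {
      const double *xc = xm + (size_t)n * k;
      const double b = beta[k];
      for (int i = 0; i < n; ++i) xb[i] += xc[i] * b;
    }

    // (iii) a_j single-site, pedigree code order
    const double inv_s2a = 1.0 / s2a;
    for (int j = 0; j < q; ++j) {
      double num = 0.0, prec = 0.0, djj = 0.0, off = 0.0;
      for (int t = rec_ptr[j]; t < rec_ptr[j + 1]; ++t) {
        const int i = rec_idx[t];
        num += l[i] - xb[i];
        prec += 1.0;                     // residual variance is 1
      }
      for (int idx = aip[j]; idx < aip[j + 1]; ++idx) {
        const int k = aij[idx];
        if (k == j) djj = aix[idx];
        else off += aix[idx] * a[k];
      }
      prec += djj * inv_s2a;
      num -= off * inv_s2a;
      a[j] = num / prec + norm_rand() / std::sqrt(prec);
    }

    // (iv) sigma2_a ~ (ss + nu S2) / chisq(n_subset + nu)
    double ss = 0.0;
    if (parents_only) {
      for (int r = 0; r < nP; ++r) {
        aP[r] = a[pidx[r]];
        yP[r] = 0.0;
      }
      // yP = U_pp aP, column-major upper triangular
      for (int c = 0; c < nP; ++c) {
        const double *uc = upp + (size_t)nP * c;
        const double v = aP[c];
        for (int r = 0; r <= c; ++r) yP[r] += uc[r] * v;
      }
      for (int r = 0; r < nP; ++r) ss += yP[r] * yP[r];
    } else {
      for (int j = 0; j < q; ++j) {
        double s = 0.0;
        for (int idx = aip[j]; idx < aip[j + 1]; ++idx)
          s += aix[idx] * a[aij[idx]];
        ss += a[j] * s;
      }
    }
    const double df = (parents_only ? (double)nP : (double)q) + nu;
    s2a = (ss + nu * S2) / R::rchisq(df);

    if (round > burn_in && (round - burn_in) % thin == 0 &&
        stored < n_store) {
      st_round[stored] = round;
      st_s2a[stored] = s2a;
      st_h2[stored] = s2a / (s2a + 1.0);
      for (int j = 0; j < q; ++j) ebv_sum[j] += a[j];
      for (int k = 0; k < p; ++k) beta_sum[k] += beta[k];
      ++stored;
    }
  }
  PutRNGstate();

  NumericVector lia(n);
  for (int i = 0; i < n; ++i) lia[i] = l[i];
  return List::create(_["round"] = st_round,
                      _["sigma2_a"] = st_s2a,
                      _["h2"] = st_h2,
                      _["ebv_mean"] = ebv_sum / (double)stored,
                      _["beta_mean"] = beta_sum / (double)stored,
                      _["final_liability"] = lia,
                      _["n_stored"] = stored);
}
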