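#include <Rcpp.h>
using namespace Rcpp;

// Linear epsilon-insensitive SVR solved in the dual by coordinate descent
// (L1-loss dual CD; bias handled as an augmented constant feature).
// Objective: min_w 1/2 ||w||^2 + C * sum_i max(0, |w.x_i - y_i| - eps).
// Deterministic: sequential sweeps, no internal RNG.
//
// X: n x p design (already standardized by the caller, no bias column),
// returns (p+1)-vector: weights then intercept.
// [[Rcpp::export]]
NumericVector svr_linear_cd(NumericMatrix X, NumericVector y,
                            double cost, double epsilon,
                            double tol = 1e-3, int max_sweeps = 200) {
  const int n = X.nrow(), p = X.ncol(), pa = p + 1;
  std::vector<double> w(pa, 0.0), beta(n, 0.0), qd(n);
  std::vector<int> ord(n);
  // row squared norms incl. the augmented bias feature (value 1)
  for (int i = 0; i < n; ++i) {
    double s = 1.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qd[i] = s;
    ord[i] = i;
  }
  unsigned long long lcg = 88172645463325252ULL;  // fixed stream: determinism
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // Fisher-Yates shuffle of the coordinate order (speeds convergence)
    for (int i = n - 1; i > 0; --i) {
      lcg = lcg * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = (int)((lcg >> 33) % (unsigned long long)(i + 1));
      std::swap(ord[i], ord[j]);
    }
    double max_viol = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      const int i = ord[oi];
      // G = w . x_i - y_i
      double G = w[p];
      for (int j = 0; j < p; ++j) G += w[j] * X(i, j);
      G -= y[i];
      const double Gp = G + epsilon, Gn = G - epsilon;
      double viol = 0.0, d;
      const double b = beta[i];
      if (b >= cost) {
        if (Gp > 0) viol = Gp;
      } else if (b <= -cost) {
        if (Gn < 0) viol = -Gn;
      } else if (b > 0) {
        viol = std::fabs(Gp);
      } else if (b < 0) {
        viol = std::fabs(Gn);
      } else {
        if (Gp < 0) viol = -Gp;
        else if (Gn > 0) viol = Gn;
      }
      if (viol > max_viol) max_viol = viol;
      if (Gp < qd[i] * b)      d = -Gp / qd[i];
      else if (Gn > qd[i] * b) d = -Gn / qd[i];
      else                     d = -b;
      double bnew = std::min(std::max(b + d, -cost), cost);
      d = bnew - b;
      if (std::fabs(d) > 1e-14) {
        beta[i] = bnew;
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        w[p] += d;
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}

// internal CD core; Xtr is sample-contiguous (row-major: sample i occupies
// Xtr[i*p .. i*p+p-1]) so each coordinate update touches one cache line run.
// Returns weights in w (length p+1, last = bias).
static void cd_core(const double *Xtr, const double *ytr, int ntr, int p,
                    double cost, double epsilon, double tol, int max_sweeps,
                    double *w, double *beta, int *ord) {
  const int pa = p + 1;
  for (int j = 0; j < pa; ++j) w[j] = 0.0;
  std::vector<double> qd(ntr);
  for (int i = 0; i < ntr; ++i) {
    const double *xi = Xtr + (size_t)i * p;
    double s = 1.0;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qd[i] = s;
    beta[i] = 0.0;
    ord[i] = i;
  }
  unsigned long long lcg = 88172645463325252ULL;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int i = ntr - 1; i > 0; --i) {
      lcg = lcg * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = (int)((lcg >> 33) % (unsigned long long)(i + 1));
      std::swap(ord[i], ord[j]);
    }
    double max_viol = 0.0;
    for (int oi = 0; oi < ntr; ++oi) {
      const int i = ord[oi];
      const double *xi = Xtr + (size_t)i * p;
      double G = w[p];
      for (int j = 0; j < p; ++j) G += w[j] * xi[j];
      G -= ytr[i];
      const double Gp = G + epsilon, Gn = G - epsilon;
      double viol = 0.0, d;
      const double b = beta[i];
      if (b >= cost)       { if (Gp > 0) viol = Gp; }
      else if (b <= -cost) { if (Gn < 0) viol = -Gn; }
      else if (b > 0)      viol = std::fabs(Gp);
      else if (b < 0)      viol = std::fabs(Gn);
      else { if (Gp < 0) viol = -Gp; else if (Gn > 0) viol = Gn; }
      if (viol > max_viol) max_viol = viol;
      if (Gp < qd[i] * b)      d = -Gp / qd[i];
      else if (Gn > qd[i] * b) d = -Gn / qd[i];
      else                     d = -b;
      double bnew = std::min(std::max(b + d, -cost), cost);
      d = bnew - b;
      if (std::fabs(d) > 1e-14) {
        beta[i] = bnew;
        for (int j = 0; j < p; ++j) w[j] += d * xi[j];
        w[p] += d;
      }
    }
    if (max_viol < tol) break;
  }
}

// workspace for repeated CV decoding
struct cv_work {
  std::vector<double> Xtr, ytr, beta, w, mu, sdv, pred;
  std::vector<int> ord, tr_idx, te_idx;
  cv_work(int n, int p, int nb)
      : Xtr((size_t)n * p), ytr(n), beta(n), w(p + 1), mu(p), sdv(p),
        pred((size_t)n * nb), ord(n), tr_idx(n), te_idx(n) {}
};

// core of repeated cross-validated decoding: fills out (reps x nb, column-
// major) with the Pearson r between pooled out-of-fold predictions and y
static void cv_r_mat(const double *F, int n, int p, int nb, const double *y,
                     const int *fold_ids /* n x reps */, int reps, int folds,
                     double cost, double epsilon, double tol, int max_sweeps,
                     cv_work &wk, double *out) {
  std::vector<double> &Xtr = wk.Xtr, &ytr = wk.ytr, &beta = wk.beta,
      &w = wk.w, &mu = wk.mu, &sdv = wk.sdv, &pred = wk.pred;
  std::vector<int> &ord = wk.ord, &tr_idx = wk.tr_idx, &te_idx = wk.te_idx;
  for (int r = 0; r < reps; ++r) {
    const int *fid = fold_ids + (size_t)n * r;
    for (int k = 1; k <= folds; ++k) {
      int ntr = 0, nte = 0;
      for (int i = 0; i < n; ++i) {
        if (fid[i] == k) te_idx[nte++] = i; else tr_idx[ntr++] = i;
      }
      if (nte == 0) continue;
      double muy = 0.0, sdy = 0.0;
      for (int i = 0; i < ntr; ++i) muy += y[tr_idx[i]];
      muy /= ntr;
      for (int i = 0; i < ntr; ++i) {
        double d = y[tr_idx[i]] - muy; sdy += d * d;
      }
      sdy = std::sqrt(sdy / (ntr - 1));
      if (sdy <= 0) sdy = 1.0;
      for (int i = 0; i < ntr; ++i) ytr[i] = (y[tr_idx[i]] - muy) / sdy;
      for (int b = 0; b < nb; ++b) {
        const double *Fb = F + (size_t)n * p * b;
        // train-fold column stats
        for (int j = 0; j < p; ++j) {
          double m = 0.0, s = 0.0;
          const double *col = Fb + (size_t)n * j;
          for (int i = 0; i < ntr; ++i) m += col[tr_idx[i]];
          m /= ntr;
          for (int i = 0; i < ntr; ++i) { double d = col[tr_idx[i]] - m; s += d * d; }
          s = std::sqrt(s / (ntr - 1));
          mu[j] = m; sdv[j] = s > 0 ? s : -1.0;   // -1 marks zero variance
          for (int i = 0; i < ntr; ++i)
            Xtr[(size_t)i * p + j] =
              sdv[j] > 0 ? (col[tr_idx[i]] - m) / sdv[j] : 0.0;
        }
        cd_core(Xtr.data(), ytr.data(), ntr, p, cost, epsilon, tol,
                max_sweeps, w.data(), beta.data(), ord.data());
        for (int i = 0; i < nte; ++i) {
          const int row = te_idx[i];
          double yhat = w[p];
          for (int j = 0; j < p; ++j) {
            double v = sdv[j] > 0
              ? (Fb[row + (size_t)n * j] - mu[j]) / sdv[j] : 0.0;
            yhat += w[j] * v;
          }
          pred[row + (size_t)n * b] = yhat * sdy + muy;
        }
      }
    }
    // per-bin Pearson r of pooled out-of-fold predictions vs y
    for (int b = 0; b < nb; ++b) {
      const double *pb = pred.data() + (size_t)n * b;
      double mx = 0.0, my = 0.0;
      for (int i = 0; i < n; ++i) { mx += pb[i]; my += y[i]; }
      mx /= n; my /= n;
      double sxy = 0.0, sxx = 0.0, syy = 0.0;
      for (int i = 0; i < n; ++i) {
        double dx = pb[i] - mx, dy = y[i] - my;
        sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
      }
      out[(size_t)reps * b + r] =
        (sxx > 0 && syy > 0) ? sxy / std::sqrt(sxx * syy) : 0.0;
    }
  }
}

// Repeated cross-validated linear-SVR decoding of every frequency bin.
// feats: n x p x nb array (participants x channels x bins), fold_ids:
// n x reps matrix of fold labels in 1..folds. Per repetition and fold the
// training-fold features and scores are standardized, the SVR fit, and the
// held-out rows predicted on the raw score scale; returns reps x nb matrix
// of Pearson r between pooled out-of-fold predictions and y.
// [[Rcpp::export]]
NumericMatrix cv_decode_batch(NumericVector feats, NumericVector y,
                              IntegerMatrix fold_ids, int folds,
                              double cost, double epsilon,
                              double tol = 1e-3, int max_sweeps = 60) {
  IntegerVector dims = feats.attr("dim");
  const int n = dims[0], p = dims[1], nb = dims[2];
  const int reps = fold_ids.ncol();
  NumericMatrix out(reps, nb);
  cv_work wk(n, p, nb);
  cv_r_mat(feats.begin(), n, p, nb, y.begin(), fold_ids.begin(), reps,
           folds, cost, epsilon, tol, max_sweeps, wk, out.begin());
  return out;
}

// Full permutation-null batch: yperm is n x B (one permuted score vector
// per column), fold_ids is n x (reps*B) with the B blocks of reps columns
// laid out consecutively. Returns B x nb matrix of the Fisher-Z-averaged
// decoding r per permutation and bin.
// [[Rcpp::export]]
NumericMatrix cv_perm_null_batch(NumericVector feats, NumericMatrix yperm,
                                 IntegerMatrix fold_ids, int reps, int folds,
                                 double cost, double epsilon,
                                 double tol = 1e-3, int max_sweeps = 60) {
  IntegerVector dims = feats.attr("dim");
  const int n = dims[0], p = dims[1], nb = dims[2];
  const int B = yperm.ncol();
  NumericMatrix out(B, nb);
  cv_work wk(n, p, nb);
  std::vector<double> rmat((size_t)reps * nb);
  for (int b = 0; b < B; ++b) {
    cv_r_mat(feats.begin(), n, p, nb, &yperm(0, b),
             fold_ids.begin() + (size_t)n * reps * b, reps, folds,
             cost, epsilon, tol, max_sweeps, wk, rmat.data());
    for (int j = 0; j < nb; ++j) {
      double zsum = 0.0;
      for (int r = 0; r < reps; ++r) {
        double rr = rmat[(size_t)reps * j + r];
        rr = std::min(std::max(rr, -1.0 + 1e-12), 1.0 - 1e-12);
        zsum += std::atanh(rr);
      }
      out(b, j) = std::tanh(zsum / reps);
    }
  }
  return out;
}

// Per-channel artifact-criterion scan of one epoch.
// x: samples x channels (microvolts); fs in Hz.
// Criterion 1: |dv| between consecutive samples, expressed per ms, > grad_uv_ms.
// Criterion 2: (max - min) inside any sliding win2_s window > range2_uv.
// Criterion 3: (max - min) inside any sliding win3_s window < flat_uv.
// Windows advance sample by sample. Returns 3-vector of 0/1 flags (any channel).
// [[Rcpp::export]]
IntegerVector epoch_criteria(NumericMatrix x, double fs,
                             double grad_uv_ms = 50.0,
                             double range2_uv = 200.0, double win2_s = 0.2,
                             double flat_uv = 0.5, double win3_s = 0.1) {
  const int n = x.nrow(), nc = x.ncol();
  const double dt_ms = 1000.0 / fs;
  const int w2 = std::max(2, (int)std::lround(win2_s * fs));
  const int w3 = std::max(2, (int)std::lround(win3_s * fs));
  IntegerVector out(3);
  for (int c = 0; c < nc && !(out[0] && out[1] && out[2]); ++c) {
    const double *v = &x(0, c);
    if (!out[0]) {
      for (int i = 1; i < n; ++i)
        if (std::fabs(v[i] - v[i - 1]) / dt_ms > grad_uv_ms) { out[0] = 1; break; }
    }
    // monotonic deques for sliding max/min over window w
    for (int pass = 0; pass < 2; ++pass) {
      const int w = pass == 0 ? w2 : w3;
      if ((pass == 0 && out[1]) || (pass == 1 && out[2]) || n < w) continue;
      std::deque<int> qmax, qmin;
      bool hit = false;
      for (int i = 0; i < n; ++i) {
        while (!qmax.empty() && v[qmax.back()] <= v[i]) qmax.pop_back();
        qmax.push_back(i);
        while (!qmin.empty() && v[qmin.back()] >= v[i]) qmin.pop_back();
        qmin.push_back(i);
        if (qmax.front() <= i - w) qmax.pop_front();
        if (qmin.front() <= i - w) qmin.pop_front();
        if (i >= w - 1) {
          const double rng = v[qmax.front()] - v[qmin.front()];
          if (pass == 0 && rng > range2_uv) { hit = true; break; }
          if (pass == 1 && rng < flat_uv)   { hit = true; break; }
        }
      }
      if (hit) { if (pass == 0) out[1] = 1; else out[2] = 1; }
    }
  }
  return out;
}
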