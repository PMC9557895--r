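#include <Rcpp.h>
using namespace Rcpp;

// Random-restart swap descent: find an n-subset of `pool` whose sample mean
// and SD (denominator n-1) are each within `tol` of the targets.  The loss is
// (mean - target_mean)^2 + (sd - target_sd)^2; a proposed member/non-member
// swap is accepted iff it lowers the loss.  Uses R's RNG so results are
// reproducible under set.seed() on the R side.
//
// Returns 1-based indices into `pool`, achieved moments, iterations used and
// a convergence flag; on failure the best restart's state is returned.

static inline double sd_from(double sum, double sumsq, int n) {
  double var = (sumsq - sum * sum / n) / (n - 1);
  return var > 0 ? std::sqrt(var) : 0.0;
}

// [[Rcpp::export(name = ".selectMatchedCpp")]]
List select_matched_cpp(NumericVector pool, int n, double target_mean,
                        double target_sd, double tol, int max_iter,
                        int restarts) {
  const int P = pool.size();
  if (n < 2 || n > P) stop("subset size out of range");
  if (restarts < 1) restarts = 1;
  const int iter_per_restart = std::max(1, max_iter / restarts);

  std::vector<int> perm(P), best_perm(n);
  double best_loss = R_PosInf, best_mean = NA_REAL, best_sd = NA_REAL;
  int iters_total = 0;
  bool converged = false;

  for (int r = 0; r < restarts && !converged; ++r) {
    for (int k = 0; k < P; ++k) perm[k] = k;
    // partial Fisher-Yates: random initial subset in perm[0..n-1]
    for (int k = 0; k < n; ++k) {
      int j = k + (int)(unif_rand() * (P - k));
      if (j >= P) j = P - 1;
      std::swap(perm[k], perm[j]);
    }
    double sum = 0.0, sumsq = 0.0;
    for (int k = 0; k < n; ++k) {
      double v = pool[perm[k]];
      sum += v; sumsq += v * v;
    }
    double mean = sum / n, sd = sd_from(sum, sumsq, n);
    double loss = (mean - target_mean) * (mean - target_mean) +
                  (sd - target_sd) * (sd - target_sd);

    for (int it = 0; it < iter_per_restart; ++it) {
      if (std::abs(mean - target_mean) < tol &&
          std::abs(sd - target_sd) < tol) {
        converged = true;
        break;
      }
      ++iters_total;
      int i = (int)(unif_rand() * n);
      int j = n + (int)(unif_rand() * (P - n));
      if (i >= n) i = n - 1;
      if (j >= P) j = P - 1;
      double a = pool[perm[i]], b = pool[perm[j]];
      double new_sum = sum - a + b;
      double new_sumsq = sumsq - a * a + b * b;
      double new_mean = new_sum / n, new_sd = sd_from(new_sum, new_sumsq, n);
      double new_loss = (new_mean - target_mean) * (new_mean - target_mean) +
                        (new_sd - target_sd) * (new_sd - target_sd);
      if (new_loss < loss) {
        std::swap(perm[i], perm[j]);
        sum = new_sum; sumsq = new_sumsq;
        mean = new_mean; sd = new_sd; loss = new_loss;
      }
    }
    // re-check convergence in case the loop ended exactly on it
    if (std::abs(mean - target_mean) < tol &&
        std::abs(sd - target_sd) < tol)
      converged = true;
    if (loss < best_loss) {
      best_loss = loss; best_mean = mean; best_sd = sd;
      std::copy(perm.begin(), perm.begin() + n, best_perm.begin());
    }
  }

  IntegerVector idx(n);
  for (int k = 0; k < n; ++k) idx[k] = best_perm[k] + 1;
  return List::create(_["indices"] = idx,
                      _["mean"] = best_mean,
                      _["sd"] = best_sd,
                      _["iterations"] = iters_total,
                      _["converged"] = converged);
}
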