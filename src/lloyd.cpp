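#include <Rcpp.h>
using namespace Rcpp;

// Lloyd k-means for one start. Squared Euclidean distance, assignment ties
// broken toward the lowest cluster index. An empty cluster is reseeded at the
// point currently farthest from its own center so that k stays fixed.
// [[Rcpp::export]]
List cpp_lloyd(NumericMatrix x, NumericMatrix centers0, int max_iter,
               double tol) {
  const int n = x.nrow(), d = x.ncol(), k = centers0.nrow();
  NumericMatrix centers = clone(centers0);
  IntegerVector assign(n, -1);
  IntegerVector prev(n, -2);
  std::vector<double> dist2(n);
  std::vector<int> count(k);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // assignment step
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int best_j = 0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          double diff = x(i, c) - centers(j, c);
          s += diff * diff;
        }
        if (s < best) { best = s; best_j = j; }
      }
      assign[i] = best_j;
      dist2[i] = best;
      count[best_j]++;
    }

    // reseed empty clusters at the farthest point from its current center
    for (int j = 0; j < k; ++j) {
      if (count[j] == 0) {
        double worst = -1.0;
        int worst_i = -1;
        for (int i = 0; i < n; ++i) {
          if (count[assign[i]] > 1 && dist2[i] > worst) {
            worst = dist2[i];
            worst_i = i;
          }
        }
        if (worst_i >= 0) {
          count[assign[worst_i]]--;
          assign[worst_i] = j;
          count[j] = 1;
          for (int c = 0; c < d; ++c) centers(j, c) = x(worst_i, c);
          dist2[worst_i] = 0.0;
        }
      }
    }

    bool stable = true;
    for (int i = 0; i < n; ++i) {
      if (assign[i] != prev[i]) { stable = false; break; }
    }
    if (stable) { converged = true; break; }
    prev = clone(assign);

    // update step: centers become means of their members
    NumericMatrix newc(k, d);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < d; ++c) newc(assign[i], c) += x(i, c);
    double max_shift2 = 0.0;
    for (int j = 0; j < k; ++j) {
      double s2 = 0.0;
      for (int c = 0; c < d; ++c) {
        newc(j, c) /= count[j];
        double diff = newc(j, c) - centers(j, c);
        s2 += diff * diff;
      }
      if (s2 > max_shift2) max_shift2 = s2;
    }
    centers = newc;
    if (max_shift2 < tol * tol) { converged = true; iter++; break; }
  }

  // final centers are the means of the final assignment; recompute wcss
  NumericMatrix finalc(k, d);
  std::fill(count.begin(), count.end(), 0);
  for (int i = 0; i < n; ++i) {
    count[assign[i]]++;
    for (int c = 0; c < d; ++c) finalc(assign[i], c) += x(i, c);
  }
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) finalc(j, c) /= count[j];
  double wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < d; ++c) {
      double diff = x(i, c) - finalc(assign[i], c);
      wcss += diff * diff;
    }
  }

  IntegerVector cluster(n);
  for (int i = 0; i < n; ++i) cluster[i] = assign[i] + 1;
  return List::create(_["cluster"] = cluster, _["centers"] = finalc,
                      _["wcss"] = wcss, _["iterations"] = iter + 1,
                      _["converged"] = converged);
}

// Mean pairwise Euclidean distances within and between clusters, computed in
// one O(n^2) pass without materialising the distance matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pair_dist_means(NumericMatrix x, IntegerVector cluster,
                                  int k) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix sum(k, k);
  NumericMatrix cnt(k, k);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      s = std::sqrt(s);
      int a = cluster[i] - 1, b = cluster[j] - 1;
      if (a > b) std::swap(a, b);
      sum(a, b) += s;
      cnt(a, b) += 1.0;
    }
  }
  NumericMatrix out(k, k);
  for (int a = 0; a < k; ++a)
    for (int b = a; b < k; ++b) {
      double m = cnt(a, b) > 0 ? sum(a, b) / cnt(a, b) : 0.0;
      out(a, b) = m;
      out(b, a) = m;
    }
  return out;
}

// Per-point mean distance to every cluster (n x k), used by the silhouette.
// [[Rcpp::export]]
NumericMatrix cpp_mean_dist_to_clusters(NumericMatrix x,
                                        IntegerVector cluster, int k) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix sum(n, k);
  IntegerVector size(k);
  for (int i = 0; i < n; ++i) size[cluster[i] - 1]++;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      s = std::sqrt(s);
      sum(i, cluster[j] - 1) += s;
      sum(j, cluster[i] - 1) += s;
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      int m = size[j] - (cluster[i] - 1 == j ? 1 : 0);
      sum(i, j) = m > 0 ? sum(i, j) / m : NA_REAL;
    }
  }
  return sum;
}
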