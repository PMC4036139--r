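#include <Rcpp.h>
#include <R_ext/Random.h>
using namespace Rcpp;

// Flat row-major storage: point i occupies X[i*d .. i*d+d-1].

static inline double sqdist(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = a[c] - b[c];
    s += diff * diff;
  }
  return s;
}

// Greedy k-means++ seeding: each new center is drawn from the current
// squared-distance distribution, trying n_cand candidates and keeping the
// one that minimizes the resulting potential. Uses R's RNG.
static void seed_greedy_pp(const std::vector<double>& X, int n, int d, int k,
                           std::vector<double>& C) {
  int n_cand = 2 + (int)std::log((double)k + 1.0);
  std::vector<double> d2(n), cand_d2(n), best_d2(n);
  int first = (int)(unif_rand() * n);
  if (first >= n) first = n - 1;
  std::copy(X.begin() + first * d, X.begin() + (first + 1) * d, C.begin());
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    d2[i] = sqdist(&X[i * d], &C[0], d);
    total += d2[i];
  }
  for (int j = 1; j < k; ++j) {
    double best_pot = R_PosInf;
    int best_idx = 0;
    for (int c = 0; c < n_cand; ++c) {
      double u = unif_rand() * total, acc = 0.0;
      int idx = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (acc >= u) { idx = i; break; }
      }
      double pot = 0.0;
      for (int i = 0; i < n; ++i) {
        double nd = sqdist(&X[i * d], &X[idx * d], d);
        cand_d2[i] = nd < d2[i] ? nd : d2[i];
        pot += cand_d2[i];
      }
      if (pot < best_pot) {
        best_pot = pot;
        best_idx = idx;
        std::swap(cand_d2, best_d2);
      }
    }
    std::copy(X.begin() + best_idx * d, X.begin() + (best_idx + 1) * d,
              C.begin() + j * d);
    std::swap(d2, best_d2);
    total = best_pot;
  }
}

// Lloyd iterations; ties go to the lowest centroid index, emptied clusters
// are re-seeded at the point farthest from its assigned centroid.
static double lloyd_run(const std::vector<double>& X, int n, int d, int k,
                        std::vector<double>& C, std::vector<int>& labels,
                        int max_iter, double tol, int& iters, int& n_reseed) {
  std::vector<double> dist2(n);
  std::vector<int> count(k);
  double prev_cost = R_PosInf, cost = R_PosInf;
  bool changed = true;
  for (iters = 0; iters < max_iter; ++iters) {
    cost = 0.0;
    changed = false;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      const double* xi = &X[i * d];
      for (int j = 0; j < k; ++j) {
        double s = sqdist(xi, &C[j * d], d);
        if (s < best) { best = s; bj = j; }
      }
      if (labels[i] != bj) { labels[i] = bj; changed = true; }
      dist2[i] = best;
      cost += best;
    }
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n; ++i) count[labels[i]]++;
    bool reseeded = false;
    for (int j = 0; j < k; ++j) {
      if (count[j] == 0) {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (count[labels[i]] > 1 && dist2[i] > fd) { fd = dist2[i]; far = i; }
        count[labels[far]]--;
        labels[far] = j;
        count[j] = 1;
        dist2[far] = 0.0;
        reseeded = true;
        n_reseed++;
      }
    }
    if (!reseeded && (!changed || prev_cost - cost < tol)) break;
    prev_cost = cost;
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* xi = &X[i * d];
      double* cj = &C[labels[i] * d];
      for (int c = 0; c < d; ++c) cj[c] += xi[c];
    }
    for (int j = 0; j < k; ++j)
      if (count[j] > 0)
        for (int c = 0; c < d; ++c) C[j * d + c] /= count[j];
  }
  return cost;
}

// [[Rcpp::export(name = ".kmeans_cpp")]]
List kmeans_cpp(NumericMatrix x, int k, int n_init, int max_iter, double tol) {
  const int n = x.nrow(), d = x.ncol();
  std::vector<double> X(n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) X[i * d + c] = x(i, c);

  GetRNGstate();
  std::vector<double> bestC;
  std::vector<int> bestL;
  double best_cost = R_PosInf;
  int best_iters = 0, best_reseed = 0;
  for (int init = 0; init < n_init; ++init) {
    std::vector<double> C(k * d);
    std::vector<int> labels(n, -1);
    seed_greedy_pp(X, n, d, k, C);
    int iters = 0, n_reseed = 0;
    double cost = lloyd_run(X, n, d, k, C, labels, max_iter, tol, iters, n_reseed);
    if (cost < best_cost) {
      best_cost = cost;
      bestC = C;
      bestL = labels;
      best_iters = iters;
      best_reseed = n_reseed;
    }
  }
  PutRNGstate();

  NumericMatrix centers(k, d);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) centers(j, c) = bestC[j * d + c];
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = bestL[i] + 1;
  return List::create(_["centers"] = centers, _["labels"] = lab,
                      _["cost"] = best_cost, _["iterations"] = best_iters,
                      _["n_reseeds"] = best_reseed);
}

// Lloyd from user-supplied initial centers (deterministic; used by tests).
// [[Rcpp::export(name = ".lloyd_kmeans")]]
List lloyd_kmeans(NumericMatrix x, NumericMatrix init, int max_iter,
                  double tol) {
  const int n = x.nrow(), d = x.ncol(), k = init.nrow();
  std::vector<double> X(n * d), C(k * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) X[i * d + c] = x(i, c);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) C[j * d + c] = init(j, c);
  std::vector<int> labels(n, -1);
  int iters = 0, n_reseed = 0;
  double cost = lloyd_run(X, n, d, k, C, labels, max_iter, tol, iters, n_reseed);
  NumericMatrix centers(k, d);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) centers(j, c) = C[j * d + c];
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i] + 1;
  return List::create(_["centers"] = centers, _["labels"] = lab,
                      _["cost"] = cost, _["iterations"] = iters,
                      _["n_reseeds"] = n_reseed);
}

// Nearest-centroid assignment (squared Euclidean, lowest index wins ties).
// [[Rcpp::export(name = ".nearest_centroid")]]
IntegerVector nearest_centroid(NumericMatrix x, NumericMatrix centers) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  std::vector<double> X(n * d), C(k * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) X[i * d + c] = x(i, c);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) C[j * d + c] = centers(j, c);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = sqdist(&X[i * d], &C[j * d], d);
      if (s < best) { best = s; bj = j; }
    }
    labels[i] = bj + 1;
  }
  return labels;
}
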