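#include <Rcpp.h>
using namespace Rcpp;

// Affinity bookkeeping: with w_ij = 2*s_ij - 1 on observed pairs (0 where
// unobserved) and B = sum over observed pairs of (1 - s_ij),
//   alpha(c, S) = (B + Q(c)) / M,  Q(c) = sum over same-cluster pairs of w_ij,
// where M is the number of observed pairs. Moving item i from cluster a to b
// changes Q by sum_{j != i} w_ij * ((c_j == b) - (c_j == a)): O(n) per
// proposal.

static const double EPS = 1e-9;  // strict-increase tolerance (ties rejected)

static inline int rand_int(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

static double q_from_scratch(const NumericMatrix& W, const IntegerVector& c) {
  const int n = c.size();
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (c[i] == c[j]) q += W(i, j);
  return q;
}

static inline double move_delta(const NumericMatrix& W, const IntegerVector& c,
                                int i, int a, int b) {
  const int n = c.size();
  double d = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (c[j] == b) d += W(i, j);
    else if (c[j] == a) d -= W(i, j);
  }
  return d;
}

// Coordinate ascent from a given initial assignment (0-based clusters).
// Random single-item reassignment proposals are accepted iff they strictly
// increase alpha; after n*(k-1) consecutive rejections an exhaustive sweep
// over all single-item moves certifies the local maximum (or resumes the
// random phase from the improving move it finds). Uses R's RNG.
// [[Rcpp::export]]
List cpp_coordinate_ascent(NumericMatrix W, double M, double B, int k,
                           IntegerVector init) {
  const int n = init.size();
  IntegerVector c = clone(init);
  double Q = q_from_scratch(W, c);
  long proposals = 0, accepted = 0;
  const long stall_limit = (long)n * (k - 1);

  bool done = (k <= 1);
  long stall = 0;
  while (!done) {
    // random-proposal phase
    while (stall < stall_limit) {
      int i = rand_int(n);
      int a = c[i];
      int r = rand_int(k - 1);
      int b = (r >= a) ? r + 1 : r;
      ++proposals;
      double d = move_delta(W, c, i, a, b);
      if (d > EPS) {
        c[i] = b; Q += d; ++accepted; stall = 0;
      } else {
        ++stall;
      }
    }
    // exhaustive sweep: certify stationarity or find an improving move
    bool improved = false;
    for (int i = 0; i < n && !improved; ++i) {
      int a = c[i];
      for (int b = 0; b < k; ++b) {
        if (b == a) continue;
        ++proposals;
        double d = move_delta(W, c, i, a, b);
        if (d > EPS) {
          c[i] = b; Q += d; ++accepted; improved = true; break;
        }
      }
    }
    if (improved) stall = 0; else done = true;
  }

  Q = q_from_scratch(W, c);  // remove accumulated rounding before reporting
  return List::create(_["assign"] = c, _["alpha"] = (B + Q) / M,
                      _["proposals"] = (double)proposals,
                      _["accepted"] = (double)accepted);
}

// Mean affinity of uniformly random k-cluster assignments against S,
// the Monte-Carlo chance term of the soft-clustering ARI. Returns the
// per-draw affinities. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_random_affinities(NumericMatrix W, double M, double B,
                                    int k, int n_random) {
  const int n = W.nrow();
  NumericVector out(n_random);
  IntegerVector c(n);
  for (int r = 0; r < n_random; ++r) {
    for (int i = 0; i < n; ++i) c[i] = rand_int(k);
    out[r] = (B + q_from_scratch(W, c)) / M;
  }
  return out;
}
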