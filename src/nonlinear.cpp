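#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance between delay vectors starting at samples i
// and j: coordinates x[i + k*tau], k = 0..m-1.
static inline double dist2_lagged(const double* x, int i, int j, int m,
                                  int tau) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = x[i + k * tau] - x[j + k * tau];
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector fnn_cpp(NumericVector x, int tau, int m_max, double r_tol,
                      double a_tol, int theiler) {
  const int n = x.size();
  const double* px = REAL(x);
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += px[i];
  mean /= n;
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += (px[i] - mean) * (px[i] - mean);
  const double ra = std::sqrt(var / n);  // attractor size

  NumericVector out(m_max);
  for (int m = 1; m <= m_max; ++m) {
    // need the (m+1)-th coordinate x[i + m*tau] for the extension test
    const int n_vec = n - m * tau;
    if (n_vec < 2) { out[m - 1] = NA_REAL; continue; }
    long false_count = 0, total = 0;
    for (int i = 0; i < n_vec; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bj = -1;
      for (int j = 0; j < n_vec; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double d2 = dist2_lagged(px, i, j, m, tau);
        if (d2 > 0.0 && d2 < best) { best = d2; bj = j; }
      }
      if (bj < 0) continue;
      double d = std::sqrt(best);
      double extra = std::fabs(px[i + m * tau] - px[bj + m * tau]);
      bool is_false = (extra / d > r_tol) ||
                      (std::sqrt(d * d + extra * extra) / ra > a_tol);
      ++total;
      if (is_false) ++false_count;
    }
    out[m - 1] = total > 0 ? (double)false_count / total : NA_REAL;
  }
  return out;
}

static inline double dist_rows(const NumericMatrix& E, int i, int j) {
  double s = 0.0;
  for (int k = 0; k < E.ncol(); ++k) {
    double d = E(i, k) - E(j, k);
    s += d * d;
  }
  return std::sqrt(s);
}

// Find a replacement neighbor for fiducial index i: separation in
// [min_sep, max_sep], temporally non-adjacent, and (when a previous
// displacement direction u is supplied) small orientation change.
// Fallback chain: in-range & in-angle -> in-range (smallest angle) ->
// nearest positive-distance point. Returns -1 only if no point with
// positive distance exists.
static int find_neighbor(const NumericMatrix& E, int i, int last_valid,
                         double min_sep, double max_sep, double angle_max,
                         int theiler, const std::vector<double>* u) {
  const int m = E.ncol();
  double unorm = 0.0;
  if (u) {
    for (int k = 0; k < m; ++k) unorm += (*u)[k] * (*u)[k];
    unorm = std::sqrt(unorm);
    if (unorm <= 0.0) u = nullptr;
  }
  const double cos_min = std::cos(angle_max);
  int best_in = -1, best_ang = -1, best_any = -1;
  double best_in_d = std::numeric_limits<double>::infinity();
  double best_ang_cos = -2.0;
  double best_any_d = std::numeric_limits<double>::infinity();
  for (int j = 0; j <= last_valid; ++j) {
    if (std::abs(i - j) <= theiler) continue;
    double d = dist_rows(E, i, j);
    if (d <= 0.0) continue;
    if (d < best_any_d) { best_any_d = d; best_any = j; }
    if (d < min_sep || d > max_sep) continue;
    double c = 2.0;  // "no direction constraint" marker
    if (u) {
      double dot = 0.0;
      for (int k = 0; k < m; ++k) dot += (E(j, k) - E(i, k)) * (*u)[k];
      c = dot / (d * unorm);
      if (std::fabs(c) > best_ang_cos) { best_ang_cos = std::fabs(c); best_ang = j; }
      if (std::fabs(c) < cos_min) continue;  // orientation change too large
    }
    if (d < best_in_d) { best_in_d = d; best_in = j; }
  }
  if (best_in >= 0) return best_in;
  if (best_ang >= 0) return best_ang;
  return best_any;
}

// Wolf fixed-evolution-time estimate of the dominant Lyapunov exponent
// from a delay embedding. The fiducial trajectory is followed through the
// embedding; a neighbor within [min_sep, max_sep] is co-evolved for
// `evolve` samples, the log separation ratio is accumulated, and the
// neighbor is replaced (preferring small orientation change, angle_max in
// radians) whenever its separation leaves the admissible range.
// lambda = sum(ln(d1/d0)) / total evolved time.
// [[Rcpp::export]]
List wolf_cpp(NumericMatrix E, double dt, int evolve, double min_sep,
              double max_sep, double angle_max, int theiler) {
  const int n = E.nrow();
  if (n < 10 * evolve) stop("embedding too short for the requested evolve time");
  const int m = E.ncol();
  const int last_valid = n - 1 - evolve;  // neighbors must survive one evolve

  int i = 0;
  int j = find_neighbor(E, i, last_valid, min_sep, max_sep, angle_max,
                        theiler, nullptr);
  if (j < 0 || dist_rows(E, i, j) > max_sep) {
    stop("no admissible neighbor found; increase max_sep or supply a longer series");
  }
  double sum_log = 0.0, total_time = 0.0;
  int n_repl = 1;  // the initial anchor counts as the first renormalization
  std::vector<double> trace_t, trace_est;
  std::vector<double> u(m);

  while (i + evolve <= n - 1 && j + evolve <= n - 1) {
    double d0 = dist_rows(E, i, j);
    int i2 = i + evolve, j2 = j + evolve;
    double d1 = dist_rows(E, i2, j2);
    if (d0 > 0.0 && d1 > 0.0) {
      sum_log += std::log(d1 / d0);
      total_time += evolve * dt;
      trace_t.push_back(total_time);
      trace_est.push_back(sum_log / total_time);
    }
    i = i2;
    if (i + evolve > n - 1) break;
    bool need_repl = (d1 > max_sep) || (d1 <= 0.0) || (d0 <= 0.0);
    if (need_repl) {
      for (int k = 0; k < m; ++k) u[k] = E(j2, k) - E(i, k);
      int jn = find_neighbor(E, i, last_valid, min_sep, max_sep, angle_max,
                             theiler, &u);
      if (jn < 0) break;  // degenerate: nothing left to follow
      if (jn != j2) ++n_repl;
      j = jn;
    } else {
      j = j2;
    }
  }
  if (total_time <= 0.0) {
    stop("no admissible neighbor evolution possible; increase max_sep or supply a longer series");
  }
  return List::create(
    _["exponent"] = sum_log / total_time,
    _["n_replacements"] = n_repl,
    _["trace_time"] = NumericVector(trace_t.begin(), trace_t.end()),
    _["trace_estimate"] = NumericVector(trace_est.begin(), trace_est.end()));
}
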