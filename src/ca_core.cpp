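#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional CA core.  The lattice is a permutation `order` of
// 0..N-1 (0-based read indices); `dmat` holds all pairwise distances.
// Rule phi_r applied at cell i compares d(x_i, x_{i+1}) with
// d(x_i, x_{i+r-1}) (indices mod N, periodic boundary) and swaps the
// contents of cells i+1 and i+r-1 when the first distance is strictly
// larger.  A sweep visits cells i = 0..N-1 ascending and applies every
// rule phi_r, r = 3..R ascending, at each cell before moving on, with
// swaps taking effect immediately.

static int sweep_once(IntegerVector order, const NumericMatrix& dmat, int R) {
  const int n = order.size();
  int swaps = 0;
  for (int i = 0; i < n; ++i) {
    for (int r = 3; r <= R; ++r) {
      const int inext = (i + 1) % n;
      const int ifar  = (i + r - 1) % n;
      const int xi = order[i], xn = order[inext], xf = order[ifar];
      if (dmat(xi, xn) > dmat(xi, xf)) {
        order[inext] = xf;
        order[ifar]  = xn;
        ++swaps;
      }
    }
  }
  return swaps;
}

// [[Rcpp::export]]
List ca_sweep_cpp(IntegerVector order0, NumericMatrix dmat, int R) {
  IntegerVector order = clone(order0);
  int swaps = sweep_once(order, dmat, R);
  return List::create(_["order"] = order, _["swaps"] = swaps);
}

// FNV-1a fingerprint of the lattice state, for cycle detection.
static uint64_t state_hash(const IntegerVector& order) {
  uint64_t h = 1469598103934665603ULL;
  for (int v : order) {
    for (int b = 0; b < 4; ++b) {
      h ^= (uint64_t)((v >> (8 * b)) & 0xff);
      h *= 1099511628211ULL;
    }
  }
  return h;
}

// The swap dynamics has no global objective that every swap decreases,
// so on some inputs it enters a limit cycle instead of reaching a
// zero-swap fixed point.  We detect cycles by fingerprinting the state
// after each iteration; when the walk revisits a state (or the
// iteration cap is hit) the best-sorted state seen so far -- minimum
// total consecutive-cell distance -- is returned instead of an
// arbitrary point of the cycle.
// [[Rcpp::export]]
List ca_converge_cpp(IntegerVector order0, NumericMatrix dmat, int R,
                     int max_iterations, bool trace) {
  IntegerVector order = clone(order0);
  const int n = order.size();
  std::vector<int> swap_counts;
  std::vector<int> traces;
  std::set<uint64_t> seen;
  seen.insert(state_hash(order));
  std::vector<int> best(order.begin(), order.end());
  double best_energy = R_PosInf;
  int best_iteration = 0;
  bool converged = false;
  std::string stopped = "max_iterations";
  int iter = 0;
  while (iter < max_iterations) {
    int swaps = sweep_once(order, dmat, R);
    ++iter;
    swap_counts.push_back(swaps);
    if (trace)
      traces.insert(traces.end(), order.begin(), order.end());
    double energy = 0.0;
    for (int i = 0; i < n; ++i) energy += dmat(order[i], order[(i + 1) % n]);
    if (energy < best_energy) {
      best_energy = energy;
      std::copy(order.begin(), order.end(), best.begin());
      best_iteration = iter;
    }
    if (swaps == 0) { converged = true; stopped = "fixpoint"; break; }
    if (!seen.insert(state_hash(order)).second) { stopped = "cycle"; break; }
  }
  if (!converged)
    for (int i = 0; i < n; ++i) order[i] = best[i];
  List out = List::create(
    _["order"] = order,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["stopped"] = stopped,
    _["best_iteration"] = best_iteration,
    _["swaps_per_iteration"] = wrap(swap_counts));
  if (trace) {
    IntegerMatrix tr(n, iter);
    std::copy(traces.begin(), traces.end(), tr.begin());
    out["trace"] = tr;
  }
  return out;
}

// ---- evaluation-metric kernels ---------------------------------------
// A confusion matrix has K cluster rows and Ns species columns; entry
// (i, j) counts reads of species j in cluster i.  The same kernels back
// the scalar R wrappers and the batch form used for large simulation
// sweeps, so both paths are literally one code path.

static double precision_kernel(const double* cm, int K, int Ns) {
  double num = 0.0, den = 0.0;
  for (int i = 0; i < K; ++i) {
    double mx = 0.0;
    for (int j = 0; j < Ns; ++j) {
      const double v = cm[i + (size_t)j * K];
      den += v;
      if (v > mx) mx = v;
    }
    num += mx;
  }
  return num / den;
}

// arg max over species per cluster row; ties go to the lowest species index
static void call_kernel(const double* cm, int K, int Ns, int* calls) {
  for (int i = 0; i < K; ++i) {
    int best = 0;
    double mx = cm[i];
    for (int j = 1; j < Ns; ++j) {
      const double v = cm[i + (size_t)j * K];
      if (v > mx) { mx = v; best = j; }
    }
    calls[i] = best;
  }
}

// FP rate of species s (0-based): over clusters called s, foreign reads /
// all reads; NaN when no cluster is called s.
static double fp_kernel(const double* cm, int K, int Ns, const int* calls,
                        int s) {
  double tot = 0.0, foreign = 0.0;
  bool any = false;
  for (int i = 0; i < K; ++i) {
    if (calls[i] != s) continue;
    any = true;
    for (int j = 0; j < Ns; ++j) {
      const double v = cm[i + (size_t)j * K];
      tot += v;
      if (j != s) foreign += v;
    }
  }
  if (!any) return NA_REAL;
  return foreign / tot;
}

// [[Rcpp::export]]
double precision_cpp(NumericMatrix cm) {
  return precision_kernel(cm.begin(), cm.nrow(), cm.ncol());
}

// [[Rcpp::export]]
IntegerVector call_species_cpp(NumericMatrix cm) {
  const int K = cm.nrow();
  IntegerVector calls(K);
  call_kernel(cm.begin(), K, cm.ncol(), calls.begin());
  for (int i = 0; i < K; ++i) calls[i] += 1;  // back to 1-based
  return calls;
}

// [[Rcpp::export]]
NumericVector fp_rate_cpp(NumericMatrix cm) {
  const int K = cm.nrow(), Ns = cm.ncol();
  std::vector<int> calls(K);
  call_kernel(cm.begin(), K, Ns, calls.data());
  NumericVector out(Ns);
  for (int s = 0; s < Ns; ++s)
    out[s] = fp_kernel(cm.begin(), K, Ns, calls.data(), s);
  return out;
}

// Batch form: each row of `flat` is one K x Ns confusion matrix in
// column-major order.  Returns precision and all Ns FP rates per matrix.
// [[Rcpp::export]]
List metrics_many_cpp(NumericMatrix flat, int K, int Ns) {
  const int n = flat.nrow();
  NumericVector prec(n);
  NumericMatrix fp(n, Ns);
  std::vector<double> cm((size_t)K * Ns);
  std::vector<int> calls(K);
  for (int m = 0; m < n; ++m) {
    for (int c = 0; c < K * Ns; ++c) cm[c] = flat(m, c);
    prec[m] = precision_kernel(cm.data(), K, Ns);
    call_kernel(cm.data(), K, Ns, calls.data());
    for (int s = 0; s < Ns; ++s)
      fp(m, s) = fp_kernel(cm.data(), K, Ns, calls.data(), s);
  }
  return List::create(_["precision"] = prec, _["fp_rate"] = fp);
}
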