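#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Row-sum tolerance used when comparing within-subgroup grooming sums
// against the irreversible-fission threshold.
static const double EPS = 1e-9;

// One daily assignment: every individual starts in the resting area (0) and
// is offered one draw per round, in a freshly randomised order, until the
// resting area is empty.  Probabilities are recomputed from the current
// occupancy before every single draw, so early movers exert mimetic pull on
// later ones within the same round.
//
// RNG discipline: the draw sequence is (round keys in ascending individual
// order, then one uniform per individual in key order), which is mirrored
// exactly by the plain-R engine so that both produce identical trajectories
// from the same seed.
static void assign_day_cpp(const NumericMatrix& w, double C, double l1,
                           double l2, IntegerVector& occ, int max_rounds) {
  const int n = w.nrow();
  std::vector<int> rest;
  rest.reserve(n);
  for (int i = 0; i < n; ++i) {
    occ[i] = 0;
    rest.push_back(i);
  }
  int round = 0;
  std::vector<double> keys(n);
  std::vector<int> idx(n);
  while (!rest.empty()) {
    if (++round > max_rounds)
      stop("movement round limit (%d) exceeded: with lambda1 + lambda2 = 0 "
           "and empty resource areas no individual can ever leave the "
           "resting area", max_rounds);
    const int m = (int)rest.size();
    for (int j = 0; j < m; ++j) keys[j] = unif_rand();
    for (int j = 0; j < m; ++j) idx[j] = j;
    std::stable_sort(idx.begin(), idx.begin() + m,
                     [&](int a, int b) { return keys[a] < keys[b]; });
    for (int j = 0; j < m; ++j) {
      const int i = rest[idx[j]];
      double s1 = 0.0, s2 = 0.0;
      for (int k = 0; k < n; ++k) {
        if (occ[k] == 1) s1 += w(i, k);
        else if (occ[k] == 2) s2 += w(i, k);
      }
      const double p1 = l1 + C * s1;
      const double p2 = l2 + C * s2;
      const double x = unif_rand();
      if (p1 >= x) occ[i] = 1;
      else if (p1 + p2 >= x) occ[i] = 2;
    }
    std::vector<int> next;
    next.reserve(m);
    for (int i = 0; i < n; ++i)
      if (occ[i] == 0) next.push_back(i);
    rest.swap(next);
  }
}

// Link-transfer rewiring after a temporary fission.  Each row is updated
// independently: individual i's cross-area links shrink by T% and the total
// removed is shared equally among i's N same-area companions; an individual
// alone in its area keeps its outgoing links frozen.
static void transfer_update_cpp(NumericMatrix& w, const IntegerVector& occ,
                                double Tpct) {
  const int n = w.nrow();
  const double f = Tpct / 100.0;
  for (int i = 0; i < n; ++i) {
    const int a = occ[i];
    int N = 0;
    for (int k = 0; k < n; ++k)
      if (k != i && occ[k] == a) ++N;
    if (N == 0) continue;
    double loss = 0.0;
    for (int k = 0; k < n; ++k) {
      if (k == i || occ[k] == a) continue;
      loss += w(i, k) * f;
      w(i, k) *= (1.0 - f);
    }
    if (loss == 0.0) continue;
    const double share = loss / N;
    for (int k = 0; k < n; ++k)
      if (k != i && occ[k] == a) w(i, k) += share;
  }
}

// Irreversible-fission test: both subgroups at least min_subgroup strong and
// every individual's within-subgroup outgoing grooming sum at or above the
// threshold (in % of social time).
static bool check_irreversible_cpp(const NumericMatrix& w,
                                   const IntegerVector& occ, double threshold,
                                   int min_subgroup) {
  const int n = w.nrow();
  int n1 = 0, n2 = 0;
  for (int i = 0; i < n; ++i) {
    if (occ[i] == 1) ++n1;
    else if (occ[i] == 2) ++n2;
  }
  if (n1 == 0 || n2 == 0) return false;
  if (n1 < min_subgroup || n2 < min_subgroup) return false;
  for (int i = 0; i < n; ++i) {
    double within = 0.0;
    for (int k = 0; k < n; ++k)
      if (k != i && occ[k] == occ[i]) within += w(i, k);
    if (within < threshold - EPS) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix w_init, double C, double lambda1, double lambda2,
              double transfer, int max_days, double threshold,
              int min_subgroup, bool stop_on_fission, bool record_trace,
              int max_rounds) {
  const int n = w_init.nrow();
  NumericMatrix w = clone(w_init);
  IntegerVector occ(n);

  int fission_day = NA_INTEGER;
  int days_run = 0;
  IntegerVector final_occ(n);

  NumericMatrix trace;
  if (record_trace) trace = NumericMatrix(max_days, 6);

  RNGScope scope;
  for (int day = 1; day <= max_days; ++day) {
    assign_day_cpp(w, C, lambda1, lambda2, occ, max_rounds);
    int n1 = 0, n2 = 0;
    for (int i = 0; i < n; ++i) (occ[i] == 1 ? n1 : n2)++;
    const bool temp_fission = (n1 > 0 && n2 > 0);
    if (temp_fission) transfer_update_cpp(w, occ, transfer);
    const bool fission =
        temp_fission && check_irreversible_cpp(w, occ, threshold, min_subgroup);

    if (record_trace) {
      double min_within = NA_REAL, max_dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double within = 0.0, total = 0.0;
        for (int k = 0; k < n; ++k) {
          if (k == i) continue;
          total += w(i, k);
          if (occ[k] == occ[i]) within += w(i, k);
        }
        if (i == 0 || within < min_within) min_within = within;
        const double dev = std::abs(total - 100.0);
        if (dev > max_dev) max_dev = dev;
      }
      trace(day - 1, 0) = day;
      trace(day - 1, 1) = n1;
      trace(day - 1, 2) = n2;
      trace(day - 1, 3) = temp_fission ? 1.0 : 0.0;
      trace(day - 1, 4) = min_within;
      trace(day - 1, 5) = max_dev;
    }

    days_run = day;
    if (fission && fission_day == NA_INTEGER) {
      fission_day = day;
      for (int i = 0; i < n; ++i) final_occ[i] = occ[i];
      if (stop_on_fission) break;
    }
  }
  if (fission_day == NA_INTEGER)
    for (int i = 0; i < n; ++i) final_occ[i] = occ[i];

  const bool censored = (fission_day == NA_INTEGER);
  List out = List::create(
      _["days"] = censored ? max_days : fission_day,
      _["censored"] = censored, _["network"] = w,
      _["assignment"] = final_occ, _["days_run"] = days_run);
  if (record_trace) {
    out["trace"] = trace(Range(0, days_run - 1), _);
  }
  return out;
}
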