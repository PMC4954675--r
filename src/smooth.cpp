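#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Minimum-duration smoothing on maximal runs: repeatedly absorb the
// shortest run below min_s (earliest on ties) into its longer-duration
// neighbor (earlier neighbor on ties), merging adjacent same-role runs,
// until every run is at least min_s or one run remains. Linked list +
// lazy-deletion min-heap; O(n log n).

namespace {
struct HeapItem {
  double dur;
  int pos;   // position key: original index of the run's first element
  int idx;   // slot in the arrays
  bool operator>(const HeapItem& o) const {
    if (dur != o.dur) return dur > o.dur;
    return pos > o.pos;
  }
};
}  // namespace

// [[Rcpp::export(name = ".smooth_runs_dp")]]
List smooth_runs_dp(NumericVector durations, IntegerVector roles,
                    double min_s) {
  const int n = durations.size();
  if (n == 0) stop("empty run sequence");
  std::vector<double> dur(durations.begin(), durations.end());
  std::vector<int> role(roles.begin(), roles.end());
  std::vector<int> prev(n), next(n), pos(n);
  std::vector<bool> alive(n, true);
  for (int i = 0; i < n; ++i) {
    prev[i] = i - 1;
    next[i] = (i + 1 < n) ? i + 1 : -1;
    pos[i] = i;
  }
  int n_alive = n;

  std::priority_queue<HeapItem, std::vector<HeapItem>,
                      std::greater<HeapItem>> heap;
  for (int i = 0; i < n; ++i) {
    if (dur[i] < min_s) heap.push({dur[i], pos[i], i});
  }

  // merge b into a (a keeps its links on one side; b must be next[a])
  auto merge_next = [&](int a) {
    int b = next[a];
    dur[a] += dur[b];
    alive[b] = false;
    next[a] = next[b];
    if (next[b] != -1) prev[next[b]] = a;
    --n_alive;
  };

  while (!heap.empty() && n_alive > 1) {
    HeapItem it = heap.top();
    heap.pop();
    int i = it.idx;
    if (!alive[i] || dur[i] != it.dur || pos[i] != it.pos) continue;  // stale
    if (dur[i] >= min_s) continue;
    int L = prev[i], R = next[i];
    int j;
    if (L == -1) j = R;
    else if (R == -1) j = L;
    else j = (dur[L] >= dur[R]) ? L : R;  // tie -> earlier neighbor
    role[i] = role[j];
    // merge with same-role neighbors (j, and possibly the other side)
    if (L != -1 && role[L] == role[i]) {
      int a = L;
      merge_next(a);
      i = a;
    }
    if (next[i] != -1 && role[next[i]] == role[i]) merge_next(i);
    pos[i] = std::min(pos[i], it.pos);
    if (dur[i] < min_s) heap.push({dur[i], pos[i], i});
  }

  std::vector<double> out_dur;
  std::vector<int> out_role;
  int head = 0;
  while (head < n && !alive[head]) ++head;
  // walk from the first alive run
  for (int i = head; i != -1; i = next[i]) {
    out_dur.push_back(dur[i]);
    out_role.push_back(role[i]);
  }
  return List::create(_["dur"] = wrap(out_dur), _["role"] = wrap(out_role));
}
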