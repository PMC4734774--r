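#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over clone sizes so that the clone hit by an
// event can be sampled proportional to its size in O(log n), and updated in
// O(log n). Positions are 1-based; clone i lives at position i + 1.
struct Fenwick {
  std::vector<double> t;
  int n;
  int logn; // largest power of two <= n

  explicit Fenwick(int cap) : t(cap + 1, 0.0), n(cap) {
    logn = 1;
    while ((logn << 1) <= n) logn <<= 1;
  }
  void add(int i, double v) { // i: 1-based position
    for (; i <= n; i += i & -i) t[i] += v;
  }
  // largest idx with prefix(idx) <= r; the sampled clone is 0-based idx
  int search(double r) const {
    int idx = 0;
    for (int bit = logn; bit; bit >>= 1) {
      int nxt = idx + bit;
      if (nxt <= n && t[nxt] <= r) { idx = nxt; r -= t[nxt]; }
    }
    return idx; // 0-based clone index
  }
  void grow(const std::vector<int>& sizes) {
    int cap = n * 2;
    t.assign(cap + 1, 0.0);
    n = cap;
    logn = 1;
    while ((logn << 1) <= n) logn <<= 1;
    for (size_t i = 0; i < sizes.size(); ++i)
      if (sizes[i] != 0) add((int)i + 1, sizes[i]);
  }
};

// Clone-level Gillespie simulation of the multi-type birth-death process
// with infinite-allele mutation. Cells within a clone are exchangeable, so
// the clone experiencing an event is drawn proportional to its size; this is
// an exact simulation of the cell-level process. Uses R's RNG stream.
// [[Rcpp::export(name = ".gillespie_run")]]
List gillespie_run(double b, double d, double u, int stop_size,
                   double max_events, bool track_time) {
  RNGScope scope;
  const double pb = b / (b + d);

  std::vector<int> parent;       // parent clone id (-1 for founder type 0)
  std::vector<int> origin_z;     // total cells present just before the clone arose
  std::vector<double> origin_t;  // time of the founding division
  std::vector<int> count;        // live cells in the clone

  parent.reserve(1024); origin_z.reserve(1024);
  origin_t.reserve(1024); count.reserve(1024);

  parent.push_back(-1); origin_z.push_back(0);
  origin_t.push_back(0.0); count.push_back(1);

  Fenwick fen(1024);
  fen.add(1, 1.0);

  long long N = 1;
  double t = 0.0;
  double events = 0.0;
  std::string outcome = "truncated";

  while (true) {
    if (N <= 0) { outcome = "extinct"; break; }
    if (N >= stop_size) { outcome = "complete"; break; }
    if (events >= max_events) { outcome = "truncated"; break; }
    events += 1.0;
    if (track_time) t += exp_rand() / ((double)N * (b + d));
    const bool birth = unif_rand() < pb;
    int c = fen.search(unif_rand() * (double)N);
    // an exact prefix-boundary hit can land on a dead (size-0) clone or just
    // past the last one; the interval [prefix, prefix + size) of the next
    // live clone owns that point
    const int ncl = (int)count.size();
    if (c >= ncl) c = ncl - 1;
    while (c < ncl && count[c] == 0) ++c;
    if (c >= ncl) { c = ncl - 1; while (count[c] == 0) --c; }
    if (birth) {
      if (u > 0.0 && unif_rand() < u) {
        // one daughter founds a new clone; z = total before adding her
        parent.push_back(c);
        origin_z.push_back((int)N);
        origin_t.push_back(t);
        count.push_back(1);
        if ((int)count.size() > fen.n) fen.grow(count);
        fen.add((int)count.size(), 1.0);
      } else {
        count[c] += 1;
        fen.add(c + 1, 1.0);
      }
      ++N;
    } else {
      count[c] -= 1;
      fen.add(c + 1, -1.0);
      --N;
    }
  }

  // subtree (carrier) counts: cells carrying each clone's defining mutation;
  // parents precede children, so one reverse sweep suffices
  const int nc = (int)count.size();
  std::vector<int> subtree(count);
  for (int i = nc - 1; i >= 1; --i) subtree[parent[i]] += subtree[i];

  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["origin_z"] = IntegerVector(origin_z.begin(), origin_z.end()),
    _["origin_time"] = NumericVector(origin_t.begin(), origin_t.end()),
    _["count"] = IntegerVector(count.begin(), count.end()),
    _["subtree_count"] = IntegerVector(subtree.begin(), subtree.end()),
    _["n_cells"] = (double)N,
    _["n_events"] = events,
    _["outcome"] = outcome);
}
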