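#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Bulk classification of encoded query windows against a flattened dictree.
//
// `taboo` holds the stored vectors sorted by address key; `ukeys`/`starts`
// are the CSR-style index (rows starts[a]..starts[a+1]-1 share ukeys[a],
// key = i * sigma_n + j). Sub-lists are visited in ascending prefix-distance
// order so exact matches short-circuit fastest; any order would be correct.
//
// Returns TRUE where some stored vector lies within k (the k-intersection).
// With self_exclude, one exact occurrence of the query vector itself is
// discounted: a window is intersecting iff a distinct vector lies within k
// or its exact multiplicity is >= 2. All copies of an exact match share one
// sub-list, so counting exact hits during the scan suffices.
// [[Rcpp::export]]
LogicalVector dictree_scan_cpp(IntegerMatrix query, IntegerMatrix taboo,
                               NumericVector ukeys, IntegerVector starts,
                               IntegerMatrix M, int sigma_n, int k,
                               bool self_exclude) {
  const int nq = query.nrow();
  const int L = query.ncol();
  const int nkeys = ukeys.size();
  LogicalVector intersecting(nq);

  for (int r = 0; r < nq; ++r) {
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
    const int x1 = query(r, 0), x2 = query(r, 1);

    // distance shells of the first two blocks, up to k
    std::vector<std::vector<int> > s1(k + 1), s2(k + 1);
    for (int c = 0; c < sigma_n; ++c) {
      const int d1 = M(x1, c);
      if (d1 <= k) s1[d1].push_back(c);
      const int d2 = M(x2, c);
      if (d2 <= k) s2[d2].push_back(c);
    }

    int n_exact = 0;
    bool hit = false;
    for (int dtot = 0; dtot <= k && !hit; ++dtot) {
      for (int d1 = 0; d1 <= dtot && !hit; ++d1) {
        const int d2 = dtot - d1;
        for (size_t a = 0; a < s1[d1].size() && !hit; ++a) {
          const double base = (double)s1[d1][a] * sigma_n;
          for (size_t b = 0; b < s2[d2].size() && !hit; ++b) {
            const double key = base + s2[d2][b];
            // binary search in ukeys
            int lo = 0, hi = nkeys - 1, at = -1;
            while (lo <= hi) {
              const int mid = (lo + hi) / 2;
              if (ukeys[mid] < key) lo = mid + 1;
              else if (ukeys[mid] > key) hi = mid - 1;
              else { at = mid; break; }
            }
            if (at < 0) continue;
            for (int t = starts[at]; t < starts[at + 1]; ++t) {
              int dd = dtot;
              for (int l = 2; l < L; ++l) {
                dd += M(query(r, l), taboo(t, l));
                if (dd > k) break;
              }
              if (dd > k) continue;
              if (dd == 0) {
                ++n_exact;
                if (!self_exclude || n_exact >= 2) { hit = true; break; }
              } else {
                hit = true;
                break;
              }
            }
          }
        }
      }
    }
    intersecting[r] = hit;
  }
  return intersecting;
}

// Naive letter-by-letter reference: for each query window, slide over every
// taboo sequence (callers pass both strands) and compare positionwise,
// stopping past k. No encoding, no index, no pruning — the independent
// ground truth the engine is verified against.
// [[Rcpp::export]]
LogicalVector brute_window_scan_cpp(CharacterVector query_windows,
                                    CharacterVector taboo_seqs,
                                    int W, int k) {
  const int nq = query_windows.size();
  std::vector<std::string> taboo;
  for (int s = 0; s < taboo_seqs.size(); ++s)
    taboo.push_back(as<std::string>(taboo_seqs[s]));

  LogicalVector intersecting(nq);
  for (int r = 0; r < nq; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    const std::string q = as<std::string>(query_windows[r]);
    bool hit = false;
    for (size_t s = 0; s < taboo.size() && !hit; ++s) {
      const std::string& t = taboo[s];
      if ((int)t.size() < W) continue;
      const int last = (int)t.size() - W;
      for (int p = 0; p <= last; ++p) {
        int mm = 0;
        const char* tp = t.data() + p;
        for (int l = 0; l < W; ++l) {
          if (q[l] != tp[l] && ++mm > k) break;
        }
        if (mm <= k) { hit = true; break; }
      }
    }
    intersecting[r] = hit;
  }
  return intersecting;
}
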