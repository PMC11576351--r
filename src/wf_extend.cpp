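#include <Rcpp.h>
using namespace Rcpp;

// Longest-common-prefix extension of a wavefront: each reachable offset h on
// diagonal k (query position v = h - k) advances while the remaining suffixes
// agree. Offsets never decrease; sentinel slots pass through untouched.
// [[Rcpp::export]]
IntegerVector wf_extend_cpp(RawVector q, RawVector r, int lo,
                            IntegerVector offsets, int sentinel) {
  const int n = q.size(), m = r.size();
  const int len = offsets.size();
  IntegerVector out(len);
  for (int i = 0; i < len; ++i) {
    int h = offsets[i];
    if (h == sentinel) { out[i] = sentinel; continue; }
    const int k = lo + i;
    int v = h - k;
    while (h < m && v < n && q[v] == r[h]) { ++h; ++v; }
    out[i] = h;
  }
  return out;
}
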