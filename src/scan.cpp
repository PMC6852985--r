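#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Exhaustive ungapped local scan of tags against reference sequences.
//
// For each tag (length w) and reference (length L), every diagonal offset
// d in [-(w-1), L-1] is evaluated: the tag may overhang either end of the
// reference, and the alignment at an offset is the full overlap region
// (maximal ungapped local alignment on that diagonal). An alignment
// qualifies when its aligned length satisfies aligned/w >= min_coverage and
// its substitution count is <= max_mismatch.
//
// Returns one row per qualifying (tag, reference, offset) triple with the
// 0-based offset of tag position 1 in reference coordinates (negative for a
// 5' overhang), the aligned length, and the mismatch count.
// [[Rcpp::export]]
DataFrame local_scan_cpp(CharacterVector tags, CharacterVector refs,
                         int max_mismatch, double min_coverage) {
  std::vector<int> out_tag, out_ref, out_off, out_alen, out_mm;
  for (int r = 0; r < refs.size(); ++r) {
    const char *ref = CHAR(STRING_ELT(refs, r));
    int L = (int) std::strlen(ref);
    for (int t = 0; t < tags.size(); ++t) {
      const char *tag = CHAR(STRING_ELT(tags, t));
      int w = (int) std::strlen(tag);
      if (w == 0) continue;
      // minimum aligned length implied by the coverage threshold
      int min_alen = (int) std::ceil(min_coverage * w - 1e-9);
      if (min_alen < 1) min_alen = 1;
      for (int d = -(w - 1); d <= L - 1; ++d) {
        int i0 = d < 0 ? -d : 0;          // first tag position in overlap
        int i1 = (w < L - d) ? w : L - d; // one past last tag position
        int alen = i1 - i0;
        if (alen < min_alen) continue;
        int mm = 0;
        for (int i = i0; i < i1; ++i) {
          if (tag[i] != ref[d + i]) {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm <= max_mismatch) {
          out_tag.push_back(t + 1);
          out_ref.push_back(r + 1);
          out_off.push_back(d);
          out_alen.push_back(alen);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(
    _["tag"] = out_tag, _["ref"] = out_ref, _["offset"] = out_off,
    _["aligned_length"] = out_alen, _["mismatches"] = out_mm);
}
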