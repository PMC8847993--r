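#include <Rcpp.h>
using namespace Rcpp;

// For each read window, scan all barcodes for the minimal Hamming distance
// within max_mismatch. Returns a 3-column matrix: best barcode index
// (1-based, NA_INTEGER if none within threshold), best distance, and the
// number of barcodes tied at that distance (>1 means ambiguous).
// Early exit once a running distance exceeds min(max_mismatch, current best).
// [[Rcpp::export]]
IntegerMatrix hamming_scan(CharacterVector reads, CharacterVector barcodes,
                           int max_mismatch) {
  const int nr = reads.size(), nb = barcodes.size();
  std::vector<std::string> bc(nb);
  for (int j = 0; j < nb; ++j) bc[j] = as<std::string>(barcodes[j]);
  const int L = nb > 0 ? (int)bc[0].size() : 0;

  IntegerMatrix out(nr, 3);
  for (int i = 0; i < nr; ++i) {
    const std::string r = as<std::string>(reads[i]);
    int best = max_mismatch + 1, best_j = -1, nbest = 0;
    if ((int)r.size() == L) {
      for (int j = 0; j < nb; ++j) {
        const char* b = bc[j].data();
        const char* rd = r.data();
        int d = 0;
        const int limit = best; // ties at current best still matter
        for (int k = 0; k < L; ++k) {
          d += (b[k] != rd[k]);
          if (d > limit) break;
        }
        if (d < best) { best = d; best_j = j; nbest = 1; }
        else if (d == best && d <= max_mismatch) ++nbest;
      }
    }
    if (best_j >= 0 && best <= max_mismatch) {
      out(i, 0) = best_j + 1;
      out(i, 1) = best;
      out(i, 2) = nbest;
    } else {
      out(i, 0) = NA_INTEGER;
      out(i, 1) = NA_INTEGER;
      out(i, 2) = 0;
    }
  }
  return out;
}
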