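#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan of each read against every reference at every
// offset (read fully contained in the reference). For one read, all
// references reaching the read's global minimum mismatch count are
// reported, provided that minimum is <= max_mismatch; per reference the
// smallest qualifying offset is kept. 'N' in a read never matches.
// Early bail-out once a placement exceeds the current best keeps the scan
// cheap on random sequence.
// [[Rcpp::export]]
DataFrame hamming_scan(CharacterVector reads, CharacterVector refs,
                       int max_mismatch) {
  const int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> R(n_refs);
  for (int j = 0; j < n_refs; ++j) R[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_start, out_nm;
  std::vector<int> ref_best(n_refs), ref_off(n_refs);

  for (int i = 0; i < n_reads; ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int lq = (int)q.size();
    int best = max_mismatch + 1;
    for (int j = 0; j < n_refs; ++j) {
      ref_best[j] = max_mismatch + 1;
      ref_off[j] = -1;
      const std::string &s = R[j];
      const int lmax = (int)s.size() - lq;
      for (int off = 0; off <= lmax; ++off) {
        int nm = 0;
        for (int k = 0; k < lq; ++k) {
          if (q[k] != s[off + k]) {
            if (++nm > best) break;
          }
        }
        if (nm < ref_best[j]) {
          ref_best[j] = nm;
          ref_off[j] = off;
          if (nm < best) best = nm;
          if (nm == 0) break;
        }
      }
    }
    if (best <= max_mismatch) {
      for (int j = 0; j < n_refs; ++j) {
        if (ref_best[j] == best) {
          out_read.push_back(i + 1);
          out_ref.push_back(j + 1);
          out_start.push_back(ref_off[j] + 1);
          out_nm.push_back(best);
        }
      }
    }
  }
  return DataFrame::create(_["read_index"] = out_read,
                           _["ref_index"] = out_ref,
                           _["start"] = out_start,
                           _["n_mismatch"] = out_nm);
}

// Weighted base-count pileup. One entry per alignment hit; 'reads' is the
// hit's read sequence, placed at 1-based 'start' on reference 'ref_index'.
// Returns, per reference, a length x 6 matrix: A, C, G, T counts plus
// 5'-end and 3'-end counters, each incremented by the hit's weight.
// [[Rcpp::export]]
List pileup_counts(CharacterVector reads, IntegerVector ref_index,
                   IntegerVector start, NumericVector weight,
                   IntegerVector ref_len) {
  const int n_refs = ref_len.size(), n_hits = reads.size();
  List out(n_refs);
  std::vector<NumericMatrix> mats;
  mats.reserve(n_refs);
  for (int j = 0; j < n_refs; ++j) {
    NumericMatrix m(ref_len[j], 6);
    mats.push_back(m);
    out[j] = m;
  }
  for (int i = 0; i < n_hits; ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int j = ref_index[i] - 1, s0 = start[i] - 1;
    const double w = weight[i];
    if (j < 0 || j >= n_refs) stop("ref_index out of range");
    if (s0 < 0 || s0 + (int)q.size() > ref_len[j])
      stop("alignment extends outside reference (aligner bug?)");
    NumericMatrix &m = mats[j];
    for (int k = 0; k < (int)q.size(); ++k) {
      int col;
      switch (q[k]) {
        case 'A': col = 0; break;
        case 'C': col = 1; break;
        case 'G': col = 2; break;
        case 'T': col = 3; break;
        default: col = -1;  // N and friends: depth contribution skipped
      }
      if (col >= 0) m(s0 + k, col) += w;
    }
    m(s0, 4) += w;                      // 5' end
    m(s0 + (int)q.size() - 1, 5) += w;  // 3' end
  }
  return out;
}
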