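# Independent oracles and fixture builders used across the suite.

# String-suffix oracle: the shortest append that makes the sequence end in
# CCA (try suffixes in increasing length).
oracle_cca <- function(x) {
  for (suffix in c("", "A", "CA", "CCA")) {
    if (endsWith(paste0(x, suffix), "CCA")) return(paste0(x, suffix))
  }
  x
}

# Brute-force minimum-Hamming-distance scan: every reference, every offset,
# character-by-character comparison. Returns per read the minimum distance
# and the set of reference indices achieving it.
oracle_best_hits <- function(read, refs) {
  q <- strsplit(read, "")[[1L]]
  best <- Inf; who <- integer(0)
  for (j in seq_along(refs)) {
    s <- strsplit(refs[j], "")[[1L]]
    if (length(q) > length(s)) next
    ref_best <- Inf
    for (off in 0:(length(s) - length(q))) {
      d <- sum(q != s[(off + 1):(off + length(q))])
      ref_best <- min(ref_best, d)
    }
    if (ref_best < best) { best <- ref_best; who <- j }
    else if (ref_best == best) who <- c(who, j)
  }
  list(min = best, refs = who)
}

# One-sided exact conditional p of a 2x2 table by explicit enumeration of
# the hypergeometric support with choose() arithmetic (no phyper).
oracle_fisher_greater <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(m1, k)
  pr <- choose(m1, support) * choose(m2, k - support) / choose(N, k)
  sum(pr[support >= a])
}

# Central 99.7% binomial interval.
binom_band <- function(n, p) qbinom(c(0.0015, 0.9985), n, p)

# A rate track with explicit base counts, for driving call_sites without a
# simulation. counts: matrix with columns A, C, G, T; ref_seq gives the
# reference base per row.
track_from_counts <- function(group, ref_seq, counts,
                              three_prime_ends = NULL) {
  n <- nchar(ref_seq)
  stopifnot(nrow(counts) == n)
  refs <- data.frame(ref_id = group, amino_acid = "Ser", anticodon = "GCT",
                     sequence = ref_seq, isodecoder_group = group,
                     length = n, stringsAsFactors = FALSE)
  class(refs) <- c("trmc_refs", "data.frame")
  pile <- data.frame(group = group, pos = seq_len(n),
                     A = counts[, 1], C = counts[, 2], G = counts[, 3],
                     T = counts[, 4],
                     depth = rowSums(counts),
                     five_prime_ends = 0,
                     three_prime_ends = if (is.null(three_prime_ends)) 0
                                        else three_prime_ends)
  attr(pile, "groups") <- reference_groups(refs)
  class(pile) <- c("trmc_pileup", "data.frame")
  compute_rates(pile, refs)
}

# Binomial-draw rate track over an all-C reference: depth reads per
# position, mismatches Binomial(depth, p_mm), two thirds of mismatches
# split over A/G and the rest T unless t_dominant.
binom_track <- function(n_pos, depth, p_mm, t_dominant = TRUE) {
  mm <- rbinom(n_pos, depth, p_mm)
  t_share <- if (t_dominant) rbinom(n_pos, mm, 0.9) else rbinom(n_pos, mm, 1 / 3)
  rest <- mm - t_share
  a <- rbinom(n_pos, rest, 0.5)
  counts <- cbind(A = a, C = depth - mm, G = rest - a, T = t_share)
  track_from_counts("g1", strrep("C", n_pos), counts)
}

# Tiny FASTA writer for header-dialect fixtures (may contain U, so it is
# written as plain text rather than through a DNA container).
write_test_fasta <- function(headers, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# Minimal single-end SAM file over the given references.
write_test_sam <- function(refs, records, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$ref_id, nchar(refs$sequence)))
  writeLines(c(hdr, records), path)
  path
}
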