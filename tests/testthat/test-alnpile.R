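mini_refs <- function(seqs, ids = sprintf("ref%d", seq_along(seqs))) {
  refs <- data.frame(ref_id = ids, amino_acid = "Ser", anticodon = "GCT",
                     sequence = seqs, length = nchar(seqs),
                     stringsAsFactors = FALSE)
  refs <- refs[order(refs$ref_id), ]
  refs$isodecoder_group <- refs$ref_id[match(refs$sequence, refs$sequence)]
  class(refs) <- c("trmc_refs", "data.frame")
  refs
}

mutate_at <- function(s, pos, to) {
  substr(s, pos, pos) <- to
  s
}

test_that("exact substring reads give unique full-weight hits", {
  set.seed(14)
  s1 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  refs <- mini_refs(c(s1, s2))
  reads <- data.frame(read_id = "r1", sequence = substr(s1, 11, 40))
  hits <- align_reads(reads, refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$group, "ref1")
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 40L)
  expect_equal(hits$n_mismatch, 0L)
  expect_equal(hits$weight, 1)
})

test_that("the two-mismatch cap drops three-substitution reads", {
  set.seed(15)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  refs <- mini_refs(s)
  r2 <- mutate_at(mutate_at(s, 5, "N"), 20, "N")   # N counts as mismatch
  r3 <- mutate_at(r2, 40, "N")
  hits <- align_reads(data.frame(read_id = c("two", "three"),
                                 sequence = c(r2, r3)), refs)
  expect_equal(hits$read_id, "two")
  expect_equal(hits$n_mismatch, 2L)
  expect_equal(attr(hits, "unmapped"), "three")
})

test_that("identical references collapse to one group hit; true ties split weight", {
  set.seed(16)
  s <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE), collapse = "")
  # two identical isodecoders = one group; a third distinct reference
  s3 <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE), collapse = "")
  refs <- mini_refs(c(s, s, s3))
  hits <- align_reads(data.frame(read_id = "r", sequence = s), refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$weight, 1)
  # a read equidistant from two distinct groups gets weight 1/2 each:
  # references differ only at position 10; the read carries a third base
  # there, so it is one mismatch from both
  sA <- s
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, 10, 10))
  sB <- mutate_at(s, 10, alt[1])
  refs2 <- mini_refs(c(sA, sB))
  mid <- mutate_at(s, 10, alt[2])
  h2 <- align_reads(data.frame(read_id = "m", sequence = mid), refs2)
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$weight, c(0.5, 0.5))
  expect_equal(sum(h2$weight), 1)
})

test_that("reads dominated by N are skipped with a warning; empty refs error", {
  refs <- mini_refs(strrep("ACGT", 20))
  expect_warning(
    h <- align_reads(data.frame(read_id = "n", sequence = strrep("N", 30)),
                     refs),
    "N fraction")
  expect_equal(nrow(h), 0L)
  expect_error(align_reads(data.frame(read_id = "r", sequence = "ACGT"),
                           refs[0, ]), "empty reference")
})

test_that("aligner equals the brute-force minimum-Hamming oracle", {
  set.seed(17)
  for (rep in 1:3) {
    refs_seq <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(60:100, 1), replace = TRUE),
            collapse = ""), "")
    refs <- mini_refs(refs_seq)
    reads <- vapply(1:40, function(i) {
      src <- sample(refs_seq, 1)
      len <- sample(20:min(60, nchar(src)), 1)
      st <- sample(nchar(src) - len + 1, 1)
      r <- substr(src, st, st + len - 1)
      for (k in seq_len(sample(0:3, 1)))
        r <- mutate_at(r, sample(len, 1), sample(c("A", "C", "G", "T"), 1))
      r
    }, "")
    hits <- align_reads(data.frame(read_id = as.character(1:40),
                                   sequence = reads), refs)
    for (i in 1:40) {
      o <- oracle_best_hits(reads[i], refs$sequence)
      mine <- hits[hits$read_id == as.character(i), ]
      if (o$min > 2) {
        expect_equal(nrow(mine), 0L)
      } else {
        expect_setequal(mine$group, refs$ref_id[o$refs])
        expect_true(all(mine$n_mismatch == o$min))
      }
    }
  }
})

test_that("pileup counts, end counters and conservation", {
  set.seed(18)
  s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  s <- mutate_at(s, 12, "C")
  refs <- mini_refs(s)
  base <- substr(s, 1, 30)
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    sequence = c(rep(base, 8), rep(mutate_at(base, 12, "T"), 2)))
  hits <- align_reads(reads, refs)
  pile <- build_pileup(hits, reads, refs)
  expect_equal(pile$depth[pile$pos <= 30], rep(10, 30))
  expect_equal(pile$depth[pile$pos > 30], rep(0, 10))
  expect_equal(pile$C[pile$pos == 12], 8)
  expect_equal(pile$T[pile$pos == 12], 2)
  expect_equal(pile$five_prime_ends[pile$pos == 1], 10)
  expect_equal(pile$three_prime_ends[pile$pos == 30], 10)
  # conservation: sum of depth == sum over hits of length x weight
  expect_equal(sum(pile$depth), sum((hits$end - hits$start + 1) * hits$weight))
  # A+C+G+T == depth everywhere
  expect_equal(pile$A + pile$C + pile$G + pile$T, pile$depth)
})

test_that("half-weight group hits contribute half counts", {
  set.seed(19)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  sB <- mutate_at(s, 50, setdiff(c("A", "C", "G", "T"),
                                 substr(s, 50, 50))[1])
  refs <- mini_refs(c(s, sB))
  mid <- substr(mutate_at(s, 20, setdiff(c("A", "C", "G", "T"),
                                         substr(s, 20, 20))[1]), 1, 40)
  reads <- data.frame(read_id = "m", sequence = mid)
  hits <- align_reads(reads, refs)
  expect_equal(sort(hits$weight), c(0.5, 0.5))
  pile <- build_pileup(hits, reads, refs)
  expect_equal(pile$depth[pile$group == "ref1" & pile$pos == 1], 0.5)
  expect_equal(pile$depth[pile$group == "ref2" & pile$pos == 1], 0.5)
})

test_that("rate arithmetic, degenerate depth and dominant alternative", {
  counts <- matrix(0, nrow = 3, ncol = 4)
  counts[1, ] <- c(0, 80, 0, 20)   # ref C: 20% T
  counts[2, ] <- c(0, 0, 0, 0)     # no coverage
  counts[3, ] <- c(0, 50, 0, 0)    # pure reference
  tr <- track_from_counts("g", "CCC", counts)
  expect_equal(tr$misinc_rate[1], 0.20)
  expect_equal(tr$dominant_alt[1], "T")
  expect_equal(tr$ct_rate[1], 0.20)
  expect_true(is.na(tr$misinc_rate[2]))
  expect_equal(tr$misinc_rate[3], 0)
  expect_true(tr$low_coverage[2])
  expect_false(tr$low_coverage[3])
})

test_that("pipeline recovers embedded rates within the binomial band", {
  set.seed(20)
  body <- sample(c("A", "C", "G", "T"), 76, replace = TRUE)
  body[12] <- "C"; body[74:76] <- c("C", "C", "A")
  refs <- mini_refs(paste(body, collapse = ""))
  n_ok <- 0L
  n_seeds <- 50L
  for (sd in seq_len(n_seeds)) {
    sim <- simulate_library(sim_config(
      refs, data.frame(ref_id = "ref1", position = 12L, rate = 0.10),
      condition = "reduced", depth_per_ref = 500L, seed = 1000L + sd))
    hits <- align_reads(sim$reads, refs)
    tr <- compute_rates(build_pileup(hits, sim$reads, refs), refs)
    est_T <- tr$T[tr$pos == 12]
    band <- binom_band(500L, 0.10 + (1 - 0.10) * 0.002 / 3)
    if (est_T >= band[1] && est_T <= band[2]) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 48L)  # >= 99% of seeds up to sampling slack
})

test_that("SAM ingestion honors flags, NM and the mismatch cap", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  refs <- mini_refs(s)
  perfect <- substr(s, 1, 30)
  two_mm <- mutate_at(mutate_at(perfect, 3, "N"), 7, "N")
  two_mm <- chartr("N", "A", two_mm)  # make it ACGT with <=2 diffs
  rec <- c(
    sprintf("r1\t0\tref1\t1\t255\t30M\t*\t0\t0\t%s\t*\tNM:i:0", perfect),
    sprintf("r2\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", perfect),          # unmapped
    sprintf("r3\t0\tref1\t1\t255\t30M\t*\t0\t0\t%s\t*\tNM:i:5", perfect),
    sprintf("r4\t0\tref1\t1\t255\t30M\t*\t0\t0\t%s\t*", two_mm))    # no NM
  sam <- write_test_sam(refs, rec)
  hits <- ingest_sam(sam, refs)
  expect_setequal(hits$read_id, c("r1", "r4"))
  expect_equal(hits$n_mismatch[hits$read_id == "r1"], 0L)
  expect_lte(hits$n_mismatch[hits$read_id == "r4"], 2L)
  # pileup can be built straight from the SAM sequences
  pile <- build_pileup(hits, NULL, refs)
  expect_equal(pile$depth[pile$pos == 1], 2)
  # unknown target
  bad <- write_test_sam(refs, rec)
  txt <- sub("ref1", "refX", readLines(bad))
  writeLines(txt, bad)
  expect_error(ingest_sam(bad, refs), "refX")
})

test_that("3' adapter is trimmed before alignment", {
  set.seed(22)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  refs <- mini_refs(s)
  adapter <- "AGATCGGAAGAG"
  reads <- data.frame(read_id = c("full", "partial", "clean"),
                      sequence = c(paste0(substr(s, 1, 30), adapter),
                                   paste0(substr(s, 1, 30),
                                          substr(adapter, 1, 6)),
                                   substr(s, 1, 30)))
  hits <- align_reads(reads, refs, adapter = adapter)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$n_mismatch == 0L))
  expect_true(all(hits$end == 30L))
})
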