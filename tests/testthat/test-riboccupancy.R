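toy_ann <- function(cds, utr = 18L) {
  data.frame(transcript_id = names(cds), cds_start = utr + 1L,
             cds_end = utr + nchar(cds), gene_id = names(cds),
             stringsAsFactors = FALSE)
}

test_that("length/frame filter retains exactly 26-32 nt frame-0 footprints", {
  cds <- random_cds_set(1, 60, seed = 40L)
  ann <- toy_ann(cds)
  # exhaustive sweep: lengths 20..40 x frame shifts 0..2
  grid <- expand.grid(len = 20:40, shift = 0:2)
  pl <- data.frame(
    read_id = sprintf("r%03d", seq_len(nrow(grid))),
    transcript_id = names(cds),
    five_prime_pos = ann$cds_start + 30L + grid$shift - 12L,
    length = grid$len)
  asg <- assign_psites(pl, ann, offset = 12L)
  kept <- grid[match(asg$read_id, pl$read_id), ]
  expect_true(all(kept$len >= 26 & kept$len <= 32))
  expect_true(all(kept$shift == 0))
  expect_equal(nrow(asg), sum(grid$len %in% 26:32 & grid$shift == 0))
  expect_true(all(asg$frame == 0L))
})

test_that("P/A-site arithmetic under the fixed 12-nt offset", {
  cds <- random_cds_set(1, 60, seed = 41L)
  ann <- toy_ann(cds)
  pl <- data.frame(read_id = c("a", "b"), transcript_id = names(cds),
                   five_prime_pos = c(ann$cds_start, ann$cds_start + 1L),
                   length = 28L)
  asg <- assign_psites(pl, ann, offset = 12L)
  expect_equal(asg$read_id, "a")          # offset 1 -> frame 1 -> dropped
  expect_equal(asg$five_prime_cds_offset, 0L)
  expect_equal(asg$p_site_codon, 4L)
  expect_equal(asg$a_site_codon, 5L)
  # CDS not divisible by 3 is skipped with a warning
  bad_ann <- ann; bad_ann$cds_end <- bad_ann$cds_end - 1L
  expect_warning(asg2 <- assign_psites(pl, bad_ann), "divisible")
  expect_equal(nrow(asg2), 0L)
})

test_that("uniform density gives normalized occupancy exactly 1", {
  cds <- random_cds_set(2, 80, seed = 42L)
  ann <- toy_ann(cds)
  # one A-site event on every sense codon of both genes
  asg <- do.call(rbind, lapply(names(cds), function(g) {
    n_cod <- nchar(cds[[g]]) %/% 3L
    data.frame(read_id = NA, transcript_id = g, gene_id = g, length = 28L,
               five_prime_cds_offset = NA, frame = 0L,
               p_site_codon = seq_len(n_cod - 1L) - 2L,
               a_site_codon = seq_len(n_cod - 1L) - 1L)
  }))
  occ <- codon_occupancy(asg, cds)
  seen <- !is.na(occ$normalized)
  expect_gt(sum(seen), 50)
  expect_equal(occ$normalized[seen], rep(1, sum(seen)))
  expect_equal(occ$raw[seen], rep(1, sum(seen)))
})

test_that("arithmetic of the basal window: 10 over (5,5,5) gives 2", {
  # one gene where a single codon occurrence carries count 10 and its
  # three downstream codons carry 5 each; the focus codon occurs once
  cds <- c(g = paste0("ATG", strrep("GGA", 8), "TGC",
                      strrep("GGA", 8), "TAA"))
  n_cod <- nchar(cds) %/% 3L
  tgc_idx <- 9L  # 0-based index of the TGC codon
  counts <- data.frame(codon_idx = c(tgc_idx, tgc_idx + 1:3),
                       n = c(10L, 5L, 5L, 5L))
  asg <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    data.frame(read_id = NA, transcript_id = "g", gene_id = "g",
               length = 28L, five_prime_cds_offset = NA, frame = 0L,
               p_site_codon = counts$codon_idx[i] - 1L,
               a_site_codon = rep(counts$codon_idx[i], counts$n[i]))))
  occ <- codon_occupancy(asg, cds)
  expect_equal(occ$normalized[occ$codon == "TGC"], 2.0)
})

test_that("a 3x pause on one codon tops the normalized occupancy ranking", {
  cds <- random_cds_set(10, 150, seed = 43L)
  rpf <- simulate_rpf(cds, pause_codons = "TTA", pause_factor = 3,
                      n_reads = 60000L, seed = 43L)
  asg <- assign_psites(rpf$placements, rpf$annotation, offset = 12L)
  # the simulator places 5' ends 12 nt upstream of the P-site codon, and
  # its A-site convention matches assign_psites' P+1
  occ <- codon_occupancy(asg, cds, site = "P")
  top <- occ$codon[which.max(occ$normalized)]
  expect_equal(top, "TTA")
  ratio <- occ$normalized[occ$codon == "TTA"] /
    median(occ$normalized[occ$codon != "TTA"], na.rm = TRUE)
  expect_gt(ratio, 2.25)
  expect_lt(ratio, 3.75)
})

test_that("occupancy differences rank pause-shifted codons first", {
  cds <- random_cds_set(10, 150, seed = 44L)
  focus <- ac4c_decoder_codons()
  mk <- function(pf, seed) {
    rpf <- simulate_rpf(cds, pause_codons = focus, pause_factor = pf,
                        n_reads = 60000L, seed = seed)
    codon_occupancy(assign_psites(rpf$placements, rpf$annotation),
                    cds, site = "P")
  }
  ctl <- mk(1, 45L)
  kd <- mk(2.5, 46L)
  d <- occupancy_diff(kd, ctl, focus)
  expect_true(all(d$codon[1:10] %in% focus))
  expect_lt(attr(d, "p_value"), 1e-6)
  # identical tables -> all-zero differences
  d0 <- occupancy_diff(ctl, ctl, focus)
  expect_true(all(abs(d0$diff) < 1e-12, na.rm = TRUE))
  expect_error(occupancy_diff(kd, ctl, character(0)), "nonempty")
})

test_that("TE arithmetic, scale invariance and classification", {
  input <- c(g1 = 50, g2 = 450, g3 = 500)
  ribo <- c(g1 = 100, g2 = 400, g3 = 500)
  te <- compute_te(input, ribo)
  expect_equal(te$ratio[te$gene_id == "g1"], 2.0)
  # per-library constant scaling leaves ratios identical
  te_s <- compute_te(input * 3, ribo)
  expect_equal(te_s$ratio, te$ratio)
  # zero input -> NA
  te0 <- compute_te(c(g1 = 0, g2 = 10), c(g1 = 5, g2 = 5))
  expect_true(is.na(te0$ratio[1]))
  expect_error(compute_te(c(a = 1), c(b = 1)), "gene set")
})

test_that("simulated TE effects are classified up", {
  te_eff <- c(rep(1, 99), 2)
  cts <- simulate_counts(100, te_effects = te_eff, seed = 47L)
  te <- compute_te(setNames(cts$input, cts$gene_id),
                   setNames(cts$rpf, cts$gene_id),
                   min_abs_log2 = 0.5)
  expect_equal(te$class[100], "up")
  expect_equal(sum(te$class == "up"), 1L)
})

test_that("Kruskal-Wallis statistic matches the reference implementation", {
  set.seed(48)
  for (i in 1:30) {
    g <- sample(2:4, 1)
    x <- round(rnorm(sample(10:30, 1)), sample(0:2, 1))  # induce ties
    grp <- sample(letters[1:g], length(x), replace = TRUE)
    if (length(unique(grp)) < 2) next
    ours <- trmcseq:::kw_test(x, grp)
    ref <- kruskal.test(x, factor(grp))
    if (is.na(ours$p_value)) { expect_true(is.nan(ref$p.value) ||
                                             is.na(ref$p.value)); next }
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-8)
  }
})

test_that("codon frequencies separate a depleted 'up' class", {
  focus <- ac4c_decoder_codons()
  other <- setdiff(sense_codons(), focus)
  set.seed(49)
  mk_gene <- function(p_focus, n = 200) {
    k <- rbinom(1, n, p_focus)   # composition varies gene to gene
    pool <- c(sample(focus, k, replace = TRUE),
              sample(other, n - k, replace = TRUE))
    paste0("ATG", paste(sample(pool), collapse = ""), "TAA")
  }
  cds <- c(vapply(1:15, function(i) mk_gene(0.05), ""),   # up: depleted
           vapply(1:15, function(i) mk_gene(0.20), ""),   # down
           vapply(1:15, function(i) mk_gene(0.20), ""))   # non
  names(cds) <- sprintf("g%02d", 1:45)
  te <- structure(
    data.frame(gene_id = names(cds),
               class = rep(c("up", "down", "non"), each = 15)),
    class = c("trmc_te", "data.frame"))
  res <- codon_freq_by_class(te, cds, focus)
  expect_lt(res$medians[["up"]], res$medians[["down"]])
  expect_lt(res$p_value, 1e-4)
  # null: all classes from one composition
  cds0 <- c(vapply(1:30, function(i) mk_gene(0.2), ""))
  names(cds0) <- sprintf("n%02d", 1:30)
  te0 <- structure(
    data.frame(gene_id = names(cds0),
               class = rep(c("up", "down", "non"), each = 10)),
    class = c("trmc_te", "data.frame"))
  res0 <- codon_freq_by_class(te0, cds0, focus)
  expect_gt(res0$p_value, 0.01)
  # degenerate: focus codons absent everywhere -> NA
  resNA <- codon_freq_by_class(te0, cds0, "ZZZ")
  expect_true(is.na(resNA$p_value))
  # class with < 2 genes errors
  te_bad <- te0; te_bad$class[1:10] <- "non"; te_bad$class[11] <- "up"
  expect_error(codon_freq_by_class(te_bad, cds0, focus), ">= 2")
})
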