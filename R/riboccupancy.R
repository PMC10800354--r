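STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Sense codons (61) in alphabetical order
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

#' Assign ribosome P/A-sites to footprint placements
#'
#' Retains footprints of length 26-32 nt whose 5' end, shifted by the
#' P-site offset, lands in frame 0 of the CDS; everything else is dropped.
#' The A-site is the codon after the P-site. A single fixed offset
#' (default 12 nt) is used for all lengths; per-length offsets can be
#' supplied as a named vector.
#'
#' @param placements data.frame with \code{read_id}, \code{transcript_id},
#'   \code{five_prime_pos} (1-based on the transcript), \code{length}.
#' @param cds_annotations data.frame with \code{transcript_id},
#'   \code{cds_start}, \code{cds_end}, \code{gene_id}. Transcripts whose
#'   CDS length is not divisible by 3 are skipped with a warning.
#' @param offset P-site offset in nt from the 5' end (single value or
#'   vector named by read length), default 12.
#' @param length_range Retained lengths, default 26:32.
#' @return data.frame of class \code{trmc_psites}: retained reads with
#'   \code{five_prime_cds_offset} (0-based), \code{frame} (always 0),
#'   \code{p_site_codon} and \code{a_site_codon} (0-based codon indices).
#' @export
assign_psites <- function(placements, cds_annotations, offset = 12L,
                          length_range = 26:32) {
  ann <- cds_annotations
  badlen <- (ann$cds_end - ann$cds_start + 1L) %% 3L != 0L
  if (any(badlen)) {
    warning("CDS length not divisible by 3; skipping: ",
            paste(ann$transcript_id[badlen], collapse = ", "))
    ann <- ann[!badlen, , drop = FALSE]
  }
  m <- match(placements$transcript_id, ann$transcript_id)
  keep <- !is.na(m) & placements$length %in% length_range
  x <- placements[keep, , drop = FALSE]
  m <- m[keep]
  off <- if (length(offset) > 1L) {
    o <- offset[as.character(x$length)]
    if (anyNA(o)) stop("offset vector must cover every retained length")
    as.integer(o)
  } else rep.int(as.integer(offset), nrow(x))
  cds_off <- x$five_prime_pos - ann$cds_start[m]   # 0-based nt in CDS
  shifted <- cds_off + off
  n_cod <- (ann$cds_end[m] - ann$cds_start[m] + 1L) %/% 3L
  frame <- shifted %% 3L
  p_cod <- shifted %/% 3L
  ok <- frame == 0L & shifted >= 0L & p_cod + 1L <= n_cod - 1L
  out <- data.frame(read_id = x$read_id[ok],
                    transcript_id = x$transcript_id[ok],
                    gene_id = ann$gene_id[m][ok],
                    length = x$length[ok],
                    five_prime_cds_offset = cds_off[ok],
                    frame = frame[ok],
                    p_site_codon = p_cod[ok],
                    a_site_codon = p_cod[ok] + 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("trmc_psites", "data.frame")
  out
}

#' Basal-normalized codon occupancy
#'
#' Raw occupancy of a codon is the mean ribosome count (A-site events by
#' default) over that codon's occurrences in the CDS set; basal occupancy
#' is the mean count at the +1, +2 and +3 codons downstream of the same
#' occurrences; the reported occupancy is their ratio. Occurrences within
#' 3 codons of the stop are excluded (the downstream window must exist),
#' as are the first and last \code{exclude_edge} codons of each CDS.
#'
#' @param assignments A \code{trmc_psites} table.
#' @param cds_sequences Named character vector (or DNAStringSet) of CDS
#'   sequences including the stop codon.
#' @param site Count \code{"A"}-site (default, the pause readout) or
#'   \code{"P"}-site events.
#' @param exclude_edge Codons trimmed from each CDS end, default 5.
#' @return data.frame of class \code{trmc_occupancy}: \code{codon},
#'   \code{amino_acid}, \code{n_occurrences}, \code{raw}, \code{basal},
#'   \code{normalized} over the 61 sense codons (NA where unobserved).
#' @export
codon_occupancy <- function(assignments, cds_sequences, site = c("A", "P"),
                            exclude_edge = 5L) {
  site <- match.arg(site)
  if (inherits(cds_sequences, "DNAStringSet"))
    cds_sequences <- setNames(as.character(cds_sequences),
                              names(cds_sequences))
  cds_sequences <- toupper(chartr("U", "T", cds_sequences))
  genes <- intersect(unique(assignments$gene_id), names(cds_sequences))
  idx_col <- if (site == "A") "a_site_codon" else "p_site_codon"
  occ <- lapply(genes, function(g) {
    s <- cds_sequences[[g]]
    n_cod <- nchar(s) %/% 3L
    n_sense <- n_cod - 1L                       # final codon = stop
    counts <- tabulate(
      assignments[[idx_col]][assignments$gene_id == g] + 1L, n_cod)
    i <- seq_len(n_sense) - 1L                  # 0-based codon index
    valid <- i >= exclude_edge & i <= n_sense - 1L - exclude_edge &
      (i + 3L) <= n_sense - 1L
    i <- i[valid]
    if (!length(i)) return(NULL)
    data.frame(codon = substring(s, 3L * i + 1L, 3L * i + 3L),
               count = counts[i + 1L],
               down = (counts[i + 2L] + counts[i + 3L] + counts[i + 4L]) / 3,
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, occ)
  out <- data.frame(codon = sense_codons(), stringsAsFactors = FALSE)
  out$amino_acid <- unname(Biostrings::GENETIC_CODE[out$codon])
  agg_n <- table(factor(occ$codon, levels = out$codon))
  out$n_occurrences <- as.integer(agg_n)
  f <- factor(occ$codon, levels = out$codon)
  out$raw <- as.numeric(tapply(occ$count, f, mean))
  out$basal <- as.numeric(tapply(occ$down, f, mean))
  out$normalized <- ifelse(!is.na(out$basal) & out$basal > 0,
                           out$raw / out$basal, NA_real_)
  class(out) <- c("trmc_occupancy", "data.frame")
  out
}

#' Per-codon occupancy difference between conditions
#'
#' Computes knockdown-minus-control normalized occupancy per codon and
#' tests whether the ac4C-decoded codons shift relative to the remaining
#' codons with a two-sided Wilcoxon rank-sum test on the differences.
#'
#' @param table_kd,table_control \code{trmc_occupancy} tables over the
#'   same codons.
#' @param ac4c_codons Nonempty character vector of focus codons.
#' @return data.frame of class \code{trmc_occdiff} with \code{codon},
#'   \code{diff}, \code{is_ac4c}; Wilcoxon p in \code{attr(, "p_value")}.
#' @export
occupancy_diff <- function(table_kd, table_control, ac4c_codons) {
  if (length(ac4c_codons) == 0L) stop("ac4c_codons must be nonempty")
  common <- intersect(table_kd$codon, table_control$codon)
  if (length(common) == 0L) stop("codon sets are disjoint")
  d <- data.frame(
    codon = common,
    diff = table_kd$normalized[match(common, table_kd$codon)] -
      table_control$normalized[match(common, table_control$codon)],
    stringsAsFactors = FALSE)
  d$is_ac4c <- d$codon %in% ac4c_codons
  ok <- !is.na(d$diff)
  p <- if (any(d$is_ac4c & ok) && any(!d$is_ac4c & ok))
    wilcox.test(d$diff[d$is_ac4c & ok], d$diff[!d$is_ac4c & ok],
                exact = FALSE)$p.value else NA_real_
  d <- d[order(-d$diff), ]
  rownames(d) <- NULL
  attr(d, "p_value") <- p
  class(d) <- c("trmc_occdiff", "data.frame")
  d
}

#' Translation efficiency / translation ratio per gene
#'
#' CPM-normalizes both channels, then TE (or TR) is the ribosome-channel
#' CPM over the input CPM per gene (NA at zero input). Genes are classed
#' up/down when the absolute log2 ratio and a two-proportion test against
#' the library totals pass the configured thresholds.
#'
#' @param input_counts Named numeric vector of input RNA-seq counts.
#' @param ribo_counts Named numeric vector of RPF (TE) or RNC (TR) counts
#'   over the same genes.
#' @param mode \code{"TE"} or \code{"TR"} (label only).
#' @param min_abs_log2,max_p Class thresholds, defaults 1 and 0.05.
#' @return data.frame of class \code{trmc_te}: \code{gene_id},
#'   \code{input}, \code{ribo}, \code{ratio}, \code{log2_ratio},
#'   \code{p_value}, \code{class} in \{up, down, non\}.
#' @export
compute_te <- function(input_counts, ribo_counts, mode = c("TE", "TR"),
                       min_abs_log2 = 1, max_p = 0.05) {
  mode <- match.arg(mode)
  genes <- names(input_counts)
  if (is.null(genes) || !identical(sort(genes), sort(names(ribo_counts))))
    stop("input and ribosome channels must share one gene set")
  ribo_counts <- ribo_counts[genes]
  t_in <- sum(input_counts); t_ri <- sum(ribo_counts)
  cpm_in <- input_counts / t_in * 1e6
  cpm_ri <- ribo_counts / t_ri * 1e6
  ratio <- ifelse(cpm_in > 0, cpm_ri / cpm_in, NA_real_)
  p <- vapply(seq_along(genes), function(i) {
    if (input_counts[i] + ribo_counts[i] == 0) return(NA_real_)
    suppressWarnings(prop.test(
      c(ribo_counts[i], input_counts[i]),
      c(t_ri, t_in))$p.value)
  }, numeric(1))
  l2 <- log2(ratio)
  cls <- rep("non", length(genes))
  sig <- !is.na(l2) & !is.na(p) & p <= max_p & abs(l2) >= min_abs_log2
  cls[sig & l2 > 0] <- "up"
  cls[sig & l2 < 0] <- "down"
  out <- data.frame(gene_id = genes, input = as.numeric(input_counts),
                    ribo = as.numeric(ribo_counts), ratio = ratio,
                    log2_ratio = l2, p_value = p, class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("trmc_te", "data.frame")
  out
}

# Kruskal-Wallis rank-sum statistic with tie correction, written out from
# the rank definition so it can be cross-checked against stats::kruskal.test.
kw_test <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  n <- length(x); k <- nlevels(g)
  if (n < 2L || k < 2L) return(list(statistic = NA_real_, df = NA_integer_,
                                    p_value = NA_real_))
  r <- rank(x)
  ni <- tabulate(g)
  ri <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(ri^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(list(statistic = NA_real_, df = k - 1L,
                             p_value = NA_real_))
  H <- H / corr
  list(statistic = H, df = k - 1L,
       p_value = pchisq(H, k - 1L, lower.tail = FALSE))
}

#' Codon frequency distributions across TE classes
#'
#' Per gene, the frequency of the focus codons among all sense codons of
#' its CDS (stop excluded); distributions are grouped by the gene's TE
#' class (up/down/non) and compared with a Kruskal-Wallis rank test.
#'
#' @param te_table A \code{trmc_te} table with assigned classes.
#' @param cds_sequences Named character vector (or DNAStringSet) of CDS
#'   sequences for every gene in \code{te_table}.
#' @param focus_codons Codon set of interest (e.g.
#'   [ac4c_decoder_codons()]).
#' @return list: \code{per_gene} (gene_id, class, frequency),
#'   \code{medians} per class, \code{statistic}, \code{df},
#'   \code{p_value} (NA when the frequencies are degenerate).
#' @export
codon_freq_by_class <- function(te_table, cds_sequences, focus_codons) {
  if (inherits(cds_sequences, "DNAStringSet"))
    cds_sequences <- setNames(as.character(cds_sequences),
                              names(cds_sequences))
  cds_sequences <- toupper(chartr("U", "T", cds_sequences))
  genes <- te_table$gene_id
  if (!all(genes %in% names(cds_sequences)))
    stop("every gene needs a CDS sequence")
  tab <- table(te_table$class)
  if (any(tab < 2L))
    stop("each class needs >= 2 genes; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  freq <- vapply(genes, function(g) {
    s <- cds_sequences[[g]]
    n_cod <- nchar(s) %/% 3L
    i <- seq_len(n_cod - 1L) - 1L
    cods <- substring(s, 3L * i + 1L, 3L * i + 3L)
    mean(cods %in% focus_codons)
  }, numeric(1))
  per_gene <- data.frame(gene_id = genes, class = te_table$class,
                         frequency = freq, stringsAsFactors = FALSE)
  kw <- kw_test(per_gene$frequency, per_gene$class)
  meds <- tapply(per_gene$frequency, per_gene$class, stats::median)
  list(per_gene = per_gene, medians = meds, statistic = kw$statistic,
       df = kw$df, p_value = kw$p_value)
}
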