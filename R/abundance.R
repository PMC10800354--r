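#' Quantify tRNA abundance from alignment weights
#'
#' Weighted read counts per isodecoder group and library, with
#' counts-per-million normalization over each library's mapped total.
#'
#' @param hits_list Named list of \code{trmc_hits} tables, one per
#'   library; names are the library ids.
#' @param references A \code{trmc_refs} table.
#' @return list of class \code{trmc_counts}: \code{counts} and \code{cpm}
#'   (group x library matrices) and \code{library_sizes}.
#' @export
quantify <- function(hits_list, references) {
  stopifnot(is.list(hits_list), length(hits_list) >= 1L,
            !is.null(names(hits_list)))
  grp <- reference_groups(references)
  counts <- sapply(hits_list, function(h) {
    # one row per (read, group); a read contributes its weight once per group
    per <- unique(h[, c("read_id", "group", "weight")])
    s <- tapply(per$weight, factor(per$group, levels = grp$group), sum)
    ifelse(is.na(s), 0, s)
  })
  counts <- matrix(counts, nrow = nrow(grp),
                   dimnames = list(grp$group, names(hits_list)))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero mapped reads in library: ",
                          paste(names(lib)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  structure(list(counts = counts, cpm = cpm, library_sizes = lib,
                 groups = grp),
            class = "trmc_counts")
}

# The published differential-expression rule: significant at P <= 0.05
# with at least 1.5-fold change in either direction (boundary inclusive).
de_rule <- function(fold_change, p_value, min_fc = 1.5, max_p = 0.05) {
  !is.na(p_value) & p_value <= max_p &
    (fold_change >= min_fc | fold_change <= 1 / min_fc)
}

#' Differential tRNA expression between two library sets
#'
#' Fold change is the ratio of mean normalized counts (0.5 pseudocount on
#' raw counts). With fewer than 3 replicates on either side the p-value
#' comes from a two-sided Fisher exact test on pooled counts versus pooled
#' library remainders; with 3+ replicates per side, from Welch's t-test on
#' log2 CPM. A group is differentially expressed iff p <= 0.05 and the
#' fold change is at least 1.5 in either direction.
#'
#' @param table A \code{trmc_counts} object.
#' @param control_ids,kd_ids Library id vectors (columns of the table).
#' @param min_fc,max_p Rule thresholds, defaults 1.5 and 0.05.
#' @return data.frame of class \code{trmc_de}: \code{group},
#'   \code{mean_cpm_control}, \code{mean_cpm_kd}, \code{fold_change}
#'   (KD/control), \code{p_value}, \code{is_DE}, plus the test used in
#'   \code{attr(, "test")}.
#' @export
de_test <- function(table, control_ids, kd_ids, min_fc = 1.5,
                    max_p = 0.05) {
  miss <- setdiff(c(control_ids, kd_ids), colnames(table$counts))
  if (length(miss)) stop("library id(s) absent: ", paste(miss, collapse = ", "))
  cnt <- table$counts
  lib <- table$library_sizes
  cpm_ps <- sweep(cnt + 0.5, 2L, lib, "/") * 1e6
  mc <- rowMeans(cpm_ps[, control_ids, drop = FALSE])
  mk <- rowMeans(cpm_ps[, kd_ids, drop = FALSE])
  fc <- mk / mc
  few <- length(control_ids) < 3L || length(kd_ids) < 3L
  p <- if (few) {
    cc <- rowSums(cnt[, control_ids, drop = FALSE])
    ck <- rowSums(cnt[, kd_ids, drop = FALSE])
    tc <- sum(lib[control_ids]); tk <- sum(lib[kd_ids])
    vapply(seq_len(nrow(cnt)), function(i)
      fisher_two_sided(round(ck[i]), round(tk - ck[i]),
                       round(cc[i]), round(tc - cc[i])), numeric(1))
  } else {
    lc <- log2(cpm_ps[, control_ids, drop = FALSE])
    lk <- log2(cpm_ps[, kd_ids, drop = FALSE])
    vapply(seq_len(nrow(cnt)), function(i) {
      if (sd(lc[i, ]) == 0 && sd(lk[i, ]) == 0)
        return(if (isTRUE(all.equal(mean(lc[i, ]), mean(lk[i, ])))) 1
               else 0)
      t.test(lk[i, ], lc[i, ])$p.value
    }, numeric(1))
  }
  out <- data.frame(group = rownames(cnt), mean_cpm_control = mc,
                    mean_cpm_kd = mk, fold_change = fc, p_value = p,
                    is_DE = de_rule(fc, p, min_fc, max_p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "test") <- if (few) "fisher_pooled" else "welch_t_log2cpm"
  class(out) <- c("trmc_de", "data.frame")
  out
}

#' Compare abundance changes of ac4C versus non-ac4C tRNA classes
#'
#' Splits the differential-expression results into site-carrying and
#' non-carrying isodecoder groups, reports each class's mean log2 fold
#' change, and tests the two classes' fold-change distributions with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param de A \code{trmc_de} table from [de_test()].
#' @param ac4c_groups Character vector of site-carrying isodecoder groups.
#' @return list with \code{mean_log2fc_ac4c}, \code{mean_log2fc_other},
#'   \code{difference}, \code{p_value}, \code{n_ac4c}, \code{n_other}.
#' @export
class_compare <- function(de, ac4c_groups) {
  if (!all(ac4c_groups %in% de$group))
    stop("unknown group(s): ",
         paste(setdiff(ac4c_groups, de$group), collapse = ", "))
  in_class <- de$group %in% ac4c_groups
  if (!any(in_class) || all(in_class))
    stop("both classes must be nonempty")
  la <- log2(de$fold_change[in_class])
  lo <- log2(de$fold_change[!in_class])
  p <- if (sd(c(la, lo)) == 0) 1
       else wilcox.test(la, lo, exact = FALSE)$p.value
  list(mean_log2fc_ac4c = mean(la), mean_log2fc_other = mean(lo),
       difference = mean(la) - mean(lo), p_value = p,
       n_ac4c = sum(in_class), n_other = sum(!in_class))
}
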