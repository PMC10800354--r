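#' Thresholds for de-novo site calling
#'
#' Defaults: depth >= 50 in every condition, reduced misincorporation rate
#' >= 0.05, margin over the larger control rate >= 0.05, dominant
#' alternative base T, Benjamini-Hochberg FDR 0.05 across all candidate C
#' positions. The one-sided exact test compares reduced against
#' deacetylated (the matched control sharing the reduction treatment);
#' mock enters through the margin only.
#'
#' @param min_depth,min_rate,min_delta,fdr See description.
#' @return list of class \code{trmc_site_params}.
#' @export
site_params <- function(min_depth = 50, min_rate = 0.05, min_delta = 0.05,
                        fdr = 0.05) {
  if (min_rate < 0 || min_rate > 1 || min_delta < 0 || min_delta > 1 ||
      fdr <= 0 || fdr > 1 || min_depth < 0)
    stop("site-calling threshold outside its domain")
  structure(list(min_depth = min_depth, min_rate = min_rate,
                 min_delta = min_delta, fdr = fdr),
            class = "trmc_site_params")
}

# One-sided (enrichment) p-value of a 2x2 table by the hypergeometric
# (Fisher) conditional distribution; vectorized over tables.
fisher_one_sided <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# Two-sided Fisher exact p for one 2x2 table.
fisher_two_sided <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
}

#' Call ac4C sites from the three-condition design
#'
#' Candidates are reference-C positions with adequate depth in all three
#' tracks. Each candidate gets a one-sided exact conditional test of
#' mismatch enrichment, reduced versus deacetylated, on rounded weighted
#' counts; BH correction runs across all candidates. A candidate is
#' \emph{called} when its q-value passes the FDR, its reduced rate and its
#' margin over the larger control rate pass their thresholds, and its
#' dominant alternative base is T (the chemistry's signature).
#'
#' @param rates_reduced,rates_deacetylated,rates_mock \code{trmc_rates}
#'   tracks over the same references.
#' @param params A [site_params()].
#' @return data.frame of class \code{trmc_sites}, one row per reference-C
#'   position, sorted by (ref_id, position), with per-condition rates and
#'   depths, \code{p_value}, \code{q_value} and a verdict in
#'   \{called, not_called, low_coverage\}.
#' @export
call_sites <- function(rates_reduced, rates_deacetylated, rates_mock,
                       params = site_params()) {
  key <- function(x) paste(x$group, x$pos)
  if (!identical(sort(key(rates_reduced)), sort(key(rates_deacetylated))) ||
      !identical(sort(key(rates_reduced)), sort(key(rates_mock))))
    stop("rate tracks cover different reference sets")
  red <- rates_reduced[order(rates_reduced$group, rates_reduced$pos), ]
  dea <- rates_deacetylated[match(key(red), key(rates_deacetylated)), ]
  moc <- rates_mock[match(key(red), key(rates_mock)), ]

  cpos <- red$ref_base == "C"
  out <- data.frame(
    ref_id = red$group[cpos], position = red$pos[cpos],
    ref_base = rep("C", sum(cpos)),
    rate_reduced = red$misinc_rate[cpos],
    rate_deacetylated = dea$misinc_rate[cpos],
    rate_mock = moc$misinc_rate[cpos],
    ct_rate_reduced = red$ct_rate[cpos],
    stop_rate_reduced = red$stop_rate[cpos],
    dominant_alt = red$dominant_alt[cpos],
    depth_reduced = red$depth[cpos],
    depth_deacetylated = dea$depth[cpos],
    depth_mock = moc$depth[cpos],
    stringsAsFactors = FALSE)
  cand <- out$depth_reduced >= params$min_depth &
    out$depth_deacetylated >= params$min_depth &
    out$depth_mock >= params$min_depth
  mm_r <- round(out$depth_reduced - red$ref_count[cpos])
  ok_r <- round(red$ref_count[cpos])
  mm_d <- round(out$depth_deacetylated - dea$ref_count[cpos])
  ok_d <- round(dea$ref_count[cpos])
  out$p_value <- rep(NA_real_, nrow(out))
  out$p_value[cand] <- fisher_one_sided(mm_r[cand], ok_r[cand],
                                        mm_d[cand], ok_d[cand])
  out$q_value <- rep(NA_real_, nrow(out))
  out$q_value[cand] <- p.adjust(out$p_value[cand], method = "BH")
  called <- cand & !is.na(out$q_value) & out$q_value <= params$fdr &
    out$rate_reduced >= params$min_rate &
    (out$rate_reduced - pmax(out$rate_deacetylated, out$rate_mock)) >=
      params$min_delta &
    out$dominant_alt == "T"
  out$verdict <- ifelse(!cand, "low_coverage",
                        ifelse(called, "called", "not_called"))
  out <- out[order(out$ref_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("trmc_sites", "data.frame")
  out
}

#' Test differential modification between two biological conditions
#'
#' Per listed site, a two-sided Fisher exact test on (mismatch, match)
#' counts, control versus knockdown; BH correction across the site list
#' only (sites below the depth floor are flagged low_coverage and excluded
#' from the family). Direction follows the sign of the rate difference at
#' q <= fdr.
#'
#' @param rates_control,rates_kd \code{trmc_rates} tracks.
#' @param site_list data.frame with \code{ref_id} (isodecoder group) and
#'   \code{position}.
#' @param min_depth,fdr Depth floor (default 50) and FDR (default 0.05).
#' @return data.frame of class \code{trmc_diffmod} with per-site rates,
#'   depths, \code{p_value}, \code{q_value}, \code{direction} in
#'   \{decreased, increased, unchanged, low_coverage\}.
#' @export
diff_modification <- function(rates_control, rates_kd, site_list,
                              min_depth = 50, fdr = 0.05) {
  key <- function(g, p) paste(g, p)
  kc <- key(rates_control$group, rates_control$pos)
  kk <- key(rates_kd$group, rates_kd$pos)
  ks <- key(site_list$ref_id, site_list$position)
  ic <- match(ks, kc); ik <- match(ks, kk)
  if (anyNA(ic) || anyNA(ik))
    stop("site_list positions missing from the rate tracks")
  ctl <- rates_control[ic, ]; kd <- rates_kd[ik, ]
  out <- data.frame(
    ref_id = site_list$ref_id, position = site_list$position,
    rate_control = ctl$misinc_rate, rate_kd = kd$misinc_rate,
    depth_control = ctl$depth, depth_kd = kd$depth,
    stringsAsFactors = FALSE)
  ok <- out$depth_control >= min_depth & out$depth_kd >= min_depth
  out$p_value <- NA_real_
  for (i in which(ok)) {
    out$p_value[i] <- fisher_two_sided(
      round(ctl$depth[i] - ctl$ref_count[i]), round(ctl$ref_count[i]),
      round(kd$depth[i] - kd$ref_count[i]), round(kd$ref_count[i]))
  }
  out$q_value <- NA_real_
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out$direction <- ifelse(!ok, "low_coverage", "unchanged")
  sig <- ok & !is.na(out$q_value) & out$q_value <= fdr
  out$direction[sig & out$rate_kd < out$rate_control] <- "decreased"
  out$direction[sig & out$rate_kd > out$rate_control] <- "increased"
  class(out) <- c("trmc_diffmod", "data.frame")
  out
}

#' Summarize a site-call table
#'
#' @param calls A \code{trmc_sites} table.
#' @param references A \code{trmc_refs} table (maps isodecoder groups to
#'   isoacceptors).
#' @return list with \code{n_sites}, \code{n_isodecoders},
#'   \code{n_isoacceptors}, \code{n_positions} and a per-isoacceptor table
#'   of called sites.
#' @export
summarize_sites <- function(calls, references) {
  hit <- calls[calls$verdict == "called", , drop = FALSE]
  grp <- reference_groups(references)
  iso <- paste0(grp$amino_acid, "(", grp$anticodon, ")")[
    match(hit$ref_id, grp$group)]
  per <- if (nrow(hit)) {
    aggregate(hit$position, by = list(isoacceptor = iso),
              FUN = function(p) paste(sort(unique(p)), collapse = ","))
  } else data.frame(isoacceptor = character(0), x = character(0))
  names(per)[2L] <- "positions"
  list(n_sites = nrow(hit),
       n_isodecoders = length(unique(hit$ref_id)),
       n_isoacceptors = length(unique(iso)),
       n_positions = length(unique(hit$position)),
       per_isoacceptor = per)
}

#' Export called sites as TSV or BED
#'
#' The BED export is in tRNA space: 0-based half-open interval around each
#' called position, name "ac4C", score \eqn{-10 \log_{10} q} (capped at
#' 9999), forward strand.
#'
#' @param calls A \code{trmc_sites} table.
#' @param path Output path.
#' @export
export_sites <- function(calls, path) {
  write_tsv_hash(as.data.frame(calls), path)
}

#' @rdname export_sites
#' @export
export_sites_bed <- function(calls, path) {
  hit <- calls[calls$verdict == "called", , drop = FALSE]
  score <- ifelse(hit$q_value <= 0, 9999,
                  pmin(round(-10 * log10(hit$q_value)), 9999))
  bed <- data.frame(chrom = hit$ref_id, start = hit$position - 1L,
                    end = hit$position, name = "ac4C", score = score,
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
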