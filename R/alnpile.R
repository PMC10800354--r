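#' Distinct isodecoder groups of a reference set
#'
#' One representative record per isodecoder group (members are
#' byte-identical, so any member represents the group).
#' @param references A \code{trmc_refs} table.
#' @return data.frame with \code{group}, \code{sequence}, \code{length},
#'   \code{amino_acid}, \code{anticodon}.
#' @export
reference_groups <- function(references) {
  g <- references[!duplicated(references$isodecoder_group), , drop = FALSE]
  data.frame(group = g$isodecoder_group, sequence = g$sequence,
             length = nchar(g$sequence), amino_acid = g$amino_acid,
             anticodon = g$anticodon, stringsAsFactors = FALSE)
}

# Exact-prefix 3' adapter trimming: cut at the first occurrence of the
# full adapter; otherwise strip a terminal exact prefix of the adapter
# (>= min_overlap nt). Reads without adapter pass through unchanged.
trim_adapter <- function(sequences, adapter, min_overlap = 5L) {
  hit <- regexpr(adapter, sequences, fixed = TRUE)
  out <- ifelse(hit > 0L, substr(sequences, 1L, hit - 1L), sequences)
  for (k in seq(min(nchar(adapter) - 1L, max(nchar(out))),
                min_overlap, by = -1L)) {
    pre <- substr(adapter, 1L, k)
    ends <- endsWith(out, pre)
    out[ends] <- substr(out[ends], 1L, nchar(out[ends]) - k)
  }
  out
}

#' Align reads to a small reference set with a mismatch cap
#'
#' Built-in exhaustive ungapped scan: every read is tested against every
#' isodecoder group at every offset (full containment, forward strand),
#' and all groups achieving the read's minimum mismatch count are kept,
#' provided that minimum is at most \code{max_mismatch}. A read tying
#' across k groups receives weight 1/k per group, so pileups stay
#' deterministic and rates unbiased. Reads with more than 50% N are
#' skipped with a warning.
#'
#' @param reads data.frame with \code{read_id}, \code{sequence}, or a
#'   FASTQ path.
#' @param references A \code{trmc_refs} table.
#' @param max_mismatch Maximum mismatches, default 2.
#' @param adapter Optional 3' adapter sequence to trim before alignment.
#' @return data.frame of class \code{trmc_hits}: \code{read_id},
#'   \code{group}, \code{start}, \code{end} (1-based closed),
#'   \code{n_mismatch}, \code{weight}; unmapped read ids in
#'   \code{attr(, "unmapped")}.
#' @export
align_reads <- function(reads, references, max_mismatch = 2L,
                        adapter = NULL) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (nrow(references) == 0L) stop("empty reference set")
  grp <- reference_groups(references)
  seqs <- toupper(reads$sequence)
  if (!is.null(adapter)) seqs <- trim_adapter(seqs, toupper(adapter))
  n_frac <- vapply(gregexpr("N", seqs, fixed = TRUE),
                   function(m) if (m[1L] == -1L) 0L else length(m),
                   integer(1)) / pmax(nchar(seqs), 1L)
  skip <- n_frac > 0.5
  if (any(skip))
    warning(sum(skip), " read(s) skipped: N fraction > 50%")
  keep <- which(!skip)
  useq <- unique(seqs[keep])
  sc <- hamming_scan(useq, grp$sequence, as.integer(max_mismatch))
  idx <- match(seqs[keep], useq)
  # expand unique-sequence hits back to reads
  per_u <- split(seq_len(nrow(sc)), sc$read_index)
  hit_rows <- per_u[as.character(idx)]
  n_hits <- lengths(hit_rows)
  has <- n_hits > 0L
  rows <- unlist(hit_rows[has], use.names = FALSE)
  read_i <- rep(keep[has], n_hits[has])
  hits <- data.frame(
    read_id = reads$read_id[read_i],
    group = grp$group[sc$ref_index[rows]],
    start = sc$start[rows],
    end = sc$start[rows] + nchar(seqs[read_i]) - 1L,
    n_mismatch = sc$n_mismatch[rows],
    weight = rep(1 / n_hits[has], n_hits[has]),
    stringsAsFactors = FALSE)
  attr(hits, "unmapped") <- reads$read_id[c(keep[!has], which(skip))]
  attr(hits, "sequences") <- seqs
  class(hits) <- c("trmc_hits", "data.frame")
  hits
}

#' Ingest external SAM/BAM alignments
#'
#' Converts primary alignments to the package's hit table, honoring the
#' two-mismatch cap: mismatch counts come from the NM tag when present and
#' are otherwise recomputed from the sequence (ungapped records only);
#' hits exceeding the cap are dropped. Target names must match loaded
#' \code{ref_id}s.
#'
#' @param sam Path to a SAM or BAM file.
#' @param references A \code{trmc_refs} table.
#' @param max_mismatch Maximum mismatches, default 2.
#' @return A \code{trmc_hits} data.frame (weight 1 per primary hit).
#' @export
ingest_sam <- function(sam, references, max_mismatch = 2L) {
  bam <- sam
  if (grepl("\\.sam$", sam, ignore.case = TRUE))
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "seq", "cigar"),
      tag = "NM"))[[1L]]
  flag <- res$flag
  primary <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) &
    !bitwAnd(flag, 0x800)
  rname <- as.character(res$rname)[primary]
  if (length(rname) == 0L)
    return(structure(data.frame(read_id = character(0), group = character(0),
                                start = integer(0), end = integer(0),
                                n_mismatch = integer(0), weight = numeric(0)),
                     class = c("trmc_hits", "data.frame")))
  unknown <- setdiff(unique(rname), references$ref_id)
  if (length(unknown))
    stop("unknown SAM target name(s): ", paste(unknown, collapse = ", "))
  seqs <- as.character(res$seq)[primary]
  pos <- res$pos[primary]
  nm <- res$tag$NM[primary]
  cigar <- res$cigar[primary]
  qname <- res$qname[primary]
  ref_seq <- references$sequence[match(rname, references$ref_id)]
  need <- is.na(nm)
  if (any(need)) {
    ungapped <- grepl("^[0-9]+M$", cigar[need])
    if (!all(ungapped))
      warning(sum(!ungapped), " gapped record(s) without NM dropped")
    for (i in which(need)) {
      if (!grepl("^[0-9]+M$", cigar[i])) { nm[i] <- NA; next }
      a <- strsplit(seqs[i], "")[[1L]]
      b <- strsplit(substr(ref_seq[i], pos[i],
                           pos[i] + nchar(seqs[i]) - 1L), "")[[1L]]
      nm[i] <- sum(a != b)
    }
  }
  ok <- !is.na(nm) & nm <= max_mismatch
  grp_of <- references$isodecoder_group[match(rname, references$ref_id)]
  hits <- data.frame(read_id = qname[ok], group = grp_of[ok],
                     start = pos[ok],
                     end = pos[ok] + nchar(seqs[ok]) - 1L,
                     n_mismatch = as.integer(nm[ok]), weight = 1,
                     stringsAsFactors = FALSE)
  attr(hits, "sam_sequences") <- setNames(seqs[ok], qname[ok])
  class(hits) <- c("trmc_hits", "data.frame")
  hits
}

#' Build a weighted per-position base-count pileup
#'
#' Every aligned base increments the matching base counter by the hit's
#' weight; read 5' and 3' termini increment end counters at the terminal
#' positions. Column sums (A+C+G+T) equal the weighted depth wherever
#' reads contain no ambiguity codes.
#'
#' @param hits A \code{trmc_hits} table.
#' @param reads data.frame with \code{read_id}, \code{sequence} (the reads
#'   given to the aligner); may be NULL if \code{hits} came from
#'   [ingest_sam()] (sequences are taken from the SAM records).
#' @param references A \code{trmc_refs} table.
#' @return data.frame of class \code{trmc_pileup}: \code{group},
#'   \code{pos}, \code{A}, \code{C}, \code{G}, \code{T}, \code{depth},
#'   \code{five_prime_ends}, \code{three_prime_ends}.
#' @export
build_pileup <- function(hits, reads, references) {
  grp <- reference_groups(references)
  if (is.null(reads)) {
    sam_seq <- attr(hits, "sam_sequences")
    if (is.null(sam_seq)) stop("reads required when hits lack sequences")
    hseq <- unname(sam_seq[hits$read_id])
  } else {
    hseq <- toupper(reads$sequence[match(hits$read_id, reads$read_id)])
    # if the aligner trimmed adapters, use what it aligned
    trimmed <- attr(hits, "sequences")
    if (!is.null(trimmed))
      hseq <- trimmed[match(hits$read_id, reads$read_id)]
  }
  if (anyNA(hseq)) stop("hit read_id absent from reads")
  gi <- match(hits$group, grp$group)
  if (anyNA(gi)) stop("hit group absent from references")
  mats <- pileup_counts(hseq, gi, hits$start, hits$weight, grp$length)
  out <- do.call(rbind, lapply(seq_len(nrow(grp)), function(j) {
    m <- mats[[j]]
    data.frame(group = grp$group[j], pos = seq_len(grp$length[j]),
               A = m[, 1L], C = m[, 2L], G = m[, 3L], T = m[, 4L],
               depth = m[, 1L] + m[, 2L] + m[, 3L] + m[, 4L],
               five_prime_ends = m[, 5L], three_prime_ends = m[, 6L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "groups") <- grp
  class(out) <- c("trmc_pileup", "data.frame")
  out
}

#' Per-position misincorporation, C-to-T and stop rates
#'
#' \code{misinc_rate} is the fraction of aligned bases differing from the
#' reference base; \code{ct_rate} (defined at reference C only) is the T
#' fraction; \code{stop_rate} is the 3'-end count over depth. Rates are NA
#' at zero depth; positions under \code{min_depth} are flagged, not
#' removed.
#'
#' @param pileup A \code{trmc_pileup} table.
#' @param references A \code{trmc_refs} table (for reference bases).
#' @param min_depth Low-coverage flag threshold, default 50.
#' @return data.frame of class \code{trmc_rates} extending the pileup with
#'   \code{ref_base}, \code{ref_count}, \code{misinc_rate},
#'   \code{dominant_alt}, \code{ct_rate}, \code{stop_rate},
#'   \code{low_coverage}.
#' @export
compute_rates <- function(pileup, references, min_depth = 50) {
  grp <- attr(pileup, "groups")
  if (is.null(grp)) grp <- reference_groups(references)
  seq_of <- setNames(grp$sequence, grp$group)
  out <- pileup
  out$ref_base <- substr(seq_of[out$group], out$pos, out$pos)
  cnt <- as.matrix(out[, c("A", "C", "G", "T")])
  out$ref_count <- cnt[cbind(seq_len(nrow(out)),
                             match(out$ref_base, BASES))]
  out$misinc_rate <- ifelse(out$depth > 0,
                            1 - out$ref_count / out$depth, NA_real_)
  alt <- cnt
  alt[cbind(seq_len(nrow(out)), match(out$ref_base, BASES))] <- -1
  out$dominant_alt <- BASES[max.col(alt, ties.method = "first")]
  out$dominant_alt[out$depth == 0] <- NA_character_
  out$ct_rate <- ifelse(out$ref_base == "C" & out$depth > 0,
                        out$T / out$depth, NA_real_)
  out$stop_rate <- ifelse(out$depth > 0,
                          out$three_prime_ends / out$depth, NA_real_)
  out$low_coverage <- out$depth < min_depth
  attr(out, "groups") <- grp
  attr(out, "min_depth") <- min_depth
  class(out) <- c("trmc_rates", "data.frame")
  out
}

#' Export a pileup or rate track as TSV
#' @param x A \code{trmc_pileup} or \code{trmc_rates} table.
#' @param path Output path.
#' @export
export_track <- function(x, path) {
  write_tsv_hash(as.data.frame(x), path)
}
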