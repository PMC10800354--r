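#' Load and normalize mature tRNA / rRNA reference sequences
#'
#' Reads a FASTA file of mature reference sequences, uppercases them,
#' converts U to T, appends the 3' CCA tail to tRNAs that lack it (only the
#' missing suffix of \code{"CCA"} is added, so \code{"...CC"} gains a single
#' \code{"A"}), and collapses byte-identical sequences into isodecoder
#' groups. Two header dialects are recognized for tRNAs: gtRNAdb-style ids
#' containing \code{tRNA-<Aa>-<anticodon>} and plain
#' \code{<id> <aa> <anticodon>} headers; anything else is kept as an opaque
#' id with unknown anticodon.
#'
#' @param fasta Path to a FASTA file.
#' @param kind \code{"tRNA"} (default) or \code{"rRNA"}. rRNA records get
#'   no CCA tail, an empty anticodon, and amino acid \code{"rRNA"}.
#' @param add_his_g1 Prepend the post-transcriptional G-1 to histidine
#'   tRNAs that do not already start with G. Off by default.
#' @return A data.frame of class \code{trmc_refs} with columns
#'   \code{ref_id}, \code{amino_acid}, \code{anticodon}, \code{sequence},
#'   \code{isodecoder_group}, \code{length}, ordered by \code{ref_id}.
#'   The \code{isodecoder_group} label is the \code{ref_id} of the group's
#'   first member, so records with identical sequences share one label.
#' @export
load_references <- function(fasta, kind = c("tRNA", "rRNA"),
                            add_his_g1 = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta)
  headers <- names(seqs)
  sequences <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTU]", sequences)
  if (any(bad))
    stop("non-ACGTU characters in record(s): ",
         paste(sub("\\s.*", "", headers[bad]), collapse = ", "))
  sequences <- chartr("U", "T", sequences)

  ref_id <- sub("\\s.*", "", headers)
  amino_acid <- rep(NA_character_, length(seqs))
  anticodon <- rep(NA_character_, length(seqs))
  if (kind == "tRNA") {
    gt <- regmatches(headers,
      regexec("tRNA-([A-Za-z]{3}|iMet|SeC|Und)-([ACGTUacgtu]{3})", headers))
    plain <- regmatches(headers,
      regexec("^\\S+\\s+([A-Za-z]{3})\\s+([ACGTUacgtu]{3})(\\s|$)", headers))
    for (i in seq_along(seqs)) {
      m <- if (length(gt[[i]])) gt[[i]] else plain[[i]]
      if (length(m)) {
        amino_acid[i] <- m[2L]
        anticodon[i] <- chartr("U", "T", toupper(m[3L]))
      }
    }
    sequences <- vapply(sequences, append_cca, character(1), USE.NAMES = FALSE)
    if (add_his_g1) {
      his <- !is.na(amino_acid) & amino_acid == "His" &
        !startsWith(sequences, "G")
      sequences[his] <- paste0("G", sequences[his])
    }
    len <- nchar(sequences)
    if (any(len < 60 | len > 120))
      warning("tRNA length outside [60, 120] nt for: ",
              paste(ref_id[len < 60 | len > 120], collapse = ", "))
  } else {
    amino_acid[] <- "rRNA"
    anticodon[] <- ""
  }

  ord <- order(ref_id, method = "radix")
  df <- data.frame(ref_id = ref_id, amino_acid = amino_acid,
                   anticodon = anticodon, sequence = sequences,
                   length = nchar(sequences),
                   stringsAsFactors = FALSE)[ord, , drop = FALSE]
  if (anyDuplicated(df$ref_id)) stop("duplicate ref_id in FASTA")
  # identical sequences share one isodecoder group, labeled by the first
  # member in ref_id order
  df$isodecoder_group <- df$ref_id[match(df$sequence, df$sequence)]
  rownames(df) <- NULL
  df <- df[, c("ref_id", "amino_acid", "anticodon", "sequence",
               "isodecoder_group", "length")]
  class(df) <- c("trmc_refs", "data.frame")
  df
}

# Append the shortest suffix that makes the sequence end in CCA; a no-op on
# sequences that already do (idempotent).
append_cca <- function(x) {
  if (endsWith(x, "CCA")) return(x)
  if (endsWith(x, "CC")) return(paste0(x, "A"))
  if (endsWith(x, "C")) return(paste0(x, "CA"))
  paste0(x, "CCA")
}

#' Decoded codon of an anticodon
#'
#' A tRNA anticodon pairs antiparallel with its codon, so the decoded codon
#' is the reverse complement of the anticodon (wobble decoding is not
#' expanded).
#'
#' @param anticodon Character vector of 3-mers over A/C/G/T (U accepted).
#' @return Character vector of decoded codons.
#' @examples
#' anticodon_to_codon("GCT")  # "AGC"
#' @export
anticodon_to_codon <- function(anticodon) {
  anticodon <- chartr("U", "T", toupper(anticodon))
  if (any(nchar(anticodon) != 3L))
    stop("anticodon must have length 3")
  if (any(grepl("[^ACGT]", anticodon)))
    stop("anticodon must be over {A,C,G,T}")
  revcomp(anticodon)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Printed ac4C site inventories on tRNA
#'
#' The site inventories reported by the two assay modes, used as fixtures
#' and as the default modified-isoacceptor set. \code{"totalrna"} is the
#' total-RNA reduction assay inventory: 13 sites on 13 isodecoders across 9
#' isoacceptors. \code{"trmc"} is the small-RNA (TRMC) inventory: 17 sites
#' on 16 isodecoders across 10 isoacceptors, adding the acceptor-stem /
#' variable-arm positions 3, 50 and 65 and the Val(AAC) isoacceptor. Site
#' positions are 1-based linear coordinates on the mature sequence
#' including the CCA tail. The per-isoacceptor isodecoder multiplicities
#' are this package's synthetic-world allocation consistent with the
#' printed totals (see the methods vignette).
#'
#' @param mode \code{"trmc"} (default) or \code{"totalrna"}.
#' @return data.frame with columns \code{amino_acid}, \code{anticodon},
#'   \code{isodecoder} (index within the isoacceptor), \code{position}.
#' @export
ac4c_site_inventory <- function(mode = c("trmc", "totalrna")) {
  mode <- match.arg(mode)
  L <- list(
    totalrna = list(
      c("Ser", "GCT", 1, 12), c("Ser", "GCT", 2, 12),
      c("Leu", "TAA", 1, 79), c("Leu", "TAA", 2, 79),
      c("Leu", "TAG", 1, 12),
      c("Ser", "TGA", 1, 12), c("Ser", "TGA", 2, 12),
      c("Ser", "AGA", 1, 12), c("Ser", "AGA", 2, 12),
      c("Ser", "CGA", 1, 12),
      c("Arg", "TCG", 1, 4),
      c("Leu", "AAG", 1, 6),
      c("Leu", "CAA", 1, 12)),
    trmc = list(
      c("Ser", "GCT", 1, 12), c("Ser", "GCT", 2, 12),
      c("Leu", "TAA", 1, 79), c("Leu", "TAA", 2, 79),
      c("Leu", "TAG", 1, 12),
      c("Ser", "TGA", 1, 12), c("Ser", "TGA", 2, 12),
      c("Ser", "AGA", 1, 12), c("Ser", "AGA", 2, 12),
      c("Ser", "CGA", 1, 12), c("Ser", "CGA", 1, 3),
      c("Arg", "TCG", 1, 4), c("Arg", "TCG", 2, 4),
      c("Leu", "AAG", 1, 6), c("Leu", "AAG", 2, 50),
      c("Leu", "CAA", 1, 12),
      c("Val", "AAC", 1, 65)))[[mode]]
  df <- as.data.frame(do.call(rbind, L), stringsAsFactors = FALSE)
  names(df) <- c("amino_acid", "anticodon", "isodecoder", "position")
  df$isodecoder <- as.integer(df$isodecoder)
  df$position <- as.integer(df$position)
  df
}

#' Codons decoded by ac4C-carrying isoacceptors
#'
#' Maps every isoacceptor carrying at least one called site to its decoded
#' codon (reverse complement of the anticodon) and returns the sorted
#' unique codon set. With the default TRMC inventory this is the 10-codon
#' set decoded by the 10 modified isoacceptors.
#'
#' @param records A \code{trmc_refs} table, or NULL to skip validation
#'   against a loaded reference set.
#' @param site_table data.frame with \code{amino_acid} and \code{anticodon}
#'   columns (e.g. [ac4c_site_inventory()] or a called-site summary).
#' @return Sorted character vector of codons.
#' @export
ac4c_decoder_codons <- function(records = NULL,
                                site_table = ac4c_site_inventory("trmc")) {
  if (nrow(site_table) == 0L) return(character(0))
  if (!all(c("amino_acid", "anticodon") %in% names(site_table)))
    stop("site_table needs amino_acid and anticodon columns")
  if (!is.null(records)) {
    known <- paste(records$amino_acid, records$anticodon)
    ask <- paste(site_table$amino_acid, site_table$anticodon)
    if (!all(ask %in% known))
      stop("unknown isoacceptor(s): ",
           paste(unique(ask[!ask %in% known]), collapse = ", "))
  }
  sort(unique(anticodon_to_codon(site_table$anticodon)))
}

#' Export a reference table as TSV
#'
#' @param records A \code{trmc_refs} table.
#' @param path Output file; a single '#'-prefixed header line, then one row
#'   per reference with its decoded codon.
#' @export
export_reference_table <- function(records, path) {
  out <- records[, c("ref_id", "amino_acid", "anticodon",
                     "isodecoder_group", "length")]
  out$decoded_codon <- ifelse(is.na(records$anticodon) |
                                records$anticodon == "",
                              NA_character_,
                              anticodon_to_codon(
                                ifelse(is.na(records$anticodon) |
                                         records$anticodon == "",
                                       "AAA", records$anticodon)))
  write_tsv_hash(out, path)
}
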