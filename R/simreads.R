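BASES <- c("A", "C", "G", "T")

#' Synthetic tRNA reference set carrying a printed site inventory
#'
#' Builds one random-body mature tRNA per isodecoder of
#' [ac4c_site_inventory()], with the isoacceptor's anticodon at positions
#' 34-36, a cytidine at every inventoried site position, and a terminal
#' CCA. Leucine and serine isodecoders are 85 nt (long variable arm); all
#' others are 76 nt. Sequences are random but fully determined by
#' \code{seed}; isodecoders of one isoacceptor differ throughout the body,
#' so error-free reads map uniquely.
#'
#' @param mode Inventory to embed, \code{"trmc"} or \code{"totalrna"}.
#' @param seed Integer seed for the sequence bodies.
#' @return list with \code{references} (a \code{trmc_refs} table) and
#'   \code{sites} (data.frame \code{ref_id}, \code{position}).
#' @export
synthetic_trna_set <- function(mode = c("trmc", "totalrna"), seed = 1001L) {
  mode <- match.arg(mode)
  inv <- ac4c_site_inventory(mode)
  key <- paste(inv$amino_acid, inv$anticodon, inv$isodecoder)
  uniq <- !duplicated(key)
  with_seed(seed, {
    recs <- lapply(which(uniq), function(i) {
      aa <- inv$amino_acid[i]; ac <- inv$anticodon[i]
      pos <- inv$position[key == key[i]]
      len <- if (aa %in% c("Leu", "Ser")) 85L else 76L
      body <- sample(BASES, len, replace = TRUE)
      body[34:36] <- strsplit(ac, "")[[1L]]
      body[pos] <- "C"
      body[(len - 2L):len] <- c("C", "C", "A")
      id <- sprintf("tRNA-%s-%s-%d-1", aa, ac, inv$isodecoder[i])
      list(ref_id = id, amino_acid = aa, anticodon = ac,
           sequence = paste(body, collapse = ""), length = len,
           positions = pos)
    })
    refs <- data.frame(
      ref_id = vapply(recs, `[[`, "", "ref_id"),
      amino_acid = vapply(recs, `[[`, "", "amino_acid"),
      anticodon = vapply(recs, `[[`, "", "anticodon"),
      sequence = vapply(recs, `[[`, "", "sequence"),
      stringsAsFactors = FALSE)
    refs$length <- nchar(refs$sequence)
    refs <- refs[order(refs$ref_id, method = "radix"), , drop = FALSE]
    refs$isodecoder_group <- refs$ref_id[match(refs$sequence, refs$sequence)]
    refs <- refs[, c("ref_id", "amino_acid", "anticodon", "sequence",
                     "isodecoder_group", "length")]
    rownames(refs) <- NULL
    class(refs) <- c("trmc_refs", "data.frame")
    sites <- do.call(rbind, lapply(recs, function(r)
      data.frame(ref_id = r$ref_id, position = r$positions,
                 stringsAsFactors = FALSE)))
    sites <- sites[order(sites$ref_id, sites$position), , drop = FALSE]
    rownames(sites) <- NULL
    list(references = refs, sites = sites)
  })
}

#' Synthetic rRNA fragment with embedded cytidines
#'
#' A random stand-in for an 18S rRNA segment (clearly synthetic, not the
#' real 18S sequence) with C at the requested positions, for exercising the
#' total-RNA mode of the pipeline.
#'
#' @param length Fragment length in nt.
#' @param positions 1-based positions forced to C (candidate ac4C sites).
#' @param seed Integer seed.
#' @return list with \code{references} and \code{sites} as in
#'   [synthetic_trna_set()].
#' @export
synthetic_rrna_set <- function(length = 180L, positions = c(66L, 130L),
                               seed = 1001L) {
  stopifnot(all(positions >= 1L), all(positions <= length))
  with_seed(seed, {
    body <- sample(BASES, length, replace = TRUE)
    body[positions] <- "C"
    refs <- data.frame(ref_id = "rRNA-18S-synthetic", amino_acid = "rRNA",
                       anticodon = "", sequence = paste(body, collapse = ""),
                       isodecoder_group = "rRNA-18S-synthetic",
                       length = length, stringsAsFactors = FALSE)
    class(refs) <- c("trmc_refs", "data.frame")
    list(references = refs,
         sites = data.frame(ref_id = "rRNA-18S-synthetic",
                            position = as.integer(positions),
                            stringsAsFactors = FALSE))
  })
}

#' Specify a synthetic reduction-sequencing library
#'
#' @param references \code{trmc_refs} table (or any data.frame with
#'   \code{ref_id} and \code{sequence}).
#' @param sites data.frame with \code{ref_id}, \code{position} and
#'   optionally \code{rate} (C-to-T misincorporation probability under the
#'   reduced condition, default 0.2) and \code{stop_rate} (probability of a
#'   reverse-transcription stop truncating the read just before the site,
#'   default 0). Every site must sit on a reference C.
#' @param condition \code{"reduced"}, \code{"deacetylated"} or
#'   \code{"mock"}. Only the reduced condition expresses the signature;
#'   the two controls are statistically identical background.
#' @param depth_per_ref Reads per reference: a single count or a vector
#'   named by \code{ref_id}.
#' @param background_error Per-base substitution probability, uniform over
#'   the three alternative bases (default 0.002).
#' @param truncation_background Per-read probability of a random 3'
#'   truncation, default 0.
#' @param fragment_length If set, reads are random windows of this length
#'   instead of full-length molecules (total-RNA mode).
#' @param seed Integer seed; the only source of randomness.
#' @return A \code{trmc_sim_config} list.
#' @export
sim_config <- function(references, sites = NULL,
                       condition = c("reduced", "deacetylated", "mock"),
                       depth_per_ref = 2000L, background_error = 0.002,
                       truncation_background = 0, fragment_length = NULL,
                       seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(references), nrow(references) >= 1L)
  if (is.null(sites))
    sites <- data.frame(ref_id = character(0), position = integer(0))
  if (is.null(sites$rate)) sites$rate <- rep(0.2, nrow(sites))
  if (is.null(sites$stop_rate)) sites$stop_rate <- rep(0, nrow(sites))
  if (nrow(sites)) {
    m <- match(sites$ref_id, references$ref_id)
    if (anyNA(m)) stop("site ref_id not in references: ",
                       paste(unique(sites$ref_id[is.na(m)]), collapse = ", "))
    len <- nchar(references$sequence)[m]
    if (any(sites$position < 1L | sites$position > len))
      stop("site position outside reference")
    base <- substr(references$sequence[m], sites$position, sites$position)
    if (any(base != "C"))
      stop("site reference base must be C (found ",
           paste(unique(base[base != "C"]), collapse = ","), ")")
    if (any(sites$rate < 0 | sites$rate > 1 |
            sites$stop_rate < 0 | sites$stop_rate > 1))
      stop("site rates must lie in [0, 1]")
  }
  if (length(depth_per_ref) == 1L && is.null(names(depth_per_ref)))
    depth_per_ref <- setNames(rep(as.integer(depth_per_ref),
                                  nrow(references)), references$ref_id)
  if (any(depth_per_ref < 0L)) stop("depth must be >= 0")
  if (!all(references$ref_id %in% names(depth_per_ref)))
    stop("depth_per_ref must cover every reference")
  if (background_error < 0 || background_error > 1 ||
      truncation_background < 0 || truncation_background > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(references = references, sites = sites,
                 condition = condition, depth_per_ref = depth_per_ref,
                 background_error = background_error,
                 truncation_background = truncation_background,
                 fragment_length = fragment_length,
                 seed = as.integer(seed)),
            class = "trmc_sim_config")
}

OTHER_BASE <- matrix(c("C", "G", "T",
                       "A", "G", "T",
                       "A", "C", "T",
                       "A", "C", "G"), nrow = 4, byrow = TRUE,
                     dimnames = list(BASES, NULL))

#' Simulate one reduction-sequencing library
#'
#' Emits \code{depth_per_ref} reads per reference. Background substitution
#' errors hit every position independently; under the reduced condition
#' each embedded site converts its C to T with the site's rate and, with
#' the site's stop rate, truncates the read so its 3' end falls just
#' before the site. Truncated reads shorter than 15 nt are dropped
#' (adapter/length filtering). Identical configs give byte-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return list of class \code{trmc_sim}: \code{reads} (data.frame
#'   \code{read_id}, \code{sequence}), \code{truth} (per-site realized
#'   conversion counts among reads covering the site), \code{config}.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "trmc_sim_config"))
  refs <- config$references
  reduced <- config$condition == "reduced"
  with_seed(config$seed, {
    per_ref <- lapply(seq_len(nrow(refs)), function(j) {
      ref <- refs$ref_id[j]
      L <- nchar(refs$sequence[j])
      d <- config$depth_per_ref[[ref]]
      if (d == 0L)
        return(list(reads = character(0), ids = character(0),
                    truth = NULL))
      chars <- strsplit(refs$sequence[j], "", fixed = TRUE)[[1L]]
      m <- matrix(chars, nrow = L, ncol = d)
      e <- config$background_error
      if (e > 0) {
        n_err <- rbinom(1L, L * d, e)
        if (n_err > 0) {
          idx <- sample.int(L * d, n_err)
          m[idx] <- OTHER_BASE[cbind(match(m[idx], BASES),
                                     sample.int(3L, n_err, replace = TRUE))]
        }
      }
      ends <- rep.int(L, d)
      sites_j <- config$sites[config$sites$ref_id == ref, , drop = FALSE]
      truth <- NULL
      if (reduced && nrow(sites_j)) {
        for (k in seq_len(nrow(sites_j))) {
          p <- sites_j$position[k]
          conv <- runif(d) < sites_j$rate[k]
          m[p, conv] <- "T"
          if (sites_j$stop_rate[k] > 0) {
            stopped <- runif(d) < sites_j$stop_rate[k]
            ends[stopped] <- pmin(ends[stopped], p - 1L)
          }
        }
      }
      if (config$truncation_background > 0) {
        tb <- runif(d) < config$truncation_background
        ends[tb] <- pmin(ends[tb], sample.int(L, sum(tb), replace = TRUE))
      }
      starts <- rep.int(1L, d)
      if (!is.null(config$fragment_length)) {
        fl <- min(config$fragment_length, L)
        starts <- sample.int(L - fl + 1L, d, replace = TRUE)
        ends <- pmin(ends, starts + fl - 1L)
      }
      full <- do.call(paste0, asplit(m, 1L))
      keep <- (ends - starts + 1L) >= 15L
      if (nrow(sites_j)) {
        covered <- outer(sites_j$position, which(keep), function(p, i)
          p >= starts[i] & p <= ends[i])
        truth <- data.frame(
          ref_id = ref, position = sites_j$position,
          n_covering = rowSums(covered),
          n_T = vapply(seq_len(nrow(sites_j)), function(k) {
            i <- which(keep)[covered[k, ]]
            sum(m[sites_j$position[k], i] == "T")
          }, numeric(1)),
          stringsAsFactors = FALSE)
      }
      list(reads = substring(full[keep], starts[keep], ends[keep]),
           ids = sprintf("%s|%s|%05d", ref, config$condition,
                         which(keep)),
           truth = truth)
    })
    reads <- data.frame(
      read_id = unlist(lapply(per_ref, `[[`, "ids"), use.names = FALSE),
      sequence = unlist(lapply(per_ref, `[[`, "reads"), use.names = FALSE),
      stringsAsFactors = FALSE)
    truth <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(per_ref, `[[`, "truth")))
    structure(list(reads = reads,
                   truth = list(sites = config$sites, realized = truth,
                                seed = config$seed),
                   config = config),
              class = "trmc_sim")
  })
}

#' Simulate the three-condition chemistry design
#'
#' Convenience wrapper producing matched reduced, deacetylated and mock
#' libraries from one reference set; the three sub-seeds are derived from
#' \code{seed}.
#'
#' @inheritParams sim_config
#' @return Named list of three \code{trmc_sim} objects.
#' @export
simulate_design <- function(references, sites, depth_per_ref = 2000L,
                            background_error = 0.002, seed = 1L, ...) {
  conds <- c("reduced", "deacetylated", "mock")
  out <- lapply(seq_along(conds), function(i)
    simulate_library(sim_config(references, sites, condition = conds[i],
                                depth_per_ref = depth_per_ref,
                                background_error = background_error,
                                seed = seed + (i - 1L), ...)))
  names(out) <- conds
  out
}

#' Simulate a knockdown / control library pair
#'
#' The knockdown library scales every embedded site's conversion rate by
#' \code{misinc_multiplier} (loss of the writer reduces the modified
#' fraction) and scales the sequencing depth of every site-carrying
#' reference by \code{abundance_multiplier} (modified tRNAs are
#' destabilized); references without sites are untouched.
#'
#' @param config_control A [sim_config()] for the control condition.
#' @param misinc_multiplier,abundance_multiplier Values in \[0, 1\].
#' @param seed Integer seed (control uses \code{seed}, KD \code{seed + 1}).
#' @return list with \code{control} and \code{kd} \code{trmc_sim} objects.
#' @export
simulate_kd_pair <- function(config_control, misinc_multiplier = 0.3,
                             abundance_multiplier = 0.5, seed = 1L) {
  if (misinc_multiplier < 0 || misinc_multiplier > 1 ||
      abundance_multiplier < 0 || abundance_multiplier > 1)
    stop("multipliers must lie in [0, 1]")
  ctrl <- config_control
  ctrl$seed <- as.integer(seed)
  kd <- config_control
  kd$seed <- as.integer(seed) + 1L
  kd$sites$rate <- kd$sites$rate * misinc_multiplier
  mod_refs <- unique(kd$sites$ref_id)
  kd$depth_per_ref[mod_refs] <-
    as.integer(round(kd$depth_per_ref[mod_refs] * abundance_multiplier))
  list(control = simulate_library(ctrl), kd = simulate_library(kd))
}

#' Simulate ribosome-protected fragments over a CDS set
#'
#' Footprint P-sites are drawn over in-frame sense codons with sampling
#' weight \code{pause_factor} at \code{pause_codons} and 1 elsewhere; the
#' read 5' end is placed \code{offset} nt upstream of the P-site codon so
#' the standard offset recovers frame 0 exactly. Lengths are uniform over
#' \code{length_range}. Transcripts carry fixed-length random UTRs so
#' every footprint fits.
#'
#' @param cds Named character vector of CDS sequences (lengths divisible
#'   by 3, final codon treated as stop), or a FASTA path.
#' @param pause_codons Character vector of codons with elevated dwell.
#' @param pause_factor Sampling weight multiplier, >= 1.
#' @param n_reads Total footprints to draw.
#' @param length_range Footprint lengths, default 26:32.
#' @param offset P-site offset from the 5' end, default 12 nt.
#' @param seed Integer seed.
#' @return list: \code{placements} (read_id, transcript_id,
#'   five_prime_pos, length, sequence), \code{annotation} (transcript_id,
#'   cds_start, cds_end, gene_id), \code{transcripts}, \code{cds},
#'   \code{truth} (drawn P-site codon counts).
#' @export
simulate_rpf <- function(cds, pause_codons = character(0), pause_factor = 1,
                         n_reads = 10000L, length_range = 26:32,
                         offset = 12L, seed = 1L) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  if (inherits(cds, "DNAStringSet"))
    cds <- setNames(as.character(cds), names(cds))
  if (length(cds) == 0L) stop("empty CDS set")
  if (is.null(names(cds)) || any(names(cds) == ""))
    names(cds) <- sprintf("gene%03d", seq_along(cds))
  if (any(nchar(cds) %% 3L != 0L)) stop("CDS length must be divisible by 3")
  if (pause_factor < 1) stop("pause_factor must be >= 1")
  utr <- 3L * ceiling((offset + 3L) / 3) + 3L
  with_seed(seed, {
    utr5 <- vapply(cds, function(x)
      paste(sample(BASES, utr, replace = TRUE), collapse = ""), "")
    utr3 <- vapply(cds, function(x)
      paste(sample(BASES, utr + max(length_range), replace = TRUE),
            collapse = ""), "")
    tx <- paste0(utr5, cds, utr3)
    names(tx) <- names(cds)
    ann <- data.frame(transcript_id = names(cds), cds_start = utr + 1L,
                      cds_end = utr + nchar(cds), gene_id = names(cds),
                      stringsAsFactors = FALSE)
    n_cod <- nchar(cds) %/% 3L
    occ <- do.call(rbind, lapply(seq_along(cds), function(g) {
      i <- seq_len(n_cod[g] - 1L) - 1L           # 0-based, stop excluded
      data.frame(gene = g, codon_idx = i,
                 codon = substring(cds[g], 3L * i + 1L, 3L * i + 3L),
                 stringsAsFactors = FALSE)
    }))
    w <- ifelse(occ$codon %in% pause_codons, pause_factor, 1)
    pick <- sample.int(nrow(occ), n_reads, replace = TRUE, prob = w)
    len <- sample(length_range, n_reads, replace = TRUE)
    g <- occ$gene[pick]
    five <- ann$cds_start[g] + 3L * occ$codon_idx[pick] - offset
    placements <- data.frame(
      read_id = sprintf("rpf%06d", seq_len(n_reads)),
      transcript_id = ann$transcript_id[g],
      five_prime_pos = five, length = len,
      sequence = substring(tx[g], five, five + len - 1L),
      stringsAsFactors = FALSE)
    truth <- as.data.frame(table(codon = occ$codon[pick]),
                           stringsAsFactors = FALSE)
    list(placements = placements, annotation = ann, transcripts = tx,
         cds = cds, truth = truth)
  })
}

#' Simulate matched input / RPF / RNC count tables
#'
#' Per-gene expression weights are log-normal; input counts are Poisson at
#' the input library size, RPF and RNC counts are Poisson with the gene's
#' weight multiplied by its translation-efficiency effect (and
#' renormalized), so a gene with \code{te_effects = 2} has twice the
#' relative ribosome loading of the background.
#'
#' @param n_genes Number of genes (>= 1).
#' @param te_effects Scalar or per-gene vector of TE multipliers; recycled.
#' @param tr_effects Same for the RNC channel; defaults to
#'   \code{te_effects}.
#' @param library_sizes Named list/vector with \code{input}, \code{rpf},
#'   \code{rnc} expected totals.
#' @param seed Integer seed.
#' @return data.frame \code{gene_id}, \code{input}, \code{rpf},
#'   \code{rnc}; the generating weights are kept in
#'   \code{attr(, "expected")}.
#' @export
simulate_counts <- function(n_genes, te_effects = 1, tr_effects = te_effects,
                            library_sizes = c(input = 1e6, rpf = 1e6,
                                              rnc = 1e6),
                            seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (any(unlist(library_sizes) < 0)) stop("negative library size")
  te <- rep_len(te_effects, n_genes)
  tr <- rep_len(tr_effects, n_genes)
  with_seed(seed, {
    w <- exp(rnorm(n_genes, 0, 1))
    p_in <- w / sum(w)
    p_rpf <- w * te / sum(w * te)
    p_rnc <- w * tr / sum(w * tr)
    df <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      input = rpois(n_genes, library_sizes[["input"]] * p_in),
      rpf = rpois(n_genes, library_sizes[["rpf"]] * p_rpf),
      rnc = rpois(n_genes, library_sizes[["rnc"]] * p_rnc),
      stringsAsFactors = FALSE)
    attr(df, "expected") <- data.frame(gene_id = df$gene_id, weight = w,
                                       te = te, tr = tr)
    df
  })
}

#' Random CDS set for simulations
#'
#' Each gene is ATG, then random sense codons, then a TAA stop; useful as
#' the transcript universe for footprint and TE simulations.
#'
#' @param n_genes Number of genes.
#' @param n_codons Sense codons per gene (scalar or vector; includes the
#'   leading ATG).
#' @param seed Integer seed.
#' @return Named character vector of CDS sequences.
#' @export
random_cds_set <- function(n_genes, n_codons = 150L, seed = 1L) {
  n_codons <- rep_len(as.integer(n_codons), n_genes)
  with_seed(seed, {
    out <- vapply(seq_len(n_genes), function(g)
      paste0("ATG",
             paste(sample(sense_codons(), n_codons[g] - 1L, replace = TRUE),
                   collapse = ""),
             "TAA"), "")
    names(out) <- sprintf("gene%03d", seq_len(n_genes))
    out
  })
}

#' Write simulated reads as FASTQ
#'
#' Constant 'I' base qualities; quality modeling is out of scope.
#'
#' @param reads data.frame with \code{read_id} and \code{sequence} (e.g.
#'   \code{sim$reads}).
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#'
#' @param path FASTQ path.
#' @return data.frame with \code{read_id} and \code{sequence}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}
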