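# Reference panel construction, dereplication and gene-family screening.
#
# The panel is a tibble (one row per unique family member) carrying a
# baseline abundance that sums to 1. A k-mer index over the panel supports
# both the off-target screen and candidate preselection for alignment.

#' Load a reference amplicon panel
#'
#' Reads unique gene-family member sequences ("reference Amps") from FASTA
#' and attaches per-record baseline abundances, uniform when no table is
#' given, normalized to sum to 1 otherwise.
#'
#' @param path FASTA path.
#' @param abundances Optional path to a two-column TSV (id, abundance), or a
#'   tibble with those columns.
#' @param k K-mer size for the panel index (default 12).
#' @return An `amp_panel` tibble with columns `id`, `sequence`,
#'   `baseline_abundance`, `alpha_type`, `pseudogene`, `frame_offset`.
#' @export
load_reference_panel <- function(path, abundances = NULL, k = 12L) {
  df <- read_fasta(path)
  if (anyDuplicated(df$id)) abort("duplicate reference ids in panel FASTA")
  .check_dna(setNames(df$sequence, df$id), "reference panel")
  ab <- rep(1 / nrow(df), nrow(df))
  if (!is.null(abundances)) {
    tab <- if (is.character(abundances)) read_abundance_table(abundances) else abundances
    if (!all(df$id %in% tab$id)) abort("abundance table is missing panel ids")
    ab <- tab$abundance[match(df$id, tab$id)]
    if (any(ab < 0)) abort("negative baseline abundance")
    ab <- ab / sum(ab)
  }
  panel <- tibble(
    id = df$id, sequence = df$sequence, baseline_abundance = ab,
    alpha_type = NA_integer_, pseudogene = FALSE, frame_offset = 0L,
    epi_start = NA_integer_, epi_end = NA_integer_
  )
  new_amp_panel(panel, k = k)
}

new_amp_panel <- function(panel, k = 12L) {
  panel <- as_tibble(panel)
  attr(panel, "k") <- as.integer(k)
  attr(panel, "kmer_index") <- .build_kmer_index(panel$sequence, k)
  class(panel) <- unique(c("amp_panel", class(panel)))
  panel
}

# all k-mers of one sequence (character vector, with repeats)
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# environment mapping k-mer -> integer vector of panel row indices
.build_kmer_index <- function(sequences, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(sequences)) {
    for (km in unique(.kmers(sequences[i], k))) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  env
}

.panel_index <- function(panel, k = NULL) {
  k0 <- attr(panel, "k")
  idx <- attr(panel, "kmer_index")
  if (is.null(k)) k <- k0 %||% 12L
  if (is.null(idx) || is.null(k0) || k0 != k) {
    idx <- .build_kmer_index(panel$sequence, k)
  }
  list(k = as.integer(k), index = idx)
}

#' Annotate a panel with epitope-based Alpha types
#'
#' Translates every reference in its annotated frame, scans the configured
#' motifs and stores the resulting type (total motif hit count capped at 7)
#' and pseudogene flag on the panel.
#'
#' @param panel An `amp_panel`.
#' @param motifs Named character vector of peptide motifs
#'   (default [default_epitope_motifs()]).
#' @return The panel with `alpha_type` and `pseudogene` filled in.
#' @export
annotate_panel_types <- function(panel, motifs = default_epitope_motifs()) {
  prof <- lapply(seq_len(nrow(panel)), function(i) {
    pep <- translate_amp(panel$sequence[i], panel$frame_offset[i])
    scan_epitopes(pep, motifs)
  })
  panel$alpha_type <- vapply(prof, classify_alpha_type, integer(1))
  panel$pseudogene <- vapply(prof, function(p) p$internal_stop, logical(1))
  panel
}

#' Dereplicate reads into unique amplicons
#'
#' Collapses identical sequences into one Amp with a read count and removes
#' Amps below a minimum count. The minimum-count filter stands in for a
#' denoising stage: sequences seen fewer than `min_count` times are treated
#' as likely error reads.
#'
#' @param reads Character vector of sequences, or a tibble with a `sequence`
#'   column.
#' @param min_count Minimum read count to retain an Amp (default 2).
#' @param sample_id Sample label stored on the result.
#' @return An amp set: tibble with columns `sample_id`, `amp_id`, `sequence`,
#'   `count`, sorted by decreasing count then sequence; attributes
#'   `total_reads` and `discarded_offtarget`.
#' @export
dereplicate <- function(reads, min_count = 2L, sample_id = "sample") {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0) {
    out <- tibble(sample_id = character(), amp_id = character(),
                  sequence = character(), count = integer())
    attr(out, "total_reads") <- 0L
    attr(out, "discarded_offtarget") <- 0L
    return(out)
  }
  tab <- table(seqs)
  df <- tibble(sequence = names(tab), count = as.integer(tab)) %>%
    filter(.data$count >= min_count) %>%
    arrange(desc(.data$count), .data$sequence) %>%
    mutate(sample_id = sample_id,
           amp_id = sprintf("%s_amp%04d", sample_id, row_number())) %>%
    select("sample_id", "amp_id", "sequence", "count")
  attr(df, "total_reads") <- length(seqs)
  attr(df, "discarded_offtarget") <- 0L
  df
}

#' Re-quantify Amp abundances against raw reads
#'
#' Sets each Amp's count to the number of raw reads exactly equal to its
#' sequence (an exact-search re-mapping); reads matching no Amp are counted
#' as unassigned.
#'
#' @param ampset An amp set tibble (see [dereplicate()]).
#' @param raw_reads Character vector of raw read sequences, or tibble with a
#'   `sequence` column.
#' @return The amp set with updated counts; attributes `total_reads` and
#'   `unassigned_reads` refreshed.
#' @export
quantify_abundance <- function(ampset, raw_reads) {
  seqs <- if (is.data.frame(raw_reads)) raw_reads$sequence else raw_reads
  if (anyDuplicated(ampset$sequence)) abort("amp set sequences must be unique")
  tab <- table(seqs)
  cnt <- as.integer(tab[ampset$sequence])
  cnt[is.na(cnt)] <- 0L
  out <- ampset
  out$count <- cnt
  attr(out, "total_reads") <- length(seqs)
  attr(out, "discarded_offtarget") <- attr(ampset, "discarded_offtarget") %||% 0L
  attr(out, "unassigned_reads") <- length(seqs) - sum(cnt)
  out
}

#' Screen Amps for gene-family membership
#'
#' An Amp is retained iff the fraction of its k-mers found anywhere in the
#' reference panel is at least `min_shared_frac`. This k-mer containment
#' screen removes off-target amplification products. Defaults (`k = 12`,
#' `min_shared_frac = 0.5`) keep family members carrying even a full
#' inter-guide excision while discarding unrelated sequences.
#'
#' @param ampset Amp set tibble.
#' @param panel An `amp_panel`.
#' @param k K-mer size (>= 8).
#' @param min_shared_frac Minimum shared k-mer fraction in (0, 1].
#' @return Filtered amp set; attribute `discarded_offtarget` holds the read
#'   count removed.
#' @export
filter_gene_family <- function(ampset, panel, k = 12L, min_shared_frac = 0.5) {
  stopifnot(k >= 8L, min_shared_frac > 0, min_shared_frac <= 1)
  pidx <- .panel_index(panel, k)
  shared <- vapply(ampset$sequence, function(s) {
    kms <- .kmers(s, pidx$k)
    if (length(kms) == 0) return(NA_real_)
    mean(vapply(kms, function(z) !is.null(pidx$index[[z]]), logical(1)))
  }, numeric(1), USE.NAMES = FALSE)
  short <- is.na(shared)
  if (any(short)) warn(sprintf("%d amp(s) shorter than k = %d discarded", sum(short), k))
  keep <- !short & shared >= min_shared_frac
  out <- ampset[keep, , drop = FALSE]
  attr(out, "total_reads") <- attr(ampset, "total_reads") %||% sum(ampset$count)
  attr(out, "discarded_offtarget") <-
    (attr(ampset, "discarded_offtarget") %||% 0L) + sum(ampset$count[!keep])
  out
}

#' Write an amp set to disk
#'
#' Emits a Usearch-style FASTA (`;size=N` headers) and a TSV
#' (sample_id, amp_id, sequence, count).
#'
#' @param ampset Amp set tibble.
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @return `ampset`, invisibly.
#' @export
write_ampset <- function(ampset, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    write_fasta(tibble(id = ampset$amp_id, sequence = ampset$sequence,
                       count = ampset$count), fasta, size_annot = TRUE)
  }
  if (!is.null(tsv)) {
    readr::write_tsv(ampset[, c("sample_id", "amp_id", "sequence", "count")], tsv,
                     progress = FALSE)
  }
  invisible(ampset)
}

#' Write a reference panel to FASTA (plus abundance TSV)
#'
#' @param panel An `amp_panel`.
#' @param fasta FASTA output path.
#' @param tsv Optional abundance TSV path.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, fasta, tsv = NULL) {
  write_fasta(panel, fasta)
  if (!is.null(tsv)) {
    readr::write_tsv(
      tibble(id = panel$id, abundance = panel$baseline_abundance), tsv,
      progress = FALSE)
  }
  invisible(panel)
}
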