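# Celiac-disease epitope profiling.
#
# Alpha-gliadin amplicons are typed by the number of DQ2.5-restricted
# 9-mer epitope occurrences their translation carries: the canonical
# "33-mer" peptide holds six overlapping copies of three motifs (alpha-1a
# once, alpha-1b twice, alpha-2 three times) with the alpha-3 motif just
# downstream, so the complete region scores 7 (type Alpha7) and a member
# with no epitopes scores 0 (Alpha0). Overlapping matches must be counted:
# the motifs overlap each other inside the repeat.

#' Default DQ2.5 epitope motifs
#'
#' @return Named character vector of the four DQ2.5 alpha-gliadin epitope
#'   core motifs.
#' @export
default_epitope_motifs <- function() {
  c(DQ2.5_glia_a1a = "PFPQPQLPY",
    DQ2.5_glia_a1b = "PYPQPQLPY",
    DQ2.5_glia_a2  = "PQPQLPYPQ",
    DQ2.5_glia_a3  = "FRPQQPYPQ")
}

#' Translate an amplicon in a given frame
#'
#' Standard genetic code; trailing partial codons are dropped and stop
#' codons are retained as `*`.
#'
#' @param sequence DNA string.
#' @param frame_offset 0, 1 or 2.
#' @return Peptide string (possibly empty).
#' @export
translate_amp <- function(sequence, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  n <- nchar(sequence) - frame_offset
  n <- n - n %% 3L
  if (n < 3L) return("")
  dna <- substr(sequence, frame_offset + 1L, frame_offset + n)
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

# overlapping occurrence count via zero-width lookahead
.count_overlapping <- function(peptide, motif) {
  if (nchar(peptide) < nchar(motif)) return(0L)
  hits <- gregexpr(paste0("(?=", motif, ")"), peptide, perl = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

#' Scan a peptide for epitope motifs
#'
#' Counts every occurrence of every motif at every offset (overlaps
#' allowed).
#'
#' @param peptide Peptide string.
#' @param motifs Named character vector of motifs
#'   (default [default_epitope_motifs()]).
#' @param p31_43 Optional peptide motif tracked separately from the DQ2.5
#'   count (default `NULL`).
#' @return An `epitope_profile` list: `motif_hits` (named integer),
#'   `total_hits` (sum over `motifs`), `p31_43_present`, `internal_stop`.
#' @export
scan_epitopes <- function(peptide, motifs = default_epitope_motifs(),
                          p31_43 = NULL) {
  stopifnot(length(motifs) > 0)
  hits <- vapply(motifs, .count_overlapping, integer(1), peptide = peptide)
  star <- regexpr("*", peptide, fixed = TRUE)[1]
  structure(list(
    motif_hits = hits,
    total_hits = sum(hits),
    p31_43_present = if (is.null(p31_43)) NA else .count_overlapping(peptide, p31_43) > 0,
    internal_stop = star != -1 && star < nchar(peptide)
  ), class = "epitope_profile")
}

#' Classify an epitope profile into an Alpha type
#'
#' The type index equals the total DQ2.5 hit count, capped at 7 (the
#' complete 33-mer plus the downstream alpha-3 motif). A profile whose
#' translation hits an internal stop codon is a pseudogene and gets
#' `NA_integer_`.
#'
#' @param profile An `epitope_profile` from [scan_epitopes()].
#' @return Integer 0-7, or `NA` for pseudogenes.
#' @export
classify_alpha_type <- function(profile) {
  if (isTRUE(profile$internal_stop)) return(NA_integer_)
  as.integer(min(profile$total_hits, 7L))
}

#' Relative epitope loss across a sample
#'
#' For each motif e, the loss aggregates over references r carrying it:
#' \deqn{loss(e) = 100 \sum_r hits_e(r)\, a_r\, d_{e}(r) \Big/
#'   \sum_{r:\,hits_e(r) \ge 1} a_r}
#' where \eqn{a_r} is the baseline abundance and \eqn{d_e(r)} the abundance
#' fraction of amps assigned to r whose re-scanned translation lost at
#' least one occurrence of e. Because references carry multiple copies of a
#' motif, individual and combined losses can exceed 100%. Re-scanning (not
#' coordinate bookkeeping) decides loss, so substitutions and frameshifts
#' that break a motif count too.
#'
#' @param classified Classified-amp tibble (see [classify_amps()]).
#' @param panel An annotated `amp_panel`.
#' @param motifs Named motif vector.
#' @param p31_43 Optional p31-43 motif; when given, its loss joins the
#'   combined total.
#' @return A tibble `(motif, loss_pct)` plus one `combined` row.
#' @export
relative_epitope_loss <- function(classified, panel,
                                  motifs = default_epitope_motifs(),
                                  p31_43 = NULL) {
  all_motifs <- motifs
  if (!is.null(p31_43)) all_motifs <- c(all_motifs, p31_43 = p31_43)
  ref_pep <- setNames(
    vapply(seq_len(nrow(panel)),
           function(i) translate_amp(panel$sequence[i], panel$frame_offset[i]),
           character(1)),
    panel$id)
  ref_hits <- vapply(all_motifs, function(m) {
    vapply(ref_pep, .count_overlapping, integer(1), motif = m)
  }, integer(nrow(panel)))
  if (nrow(panel) == 1L) ref_hits <- matrix(ref_hits, nrow = 1,
                                            dimnames = list(panel$id, names(all_motifs)))
  # per-amp re-scan, in the frame of the assigned reference
  amp_hits <- NULL
  if (nrow(classified) > 0) {
    fo <- panel$frame_offset[match(classified$ref_id, panel$id)]
    amp_hits <- vapply(all_motifs, function(m) {
      vapply(seq_len(nrow(classified)), function(i) {
        .count_overlapping(translate_amp(classified$sequence[i], fo[i]), m)
      }, integer(1))
    }, integer(nrow(classified)))
    if (nrow(classified) == 1L) amp_hits <- matrix(amp_hits, nrow = 1)
  }
  loss <- vapply(seq_along(all_motifs), function(e) {
    carriers <- which(ref_hits[, e] >= 1)
    if (length(carriers) == 0) return(NA_real_)
    denom <- sum(panel$baseline_abundance[carriers])
    num <- 0
    for (r in carriers) {
      assigned <- which(classified$ref_id == panel$id[r])
      if (length(assigned) == 0) next
      tot <- sum(classified$count[assigned])
      lost <- sum(classified$count[assigned][amp_hits[assigned, e] < ref_hits[r, e]])
      dfrac <- if (tot > 0) lost / tot else 0
      num <- num + ref_hits[r, e] * panel$baseline_abundance[r] * dfrac
    }
    100 * num / denom
  }, numeric(1))
  out <- tibble(motif = names(all_motifs), loss_pct = loss)
  combined <- sum(loss[names(all_motifs) %in% c(names(motifs), "p31_43")], na.rm = TRUE)
  bind_rows(out, tibble(motif = "combined", loss_pct = combined))
}
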