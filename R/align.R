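# Affine-gap alignment of sample Amps to the closest reference.
#
# Two modes stand behind the reference assignment: a Smith-Waterman local
# alignment (fast, clips divergent ends) and a semi-global alignment with
# free end gaps on both sequences, which recovers large interior deletions
# that local alignment truncates. Both run the same Gotoh kernel with a
# deterministic traceback (M/X preferred over D over I), so identical inputs
# give identical single paths on every platform.

#' Alignment scoring scheme
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (>= 0, applied negatively).
#' @param gap_open Gap-open penalty (>= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap-extension penalty (>= 0).
#' @return A `scoring` list.
#' @export
scoring <- function(match = 2, mismatch = 3, gap_open = 6, gap_extend = 1) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring")
}

#' Default scoring for local alignment
#' @return A [scoring()] object (match 2, mismatch 3, gap open 6, extend 1).
#' @export
scoring_local <- function() scoring(2, 3, 6, 1)

#' Default scoring for semi-global alignment
#'
#' The near-free gap extension (0.1 per base) makes one long deletion
#' preferable to fragmentary mismatch runs, so inter-guide excisions align
#' as a single D operation.
#' @return A [scoring()] object (match 2, mismatch 3, gap open 6, extend 0.1).
#' @export
scoring_global <- function() scoring(2, 3, 6, 0.1)

.gotoh <- function(query, ref, sc, mode) {
  r <- .gotoh_align_cpp(query, ref, sc$match, sc$mismatch,
                        sc$gap_open, sc$gap_extend, mode)
  ops <- tibble::new_tibble(list(op = as.character(r$op),
                                 len = as.integer(r$len)),
                            nrow = length(r$op))
  n_match <- sum(ops$len[ops$op == "M"])
  qlen <- nchar(query)
  clipped <- if (mode == "local") qlen - (r$query_end - r$query_start) else 0L
  structure(list(
    ref_id = NA_character_, mode = if (mode == "local") "local" else "global",
    score = r$score, ops = ops,
    query_start = r$query_start, query_end = r$query_end,
    ref_start = r$ref_start, ref_end = r$ref_end,
    query_clipped = as.integer(clipped),
    n_match = n_match, identity = n_match / qlen
  ), class = "amp_alignment")
}

#' Local (Smith-Waterman) affine-gap alignment
#'
#' @param query,ref DNA sequences (character scalars).
#' @param sc A [scoring()] scheme (default [scoring_local()]).
#' @return An `amp_alignment`: score, op runs (M/X/I/D tibble), aligned
#'   intervals on both sequences (0-based half-open), clipped query bases,
#'   and identity (matches / query length).
#' @export
align_local <- function(query, ref, sc = scoring_local()) {
  stopifnot(nchar(query) > 0, nchar(ref) > 0)
  .gotoh(query, ref, sc, "local")
}

#' Semi-global affine-gap alignment with free end gaps
#'
#' End gaps on either sequence are unpenalized and reported as start/end
#' offsets, never as indel operations, so alignment ends can not produce
#' spurious edge events.
#'
#' @inheritParams align_local
#' @return An `amp_alignment` (see [align_local()]); `query_clipped` is 0.
#' @export
align_global <- function(query, ref, sc = scoring_global()) {
  stopifnot(nchar(query) > 0, nchar(ref) > 0)
  .gotoh(query, ref, sc, "overlap")
}

#' @export
print.amp_alignment <- function(x, ...) {
  cigar <- paste0(x$ops$len, x$ops$op, collapse = "")
  cat(sprintf("<amp_alignment> %s score=%.1f ref=%s [%d,%d) query=[%d,%d) %s\n",
              x$mode, x$score, x$ref_id %||% "?", x$ref_start, x$ref_end,
              x$query_start, x$query_end, cigar))
  invisible(x)
}

# shared k-mer counts of one sequence against every panel reference
.shared_kmer_counts <- function(seq, panel) {
  pidx <- .panel_index(panel)
  counts <- numeric(nrow(panel))
  for (km in unique(.kmers(seq, pidx$k))) {
    hits <- pidx$index[[km]]
    if (!is.null(hits)) counts[hits] <- counts[hits] + 1
  }
  counts
}

#' Assign an Amp to its closest reference
#'
#' Candidates are preselected by shared k-mer count (top `top_c`); the best
#' local alignment wins unless it clips more than `clip_frac` of the query,
#' in which case the semi-global alignment of the same candidates is used
#' when its identity is higher (large deletions align globally). Ties break
#' by higher score, then higher baseline abundance, then lexicographic id.
#'
#' @param seq Amp sequence.
#' @param panel An `amp_panel`.
#' @param sc_local,sc_global Scoring schemes for the two modes.
#' @param top_c Number of k-mer-preselected candidates (default 8).
#' @param clip_frac Clipped-query fraction triggering the global fallback
#'   (default 0.15).
#' @param exhaustive Align against every reference, skipping preselection.
#' @return A list `(ref = <one-row panel tibble>, alignment)` or `NULL` when
#'   no reference shares a k-mer (unalignable).
#' @export
choose_reference <- function(seq, panel, sc_local = scoring_local(),
                             sc_global = scoring_global(), top_c = 8L,
                             clip_frac = 0.15, exhaustive = FALSE) {
  if (exhaustive) {
    cand <- seq_len(nrow(panel))
  } else {
    counts <- .shared_kmer_counts(seq, panel)
    if (all(counts == 0)) return(NULL)
    ord <- order(-counts, -panel$baseline_abundance, panel$id)
    cand <- head(ord[counts[ord] > 0], top_c)
  }
  pick <- function(alns) {
    score <- vapply(alns, function(a) a$score, numeric(1))
    ord <- order(-score, -panel$baseline_abundance[cand], panel$id[cand])
    ord[1]
  }
  loc <- lapply(cand, function(i) align_local(seq, panel$sequence[i], sc_local))
  bi <- pick(loc)
  best <- loc[[bi]]; best_i <- cand[bi]
  if (best$query_clipped > clip_frac * nchar(seq)) {
    glo <- lapply(cand, function(i) align_global(seq, panel$sequence[i], sc_global))
    gi <- pick(glo)
    if (glo[[gi]]$identity > best$identity) {
      best <- glo[[gi]]; best_i <- cand[gi]
    }
  }
  best$ref_id <- panel$id[best_i]
  list(ref = panel[best_i, , drop = FALSE], alignment = best)
}
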