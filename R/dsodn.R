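# Targeted dsODN insertion detection.
#
# A double-stranded oligodeoxynucleotide delivered with the nuclease can be
# captured at a cut by NHEJ in either orientation, in two scenarios:
# (i) single_cut -- inserted at one guide's cut site, or (ii) replacement --
# inserted between two guide sites whose intervening fragment was excised.
# Detection matches each inserted sequence against the dsODN top strand and
# its reverse complement by local alignment.

#' Specify a dsODN
#'
#' @param name dsODN name.
#' @param top_strand Top-strand sequence (typically 51 or 75 nt).
#' @param end_type `"blunt"` or `"overhang"` end chemistry (annotation
#'   only; both chemistries are detected identically).
#' @param min_identity Minimum alignment identity over the aligned region
#'   (default 0.9).
#' @param min_covered_frac Minimum fraction of the dsODN covered by the
#'   alignment (default 0.8).
#' @return A `dsodn_spec` list.
#' @export
dsodn_spec <- function(name, top_strand, end_type = c("blunt", "overhang"),
                       min_identity = 0.9, min_covered_frac = 0.8) {
  end_type <- match.arg(end_type)
  top_strand <- toupper(top_strand)
  .check_dna(setNames(top_strand, name), "dsODN top strand")
  stopifnot(min_identity > 0, min_identity <= 1,
            min_covered_frac > 0, min_covered_frac <= 1)
  structure(list(name = name, top_strand = top_strand, end_type = end_type,
                 min_identity = min_identity,
                 min_covered_frac = min_covered_frac),
            class = "dsodn_spec")
}

# identity and coverage of an inserted sequence vs one dsODN strand
.dsodn_match <- function(inserted, strand_seq, sc) {
  aln <- align_local(inserted, strand_seq, sc)
  cols <- sum(aln$ops$len)
  list(score = aln$score,
       identity = if (cols > 0) aln$n_match / cols else 0,
       coverage = (aln$ref_end - aln$ref_start) / nchar(strand_seq))
}

#' Detect a targeted dsODN insertion on one classified Amp
#'
#' Each insertion event is aligned against the dsODN top strand and its
#' reverse complement; a call requires identity of at least `min_identity`
#' over at least `min_covered_frac` of the dsODN, with the insertion point
#' inside a cut window. The better-matching strand gives the orientation. The
#' scenario is `replacement` when the same Amp carries a deletion spanning
#' at least two expected cuts, else `single_cut`. Insertions matching the
#' dsODN outside every cut window yield no call (they stay non-targeted).
#'
#' @param amp_row One row of a classified tibble (see [classify_amps()]).
#' @param spec A [dsodn_spec()].
#' @param sites Site tibble for the Amp's reference.
#' @param sc Local alignment scoring for the dsODN match.
#' @return A one-row call tibble (`amp_id`, `orientation`, `scenario`,
#'   `identity`, `coverage`, `guides_covered`, `insertion_pos`,
#'   `insertion_len`, `count`) or `NULL`.
#' @export
detect_dsodn <- function(amp_row, spec, sites, sc = scoring_local()) {
  ev <- amp_row$events[[1]]
  ins <- which(ev$kind == "insertion")
  if (length(ins) == 0) return(NULL)
  rc <- .revcomp(spec$top_strand)
  for (i in ins) {
    pos <- ev$ref_pos[i]
    in_window <- nrow(sites) > 0 &&
      any(sites$window_start <= pos & pos < sites$window_end)
    if (!in_window) next
    fwd <- .dsodn_match(ev$inserted_seq[i], spec$top_strand, sc)
    rev <- .dsodn_match(ev$inserted_seq[i], rc, sc)
    best <- if (rev$score > fwd$score) c(rev, orientation = "reverse")
            else c(fwd, orientation = "forward")
    if (best$identity < spec$min_identity ||
        best$coverage < spec$min_covered_frac) next
    # replacement when a co-occurring deletion spans >= 2 expected cuts
    del <- which(ev$kind == "deletion")
    spanned <- character(0)
    for (d in del) {
      gv <- .cuts_covered(ev$ref_pos[d], ev$ref_pos[d] + ev$length[d], sites)
      if (length(gv) > length(spanned)) spanned <- gv
    }
    scenario <- if (length(spanned) >= 2) "replacement" else "single_cut"
    guides <- if (scenario == "replacement") {
      union(spanned, ev$guides[[i]])
    } else {
      ev$guides[[i]]
    }
    return(tibble(
      amp_id = amp_row$amp_id, dsodn = spec$name,
      orientation = best$orientation, scenario = scenario,
      identity = best$identity, coverage = best$coverage,
      guides_covered = list(guides),
      insertion_pos = pos, insertion_len = ev$length[i],
      count = amp_row$count))
  }
  NULL
}

#' Detect dsODN insertions across a classified sample
#'
#' Applies [detect_dsodn()] to every Amp carrying an insertion and updates
#' the Amp category to `dsodn_targeted` where a call is made.
#'
#' @param classified Classified tibble.
#' @param specs List of [dsodn_spec()] objects.
#' @param sites Site tibble.
#' @param sc Local scoring for the dsODN match.
#' @return List: `classified` (categories updated), `calls` (call tibble).
#' @export
detect_dsodn_sample <- function(classified, specs, sites, sc = scoring_local()) {
  calls <- list()
  for (i in seq_len(nrow(classified))) {
    ref_sites <- sites[sites$ref_id == classified$ref_id[i], , drop = FALSE]
    for (spec in specs) {
      call <- detect_dsodn(classified[i, ], spec, ref_sites, sc)
      if (!is.null(call)) {
        calls[[length(calls) + 1]] <- call
        classified$category[i] <- "dsodn_targeted"
        break
      }
    }
  }
  calls <- if (length(calls)) bind_rows(calls) else tibble(
    amp_id = character(), dsodn = character(), orientation = character(),
    scenario = character(), identity = numeric(), coverage = numeric(),
    guides_covered = list(), insertion_pos = integer(),
    insertion_len = integer(), count = integer())
  list(classified = classified, calls = calls)
}

#' dsODN insertion frequency per orientation
#'
#' The frequency of each orientation is its abundance-weighted share of ALL
#' insertion events in the sample, targeted and non-targeted alike.
#'
#' @param calls Call tibble from [detect_dsodn_sample()].
#' @param classified Classified tibble (for the denominator).
#' @return Tibble `(orientation, frequency_pct)`; `NA` when the sample has
#'   no insertions at all.
#' @export
dsodn_frequency <- function(calls, classified) {
  evt <- .event_table(classified)
  total_ins <- sum(evt$count[evt$kind == "insertion"])
  out <- tibble(orientation = c("forward", "reverse"))
  if (total_ins == 0) {
    out$frequency_pct <- NA_real_
    return(out)
  }
  out$frequency_pct <- vapply(out$orientation, function(o) {
    100 * sum(calls$count[calls$orientation == o]) / total_ins
  }, numeric(1), USE.NAMES = FALSE)
  out
}
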