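# Indel events on reference coordinates, and their normalization.
#
# Deletions carry the start of the deleted reference span; insertions carry
# a between-base index. `signed_length` is negative for deletions (so the
# canonical full excision of the 33-mer region appears as -129). In
# repetitive sequence one edit has many equivalent placements; events are
# normalized to the placement that maximizes overlap with the guide cut
# windows (left-aligned when no placement touches a window), which never
# changes the edited haplotype.

.empty_events <- function() {
  tibble(kind = character(), ref_pos = integer(), length = integer(),
         signed_length = integer(), inserted_seq = character(),
         normalized = logical())
}

#' Extract indel events from an alignment
#'
#' One event per I/D run; substitutions (X) never produce events, and end
#' gaps / clipped ends are not events.
#'
#' @param aln An `amp_alignment`.
#' @param query The query sequence the alignment was computed from (needed
#'   to recover inserted bases).
#' @return Event tibble: `kind`, `ref_pos`, `length`, `signed_length`,
#'   `inserted_seq`, `normalized`.
#' @export
extract_indels <- function(aln, query) {
  ops <- aln$ops
  if (nrow(ops) == 0) return(.empty_events())
  rows <- list()
  rpos <- aln$ref_start
  qpos <- aln$query_start
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "X")) {
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      rows[[length(rows) + 1]] <- tibble(
        kind = "deletion", ref_pos = rpos, length = len,
        signed_length = -len, inserted_seq = NA_character_,
        normalized = FALSE)
      rpos <- rpos + len
    } else if (op == "I") {
      rows[[length(rows) + 1]] <- tibble(
        kind = "insertion", ref_pos = rpos, length = len,
        signed_length = len,
        inserted_seq = substr(query, qpos + 1L, qpos + len),
        normalized = FALSE)
      qpos <- qpos + len
    }
  }
  if (length(rows) == 0) return(.empty_events())
  bind_rows(rows)
}

# enumerate every placement of a deletion equivalent to deleting
# ref[pos, pos+len) (0-based); returns integer vector of candidate positions
.del_placements <- function(ref, pos, len) {
  rc <- strsplit(ref, "")[[1]]
  n <- length(rc)
  p <- pos
  while (p > 0 && rc[p] == rc[p + len]) p <- p - 1L   # rc is 1-based: ref[p-1]==ref[p+len-1]
  left <- p
  p <- pos
  while (p + len < n && rc[p + 1L] == rc[p + len + 1L]) p <- p + 1L
  seq.int(left, p)
}

# placements of inserting `s` at between-base index pos; returns tibble of
# (pos, seq) since the inserted string rotates as it shifts
.ins_placements <- function(ref, pos, s) {
  rc <- strsplit(ref, "")[[1]]
  n <- length(rc)
  L <- nchar(s)
  ss <- strsplit(s, "")[[1]]
  # shift left: allowed when last inserted char equals ref char left of point
  p <- pos; cur <- ss; out_pos <- pos; out_seq <- s
  while (p > 0 && cur[L] == rc[p]) {
    cur <- c(rc[p], cur[-L])
    p <- p - 1L
    out_pos <- c(p, out_pos); out_seq <- c(paste(cur, collapse = ""), out_seq)
  }
  # shift right from the original placement
  p <- pos; cur <- ss
  while (p < n && cur[1] == rc[p + 1L]) {
    cur <- c(cur[-1], rc[p + 1L])
    p <- p + 1L
    out_pos <- c(out_pos, p); out_seq <- c(out_seq, paste(cur, collapse = ""))
  }
  tibble(pos = as.integer(out_pos), seq = out_seq)
}

.window_overlap_del <- function(pos, len, windows) {
  if (nrow(windows) == 0) return(0)
  sum(pmax(0, pmin(pos + len, windows$window_end) - pmax(pos, windows$window_start)))
}

.window_overlap_ins <- function(pos, windows) {
  if (nrow(windows) == 0) return(0)
  sum(windows$window_start <= pos & pos < windows$window_end)
}

#' Normalize one indel event toward guide cut windows
#'
#' The event is moved within its equivalence class (placements producing the
#' same edited sequence): among all placements the one with maximal total
#' cut-window overlap wins, ties going to the leftmost, so an edit in a
#' repeat run is pulled into the cut window it most plausibly came from.
#' Events abutting another event on the same Amp (complex edits such as an
#' excision-plus-insertion replacement signature) are left in place: their
#' placements are not independent.
#'
#' @param ev One-row event tibble.
#' @param ref Reference sequence.
#' @param windows Tibble with `window_start`, `window_end` columns (possibly
#'   empty).
#' @return The event, possibly shifted, with `normalized = TRUE`.
#' @export
normalize_indel <- function(ev, ref, windows) {
  if (ev$kind == "deletion") {
    cand <- .del_placements(ref, ev$ref_pos, ev$length)
    ov <- vapply(cand, .window_overlap_del, numeric(1), len = ev$length,
                 windows = windows)
    best <- cand[which.max(ov)]   # which.max: first (leftmost) maximum
    ev$ref_pos <- best
  } else {
    cand <- .ins_placements(ref, ev$ref_pos, ev$inserted_seq)
    ov <- vapply(cand$pos, .window_overlap_ins, numeric(1), windows = windows)
    i <- which.max(ov)
    ev$ref_pos <- cand$pos[i]
    ev$inserted_seq <- cand$seq[i]
  }
  ev$normalized <- TRUE
  ev
}

#' Normalize all events of one Amp
#'
#' @param events Event tibble (one Amp).
#' @param ref Reference sequence.
#' @param windows Cut-window tibble.
#' @return Event tibble with placements normalized, sorted by position.
#' @export
normalize_indels <- function(events, ref, windows) {
  if (nrow(events) == 0) return(events)
  # spans on the reference; insertions occupy a zero-width point
  starts <- events$ref_pos
  ends <- events$ref_pos + ifelse(events$kind == "deletion", events$length, 0L)
  out <- events
  for (i in seq_len(nrow(events))) {
    adjacent <- any(vapply(seq_len(nrow(events)), function(j) {
      if (j == i) return(FALSE)
      starts[j] <= ends[i] + 1L && starts[i] <= ends[j] + 1L
    }, logical(1)))
    if (adjacent) {
      out$normalized[i] <- TRUE   # placement kept; flagged as processed
    } else {
      out[i, ] <- normalize_indel(events[i, ], ref, windows)
    }
  }
  arrange(out, .data$ref_pos)
}

#' Apply indel events to a reference sequence
#'
#' Reconstructs the edited haplotype implied by a set of events; used by the
#' simulator and by the normalization invariants (normalization must never
#' change the reconstructed sequence).
#'
#' @param ref Reference sequence.
#' @param events Event tibble.
#' @return The edited sequence (character scalar).
#' @export
apply_indels <- function(ref, events) {
  if (nrow(events) == 0) return(ref)
  # right-to-left so earlier positions stay valid; at equal positions the
  # deletion must be applied before the insertion (replacement signature)
  ev <- arrange(events, desc(.data$ref_pos), .data$kind)
  out <- ref
  for (i in seq_len(nrow(ev))) {
    p <- ev$ref_pos[i]
    if (ev$kind[i] == "deletion") {
      out <- paste0(substr(out, 1, p), substr(out, p + ev$length[i] + 1L, nchar(out)))
    } else {
      out <- paste0(substr(out, 1, p), ev$inserted_seq[i],
                    substr(out, p + 1L, nchar(out)))
    }
  }
  out
}
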