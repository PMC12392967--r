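# Edit classification and abundance-weighted sample statistics.
#
# An Amp is wild-type, a single-guide indel carrier, a multi-guide excision
# (one deletion spanning at least two expected cut positions), a dsODN
# target, or an unassigned-indel carrier (events touching no cut window --
# likely PCR/sequencing artifacts, reported but excluded from editing
# percentages). All percentages are weighted by Amp read counts.

#' Assign events to guides by cut-window overlap
#'
#' A deletion is assigned to every guide whose window it intersects; an
#' insertion to every guide whose window contains its insertion point.
#'
#' @param events Event tibble (one Amp).
#' @param sites Site tibble for the Amp's reference (with windows).
#' @return The events with a `guides` list-column of guide names (possibly
#'   empty character vectors).
#' @export
assign_events <- function(events, sites) {
  if (nrow(events) == 0) {
    events$guides <- list()
    return(events)
  }
  events$guides <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (nrow(sites) == 0) return(character(0))
    hit <- if (ev$kind == "deletion") {
      ev$ref_pos < sites$window_end & sites$window_start < ev$ref_pos + ev$length
    } else {
      sites$window_start <= ev$ref_pos & ev$ref_pos < sites$window_end
    }
    unique(sites$guide[hit])
  })
  events
}

# cuts covered by a deletion: expected cut c with start <= c <= end
.cuts_covered <- function(del_start, del_end, sites) {
  hit <- del_start <= sites$expected_cut & sites$expected_cut <= del_end
  unique(sites$guide[hit])
}

#' Detect a multi-guide excision on one Amp
#'
#' An excision requires ONE deletion containing at least two distinct
#' guides' expected cut positions (two adjacent small deletions do not
#' qualify). Frame status uses the net signed length of all events.
#'
#' @param events Assigned event tibble (one Amp).
#' @param sites Site tibble for the Amp's reference.
#' @return List: `category`, `frame_status`, `net_signed`, `excised_start`,
#'   `excised_end`, `excision_guides`.
#' @export
detect_excision <- function(events, sites) {
  net <- if (nrow(events)) sum(events$signed_length) else 0L
  res <- list(category = "wild_type", frame_status = "not_applicable",
              net_signed = as.integer(net),
              excised_start = NA_integer_, excised_end = NA_integer_,
              excision_guides = character(0))
  if (nrow(events) == 0) return(res)
  res$frame_status <- if (net %% 3L == 0L) "in_frame" else "frameshift"
  assigned <- vapply(events$guides, length, integer(1)) > 0
  dels <- which(events$kind == "deletion")
  best <- character(0)
  for (i in dels) {
    gv <- .cuts_covered(events$ref_pos[i], events$ref_pos[i] + events$length[i],
                        sites)
    if (length(gv) >= 2 && length(gv) > length(best)) {
      best <- gv
      res$excised_start <- events$ref_pos[i]
      res$excised_end <- events$ref_pos[i] + events$length[i]
    }
  }
  if (length(best) >= 2) {
    res$category <- "multi_guide_excision"
    res$excision_guides <- best
  } else if (any(assigned)) {
    res$category <- "single_guide_indel"
  } else {
    res$category <- "unassigned_indel"
  }
  res
}

# Canonical edit haplotypes expected at the guide cuts of one reference:
# the inter-cut excision, the excision with the dsODN at the junction
# (both orientations) and single-cut dsODN captures. Returns a list of
# (sequence, events) candidates.
.edit_templates <- function(ref_seq, ref_sites, dsodn = list()) {
  cuts <- sort(unique(ref_sites$expected_cut[ref_sites$seed_perfect]))
  out <- list()
  add <- function(events) {
    out[[length(out) + 1]] <<- list(sequence = apply_indels(ref_seq, events),
                                    events = events)
  }
  del_ev <- function(a, b) tibble(
    kind = "deletion", ref_pos = as.integer(a), length = as.integer(b - a),
    signed_length = as.integer(-(b - a)), inserted_seq = NA_character_,
    normalized = TRUE)
  ins_ev <- function(p, s) tibble(
    kind = "insertion", ref_pos = as.integer(p), length = nchar(s),
    signed_length = nchar(s), inserted_seq = s, normalized = TRUE)
  strands <- unlist(lapply(dsodn, function(d) {
    c(d$top_strand, .revcomp(d$top_strand))
  }))
  if (length(cuts) >= 2) {
    pairs <- utils::combn(cuts, 2, simplify = FALSE)
    for (pr in pairs) {
      add(del_ev(pr[1], pr[2]))
      for (s in strands) add(bind_rows(del_ev(pr[1], pr[2]), ins_ev(pr[1], s)))
    }
  }
  for (ct in cuts) for (s in strands) add(ins_ev(ct, s))
  out
}

# rescue a read that is a near-exact match to a canonical edit haplotype
# (Hamming over equal length); returns its events or NULL
.template_rescue <- function(seq, ref_seq, ref_sites, dsodn,
                             max_mm_frac = 0.02, cache = NULL) {
  if (seq == ref_seq) return(NULL)
  key <- if (nrow(ref_sites)) ref_sites$ref_id[1] else "none"
  tmpl <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
          else .edit_templates(ref_seq, ref_sites, dsodn)
  if (!is.null(cache)) cache[[key]] <- tmpl
  best <- NULL; best_d <- Inf
  n <- nchar(seq)
  sc <- NULL
  for (tp in tmpl) {
    if (nchar(tp$sequence) != n) next
    if (is.null(sc)) sc <- strsplit(seq, "")[[1]]
    d <- sum(sc != strsplit(tp$sequence, "")[[1]])
    if (d <= max_mm_frac * n && d < best_d) { best <- tp; best_d <- d }
  }
  if (is.null(best)) return(NULL)
  ev <- best$events
  # inserted bases come from the read itself (it may carry errors)
  for (i in which(ev$kind == "insertion")) {
    ofs <- 0L
    for (j in seq_len(nrow(ev))) {
      # an equal-position deletion (replacement signature) deletes bases
      # situated after the insertion point, so it does not shift the insert
      if (j == i || ev$ref_pos[j] >= ev$ref_pos[i]) next
      if (ev$kind[j] == "insertion") ofs <- ofs + ev$length[j]
      else ofs <- ofs - ev$length[j]
    }
    at <- ev$ref_pos[i] + ofs
    ev$inserted_seq[i] <- substr(seq, at + 1L, at + ev$length[i])
  }
  ev
}

#' Classify every Amp of a sample
#'
#' Runs reference assignment, indel extraction, normalization, guide
#' assignment and excision detection over an amp set. Before dynamic
#' programming is trusted, each Amp is compared against the canonical edit
#' haplotypes implied by the reference's cut sites (inter-cut excision,
#' dsODN replacement and single-cut capture): a near-exact match takes the
#' canonical event representation. This targeted realignment keeps large
#' excision/replacement signatures intact where a free alignment would
#' fragment the inserted oligo against the excised span into spurious
#' small indels.
#'
#' @param ampset Amp set tibble (family-filtered).
#' @param panel Annotated `amp_panel`.
#' @param sites Site tibble from [guide_sites()].
#' @param sc_local,sc_global Scoring schemes.
#' @param top_c,clip_frac Reference-choice parameters (see
#'   [choose_reference()]).
#' @param dsodn Optional list of [dsodn_spec()] objects used to build
#'   replacement templates.
#' @return Classified tibble: one row per Amp with `ref_id`, `alpha_type`,
#'   `mode`, `identity`, `category`, `frame_status`, `net_signed`,
#'   excision span and a nested `events` list-column; unalignable Amps are
#'   dropped and counted in attribute `n_unalignable` /
#'   `unalignable_reads`.
#' @export
classify_amps <- function(ampset, panel, sites,
                          sc_local = scoring_local(),
                          sc_global = scoring_global(),
                          top_c = 8L, clip_frac = 0.15, dsodn = list()) {
  rows <- list()
  n_unalignable <- 0L
  unalignable_reads <- 0L
  mode_reads <- c(local = 0L, global = 0L)
  template_cache <- new.env(parent = emptyenv())
  # fast path: reads identical (or near-identical, substitutions only) to a
  # same-length reference skip the DP entirely
  ref_ints <- lapply(panel$sequence, utf8ToInt)
  ref_lens <- nchar(panel$sequence)
  hamming_pick <- function(seq_i, max_frac = 0.02) {
    n <- nchar(seq_i)
    cand <- which(ref_lens == n)
    if (length(cand) == 0) return(NULL)
    a <- utf8ToInt(seq_i)
    d <- vapply(cand, function(r) sum(a != ref_ints[[r]]), numeric(1))
    ord <- order(d, -panel$baseline_abundance[cand], panel$id[cand])
    best <- cand[ord[1]]
    if (d[ord[1]] > max_frac * n) return(NULL)
    mism <- d[ord[1]]
    sc <- sc_local
    eq <- a == ref_ints[[best]]
    runs <- rle(eq)
    list(idx = best, alignment = structure(list(
      ref_id = panel$id[best], mode = "local",
      score = sc$match * sum(eq) - sc$mismatch * mism,
      ops = tibble::new_tibble(list(op = ifelse(runs$values, "M", "X"),
                                    len = as.integer(runs$lengths)),
                               nrow = length(runs$values)),
      query_start = 0L, query_end = n, ref_start = 0L, ref_end = n,
      query_clipped = 0L, n_match = sum(eq), identity = sum(eq) / n),
      class = "amp_alignment"))
  }
  for (i in seq_len(nrow(ampset))) {
    seq_i <- ampset$sequence[i]
    hp <- hamming_pick(seq_i)
    ch <- if (!is.null(hp)) {
      list(ref = panel[hp$idx, , drop = FALSE], alignment = hp$alignment)
    } else {
      choose_reference(seq_i, panel, sc_local, sc_global, top_c, clip_frac)
    }
    if (is.null(ch)) {
      n_unalignable <- n_unalignable + 1L
      unalignable_reads <- unalignable_reads + ampset$count[i]
      next
    }
    ref <- ch$ref; aln <- ch$alignment
    mode_reads[aln$mode] <- mode_reads[aln$mode] + ampset$count[i]
    ref_sites <- sites[sites$ref_id == ref$id, , drop = FALSE]
    ev <- .template_rescue(seq_i, ref$sequence, ref_sites, dsodn,
                           cache = template_cache)
    if (is.null(ev)) {
      ev <- extract_indels(aln, seq_i)
      ev <- normalize_indels(ev, ref$sequence, ref_sites)
    }
    ev <- assign_events(ev, ref_sites)
    cls <- detect_excision(ev, ref_sites)
    rows[[length(rows) + 1]] <- tibble(
      amp_id = ampset$amp_id[i], sequence = seq_i, count = ampset$count[i],
      ref_id = ref$id, alpha_type = ref$alpha_type,
      pseudogene = ref$pseudogene,
      mode = aln$mode, score = aln$score, identity = aln$identity,
      category = cls$category, frame_status = cls$frame_status,
      net_signed = cls$net_signed,
      excised_start = cls$excised_start, excised_end = cls$excised_end,
      excision_guides = list(cls$excision_guides),
      events = list(ev))
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    amp_id = character(), sequence = character(), count = integer(),
    ref_id = character(), alpha_type = integer(), pseudogene = logical(),
    mode = character(), score = numeric(), identity = numeric(),
    category = character(), frame_status = character(),
    net_signed = integer(), excised_start = integer(),
    excised_end = integer(), excision_guides = list(), events = list())
  attr(out, "n_unalignable") <- n_unalignable
  attr(out, "unalignable_reads") <- unalignable_reads
  attr(out, "mode_reads") <- mode_reads
  out
}

.EDITED_CATEGORIES <- c("single_guide_indel", "multi_guide_excision",
                        "dsodn_targeted")

# flatten the nested events of a classified tibble, carrying amp abundance
.event_table <- function(classified) {
  if (nrow(classified) == 0) {
    ev <- .empty_events()
    ev$guides <- list(); ev$count <- integer(); ev$amp_id <- character()
    return(ev)
  }
  out <- list()
  for (i in seq_len(nrow(classified))) {
    ev <- classified$events[[i]]
    if (nrow(ev) == 0) next
    ev$count <- classified$count[i]
    ev$amp_id <- classified$amp_id[i]
    out[[length(out) + 1]] <- ev
  }
  if (length(out) == 0) {
    ev <- .empty_events()
    ev$guides <- list(); ev$count <- integer(); ev$amp_id <- character()
    return(ev)
  }
  bind_rows(out)
}

#' Abundance-weighted sample statistics
#'
#' Editing percentage is the abundance share of Amps carrying at least one
#' guide-assigned event; deletion/insertion percentages count Amps carrying
#' at least one assigned deletion/insertion (an Amp with both counts in
#' both, so editing <= deletions + insertions). Per-guide efficiency
#' divides by the abundance of Amps whose reference carries a perfect-seed
#' site for that guide. The indel spectrum is the abundance-weighted
#' frequency of assigned events by signed length, summing to 100.
#'
#' @param classified Classified tibble from [classify_amps()].
#' @param sites Site tibble (for per-guide denominators).
#' @param guides Optional character vector fixing the guide order.
#' @return List of tibbles: `summary`, `per_guide`, `spectrum`.
#' @export
sample_statistics <- function(classified, sites, guides = NULL) {
  fam <- sum(classified$count)
  if (fam == 0) {
    return(list(
      summary = tibble(editing_pct = NA_real_, deletions_pct = NA_real_,
                       insertions_pct = NA_real_, family_reads = 0L),
      per_guide = tibble(guide = character(), efficiency_pct = numeric(),
                         edited_reads = integer(), target_reads = integer()),
      spectrum = tibble(signed_length = integer(), frequency_pct = numeric())))
  }
  evt <- .event_table(classified)
  evt_assigned <- evt[vapply(evt$guides, length, integer(1)) > 0, , drop = FALSE]
  amp_edited <- classified$category %in% .EDITED_CATEGORIES
  has_kind <- function(kind) {
    vapply(seq_len(nrow(classified)), function(i) {
      ev <- classified$events[[i]]
      if (nrow(ev) == 0) return(FALSE)
      any(ev$kind == kind & vapply(ev$guides, length, integer(1)) > 0)
    }, logical(1))
  }
  summary <- tibble(
    editing_pct = 100 * sum(classified$count[amp_edited]) / fam,
    deletions_pct = 100 * sum(classified$count[has_kind("deletion")]) / fam,
    insertions_pct = 100 * sum(classified$count[has_kind("insertion")]) / fam,
    family_reads = as.integer(fam))
  if (is.null(guides)) guides <- sort(unique(sites$guide))
  per_guide <- lapply(guides, function(g) {
    target_refs <- unique(sites$ref_id[sites$guide == g & sites$seed_perfect])
    denom_amps <- classified$ref_id %in% target_refs
    denom <- sum(classified$count[denom_amps])
    hit <- vapply(seq_len(nrow(classified)), function(i) {
      ev <- classified$events[[i]]
      nrow(ev) > 0 && any(vapply(ev$guides, function(v) g %in% v, logical(1)))
    }, logical(1))
    num <- sum(classified$count[hit & denom_amps])
    tibble(guide = g,
           efficiency_pct = if (denom > 0) 100 * num / denom else NA_real_,
           edited_reads = as.integer(num), target_reads = as.integer(denom))
  }) %>% bind_rows()
  spectrum <- if (nrow(evt_assigned) == 0) {
    tibble(signed_length = integer(), frequency_pct = numeric())
  } else {
    evt_assigned %>%
      group_by(signed_length = .data$signed_length) %>%
      summarise(weight = sum(.data$count), .groups = "drop") %>%
      mutate(frequency_pct = 100 * .data$weight / sum(.data$weight)) %>%
      select("signed_length", "frequency_pct") %>%
      arrange(.data$signed_length)
  }
  list(summary = summary, per_guide = per_guide, spectrum = spectrum)
}

#' Excision frequency by Amp type
#'
#' For each Alpha type, the abundance share of its Amps whose category is a
#' multi-guide excision with a span covering the type's epitope-coding
#' interval (when the panel annotates one; otherwise any excision
#' qualifies).
#'
#' @param classified Classified tibble.
#' @param panel Annotated `amp_panel`.
#' @return Tibble `(alpha_type, excision_pct, excised_reads, total_reads)`;
#'   types with zero assigned abundance get `NA`.
#' @export
excision_frequency_by_type <- function(classified, panel) {
  types <- sort(unique(panel$alpha_type[!is.na(panel$alpha_type)]))
  epi <- panel[, c("id", "epi_start", "epi_end")]
  rows <- lapply(types, function(t) {
    refs <- panel$id[!is.na(panel$alpha_type) & panel$alpha_type == t]
    sel <- classified$ref_id %in% refs
    denom <- sum(classified$count[sel])
    if (denom == 0) {
      return(tibble(alpha_type = t, excision_pct = NA_real_,
                    excised_reads = 0L, total_reads = 0L))
    }
    exc <- sel & classified$category == "multi_guide_excision"
    covers <- vapply(seq_len(nrow(classified)), function(i) {
      if (!exc[i]) return(FALSE)
      e <- epi[epi$id == classified$ref_id[i], ]
      if (is.na(e$epi_start)) return(TRUE)
      classified$excised_start[i] <= e$epi_start &&
        classified$excised_end[i] >= e$epi_end
    }, logical(1))
    num <- sum(classified$count[covers])
    tibble(alpha_type = t, excision_pct = 100 * num / denom,
           excised_reads = as.integer(num), total_reads = as.integer(denom))
  })
  bind_rows(rows)
}
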