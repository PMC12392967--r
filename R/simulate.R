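# Synthetic reference panels and edited read sets with per-read truth.
#
# The generator emulates a tandem gene family of eight archetypes
# (Alpha0-Alpha7) that differ in the epitope content of a central
# epitope-coding block, flanked by conserved regions carrying one upstream
# and one downstream guide site. The Alpha7 archetype codes the canonical
# 33-mer followed by the alpha-3 motif (42 aa, 126 nt), and its two cut
# sites lie exactly 129 bp apart, so a guide-to-guide excision removes the
# complete immunogenic region in frame. Panels, reads and truth tables are
# deterministic given a seed.
#
# Layout of every reference (coordinates 0-based, frame 0):
#   [0,90)    5' flank, per-reference synonymous wobble ("family polymorphism")
#   [90,117)  5' fixed region: Cas12a PAM (TTTC), Cas9 PAM (CCA, minus
#             strand) and both upstream guide seeds; upstream cut at 114
#   [117,e)   epitope block; first two codons pinned CTG CAG ("LQ"), last
#             two pinned CCA CAG ("PQ"); interior codons randomized per ref
#   [e,e+24)  3' fixed region: downstream guide seeds and PAMs; cut at e
#   [e+24,e+114) 3' flank wobble
# with e = 117 + 3 * (block length in aa); inter-cut distance = 3*aa + 3.
# Amplicons run 267 nt (Alpha0) to 357 nt (Alpha7), so even the largest
# planted deletions leave alignable anchors on both sides.

.AA_CODONS <- list(
  A = c("GCT", "GCA", "GCC", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGA", "GGC", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("CTG", "CTT", "CTC", "CTA", "TTA", "TTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCA", "CCT", "CCC", "CCG"), Q = c("CAG", "CAA"),
  R = c("CGT", "CGA", "AGA", "AGG"), S = c("TCT", "TCA", "AGT", "AGC"),
  T = c("ACA", "ACT", "ACC"), V = c("GTT", "GTA", "GTC"),
  W = "TGG", Y = c("TAT", "TAC"), `*` = c("TAA", "TAG", "TGA")
)

# canonical (first-listed) codon back-translation; random = seeded draw
.backtranslate <- function(pep, random = FALSE) {
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- .AA_CODONS[[a]]
    if (random) cods[sample.int(length(cods), 1)] else cods[1]
  }, character(1)), collapse = "")
}

# fixed flank constants (see layout above)
.F5_FIXED <- "AGTTTCCAACCTCAACAACCACAATCA"                # positions [90,117)
.F5_WOBBLE_PEP <- "LPQEQVPFSQNLASHKIVDSTRGEFNPLTS"       # 30 codons, [0,90)
.F3_FIXED <- "GGTACAACAGTTCCTGTTCAAACA"                   # positions [e, e+24)
.F3_WOBBLE_PEP <- "ISQVLHQQQKPATDENRGLFSVYHIPTKAS"       # 30 codons, [e+24, e+114)
.S_BLOCK <- 117L   # epitope-block start; upstream cut at .S_BLOCK - 3

.P33 <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"

# archetype epitope-block peptides: exactly N DQ2.5 hits each
.type_peptide <- function(N) {
  if (N == 0) return("LQASASASASPQ")
  if (N <= 5) return(paste0("LQ", strrep("AFRPQQPYPQ", N), "PQ"))
  if (N == 6) return(paste0(.P33, "PQ"))
  paste0(.P33, "FRPQQPYPQ")
}

# epitope block DNA: boundary codons pinned, interior randomized
.block_dna <- function(pep, random = TRUE, stop_at = NA) {
  aa <- strsplit(pep, "")[[1]]
  L <- length(aa)
  cods <- character(L)
  for (i in seq_len(L)) {
    pinned <- i <= 2L || i >= L - 1L
    cc <- .AA_CODONS[[aa[i]]]
    cods[i] <- if (pinned || !random) cc[1] else cc[sample.int(length(cc), 1)]
  }
  if (!is.na(stop_at)) cods[stop_at] <- "TAG"
  paste(cods, collapse = "")
}

#' Default guides matching the simulated reference layout
#'
#' Two guides flank the epitope block: `sg_up` (upstream cut 3 nt before
#' the block) and `sg_dn` (downstream cut at the block end), designed
#' against the Alpha7 archetype; both have perfect-seed sites on every
#' archetype, with distal protospacer mismatches on the others, mirroring
#' a guide designed on one family member and applied to all.
#'
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @return List of two [guide_spec()] objects.
#' @export
sim_guides <- function(nuclease = c("Cas9", "Cas12a")) {
  nuclease <- match.arg(nuclease)
  e7_head <- .block_dna(.type_peptide(7), random = FALSE)
  if (nuclease == "Cas9") {
    # minus-strand protospacers; PAMs CCA at [51,54) and the pinned CCA
    # codon two codons before the block end
    up <- .revcomp(paste0(substr(.F5_FIXED, 22, 27), substr(e7_head, 1, 14)))
    dn <- .revcomp(paste0("CAG", substr(.F3_FIXED, 1, 17)))
    list(guide_spec("sg_up", up, "Cas9"), guide_spec("sg_dn", dn, "Cas9"))
  } else {
    # plus-strand upstream (PAM TTTC at [35,39)), minus-strand downstream
    # (PAM complement CAAA at F3 positions [18,22))
    up <- paste0(substr(.F5_FIXED, 7, 27), substr(e7_head, 1, 2))
    dn <- .revcomp(paste0("CACAG", substr(.F3_FIXED, 1, 18)))
    list(guide_spec("sg_up", up, "Cas12a"), guide_spec("sg_dn", dn, "Cas12a"))
  }
}

#' Default simulated dsODN
#'
#' A synthetic insert: codon-divergent from the gliadin-like references and
#' free of epitope motifs, so targeted insertions align as one clean
#' insertion event. Lengths 75 and 51 are multiples of 3 (in-frame
#' replacement products).
#'
#' @param length 75 or 51.
#' @return A [dsodn_spec()].
#' @export
sim_dsodn <- function(length = 75L) {
  stopifnot(length %in% c(51L, 75L))
  pep <- substr("DSGIRNVDIARSEGKPDVRHGSNGR", 1, length / 3L)
  dsodn_spec(sprintf("dsODN-%d", length), .backtranslate(pep), "blunt")
}

#' Build a synthetic reference panel
#'
#' One reference per request, with skewed baseline abundances drawn from a
#' Dirichlet whose concentration decreases with Alpha type (Alpha0 most
#' abundant, Alpha7 rare). Every reference carries both guide sites; the
#' builder verifies each epitope block against [scan_epitopes()] and each
#' designed cut against [find_sites()] before returning.
#'
#' @param n_per_type Named integer vector, names in `0:7`, giving the number
#'   of references per archetype.
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param seed Integer seed.
#' @param n_pseudogene Number of pseudogene references (internal stop in the
#'   block) to add.
#' @param concentration Dirichlet concentration per type (named `0:7`).
#' @return An `amp_panel` with `alpha_type`, `pseudogene`, epitope-block
#'   interval (`epi_start`, `epi_end`) and designed cut positions
#'   (`sim_cut_up`, `sim_cut_dn`); attribute `sim_nuclease`.
#' @export
sim_reference_panel <- function(n_per_type = c(`0` = 2, `1` = 1, `2` = 1,
                                               `3` = 1, `4` = 1, `5` = 1,
                                               `6` = 1, `7` = 2),
                                nuclease = c("Cas9", "Cas12a"), seed = 1L,
                                n_pseudogene = 0L,
                                concentration = c(`0` = 8, `1` = 5, `2` = 4,
                                                  `3` = 3, `4` = 3, `5` = 2,
                                                  `6` = 1.5, `7` = 1)) {
  nuclease <- match.arg(nuclease)
  stopifnot(all(names(n_per_type) %in% as.character(0:7)), all(n_per_type >= 0))
  guides <- sim_guides(nuclease)
  .with_seed(seed, {
    rows <- list()
    seen <- character(0)
    build_one <- function(type, id, pseudo = FALSE) {
      pep <- .type_peptide(if (pseudo) 3L else type)
      repeat {
        f5 <- paste0(.backtranslate(.F5_WOBBLE_PEP, random = TRUE), .F5_FIXED)
        stop_at <- if (pseudo) 6L else NA
        blk <- .block_dna(pep, random = TRUE, stop_at = stop_at)
        f3 <- paste0(.F3_FIXED, .backtranslate(.F3_WOBBLE_PEP, random = TRUE))
        seq <- paste0(f5, blk, f3)
        if (!(seq %in% seen)) break
      }
      seen <<- c(seen, seq)
      e <- .S_BLOCK + nchar(blk)
      tibble(id = id, sequence = seq, baseline_abundance = NA_real_,
             alpha_type = if (pseudo) NA_integer_ else as.integer(type),
             pseudogene = pseudo, frame_offset = 0L,
             epi_start = .S_BLOCK, epi_end = e,
             sim_cut_up = .S_BLOCK - 3L, sim_cut_dn = e)
    }
    k <- 0L
    for (t in as.integer(names(n_per_type))) {
      for (j in seq_len(n_per_type[[as.character(t)]])) {
        k <- k + 1L
        rows[[k]] <- build_one(t, sprintf("Amp%02d_t%d", k, t))
      }
    }
    for (j in seq_len(n_pseudogene)) {
      k <- k + 1L
      rows[[k]] <- build_one(3L, sprintf("Amp%02d_ps", k), pseudo = TRUE)
    }
    panel <- bind_rows(rows)
    conc <- concentration[as.character(ifelse(is.na(panel$alpha_type), 3L,
                                              panel$alpha_type))]
    g <- rgamma(nrow(panel), shape = as.numeric(conc))
    panel$baseline_abundance <- g / sum(g)
    panel <- new_amp_panel(panel, k = 12L)
    attr(panel, "sim_nuclease") <- nuclease
    # post-conditions: epitope content and designed cuts
    for (i in seq_len(nrow(panel))) {
      prof <- scan_epitopes(translate_amp(panel$sequence[i], 0L))
      if (panel$pseudogene[i]) {
        if (!prof$internal_stop) abort("pseudogene reference lacks its stop")
      } else if (classify_alpha_type(prof) != panel$alpha_type[i]) {
        abort(sprintf("archetype %d unconstructible: scanned type %d",
                      panel$alpha_type[i], classify_alpha_type(prof)))
      }
      cuts <- c(panel$sim_cut_up[i], panel$sim_cut_dn[i])
      for (gi in 1:2) {
        st <- find_sites(guides[[gi]], panel$sequence[i], panel$id[i])
        if (!any(st$expected_cut == cuts[gi])) {
          abort(sprintf("designed %s site missing on %s",
                        guides[[gi]]$name, panel$id[i]))
        }
      }
    }
    panel
  })
}

#' Default planted indel length distribution
#'
#' Deletions (85% of mass) peak at -36 bp, insertions (15%) at +1 bp, over
#' the range -141 to +49 bp.
#'
#' @return Tibble `(signed_length, prob)` summing to 1.
#' @export
default_indel_length_dist <- function() {
  del <- tibble(signed_length = -141:-1,
                prob = exp(-abs(-141:-1 - (-36)) / 15))
  ins <- tibble(signed_length = 1:49, prob = exp(-(1:49 - 1) / 6))
  del$prob <- 0.85 * del$prob / sum(del$prob)
  ins$prob <- 0.15 * ins$prob / sum(ins$prob)
  bind_rows(del, ins)
}

#' Specify planted edit rates for the simulator
#'
#' @param per_guide_indel_probs Named per-read probability of an indel at
#'   each guide's cut.
#' @param indel_length_dist Tibble `(signed_length, prob)`.
#' @param excision_prob_by_type Named (type 0-7) probability of a full
#'   inter-cut excision.
#' @param dsodn_insert_prob Probability that an excised read captures the
#'   dsODN (replacement), or that an unexcised read captures it at one cut
#'   (single_cut).
#' @param dsodn_orientation_probs Named probabilities `(forward, reverse)`.
#' @param error_rate Per-base substitution error probability.
#' @return A `sim_edit_spec` list.
#' @export
sim_edit_spec <- function(per_guide_indel_probs = c(sg_up = 0.10, sg_dn = 0.05),
                          indel_length_dist = default_indel_length_dist(),
                          excision_prob_by_type = c(`0` = 0, `1` = 0.02,
                                                    `2` = 0.02, `3` = 0.03,
                                                    `4` = 0.03, `5` = 0.05,
                                                    `6` = 0.05, `7` = 0.15),
                          dsodn_insert_prob = 0,
                          dsodn_orientation_probs = c(forward = 0.8,
                                                      reverse = 0.2),
                          error_rate = 0) {
  stopifnot(abs(sum(indel_length_dist$prob) - 1) < 1e-9,
            all(indel_length_dist$signed_length != 0),
            all(per_guide_indel_probs >= 0 & per_guide_indel_probs <= 1),
            all(excision_prob_by_type >= 0 & excision_prob_by_type <= 1),
            dsodn_insert_prob >= 0, dsodn_insert_prob <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(per_guide_indel_probs = per_guide_indel_probs,
                 indel_length_dist = indel_length_dist,
                 excision_prob_by_type = excision_prob_by_type,
                 dsodn_insert_prob = dsodn_insert_prob,
                 dsodn_orientation_probs = dsodn_orientation_probs /
                   sum(dsodn_orientation_probs),
                 error_rate = error_rate),
            class = "sim_edit_spec")
}

# truth windows around the designed cuts, matching the nuclease cut model
.sim_windows <- function(cut_up, cut_dn, nuclease, pad = 5L) {
  if (nuclease == "Cas9") {
    tibble(guide = c("sg_up", "sg_dn"),
           window_start = c(cut_up - pad, cut_dn - pad),
           window_end = c(cut_up + 1L + pad, cut_dn + 1L + pad))
  } else {
    tibble(guide = c("sg_up", "sg_dn"),
           window_start = c(cut_up - pad, cut_dn - 5L - pad),
           window_end = c(cut_up + 5L + pad, cut_dn + pad))
  }
}

#' Simulate an edited read set with per-read truth
#'
#' Reads are drawn from the panel proportional to baseline abundance;
#' excisions delete cut-to-cut, single-guide indels land at the cuts with
#' lengths from the configured distribution, dsODN insertions follow their
#' scenario and orientation, and substitution errors are applied last.
#' The truth table records, per read, the planted events and the category
#' they imply by coordinate arithmetic (so a planted "single-guide"
#' deletion long enough to span both cuts is recorded as an excision).
#'
#' @param panel Panel from [sim_reference_panel()].
#' @param spec A [sim_edit_spec()].
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param dsodn A [dsodn_spec()] (default [sim_dsodn()]).
#' @param pad Cut-window padding used for truth guide assignment (must
#'   match the pipeline's pad).
#' @return List: `reads` tibble `(read_id, sequence)`, `truth` tibble with
#'   per-read source, category, guides, orientation, net signed length and
#'   a nested `events` list-column.
#' @export
sim_sample <- function(panel, spec, n_reads, seed = 1L, dsodn = sim_dsodn(),
                       pad = 5L) {
  nuclease <- attr(panel, "sim_nuclease") %||% "Cas9"
  .with_seed(seed, {
    ridx <- sample.int(nrow(panel), n_reads, replace = TRUE,
                       prob = panel$baseline_abundance)
    reads <- character(n_reads)
    cat_v <- character(n_reads)
    orient_v <- rep(NA_character_, n_reads)
    scen_v <- rep(NA_character_, n_reads)
    net_v <- integer(n_reads)
    guides_l <- vector("list", n_reads)
    events_l <- vector("list", n_reads)
    no_events <- .empty_events()
    no_events$guides <- list()
    ld <- spec$indel_length_dist
    bases <- c("A", "C", "G", "T")
    mk_ev <- function(kind, pos, len, ins) {
      tibble::new_tibble(list(
        kind = kind, ref_pos = as.integer(pos), length = as.integer(len),
        signed_length = as.integer(ifelse(kind == "deletion", -len, len)),
        inserted_seq = ins, normalized = rep(FALSE, length(kind))),
        nrow = length(kind))
    }
    win_cache <- lapply(seq_len(nrow(panel)), function(r) {
      .sim_windows(panel$sim_cut_up[r], panel$sim_cut_dn[r], nuclease, pad)
    })
    p_exc_by_ref <- vapply(seq_len(nrow(panel)), function(r) {
      type <- panel$alpha_type[r]
      if (is.na(type)) return(0)
      v <- spec$excision_prob_by_type[as.character(type)]
      if (length(v) == 1 && !is.na(v)) as.numeric(v) else 0
    }, numeric(1))
    for (i in seq_len(n_reads)) {
      r <- ridx[i]
      ref_seq <- panel$sequence[r]
      cuts <- c(sg_up = panel$sim_cut_up[r], sg_dn = panel$sim_cut_dn[r])
      windows <- win_cache[[r]]
      kind_v <- character(0); pos_v <- integer(0); len_v <- integer(0)
      ins_v <- character(0)
      orientation <- NA_character_
      scenario <- NA_character_
      excised <- runif(1) < p_exc_by_ref[r]
      ds <- runif(1) < spec$dsodn_insert_prob
      if (excised) {
        kind_v <- "deletion"
        pos_v <- cuts[["sg_up"]]
        len_v <- cuts[["sg_dn"]] - cuts[["sg_up"]]
        ins_v <- NA_character_
      }
      if (ds) {
        orientation <- sample(names(spec$dsodn_orientation_probs), 1,
                              prob = spec$dsodn_orientation_probs)
        ins_seq <- if (orientation == "forward") dsodn$top_strand
                   else .revcomp(dsodn$top_strand)
        at <- if (excised) cuts[["sg_up"]]
              else cuts[[sample(names(cuts), 1)]]
        scenario <- if (excised) "replacement" else "single_cut"
        kind_v <- c(kind_v, "insertion")
        pos_v <- c(pos_v, as.integer(at))
        len_v <- c(len_v, nchar(ins_seq))
        ins_v <- c(ins_v, ins_seq)
      }
      if (!excised && !ds) {
        for (g in names(spec$per_guide_indel_probs)) {
          if (runif(1) >= spec$per_guide_indel_probs[[g]]) next
          l <- sample(ld$signed_length, 1, prob = ld$prob)
          cut <- cuts[[g]]
          if (l < 0) {
            L <- -l
            start <- cut - ceiling(L / 2)
            start <- max(2L, min(start, nchar(ref_seq) - L - 2L))
            if (start > cut || start + L < cut) next  # cannot fit over cut
            nk <- "deletion"; np <- as.integer(start); nl <- L
            ni <- NA_character_
          } else {
            nk <- "insertion"; np <- as.integer(cut); nl <- as.integer(l)
            ni <- paste(sample(bases, l, replace = TRUE), collapse = "")
          }
          # drop a second event landing within 15 nt of an existing one:
          # in this repeat-rich sequence two nearby events admit multiple
          # equal-cost decompositions, which would make the planted
          # representation ill-defined
          if (length(kind_v) > 0) {
            ne <- np + if (nk == "deletion") nl else 0L
            oe <- pos_v + ifelse(kind_v == "deletion", len_v, 0L)
            if (any(pos_v <= ne + 15L & np <= oe + 15L)) next
          }
          kind_v <- c(kind_v, nk); pos_v <- c(pos_v, np)
          len_v <- c(len_v, nl); ins_v <- c(ins_v, ni)
        }
      }
      if (length(kind_v) == 0) {
        sq <- ref_seq
        ev <- no_events
        gv <- list()
        category <- "wild_type"
        net <- 0L
      } else {
        ev <- mk_ev(kind_v, pos_v, len_v, ins_v)
        # truth coordinates use the same placement convention the caller
        # reports: left-aligned, then shifted to maximal cut-window overlap
        # (haplotype-preserving, so the read itself is unaffected)
        ev <- normalize_indels(ev, ref_seq, windows)
        sq <- apply_indels(ref_seq, ev)
        # truth guide assignment + implied category, by plain arithmetic
        gv <- lapply(seq_len(nrow(ev)), function(k) {
          if (ev$kind[k] == "deletion") {
            hit <- ev$ref_pos[k] < windows$window_end &
              windows$window_start < ev$ref_pos[k] + ev$length[k]
          } else {
            hit <- windows$window_start <= ev$ref_pos[k] &
              ev$ref_pos[k] < windows$window_end
          }
          windows$guide[hit]
        })
        ev$guides <- gv
        spans2 <- any(vapply(seq_len(nrow(ev)), function(k) {
          ev$kind[k] == "deletion" &&
            sum(ev$ref_pos[k] <= cuts & cuts <= ev$ref_pos[k] + ev$length[k]) >= 2
        }, logical(1)))
        category <- if (ds) "dsodn_targeted"
          else if (spans2) "multi_guide_excision"
          else if (any(lengths(gv) > 0)) "single_guide_indel"
          else "unassigned_indel"
        net <- sum(ev$signed_length)
      }
      if (spec$error_rate > 0) {
        nb <- rbinom(1, nchar(sq), spec$error_rate)
        if (nb > 0) {
          pos <- sample.int(nchar(sq), nb)
          for (p in pos) {
            cur <- substr(sq, p, p)
            substr(sq, p, p) <- sample(setdiff(bases, cur), 1)
          }
        }
      }
      reads[i] <- sq
      cat_v[i] <- category
      orient_v[i] <- orientation
      scen_v[i] <- scenario
      net_v[i] <- as.integer(net)
      guides_l[i] <- list(as.character(sort(unique(unlist(gv)))))
      events_l[[i]] <- ev
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    list(reads = tibble(read_id = ids, sequence = reads),
         truth = tibble(read_id = ids, ref_id = panel$id[ridx],
                        alpha_type = panel$alpha_type[ridx],
                        category = cat_v, orientation = orient_v,
                        scenario = scen_v, net_signed = net_v,
                        guides_hit = guides_l, events = events_l))
  })
}

#' Summarize a truth table into the report quantities
#'
#' Computes, from planted truth alone (no alignment), the same
#' abundance-weighted statistics the pipeline reports, for planted-truth
#' recovery checks.
#'
#' @param truth Truth tibble from [sim_sample()].
#' @param panel The panel the sample was simulated from.
#' @return List of tibbles: `summary`, `per_guide`, `spectrum`,
#'   `excision_by_type`, `dsodn`.
#' @export
truth_statistics <- function(truth, panel) {
  n <- nrow(truth)
  edited <- truth$category %in% .EDITED_CATEGORIES
  has_kind <- function(kind) {
    vapply(truth$events, function(ev) {
      nrow(ev) > 0 && any(ev$kind == kind & lengths(ev$guides) > 0)
    }, logical(1))
  }
  summary <- tibble(
    editing_pct = 100 * sum(edited) / n,
    deletions_pct = 100 * sum(has_kind("deletion")) / n,
    insertions_pct = 100 * sum(has_kind("insertion")) / n,
    family_reads = n)
  guides <- c("sg_up", "sg_dn")
  per_guide <- bind_rows(lapply(guides, function(g) {
    hit <- vapply(truth$guides_hit, function(v) g %in% v, logical(1))
    tibble(guide = g, efficiency_pct = 100 * sum(hit) / n,
           edited_reads = sum(hit), target_reads = n)
  }))
  evt <- bind_rows(lapply(seq_len(n), function(i) {
    ev <- truth$events[[i]]
    ev[lengths(ev$guides) > 0, c("kind", "signed_length"), drop = FALSE]
  }))
  spectrum <- if (nrow(evt) == 0) {
    tibble(signed_length = integer(), frequency_pct = numeric())
  } else {
    evt %>% group_by(signed_length = .data$signed_length) %>%
      summarise(w = n(), .groups = "drop") %>%
      mutate(frequency_pct = 100 * .data$w / sum(.data$w)) %>%
      select("signed_length", "frequency_pct") %>%
      arrange(.data$signed_length)
  }
  types <- sort(unique(panel$alpha_type[!is.na(panel$alpha_type)]))
  excision_by_type <- bind_rows(lapply(types, function(t) {
    sel <- !is.na(truth$alpha_type) & truth$alpha_type == t
    denom <- sum(sel)
    tibble(alpha_type = t,
           excision_pct = if (denom == 0) NA_real_ else
             100 * sum(sel & truth$category == "multi_guide_excision") / denom)
  }))
  ins_total <- sum(vapply(truth$events, function(ev) sum(ev$kind == "insertion"),
                          integer(1)))
  dsodn <- tibble(
    orientation = c("forward", "reverse"),
    frequency_pct = if (ins_total == 0) NA_real_ else c(
      100 * sum(truth$orientation == "forward", na.rm = TRUE) / ins_total,
      100 * sum(truth$orientation == "reverse", na.rm = TRUE) / ins_total))
  list(summary = summary, per_guide = per_guide, spectrum = spectrum,
       excision_by_type = excision_by_type, dsodn = dsodn)
}

#' Write simulated reads as FASTQ
#'
#' Already-merged single reads with uniform Q40 qualities.
#'
#' @param reads Tibble `(read_id, sequence)`.
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep("I", nchar(reads$sequence))
  writeLines(lines, con)
  invisible(path)
}

#' Write a truth table as TSV
#'
#' Events are serialized compactly as `kind:pos:signed[:seq]` joined by
#' `;`.
#'
#' @param truth Truth tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  flat <- truth
  flat$guides_hit <- vapply(truth$guides_hit, paste, character(1), collapse = ",")
  flat$events <- vapply(truth$events, function(ev) {
    if (nrow(ev) == 0) return("")
    paste(vapply(seq_len(nrow(ev)), function(i) {
      base <- sprintf("%s:%d:%d", substr(ev$kind[i], 1, 1), ev$ref_pos[i],
                      ev$signed_length[i])
      if (ev$kind[i] == "insertion") paste0(base, ":", ev$inserted_seq[i])
      else base
    }, character(1)), collapse = ";")
  }, character(1))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
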