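# dsODN insertion calls, translation, epitope scanning/typing and loss.

P33 <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"

mk_sites2 <- function(cuts, guides = paste0("g", seq_along(cuts)), pad = 5L) {
  tibble::tibble(
    ref_id = "R", guide = guides, nuclease = "Cas9", strand = "+",
    proto_start = cuts - 17L, proto_end = cuts + 3L,
    pam_start = cuts + 3L, pam_end = cuts + 6L,
    mismatches = 0L, seed_mismatches = 0L, seed_perfect = TRUE,
    expected_cut = cuts, cut_alt = NA_integer_,
    window_start = cuts - 1L - pad, window_end = cuts + pad)
}

mk_amp_row <- function(events, count = 10L) {
  tibble::tibble(
    amp_id = "a1", sequence = strrep("A", 40), count = count, ref_id = "R",
    alpha_type = 7L, pseudogene = FALSE, mode = "local", score = 0,
    identity = 1, category = "single_guide_indel", frame_status = "in_frame",
    net_signed = 0L, excised_start = NA_integer_, excised_end = NA_integer_,
    excision_guides = list(character(0)), events = list(events))
}

test_that("an exact inter-cut replacement is called forward with both guides", {
  withr::local_seed(31)
  spec <- sim_dsodn(75)
  sites <- mk_sites2(c(57L, 186L), c("gUp", "gDn"))
  ev <- tibble::tibble(
    kind = c("deletion", "insertion"), ref_pos = c(57L, 57L),
    length = c(129L, 75L), signed_length = c(-129L, 75L),
    inserted_seq = c(NA, spec$top_strand), normalized = TRUE)
  ev <- assign_events(ev, sites)
  call <- detect_dsodn(mk_amp_row(ev), spec, sites)
  expect_equal(call$orientation, "forward")
  expect_equal(call$scenario, "replacement")
  expect_equal(call$identity, 1)
  expect_equal(sort(call$guides_covered[[1]]), c("gDn", "gUp"))
})

test_that("a reverse-complement insertion at one cut is a reverse single_cut call", {
  spec <- sim_dsodn(51)
  sites <- mk_sites2(57L, "gUp")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$top_strand)))
  ev <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 51L, signed_length = 51L,
    inserted_seq = rc, normalized = TRUE), sites)
  call <- detect_dsodn(mk_amp_row(ev), spec, sites)
  expect_equal(call$orientation, "reverse")
  expect_equal(call$scenario, "single_cut")
  expect_equal(call$guides_covered[[1]], "gUp")
})

test_that("identity thresholds separate 6% from 15% substituted inserts", {
  withr::local_seed(31)
  spec <- sim_dsodn(75)
  sites <- mk_sites2(57L, "gUp")
  mutate_seq <- function(s, k) {
    at <- sample(nchar(s), k)
    x <- strsplit(s, "")[[1]]
    for (p in at) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  mk <- function(s) {
    ev <- assign_events(tibble::tibble(
      kind = "insertion", ref_pos = 57L, length = nchar(s),
      signed_length = nchar(s), inserted_seq = s, normalized = TRUE), sites)
    detect_dsodn(mk_amp_row(ev), spec, sites)
  }
  ok <- mk(mutate_seq(spec$top_strand, 4))        # ~5% substitutions
  expect_false(is.null(ok))
  expect_gte(ok$identity, 0.9)
  bad <- mk(mutate_seq(spec$top_strand, 12))      # ~16% substitutions
  expect_null(bad)
  # with threshold 1.0 only a byte-exact strand match fires
  strict <- dsodn_spec("strict", spec$top_strand, min_identity = 1,
                       min_covered_frac = 1)
  ev1 <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 75L, signed_length = 75L,
    inserted_seq = spec$top_strand, normalized = TRUE), sites)
  expect_false(is.null(detect_dsodn(mk_amp_row(ev1), strict, sites)))
  ev2 <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 75L, signed_length = 75L,
    inserted_seq = mutate_seq(spec$top_strand, 1), normalized = TRUE), sites)
  expect_null(detect_dsodn(mk_amp_row(ev2), strict, sites))
})

test_that("a dsODN-matching insertion outside every cut window is not called", {
  spec <- sim_dsodn(75)
  sites <- mk_sites2(200L, "gFar")
  ev <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 75L, signed_length = 75L,
    inserted_seq = spec$top_strand, normalized = TRUE), sites)
  expect_null(detect_dsodn(mk_amp_row(ev), spec, sites))
})

test_that("orientation calls swap when the spec strand is reverse-complemented", {
  spec <- sim_dsodn(75)
  flipped <- dsodn_spec("flip", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$top_strand))))
  sites <- mk_sites2(57L, "gUp")
  ev <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 75L, signed_length = 75L,
    inserted_seq = spec$top_strand, normalized = TRUE), sites)
  expect_equal(detect_dsodn(mk_amp_row(ev), spec, sites)$orientation, "forward")
  expect_equal(detect_dsodn(mk_amp_row(ev), flipped, sites)$orientation,
               "reverse")
})

test_that("dsODN frequency is a share of all insertions, weighted by abundance", {
  spec <- sim_dsodn(75)
  sites <- mk_sites2(57L, "gUp")
  ds_ev <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 75L, signed_length = 75L,
    inserted_seq = spec$top_strand, normalized = TRUE), sites)
  other_ev <- assign_events(tibble::tibble(
    kind = "insertion", ref_pos = 57L, length = 6L, signed_length = 6L,
    inserted_seq = "ACGTAC", normalized = TRUE), sites)
  cl <- dplyr::bind_rows(mk_amp_row(ds_ev, count = 12L),
                         mk_amp_row(other_ev, count = 88L))
  cl$amp_id <- c("a1", "a2")
  res <- detect_dsodn_sample(cl, list(spec), sites)
  freq <- dsodn_frequency(res$calls, res$classified)
  expect_equal(freq$frequency_pct[freq$orientation == "forward"], 12)
  expect_equal(freq$frequency_pct[freq$orientation == "reverse"], 0)
  # all insertions dsODN-forward: 100 / 0
  res1 <- detect_dsodn_sample(mk_amp_row(ds_ev, 40L), list(spec), sites)
  f1 <- dsodn_frequency(res1$calls, res1$classified)
  expect_equal(f1$frequency_pct, c(100, 0))
  # no dsODN among insertions: both 0
  res0 <- detect_dsodn_sample(mk_amp_row(other_ev, 40L), list(spec), sites)
  f0 <- dsodn_frequency(res0$calls, res0$classified)
  expect_equal(f0$frequency_pct, c(0, 0))
  # no insertions at all: NA
  wt <- mk_amp_row(ds_ev[0, ], 40L)
  fna <- dsodn_frequency(res0$calls[0, ], wt)
  expect_true(all(is.na(fna$frequency_pct)))
})

test_that("translation matches a codon-table oracle in every frame", {
  expect_equal(translate_amp("ATGGCT", 0), "MA")
  expect_equal(translate_amp("TATGGCT", 1), "MA")
  expect_equal(translate_amp("AT", 0), "")
  withr::local_seed(37)
  for (i in 1:30) {
    dna <- random_dna(300)
    off <- sample(0:2, 1)
    expect_equal(translate_amp(dna, off), translate_oracle(dna, off))
  }
})

test_that("the canonical 33-mer carries six overlapping DQ2.5 epitope copies", {
  prof <- scan_epitopes(P33)
  expect_equal(unname(prof$motif_hits),
               c(1L, 2L, 3L, 0L))   # alpha-1a, alpha-1b x2, alpha-2 x3
  expect_equal(prof$total_hits, 6L)
  full <- scan_epitopes(paste0(P33, "FRPQQPYPQ"))
  expect_equal(full$total_hits, 7L)
  expect_equal(scan_epitopes("AAAAAAA")$total_hits, 0L)
})

test_that("epitope scanning equals exhaustive all-offset comparison", {
  withr::local_seed(41)
  motifs <- default_epitope_motifs()
  for (i in 1:200) {
    pep <- paste(sample(c("P", "Q", "L", "F", "Y"), sample(20:60, 1),
                        replace = TRUE), collapse = "")
    prof <- scan_epitopes(pep, motifs)
    want <- vapply(motifs, count_overlapping_oracle, integer(1), pep = pep)
    expect_equal(prof$motif_hits, want)
  }
})

test_that("alpha typing counts total hits, caps at 7, flags pseudogenes", {
  expect_equal(classify_alpha_type(scan_epitopes("AAAA")), 0L)
  expect_equal(classify_alpha_type(scan_epitopes(paste0(P33, "FRPQQPYPQ"))), 7L)
  over <- paste0(P33, P33)   # repeat-expanded: more than 7 hits
  expect_gt(scan_epitopes(over)$total_hits, 7)
  expect_equal(classify_alpha_type(scan_epitopes(over)), 7L)
  stopped <- scan_epitopes("LQLQ*PFPQ")
  expect_true(stopped$internal_stop)
  expect_true(is.na(classify_alpha_type(stopped)))
  # a trailing stop is not an internal stop
  expect_false(scan_epitopes("LQLQ*")$internal_stop)
})

test_that("relative epitope loss follows the abundance-weighted formula", {
  panel <- sim_reference_panel(n_per_type = c(`0` = 1, `7` = 1), seed = 5)
  a7 <- panel[panel$alpha_type == 7, ]
  a0 <- panel[panel$alpha_type == 0, ]
  excised <- paste0(substr(a7$sequence, 1, a7$sim_cut_up),
                    substr(a7$sequence, a7$sim_cut_dn + 1, nchar(a7$sequence)))
  mk_cl <- function(seqs, refs, counts) {
    tibble::tibble(amp_id = paste0("a", seq_along(seqs)), sequence = seqs,
                   count = as.integer(counts), ref_id = refs,
                   alpha_type = NA_integer_, pseudogene = FALSE,
                   mode = "local", score = 0, identity = 1,
                   category = "x", frame_status = "x", net_signed = 0L,
                   excised_start = NA_integer_, excised_end = NA_integer_,
                   excision_guides = list(character(0)),
                   events = list(empty_events_tbl()))
  }
  # unedited: all losses zero
  cl0 <- mk_cl(c(a7$sequence, a0$sequence), c(a7$id, a0$id), c(70, 30))
  loss0 <- relative_epitope_loss(cl0, panel)
  expect_equal(loss0$loss_pct[loss0$motif != "combined"], rep(0, 4))
  # every Alpha7 amp excised; Alpha7 is the only epitope-bearing type:
  # loss(e) = 100 * hits_e, so multi-copy motifs exceed 100%
  cl1 <- mk_cl(c(excised, a0$sequence), c(a7$id, a0$id), c(70, 30))
  loss1 <- relative_epitope_loss(cl1, panel)
  get <- function(l, m) l$loss_pct[l$motif == m]
  expect_equal(get(loss1, "DQ2.5_glia_a1a"), 100)
  expect_equal(get(loss1, "DQ2.5_glia_a1b"), 200)
  expect_equal(get(loss1, "DQ2.5_glia_a2"), 300)
  expect_equal(get(loss1, "DQ2.5_glia_a3"), 100)
  expect_equal(get(loss1, "combined"), 700)
  # half the abundance of the only alpha-1a-bearing reference edited:
  # single-copy motif loss is 50%
  cl2 <- mk_cl(c(excised, a7$sequence, a0$sequence),
               c(a7$id, a7$id, a0$id), c(50, 50, 30))
  loss2 <- relative_epitope_loss(cl2, panel)
  expect_equal(get(loss2, "DQ2.5_glia_a1a"), 50)
  expect_equal(get(loss2, "DQ2.5_glia_a2"), 150)
  # monotone: marking more amps edited never decreases any loss
  expect_true(all(loss1$loss_pct >= loss0$loss_pct))
})
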