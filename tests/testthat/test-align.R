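# Affine-gap aligners, reference choice, indel extraction/normalization.

test_that("identical sequences align as one match run without clipping", {
  withr::local_seed(21)
  s <- random_dna(60)
  a <- align_local(s, s)
  expect_equal(a$ops, tibble::tibble(op = "M", len = 60L))
  expect_equal(a$score, 120)
  expect_equal(a$query_clipped, 0L)
  g <- align_global(s, s)
  expect_equal(g$ops$op, "M")
  expect_equal(g$score, 120)
})

test_that("interior deletions are recovered as single D runs", {
  withr::local_seed(22)
  ref <- random_dna(250)
  q36 <- paste0(substr(ref, 1, 100), substr(ref, 137, 250))
  a <- align_local(q36, ref)
  expect_true(any(a$ops$op == "D" & a$ops$len == 36))
  # a 129-bp deletion needs the near-free extension of the global mode
  ref2 <- random_dna(320)
  q129 <- paste0(substr(ref2, 1, 100), substr(ref2, 230, 320))
  g <- align_global(q129, ref2)
  expect_equal(g$ops$op[g$ops$len == 129], "D")
  ev <- extract_indels(g, q129)
  expect_equal(ev$signed_length, -129L)
  expect_equal(ev$ref_pos, 100L)
})

test_that("insertions are recovered verbatim", {
  withr::local_seed(23)
  ref <- random_dna(200)
  ins <- random_dna(12)
  q <- paste0(substr(ref, 1, 40), ins, substr(ref, 41, 200))
  g <- align_global(q, ref)
  ev <- extract_indels(g, q)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$inserted_seq, ins)
  expect_equal(ev$signed_length, 12L)
})

test_that("local alignment clips down to a shared block", {
  withr::local_seed(24)
  block <- random_dna(20)
  ref <- paste0(random_dna(60), block, random_dna(60))
  query <- paste0(random_dna(25), block, random_dna(25))
  a <- align_local(query, ref)
  expect_gte(a$score, 40 - 6)  # at least the block minus minor edge noise
  expect_gte(a$query_clipped, 40)
})

test_that("both modes equal the full-matrix oracle on random pairs", {
  withr::local_seed(25)
  scl <- scoring_local(); scg <- scoring_global()
  for (i in 1:40) {
    n <- sample(30:120, 1); m <- sample(30:120, 1)
    q <- random_dna(n)
    r <- if (i %% 2 == 0) random_dna(m) else {
      # related pair: mutate + indel the query so alignments are nontrivial
      x <- strsplit(q, "")[[1]]
      nm <- sample(0:5, 1)
      if (nm > 0) {
        at <- sample(n, nm)
        x[at] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
      }
      y <- paste(x, collapse = "")
      if (i %% 3 == 0 && n > 40) {
        cut <- sample(10:(n - 20), 1)
        y <- paste0(substr(y, 1, cut), random_dna(sample(1:8, 1)),
                    substr(y, cut + sample(1:6, 1), n))
      }
      y
    }
    for (mode in c("local", "overlap")) {
      sc <- if (mode == "local") scl else scg
      got <- if (mode == "local") align_local(q, r, sc) else align_global(q, r, sc)
      want <- oracle_gotoh(q, r, sc, mode)
      expect_equal(got$score, want$score)
      expect_equal(got$ops, want$ops)
      expect_equal(got$ref_start, want$ref_start)
      expect_equal(got$query_start, want$query_start)
    }
  }
})

test_that("scores agree with Biostrings pairwiseAlignment as a cross-check", {
  withr::local_seed(26)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, baseOnly = TRUE)
  mat[mat != 2] <- -3
  for (i in 1:15) {
    q <- random_dna(80)
    x <- strsplit(q, "")[[1]]
    at <- sample(80, 6)
    x[at] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    r <- paste0(paste(x[1:40], collapse = ""), random_dna(9),
                paste(x[41:80], collapse = ""))
    bl <- Biostrings::pairwiseAlignment(q, r, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 6, gapExtension = 1,
                                        scoreOnly = TRUE)
    expect_equal(align_local(q, r)$score, bl)
    bo <- Biostrings::pairwiseAlignment(q, r, type = "overlap",
                                        substitutionMatrix = mat,
                                        gapOpening = 6, gapExtension = 1,
                                        scoreOnly = TRUE)
    expect_equal(align_global(q, r, scoring(2, 3, 6, 1))$score, bo)
  }
})

test_that("events plus substitutions reconstruct the query exactly", {
  withr::local_seed(17)
  for (i in 1:25) {
    ref <- random_dna(200)
    ev <- tibble::tibble(kind = character(), ref_pos = integer(),
                         length = integer(), signed_length = integer(),
                         inserted_seq = character(), normalized = logical())
    pos <- sort(sample(20:160, 2))
    if (pos[2] - pos[1] > 25) {
      ev <- tibble::tibble(
        kind = c("deletion", "insertion"),
        ref_pos = c(pos[1], pos[2]),
        length = c(10L, 7L), signed_length = c(-10L, 7L),
        inserted_seq = c(NA, random_dna(7)), normalized = FALSE)
    }
    q <- apply_indels(ref, ev)
    g <- align_global(q, ref)
    got <- extract_indels(g, q)
    # re-applying the called events must reproduce the query
    expect_equal(apply_indels(ref, got), q)
  }
})

test_that("reference choice picks identity, escalates to global, breaks ties", {
  withr::local_seed(27)
  refs <- vapply(rep(300, 5), random_dna, character(1))
  panel <- new_amp_panel(tibble::tibble(
    id = paste0("R", 1:5), sequence = refs,
    baseline_abundance = rep(0.2, 5), alpha_type = NA_integer_,
    pseudogene = FALSE, frame_offset = 0L,
    epi_start = NA_integer_, epi_end = NA_integer_))
  ch <- choose_reference(refs[3], panel)
  expect_equal(ch$ref$id, "R3")
  expect_equal(ch$alignment$ops$op, "M")
  # 129-bp deletion with a short 5' anchor: local clips the anchor (its
  # score is below the gap cost), so the global mode must recover the D
  q <- paste0(substr(refs[2], 1, 40), substr(refs[2], 170, 300))
  ch2 <- choose_reference(q, panel)
  expect_equal(ch2$ref$id, "R2")
  expect_equal(ch2$alignment$mode, "global")
  expect_true(any(ch2$alignment$ops$op == "D" & ch2$alignment$ops$len == 129))
  # equidistant amp: duplicate reference under two ids, equal abundance
  panel2 <- new_amp_panel(tibble::tibble(
    id = c("B", "A"), sequence = rep(refs[1], 2),
    baseline_abundance = c(0.5, 0.5), alpha_type = NA_integer_,
    pseudogene = FALSE, frame_offset = 0L,
    epi_start = NA_integer_, epi_end = NA_integer_))
  expect_equal(choose_reference(refs[1], panel2)$ref$id, "A")
  # permutation invariance over panel order
  perm <- sample(5)
  panel3 <- new_amp_panel(tibble::tibble(
    id = paste0("R", 1:5)[perm], sequence = refs[perm],
    baseline_abundance = rep(0.2, 5), alpha_type = NA_integer_,
    pseudogene = FALSE, frame_offset = 0L,
    epi_start = NA_integer_, epi_end = NA_integer_))
  expect_equal(choose_reference(q, panel3)$ref$id, "R2")
  # no shared k-mer: unalignable
  expect_null(choose_reference(strrep("A", 50), panel))
})

test_that("normalization shifts repeat-context indels into cut windows", {
  # deletion of CA inside ACACACAG: equivalence class spans the repeat
  ref <- paste0("GGTTTAA", "ACACACAG", "TTGGCC")
  # leftmost placement of a CA deletion in the repeat is at pos 7
  ev <- tibble::tibble(kind = "deletion", ref_pos = 9L, length = 2L,
                       signed_length = -2L, inserted_seq = NA_character_,
                       normalized = FALSE)
  win <- tibble::tibble(window_start = 11L, window_end = 14L)
  out <- normalize_indel(ev, ref, win)
  expect_true(out$ref_pos >= 11 && out$ref_pos + 2 <= 15)
  expect_equal(apply_indels(ref, out), apply_indels(ref, ev))
  # without any window the event is left-aligned
  out0 <- normalize_indel(ev, ref, win[0, ])
  expect_equal(out0$ref_pos, 7L)
  # non-repetitive context: position unchanged
  ref2 <- "GATCGTAGCTAGGCTTACGT"
  ev2 <- tibble::tibble(kind = "deletion", ref_pos = 8L, length = 3L,
                        signed_length = -3L, inserted_seq = NA_character_,
                        normalized = FALSE)
  expect_equal(normalize_indel(ev2, ref2, win[0, ])$ref_pos, 8L)
})

test_that("normalization is haplotype-preserving, idempotent and maximal", {
  withr::local_seed(23)
  for (i in 1:200) {
    # build a repeat-rich reference so shifts exist
    unit <- random_dna(sample(1:3, 1))
    ref <- paste0(random_dna(30), strrep(unit, sample(4:8, 1)), random_dna(30))
    n <- nchar(ref)
    kind <- sample(c("deletion", "insertion"), 1)
    if (kind == "deletion") {
      len <- sample(1:4, 1)
      pos <- sample(5:(n - len - 5), 1)
      ev <- tibble::tibble(kind = kind, ref_pos = pos, length = len,
                           signed_length = -len, inserted_seq = NA_character_,
                           normalized = FALSE)
    } else {
      len <- sample(1:4, 1)
      pos <- sample(5:(n - 5), 1)
      ev <- tibble::tibble(kind = kind, ref_pos = pos, length = len,
                           signed_length = len,
                           inserted_seq = random_dna(len), normalized = FALSE)
    }
    ws <- sample(5:(n - 10), 1)
    win <- tibble::tibble(window_start = ws, window_end = ws + 8L)
    out <- normalize_indel(ev, ref, win)
    expect_equal(apply_indels(ref, out), apply_indels(ref, ev))
    out2 <- normalize_indel(out, ref, win)
    expect_equal(out2$ref_pos, out$ref_pos)
    # maximality: enumerate the full equivalence class directly
    hap <- apply_indels(ref, ev)
    ovl <- function(e) {
      if (e$kind == "deletion") {
        max(0, min(e$ref_pos + e$length, win$window_end) -
              max(e$ref_pos, win$window_start))
      } else {
        as.numeric(win$window_start <= e$ref_pos & e$ref_pos < win$window_end)
      }
    }
    best <- 0
    for (p in 0:(n - 1)) {
      cand <- ev; cand$ref_pos <- p
      if (cand$kind == "insertion") {
        # any rotation that yields the same haplotype counts
        pre <- substr(ref, 1, p)
        post <- substr(ref, p + 1, n)
        need <- nchar(hap) - n
        if (startsWith(hap, pre) && endsWith(hap, post)) {
          cand$inserted_seq <- substr(hap, p + 1, p + need)
          if (apply_indels(ref, cand) == hap) best <- max(best, ovl(cand))
        }
      } else if (p + cand$length <= n && apply_indels(ref, cand) == hap) {
        best <- max(best, ovl(cand))
      }
    }
    expect_equal(ovl(out), best)
  }
})
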