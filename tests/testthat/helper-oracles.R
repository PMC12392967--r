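# Independent reference implementations used as test oracles. These mirror
# the documented rules (not the package internals): dense-matrix affine DP
# in plain R, exhaustive guide-site scans, and brute-force motif counting.

empty_events_tbl <- function() {
  tibble::tibble(kind = character(), ref_pos = integer(), length = integer(),
                 signed_length = integer(), inserted_seq = character(),
                 normalized = logical())
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# full-matrix Gotoh DP with the same documented tie-break rules:
# M/X preferred over D over I; local start cell = smallest (i, j) maximum;
# overlap end cell scanned over last row then last column; gap runs extend
# greedily on ties.
oracle_gotoh <- function(query, ref, sc, mode) {
  n <- nchar(query); m <- nchar(ref)
  qc <- strsplit(query, "")[[1]]; rc <- strsplit(ref, "")[[1]]
  local <- mode == "local"
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      e <- max(H[i + 1, j] - sc$gap_open, E[i + 1, j]) - sc$gap_extend
      f <- max(H[i, j + 1] - sc$gap_open, F[i, j + 1]) - sc$gap_extend
      s <- if (qc[i] == rc[j]) sc$match else -sc$mismatch
      h <- max(H[i, j] + s, e, f)
      if (local && h < 0) h <- 0
      E[i + 1, j + 1] <- e; F[i + 1, j + 1] <- f; H[i + 1, j + 1] <- h
    }
  }
  if (local) {
    best <- 0; ei <- 0; ej <- 0
    for (i in 1:n) for (j in 1:m) {
      if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; ei <- i; ej <- j }
    }
  } else {
    best <- -Inf; ei <- 0; ej <- 0
    for (j in 0:m) if (H[n + 1, j + 1] > best) { best <- H[n + 1, j + 1]; ei <- n; ej <- j }
    for (i in 0:(n - 1)) if (H[i + 1, m + 1] > best) { best <- H[i + 1, m + 1]; ei <- i; ej <- m }
  }
  ops <- character(0); lens <- integer(0)
  push <- function(op) {
    k <- length(ops)
    if (k > 0 && ops[k] == op) lens[k] <<- lens[k] + 1L
    else { ops <<- c(ops, op); lens <<- c(lens, 1L) }
  }
  i <- ei; j <- ej
  while (i > 0 && j > 0) {
    h <- H[i + 1, j + 1]
    if (local && h == 0) break
    s <- if (qc[i] == rc[j]) sc$match else -sc$mismatch
    if (h == H[i, j] + s) {
      push(if (qc[i] == rc[j]) "M" else "X"); i <- i - 1; j <- j - 1
    } else if (h == E[i + 1, j + 1]) {
      repeat {
        push("D")
        e <- E[i + 1, j + 1]
        j <- j - 1
        if (j == 0) break
        if (e == E[i + 1, j + 1] - sc$gap_extend) next
        break
      }
    } else {
      repeat {
        push("I")
        f <- F[i + 1, j + 1]
        i <- i - 1
        if (i == 0) break
        if (f == F[i + 1, j + 1] - sc$gap_extend) next
        break
      }
    }
  }
  list(score = best, ops = tibble::tibble(op = rev(ops), len = rev(lens)),
       query_start = i, query_end = ei, ref_start = j, ref_end = ej)
}

# wrap an oracle result so extract_indels() can consume it
oracle_alignment <- function(o, mode) {
  structure(list(ref_id = "o", mode = mode, score = o$score, ops = o$ops,
                 query_start = o$query_start, query_end = o$query_end,
                 ref_start = o$ref_start, ref_end = o$ref_end,
                 query_clipped = 0L, n_match = sum(o$ops$len[o$ops$op == "M"]),
                 identity = NA_real_),
            class = "amp_alignment")
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# exhaustive site scan: tries every offset on both strands independently of
# the package's scanner (works on explicit character vectors)
oracle_scan_sites <- function(guide, ref_seq, max_mm = Inf, require_seed = TRUE) {
  n <- nchar(ref_seq)
  L <- nchar(guide$protospacer)
  plen <- nchar(guide$pam_pattern)
  sl <- guide$seed_length
  cas9 <- guide$nuclease == "Cas9"
  pamc <- strsplit(guide$pam_pattern, "")[[1]]
  pc <- strsplit(guide$protospacer, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") ref_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref_seq)))
    sc <- strsplit(seq_s, "")[[1]]
    for (p in 0:(n - L)) {
      pam_start <- if (cas9) p + L else p - plen
      if (pam_start < 0 || pam_start + plen > n) next
      ok_pam <- all(vapply(1:plen, function(t) {
        sc[pam_start + t] %in% IUPAC_SETS[[pamc[t]]]
      }, logical(1)))
      if (!ok_pam) next
      mm <- which(sc[(p + 1):(p + L)] != pc)
      seed_rng <- if (cas9) (L - sl + 1):L else 1:sl
      smm <- sum(mm %in% seed_rng)
      if (require_seed && smm > 0) next
      if (length(mm) > max_mm) next
      ps <- if (strand == "+") p else n - p - L
      hits[[length(hits) + 1]] <- data.frame(
        strand = strand, proto_start = ps, proto_end = ps + L,
        mismatches = length(mm), seed_perfect = smm == 0)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(), proto_start = integer(),
                      proto_end = integer(), mismatches = integer(),
                      seed_perfect = logical()))
  }
  out <- do.call(rbind, hits)
  out[order(out$proto_start, out$strand), , drop = FALSE]
}

# brute-force overlapping motif count by explicit substring comparison
count_overlapping_oracle <- function(pep, motif) {
  n <- nchar(pep); m <- nchar(motif)
  if (n < m) return(0L)
  sum(vapply(1:(n - m + 1), function(i) substr(pep, i, i + m - 1) == motif,
             logical(1)))
}

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

translate_oracle <- function(dna, offset = 0) {
  n <- nchar(dna) - offset
  n <- n - n %% 3
  if (n < 3) return("")
  cods <- substring(dna, offset + seq(1, n, 3), offset + seq(3, n, 3))
  paste(CODON_TABLE[cods], collapse = "")
}
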