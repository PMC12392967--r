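# Guide-site scanning under nuclease-specific PAM and seed rules.
#
# Coordinates are 0-based half-open on the reference forward strand. The
# "seed" is the PAM-proximal stretch of the protospacer (default 12 nt)
# whose mismatches abolish cleavage; a primary site call requires a perfect
# seed and PAM, with mismatches over the rest of the protospacer counted
# but not limited. Degenerate calls allow mismatches anywhere up to a cap.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.pam_matches <- function(chars, pattern_chars) {
  all(mapply(function(ch, pc) ch %in% .IUPAC[[pc]], chars, pattern_chars))
}

#' Specify a guide RNA
#'
#' @param name Guide name.
#' @param protospacer Protospacer sequence, uppercase ACGT (typically 20 nt
#'   for Cas9, 23 nt for Cas12a).
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param pam_pattern IUPAC PAM pattern; defaults to `NGG` (3' PAM) for Cas9
#'   and `TTTV` (5' PAM) for Cas12a.
#' @param seed_length PAM-proximal seed length (default 12).
#' @return A `guide_spec` list.
#' @export
guide_spec <- function(name, protospacer, nuclease = c("Cas9", "Cas12a"),
                       pam_pattern = NULL, seed_length = 12L) {
  nuclease <- match.arg(nuclease)
  protospacer <- toupper(protospacer)
  .check_dna(setNames(protospacer, name), "protospacer")
  if (is.null(pam_pattern)) pam_pattern <- if (nuclease == "Cas9") "NGG" else "TTTV"
  stopifnot(seed_length <= nchar(protospacer))
  structure(list(name = name, protospacer = protospacer, nuclease = nuclease,
                 pam_pattern = toupper(pam_pattern),
                 seed_length = as.integer(seed_length)),
            class = "guide_spec")
}

# scan one strand of `seq` (already oriented so the guide reads 5'->3') and
# return candidate sites as offsets into that orientation
.scan_strand <- function(seq, guide) {
  n <- nchar(seq)
  L <- nchar(guide$protospacer)
  plen <- nchar(guide$pam_pattern)
  sl <- guide$seed_length
  cas9 <- guide$nuclease == "Cas9"
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(guide$protospacer, "")[[1]]
  pamc <- strsplit(guide$pam_pattern, "")[[1]]
  out <- list()
  if (n < L + plen) return(out)
  for (p in 0:(n - L)) {
    if (cas9) {
      pam_start <- p + L
      if (pam_start + plen > n) next
    } else {
      pam_start <- p - plen
      if (pam_start < 0) next
    }
    if (!.pam_matches(sc[(pam_start + 1):(pam_start + plen)], pamc)) next
    mm_pos <- which(sc[(p + 1):(p + L)] != pc)
    # seed = PAM-proximal sl bases: positions (L-sl+1)..L for Cas9 (3' PAM),
    # 1..sl for Cas12a (5' PAM), in protospacer coordinates
    seed_rng <- if (cas9) (L - sl + 1):L else 1:sl
    seed_mm <- sum(mm_pos %in% seed_rng)
    out[[length(out) + 1]] <- list(p = p, pam_start = pam_start,
                                   mismatches = length(mm_pos),
                                   seed_mm = seed_mm)
  }
  out
}

.sites_for_ref <- function(guide, ref_seq, ref_id, pad = 5L) {
  n <- nchar(ref_seq)
  L <- nchar(guide$protospacer)
  plen <- nchar(guide$pam_pattern)
  gname <- guide$name
  gnuc <- guide$nuclease
  rows <- list()
  fwd <- .scan_strand(ref_seq, guide)
  for (h in fwd) {
    rows[[length(rows) + 1]] <- tibble(
      ref_id = ref_id, guide = gname, nuclease = gnuc,
      strand = "+", proto_start = h$p, proto_end = h$p + L,
      pam_start = h$pam_start, pam_end = h$pam_start + plen,
      mismatches = h$mismatches, seed_mismatches = h$seed_mm,
      seed_perfect = h$seed_mm == 0L)
  }
  rev <- .scan_strand(.revcomp(ref_seq), guide)
  for (h in rev) {
    # offset p on the reverse strand maps to forward [n-p-L, n-p)
    rows[[length(rows) + 1]] <- tibble(
      ref_id = ref_id, guide = gname, nuclease = gnuc,
      strand = "-", proto_start = n - h$p - L, proto_end = n - h$p,
      pam_start = n - h$pam_start - plen, pam_end = n - h$pam_start,
      mismatches = h$mismatches, seed_mismatches = h$seed_mm,
      seed_perfect = h$seed_mm == 0L)
  }
  if (length(rows) == 0) return(.empty_sites())
  df <- bind_rows(rows) %>% arrange(.data$proto_start, .data$strand)
  .add_cut_windows(df, n, pad)
}

.empty_sites <- function() {
  tibble(ref_id = character(), guide = character(), nuclease = character(),
         strand = character(), proto_start = integer(), proto_end = integer(),
         pam_start = integer(), pam_end = integer(), mismatches = integer(),
         seed_mismatches = integer(), seed_perfect = logical(),
         expected_cut = integer(), cut_alt = integer(),
         window_start = integer(), window_end = integer())
}

# cut-site model:
#  Cas9 cuts bluntly 3 nt 5' of the PAM, with 1 nt of uncertainty toward the
#  PAM-distal side; Cas12a cuts staggered, 18 nt (non-target strand) and
#  23 nt (target strand) 3' of the PAM, and the window spans both cuts.
.add_cut_windows <- function(sites, ref_len, pad = 5L) {
  n <- nrow(sites)
  cut <- integer(n); alt <- rep(NA_integer_, n)
  ws <- integer(n); we <- integer(n)
  for (i in seq_len(n)) {
    s <- sites[i, ]
    if (s$nuclease == "Cas9") {
      if (s$strand == "+") {
        cut[i] <- s$proto_end - 3L
        ws[i] <- cut[i] - 1L - pad; we[i] <- cut[i] + pad
      } else {
        cut[i] <- s$proto_start + 3L
        ws[i] <- cut[i] - pad; we[i] <- cut[i] + 1L + pad
      }
    } else {
      if (s$strand == "+") {
        cut[i] <- s$pam_end + 18L; alt[i] <- s$pam_end + 23L
        ws[i] <- cut[i] - pad; we[i] <- alt[i] + pad
      } else {
        cut[i] <- s$pam_start - 18L; alt[i] <- s$pam_start - 23L
        ws[i] <- alt[i] - pad; we[i] <- cut[i] + pad
      }
    }
  }
  sites$expected_cut <- pmin(pmax(cut, 0L), ref_len)
  sites$cut_alt <- ifelse(is.na(alt), NA_integer_, pmin(pmax(alt, 0L), ref_len))
  sites$window_start <- pmax(ws, 0L)
  sites$window_end <- pmin(we, ref_len)
  sites
}

#' Find perfect-seed guide binding sites on a reference
#'
#' Reports every position on either strand where the PAM matches its IUPAC
#' pattern and the PAM-proximal seed matches exactly; mismatches over the
#' remaining protospacer are counted but do not disqualify a site.
#'
#' @param guide A [guide_spec()].
#' @param ref_seq Reference sequence (character scalar).
#' @param ref_id Reference id stored on the result.
#' @param pad Cut-window padding in nt (default 5).
#' @return Site tibble with protospacer/PAM intervals (0-based half-open,
#'   forward strand), strand, mismatch counts, `seed_perfect`, the expected
#'   cut position(s) and the attribution window.
#' @export
find_sites <- function(guide, ref_seq, ref_id = "ref", pad = 5L) {
  df <- .sites_for_ref(guide, ref_seq, ref_id, pad)
  df[df$seed_perfect, , drop = FALSE]
}

#' Find degenerate guide binding sites (mismatches allowed in the seed)
#'
#' Like [find_sites()] but allows up to `max_mm` mismatches anywhere in the
#' protospacer, seed included; `seed_perfect` distinguishes primary sites.
#'
#' @inheritParams find_sites
#' @param max_mm Maximum total protospacer mismatches (default 3, max 5).
#' @return Site tibble (see [find_sites()]).
#' @export
find_degenerate_sites <- function(guide, ref_seq, ref_id = "ref", max_mm = 3L,
                                  pad = 5L) {
  stopifnot(max_mm <= 5L)
  df <- .sites_for_ref(guide, ref_seq, ref_id, pad)
  df[df$mismatches <= max_mm, , drop = FALSE]
}

#' Compute the cut window for one site
#'
#' @param site One-row site tibble (as returned by [find_sites()]).
#' @param pad Padding in nt.
#' @param ref_len Reference length for clipping.
#' @return A list with `expected_cut`, `window_start`, `window_end`.
#' @export
cut_window <- function(site, pad = 5L, ref_len = Inf) {
  df <- .add_cut_windows(site, ref_len, pad)
  list(expected_cut = df$expected_cut[1],
       window_start = df$window_start[1], window_end = df$window_end[1])
}

#' Scan a panel with a set of guides
#'
#' Union of perfect-seed sites (any number of distal mismatches) and
#' degenerate sites (any seed, at most `max_mm` total mismatches), per
#' reference.
#'
#' @param guides List of [guide_spec()] objects.
#' @param panel An `amp_panel`.
#' @param pad Cut-window padding.
#' @param max_mm Mismatch cap for degenerate sites.
#' @return Combined site tibble over all references and guides.
#' @export
guide_sites <- function(guides, panel, pad = 5L, max_mm = 3L) {
  out <- list()
  for (g in guides) {
    for (i in seq_len(nrow(panel))) {
      df <- .sites_for_ref(g, panel$sequence[i], panel$id[i], pad)
      df <- df[df$seed_perfect | df$mismatches <= max_mm, , drop = FALSE]
      out[[length(out) + 1]] <- df
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(.empty_sites())
  arrange(res, .data$ref_id, .data$proto_start)
}
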