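# End-to-end pipeline: dereplicate -> family screen -> reference choice ->
# indel extraction/normalization -> guide assignment/classification ->
# dsODN detection -> epitope profiling -> report.

#' Pipeline configuration
#'
#' Collects inputs and thresholds for one run. `panel` and `reads` may be
#' file paths (FASTA/FASTQ, optionally gzipped) or in-memory objects.
#'
#' @param panel `amp_panel` or FASTA path.
#' @param reads Tibble/character vector of merged reads, or FASTQ/FASTA
#'   path.
#' @param guides List of [guide_spec()] objects.
#' @param sample_id Sample label.
#' @param abundances Optional baseline-abundance table path (when `panel`
#'   is a path).
#' @param dsodn List of [dsodn_spec()] objects (possibly empty).
#' @param motifs Epitope motif vector.
#' @param p31_43 Optional p31-43 motif (tracked separately; default off).
#' @param min_count Dereplication minimum count (default 2).
#' @param k,min_shared_frac Family-screen parameters.
#' @param pad Cut-window padding.
#' @param max_mm Degenerate-site mismatch cap.
#' @param top_c,clip_frac Reference-choice parameters.
#' @param sc_local,sc_global Alignment scoring.
#' @param display_threshold Spectrum display threshold in percent.
#' @param min_mean_q Optional FASTQ mean-quality filter.
#' @param out_dir Optional output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(panel, reads, guides, sample_id = "sample",
                       abundances = NULL, dsodn = list(),
                       motifs = default_epitope_motifs(), p31_43 = NULL,
                       min_count = 2L, k = 12L, min_shared_frac = 0.5,
                       pad = 5L, max_mm = 3L, top_c = 8L, clip_frac = 0.15,
                       sc_local = scoring_local(), sc_global = scoring_global(),
                       display_threshold = 0.5, min_mean_q = NULL,
                       out_dir = NULL) {
  stopifnot(min_count >= 1L, k >= 8L, min_shared_frac > 0, min_shared_frac <= 1,
            pad >= 0L, max_mm <= 5L, top_c >= 1L, clip_frac >= 0, clip_frac <= 1,
            display_threshold >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Guide, dsODN and motif blocks are converted to their spec objects; all
#' other fields are passed to [run_config()] unchanged, so a round-tripped
#' configuration reproduces the run.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  guides <- lapply(y$guides, function(g) {
    guide_spec(g$name, g$protospacer, g$nuclease,
               pam_pattern = g$pam_pattern %||% NULL,
               seed_length = g$seed_length %||% 12L)
  })
  dsodn <- lapply(y$dsodn %||% list(), function(d) {
    dsodn_spec(d$name, d$top_strand, d$end_type %||% "blunt",
               min_identity = d$min_identity %||% 0.9,
               min_covered_frac = d$min_covered_frac %||% 0.8)
  })
  motifs <- if (!is.null(y$motifs)) unlist(y$motifs) else default_epitope_motifs()
  args <- y[setdiff(names(y), c("guides", "dsodn", "motifs"))]
  do.call(run_config, c(list(guides = guides, dsodn = dsodn, motifs = motifs),
                        args))
}

.read_seqs <- function(x, min_mean_q = NULL) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) return(read_fastq(x, min_mean_q))
    return(read_fasta(x))
  }
  if (is.data.frame(x)) return(x)
  tibble(id = sprintf("read%06d", seq_along(x)), sequence = x)
}

#' Run the full edit-calling pipeline on one sample
#'
#' @param config A [run_config()].
#' @return An `amp_report`; when `config$out_dir` is set, the report
#'   tables, the retained amp set and a plain-text log are written there.
#' @export
run_pipeline <- function(config) {
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(paste0("[ampedit] ", msg))
  }
  panel <- config$panel
  if (is.character(panel)) {
    panel <- load_reference_panel(panel, config$abundances, k = config$k)
  }
  if (all(is.na(panel$alpha_type)) && !any(panel$pseudogene)) {
    panel <- annotate_panel_types(panel, config$motifs)
  }
  reads <- .read_seqs(config$reads, config$min_mean_q)
  say("sample '%s': %d reads, panel of %d references", config$sample_id,
      nrow(reads), nrow(panel))

  ampset <- dereplicate(reads, config$min_count, config$sample_id)
  say("dereplication: %d amps (min_count %d), %d of %d reads retained",
      nrow(ampset), config$min_count, sum(ampset$count), nrow(reads))

  ampset <- filter_gene_family(ampset, panel, config$k, config$min_shared_frac)
  say("family screen (k=%d, frac>=%.2f): %d amps kept, %d reads discarded",
      config$k, config$min_shared_frac, nrow(ampset),
      attr(ampset, "discarded_offtarget"))

  sites <- guide_sites(config$guides, panel, pad = config$pad,
                       max_mm = config$max_mm)
  say("guide scan: %d sites over the panel (%d perfect-seed)",
      nrow(sites), sum(sites$seed_perfect))

  classified <- classify_amps(ampset, panel, sites,
                              sc_local = config$sc_local,
                              sc_global = config$sc_global,
                              top_c = config$top_c,
                              clip_frac = config$clip_frac,
                              dsodn = config$dsodn)
  mode_reads <- attr(classified, "mode_reads")
  fam_reads <- sum(classified$count)
  split <- list(
    pct_local = if (fam_reads > 0) 100 * mode_reads[["local"]] / fam_reads else NA_real_,
    pct_global = if (fam_reads > 0) 100 * mode_reads[["global"]] / fam_reads else NA_real_)
  say("alignment: %d amps assigned (%.1f%% of reads local, %.1f%% global), %d unalignable",
      nrow(classified), split$pct_local, split$pct_global,
      attr(classified, "n_unalignable"))

  dsres <- detect_dsodn_sample(classified, config$dsodn, sites,
                               sc = config$sc_local)
  classified <- dsres$classified
  say("dsODN: %d targeted call(s)", nrow(dsres$calls))

  stats <- sample_statistics(classified, sites,
                             guides = vapply(config$guides, `[[`, character(1),
                                             "name"))
  exc <- excision_frequency_by_type(classified, panel)
  loss <- relative_epitope_loss(classified, panel, config$motifs,
                                config$p31_43)
  dsf <- dsodn_frequency(dsres$calls, classified)

  counts <- list(
    total_reads = as.integer(attr(ampset, "total_reads") %||% nrow(reads)),
    family_reads = as.integer(fam_reads),
    discarded_offtarget = as.integer(attr(ampset, "discarded_offtarget") %||% 0L),
    unalignable_reads = as.integer(attr(classified, "unalignable_reads")),
    n_amps = nrow(classified),
    n_unalignable = attr(classified, "n_unalignable"))
  say("accounting: %d total = %d family + %d below min_count/off-target + %d unalignable",
      counts$total_reads, counts$family_reads,
      counts$total_reads - counts$family_reads - counts$unalignable_reads,
      counts$unalignable_reads)

  report <- new_amp_report(
    sample_id = config$sample_id, counts = counts, alignment_split = split,
    summary = stats$summary, per_guide = stats$per_guide,
    spectrum = stats$spectrum, excision_by_type = exc, dsodn_freq = dsf,
    dsodn_calls = dsres$calls, epitope_loss = loss, classified = classified,
    display_threshold = config$display_threshold)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, config$out_dir)
    write_ampset(ampset, fasta = file.path(config$out_dir, "amps.fasta"),
                 tsv = file.path(config$out_dir, "amps.tsv"))
    writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  }
  report
}
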