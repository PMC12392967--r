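# The per-sample report object and its broom/ggplot2 surface.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

new_amp_report <- function(sample_id, counts, alignment_split, summary,
                           per_guide, spectrum, excision_by_type, dsodn_freq,
                           dsodn_calls, epitope_loss, classified,
                           display_threshold = 0.5) {
  structure(list(
    schema_version = "1.0",
    sample_id = sample_id,
    counts = counts,
    alignment_split = alignment_split,
    summary = summary,
    per_guide = per_guide,
    spectrum = spectrum,
    excision_by_type = excision_by_type,
    dsodn_freq = dsodn_freq,
    dsodn_calls = dsodn_calls,
    epitope_loss = epitope_loss,
    classified = classified,
    display_threshold = display_threshold
  ), class = "amp_report")
}

#' Tidy an amp_report table
#'
#' @param x An `amp_report`.
#' @param table Which table: `"summary"`, `"per_guide"`, `"spectrum"`,
#'   `"excision_by_type"`, `"dsodn"`, or `"epitope_loss"`.
#' @param ... Unused.
#' @return A tibble with a `sample_id` column prepended.
#' @export
tidy.amp_report <- function(x, table = c("summary", "per_guide", "spectrum",
                                         "excision_by_type", "dsodn",
                                         "epitope_loss"), ...) {
  table <- match.arg(table)
  tb <- switch(table,
    summary = x$summary, per_guide = x$per_guide, spectrum = x$spectrum,
    excision_by_type = x$excision_by_type, dsodn = x$dsodn_freq,
    epitope_loss = x$epitope_loss)
  dplyr::bind_cols(tibble(sample_id = rep(x$sample_id, nrow(tb))), tb)
}

#' One-row overview of an amp_report
#'
#' @param x An `amp_report`.
#' @param ... Unused.
#' @return One-row tibble with the headline percentages and read
#'   accounting.
#' @export
glance.amp_report <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    editing_pct = x$summary$editing_pct,
    deletions_pct = x$summary$deletions_pct,
    insertions_pct = x$summary$insertions_pct,
    total_reads = x$counts$total_reads,
    family_reads = x$counts$family_reads,
    discarded_offtarget = x$counts$discarded_offtarget,
    n_amps = x$counts$n_amps,
    pct_local = x$alignment_split$pct_local,
    pct_global = x$alignment_split$pct_global)
}

#' @export
print.amp_report <- function(x, ...) {
  f1 <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  cat(sprintf("<amp_report> sample '%s' (schema %s)\n", x$sample_id,
              x$schema_version))
  cat(sprintf("  reads: %d total, %d family, %d off-target, %d unassigned to any reference\n",
              x$counts$total_reads, x$counts$family_reads,
              x$counts$discarded_offtarget, x$counts$unalignable_reads))
  cat(sprintf("  alignment: %s%% local + %s%% global of family reads\n",
              f1(x$alignment_split$pct_local), f1(x$alignment_split$pct_global)))
  cat(sprintf("  editing %s%% (deletions %s%%, insertions %s%%)\n",
              f1(x$summary$editing_pct), f1(x$summary$deletions_pct),
              f1(x$summary$insertions_pct)))
  if (nrow(x$per_guide)) {
    cat("  per-guide efficiency:",
        paste(sprintf("%s %s%%", x$per_guide$guide,
                      f1(x$per_guide$efficiency_pct)), collapse = ", "), "\n")
  }
  sp <- x$spectrum[x$spectrum$frequency_pct >= x$display_threshold, ,
                   drop = FALSE]
  if (nrow(sp)) {
    cat(sprintf("  indel spectrum (>= %.1f%%):\n", x$display_threshold))
    for (i in seq_len(nrow(sp))) {
      cat(sprintf("    %+d bp  %s%%\n", sp$signed_length[i],
                  f1(sp$frequency_pct[i])))
    }
  }
  invisible(x)
}

#' Plot the indel length spectrum
#'
#' Bars of abundance-weighted indel frequency by signed length, with the
#' display threshold applied; deletions negative, insertions positive.
#'
#' @param report An `amp_report`.
#' @param threshold Display threshold in percent (default the report's,
#'   0.5).
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(report, threshold = NULL) {
  threshold <- threshold %||% report$display_threshold
  sp <- report$spectrum[report$spectrum$frequency_pct >= threshold, ,
                        drop = FALSE]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$signed_length,
                                   y = .data$frequency_pct,
                                   fill = .data$signed_length < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "indel length (bp)", y = "frequency (% of indels)",
                  title = report$sample_id) +
    ggplot2::theme_minimal()
}

#' @rdname plot_indel_spectrum
#' @param object An `amp_report`.
#' @param ... Passed on (unused).
#' @export
autoplot.amp_report <- function(object, ...) plot_indel_spectrum(object)

#' Plot excision frequency by Amp type
#'
#' @param report An `amp_report`.
#' @return A ggplot object.
#' @export
plot_excision_by_type <- function(report) {
  df <- report$excision_by_type
  df$alpha_type <- factor(df$alpha_type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha_type,
                                   y = .data$excision_pct)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Amp type", y = "excision frequency (%)",
                  title = report$sample_id) +
    ggplot2::theme_minimal()
}

#' Serialize a report to JSON
#'
#' @param report An `amp_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$classified <- NULL   # sequences live in the TSV/FASTA outputs
  x$dsodn_calls$guides_covered <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Write all report tables to a directory
#'
#' Emits `report.json` plus flat TSVs (summary, per-guide, spectrum,
#' excision-by-type, dsODN calls, epitope loss).
#'
#' @param report An `amp_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(report, file.path(dir, "report.json"))
  w <- function(df, f) readr::write_tsv(df, file.path(dir, f), progress = FALSE)
  w(tidy(report, "summary"), "summary.tsv")
  w(tidy(report, "per_guide"), "per_guide.tsv")
  w(tidy(report, "spectrum"), "spectrum.tsv")
  w(tidy(report, "excision_by_type"), "excision_by_type.tsv")
  w(tidy(report, "epitope_loss"), "epitope_loss.tsv")
  calls <- report$dsodn_calls
  if (nrow(calls)) {
    calls$guides_covered <- vapply(calls$guides_covered, paste, character(1),
                                   collapse = ",")
  } else {
    calls$guides_covered <- character(0)
  }
  w(calls, "dsodn_calls.tsv")
  invisible(dir)
}
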