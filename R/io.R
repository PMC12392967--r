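#' Read sequences from a FASTA file
#'
#' Wrapped and single-line records are both accepted; the record id is the
#' first whitespace-delimited token of the header. Gzip input is transparent.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `id` and `sequence` (uppercase DNA).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  tibble(id = ids, sequence = unname(toupper(as.character(x))))
}

#' Read merged amplicon reads from a FASTQ file
#'
#' Qualities are parsed but ignored by default, matching a workflow whose
#' quality filtering happens upstream of this entry point. An optional mean
#' Phred-score filter can be switched on.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @param min_mean_q Optional minimum mean Phred quality; reads below it are
#'   dropped. Default `NULL` (off).
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fastq <- function(path, min_mean_q = NULL) {
  if (is.null(min_mean_q)) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- sub("\\s.*$", "", names(x))
    return(tibble(id = ids, sequence = unname(toupper(as.character(x)))))
  }
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  q <- methods::as(Biostrings::quality(x), "IntegerList")
  keep <- vapply(q, function(v) mean(v) >= min_mean_q, logical(1))
  x <- x[keep]
  ids <- sub("\\s.*$", "", names(x))
  tibble(id = ids, sequence = unname(toupper(as.character(x))))
}

#' Write sequences to FASTA
#'
#' Output is wrapped at 80 columns. With `size_annot = TRUE` a Usearch-style
#' `;size=N` suffix is appended to each header from the `count` column.
#'
#' @param df Tibble with columns `id` and `sequence` (and `count` if
#'   `size_annot`).
#' @param path Output path.
#' @param size_annot Append `;size=N` to headers. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, size_annot = FALSE) {
  ids <- df$id
  if (size_annot) ids <- paste0(ids, ";size=", df$count)
  x <- Biostrings::DNAStringSet(df$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a two-column abundance table
#'
#' @param path TSV with columns id and abundance (no header required; a
#'   header line is auto-detected).
#' @return Tibble with columns `id`, `abundance`.
#' @export
read_abundance_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("abundance", first, ignore.case = TRUE)
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE,
                        progress = FALSE)
  if (!has_header) names(df)[1:2] <- c("id", "abundance")
  names(df) <- tolower(names(df))
  tibble(id = as.character(df$id), abundance = as.numeric(df$abundance))
}
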