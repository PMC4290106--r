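#' Read a life-history trait table
#'
#' TSV with header and columns `species`, `body_mass_g`, `max_longevity_yr`,
#' `age_first_maturity_yr`. Missing values may be empty or `NA`. All present
#' values must be positive.
#'
#' @param path TSV file.
#' @return data.frame with one row per species.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("species", "body_mass_g", "max_longevity_yr", "age_first_maturity_yr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_avigc("trait table missing columns: ",
                               paste(miss, collapse = ", "))
  df <- df[, need]
  for (col in need[-1L]) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.na(df[[col]]) & df[[col]] <= 0))
      stop_avigc("non-positive values in ", col)
  }
  if (anyDuplicated(df$species)) stop_avigc("duplicate species in trait table")
  df <- df[order(df$species), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a recombination map (BED-like TSV)
#'
#' Columns `chrom`, `start`, `end`, `rate_cm_mb`; coordinates are 0-based
#' half-open. Windows must be non-overlapping within a chromosome and rates
#' non-negative.
#'
#' @param path TSV file.
#' @param genome optional reference genome id stored as an attribute.
#' @return data.frame of windows, sorted by (chrom, start).
#' @export
read_recomb_map <- function(path, genome = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("chrom", "start", "end", "rate_cm_mb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_avigc("recombination map missing columns: ",
                               paste(miss, collapse = ", "))
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$rate_cm_mb <- as.numeric(df$rate_cm_mb)
  if (any(df$end <= df$start)) stop_avigc("recombination window with end <= start")
  if (any(df$rate_cm_mb < 0, na.rm = TRUE)) stop_avigc("negative recombination rate")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, ]
    if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)]))
      stop_avigc("overlapping windows on chromosome ", ch)
  }
  attr(df, "genome") <- genome
  rownames(df) <- NULL
  df
}

#' Read ortholog genomic locations
#'
#' Columns `ortholog_id`, `genome`, `chrom`, `start`, `end`; 0-based
#' half-open coordinates.
#'
#' @param path TSV file.
#' @return data.frame sorted by ortholog id.
#' @export
read_locations <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("ortholog_id", "genome", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_avigc("location table missing columns: ",
                               paste(miss, collapse = ", "))
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$end <= df$start)) stop_avigc("location with end <= start")
  df[order(df$ortholog_id), , drop = FALSE]
}

#' Write a table as deterministic TSV
#'
#' Writes tab-separated output with a header, no quoting, `NA` for missing
#' values, rows sorted by the first column (then the second, if present) so
#' that repeated runs are byte-identical.
#'
#' @param rows data.frame.
#' @param path output file.
#' @param sort sort rows by leading columns first (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, sort = TRUE) {
  stopifnot(is.data.frame(rows))
  if (sort && nrow(rows) > 1L) {
    keys <- rows[, seq_len(min(2L, ncol(rows))), drop = FALSE]
    rows <- rows[do.call(order, unname(keys)), , drop = FALSE]
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
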