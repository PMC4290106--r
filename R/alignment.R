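ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Ortholog alignment object
#'
#' A multiple sequence alignment for one ortholog, either protein-coding
#' (frame starts at column 1, length divisible by 3) or intronic. Sequences
#' are stored as an upper-case character matrix (species x sites) over the
#' alphabet A, C, G, T, N, -. IUPAC ambiguity codes other than N are mapped
#' to N (with a message giving the count).
#'
#' @param ortholog_id single string identifying the ortholog.
#' @param kind `"coding"`, `"intron"`, or `"c3"` (an alignment of
#'   pre-extracted third codon positions only).
#' @param sequences named character vector of aligned sequences (names are
#'   species ids), or a character matrix with one row per species.
#' @return an object of class `ortholog_alignment` with fields
#'   `ortholog_id`, `kind`, `species`, `matrix` (species x sites) and
#'   `length`.
#' @export
ortholog_alignment <- function(ortholog_id, kind = c("coding", "intron", "c3"),
                               sequences) {
  kind <- match.arg(kind)
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences)))
      stop_avigc("sequences must be named by species id")
    seqs <- toupper(as.character(sequences))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[lens != lens[1L]]
      stop_avigc("alignment '", ortholog_id, "': sequence length mismatch for ",
                 paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (is.null(rownames(m))) stop_avigc("sequence matrix must have species rownames")
  if (anyDuplicated(rownames(m)))
    stop_avigc("duplicate species ids in alignment '", ortholog_id, "'")
  bad <- !(m %in% ALPHABET)
  if (any(bad)) {
    message("alignment '", ortholog_id, "': ", sum(bad),
            " ambiguity/unknown characters mapped to N")
    m[bad] <- "N"
  }
  if (kind == "coding" && ncol(m) %% 3L != 0L)
    stop_avigc("coding alignment '", ortholog_id,
               "' length ", ncol(m), " not divisible by 3")
  structure(
    list(ortholog_id = as.character(ortholog_id), kind = kind,
         species = rownames(m), matrix = m, length = ncol(m)),
    class = "ortholog_alignment")
}

## low-level constructor for internally generated matrices that are
## upper-case A/C/G/T/N/- by construction (no re-canonicalization)
new_ortholog_alignment <- function(ortholog_id, kind, m) {
  structure(
    list(ortholog_id = as.character(ortholog_id), kind = kind,
         species = rownames(m), matrix = m, length = ncol(m)),
    class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("<ortholog_alignment> ", x$ortholog_id, " (", x$kind, "): ",
      length(x$species), " species x ", x$length, " sites\n", sep = "")
  invisible(x)
}

#' Read an ortholog alignment from FASTA
#'
#' Headers are truncated at the first whitespace to obtain species ids; an
#' optional `name_map` (named character vector, raw id -> species id) is
#' applied afterwards. Sequences are upper-cased and validated; ragged
#' lengths are rejected with the offending species named.
#'
#' @param path FASTA file.
#' @param kind `"coding"` or `"intron"`.
#' @param ortholog_id id to assign; defaults to the file name without
#'   extension.
#' @param name_map optional named character vector renaming sequences.
#' @return an [ortholog_alignment].
#' @export
read_alignment <- function(path, kind = c("coding", "intron"),
                           ortholog_id = NULL, name_map = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_avigc("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop_avigc("malformed FASTA at line 1 of ", path, ": expected '>' header")
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_avigc("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (!is.null(name_map)) {
    hit <- ids %in% names(name_map)
    ids[hit] <- unname(name_map[ids[hit]])
  }
  seqs <- setNames(as.character(ss), ids)
  if (is.null(ortholog_id))
    ortholog_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  ortholog_alignment(ortholog_id, kind, seqs)
}

#' Write an ortholog alignment to FASTA
#'
#' @param aln an [ortholog_alignment].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", aln$species), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Extract third codon position columns as a state matrix
#'
#' @param aln coding [ortholog_alignment].
#' @return integer matrix (species x sites) with states 1..4 = A,C,G,T and
#'   NA for gaps/N.
#' @export
third_position_states <- function(aln) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  m <- switch(aln$kind,
              coding = aln$matrix[, seq(3L, aln$length, by = 3L), drop = FALSE],
              c3 = aln$matrix,
              stop_avigc("third positions undefined for kind '", aln$kind, "'"))
  encode_states(m)
}

encode_states <- function(m) {
  matrix(match(m, c("A", "C", "G", "T")), nrow(m), ncol(m),
         dimnames = dimnames(m))
}

decode_states <- function(s) {
  m <- c("A", "C", "G", "T")[s]
  if (anyNA(m)) m[is.na(m)] <- "N"
  matrix(m, nrow(s), ncol(s), dimnames = dimnames(s))
}
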