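#' Read a feature-by-sample abundance table
#'
#' Reads a tab-separated matrix whose first column holds feature identifiers
#' and whose header row holds sample identifiers. This wide tibble -- one row
#' per feature, one numeric column per sample -- is the common currency of
#' every pipeline stage (counts, RPKM, raw or log2 intensities).
#'
#' @param path Path to a TSV file. Lines starting with `#` are treated as
#'   comments (stage provenance headers written by [write_omics_tsv()]).
#' @param kind One of `"counts"`, `"intensity"`, `"log2"`; recorded as the
#'   `omics_kind` attribute and otherwise not interpreted.
#' @return A tibble with a `feature_id` character column followed by numeric
#'   sample columns.
#' @export
read_omics_tsv <- function(path, kind = c("intensity", "counts", "log2")) {
  kind <- match.arg(kind)
  if (!file.size(path) > 0) abort(paste0("empty file: ", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) < 2) abort("matrix needs a feature column and >= 1 sample column")
  names(tbl)[1] <- "feature_id"
  tbl$feature_id <- as.character(tbl$feature_id)
  dup <- tbl$feature_id[duplicated(tbl$feature_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated feature id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad <- names(tbl)[-1][!vapply(tbl[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  attr(tbl, "omics_kind") <- kind
  tbl
}

#' Write a feature-by-sample table as TSV
#'
#' @param tbl Wide tibble with `feature_id` first column.
#' @param path Output path.
#' @param comment Optional character vector written as `# `-prefixed header
#'   lines (stage name, parameter hash) before the table.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(tbl, path, comment = NULL) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "feature_id")
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a gene-set / protein-complex catalog in GMT format
#'
#' One set per line: name, description, then member identifiers, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- setNames(lapply(lines, function(x) x[-(1:2)]),
                     vapply(lines, `[`, character(1), 1))
  }
  if (anyDuplicated(names(sets))) {
    abort(paste0("duplicate set name(s): ",
                 paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  lapply(sets, unique)
}

#' Write a catalog as GMT
#'
#' @param catalog Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions (defaults
#'   to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  stopifnot(is.list(catalog), !is.null(names(catalog)))
  if (is.null(descriptions)) descriptions <- rep("na", length(catalog))
  lines <- vapply(seq_along(catalog), function(i) {
    paste(c(names(catalog)[i], descriptions[i], catalog[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Headers are truncated at the first whitespace to form identifiers.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    lines <- readLines(path)
    idx <- cumsum(startsWith(lines, ">"))
    hdr <- sub("\\s.*$", "", sub("^>", "", lines[startsWith(lines, ">")]))
    seqs <- vapply(split(lines[!startsWith(lines, ">")], idx[!startsWith(lines, ">")]),
                   paste0, character(1), collapse = "")
    names(seqs) <- hdr
  }
  if (anyDuplicated(names(seqs))) abort("duplicate sequence id(s) in FASTA")
  seqs
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Convert between wide omics tibbles and numeric matrices
#'
#' `omics_as_matrix()` turns a wide tibble (`feature_id` + sample columns)
#' into a numeric matrix with feature rownames; `matrix_as_omics()` is its
#' inverse.
#'
#' @param tbl Wide omics tibble.
#' @return A numeric matrix (respectively a wide tibble).
#' @export
omics_as_matrix <- function(tbl) {
  stopifnot(names(tbl)[1] == "feature_id")
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl$feature_id
  m
}

#' @rdname omics_as_matrix
#' @param m Numeric matrix with feature rownames.
#' @export
matrix_as_omics <- function(m) {
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}
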