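# Text interchange formats: GCT 1.2 matrices, GRP gene lists, TSV tables.

#' Write a numeric matrix as GCT 1.2 text
#'
#' @param m numeric matrix with row (gene/probe) and column (sample or
#'   profile) names.
#' @param path output file path.
#' @param description optional per-row description column (defaults to the
#'   row names).
#' @export
write_gct <- function(m, path, description = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (is.null(description)) description <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = description, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 / 1.3 text matrix
#'
#' @param path GCT file path.
#' @return numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || !startsWith(lines[1], "#1."))
    stop(sprintf("%s: line 1: not a GCT version header", path))
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2 || any(is.na(dims[1:2])))
    stop(sprintf("%s: line 2: cannot parse dimensions", path))
  body <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            stringsAsFactors = FALSE)
  # GCT 1.3 may carry extra annotation columns/rows; 1.2 has exactly two
  n_meta <- ncol(body) - dims[2]
  if (n_meta < 1 || nrow(body) < dims[1])
    stop(sprintf("%s: header dimensions (%d x %d) disagree with body (line 3+)",
                 path, dims[1], dims[2]))
  body <- utils::tail(body, dims[1])
  m <- as.matrix(body[, seq(n_meta + 1, ncol(body)), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- body[[1]]
  if (nrow(m) != dims[1] || ncol(m) != dims[2])
    stop(sprintf("%s: header dimensions (%d x %d) disagree with body (%d x %d)",
                 path, dims[1], dims[2], nrow(m), ncol(m)))
  m
}

#' Write a gene list as a GRP file (one id per line)
#' @param genes character vector of gene ids.
#' @param path output file path.
#' @export
write_grp <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a GRP gene list
#'
#' One gene id per line; blank lines are skipped and `#` comment lines
#' ignored; order preserved.
#'
#' @param path GRP file path.
#' @return character vector of gene ids.
#' @export
read_grp <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a signature as a paired UP/DN GRP file set
#' @param sig a `cmap_signature`.
#' @param prefix path prefix; files `<prefix>_UP.grp` and `<prefix>_DN.grp`
#'   are written.
#' @export
write_signature_grp <- function(sig, prefix) {
  write_grp(sig$up_genes, paste0(prefix, "_UP.grp"))
  write_grp(sig$down_genes, paste0(prefix, "_DN.grp"))
  invisible(prefix)
}

# deterministic TSV writer used for all pipeline outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
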