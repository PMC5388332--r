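#' Read a gene-by-time expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns, with a header row of
#' time-point labels and the gene identifier in the first column.  The
#' delimiter is auto-detected from the header (tab preferred, then comma)
#' unless given explicitly.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @return numeric matrix with gene ids as row names and time labels as
#'   column names.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop("ragged table in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3L) stop("need a gene-id column plus at least two time points")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifier: ", ids[anyDuplicated(ids)])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- is.na(v) & !is.na(vals[[j]])
    if (any(bad))
      stop("non-numeric value '", vals[[j]][which(bad)[1L]], "' at gene '",
           ids[which(bad)[1L]], "', column '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  validate_expression_matrix(x, require_ids = TRUE)
  x
}

#' Write a matrix in the package's delimited layout
#'
#' Writes genes in rows with the identifier in the first column (header
#' `gene`) and one column per variable, so that
#' [read_expression_matrix()] round-trips the values exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param sep field delimiter (tab by default).
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
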