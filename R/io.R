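#' Read a delimited expression matrix
#'
#' Parses a delimited text file whose first row holds time-point labels and
#' whose first column holds gene identifiers; every other cell is a numeric
#' expression value (e.g. RPKM). Row order in the file is preserved.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, default tab.
#' @return A list with components \code{ids} (character vector of gene
#'   identifiers), \code{matrix} (numeric genes x time matrix with
#'   \code{dimnames}) and \code{time_labels} (character vector).
#' @details Errors name the offending line for ragged rows and the
#'   (line, column) coordinates for non-numeric cells; duplicated gene
#'   identifiers abort.
#' @seealso [write_expression_matrix()], [expression_dataset()]
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and at least one gene row: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell over the id column
  ncol_body <- length(fields[[2L]])
  time_labels <- if (length(header) == ncol_body) header[-1L] else header
  ntime <- length(time_labels)
  body <- fields[-1L]
  n <- length(body)
  ids <- character(n)
  mat <- matrix(NA_real_, n, ntime)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ntime + 1L) {
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + 1L, ntime + 1L, length(row)))
    }
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(vals) & !(toupper(row[-1L]) %in% c("NA", "NAN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at line %d, column %d",
                   row[-1L][bad[1L]], i + 1L, bad[1L] + 1L))
    }
    mat[i, ] <- vals
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated gene identifier(s): ", paste(dup, collapse = ", "))
  }
  dimnames(mat) <- list(ids, time_labels)
  list(ids = ids, matrix = mat, time_labels = time_labels)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: values are written with 17
#' significant digits so a write/read round trip is bitwise exact for
#' doubles.
#'
#' @param ids Character vector of gene identifiers, one per row.
#' @param matrix Numeric genes x time matrix.
#' @param time_labels Column labels.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(ids, matrix, time_labels, path,
                                    delimiter = "\t") {
  stopifnot(length(ids) == nrow(matrix), length(time_labels) == ncol(matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", time_labels), collapse = delimiter), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(ids[i], sprintf("%.17g", matrix[i, ])),
                     collapse = delimiter), con)
  }
  invisible(path)
}

#' Read a gene set from a plain-text list
#'
#' One identifier per line; blank lines and lines starting with \code{#} are
#' ignored; Windows line endings are tolerated. Duplicates are dropped,
#' case is preserved.
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers, in first-seen order.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (!length(ids)) stop("gene set file contains no identifiers: ", path)
  ids
}

#' Assemble and validate an internal/external expression dataset
#'
#' Pairs the expression matrix of the gene group under study (the internal
#' group, whose dynamics will be decomposed) with the matrix of an external
#' regulator group (e.g. species-specific transcription factors) sharing the
#' same time grid. Time labels are metadata only: all downstream computation
#' uses the sample index t = 1..T, which is what makes datasets on different
#' absolute time grids comparable.
#'
#' @param internal A list with \code{ids} and \code{matrix} (as returned by
#'   [read_expression_matrix()]) for the internal group.
#' @param external Same, for the external regulator group.
#' @param time_labels Optional column labels; defaults to those of the
#'   internal matrix, else \code{1..T}.
#' @param name Text label for the dataset.
#' @param log2 If \code{TRUE}, apply \code{log2(x + 1)} to both matrices.
#'   Off by default: values are used as-is.
#' @param center If \code{TRUE}, mean-center each gene across time.
#'   Off by default.
#' @return An object of class \code{expression_dataset} with fields
#'   \code{name}, \code{internal_ids}, \code{external_ids},
#'   \code{internal_matrix}, \code{external_matrix}, \code{time_labels},
#'   \code{T}.
#' @details Genes present in both groups are permitted (regulators can sit
#'   inside the group they regulate) but are reported in a warning.
#'   Zero-variance genes are retained, with a warning listing them. Any
#'   missing or non-finite value aborts: the estimator has no missing-data
#'   mechanism.
#' @export
expression_dataset <- function(internal, external, time_labels = NULL,
                               name = "dataset", log2 = FALSE, center = FALSE) {
  im <- as.matrix(internal$matrix)
  em <- as.matrix(external$matrix)
  iid <- as.character(internal$ids)
  eid <- as.character(external$ids)
  if (ncol(im) != ncol(em)) {
    stop(sprintf("time grids differ: internal has %d samples, external %d",
                 ncol(im), ncol(em)))
  }
  tt <- ncol(im)
  if (tt < 4L) stop("too few time samples (T = ", tt, "); at least 4 required")
  if (nrow(im) < 2L) stop("internal group needs at least 2 genes")
  if (nrow(em) < 1L) stop("external group needs at least 1 gene")
  if (anyDuplicated(iid)) stop("duplicated identifiers in internal group")
  if (anyDuplicated(eid)) stop("duplicated identifiers in external group")
  if (!all(is.finite(im)) || !all(is.finite(em))) {
    stop("non-finite expression values present; missing data are not imputed")
  }
  if (is.null(time_labels)) {
    time_labels <- colnames(im)
    if (is.null(time_labels)) time_labels <- as.character(seq_len(tt))
  }
  if (length(time_labels) != tt) stop("time_labels length must equal T")
  if (log2) {
    if (any(im < 0) || any(em < 0)) {
      stop("log2(x + 1) preprocessing requires nonnegative values")
    }
    im <- log2(im + 1)
    em <- log2(em + 1)
  }
  if (center) {
    im <- im - rowMeans(im)
    em <- em - rowMeans(em)
  }
  overlap <- intersect(iid, eid)
  if (length(overlap)) {
    warning("identifiers present in both groups: ",
            paste(utils::head(overlap, 10L), collapse = ", "),
            if (length(overlap) > 10L) ", ..." else "")
  }
  flat <- c(iid[apply(im, 1L, stats::var) == 0], eid[apply(em, 1L, stats::var) == 0])
  if (length(flat)) {
    warning("zero-variance gene(s) retained: ",
            paste(utils::head(flat, 10L), collapse = ", "),
            if (length(flat) > 10L) ", ..." else "")
  }
  dimnames(im) <- list(iid, time_labels)
  dimnames(em) <- list(eid, time_labels)
  structure(
    list(name = name, internal_ids = iid, external_ids = eid,
         internal_matrix = im, external_matrix = em,
         time_labels = as.character(time_labels), T = tt),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s'\n", x$name))
  cat(sprintf("  internal group: %d genes\n", length(x$internal_ids)))
  cat(sprintf("  external group: %d genes\n", length(x$external_ids)))
  cat(sprintf("  time samples:   T = %d (%s%s)\n", x$T,
              paste(utils::head(x$time_labels, 5L), collapse = ", "),
              if (x$T > 5L) ", ..." else ""))
  invisible(x)
}
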