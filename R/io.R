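#' Read an expression matrix with missing cells
#'
#' Reads a delimited text file whose header row holds sample identifiers and
#' whose first column holds gene identifiers. Cells equal to `missing_token`
#' (or any of `""`, `"NA"`, `"NaN"`, `"null"`) are recorded as unobserved;
#' all other cells must parse as numbers. Malformed input — a ragged row, a
#' duplicate identifier, a non-numeric cell — fails with a message naming the
#' offending line.
#'
#' @param path file path.
#' @param dialect `"tsv"` (tab-separated, default) or `"csv"`.
#' @param missing_token string marking unobserved cells; default `"NA"`.
#' @param scale scale tag to attach, `"raw"` (default) or `"log"`.
#' @return a list with components `matrix` (an [expression_matrix()], `NA`
#'   at unobserved cells) and `mask` (an [observation_mask()] over the
#'   observed cells).
#' @export
read_matrix <- function(path, dialect = c("tsv", "csv"), missing_token = "NA",
                        scale = c("raw", "log")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_("%s: need a header row and at least one gene row", path)
  na_tokens <- unique(c(missing_token, "", "NA", "NaN", "null"))

  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop_("%s, line 1: malformed header (no sample columns)", path)
  sample_ids <- header[-1L]
  if (any(!nzchar(sample_ids))) stop_("%s, line 1: empty sample id in header", path)
  if (anyDuplicated(sample_ids))
    stop_("%s, line 1: duplicate sample id '%s'", path,
          sample_ids[duplicated(sample_ids)][1L])
  n <- length(sample_ids)

  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  m <- length(body)
  gene_ids <- character(m)
  values <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    fields <- body[[i]]
    if (length(fields) != n + 1L)
      stop_("%s, line %d: expected %d fields, found %d", path, i + 1L, n + 1L, length(fields))
    gene_ids[i] <- fields[1L]
    cells <- fields[-1L]
    miss <- cells %in% na_tokens
    parsed <- suppressWarnings(as.numeric(cells[!miss]))
    if (anyNA(parsed)) {
      bad <- which(!miss)[which(is.na(parsed))[1L]]
      stop_("%s, line %d: cell '%s' in column %d is not numeric", path,
            i + 1L, cells[bad], bad + 1L)
    }
    values[i, !miss] <- parsed
  }
  if (anyDuplicated(gene_ids)) {
    d <- which(duplicated(gene_ids))[1L]
    stop_("%s, line %d: duplicate gene id '%s'", path, d + 1L, gene_ids[d])
  }
  x <- expression_matrix(values, gene_ids, sample_ids, scale = scale)
  mask <- observation_mask(which(!is.na(values)), m, n)
  list(matrix = x, mask = mask)
}

#' Write an expression matrix with missing cells
#'
#' Inverse of [read_matrix()]: observed cells are written as decimal
#' numerals at full precision (`%.17g`), unobserved cells as
#' `missing_token`.
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @param mask an [observation_mask()]; defaults to the non-`NA` cells.
#' @param dialect `"tsv"` or `"csv"`.
#' @param missing_token string written for unobserved cells.
#' @export
write_matrix <- function(x, path, mask = NULL, dialect = c("tsv", "csv"),
                         missing_token = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  v <- values_of(x)
  if (is.null(mask)) mask <- observation_mask(which(!is.na(v)), nrow(v), ncol(v))
  if (!all(dim(v) == mask$shape)) stop_("matrix and mask dimensions disagree")
  cells <- matrix(missing_token, nrow(v), ncol(v))
  cells[mask$idx] <- sprintf("%.17g", v[mask$idx])
  lines <- c(paste(c("gene_id", colnames(v)), collapse = sep),
             paste(rownames(v), apply(cells, 1L, paste, collapse = sep), sep = sep))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read / write an observation mask
#'
#' Masks are exchanged either as MatrixMarket coordinate `pattern` files
#' (1-based indices, as that standard prescribes) or as two-column
#' tab-separated (gene_id, sample_id) pairs resolved against the supplied
#' identifier vectors.
#'
#' @param path file path.
#' @param format `"matrixmarket"` or `"pairs"`.
#' @param gene_ids,sample_ids identifier vectors; required for the `"pairs"`
#'   format.
#' @return `read_mask` returns an [observation_mask()].
#' @export
read_mask <- function(path, format = c("matrixmarket", "pairs"),
                      gene_ids = NULL, sample_ids = NULL) {
  format <- match.arg(format)
  if (format == "matrixmarket") {
    sm <- Matrix::readMM(path)
    tm <- methods::as(sm, "TsparseMatrix")
    observation_mask(cbind(tm@i + 1L, tm@j + 1L), nrow(sm), ncol(sm))
  } else {
    if (is.null(gene_ids) || is.null(sample_ids))
      stop_("the pairs format needs `gene_ids` and `sample_ids`")
    pairs <- utils::read.delim(path, header = FALSE, colClasses = "character")
    i <- match(pairs[[1L]], gene_ids)
    j <- match(pairs[[2L]], sample_ids)
    if (anyNA(i)) stop_("%s: unknown gene id '%s'", path, pairs[[1L]][which(is.na(i))[1L]])
    if (anyNA(j)) stop_("%s: unknown sample id '%s'", path, pairs[[2L]][which(is.na(j))[1L]])
    observation_mask(cbind(i, j), length(gene_ids), length(sample_ids))
  }
}

#' @rdname read_mask
#' @param mask an [observation_mask()].
#' @export
write_mask <- function(mask, path, format = c("matrixmarket", "pairs"),
                       gene_ids = NULL, sample_ids = NULL) {
  format <- match.arg(format)
  ent <- mask_entries(mask)
  if (format == "matrixmarket") {
    sm <- Matrix::sparseMatrix(i = ent[, "row"], j = ent[, "col"], x = rep(1, nrow(ent)),
                               dims = mask$shape)
    Matrix::writeMM(methods::as(sm, "nMatrix"), path)
  } else {
    if (is.null(gene_ids) || is.null(sample_ids))
      stop_("the pairs format needs `gene_ids` and `sample_ids`")
    utils::write.table(data.frame(gene_ids[ent[, "row"]], sample_ids[ent[, "col"]]),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
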