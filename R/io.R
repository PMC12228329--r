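# Readers and writers: Matrix Market sparse matrices with gene/barcode
# sidecars, dense delimited matrices, marker-set JSON/CSV, annotation TSV.
# All readers are gzip-transparent.

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an expression matrix
#'
#' Two on-disk layouts are supported: Matrix Market triplet (`.mtx`,
#' 1-based indices on disk) with `features`/`barcodes` sidecar tables,
#' and dense delimited text with genes as rows (first column gene ids,
#' header line cell ids; tab or comma, auto-detected). Either may be
#' gzipped.
#'
#' @param path path to the `.mtx`/`.mtx.gz` file or the dense table.
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param features,barcodes sidecar paths for `mtx` input; default to
#'   `features.tsv[.gz]` (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`
#'   next to the matrix. First column is used as the identifier.
#' @param layer layer tag for the result (`"raw"` or `"normalized"`).
#' @return an `expr_matrix` (sparse for mtx input, dense otherwise).
#' @export
read_expression <- function(path, format = c("auto", "mtx", "dense"),
                            features = NULL, barcodes = NULL,
                            layer = "raw") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "dense"
  }
  if (format == "mtx") {
    read_expression_mtx(path, features, barcodes, layer)
  } else {
    read_expression_dense(path, layer)
  }
}

read_expression_mtx <- function(path, features, barcodes, layer) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  features <- features %||% find_sidecar(path, c("features.tsv",
                                                 "genes.tsv"))
  barcodes <- barcodes %||% find_sidecar(path, "barcodes.tsv")
  m <- tryCatch({
    con <- open_maybe_gz(path)
    on.exit(close(con))
    Matrix::readMM(con)
  }, error = function(e) {
    diagnose_mtx(path)
    stop("failed to read Matrix Market file ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  gid <- read_sidecar_column(features)
  cid <- read_sidecar_column(barcodes)
  if (length(gid) != nrow(m)) {
    stop(sprintf("features sidecar has %d entries for %d matrix rows",
                 length(gid), nrow(m)), call. = FALSE)
  }
  if (length(cid) != ncol(m)) {
    stop(sprintf("barcodes sidecar has %d entries for %d matrix columns",
                 length(cid), ncol(m)), call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(gid, cid)
  expression_matrix(m, layer = layer)
}

find_sidecar <- function(mtx_path, names) {
  dir <- dirname(mtx_path)
  for (nm in names) {
    for (cand in file.path(dir, c(nm, paste0(nm, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  stop("sidecar file not found next to ", mtx_path, " (tried: ",
       paste(names, collapse = ", "), ")", call. = FALSE)
}

read_sidecar_column <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  as.character(df[[1]])
}

# locate the first malformed triplet line so the error can cite it
diagnose_mtx <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  body <- which(!grepl("^%", lines) & nzchar(lines))
  for (pos in seq_along(body)) {
    ln <- body[pos]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    n_expect <- if (pos == 1) 3L else c(2L, 3L)
    ok <- length(fields) %in% n_expect &&
      !anyNA(suppressWarnings(as.numeric(fields)))
    if (!ok) {
      stop("malformed Matrix Market entry at line ", ln, ": '",
           lines[ln], "'", call. = FALSE)
    }
  }
  invisible(NULL)
}

read_expression_dense <- function(path, layer) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- open_maybe_gz(path)
  first <- readLines(con, n = 1)
  close(con)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          row.names = 1, check.names = FALSE,
                          quote = "", comment.char = "")
  expression_matrix(as.matrix(df), layer = layer)
}

#' Write an expression matrix
#'
#' Sparse matrices go to Matrix Market plus `features.tsv` and
#' `barcodes.tsv` sidecars in `dir`; dense matrices to a single TSV with
#' genes as rows.
#'
#' @param x an `expr_matrix`.
#' @param dir output directory for sparse output (created if missing).
#' @param path output file for dense output.
#' @export
write_expression <- function(x, dir = NULL, path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(x$values), file.path(dir, "features.tsv"))
    writeLines(colnames(x$values), file.path(dir, "barcodes.tsv"))
    invisible(file.path(dir, "matrix.mtx"))
  } else if (!is.null(path)) {
    df <- data.frame(gene = rownames(x$values),
                     as_dense(x$values), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
  } else {
    stop("give either `dir` (sparse) or `path` (dense)", call. = FALSE)
  }
}

#' Read and write marker-set files
#'
#' JSON layout: `{"tissue": ..., "cell_types": {"name": ["gene", ...]}}`.
#' CSV layout: two columns `cell_type,gene`, one row per marker, ordered.
#' Both round-trip the per-type gene order and the tissue tag (CSV has no
#' tissue field; pass `tissue` when reading).
#'
#' @param path file path, `.json` or `.csv`/`.tsv` (format by extension).
#' @param tissue tissue tag for CSV input.
#' @param bounds size bounds for the constructed `marker_set`.
#' @return [read_markers()] returns a `marker_set`.
#' @export
read_markers <- function(path, tissue = "unspecified", bounds = c(1L, 30L)) {
  if (grepl("\\.json(\\.gz)?$", path)) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyMatrix = FALSE)
    sets <- lapply(obj$cell_types, as.character)
    marker_set(sets, tissue = obj$tissue %||% tissue, bounds = bounds)
  } else {
    df <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
    if (!all(c("cell_type", "gene") %in% names(df))) {
      stop("marker table needs `cell_type` and `gene` columns",
           call. = FALSE)
    }
    sets <- split(df$gene, factor(df$cell_type,
                                  levels = unique(df$cell_type)))
    marker_set(lapply(sets, as.character), tissue = tissue,
               bounds = bounds)
  }
}

detect_sep <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
}

#' @param S a `marker_set` (for [write_markers()]).
#' @rdname read_markers
#' @export
write_markers <- function(S, path) {
  stopifnot(inherits(S, "marker_set"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(tissue = S$tissue, cell_types = S$sets),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      cell_type = rep(names(S$sets), lengths(S$sets)),
      gene = unlist(S$sets, use.names = FALSE))
    utils::write.table(df, path, sep = detect_sep(path), quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write annotation results
#'
#' TSV with `cell_id`, `label`, `top_score`; optionally the full
#' cell-types x cells score matrix as a second TSV.
#'
#' @param result a `cell_annotation` with labels assigned.
#' @param path output TSV path.
#' @param scores_path optional path for the full score matrix.
#' @export
write_annotation <- function(result, path, scores_path = NULL) {
  stopifnot(inherits(result, "cell_annotation"))
  if (is.null(result$labels)) {
    stop("labels not assigned yet; run assign_labels()", call. = FALSE)
  }
  df <- data.frame(cell_id = names(result$labels),
                   label = unname(result$labels),
                   top_score = unname(result$top_score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scores_path)) {
    sm <- data.frame(cell_type = rownames(result$scores),
                     result$scores, check.names = FALSE)
    utils::write.table(sm, scores_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
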