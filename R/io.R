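#' Read a counts matrix
#'
#' Reads a features x samples expression matrix from TSV or MatrixMarket.
#'
#' The TSV dialect is tab-separated UTF-8 with `#`-prefixed comment lines
#' skipped; the header's first column is the literal `feature_id`, the
#' remaining header fields are sample IDs, and each following row is one
#' feature. MatrixMarket input (`format = "mtx"`) expects the `.mtx` file to
#' be accompanied by `features.tsv` and `samples.tsv` sidecars (one ID per
#' line) in the same directory.
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`.
#' @return an [expression_matrix()] with `unit = "count"`, preserving input
#'   feature order.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read_tsv_table(path)
    if (names(tab)[1L] != "feature_id") {
      stop("first column of a counts TSV must be 'feature_id', found '",
           names(tab)[1L], "': ", path)
    }
    fid <- as.character(tab[[1L]])
    vals <- tab[-1L]
    for (j in seq_along(vals)) {
      col <- vals[[j]]
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d (feature '%s'), column '%s' of %s",
                     col[bad[1L]], bad[1L], fid[bad[1L]], names(vals)[j], path))
      }
      neg <- which(num < 0)
      if (length(neg)) {
        stop(sprintf("negative count %s at row %d (feature '%s'), column '%s' of %s",
                     col[neg[1L]], neg[1L], fid[neg[1L]], names(vals)[j], path))
      }
      vals[[j]] <- num
    }
    m <- as.matrix(vals)
    dimnames(m) <- list(fid, names(vals))
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("the Matrix package is required for MatrixMarket input")
    }
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    fpath <- file.path(dir, "features.tsv")
    spath <- file.path(dir, "samples.tsv")
    if (!file.exists(fpath) || !file.exists(spath)) {
      stop("MatrixMarket input requires 'features.tsv' and 'samples.tsv' sidecars in ", dir)
    }
    fid <- readLines(fpath)
    sid <- readLines(spath)
    if (length(fid) != nrow(m) || length(sid) != ncol(m)) {
      stop("sidecar ID counts do not match matrix dimensions for ", path)
    }
    dimnames(m) <- list(fid, sid)
  }
  expression_matrix(m, unit = "count")
}

#' Write an expression matrix
#'
#' Inverse of [read_counts()]. Numeric formatting round-trips exactly:
#' `read_counts(write_counts(x, p), p)` recovers `x$values` bit for bit.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (the latter writes `features.tsv` /
#'   `samples.tsv` sidecars next to the `.mtx` file).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("feature_id", sample_ids(x)), collapse = "\t"), con)
    body <- apply(x$values, 1L, function(row) paste(format_num(row), collapse = "\t"))
    writeLines(paste(feature_ids(x), body, sep = "\t"), con)
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("the Matrix package is required for MatrixMarket output")
    }
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(feature_ids(x), file.path(dir, "features.tsv"))
    writeLines(sample_ids(x), file.path(dir, "samples.tsv"))
  }
  invisible(path)
}

# Shared TSV reader: tab-separated, UTF-8, '#' comment lines skipped, no
# quoting, strings kept as-is.
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a feature annotation TSV
#'
#' @param path TSV with columns `feature_id`, `kind`, `te_type`, `te_class`,
#'   `gene_symbol`, `effective_length`.
#' @return a validated [te_annotation()].
#' @export
read_te_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  te_annotation(read_tsv_table(path))
}

#' Write a feature annotation TSV
#' @param ann a `te_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(ann, path) {
  df <- as.data.frame(ann)
  df$effective_length <- format_num(df$effective_length)
  df$effective_length[df$effective_length == "NA"] <- ""
  write_tsv_table(df, path)
}

#' Read a sample metadata TSV
#' @param path TSV with columns `sample_id`, `group`, `patient_id`.
#' @return a validated [sample_metadata()].
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(read_tsv_table(path))
}

#' Write a sample metadata TSV
#' @param meta a `sample_metadata`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  write_tsv_table(as.data.frame(meta), path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate symbols within one line are deduplicated with a warning. An
#' empty file yields an empty collection.
#'
#' @param path GMT file path.
#' @return a `gene_sets` object: named list of character vectors, with a
#'   `provenance` attribute carrying each set's description field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  prov <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    name <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      dup <- unique(members[duplicated(members)])
      warning(sprintf("GMT set '%s': duplicate symbols deduplicated: %s",
                      name, paste(dup, collapse = ", ")))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT set '%s' (line %d) has no members", name, i))
    sets[[name]] <- members
    prov[name] <- fields[2L]
  }
  gene_sets(sets, provenance = prov)
}

#' Gene set collection constructor
#'
#' @param sets named list of character vectors of gene symbols.
#' @param provenance optional named character vector of per-set provenance
#'   strings.
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, provenance = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("every gene set must be named")
    }
    sets <- lapply(sets, function(s) {
      s <- unique(as.character(s))
      if (!length(s)) stop("gene sets must be non-empty")
      s
    })
  }
  if (is.null(provenance)) provenance <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, provenance = provenance, class = "gene_sets")
}

#' Write gene sets in GMT format
#' @param col a `gene_sets` collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(col, path) {
  prov <- attr(col, "provenance") %||% stats::setNames(rep("", length(col)), names(col))
  lines <- vapply(names(col), function(nm) {
    desc <- prov[[nm]] %||% ""
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, col[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10L)) {
    cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  }
  if (length(x) > 10L) cat(sprintf("  ... %d more\n", length(x) - 10L))
  invisible(x)
}
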