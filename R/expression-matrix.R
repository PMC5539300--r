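#' Expression matrix container
#'
#' A light container for a features x samples expression matrix together with
#' a unit tag. The unit records what the values mean — raw counts, counts per
#' million (CPM), transcripts per million (TPM), or log-transformed versions
#' of the latter two — so that downstream operations can refuse inputs on the
#' wrong scale (e.g. aggregating log values, or log-transforming twice).
#'
#' @param values numeric matrix with unique, non-empty rownames (feature IDs)
#'   and colnames (sample IDs).
#' @param unit one of `"count"`, `"CPM"`, `"TPM"`, `"logCPM"`, `"logTPM"`.
#' @param log_base base of the logarithm for log units (2 or 10), `NA`
#'   otherwise.
#' @param pseudocount pseudocount used in the log transform, `NA` for linear
#'   units.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `unit`, `log_base`, `pseudocount`.
#' @examples
#' m <- matrix(c(5, 0, 1, 3), 2, 2,
#'             dimnames = list(c("AluYa5", "GENE1"), c("s1", "s2")))
#' x <- expression_matrix(m, unit = "count")
#' x
#' @export
expression_matrix <- function(values,
                              unit = c("count", "CPM", "TPM", "logCPM", "logTPM"),
                              log_base = NA_real_,
                              pseudocount = NA_real_) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || any(!nzchar(fid))) {
    stop("expression matrix requires non-empty feature IDs as rownames")
  }
  if (is.null(sid) || any(!nzchar(sid))) {
    stop("expression matrix requires non-empty sample IDs as colnames")
  }
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/NaN value at feature '%s', sample '%s'",
                 fid[bad[1L]], sid[bad[2L]]))
  }
  if (!unit %in% c("logCPM", "logTPM") && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at feature '%s', sample '%s' (unit %s)",
                 fid[bad[1L]], sid[bad[2L]], unit))
  }
  structure(list(values = values, unit = unit,
                 log_base = log_base, pseudocount = pseudocount),
            class = "expr_matrix")
}

is_log_unit <- function(unit) unit %in% c("logCPM", "logTPM")

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature IDs of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of feature IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample IDs of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of sample IDs.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix
#'
#' Row/column subsetting by index or name; always keeps both dimensions.
#' @param x an `expr_matrix`.
#' @param i,j row (feature) and column (sample) indices.
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  x$values <- v[i, j, drop = FALSE]
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, unit = %s",
              nrow(x$values), ncol(x$values), x$unit))
  if (is_log_unit(x$unit)) {
    cat(sprintf(" (log base %g, pseudocount %g)", x$log_base, x$pseudocount))
  }
  cat("\n")
  nr <- min(5L, nrow(x$values)); nc <- min(5L, ncol(x$values))
  if (nr && nc) print(x$values[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x$values) > nr) cat(sprintf("... %d more features\n", nrow(x$values) - nr))
  invisible(x)
}
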