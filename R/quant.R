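#' Counts per million
#'
#' Library-size normalisation: `cpm[f, s] = count[f, s] / libsize[s] * 1e6`,
#' where `libsize[s]` is the column total. Every sample column of the result
#' sums to 1e6.
#'
#' @param x an `expr_matrix` with `unit = "count"`.
#' @return an `expr_matrix` with `unit = "CPM"`.
#' @export
to_cpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "count") stop("to_cpm expects unit 'count', got '", x$unit, "'")
  lib <- colSums(x$values)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  }
  out <- sweep(x$values, 2L, lib, "/") * 1e6
  expression_matrix(out, unit = "CPM")
}

#' Transcripts per million
#'
#' Length-normalised abundance: per-feature read rates
#' `rate[f, s] = count[f, s] / effective_length[f]` are rescaled so each
#' sample column sums to 1e6.
#'
#' @param x an `expr_matrix` with `unit = "count"`.
#' @param ann a `te_annotation` supplying `effective_length` for every
#'   feature of `x`.
#' @return an `expr_matrix` with `unit = "TPM"`.
#' @export
to_tpm <- function(x, ann) {
  stopifnot(inherits(x, "expr_matrix"), inherits(ann, "te_annotation"))
  if (x$unit != "count") stop("to_tpm expects unit 'count', got '", x$unit, "'")
  idx <- match(feature_ids(x), ann$feature_id)
  len <- ann$effective_length[idx]
  bad <- feature_ids(x)[is.na(idx) | is.na(len)]
  if (length(bad)) {
    stop("missing effective_length for feature(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  rate <- x$values / len
  tot <- colSums(rate)
  zero <- names(tot)[tot == 0]
  if (length(zero)) {
    stop("zero total rate for sample(s): ", paste(zero, collapse = ", "))
  }
  out <- sweep(rate, 2L, tot, "/") * 1e6
  expression_matrix(out, unit = "TPM")
}

#' Log-transform a normalised expression matrix
#'
#' Applies `log(pseudocount + value)` in base 10 (display convention,
#' matching log10(1 + CPM) panels) or base 2 (the scale on which fold
#' changes are computed). The unit tag is updated to the matching log unit;
#' log-transforming an already-log matrix is an error.
#'
#' @param x an `expr_matrix` with unit `"CPM"` or `"TPM"` (aggregated TE
#'   matrices are accepted and keep their extra fields).
#' @param base10 logical; `TRUE` for log10, `FALSE` for log2.
#' @param pseudocount added before the log; default 1.
#' @return the transformed matrix, unit `"logCPM"` or `"logTPM"`.
#' @export
log_transform <- function(x, base10 = TRUE, pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is_log_unit(x$unit)) {
    stop("matrix already has log unit '", x$unit, "'")
  }
  if (!x$unit %in% c("CPM", "TPM")) {
    stop("log_transform expects unit 'CPM' or 'TPM', got '", x$unit, "'")
  }
  stopifnot(pseudocount >= 0)
  base <- if (base10) 10 else 2
  x$values <- log(pseudocount + x$values, base = base)
  x$unit <- if (x$unit == "CPM") "logCPM" else "logTPM"
  x$log_base <- base
  x$pseudocount <- pseudocount
  x
}

#' Invert a log transform
#'
#' @param x an `expr_matrix` with a log unit.
#' @return the linear-scale matrix (`CPM` or `TPM`).
#' @export
unlog_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is_log_unit(x$unit)) stop("matrix is not on a log scale")
  x$values <- x$log_base^x$values - x$pseudocount
  x$values[x$values < 0 & x$values > -1e-12] <- 0
  x$unit <- if (x$unit == "logCPM") "CPM" else "TPM"
  x$log_base <- NA_real_
  x$pseudocount <- NA_real_
  x
}

#' Aggregate repeat-transcript expression to TE type or class level
#'
#' Sums linear-scale (CPM or TPM) expression of repeat transcripts over the
#' two-level TE taxonomy. Aggregation always happens in linear space, before
#' any log transform, because abundances are additive and sums of logs are
#' not. Coding and unannotated features are excluded (their count is
#' reported via a message, never silently).
#'
#' @param x an `expr_matrix` with linear unit `"CPM"` or `"TPM"`.
#' @param ann a `te_annotation`.
#' @param level `"type"` (e.g. Alu, ERVK, L1) or `"class"` (SINE, LINE, LTR,
#'   Satellite).
#' @return an `agg_te` object: an `expr_matrix` whose rows are TE types (or
#'   classes) in lexicographic order, with fields `level` and `parent_map`
#'   (type -> class).
#' @export
aggregate_te <- function(x, ann, level = c("type", "class")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "expr_matrix"), inherits(ann, "te_annotation"))
  if (!x$unit %in% c("CPM", "TPM")) {
    stop("aggregate_te expects a linear unit ('CPM' or 'TPM'), got '", x$unit,
         "'; aggregate before log-transforming")
  }
  rep_ann <- ann[ann$kind == "repeat", , drop = FALSE]
  keep <- feature_ids(x) %in% rep_ann$feature_id
  n_excl <- sum(!keep)
  if (n_excl) {
    message(sprintf("aggregate_te: excluding %d coding/unannotated feature(s)", n_excl))
  }
  if (!any(keep)) stop("no annotated repeat features to aggregate")
  sub <- x$values[keep, , drop = FALSE]
  type_of <- rep_ann$te_type[match(rownames(sub), rep_ann$feature_id)]
  vals <- rowsum(sub, group = type_of, reorder = TRUE)
  pm <- te_parent_map(ann)
  pm <- pm[rownames(vals)]
  if (anyNA(pm)) stop("inconsistent parent map: types without class")
  if (level == "class") {
    vals <- rowsum(vals, group = unname(pm), reorder = TRUE)
  }
  structure(list(values = vals, unit = x$unit,
                 log_base = NA_real_, pseudocount = NA_real_,
                 level = level, parent_map = pm),
            class = c("agg_te", "expr_matrix"))
}

#' Write an aggregated TE matrix as TSV
#'
#' Columns: `te_type` (or `te_class`), `te_class`, then one column per
#' sample.
#'
#' @param x an `agg_te`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aggregated <- function(x, path) {
  stopifnot(inherits(x, "agg_te"))
  if (x$level == "type") {
    df <- data.frame(te_type = rownames(x$values),
                     te_class = unname(x$parent_map[rownames(x$values)]),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(te_class = rownames(x$values), stringsAsFactors = FALSE)
  }
  vals <- as.data.frame(apply(x$values, 2L, format_num))
  names(vals) <- sample_ids(x)
  write_tsv_table(cbind(df, vals), path)
}
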