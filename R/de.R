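#' Define a two-group contrast
#'
#' @param group_a,group_b group labels; fold changes are reported as
#'   `group_a` minus `group_b` on the log2 scale.
#' @param paired logical; if `TRUE`, samples are matched by `pairing_key` and
#'   the per-pair differences are analysed.
#' @param pairing_key metadata column holding the pairing key.
#' @param name optional display name; defaults to `"a_vs_b"`.
#' @return object of class `contrast`.
#' @export
define_contrast <- function(group_a, group_b, paired = FALSE,
                            pairing_key = "patient_id", name = NULL) {
  stopifnot(is.character(group_a), is.character(group_b),
            length(group_a) == 1L, length(group_b) == 1L,
            group_a != group_b)
  structure(list(group_a = group_a, group_b = group_b, paired = paired,
                 pairing_key = pairing_key,
                 name = name %||% paste0(group_a, "_vs_", group_b)),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("<contrast> %s vs %s (%s)\n", x$group_a, x$group_b,
              if (x$paired) paste0("paired by ", x$pairing_key) else "unpaired"))
  invisible(x)
}

#' Moderated-t differential expression
#'
#' Tests each feature for differential expression between two groups on the
#' log2(1 + CPM) scale with empirical-Bayes variance moderation.
#'
#' For an unpaired contrast the per-feature effect is the difference of group
#' means and `s^2` the pooled within-group variance on `d = n_a + n_b - 2`
#' degrees of freedom; for a paired contrast the effect is the mean of
#' per-pair differences and `s^2` their variance on `d = n_pairs - 1` degrees
#' of freedom. A scaled inverse-chi-square prior `(d0, s0^2)` is fitted to
#' the ensemble of `s^2` by the method of moments on `log s^2` (matching the
#' classical moment equations for the log of an F-deviate); the posterior
#' variance `s2_post = (d0 s0^2 + d s^2) / (d0 + d)` then gives the moderated
#' statistic `t = logFC / (s_post * c_n)` with `c_n = sqrt(1/n_a + 1/n_b)`
#' (unpaired) or `sqrt(1/n_pairs)` (paired), referred to a t distribution on
#' `d0 + d` degrees of freedom. If the spread of `log s^2` falls below the
#' trigamma floor the prior degrees of freedom are infinite and all variances
#' shrink fully to `s0^2`.
#'
#' Counts input is filtered (features with total count below
#' `min_total_count` across the contrast's samples are dropped, with a
#' message) and converted internally to log2(1 + CPM); a matrix already on
#' the log2-CPM scale is used as given. When only a subset of features is to
#' be tested (e.g. repeat transcripts alone), pass the full count matrix and
#' name the subset via `features`: library sizes are computed from the full
#' matrix before subsetting, so compartment-specific composition shifts do
#' not leak into the fold changes.
#'
#' @param x an `expr_matrix` with unit `"count"`, or `"logCPM"` in log base 2.
#' @param meta a `sample_metadata` covering every sample used.
#' @param contrast a [define_contrast()] object.
#' @param features optional character vector of feature IDs to test
#'   (normalisation still uses all features of `x`).
#' @param min_total_count count filter applied when `x` holds counts
#'   (default 10).
#' @param prior_df_method method for the prior degrees of freedom; only
#'   `"moment"` is implemented.
#' @return a `te_de` object: data.frame with columns `feature_id`, `logFC`
#'   (log2), `t_mod`, `p`, `fdr`, `mean_expr`, plus attributes `d0`, `s0_2`,
#'   `df_resid`, `df_total`, `contrast`, `n_a`, `n_b`.
#' @export
fit_de <- function(x, meta, contrast, features = NULL, min_total_count = 10,
                   prior_df_method = c("moment")) {
  prior_df_method <- match.arg(prior_df_method)
  stopifnot(inherits(x, "expr_matrix"), inherits(contrast, "contrast"))
  meta <- sample_metadata(as.data.frame(meta))
  sid <- sample_ids(x)
  miss <- setdiff(sid, meta$sample_id)
  if (length(miss)) {
    stop("samples absent from metadata: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  grp <- meta$group[match(sid, meta$sample_id)]
  a_ids <- sid[grp == contrast$group_a]
  b_ids <- sid[grp == contrast$group_b]
  if (!length(a_ids) || !length(b_ids)) {
    stop("both contrast groups must be present among the samples")
  }

  if (contrast$paired) {
    pat <- meta$patient_id[match(sid, meta$sample_id)]
    names(pat) <- sid
    pa <- pat[a_ids]; pb <- pat[b_ids]
    if (any(!nzchar(c(pa, pb)))) stop("paired contrast requires non-empty patient IDs")
    common <- intersect(pa, pb)
    dropped <- setdiff(union(pa, pb), common)
    if (length(dropped)) {
      warning("dropping patients without a complete pair: ",
              paste(dropped, collapse = ", "))
    }
    if (length(common) < 2L) stop("paired contrast requires >= 2 complete pairs")
    a_ids <- a_ids[match(common, pa)]
    b_ids <- b_ids[match(common, pb)]
  } else {
    if (length(a_ids) < 2L || length(b_ids) < 2L) {
      stop("unpaired contrast requires >= 2 samples per group")
    }
  }
  used <- c(a_ids, b_ids)

  if (!is.null(features)) {
    miss_f <- setdiff(features, feature_ids(x))
    if (length(miss_f)) {
      stop("features not in the matrix: ",
           paste(utils::head(miss_f, 5L), collapse = ", "))
    }
  }
  if (x$unit == "count") {
    # library sizes from the full matrix, then subset
    lib <- colSums(x$values[, used, drop = FALSE])
    zero <- used[lib == 0]
    if (length(zero)) stop("zero library size for sample(s): ",
                           paste(zero, collapse = ", "))
    counts <- x$values[features %||% feature_ids(x), used, drop = FALSE]
    tot <- rowSums(counts)
    drop <- tot < min_total_count
    if (any(drop)) {
      message(sprintf("fit_de: dropping %d feature(s) with total count < %d",
                      sum(drop), min_total_count))
    }
    if (sum(!drop) < 2L) stop("fewer than 2 features pass the count filter")
    counts <- counts[!drop, , drop = FALSE]
    cpm <- sweep(counts, 2L, lib, "/") * 1e6
    logx <- log2(1 + cpm)
  } else if (x$unit == "logCPM") {
    if (!is.na(x$log_base) && x$log_base != 2) {
      stop("fit_de requires log base 2 for a logCPM input (got base ",
           x$log_base, ")")
    }
    logx <- x$values[features %||% feature_ids(x), used, drop = FALSE]
  } else {
    stop("fit_de expects unit 'count' or 'logCPM', got '", x$unit, "'")
  }

  A <- logx[, a_ids, drop = FALSE]
  B <- logx[, b_ids, drop = FALSE]
  n_a <- ncol(A); n_b <- ncol(B)
  if (contrast$paired) {
    D <- A - B
    logfc <- rowMeans(D)
    s2 <- row_vars(D)
    df <- ncol(D) - 1L
    c_n <- sqrt(1 / ncol(D))
  } else {
    logfc <- rowMeans(A) - rowMeans(B)
    va <- row_vars(A); vb <- row_vars(B)
    df <- n_a + n_b - 2L
    s2 <- ((n_a - 1L) * va + (n_b - 1L) * vb) / df
    c_n <- sqrt(1 / n_a + 1 / n_b)
  }

  pri <- fit_variance_prior(s2, df)
  d0 <- pri$d0; s0_2 <- pri$s0_2
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- d0 + df
  } else {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  }
  t_mod <- logfc / (sqrt(s2_post) * c_n)
  t_mod[logfc == 0] <- 0  # exact nulls stay exact even if s2_post is 0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  res <- data.frame(feature_id = rownames(logx),
                    logFC = unname(logfc),
                    t_mod = unname(t_mod),
                    p = unname(p),
                    fdr = bh_adjust(unname(p)),
                    mean_expr = unname(rowMeans(logx)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("te_de", "data.frame"),
            contrast = contrast, d0 = d0, s0_2 = s0_2,
            df_resid = df, df_total = df_total,
            n_a = n_a, n_b = n_b, c_n = c_n)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior.
# z = log(s2) for s2 > 0; e = z - digamma(d/2) + log(d/2) estimates
# log(s0^2) + [digamma(d0/2) - log(d0/2)]; var(z) estimates
# trigamma(d/2) + trigamma(d0/2). Below the trigamma floor -> d0 = Inf.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L) {
    warning("too few positive variances to fit a prior; using d0 = Inf")
    return(list(d0 = Inf, s0_2 = mean(s2[is.finite(s2)], na.rm = TRUE)))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  half_d0 <- trigamma_inverse(evar)
  d0 <- 2 * half_d0
  if (!is.finite(d0) || d0 <= 0) {
    warning("prior degrees of freedom estimate non-finite; using d0 = Inf")
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_2 = s0_2)
}

#' @export
print.te_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<te_de> %d features, %s vs %s (%s)\n", nrow(x),
              ct$group_a, ct$group_b, if (ct$paired) "paired" else "unpaired"))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g, residual df = %d\n",
              attr(x, "d0"), attr(x, "s0_2"), attr(x, "df_resid")))
  ord <- order(x$p)
  print(utils::head(as.data.frame(x)[ord, ], 5L))
  invisible(x)
}

#' @export
summary.te_de <- function(object, alpha = 0.05, ...) {
  n_sig <- sum(object$fdr <= alpha)
  cat(sprintf("%d / %d features at FDR <= %g; median |log2FC| of those: %.3f\n",
              n_sig, nrow(object), alpha,
              if (n_sig) stats::median(abs(object$logFC[object$fdr <= alpha])) else NA_real_))
  invisible(object)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Quantiles of the absolute log fold change
#'
#' Summarises the magnitude of (by default, significant) expression changes
#' as empirical quantiles of |log2FC|, the summary used to compare how
#' strongly TE transcripts move in each contrast.
#'
#' @param fit a `te_de` result.
#' @param probs sorted quantile levels in `[0, 1]`.
#' @param only_significant keep only features with `fdr <= alpha` first.
#' @param alpha FDR threshold for the filter.
#' @return a `lfc_quantiles` data.frame with columns `prob`, `value`
#'   (type-7 interpolated quantiles, non-decreasing); empty (with a warning)
#'   if no feature passes the filter.
#' @export
lfc_quantiles <- function(fit, probs = seq(0, 1, 0.25), only_significant = TRUE,
                          alpha = 0.05) {
  stopifnot(inherits(fit, "te_de"))
  if (any(probs < 0) || any(probs > 1) || is.unsorted(probs)) {
    stop("probs must be sorted values in [0, 1]")
  }
  lfc <- abs(fit$logFC)
  if (only_significant) lfc <- lfc[fit$fdr <= alpha]
  if (!length(lfc)) {
    warning("no features pass the significance filter; returning empty summary")
    out <- data.frame(prob = numeric(0), value = numeric(0))
  } else {
    out <- data.frame(prob = probs,
                      value = unname(stats::quantile(lfc, probs = probs, type = 7)))
  }
  class(out) <- c("lfc_quantiles", "data.frame")
  out
}

#' Canonical panel of post-transcriptional TE regulator genes
#'
#' Autophagy components, RNA-interference machinery and DExH-box RNA
#' helicases known to modulate TE transcript abundance after transcription.
#' @export
te_regulator_genes <- c("ATG5", "KIAA0430", "CALCOCO2", "ZC3HAV1", "HNRNPL",
                        "PABPC1", "LAMP2", "HSP90AA1", "DROSHA", "DICER1",
                        "DGCR8", "DHX9", "DHX15")

#' Extract a gene panel from a differential-expression result
#'
#' Subsets a coding-gene DE result to a named panel of gene symbols (by
#' default the TE post-transcriptional regulator panel), flagging
#' significance at `p <= alpha`. Symbols absent from the result are reported
#' in the `missing` element rather than raising an error.
#'
#' @param fit a `te_de` result on coding genes.
#' @param symbols character vector of gene symbols.
#' @param ann optional `te_annotation` used to translate symbols to feature
#'   IDs; if omitted, symbols are matched against `fit$feature_id` directly.
#' @param alpha significance threshold on the (unadjusted) p-value.
#' @return list with `table` (DE rows plus `gene_symbol` and `sig` columns)
#'   and `missing` (unmatched symbols).
#' @export
regulator_panel <- function(fit, symbols = te_regulator_genes, ann = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(fit, "te_de"))
  symbols <- unique(as.character(symbols))
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "te_annotation"))
    idx <- match(symbols, ann$gene_symbol)
    fid <- ann$feature_id[idx]
  } else {
    fid <- symbols
  }
  hit <- !is.na(fid) & fid %in% fit$feature_id
  missing <- symbols[!hit]
  tab <- as.data.frame(fit)[match(fid[hit], fit$feature_id), , drop = FALSE]
  tab$gene_symbol <- symbols[hit]
  tab$sig <- tab$p <= alpha
  rownames(tab) <- NULL
  list(table = tab, missing = missing)
}

#' Write a differential-expression result as TSV
#' @param fit a `te_de`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(fit, path) {
  write_tsv_table(as.data.frame(fit), path)
}
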