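#' Combine named gene sets by union
#'
#' Builds a combined signature (e.g. an immune signature pooling canonical
#' immune pathways, or an inflammation signature pooling inflammatory
#' response sets) as the union of member symbols.
#'
#' @param col a `gene_sets` collection.
#' @param names names of the sets to combine.
#' @param combined_name name of the resulting set.
#' @return character vector of unique symbols, with attribute `provenance`
#'   recording the source set names, and attribute `name`.
#' @export
combine_sets <- function(col, names, combined_name = paste(names, collapse = "+")) {
  stopifnot(inherits(col, "gene_sets"))
  miss <- setdiff(names, base::names(col))
  if (length(miss)) stop("gene set(s) not found: ", paste(miss, collapse = ", "))
  members <- unique(unlist(col[names], use.names = FALSE))
  structure(members, provenance = names, name = combined_name)
}

#' Competitive permutation gene-set test
#'
#' Tests whether a gene set's moderated-t statistics are more extreme than
#' those of random gene sets of the same size. The set score is the mean
#' `t_mod` over member genes present in the fit; the null distribution is
#' the score of `n_perm` same-size subsets drawn without replacement from
#' all tested features, and the two-sided p-value is
#' `(1 + #\{|null| >= |score|\}) / (1 + n_perm)`. A competitive (random-set)
#' null is used rather than sample permutation because with designs as small
#' as 7 pairs, sample permutations are too coarse to give stable p-values.
#'
#' @param fit a `te_de` result.
#' @param genes gene set members: feature IDs, or gene symbols when `ann` is
#'   supplied.
#' @param n_perm number of random sets (>= 1000 recommended).
#' @param seed optional integer seed for reproducible draws.
#' @param ann optional `te_annotation` for symbol-to-feature translation.
#' @param set_name label stored in the result.
#' @return an `enrichment_result`: one-row data.frame with columns
#'   `set_name`, `direction` (`up_in_a` / `down_in_a`), `score`, `p`,
#'   `p_bonf` (`NA` until [bonferroni()]), `n_genes_used`.
#' @export
competitive_test <- function(fit, genes, n_perm = 1000L, seed = NULL,
                             ann = NULL, set_name = NULL) {
  stopifnot(inherits(fit, "te_de"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  set_name <- set_name %||% attr(genes, "name") %||% "set"
  genes <- unique(as.character(genes))
  ids <- genes
  if (!is.null(ann)) {
    idx <- match(genes, ann$gene_symbol)
    ids <- ifelse(is.na(idx), genes, ann$feature_id[idx])
  }
  members <- which(fit$feature_id %in% ids)
  m <- length(members)
  if (m < 5L) {
    stop(sprintf("set '%s': only %d member(s) present among tested features (>= 5 required)",
                 set_name, m))
  }
  t_all <- fit$t_mod
  score <- mean(t_all[members])
  if (!is.null(seed)) set.seed(seed)
  n_feat <- length(t_all)
  t_pool <- sort(t_all)  # order-invariant null draws under a fixed seed
  null_scores <- vapply(seq_len(n_perm), function(i) {
    mean(t_pool[sample.int(n_feat, m)])
  }, numeric(1L))
  p <- (1 + sum(abs(null_scores) >= abs(score))) / (1 + n_perm)
  res <- data.frame(set_name = set_name,
                    direction = if (score >= 0) "up_in_a" else "down_in_a",
                    score = score, p = p, p_bonf = NA_real_,
                    n_genes_used = m, stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Bonferroni correction for a family of enrichment results
#'
#' Sets `p_bonf = min(1, p * k)` over the `k` sets tested and flags
#' significance with a star at the two-sided display threshold
#' `p < alpha / 2` (0.025 at the default familywise `alpha = 0.05`).
#'
#' @param results an `enrichment_result` or data.frame of stacked results.
#' @param alpha familywise error level; the display star uses `alpha / 2`.
#' @return the results with `p_bonf` filled in and a logical `star` column.
#' @export
bonferroni <- function(results, alpha = 0.05) {
  if (inherits(results, "enrichment_result") || is.data.frame(results)) {
    df <- as.data.frame(results)
  } else {
    df <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!nrow(df)) stop("no enrichment results to adjust")
  k <- nrow(df)
  df$p_bonf <- pmin(1, df$p * k)
  df$star <- df$p < alpha / 2
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' Test every set of a collection against a DE result
#'
#' Convenience wrapper: runs [competitive_test()] for each set and applies
#' [bonferroni()] across them. Sets with fewer than 5 members present are
#' skipped with a message.
#'
#' @inheritParams competitive_test
#' @param col a `gene_sets` collection.
#' @param alpha familywise level passed to [bonferroni()].
#' @return stacked, Bonferroni-adjusted `enrichment_result` data.frame.
#' @export
enrich_sets <- function(fit, col, n_perm = 1000L, seed = NULL, ann = NULL,
                        alpha = 0.05) {
  stopifnot(inherits(col, "gene_sets"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(col)) {
    r <- tryCatch(
      competitive_test(fit, col[[nm]], n_perm = n_perm, ann = ann, set_name = nm),
      error = function(e) {
        message("enrich_sets: skipping '", nm, "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(r)) rows[[nm]] <- r
  }
  if (!length(rows)) stop("no gene set had enough members to test")
  bonferroni(do.call(rbind, rows), alpha = alpha)
}
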