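#' Detect co-expression modules by average-linkage hierarchical clustering
#'
#' Genes are standardised across samples (mean 0, variance 1), pairwise
#' Euclidean distances are clustered with average linkage, and the tree is
#' cut at a fixed height. Clusters reaching `min_module_size` become modules
#' numbered `1..K` by decreasing size; all other genes are assigned module 0
#' (unassigned). With `n_modules = "auto"` the cut maximising the number of
#' qualifying clusters is used (smallest cut on ties); an integer
#' `n_modules` selects the coarsest cut yielding at least that many
#' qualifying clusters.
#'
#' @param x an `expr_matrix` of coding-gene expression (log scale
#'   recommended) with at least 3 samples.
#' @param min_module_size minimum genes per module (default 30).
#' @param n_modules `"auto"` or a positive integer.
#' @param max_k largest number of tree cuts scanned.
#' @return a `module_set`: list with `assignment` (named integer vector,
#'   0 = unassigned), `eigengene` (module x sample matrix, unit variance
#'   rows), `sizes`, `direction` (all `"none"` until [module_direction()]),
#'   `direction_p`, `direction_contrast`.
#' @export
detect_modules <- function(x, min_module_size = 30L, n_modules = "auto",
                           max_k = 100L) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 3L) stop("module detection requires >= 3 samples")
  if (nrow(v) < min_module_size) {
    stop("fewer genes than min_module_size")
  }
  Z <- standardize_rows(v)
  hc <- stats::hclust(stats::dist(Z), method = "average")
  ks <- seq_len(min(nrow(Z), max_k))
  cuts <- stats::cutree(hc, k = ks)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L)
  n_qual <- apply(cuts, 2L, function(cl) sum(table(cl) >= min_module_size))
  if (identical(n_modules, "auto")) {
    k_sel <- ks[which.max(n_qual)]
  } else {
    n_modules <- as.integer(n_modules)
    ok <- which(n_qual >= n_modules)
    if (!length(ok)) {
      stop("no tree cut yields ", n_modules, " clusters of size >= ",
           min_module_size)
    }
    k_sel <- ks[ok[1L]]
  }
  cl <- cuts[, k_sel]
  tab <- table(cl)
  qual <- names(tab)[tab >= min_module_size]
  # renumber qualifying clusters 1..K by decreasing size (ties: first gene)
  ord <- order(-tab[qual], match(qual, cl))
  qual <- qual[ord]
  assignment <- integer(nrow(Z))
  names(assignment) <- rownames(Z)
  for (i in seq_along(qual)) assignment[cl == qual[i]] <- i
  eig <- module_eigengenes(x, assignment)
  K <- length(qual)
  structure(list(assignment = assignment, eigengene = eig,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(K)))),
                 direction = stats::setNames(rep("none", K), rownames(eig)),
                 direction_p = stats::setNames(rep(NA_real_, K), rownames(eig)),
                 direction_contrast = NULL,
                 k_cut = k_sel),
            class = "module_set")
}

standardize_rows <- function(v) {
  mu <- rowMeans(v)
  sd <- sqrt(row_vars(v))
  Z <- (v - mu) / sd
  Z[sd == 0 | !is.finite(sd), ] <- 0
  Z
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal-component score of its
#' standardised gene profiles across samples, scaled to unit variance, with
#' the sign oriented so the mean gene loading is positive (so the eigengene
#' rises when a typical module gene rises). A single-gene module's eigengene
#' is that gene's standardised profile.
#'
#' @param x an `expr_matrix` containing the module genes.
#' @param assignment named integer vector of module memberships (0 ignored).
#' @return matrix of eigengenes, one row per module (`"1"`, `"2"`, ...),
#'   columns matching the samples of `x`.
#' @export
module_eigengenes <- function(x, assignment) {
  stopifnot(inherits(x, "expr_matrix"))
  mods <- sort(unique(assignment[assignment > 0L]))
  if (!length(mods)) {
    return(matrix(numeric(0), 0L, ncol(x$values),
                  dimnames = list(NULL, sample_ids(x))))
  }
  out <- matrix(NA_real_, length(mods), ncol(x$values),
                dimnames = list(as.character(mods), sample_ids(x)))
  for (i in seq_along(mods)) {
    genes <- names(assignment)[assignment == mods[i]]
    genes <- intersect(genes, feature_ids(x))
    if (!length(genes)) stop("module ", mods[i], " has no genes in the matrix")
    Z <- standardize_rows(x$values[genes, , drop = FALSE])
    if (length(genes) == 1L) {
      e <- Z[1L, ]
    } else {
      sv <- svd(Z, nu = 1L, nv = 1L)
      e <- sv$v[, 1L]
      if (mean(sv$u[, 1L]) < 0) e <- -e
      s <- stats::sd(e)
      e <- if (s > 0) e / s else e
    }
    out[i, ] <- e
  }
  out
}

#' Correlate module eigengenes with TE-type expression
#'
#' Pearson correlation of each module eigengene with each TE type's
#' (log-scale) aggregated expression over the same samples, with two-sided
#' p-values from the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom. TE types with zero variance give `NA` cells, which
#' are excluded from the concordance contingency table.
#'
#' @param eig eigengene matrix (modules x samples) or a `module_set`.
#' @param te an `agg_te` on a log scale (or a plain matrix, TE types x
#'   samples) with the same samples in the same order.
#' @param alpha per-cell significance level (default 0.05).
#' @return an `association_table`: list with matrices `r`, `p`, `sig`
#'   (logical), plus `alpha` and `n` (samples).
#' @export
correlate_te <- function(eig, te, alpha = 0.05) {
  if (inherits(eig, "module_set")) eig <- eig$eigengene
  tv <- if (inherits(te, "expr_matrix")) te$values else as.matrix(te)
  if (!identical(colnames(eig), colnames(tv))) {
    if (!setequal(colnames(eig), colnames(tv))) {
      stop("eigengene and TE matrices cover different samples")
    }
    tv <- tv[, colnames(eig), drop = FALSE]
  }
  n <- ncol(eig)
  if (n < 4L) stop("correlation requires >= 4 samples")
  te_sd <- apply(tv, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(eig), t(tv)))
  r[, te_sd == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  exact1 <- which(!is.na(r) & abs(r) == 1)
  tstat[exact1] <- Inf * sign(r[exact1])
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- !is.na(p) & p <= alpha
  structure(list(r = r, p = p, sig = sig, alpha = alpha, n = n),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %d module(s) x %d TE type(s), alpha = %g\n",
              nrow(x$r), ncol(x$r), x$alpha))
  cat(sprintf("  %d significant cell(s), %d NA cell(s)\n",
              sum(x$sig, na.rm = TRUE), sum(is.na(x$r))))
  invisible(x)
}

#' Assign an immune-activity direction to each module
#'
#' Runs the competitive permutation test with each module's genes as the
#' gene set against a differential-expression fit for the defining contrast.
#' A module whose test passes `alpha` is labelled `activated_in_a` or
#' `suppressed_in_a` according to the sign of its mean moderated-t; others
#' stay `"none"`. Modules too small for the test keep `"none"` with a
#' message.
#'
#' @param modules a `module_set`.
#' @param fit a `te_de` on coding genes for the defining contrast.
#' @param n_perm,seed,ann passed to [competitive_test()].
#' @param alpha significance level (default 0.05).
#' @return the `module_set` with `direction`, `direction_p` and
#'   `direction_contrast` filled in.
#' @export
module_direction <- function(modules, fit, n_perm = 1000L, seed = NULL,
                             alpha = 0.05, ann = NULL) {
  stopifnot(inherits(modules, "module_set"), inherits(fit, "te_de"))
  if (!is.null(seed)) set.seed(seed)
  for (k in rownames(modules$eigengene)) {
    genes <- names(modules$assignment)[modules$assignment == as.integer(k)]
    res <- tryCatch(
      competitive_test(fit, genes, n_perm = n_perm, ann = ann,
                       set_name = paste0("module_", k)),
      error = function(e) {
        message("module_direction: module ", k, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    modules$direction_p[k] <- res$p
    modules$direction[k] <- if (res$p <= alpha) {
      if (res$score >= 0) "activated_in_a" else "suppressed_in_a"
    } else "none"
  }
  modules$direction_contrast <- attr(fit, "contrast")$name
  modules
}

#' @export
print.module_set <- function(x, ...) {
  K <- nrow(x$eigengene)
  cat(sprintf("<module_set> %d module(s), %d gene(s) assigned, %d unassigned\n",
              K, sum(x$assignment > 0), sum(x$assignment == 0)))
  if (K) {
    cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
    if (any(x$direction != "none")) {
      d <- x$direction[x$direction != "none"]
      cat("  directions:", paste(sprintf("%s=%s", names(d), d), collapse = ", "),
          sprintf("(contrast %s)\n", x$direction_contrast %||% "?"))
    }
  }
  invisible(x)
}

#' Global sign-concordance chi-square test
#'
#' Tests whether significant module-by-TE-type correlations align in sign
#' with the modules' immune-activity direction: among significant cells of
#' directional modules, a 2x2 contingency table counts (direction:
#' activated/suppressed) x (correlation sign: positive/negative). The
#' statistic is the Pearson chi-square without continuity correction on 1
#' degree of freedom; a Fisher exact p-value is always reported alongside
#' for sparse tables. A zero margin makes the chi-square undefined and is an
#' error advising the Fisher fallback.
#'
#' @param assoc an `association_table` from [correlate_te()].
#' @param modules a `module_set` with directions assigned.
#' @param restrict_types optional character vector restricting which TE
#'   types enter the contingency table (default: all).
#' @return a `concordance_test`: list with `contingency`, `chi2`, `df`,
#'   `p`, `fisher_p`, `n_cells`.
#' @export
concordance_chi2 <- function(assoc, modules, restrict_types = NULL) {
  stopifnot(inherits(assoc, "association_table"), inherits(modules, "module_set"))
  dir <- modules$direction
  dmod <- names(dir)[dir != "none"]
  dmod <- intersect(dmod, rownames(assoc$r))
  if (!length(dmod)) stop("no directional modules: run module_direction first")
  types <- colnames(assoc$r)
  if (!is.null(restrict_types)) types <- intersect(types, restrict_types)
  if (!length(types)) stop("no TE types selected")
  sig <- assoc$sig[dmod, types, drop = FALSE]
  r <- assoc$r[dmod, types, drop = FALSE]
  cells <- which(sig & !is.na(r), arr.ind = TRUE)
  if (!nrow(cells)) stop("no significant correlation cells in directional modules")
  activated <- dir[dmod[cells[, 1L]]] == "activated_in_a"
  positive <- r[cells] > 0
  tab <- matrix(c(sum(activated & positive), sum(activated & !positive),
                  sum(!activated & positive), sum(!activated & !positive)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(direction = c("activated_in_a", "suppressed_in_a"),
                                sign = c("positive", "negative")))
  fisher_p <- stats::fisher.test(tab)$p.value
  chi <- chisq_2x2(tab)  # errors (advising Fisher) when a margin is zero
  structure(list(contingency = tab, chi2 = chi$statistic, df = chi$df,
                 p = chi$p.value, fisher_p = fisher_p, n_cells = nrow(cells)),
            class = "concordance_test")
}

#' @export
print.concordance_test <- function(x, ...) {
  cat("<concordance_test> direction x correlation-sign, significant cells only\n")
  print(x$contingency)
  cat(sprintf("  chi2 = %.4g on %d df, p = %.4g (Fisher exact p = %.4g)\n",
              x$chi2, x$df, x$p, x$fisher_p))
  invisible(x)
}

#' Write an association table as TSV
#'
#' Long format: one row per (module, TE type) cell with `r`, `p`, `sig`.
#' @param assoc an `association_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_table"))
  grid <- expand.grid(module = rownames(assoc$r), te_type = colnames(assoc$r),
                      stringsAsFactors = FALSE)
  grid$r <- as.vector(assoc$r)
  grid$p <- as.vector(assoc$p)
  grid$sig <- as.vector(assoc$sig)
  write_tsv_table(grid, path)
}
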