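log_matrix <- function(nf, ns, seed, mean = 5, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns, mean, sd), nf, ns,
              dimnames = list(sprintf("F%03d", 1:nf), sprintf("S%02d", 1:ns)))
  structure(list(values = m, unit = "logCPM", log_base = 2, pseudocount = 1),
            class = "expr_matrix")
}

test_that("a feature with identical group means is an exact null", {
  x <- log_matrix(20, 6, seed = 1)
  x$values[1, ] <- c(4, 5, 6, 4, 5, 6)  # identical profiles in both groups
  meta <- two_group_meta(x, n_a = 3)
  fit <- fit_de(x, meta, define_contrast("A", "B"))
  expect_identical(fit$logFC[1], 0)
  expect_identical(fit$t_mod[1], 0)
  expect_identical(fit$p[1], 1)
})

test_that("moderated t agrees with a brute-force oracle (unpaired and paired)", {
  for (s in 1:20) {
    # heterogeneous true variances so d0 is finite and moderation is active
    set.seed(s)
    nf <- 80
    s2 <- 0.05 * 6 / rchisq(nf, df = 6)
    m <- matrix(rnorm(nf * 6, 5, rep(sqrt(s2), 6)), nf, 6,
                dimnames = list(sprintf("F%03d", 1:nf), sprintf("S%02d", 1:6)))
    x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                        pseudocount = 1), class = "expr_matrix")
    meta <- two_group_meta(x, n_a = 3)
    fit <- fit_de(x, meta, define_contrast("A", "B"))
    ora <- oracle_mod_t(m[, 1:3], m[, 4:6])
    expect_equal(fit$logFC, unname(ora$lfc), tolerance = 1e-10)
    expect_equal(fit$t_mod, unname(ora$t), tolerance = 1e-8)
    expect_equal(fit$p, unname(ora$p), tolerance = 1e-8)
    expect_equal(attr(fit, "d0"), ora$d0, tolerance = 1e-6)
    expect_equal(attr(fit, "s0_2"), ora$s02, tolerance = 1e-8)
  }

  # paired: 4 patients x 2 groups
  for (s in 1:5) {
    set.seed(100 + s)
    nf <- 60
    s2 <- 0.1 * 8 / rchisq(nf, df = 8)
    m <- matrix(rnorm(nf * 8, 5, rep(sqrt(s2), 8)), nf, 8,
                dimnames = list(sprintf("F%03d", 1:nf), sprintf("S%02d", 1:8)))
    x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                        pseudocount = 1), class = "expr_matrix")
    meta <- sample_metadata(data.frame(
      sample_id = sprintf("S%02d", 1:8),
      group = rep(c("A", "B"), 4),
      patient_id = rep(sprintf("P%d", 1:4), each = 2)))
    fit <- fit_de(x, meta, define_contrast("A", "B", paired = TRUE))
    ora <- oracle_mod_t(m[, c(1, 3, 5, 7)], m[, c(2, 4, 6, 8)], paired = TRUE)
    expect_equal(fit$t_mod, unname(ora$t), tolerance = 1e-8)
    expect_equal(fit$p, unname(ora$p), tolerance = 1e-8)
  }
})

test_that("in the d0 = Inf limit the statistic collapses to logFC/(s0 c_n)", {
  # identical residual profiles give every feature the same sample variance,
  # so the spread of log s^2 sits below the trigamma floor and d0 = Inf
  set.seed(7)
  resid <- rnorm(8, 0, 0.5)
  delta <- rnorm(200)
  m <- matrix(5, 200, 8) + matrix(resid, 200, 8, byrow = TRUE) +
    outer(delta, c(1, 1, 1, 1, 0, 0, 0, 0))
  dimnames(m) <- list(sprintf("F%03d", 1:200), sprintf("S%02d", 1:8))
  x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                      pseudocount = 1), class = "expr_matrix")
  meta <- two_group_meta(x, n_a = 4)
  fit <- fit_de(x, meta, define_contrast("A", "B"))
  expect_identical(attr(fit, "d0"), Inf)
  s0 <- sqrt(attr(fit, "s0_2"))
  cn <- sqrt(1 / 4 + 1 / 4)
  expect_equal(fit$t_mod, fit$logFC / (s0 * cn), tolerance = 1e-12)
  # and p-values are then normal-based
  expect_equal(fit$p, 2 * pnorm(-abs(fit$t_mod)), tolerance = 1e-12)
})

test_that("moderated t matches limma eBayes on shared input", {
  skip_if_not_installed("limma")
  set.seed(11)
  nf <- 300
  s2 <- 0.05 * 5 / rchisq(nf, df = 5)
  m <- matrix(rnorm(nf * 10, 5, rep(sqrt(s2), 10)), nf, 10,
              dimnames = list(sprintf("F%03d", 1:nf), sprintf("S%02d", 1:10)))
  x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                      pseudocount = 1), class = "expr_matrix")
  fit <- fit_de(x, two_group_meta(x, n_a = 5), define_contrast("A", "B"))
  eb <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 5))))
  expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 1e-8)
  expect_equal(attr(fit, "s0_2"), eb$s2.prior, tolerance = 1e-8)
  expect_equal(fit$t_mod, unname(eb$t[, 2]), tolerance = 1e-10)
})

test_that("swapping the contrast groups negates effects and keeps p", {
  x <- log_matrix(50, 7, seed = 3)
  meta <- two_group_meta(x, n_a = 4)
  f1 <- fit_de(x, meta, define_contrast("A", "B"))
  f2 <- fit_de(x, meta, define_contrast("B", "A"))
  expect_identical(f1$logFC, -f2$logFC)
  expect_identical(f1$t_mod, -f2$t_mod)
  expect_identical(f1$p, f2$p)
})

test_that("pairing absorbs patient offsets into smaller residual variances", {
  set.seed(5)
  nf <- 100; np <- 6
  base <- matrix(rnorm(nf * np, 0, 2), nf, np)  # large per-patient offsets
  noise <- function() matrix(rnorm(nf * np, 0, 0.3), nf, np)
  A <- base + noise(); B <- base + noise()
  m <- cbind(A, B)
  dimnames(m) <- list(sprintf("F%03d", 1:nf), sprintf("S%02d", 1:(2 * np)))
  x <- structure(list(values = m + 8, unit = "logCPM", log_base = 2,
                      pseudocount = 1), class = "expr_matrix")
  meta <- sample_metadata(data.frame(
    sample_id = colnames(m),
    group = rep(c("A", "B"), each = np),
    patient_id = rep(sprintf("P%d", 1:np), 2)))
  fp <- fit_de(x, meta, define_contrast("A", "B", paired = TRUE))
  fu <- fit_de(x, meta, define_contrast("A", "B", paired = FALSE))
  s2p <- (fp$logFC / fp$t_mod)^2  # post variance * c_n^2, comparable medians
  s2u <- (fu$logFC / fu$t_mod)^2
  expect_lt(median(s2p, na.rm = TRUE), median(s2u, na.rm = TRUE))
})

test_that("incomplete pairs are dropped with a warning", {
  x <- log_matrix(30, 5, seed = 8)
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("S%02d", 1:5),
    group = c("A", "B", "A", "B", "A"),
    patient_id = c("P1", "P1", "P2", "P2", "P3")))
  expect_warning(fit <- fit_de(x, meta, define_contrast("A", "B", paired = TRUE)),
                 "P3")
  expect_identical(attr(fit, "n_a"), 2L)
})

test_that("count input is filtered and converted with full-matrix library sizes", {
  set.seed(21)
  m <- matrix(rpois(40 * 6, 50), 40, 6,
              dimnames = list(sprintf("F%03d", 1:40), sprintf("S%02d", 1:6)))
  m[1, ] <- c(1, 0, 0, 1, 0, 0)  # total 2 < 10 -> dropped
  x <- expression_matrix(m, unit = "count")
  meta <- two_group_meta(x, n_a = 3)
  expect_message(fit <- fit_de(x, meta, define_contrast("A", "B")), "dropping 1")
  expect_false("F001" %in% fit$feature_id)
  # subsetting via features= keeps library sizes from the full matrix
  fit_sub <- suppressMessages(
    fit_de(x, meta, define_contrast("A", "B"), features = sprintf("F%03d", 2:10)))
  expect_equal(fit_sub$logFC,
               fit$logFC[match(fit_sub$feature_id, fit$feature_id)],
               tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("|logFC| quantiles follow type-7 interpolation on the filtered set", {
  fit <- fake_de(c(-2, 2))
  expect_equal(lfc_quantiles(fit, probs = 0.5, only_significant = FALSE)$value, 2)
  fit0 <- fake_de(rep(0, 10))
  expect_equal(lfc_quantiles(fit0, probs = c(0.25, 0.75),
                             only_significant = FALSE)$value, c(0, 0))
  for (s in 1:20) {
    set.seed(s)
    t <- rnorm(50, 0, 3)
    fit <- fake_de(t)
    probs <- sort(runif(5))
    q <- lfc_quantiles(fit, probs = probs, only_significant = FALSE)
    expect_equal(q$value, oracle_quantile7(abs(t), probs), tolerance = 1e-12)
    expect_false(is.unsorted(q$value))
  }
  # significance filter + empty result contract
  fit <- fake_de(rnorm(20, 0, 0.1))
  expect_warning(q <- lfc_quantiles(fit, alpha = 1e-8), "no features")
  expect_identical(nrow(q), 0L)
})

test_that("regulator panel subsets by symbol and reports missing genes", {
  x <- random_counts(30, 6, seed = 2, lambda = 100)
  ann <- random_annotation(x, n_rep = 0, seed = 2)
  meta <- two_group_meta(x)
  fit <- suppressMessages(fit_de(x, meta, define_contrast("A", "B")))
  pan <- regulator_panel(fit, c("SYM001", "SYM002", "ATG5"), ann = ann)
  expect_identical(pan$missing, "ATG5")
  expect_identical(pan$table$gene_symbol, c("SYM001", "SYM002"))
  # whole-result panel is the identity
  pan_all <- regulator_panel(fit, ann$gene_symbol, ann = ann)
  expect_identical(nrow(pan_all$table), nrow(fit))
  expect_identical(pan_all$table$logFC, fit$logFC)
})

test_that("a planted two-fold regulator effect is recovered near log2 = 1", {
  meds <- sapply(1:5, function(s) {
    b <- simulate_te_experiment(sim_config(seed = s, coupling = list(),
                                           te_suppression = list()))
    fit <- suppressMessages(
      fit_de(b$counts, b$metadata, define_contrast("LSC", "Blast", paired = TRUE),
             features = b$annotation$feature_id[b$annotation$kind == "coding"]))
    pan <- regulator_panel(fit, "ATG5", ann = b$annotation)
    pan$table$logFC
  })
  expect_equal(median(meds), 1, tolerance = 0.25)
})
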