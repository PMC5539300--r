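two_block_matrix <- function(seed, n_per = 50, ns = 12, noise = 0.05) {
  set.seed(seed)
  f <- matrix(rnorm(2 * ns), 2, ns)
  load <- runif(2 * n_per, 0.8, 1.2)
  m <- rbind(outer(load[1:n_per], f[1, ]),
             outer(load[(n_per + 1):(2 * n_per)], f[2, ])) +
    matrix(rnorm(2 * n_per * ns, 0, noise), 2 * n_per, ns)
  dimnames(m) <- list(sprintf("G%03d", 1:(2 * n_per)), sprintf("S%02d", 1:ns))
  structure(list(values = m + 8, unit = "logCPM", log_base = 2,
                 pseudocount = 1), class = "expr_matrix")
}

test_that("two planted blocks are recovered exactly", {
  skip_if_not_installed("mclust")
  for (s in 1:3) {
    x <- two_block_matrix(seed = s)
    ms <- detect_modules(x, min_module_size = 30)
    truth <- rep(1:2, each = 50)
    expect_identical(length(ms$sizes), 2L)
    expect_equal(mclust::adjustedRandIndex(ms$assignment, truth), 1)
  }
})

test_that("identical gene profiles collapse to a single module", {
  set.seed(1)
  prof <- rnorm(10)
  m <- matrix(rep(prof, each = 40), 40, 10,
              dimnames = list(sprintf("G%03d", 1:40), sprintf("S%02d", 1:10)))
  x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                      pseudocount = 1), class = "expr_matrix")
  ms <- detect_modules(x, min_module_size = 30)
  expect_identical(length(ms$sizes), 1L)
  expect_true(all(ms$assignment == 1L))
})

test_that("gene order only relabels modules by size", {
  x <- two_block_matrix(seed = 4)
  ms1 <- detect_modules(x, min_module_size = 30)
  set.seed(2)
  perm <- sample(nrow(x$values))
  ms2 <- detect_modules(x[perm, ], min_module_size = 30)
  a1 <- ms1$assignment[names(ms2$assignment)]
  # same partition up to label permutation
  expect_identical(length(unique(paste(a1, ms2$assignment))),
                   length(unique(a1)))
  expect_identical(sort(ms1$sizes), sort(ms2$sizes))
})

test_that("eigengene handles rank-1 modules, sign flips and matches SVD", {
  set.seed(6)
  prof <- rnorm(8)
  m <- matrix(rep(prof, each = 5), 5, 8,
              dimnames = list(sprintf("G%d", 1:5), sprintf("S%d", 1:8)))
  x <- structure(list(values = m, unit = "logCPM", log_base = 2,
                      pseudocount = 1), class = "expr_matrix")
  e <- module_eigengenes(x, setNames(rep(1L, 5), rownames(m)))
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(e[1, ]), z, tolerance = 1e-9)

  # the mean-loading-positive convention makes the sign canonical: negating
  # every gene flips the eigengene, and a double negation restores it
  m2 <- matrix(rnorm(6 * 10), 6, 10,
               dimnames = list(sprintf("G%d", 1:6), sprintf("S%d", 1:10)))
  x2 <- structure(list(values = m2, unit = "logCPM", log_base = 2,
                       pseudocount = 1), class = "expr_matrix")
  x2n <- x2; x2n$values <- -x2$values
  a <- setNames(rep(1L, 6), rownames(m2))
  e_pos <- module_eigengenes(x2, a)
  e_neg <- module_eigengenes(x2n, a)
  expect_equal(e_pos, -e_neg, tolerance = 1e-9)
  x2nn <- x2n; x2nn$values <- -x2n$values
  expect_equal(module_eigengenes(x2nn, a), e_pos, tolerance = 1e-12)

  # brute-force SVD oracle on a random module
  for (s in 1:5) {
    set.seed(s)
    m3 <- matrix(rnorm(20 * 9), 20, 9,
                 dimnames = list(sprintf("G%02d", 1:20), sprintf("S%d", 1:9)))
    x3 <- structure(list(values = m3, unit = "logCPM", log_base = 2,
                         pseudocount = 1), class = "expr_matrix")
    e <- module_eigengenes(x3, setNames(rep(1L, 20), rownames(m3)))[1, ]
    Z <- t(scale(t(m3)))
    sv <- svd(Z)
    ref <- sv$v[, 1] / sd(sv$v[, 1])
    if (mean(sv$u[, 1]) < 0) ref <- -ref
    expect_equal(unname(e), ref, tolerance = 1e-8)
    expect_equal(sd(e), 1, tolerance = 1e-12)
  }
})

test_that("module-TE correlations match cor.test cell by cell", {
  set.seed(12)
  eig <- matrix(rnorm(3 * 10), 3, 10,
                dimnames = list(c("1", "2", "3"), sprintf("S%d", 1:10)))
  te <- matrix(rnorm(4 * 10), 4, 10,
               dimnames = list(c("Alu", "L1", "ERVK", "SAT"), sprintf("S%d", 1:10)))
  assoc <- correlate_te(eig, te)
  for (i in 1:3) for (j in 1:4) {
    ct <- cor.test(eig[i, ], te[j, ])
    expect_equal(assoc$r[i, j], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(assoc$p[i, j], ct$p.value, tolerance = 1e-10)
  }
  # perfect correlation and an exactly orthogonal profile
  te2 <- rbind(perfect = eig[1, ], rest = te[1, ])
  a2 <- correlate_te(eig, te2)
  expect_equal(a2$r[1, "perfect"], 1)
  expect_true(a2$sig[1, "perfect"])
  expect_equal(a2$p[1, "perfect"], 0)
  # zero-variance TE type becomes an NA cell
  te3 <- rbind(flat = rep(3, 10), te)
  a3 <- correlate_te(eig, te3)
  expect_true(all(is.na(a3$r[, "flat"])))
  expect_false(any(a3$sig[, "flat"]))
})

test_that("orthogonal-by-construction profiles give r = 0, p = 1", {
  eig <- matrix(c(1, -1, 1, -1), 1, 4, dimnames = list("1", paste0("S", 1:4)))
  te <- matrix(c(1, 1, -1, -1), 1, 4, dimnames = list("Alu", paste0("S", 1:4)))
  a <- correlate_te(eig, te)
  expect_equal(a$r[1, 1], 0)
  expect_equal(a$p[1, 1], 1)
})

test_that("module direction recovers planted activation and flips with the contrast", {
  x <- two_block_matrix(seed = 31, ns = 10)
  ms <- detect_modules(x, min_module_size = 30)
  set.seed(1)
  t <- rnorm(nrow(x$values))
  up <- names(ms$assignment)[ms$assignment == 1L]
  dn <- names(ms$assignment)[ms$assignment == 2L]
  t[match(up, feature_ids(x))] <- t[match(up, feature_ids(x))] + 2
  t[match(dn, feature_ids(x))] <- t[match(dn, feature_ids(x))] - 2
  fit <- fake_de(t, feature_id = feature_ids(x))
  ms1 <- module_direction(ms, fit, n_perm = 500, seed = 3)
  expect_identical(unname(ms1$direction[ms1$assignment[up[1]]]), "activated_in_a")
  expect_identical(unname(ms1$direction[ms1$assignment[dn[1]]]), "suppressed_in_a")
  # swapped contrast negates every t: directions flip
  fit2 <- fake_de(-t, feature_id = feature_ids(x))
  ms2 <- module_direction(ms, fit2, n_perm = 500, seed = 3)
  flip <- c(activated_in_a = "suppressed_in_a",
            suppressed_in_a = "activated_in_a", none = "none")
  expect_identical(unname(flip[ms1$direction]), unname(ms2$direction))
})

test_that("null modules stay direction-free at least 90% of the time", {
  x <- two_block_matrix(seed = 40, ns = 10)
  ms <- detect_modules(x, min_module_size = 30)
  none <- sapply(1:100, function(s) {
    set.seed(s)
    fit <- fake_de(rnorm(nrow(x$values)), feature_id = feature_ids(x))
    msd <- module_direction(ms, fit, n_perm = 200, seed = s, alpha = 0.05)
    msd$direction[["1"]] == "none"
  })
  expect_gte(mean(none), 0.9)
})

test_that("sign-concordance contingency and chi-square follow the 2x2 formula", {
  mkassoc <- function(r, p, alpha = 0.05) {
    structure(list(r = r, p = p, sig = !is.na(p) & p <= alpha,
                   alpha = alpha, n = 20), class = "association_table")
  }
  mkmods <- function(dirs) {
    structure(list(assignment = integer(0),
                   eigengene = matrix(0, length(dirs), 2,
                                      dimnames = list(names(dirs), c("a", "b"))),
                   sizes = rep(1L, length(dirs)), direction = dirs,
                   direction_p = rep(NA_real_, length(dirs)),
                   direction_contrast = "A_vs_B", k_cut = 1L),
              class = "module_set")
  }
  # perfectly concordant 10 + 10 cells -> chi2 = 20
  r <- rbind(matrix(0.9, 1, 10), matrix(-0.9, 1, 10))
  dimnames(r) <- list(c("1", "2"), sprintf("T%02d", 1:10))
  p <- matrix(0.001, 2, 10, dimnames = dimnames(r))
  mods <- mkmods(c(`1` = "activated_in_a", `2` = "suppressed_in_a"))
  ct <- concordance_chi2(mkassoc(r, p), mods)
  expect_equal(ct$chi2, 20)
  expect_identical(unname(ct$contingency[1, ]), c(10L, 0L))

  # perfect independence -> chi2 = 0, p = 1
  r2 <- rbind(c(rep(0.9, 5), rep(-0.9, 5)), c(rep(0.9, 5), rep(-0.9, 5)))
  dimnames(r2) <- dimnames(r)
  ct2 <- concordance_chi2(mkassoc(r2, p), mods)
  expect_equal(ct2$chi2, 0)
  expect_equal(ct2$p, 1)

  # random tables agree with stats::chisq.test without correction
  for (s in 1:20) {
    set.seed(s)
    r3 <- matrix(runif(20, -1, 1), 2, 10, dimnames = dimnames(r))
    p3 <- matrix(runif(20, 0, 0.2), 2, 10, dimnames = dimnames(r))
    a3 <- mkassoc(r3, p3)
    ct3 <- tryCatch(concordance_chi2(a3, mods), error = function(e) NULL)
    if (is.null(ct3)) next
    ref <- suppressWarnings(chisq.test(ct3$contingency, correct = FALSE))
    expect_equal(ct3$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ct3$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ct3$fisher_p, fisher.test(ct3$contingency)$p.value,
                 tolerance = 1e-12)
    expect_identical(sum(ct3$contingency), ct3$n_cells)
  }

  # zero margin -> error advising the Fisher fallback
  r4 <- rbind(matrix(0.9, 1, 10), matrix(0.9, 1, 10))
  dimnames(r4) <- dimnames(r)
  expect_error(concordance_chi2(mkassoc(r4, p), mods), "Fisher")

  # NA cells are excluded from the contingency table
  r5 <- r; r5[1, 1] <- NA
  p5 <- p
  ct5 <- concordance_chi2(mkassoc(r5, p5), mods)
  expect_identical(ct5$n_cells, 19L)
})
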