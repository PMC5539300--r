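small_cfg <- function(seed = 1, ...) {
  sim_config(n_patients = 4L, n_coding = 120L, n_repeat = 44L,
             n_modules = 2L, module_size = 20L,
             module_effects = list(`1` = list(group = "Blast", lfc = 1),
                                   `2` = list(group = "Blast", lfc = -1)),
             coupling = list(list(module = 1L, te_type = "Alu",
                                  sign = 1L, strength = 0.5)),
             immune_set_spec = list(IMM = 1L),
             regulator_effects = list(ATG5 = list(group = "LSC", lfc = 1)),
             seed = seed, ...)
}

test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(te_suppression = list(NOPE = list(group = "LSC", lfc = -1))),
               "NOPE")
  expect_error(sim_config(te_suppression = list(Alu = list(group = "XXX", lfc = -1))),
               "XXX")
  expect_error(small_cfg(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(coupling = list(list(module = 1, te_type = "Alu",
                                               sign = 1, strength = 2))),
               "strength")
  expect_error(sim_config(n_modules = 100, module_size = 100), "exceeds")
})

test_that("simulation is seed-deterministic and seeds differ", {
  b1 <- simulate_te_experiment(small_cfg(seed = 5))
  b2 <- simulate_te_experiment(small_cfg(seed = 5))
  expect_identical(b1$counts$values, b2$counts$values)
  for (s in 1:10) {
    d1 <- simulate_te_experiment(small_cfg(seed = s))$counts$values
    d2 <- simulate_te_experiment(small_cfg(seed = s + 100))$counts$values
    expect_false(identical(d1, d2))
  }
})

test_that("marginal count means match the constructed log2 means", {
  # one feature replicated over many samples: mean within 3 MC SE
  cfg <- sim_config(n_patients = 500L, groups = c("a", "b"), paired = FALSE,
                    n_coding = 4L, n_repeat = 0L, n_modules = 0L,
                    module_effects = list(), coupling = list(),
                    te_suppression = list(), regulator_effects = list(),
                    immune_set_spec = list(),
                    noise_sd = 0, patient_effect_sd = 0,
                    baseline_log2_range = c(6, 6), seed = 2)
  b <- simulate_te_experiment(cfg)
  counts <- b$counts$values
  mu <- 64
  disp <- cfg$nb_dispersion
  se <- sqrt((mu + disp * mu^2) / ncol(counts))
  expect_true(all(abs(rowMeans(counts) - mu) <= 3 * se))
})

test_that("dispersion zero reaches the Poisson variance/mean limit", {
  cfg <- sim_config(n_patients = 800L, groups = c("a", "b"), paired = FALSE,
                    n_coding = 3L, n_repeat = 0L, n_modules = 0L,
                    module_effects = list(), coupling = list(),
                    te_suppression = list(), regulator_effects = list(),
                    immune_set_spec = list(), nb_dispersion = 0,
                    noise_sd = 0, patient_effect_sd = 0,
                    baseline_log2_range = c(7, 7), seed = 3)
  counts <- simulate_te_experiment(cfg)$counts$values
  ratio <- apply(counts, 1, var) / rowMeans(counts)
  # index of dispersion of a Poisson sample: 1 +- ~sqrt(2/n)
  expect_true(all(abs(ratio - 1) <= 3 * sqrt(2 / ncol(counts))))
})

test_that("zero planted effects give zero truth and near-zero fitted logFC", {
  cfg <- sim_config(seed = 4, te_suppression = list(), coupling = list(),
                    module_effects = list(), regulator_effects = list(),
                    immune_set_spec = list(), n_modules = 0L,
                    n_coding = 600L, n_repeat = 200L)
  b <- simulate_te_experiment(cfg)
  lfc <- true_logfc(b$truth, define_contrast("LSC", "pHSC"))
  expect_true(all(lfc == 0))
  fit <- suppressMessages(
    fit_de(b$counts, b$metadata, define_contrast("LSC", "pHSC", paired = TRUE),
           features = b$annotation$feature_id[b$annotation$kind == "repeat"]))
  expect_lt(abs(median(fit$logFC)), 0.1)
})

test_that("truth records group effects, modules and coupling consistently", {
  b <- simulate_te_experiment(small_cfg(seed = 7))
  ann <- b$annotation
  alu <- ann$feature_id[ann$te_type == "Alu"]
  lfc <- true_logfc(b$truth, define_contrast("LSC", "pHSC"))
  expect_true(all(lfc[alu] == -1))
  mir <- ann$feature_id[ann$te_type == "MIR"]
  expect_true(all(lfc[mir] == 0))
  expect_identical(sum(b$truth$modules == 1L), 20L)
  expect_identical(b$truth$coupling$te_type, "Alu")
  # regulator genes sit outside modules and carry their planted effect
  atg5 <- ann$feature_id[ann$gene_symbol == "ATG5"]
  expect_identical(unname(b$truth$modules[atg5]), 0L)
  expect_equal(unname(true_logfc(b$truth, define_contrast("LSC", "Blast"))[atg5]), 1)
})

test_that("fixtures round-trip bit for bit and are byte-stable per seed", {
  tmp <- withr::local_tempdir()
  b <- simulate_te_experiment(small_cfg(seed = 11))
  d1 <- file.path(tmp, "f1"); d2 <- file.path(tmp, "f2")
  write_fixture(b, d1)
  back <- read_fixture(d1)
  expect_identical(back$counts$values, b$counts$values)
  expect_equal(as.data.frame(back$metadata), as.data.frame(b$metadata))
  expect_equal(as.data.frame(back$annotation), as.data.frame(b$annotation))
  expect_identical(lapply(back$gene_sets, sort), lapply(b$gene_sets, sort))
  expect_equal(back$truth$group_effect, b$truth$group_effect)
  # same seed -> byte-identical files
  write_fixture(simulate_te_experiment(small_cfg(seed = 11)), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("uncoupled TE types show no systematic eigengene correlation", {
  rs <- sapply(1:20, function(s) {
    cfg <- concordance_study_config(coupled = FALSE)
    cfg$seed <- s
    b <- simulate_te_experiment(cfg)
    cpm <- to_cpm(b$counts)
    te <- log_transform(suppressMessages(aggregate_te(cpm, b$annotation, "type")),
                        base10 = TRUE)
    cod_log <- log_transform(cpm[names(b$truth$modules), ], base10 = FALSE)
    ms <- truth_module_set(b, cod_log, define_contrast("high", "low"),
                           directions = concordance_study_directions())
    mean(correlate_te(ms, te)$r)
  })
  expect_lt(abs(mean(rs)), 0.05)
})
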