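#' Study configuration for concordance-test calibration and power
#'
#' A 20-sample design with 10 modules of 20 genes over a 5000-gene
#' background transcriptome, and 68 TE types (the size of the canonical
#' repeat taxonomy) of 10 transcripts each, used to study the
#' sign-concordance chi-square in isolation. Module immune-activity
#' directions are fixed by construction — modules 1-5 are labelled activated
#' and 6-10 suppressed — rather than planted as expression group effects, so
#' that no group-level expression shift leaks into the module-TE
#' correlations through library-size composition; the direction-assignment
#' stage has its own calibration tests. The grid size matters: the
#' chi-square is an asymptotic test, and a module-by-type grid of several
#' hundred cells keeps the expected number of significant cells large
#' enough for its reference distribution to hold.
#'
#' With `coupled = TRUE`, each activated/suppressed module pair is latently
#' coupled to a block of five TE types at strength 0.8: four concordantly
#' (positive correlation with activated modules, negative with suppressed —
#' the Alu/ERVL/ERVK/LTR Retrotransposon pattern) and one discordantly
#' (negative with activated — the ERV1/L1 pattern). With `coupled = FALSE`
#' the same design carries no coupling: the null for calibrating the test.
#'
#' @param coupled plant the concordant coupling structure?
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
concordance_study_config <- function(coupled = TRUE, seed = 1L) {
  taxonomy <- default_te_taxonomy()
  # order the canonical types so the coupled blocks carry the named pattern:
  # concordant Alu/ERVL/ERVK/LTR Retrotransposon, discordant ERV1/L1
  named <- c("Alu", "ERVL", "ERVK", "LTR Retrotransposon", "ERV1", "L1")
  taxonomy <- taxonomy[order(match(taxonomy$te_type, named, nomatch = 99L)), ]
  cfg <- sim_config(
    n_patients = 10L, groups = c("low", "high"), paired = FALSE,
    n_coding = 5000L, n_repeat = 680L,
    te_types = taxonomy, n_te_types = 68L,
    n_modules = 10L, module_size = 20L,
    module_effects = list(), coupling = list(), te_suppression = list(),
    regulator_effects = list(), immune_set_spec = list(),
    seed = seed)
  if (coupled) {
    coupling <- list()
    mk <- function(module, type_idx, sign) {
      list(module = module, te_type = cfg$te_types$te_type[type_idx],
           sign = sign, strength = 0.8)
    }
    for (i in 1:5) {
      types <- 5L * (i - 1L) + 1:5
      for (j in 1:4) {  # concordant block
        coupling <- c(coupling, list(mk(i, types[j], 1L),
                                     mk(i + 5L, types[j], -1L)))
      }
      coupling <- c(coupling, list(mk(i, types[5L], -1L),   # discordant type
                                   mk(i + 5L, types[5L], 1L)))
    }
    cfg$coupling <- coupling
    validate_sim_config(cfg)
  }
  cfg
}

#' Fixed directional labels of the concordance study design
#' @return named character vector: modules 1-5 activated, 6-10 suppressed.
#' @export
concordance_study_directions <- function() {
  stats::setNames(rep(c("activated_in_a", "suppressed_in_a"), each = 5L),
                  as.character(1:10))
}

#' One replicate of the concordance study
#'
#' Simulates a dataset from `config`, computes eigengenes from the true
#' module assignment with the design's fixed directional labels (isolating
#' the concordance test from the detection stages), correlates them with
#' log10(1 + CPM) TE-type expression, and returns the sign-concordance
#' chi-square p-value (`NA` when the test is undefined, e.g. a zero table
#' margin).
#'
#' @param config a `sim_config` from [concordance_study_config()].
#' @param alpha per-cell significance level.
#' @return the chi-square p-value, or `NA`.
#' @export
concordance_replicate <- function(config, alpha = 0.05) {
  b <- simulate_te_experiment(config)
  cpm <- to_cpm(b$counts)
  te_log <- log_transform(
    suppressMessages(aggregate_te(cpm, b$annotation, level = "type")),
    base10 = TRUE, pseudocount = 1)
  cod <- names(b$truth$modules)
  cod_log <- log_transform(cpm[cod, ], base10 = FALSE, pseudocount = 1)
  contrast <- define_contrast(config$groups[2L], config$groups[1L])
  ms <- truth_module_set(b, cod_log, contrast,
                         directions = concordance_study_directions())
  assoc <- correlate_te(ms, te_log, alpha = alpha)
  tryCatch(concordance_chi2(assoc, ms)$p, error = function(e) NA_real_)
}
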