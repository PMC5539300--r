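#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic count generator.
#' The defaults emulate the study design the pipeline targets: 7 patients
#' each contributing one sample per sorted cell fraction (pHSC, LSC, Blast);
#' negative-binomial counts with dispersion 0.1 (variance `mu + 0.1 mu^2`);
#' planted log2 suppression of the Alu, ERV3, ERVK, ERVL and LTR
#' Retrotransposon TE types in the LSC fraction; six latent-factor
#' co-expression modules of 50 coding genes, the first three activated and
#' the next three suppressed in Blast relative to LSC; and latent coupling
#' that ties immune-activated modules positively to Alu/ERVL/ERVK/LTR
#' abundance and negatively to ERV1/L1. All group effects enter additively
#' on the log2 scale, so true fold changes are exact by construction.
#'
#' @param n_patients patients (paired design) or samples per group
#'   (unpaired).
#' @param groups ordered group labels.
#' @param paired logical; paired multi-fraction design vs independent
#'   groups.
#' @param n_coding,n_repeat numbers of coding genes and repeat transcripts.
#' @param te_types data.frame (`te_type`, `te_class`) taxonomy; defaults to
#'   [default_te_taxonomy()].
#' @param n_te_types optional count of TE types to simulate; if larger than
#'   the taxonomy, synthetic types (`TE_TYPE12`, ...) are appended cycling
#'   through the classes.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + disp * mu^2`); 0 gives Poisson counts.
#' @param baseline_log2_range range of per-feature baseline log2 mean
#'   counts, drawn uniformly.
#' @param te_suppression named list `te_type -> list(group, lfc)`: additive
#'   log2 effect applied to that type's transcripts in that group.
#' @param n_modules,module_size planted module structure (first
#'   `n_modules * module_size` coding genes belong to modules).
#' @param factor_loading_sd scale of gene loadings on the module factor
#'   (loadings drawn uniformly in `[0.5, 1.5] * factor_loading_sd`).
#' @param noise_sd SD of per-cell log2 biological noise beyond NB sampling.
#' @param module_effects named list `module -> list(group, lfc)`: additive
#'   log2 group effect on all genes of the module (defines its true
#'   direction).
#' @param coupling list of `list(module, te_type, sign, strength)` entries:
#'   repeat transcripts of `te_type` gain
#'   `sign * strength * factor[module]` on the log2 scale; strengths in
#'   `[0, 1]`, signs in `{-1, 1}`.
#' @param immune_set_spec named list `set_name -> module ids`: the GMT
#'   emitted with a fixture contains these sets, populated with the modules'
#'   gene symbols.
#' @param regulator_effects named list `gene_symbol -> list(group, lfc)`:
#'   planted effects on individually named (non-module) coding genes, used
#'   for the regulator-panel analyses.
#' @param patient_effect_sd SD of per-(feature, patient) log2 offsets — the
#'   between-individual baseline variation absorbed by a paired analysis.
#' @param effective_length_range range of effective lengths (bases).
#' @param seed integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 7L,
                       groups = c("pHSC", "LSC", "Blast"),
                       paired = TRUE,
                       n_coding = 2000L,
                       n_repeat = 500L,
                       te_types = NULL,
                       n_te_types = NULL,
                       nb_dispersion = 0.1,
                       baseline_log2_range = c(3, 9),
                       te_suppression = default_te_suppression(),
                       n_modules = 6L,
                       module_size = 50L,
                       factor_loading_sd = 1,
                       noise_sd = 0.3,
                       module_effects = default_module_effects(),
                       coupling = default_coupling(),
                       immune_set_spec = list(IMMUNE_COMBINED = c(1L, 2L),
                                              INFLAMMATION_COMBINED = 3L),
                       regulator_effects = default_regulator_effects(),
                       patient_effect_sd = 0.5,
                       effective_length_range = c(300, 6000),
                       seed = 1L) {
  if (is.null(te_types)) te_types <- default_te_taxonomy()
  te_types <- as.data.frame(te_types)[c("te_type", "te_class")]
  if (!is.null(n_te_types)) {
    n_te_types <- as.integer(n_te_types)
    if (n_te_types < 1L) stop("n_te_types must be positive")
    if (n_te_types <= nrow(te_types)) {
      te_types <- te_types[seq_len(n_te_types), , drop = FALSE]
    } else {
      extra <- seq.int(nrow(te_types) + 1L, n_te_types)
      te_types <- rbind(te_types, data.frame(
        te_type = sprintf("TE_TYPE%02d", extra),
        te_class = te_types$te_class[(extra - 1L) %% nrow(te_types) + 1L]))
    }
  }
  cfg <- list(n_patients = as.integer(n_patients), groups = as.character(groups),
              paired = isTRUE(paired), n_coding = as.integer(n_coding),
              n_repeat = as.integer(n_repeat), te_types = te_types,
              nb_dispersion = nb_dispersion,
              baseline_log2_range = baseline_log2_range,
              te_suppression = te_suppression,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              factor_loading_sd = factor_loading_sd, noise_sd = noise_sd,
              module_effects = module_effects, coupling = coupling,
              immune_set_spec = immune_set_spec,
              regulator_effects = regulator_effects,
              patient_effect_sd = patient_effect_sd,
              effective_length_range = effective_length_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_te_suppression <- function() {
  types <- c("Alu", "ERV3", "ERVK", "ERVL", "LTR Retrotransposon")
  stats::setNames(lapply(types, function(t) list(group = "LSC", lfc = -1)), types)
}

#' @rdname sim_config
#' @export
default_module_effects <- function() {
  eff <- c(`1` = 1, `2` = 1, `3` = 1, `4` = -1, `5` = -1, `6` = -1)
  lapply(eff, function(l) list(group = "Blast", lfc = l))
}

#' @rdname sim_config
#' @export
default_coupling <- function(strength = 0.4) {
  mk <- function(module, te_type, sign) {
    list(module = module, te_type = te_type, sign = sign, strength = strength)
  }
  list(mk(1L, "Alu", 1L), mk(1L, "ERVL", 1L), mk(1L, "ERV1", -1L),
       mk(2L, "ERVK", 1L), mk(2L, "LTR Retrotransposon", 1L), mk(2L, "L1", -1L),
       mk(4L, "Alu", -1L), mk(4L, "ERVL", -1L), mk(4L, "ERV1", 1L),
       mk(5L, "ERVK", -1L), mk(5L, "LTR Retrotransposon", -1L), mk(5L, "L1", 1L))
}

#' @rdname sim_config
#' @export
default_regulator_effects <- function() {
  genes <- c("ATG5", "KIAA0430", "LAMP2", "HSP90AA1", "DHX15")
  stats::setNames(lapply(genes, function(g) list(group = "LSC", lfc = 1)), genes)
}

validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$n_patients >= 1L, "n_patients must be positive")
  chk(length(cfg$groups) >= 2L && !anyDuplicated(cfg$groups),
      "groups must be >= 2 distinct labels")
  chk(cfg$n_coding >= 1L, "n_coding must be positive")
  chk(cfg$n_repeat >= 0L, "n_repeat must be non-negative")
  chk(cfg$nb_dispersion >= 0, "nb_dispersion must be non-negative")
  chk(length(cfg$baseline_log2_range) == 2L &&
        diff(cfg$baseline_log2_range) >= 0, "baseline_log2_range invalid")
  chk(cfg$n_modules >= 0L && cfg$module_size >= 1L, "module sizes must be positive")
  chk(cfg$n_modules * cfg$module_size <= cfg$n_coding,
      "n_modules * module_size exceeds n_coding")
  chk(cfg$noise_sd >= 0 && cfg$factor_loading_sd >= 0 && cfg$patient_effect_sd >= 0,
      "standard deviations must be non-negative")
  for (nm in names(cfg$te_suppression)) {
    s <- cfg$te_suppression[[nm]]
    chk(nm %in% cfg$te_types$te_type,
        paste0("te_suppression references unknown te_type '", nm, "'"))
    chk(s$group %in% cfg$groups,
        paste0("te_suppression['", nm, "'] references unknown group '", s$group, "'"))
  }
  for (nm in names(cfg$module_effects)) {
    chk(as.integer(nm) >= 1L && as.integer(nm) <= cfg$n_modules,
        paste0("module_effects references unknown module ", nm))
    chk(cfg$module_effects[[nm]]$group %in% cfg$groups,
        paste0("module_effects[", nm, "] references unknown group"))
  }
  for (cp in cfg$coupling) {
    chk(cp$module >= 1L && cp$module <= cfg$n_modules,
        paste0("coupling references unknown module ", cp$module))
    chk(cp$te_type %in% cfg$te_types$te_type,
        paste0("coupling references unknown te_type '", cp$te_type, "'"))
    chk(cp$sign %in% c(-1L, 1L), "coupling sign must be -1 or 1")
    chk(cp$strength >= 0 && cp$strength <= 1, "coupling strength must lie in [0, 1]")
  }
  for (nm in names(cfg$immune_set_spec)) {
    chk(all(cfg$immune_set_spec[[nm]] >= 1L & cfg$immune_set_spec[[nm]] <= cfg$n_modules),
        paste0("immune_set_spec['", nm, "'] references unknown modules"))
  }
  for (nm in names(cfg$regulator_effects)) {
    chk(cfg$regulator_effects[[nm]]$group %in% cfg$groups,
        paste0("regulator_effects['", nm, "'] references unknown group"))
  }
  chk(length(names(cfg$regulator_effects)) + cfg$n_modules * cfg$module_size <= cfg$n_coding,
      "not enough coding genes for regulator effects outside modules")
  if (length(errs)) stop("invalid sim_config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

#' Simulate a TE + coding-gene count dataset with planted structure
#'
#' Draws a features x samples negative-binomial count matrix according to a
#' [sim_config()]: per-module latent factors `f_k[s] ~ N(0, 1)`; coding
#' genes in module `k` have log2 mean
#' `baseline + loading * f_k + group effect + patient offset + noise`;
#' repeat transcripts of type `tau` have log2 mean
#' `baseline + sum_k sign * strength * f_k + suppression effect + patient
#' offset + noise`; counts are NB with mean `2^(log2 mean)` and variance
#' `mu + dispersion * mu^2`. The returned truth record carries exact
#' per-feature group effects, the module assignment, coupling signs and
#' directional module labels, so recovery tests can compare estimates
#' against construction.
#'
#' @param config a `sim_config`.
#' @return a `sim_bundle` list: `counts` (`expr_matrix`, unit count),
#'   `metadata` (`sample_metadata`), `annotation` (`te_annotation`),
#'   `gene_sets` (`gene_sets`), `truth` (list: `group_effect` feature x
#'   group matrix of log2 effects, `modules` named assignment vector,
#'   `coupling` data.frame, `te_type` per repeat feature, `factors`
#'   module x sample matrix), and `config`.
#' @export
simulate_te_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  G <- length(cfg$groups)
  if (cfg$paired) {
    patients <- sprintf("P%02d", seq_len(cfg$n_patients))
    meta <- data.frame(
      sample_id = as.vector(t(outer(patients, cfg$groups, paste, sep = "_"))),
      group = rep(cfg$groups, times = cfg$n_patients),
      patient_id = rep(patients, each = G),
      stringsAsFactors = FALSE)
  } else {
    meta <- data.frame(
      sample_id = paste0(rep(cfg$groups, each = cfg$n_patients), "_",
                         sprintf("S%02d", seq_len(cfg$n_patients))),
      group = rep(cfg$groups, each = cfg$n_patients),
      patient_id = paste0("P", seq_len(G * cfg$n_patients)),
      stringsAsFactors = FALSE)
  }
  n_s <- nrow(meta)
  g_idx <- match(meta$group, cfg$groups)
  p_idx <- match(meta$patient_id, unique(meta$patient_id))
  n_p <- max(p_idx)

  coding_ids <- sprintf("G%05d", seq_len(cfg$n_coding))
  symbols <- sprintf("GENE%05d", seq_len(cfg$n_coding))
  n_mod_genes <- cfg$n_modules * cfg$module_size
  assignment <- c(rep(seq_len(cfg$n_modules), each = cfg$module_size),
                  rep(0L, cfg$n_coding - n_mod_genes))
  names(assignment) <- coding_ids
  # regulator genes live outside modules, at the tail of the coding block
  regs <- names(cfg$regulator_effects)
  if (length(regs)) {
    tail_idx <- seq.int(cfg$n_coding - length(regs) + 1L, cfg$n_coding)
    symbols[tail_idx] <- regs
  }

  rep_ids <- if (cfg$n_repeat) sprintf("R%05d", seq_len(cfg$n_repeat)) else character()
  type_names <- cfg$te_types$te_type
  te_type_of <- if (cfg$n_repeat) {
    type_names[(seq_len(cfg$n_repeat) - 1L) %% length(type_names) + 1L]
  } else character()

  feats <- c(coding_ids, rep_ids)
  n_f <- length(feats)

  # latent module factors, per-(feature, patient) offsets, per-cell noise
  f <- matrix(stats::rnorm(cfg$n_modules * n_s), cfg$n_modules, n_s)
  baseline <- stats::runif(n_f, cfg$baseline_log2_range[1L], cfg$baseline_log2_range[2L])
  pat_off <- matrix(stats::rnorm(n_f * n_p, sd = cfg$patient_effect_sd), n_f, n_p)
  eps <- matrix(stats::rnorm(n_f * n_s, sd = cfg$noise_sd), n_f, n_s)

  # exact additive group effects per feature (log2), the simulation truth
  group_effect <- matrix(0, n_f, G, dimnames = list(feats, cfg$groups))
  for (nm in names(cfg$module_effects)) {
    eff <- cfg$module_effects[[nm]]
    gi <- which(assignment == as.integer(nm))
    group_effect[gi, eff$group] <- group_effect[gi, eff$group] + eff$lfc
  }
  for (nm in names(cfg$regulator_effects)) {
    eff <- cfg$regulator_effects[[nm]]
    gi <- which(symbols == nm)
    group_effect[gi, eff$group] <- group_effect[gi, eff$group] + eff$lfc
  }
  if (cfg$n_repeat) {
    for (nm in names(cfg$te_suppression)) {
      eff <- cfg$te_suppression[[nm]]
      ti <- cfg$n_coding + which(te_type_of == nm)
      group_effect[ti, eff$group] <- group_effect[ti, eff$group] + eff$lfc
    }
  }

  # full log2-mean matrix
  lmat <- matrix(baseline, n_f, n_s) +
    pat_off[, p_idx, drop = FALSE] + eps +
    group_effect[, g_idx, drop = FALSE]
  # module factor contributions to coding genes
  loading <- stats::runif(n_f, 0.5, 1.5) * cfg$factor_loading_sd
  for (k in seq_len(cfg$n_modules)) {
    gi <- which(assignment == k)
    lmat[gi, ] <- lmat[gi, ] + outer(loading[gi], f[k, ])
  }
  # latent coupling of TE types to module factors
  if (cfg$n_repeat && length(cfg$coupling)) {
    for (cp in cfg$coupling) {
      ti <- cfg$n_coding + which(te_type_of == cp$te_type)
      if (length(ti)) {
        lmat[ti, ] <- lmat[ti, ] +
          matrix(cp$sign * cp$strength * f[cp$module, ], length(ti), n_s, byrow = TRUE)
      }
    }
  }

  mu <- 2^lmat
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(stats::rnbinom(n_f * n_s, mu = mu, size = 1 / cfg$nb_dispersion), n_f, n_s)
  } else {
    matrix(stats::rpois(n_f * n_s, lambda = mu), n_f, n_s)
  }
  dimnames(counts) <- list(feats, meta$sample_id)

  lengths <- round(stats::runif(n_f, cfg$effective_length_range[1L],
                                cfg$effective_length_range[2L]))
  class_of <- cfg$te_types$te_class[match(te_type_of, cfg$te_types$te_type)]
  ann <- te_annotation(data.frame(
    feature_id = feats,
    kind = c(rep("coding", cfg$n_coding), rep("repeat", cfg$n_repeat)),
    te_type = c(rep("", cfg$n_coding), te_type_of),
    te_class = c(rep("", cfg$n_coding), class_of),
    gene_symbol = c(symbols, rep("", cfg$n_repeat)),
    effective_length = lengths,
    stringsAsFactors = FALSE))

  sets <- lapply(cfg$immune_set_spec, function(mods) {
    symbols[assignment %in% mods]
  })
  gs <- if (length(sets)) {
    gene_sets(sets, provenance = stats::setNames(
      vapply(cfg$immune_set_spec, function(m) paste0("modules ", paste(m, collapse = ",")),
             character(1L)), names(sets)))
  } else {
    gene_sets(list())
  }

  coupling_df <- if (length(cfg$coupling)) {
    data.frame(module = vapply(cfg$coupling, function(cp) as.numeric(cp$module), 0),
               te_type = vapply(cfg$coupling, function(cp) as.character(cp$te_type), ""),
               sign = vapply(cfg$coupling, function(cp) as.numeric(cp$sign), 0),
               strength = vapply(cfg$coupling, function(cp) as.numeric(cp$strength), 0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(module = integer(0), te_type = character(0),
               sign = integer(0), strength = numeric(0))
  }

  truth <- list(group_effect = group_effect,
                modules = assignment,
                coupling = coupling_df,
                te_type = stats::setNames(te_type_of, rep_ids),
                factors = f)

  structure(list(counts = expression_matrix(counts, unit = "count"),
                 metadata = sample_metadata(meta),
                 annotation = ann,
                 gene_sets = gs,
                 truth = truth,
                 config = cfg),
            class = "sim_bundle")
}

#' True log2 fold changes for a contrast
#'
#' @param truth the `truth` element of a `sim_bundle` (or the bundle).
#' @param contrast a [define_contrast()] object.
#' @return named numeric vector of exact log2 fold changes (a minus b).
#' @export
true_logfc <- function(truth, contrast) {
  if (inherits(truth, "sim_bundle")) truth <- truth$truth
  ge <- truth$group_effect
  ge[, contrast$group_a] - ge[, contrast$group_b]
}

#' Module set built from simulation truth
#'
#' Assembles a `module_set` from the generator's true module assignment and
#' true directional labels, with eigengenes computed from the supplied
#' expression matrix. Used in recovery and calibration studies to isolate a
#' downstream stage from the detection stages.
#'
#' @param bundle a `sim_bundle`.
#' @param x expression matrix (log scale) from which eigengenes are
#'   computed; typically the coding-gene log-CPM of the bundle.
#' @param contrast the defining contrast for directional labels (derived
#'   from the sign of the modules' true group effects).
#' @param directions optional named character vector overriding the derived
#'   labels (values `activated_in_a` / `suppressed_in_a` / `none`), for
#'   study designs where direction is fixed by construction rather than by
#'   a group effect.
#' @return a `module_set` with truth-derived assignment and directions.
#' @export
truth_module_set <- function(bundle, x, contrast, directions = NULL) {
  stopifnot(inherits(bundle, "sim_bundle"))
  assignment <- bundle$truth$modules
  assignment <- assignment[names(assignment) %in% feature_ids(x)]
  eig <- module_eigengenes(x, assignment)
  K <- nrow(eig)
  dir <- stats::setNames(rep("none", K), rownames(eig))
  for (k in rownames(eig)) {
    genes <- names(assignment)[assignment == as.integer(k)]
    lfc <- true_logfc(bundle$truth, contrast)[genes]
    m <- mean(lfc)
    if (m > 0) dir[k] <- "activated_in_a"
    if (m < 0) dir[k] <- "suppressed_in_a"
  }
  if (!is.null(directions)) dir[names(directions)] <- directions
  structure(list(assignment = assignment, eigengene = eig,
                 sizes = as.integer(table(factor(assignment[assignment > 0],
                                                 levels = seq_len(K)))),
                 direction = dir,
                 direction_p = stats::setNames(rep(NA_real_, K), rownames(eig)),
                 direction_contrast = contrast$name, k_cut = NA_integer_),
            class = "module_set")
}

#' Write a simulated bundle to disk as plain-text fixtures
#'
#' Emits `counts.tsv`, `metadata.tsv`, `annotation.tsv`, `gene_sets.gmt` and
#' `truth.json` into `dir`; reading them back with the package readers
#' reproduces the bundle exactly.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_counts(bundle$counts, paths["counts"])
  write_sample_metadata(bundle$metadata, paths["metadata"])
  write_te_annotation(bundle$annotation, paths["annotation"])
  write_gmt(bundle$gene_sets, paths["gene_sets"])
  truth <- bundle$truth
  tr <- list(group_effect = as.data.frame(truth$group_effect),
             feature_id = rownames(truth$group_effect),
             modules = as.list(truth$modules),
             coupling = truth$coupling,
             te_type = as.list(truth$te_type))
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read fixture files written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `counts`, `metadata`, `annotation`, `gene_sets`,
#'   `truth` (group-effect matrix, module assignment, coupling, te_type).
#' @export
read_fixture <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  metadata <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  annotation <- read_te_annotation(file.path(dir, "annotation.tsv"))
  gs <- read_gmt(file.path(dir, "gene_sets.gmt"))
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    tr <- jsonlite::fromJSON(tpath)
    ge <- as.matrix(tr$group_effect)
    rownames(ge) <- tr$feature_id
    truth <- list(group_effect = ge,
                  modules = unlist(tr$modules),
                  coupling = as.data.frame(tr$coupling),
                  te_type = unlist(tr$te_type))
  }
  list(counts = counts, metadata = metadata, annotation = annotation,
       gene_sets = gs, truth = truth)
}
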