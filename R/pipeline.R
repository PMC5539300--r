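#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) and checks it,
#' returning either a validated `pipeline_config` or the full list of
#' violations — all of them at once, not just the first.
#'
#' Expected fields: `seed` (integer); either `demo: true` or an `inputs`
#' block with paths `counts`, `annotation`, `metadata`, `gene_sets`;
#' `contrasts` (list of `name` / `group_a` / `group_b` / `paired`);
#' `association_contrast` (name of the contrast driving enrichment, modules
#' and the association table); `alpha` block (`de_fdr`, `cell`, `display`,
#' each in (0, 1)); `n_perm`; `modules` block (`min_module_size`,
#' `n_modules`); `outdir`.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return a `pipeline_config` when valid, otherwise a character vector of
#'   violations with class `pipeline_config_errors`.
#' @export
validate_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- tryCatch(yaml::read_yaml(path),
                    error = function(e) stop("cannot parse config ", path, ": ",
                                             conditionMessage(e)))
  } else if (is.list(path)) {
    cfg <- path
  } else {
    stop("config must be a YAML path or a list")
  }
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  cfg$seed <- cfg$seed %||% 1L
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && cfg$seed == round(cfg$seed),
      "seed must be a single integer")
  cfg$n_perm <- cfg$n_perm %||% 1000L
  chk(is.numeric(cfg$n_perm) && cfg$n_perm >= 1, "n_perm must be >= 1")

  alpha <- cfg$alpha %||% list()
  alpha$de_fdr <- alpha$de_fdr %||% 0.05
  alpha$cell <- alpha$cell %||% 0.05
  alpha$display <- alpha$display %||% 0.025
  for (nm in c("de_fdr", "cell", "display")) {
    chk(is.numeric(alpha[[nm]]) && alpha[[nm]] > 0 && alpha[[nm]] < 1,
        paste0("alpha$", nm, " must lie in (0, 1)"))
  }
  cfg$alpha <- alpha

  mods <- cfg$modules %||% list()
  mods$min_module_size <- mods$min_module_size %||% 30L
  mods$n_modules <- mods$n_modules %||% "auto"
  chk(is.numeric(mods$min_module_size) && mods$min_module_size >= 2,
      "modules$min_module_size must be >= 2")
  chk(identical(mods$n_modules, "auto") ||
        (is.numeric(mods$n_modules) && mods$n_modules >= 1),
      "modules$n_modules must be 'auto' or a positive integer")
  cfg$modules <- mods

  demo <- isTRUE(cfg$demo)
  if (!demo) {
    inp <- cfg$inputs
    if (is.null(inp)) {
      errs <- c(errs, "either demo: true or an inputs block is required")
    } else {
      for (nm in c("counts", "annotation", "metadata", "gene_sets")) {
        if (is.null(inp[[nm]])) {
          errs <- c(errs, paste0("inputs$", nm, " is required"))
        } else if (!file.exists(inp[[nm]])) {
          errs <- c(errs, paste0("inputs$", nm, " does not exist: ", inp[[nm]]))
        }
      }
    }
  }

  cts <- cfg$contrasts
  if (is.null(cts) || !length(cts)) {
    if (demo) {
      cts <- list(list(name = "LSC_vs_pHSC", group_a = "LSC", group_b = "pHSC",
                       paired = TRUE),
                  list(name = "Blast_vs_LSC", group_a = "Blast", group_b = "LSC",
                       paired = TRUE))
      cfg$association_contrast <- cfg$association_contrast %||% "Blast_vs_LSC"
    } else {
      errs <- c(errs, "at least one contrast is required")
      cts <- list()
    }
  }
  for (i in seq_along(cts)) {
    ct <- cts[[i]]
    if (is.null(ct$group_a) || is.null(ct$group_b) ||
        identical(ct$group_a, ct$group_b)) {
      errs <- c(errs, paste0("contrast ", i, " needs distinct group_a and group_b"))
    }
    cts[[i]]$paired <- isTRUE(ct$paired)
    cts[[i]]$name <- ct$name %||% paste0(ct$group_a, "_vs_", ct$group_b)
  }
  cfg$contrasts <- cts
  if (length(cts)) {
    cfg$association_contrast <- cfg$association_contrast %||% cts[[length(cts)]]$name
    chk(cfg$association_contrast %in% vapply(cts, `[[`, "", "name"),
        "association_contrast does not name a defined contrast")
  }
  cfg$outdir <- cfg$outdir %||% "teexpr_out"
  cfg$demo <- demo

  if (length(errs)) {
    return(structure(errs, class = "pipeline_config_errors"))
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config_errors <- function(x, ...) {
  cat("invalid pipeline configuration:\n")
  for (e in x) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Run the full TE-expression analysis pipeline
#'
#' Executes read -> quantify/aggregate -> differential expression (TE
#' transcripts, TE types, coding genes) -> gene-set enrichment -> module
#' detection -> module/TE-type association -> sign-concordance chi-square,
#' writing per-stage TSV/JSON outputs, a `MANIFEST.tsv` recording each
#' stage's status, and a single machine-readable `report.json`. A stage
#' failure aborts with the stage name; completed outputs and the MANIFEST
#' are retained. The TE stages are skipped (with explicit "skipped" status)
#' when the input has no annotated repeat features; coding stages still run.
#'
#' @param config a `pipeline_config` from [validate_config()], a YAML path,
#'   or a config list.
#' @return the report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config)
    if (inherits(config, "pipeline_config_errors")) {
      stop("invalid configuration:\n  - ", paste(config, collapse = "\n  - "))
    }
  }
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- data.frame(stage = character(0), status = character(0),
                         stringsAsFactors = FALSE)
  note_stage <- function(stage, status) {
    manifest <<- rbind(manifest, data.frame(stage = stage, status = status,
                                            stringsAsFactors = FALSE))
    write_tsv_table(manifest, file.path(outdir, "MANIFEST.tsv"))
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      note_stage(stage, paste0("failed: ", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note_stage(stage, "ok")
    res
  }
  report <- list(schema = "teexpr-report/1", seed = config$seed)
  set.seed(config$seed)

  ## stage: load
  loaded <- run_stage("load", {
    if (config$demo) {
      bundle <- simulate_te_experiment(sim_config(seed = config$seed))
      fx <- file.path(outdir, "fixture")
      write_fixture(bundle, fx)
      list(counts = bundle$counts, ann = bundle$annotation,
           meta = bundle$metadata, sets = bundle$gene_sets)
    } else {
      inp <- config$inputs
      list(counts = read_counts(inp$counts,
                                format = if (grepl("\\.mtx$", inp$counts)) "mtx" else "tsv"),
           ann = read_te_annotation(inp$annotation),
           meta = read_sample_metadata(inp$metadata),
           sets = read_gmt(inp$gene_sets))
    }
  })
  counts <- loaded$counts; ann <- loaded$ann
  meta <- loaded$meta; sets <- loaded$sets
  unann <- unannotated_features(counts, ann)
  if (length(unann)) {
    writeLines(unann, file.path(outdir, "unannotated_features.txt"))
    message(sprintf("run_pipeline: %d unannotated feature(s) (see unannotated_features.txt)",
                    length(unann)))
  }
  report$n_features <- nrow(counts$values)
  report$n_samples <- ncol(counts$values)

  rep_feats <- intersect(feature_ids(counts),
                         ann$feature_id[ann$kind == "repeat"])
  cod_feats <- intersect(feature_ids(counts),
                         ann$feature_id[ann$kind == "coding"])
  has_te <- length(rep_feats) > 0L

  ## stage: quantify
  quant <- run_stage("quantify", {
    cpm <- to_cpm(counts)
    out <- list(cpm = cpm)
    if (has_te) {
      out$te_type <- aggregate_te(cpm, ann, level = "type")
      out$te_class <- aggregate_te(cpm, ann, level = "class")
      write_aggregated(out$te_type, file.path(outdir, "te_type_cpm.tsv"))
      write_aggregated(out$te_class, file.path(outdir, "te_class_cpm.tsv"))
    }
    out
  })
  if (!has_te) note_stage("quantify_te", "skipped (no repeat features)")

  ## stage: de
  de <- run_stage("de", {
    out <- list()
    for (ct in config$contrasts) {
      contrast <- define_contrast(ct$group_a, ct$group_b, paired = ct$paired,
                                  name = ct$name)
      fits <- list()
      fits$coding <- fit_de(counts, meta, contrast, features = cod_feats)
      write_de(fits$coding, file.path(outdir, paste0("de_coding_", ct$name, ".tsv")))
      if (has_te) {
        fits$te_transcript <- fit_de(counts, meta, contrast, features = rep_feats)
        write_de(fits$te_transcript,
                 file.path(outdir, paste0("de_te_transcript_", ct$name, ".tsv")))
        te_log2 <- quant$te_type
        te_log2 <- log_transform(te_log2, base10 = FALSE, pseudocount = 1)
        fits$te_type <- fit_de(te_log2, meta, contrast, min_total_count = 0)
        write_de(fits$te_type,
                 file.path(outdir, paste0("de_te_type_", ct$name, ".tsv")))
        q <- lfc_quantiles(fits$te_transcript, probs = seq(0, 1, 0.25),
                           only_significant = TRUE, alpha = config$alpha$de_fdr)
        utils::write.table(q, file.path(outdir, paste0("lfc_quantiles_", ct$name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        fits$lfc_quantiles <- q
      }
      out[[ct$name]] <- fits
    }
    out
  })
  if (!has_te) note_stage("de_te", "skipped (no repeat features)")

  assoc_name <- config$association_contrast
  assoc_fit <- de[[assoc_name]]$coding
  report$contrasts <- lapply(config$contrasts, function(ct) {
    entry <- list(name = ct$name, group_a = ct$group_a, group_b = ct$group_b,
                  paired = ct$paired)
    if (has_te) {
      tt <- de[[ct$name]]$te_type
      entry$te_type_logfc <- stats::setNames(as.list(tt$logFC), tt$feature_id)
      q <- de[[ct$name]]$lfc_quantiles
      entry$lfc_quantiles <- if (nrow(q)) {
        stats::setNames(as.list(q$value), paste0("q", q$prob))
      } else {
        list()
      }
    }
    entry
  })

  ## stage: enrich
  enrich <- run_stage("enrich", {
    if (!length(sets)) {
      note_stage("enrich_sets", "skipped (no gene sets)")
      NULL
    } else {
      res <- enrich_sets(assoc_fit, sets, n_perm = config$n_perm,
                         seed = config$seed + 1L, ann = ann,
                         alpha = 2 * config$alpha$display)
      write_tsv_table(as.data.frame(res), file.path(outdir, "enrichment.tsv"))
      res
    }
  })
  if (!is.null(enrich)) {
    report$enrichment <- lapply(seq_len(nrow(enrich)), function(i) as.list(enrich[i, ]))
  }

  ## stage: modules — detected on the association contrast's samples
  assoc_ct <- Filter(function(ct) ct$name == assoc_name, config$contrasts)[[1L]]
  assoc_samples <- meta$sample_id[meta$group %in% c(assoc_ct$group_a, assoc_ct$group_b)]
  modules <- run_stage("modules", {
    cod_cpm <- to_cpm(counts[cod_feats, assoc_samples])
    cod_log <- log_transform(cod_cpm, base10 = FALSE, pseudocount = 1)
    ms <- detect_modules(cod_log, min_module_size = config$modules$min_module_size,
                         n_modules = config$modules$n_modules)
    ms <- module_direction(ms, assoc_fit, n_perm = config$n_perm,
                           seed = config$seed + 2L, alpha = config$alpha$cell)
    write_tsv_table(data.frame(feature_id = names(ms$assignment),
                               module = unname(ms$assignment)),
                    file.path(outdir, "modules.tsv"))
    ms
  })
  report$n_modules <- nrow(modules$eigengene)
  report$module_direction <- as.list(modules$direction)

  ## stage: associate
  if (has_te) {
    assoc <- run_stage("associate", {
      te_log10 <- log_transform(quant$te_type, base10 = TRUE, pseudocount = 1)
      te_sub <- te_log10
      te_sub$values <- te_sub$values[, assoc_samples, drop = FALSE]
      a <- correlate_te(modules, te_sub, alpha = config$alpha$cell)
      write_association(a, file.path(outdir, "association.tsv"))
      a
    })
    report$association <- list(
      modules = rownames(assoc$r), te_types = colnames(assoc$r),
      r = apply(assoc$r, 1L, as.list),
      n_significant = sum(assoc$sig, na.rm = TRUE))

    conc <- run_stage("concordance", {
      tryCatch(concordance_chi2(assoc, modules),
               error = function(e) {
                 message("concordance: ", conditionMessage(e))
                 NULL
               })
    })
    if (!is.null(conc)) {
      report$concordance <- list(
        contingency = list(activated = as.list(conc$contingency[1L, ]),
                           suppressed = as.list(conc$contingency[2L, ])),
        chi2 = conc$chi2, df = conc$df, p = conc$p,
        fisher_p = conc$fisher_p, n_cells = conc$n_cells)
      jsonlite::write_json(report$concordance,
                           file.path(outdir, "concordance.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      report$concordance <- NULL
    }
  } else {
    note_stage("associate", "skipped (no repeat features)")
    note_stage("concordance", "skipped (no repeat features)")
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note_stage("report", "ok")
  invisible(report)
}

#' Run the built-in demonstration pipeline
#'
#' Generates the default synthetic dataset (7 patients x 3 fractions,
#' planted TE suppression in LSC, 6 coding-gene modules, TE-immune
#' coupling), writes it under `outdir/fixture/`, and runs the full pipeline
#' on it. Deterministic given `seed`.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param n_perm permutations for the enrichment stages.
#' @return the report list, invisibly.
#' @export
run_demo <- function(outdir, seed = 1L, n_perm = 1000L) {
  cfg <- validate_config(list(demo = TRUE, seed = as.integer(seed),
                              n_perm = n_perm, outdir = outdir))
  if (inherits(cfg, "pipeline_config_errors")) {
    stop(paste(cfg, collapse = "; "))
  }
  run_pipeline(cfg)
}
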