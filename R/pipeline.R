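# End-to-end orchestration: simulate (optional) -> call (dual, plus the
# effect-only and equal-N power controls) -> specificity -> annotate /
# enrich -> report. Every stage's tables are written before the next stage
# begins; a stage failure aborts naming the stage, retaining partial output.

#' Pipeline configuration
#'
#' @param out_dir output directory for per-stage TSVs (NULL keeps results
#'   in memory only).
#' @param seed global integer seed, fanned out per stage via
#'   \code{derive_seed}.
#' @param simulate list of simulation settings: n_probes, n_genes,
#'   design (a \code{cohort_design}), effects (an \code{effect_design}),
#'   noise (a \code{noise_model}); or NULL to supply data via
#'   \code{tissues}.
#' @param tissues when not simulating: named list, one entry per tissue,
#'   each a list(betas = path, meta = path, covariates = character()).
#' @param covariates named list of covariate column selections per tissue
#'   (for simulated cohorts; default: sex where it varies, batch where
#'   present, cell fractions where present).
#' @param criteria a \code{calling_criteria}.
#' @param effect_only also run the effect-size-only calling variant.
#' @param equal_n NULL, or the target sample count for the equal-N
#'   subsampling variant.
#' @param enrichment run annotation enrichment stages.
#' @param p_relaxed relaxed raw-P cut-off for the cross-tissue check.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1, simulate = NULL,
                            tissues = NULL, covariates = NULL,
                            criteria = calling_criteria(),
                            effect_only = TRUE, equal_n = NULL,
                            enrichment = TRUE, p_relaxed = 0.001) {
  if (is.null(simulate) && is.null(tissues))
    stopf("config needs either a 'simulate' block or input 'tissues'")
  if (!is.null(tissues)) {
    for (t in names(tissues)) {
      for (f in c("betas", "meta")) {
        if (is.null(tissues[[t]][[f]]) || !file.exists(tissues[[t]][[f]]))
          stopf("config: missing %s file for tissue '%s'", f, t)
      }
    }
  }
  stopifnot(inherits(criteria, "calling_criteria"))
  seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 tissues = tissues, covariates = covariates,
                 criteria = criteria, effect_only = effect_only,
                 equal_n = equal_n, enrichment = enrichment,
                 p_relaxed = p_relaxed),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full aDMP analysis pipeline
#'
#' Executes every stage of the tissue-specificity analysis on either a
#' simulated or a file-based multi-tissue cohort and assembles the summary
#' report: per-tissue gain/loss counts, percent tissue-specific per
#' direction, sharing histograms, overlap matrices, enrichment profiles,
#' the power-control comparison (dual vs effect-only vs equal-N) and a
#' provenance block. Deterministic for a fixed config and seed.
#'
#' @param config a \code{pipeline_config}.
#' @return object of class \code{admp_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  genome <- NULL; effects <- NULL

  # --- stage: simulate / load -------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cohort <- run_stage("simulate", {
      design <- sim$design %||% default_cohort_design()
      genome <- generate_genome(
        n_probes = sim$n_probes %||% 20000,
        n_genes = sim$n_genes %||% 300,
        tissues = design$tissue,
        seed = derive_seed(config$seed, "genome"))
      effects <- plant_effects(genome, sim$effects %||% effect_design(),
                                seed = derive_seed(config$seed, "effects"))
      simulate_cohort(genome, effects, design,
                      noise = sim$noise %||% noise_model(),
                      seed = derive_seed(config$seed, "cohort"))
    })
    log_stage("simulate", tissues = length(cohort),
              probes = nrow(genome$probes),
              planted = nrow(effects$effects))
    if (!is.null(out_dir)) {
      write_genome(genome, file.path(out_dir, "genome"))
      write_effect_map(effects, file.path(out_dir, "effects.tsv"))
      write_cohort(cohort, file.path(out_dir, "cohort"))
    }
    covsel <- config$covariates %||% lapply(cohort, function(d) {
      m <- d$samples
      c(if (length(unique(m$sex)) > 1) "sex",
        if (!is.null(m$batch)) "batch",
        grep("^cf", names(m), value = TRUE))
    })
  } else {
    cohort <- run_stage("load", {
      lapply(names(config$tissues), function(t) {
        spec <- config$tissues[[t]]
        methylation_dataset(read_beta_matrix(spec$betas),
                            read_metadata(spec$meta), t)
      })
    })
    names(cohort) <- names(config$tissues)
    covsel <- lapply(config$tissues, function(s) s$covariates %||% character())
  }

  # --- stage: call -------------------------------------------------------
  call_variant <- function(datasets, criteria, tag) {
    run_stage(paste0("call_", tag), {
      calls <- lapply(names(datasets), function(t) {
        cc <- call_admps(datasets[[t]], criteria,
                         covariates = covsel[[t]] %||% character())
        log_stage(paste0("call_", tag), tissue = t,
                  tested = cc$m_tested,
                  gain = sum(cc$table$class == "gain"),
                  loss = sum(cc$table$class == "loss"))
        if (!is.null(out_dir))
          write_admp_table(cc, file.path(out_dir,
            sprintf("admps_%s_%s.tsv", tag, gsub("\\W", "_", t))))
        cc
      })
      names(calls) <- names(datasets)
      calls
    })
  }
  calls_dual <- call_variant(cohort, config$criteria, "dual")
  calls_eff <- if (isTRUE(config$effect_only)) {
    crit_eff <- config$criteria
    crit_eff$mode <- "effect_only"
    call_variant(cohort, crit_eff, "effect_only")
  } else NULL
  calls_eqn <- if (!is.null(config$equal_n)) {
    sub <- run_stage("subsample", subsample_equal_n(
      cohort, config$equal_n, seed = derive_seed(config$seed, "equal_n")))
    call_variant(sub, config$criteria, "equal_n")
  } else NULL

  # --- stage: specificity -----------------------------------------------
  spec <- run_stage("specificity", {
    lapply(stats::setNames(c("gain", "loss"), c("gain", "loss")),
           function(dir) {
      st <- build_specificity(calls_dual, dir)
      if (!is.null(out_dir))
        data.table::fwrite(as.data.frame(st),
                           file.path(out_dir,
                                     sprintf("specificity_%s.tsv", dir)),
                           sep = "\t", quote = FALSE)
      list(table = st,
           pct_specific = if (nrow(st)) percent_tissue_specific(st) else NA,
           histogram = if (nrow(st)) sharing_histogram(st) else NULL,
           overlap = overlap_matrix(calls_dual, dir),
           cross_tissue = if (nrow(st))
             cross_tissue_significance(st, calls_dual,
                                       config$p_relaxed) else NULL)
    })
  })
  for (dir in names(spec)) {
    log_stage("specificity", direction = dir,
              n_admps = nrow(spec[[dir]]$table),
              pct_specific = as.numeric(spec[[dir]]$pct_specific %||% NA))
  }

  # --- stage: annotate / enrich -----------------------------------------
  enr <- NULL
  annotation <- NULL
  if (isTRUE(config$enrichment) && !is.null(genome)) {
    annotation <- run_stage("annotate", annotate_probes(genome))
    if (!is.null(out_dir))
      data.table::fwrite(annotation, file.path(out_dir, "annotation.tsv"),
                         sep = "\t", quote = FALSE)
    enr <- run_stage("enrich", {
      res <- list()
      for (dir in c("gain", "loss")) {
        res[[dir]] <- lapply(names(calls_dual), function(t) {
          cc <- calls_dual[[t]]
          tested <- cc$table$class != "untested"
          bg <- cc$table$probe_id[tested]
          admps <- cc$table$probe_id[cc$table$class == dir]
          idx <- match(cc$table$probe_id, annotation$probe_id)
          list(states = state_enrichment_profile(
                 cc, dir, annotation[[paste0("state_", t)]][idx]),
               cgi = cgi_enrichment_profile(
                 cc, dir, annotation$cgi_class[idx]),
               ezh2 = enrichment_test(
                 admps, bg, annotation$probe_id[annotation$ezh2],
                 category = "EZH2", m_tests = 1),
               joint = cgi_ezh2_joint_enrichment(
                 admps, bg,
                 annotation$cgi_class[idx][tested],
                 annotation$ezh2[idx][tested]))
        })
        names(res[[dir]]) <- names(calls_dual)
      }
      res
    })
    if (!is.null(out_dir)) {
      flat <- do.call(rbind, lapply(names(enr), function(dir) {
        do.call(rbind, lapply(names(enr[[dir]]), function(t) {
          df <- rbind(enr[[dir]][[t]]$states, enr[[dir]][[t]]$cgi,
                      enr[[dir]][[t]]$ezh2, enr[[dir]][[t]]$joint)
          cbind(direction = dir, tissue = t, df)
        }))
      }))
      data.table::fwrite(flat, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE)
    }
  }

  # --- stage: region aggregation ----------------------------------------
  regions <- NULL
  if (!is.null(annotation)) {
    regions <- run_stage("regions", {
      lapply(spec, function(sp) {
        if (!nrow(sp$table)) return(NULL)
        list(cgi = {
          map <- data.frame(probe_id = annotation$probe_id,
                            unit = annotation$cgi_id,
                            stringsAsFactors = FALSE)
          map <- map[!is.na(map$unit), ]
          if (any(sp$table$probe_id %in% map$probe_id))
            aggregate_to_regions(sp$table, map, "CGI") else NULL
        },
        gene = aggregate_to_regions(
          sp$table,
          data.frame(probe_id = annotation$probe_id,
                     unit = annotation$nearest_gene,
                     stringsAsFactors = FALSE), "gene"))
      })
    })
  }

  # --- report ------------------------------------------------------------
  counts <- function(calls) {
    if (is.null(calls)) return(NULL)
    do.call(rbind, lapply(names(calls), function(t) {
      tab <- calls[[t]]$table
      data.frame(tissue = t, gain = sum(tab$class == "gain"),
                 loss = sum(tab$class == "loss"),
                 tested = calls[[t]]$m_tested,
                 n = calls[[t]]$n_samples, stringsAsFactors = FALSE)
    }))
  }
  power <- list(dual = counts(calls_dual), effect_only = counts(calls_eff),
                equal_n = counts(calls_eqn))
  pct_tbl <- function(calls) {
    if (is.null(calls)) return(NULL)
    vapply(c(gain = "gain", loss = "loss"), function(dir) {
      st <- build_specificity(calls, dir)
      if (nrow(st)) as.numeric(percent_tissue_specific(st)) else NA_real_
    }, numeric(1))
  }
  power$pct_specific <- list(dual = pct_tbl(calls_dual),
                             effect_only = pct_tbl(calls_eff),
                             equal_n = pct_tbl(calls_eqn))

  report <- structure(list(
    counts = power$dual,
    specificity = lapply(spec, function(s)
      list(pct_specific = s$pct_specific, histogram = s$histogram,
           overlap = s$overlap,
           cross_tissue_fraction = s$cross_tissue$fraction %||% NA_real_)),
    power_control = power,
    enrichment = enr,
    regions = regions,
    calls = list(dual = calls_dual, effect_only = calls_eff,
                 equal_n = calls_eqn),
    truth = effects,
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("admpatlas")))),
    class = "admp_report")
  if (!is.null(out_dir)) {
    data.table::fwrite(report$counts, file.path(out_dir, "report_counts.tsv"),
                       sep = "\t", quote = FALSE)
  }
  report
}

# Deterministic config fingerprint (md5 of the deparsed config).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.admp_report <- function(x, ...) {
  cat("aDMP pipeline report\n")
  cat(sprintf("  seed %d, config %s, version %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8), x$provenance$version))
  print(x$counts, row.names = FALSE)
  for (dir in names(x$specificity)) {
    s <- x$specificity[[dir]]
    cat(sprintf("  %s-aDMPs: %.1f%% tissue-specific; cross-tissue relaxed-P fraction %.3f\n",
                dir, as.numeric(s$pct_specific),
                s$cross_tissue_fraction))
  }
  invisible(x)
}
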