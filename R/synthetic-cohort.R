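# Cohort simulation: per-tissue beta matrices with planted linear age
# effects, covariate structure (sex, batch, optional cell fractions),
# additive Gaussian noise on the beta scale (clipped to [0,1]) and MCAR
# missingness.

#' A per-tissue methylation dataset
#'
#' Beta matrix (probes x samples) plus aligned sample metadata. Metadata rows
#' correspond 1:1, in order, to matrix columns, checked via shared sample ids.
#'
#' @param betas numeric probes x samples matrix in [0,1], NA allowed.
#' @param samples data.frame with \code{sample_id}, \code{age} (years) and
#'   covariate columns; one row per matrix column.
#' @param tissue tissue label.
#' @return object of class \code{methylation_dataset}.
#' @export
methylation_dataset <- function(betas, samples, tissue) {
  if (!is.matrix(betas) || !is.numeric(betas)) stopf("betas must be a numeric matrix")
  validate_betas(betas)
  if (nrow(samples) != ncol(betas))
    stopf("metadata rows (%d) != matrix columns (%d)", nrow(samples), ncol(betas))
  if (is.null(colnames(betas))) stopf("betas must have sample-id column names")
  if (!identical(as.character(samples$sample_id), colnames(betas)))
    stopf("sample_id order does not match matrix columns")
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample_ids")
  if (any(!is.finite(samples$age)) || any(samples$age < 0))
    stopf("ages must be finite and >= 0")
  structure(list(betas = betas, samples = samples, tissue = tissue),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation dataset '%s': %d probes x %d samples, ages %.1f-%.1f, %.2f%% missing\n",
              x$tissue, nrow(x$betas), ncol(x$betas),
              min(x$samples$age), max(x$samples$age),
              100 * mean(is.na(x$betas))))
  invisible(x)
}

#' Multi-tissue cohort design
#'
#' One row per tissue: sample count, age range, covariate structure and
#' missingness rate. \code{default_cohort_design()} reproduces the seven-
#' tissue compendium the package emulates: brain (n=380, ages 0-97), buccal
#' (96, 1-28), liver (147, 15-86; 3 study batches), kidney (171, 15-86),
#' subcutaneous fat (648, 39-85; females only), monocytes (1202, 44-83) and
#' T-helper cells (214, 45-79), the latter two with residual cell-impurity
#' fractions.
#'
#' @param tissue,n,age_min,age_max,sex_prop,n_batches,n_cellfrac,missing_rate
#'   equal-length vectors (recycled scalars allowed).
#' @return data.frame of class \code{cohort_design}.
#' @export
cohort_design <- function(tissue, n, age_min, age_max, sex_prop = 0.5,
                          n_batches = 1, n_cellfrac = 0, missing_rate = 0) {
  d <- data.frame(tissue = tissue, n = n, age_min = age_min, age_max = age_max,
                  sex_prop = sex_prop, n_batches = n_batches,
                  n_cellfrac = n_cellfrac, missing_rate = missing_rate,
                  stringsAsFactors = FALSE)
  n_cov <- (d$sex_prop > 0 & d$sex_prop < 1) + pmax(0, d$n_batches - 1) +
    pmax(0, d$n_cellfrac - 1)
  if (any(d$n < 3 + n_cov))
    stopf("sample count must be >= 3 + number of covariates (tissue %s)",
          d$tissue[which(d$n < 3 + n_cov)[1]])
  if (any(d$age_max <= d$age_min))
    stopf("degenerate age range for tissue %s",
          d$tissue[which(d$age_max <= d$age_min)[1]])
  if (anyDuplicated(d$tissue)) stopf("duplicate tissue labels in design")
  class(d) <- c("cohort_design", "data.frame")
  d
}

#' @rdname cohort_design
#' @export
default_cohort_design <- function() {
  cohort_design(
    tissue = c("brain", "buccal", "liver", "kidney", "fat", "monocytes",
               "thcells"),
    n = c(380, 96, 147, 171, 648, 1202, 214),
    age_min = c(0, 1, 15, 15, 39, 44, 45),
    age_max = c(97, 28, 86, 86, 85, 83, 79),
    sex_prop = c(0.5, 0.5, 0.5, 0.5, 0, 0.5, 0.5),
    n_batches = c(1, 1, 3, 1, 1, 1, 1),
    n_cellfrac = c(2, 0, 0, 0, 0, 2, 2),
    missing_rate = 0.005)
}

#' Noise and baseline model for the simulator
#'
#' Baselines are drawn uniformly per probe within a CGI-class-specific range
#' (islands hypomethylated, non-CGI hypermethylated, shores intermediate),
#' kept inside [0.1, 0.9] so planted effects remain recoverable despite
#' clipping. Noise is additive Gaussian on the beta scale by default; a
#' logit-normal alternative is available but off by default.
#'
#' @param residual_sd residual standard deviation on the beta scale (>= 0).
#' @param baseline_ranges named list of c(min, max) baseline ranges for
#'   island / shore / non_CGI probes.
#' @param sex_sd,batch_sd,cellfrac_sd standard deviations of per-probe
#'   covariate effects on the beta scale.
#' @param logit_normal apply the noise on the logit scale instead.
#' @return list of class \code{noise_model}.
#' @export
noise_model <- function(residual_sd = 0.03,
                        baseline_ranges = list(island = c(0.10, 0.30),
                                               shore = c(0.20, 0.60),
                                               non_CGI = c(0.50, 0.90)),
                        sex_sd = 0.01, batch_sd = 0.01, cellfrac_sd = 0.01,
                        logit_normal = FALSE) {
  if (residual_sd < 0) stopf("residual_sd must be >= 0")
  structure(list(residual_sd = residual_sd, baseline_ranges = baseline_ranges,
                 sex_sd = sex_sd, batch_sd = batch_sd,
                 cellfrac_sd = cellfrac_sd, logit_normal = logit_normal),
            class = "noise_model")
}

#' Simulate a multi-tissue methylation cohort
#'
#' For each tissue, draws ages uniformly within the design range, covariates
#' per the design (sex Bernoulli, batch uniform categorical, cell fractions
#' Dirichlet-like), and emits
#' \code{beta = clip(baseline + slope * age + covariate terms + noise, [0,1])}
#' with the per-(probe, tissue) slope from the effect map (0 for null probes).
#' Missing entries are inserted completely at random at the design rate,
#' capped so every probe keeps >= 90\% of its samples. Deterministic per
#' (seed, tissue label).
#'
#' @param genome a \code{synthetic_genome}.
#' @param effects an \code{effect_map} from \code{plant_effects} (or NULL for
#'   a null-only cohort).
#' @param design a \code{cohort_design} whose tissues are a subset of the
#'   genome's.
#' @param noise a \code{noise_model}.
#' @param seed integer seed.
#' @return named list of \code{methylation_dataset}, one per design tissue.
#' @export
simulate_cohort <- function(genome, effects = NULL, design, noise = noise_model(),
                            seed = 1, recoverable_baselines = TRUE) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(design, "cohort_design"))
  if (!all(design$tissue %in% genome$tissues))
    stopf("design tissue(s) not in genome: %s",
          paste(setdiff(design$tissue, genome$tissues), collapse = ", "))
  n_probes <- nrow(genome$probes)
  slopes <- if (is.null(effects)) {
    matrix(0, n_probes, nrow(design), dimnames = list(genome$probes$probe_id,
                                                      design$tissue))
  } else effects$slopes

  # baselines shared across tissues, drawn once from the CGI-class ranges
  set.seed(derive_seed(seed, "baseline"))
  cls <- as.character(classify_cgi(genome$probes, genome$cgi))
  baseline <- numeric(n_probes)
  for (cl in names(noise$baseline_ranges)) {
    i <- cls == cl
    rng <- noise$baseline_ranges[[cl]]
    baseline[i] <- stats::runif(sum(i), rng[1], rng[2])
  }

  # keep planted effects recoverable: clamp the baseline of each effect
  # probe so its linear ramp stays inside [0.05, 0.95] over the cohort's
  # age span (a gain probe starting near 1 would otherwise saturate at the
  # ceiling and lose its age signal to clipping); null probes untouched
  if (recoverable_baselines && !is.null(effects)) {
    S <- slopes[, design$tissue, drop = FALSE]
    pos <- pmax(S, 0); neg <- pmax(-S, 0)
    pos_reach <- apply(sweep(pos, 2, design$age_max, "*"), 1, max)
    neg_reach <- apply(sweep(neg, 2, design$age_max, "*"), 1, max)
    lo <- 0.05 + neg_reach
    hi <- pmax(0.95 - pos_reach, lo)
    baseline <- pmin(pmax(baseline, lo), hi)
  }

  out <- lapply(seq_len(nrow(design)), function(di) {
    d <- design[di, ]
    set.seed(derive_seed(seed, paste0("cohort:", d$tissue)))
    n <- d$n
    age <- stats::runif(n, d$age_min, d$age_max)
    meta <- data.frame(sample_id = sprintf("%s_S%04d", d$tissue, seq_len(n)),
                       age = age, stringsAsFactors = FALSE)
    mu <- baseline + slopes[, d$tissue, drop = TRUE] %o% age
    if (d$sex_prop > 0 && d$sex_prop < 1) {
      sex <- stats::rbinom(n, 1, d$sex_prop)
      meta$sex <- sex
      mu <- mu + stats::rnorm(n_probes, 0, noise$sex_sd) %o% sex
    } else {
      meta$sex <- as.integer(round(d$sex_prop))
    }
    if (d$n_batches > 1) {
      batch <- sample(seq_len(d$n_batches), n, replace = TRUE)
      meta$batch <- paste0("b", batch)
      beff <- matrix(stats::rnorm(n_probes * d$n_batches, 0, noise$batch_sd),
                     n_probes)
      beff[, 1] <- 0  # reference batch
      mu <- mu + beff[, batch]
    }
    if (d$n_cellfrac > 0) {
      g <- matrix(stats::rgamma(n * d$n_cellfrac, 2, 1), n)
      cf <- g / rowSums(g)
      colnames(cf) <- paste0("cf", seq_len(d$n_cellfrac))
      meta <- cbind(meta, as.data.frame(cf))
      ceff <- matrix(stats::rnorm(n_probes * d$n_cellfrac, 0,
                                  noise$cellfrac_sd), n_probes)
      mu <- mu + ceff %*% t(cf)
    }
    if (noise$logit_normal) {
      mu_c <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
      y <- stats::plogis(stats::qlogis(mu_c) +
                           matrix(stats::rnorm(n_probes * n, 0,
                                               noise$residual_sd * 4),
                                  n_probes))
    } else {
      y <- mu + matrix(stats::rnorm(n_probes * n, 0, noise$residual_sd),
                       n_probes)
    }
    y <- pmin(pmax(y, 0), 1)
    if (d$missing_rate > 0) {
      cap <- floor(0.10 * n)  # every probe keeps >= 90% of samples
      n_miss <- pmin(stats::rbinom(n_probes, n, d$missing_rate), cap)
      for (p in which(n_miss > 0)) {
        y[p, sample.int(n, n_miss[p])] <- NA_real_
      }
    }
    dimnames(y) <- list(genome$probes$probe_id, meta$sample_id)
    methylation_dataset(y, meta, d$tissue)
  })
  names(out) <- design$tissue
  out
}

#' Write a cohort's matrices and metadata to a directory
#' @param cohort named list of \code{methylation_dataset}.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(cohort)) {
    safe <- gsub("\\W", "_", t)
    write_beta_matrix(cohort[[t]]$betas,
                      file.path(dir, sprintf("betas_%s.tsv", safe)))
    write_metadata(cohort[[t]]$samples,
                   file.path(dir, sprintf("meta_%s.tsv", safe)))
  }
  invisible(dir)
}
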