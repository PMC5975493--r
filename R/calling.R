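# Per-tissue epigenome-wide age modelling. Each probe is fit by ordinary
# least squares, beta ~ intercept + age + covariates, age untransformed; the
# age coefficient's slope, SE and two-sided t-test P feed the dual
# effect-size / Bonferroni-significance criterion.

#' aDMP calling criteria
#'
#' The catalogue criterion: an aDMP must change by at least
#' \code{slope_threshold_pct_per_decade} percent per 10 years (gain positive,
#' loss negative) and reach Bonferroni significance \code{p_bonf_max}.
#' \code{mode = "effect_only"} drops the significance condition (the
#' power-control variant). The thresholds are inclusive by default;
#' \code{strict_inequality = TRUE} switches to strict comparison.
#'
#' @param slope_threshold_pct_per_decade effect-size cut-off in \%/10 years.
#' @param p_bonf_max Bonferroni-adjusted P cut-off.
#' @param mode "dual" or "effect_only".
#' @param strict_inequality use strict (>) rather than inclusive (>=)
#'   comparisons.
#' @return list of class \code{calling_criteria}.
#' @export
calling_criteria <- function(slope_threshold_pct_per_decade = 2.0,
                             p_bonf_max = 0.05,
                             mode = c("dual", "effect_only"),
                             strict_inequality = FALSE) {
  mode <- match.arg(mode)
  if (slope_threshold_pct_per_decade <= 0) stopf("slope threshold must be > 0")
  if (p_bonf_max <= 0 || p_bonf_max > 1) stopf("p_bonf_max must be in (0, 1]")
  structure(list(slope_threshold_pct_per_decade = slope_threshold_pct_per_decade,
                 p_bonf_max = p_bonf_max, mode = mode,
                 strict_inequality = strict_inequality),
            class = "calling_criteria")
}

#' Bonferroni adjustment
#'
#' @param p raw P value(s) in [0,1].
#' @param m number of tests (probes entering the family).
#' @return \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stopf("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p must be in [0,1]")
  pmin(1, p * m)
}

# Build the design matrix: intercept + age + encoded covariates.
# Characters/factors are reference-coded; a simplex block of cell-fraction
# columns (prefix "cf", rows summing to 1) drops its last column to keep the
# design full rank. Errors name the collinear column otherwise.
build_design <- function(age, covariates = NULL) {
  cols <- list(`(Intercept)` = rep(1, length(age)), age = as.numeric(age))
  if (!is.null(covariates) && ncol(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    cf_cols <- grep("^cf", names(covariates), value = TRUE)
    if (length(cf_cols) >= 2) {
      s <- rowSums(covariates[cf_cols])
      if (all(abs(s - 1) < 1e-6)) {
        covariates[[cf_cols[length(cf_cols)]]] <- NULL
        message(sprintf("cell-fraction columns sum to 1; dropped '%s'",
                        cf_cols[length(cf_cols)]))
      }
    }
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        cols[[nm]] <- as.numeric(v)
      } else {
        f <- factor(v)
        if (nlevels(f) < 2) stopf("covariate '%s' is constant", nm)
        for (lv in levels(f)[-1]) cols[[paste0(nm, lv)]] <- as.numeric(f == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix rank-deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  X
}

#' Fit the linear age model at a single probe
#'
#' OLS of beta values on age plus covariates; the reported slope, SE and
#' two-sided P (t distribution, n_used - k df) refer to the age coefficient.
#' Samples with missing beta are dropped (complete-case per probe). A fit
#' with zero residual variance reports se = 0 and p = 0 (p = 1 when the
#' slope is also exactly 0, as for a constant response). Probes retaining
#' fewer than (columns + 2) samples are untested (all-NA fit).
#'
#' @param beta_values numeric vector of betas (NA allowed).
#' @param ages numeric vector of ages in years.
#' @param covariates optional data.frame of covariate columns.
#' @return one-row data.frame: slope_per_year, slope_per_decade_pct, se, p,
#'   n_used.
#' @export
fit_age_model <- function(beta_values, ages, covariates = NULL) {
  X <- build_design(ages, covariates)
  fit <- fit_probe_matrix(matrix(beta_values, nrow = 1), X)
  fit
}

# Vectorised OLS over a probes x samples matrix against a fixed design.
# Fast path: probes with no missing values share one normal-equations solve;
# probes with missing entries are fit per-probe on their complete cases.
fit_probe_matrix <- function(Y, X) {
  n <- ncol(Y); k <- ncol(X)
  p <- nrow(Y)
  slope <- se <- pe <- rep(NA_real_, p)
  n_used <- integer(p)
  complete <- rowSums(is.na(Y)) == 0
  min_n <- k + 2
  n_used[complete] <- n

  if (any(complete) && n >= min_n) {
    XtXi <- chol2inv(chol(crossprod(X)))
    H <- tcrossprod(XtXi, X)               # k x n
    Yc <- Y[complete, , drop = FALSE]
    B <- Yc %*% t(H)                        # p x k coefficients
    resid <- Yc - tcrossprod(B, X)
    rss <- rowSums(resid^2)
    df <- n - k
    sigma2 <- rss / df
    s <- sqrt(sigma2 * XtXi[2, 2])
    b <- B[, 2]
    pv <- ifelse(s > 0, 2 * stats::pt(-abs(b / s), df),
                 ifelse(abs(b) > 0, 0, 1))
    # zero residual variance: se = 0, p = 0 (p = 1 for a constant response)
    zero <- sigma2 <= 1e-20
    s[zero] <- 0
    pv[zero] <- ifelse(abs(b[zero]) > 1e-12, 0, 1)
    slope[complete] <- b; se[complete] <- s; pe[complete] <- pv
    n_used[complete] <- n
  }

  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    m <- sum(ok)
    n_used[i] <- m
    if (m < min_n) next
    Xi <- X[ok, , drop = FALSE]
    qri <- qr(Xi)
    if (qri$rank < k) { n_used[i] <- m; next }  # degenerate subset: untested
    XtXi <- chol2inv(chol(crossprod(Xi)))
    b <- drop(XtXi %*% crossprod(Xi, Y[i, ok]))
    r <- Y[i, ok] - drop(Xi %*% b)
    df <- m - k
    sigma2 <- sum(r^2) / df
    s2 <- sqrt(sigma2 * XtXi[2, 2])
    slope[i] <- b[2]
    if (sigma2 <= 1e-20) {
      se[i] <- 0
      pe[i] <- if (abs(b[2]) > 1e-12) 0 else 1
    } else {
      se[i] <- s2
      pe[i] <- 2 * stats::pt(-abs(b[2] / s2), df)
    }
  }

  tested <- !is.na(slope)
  data.frame(slope_per_year = slope,
             slope_per_decade_pct = slope * 1000,
             se = se, p = pe, n_used = n_used, tested = tested)
}

#' Call age-related differentially methylated positions in one tissue
#'
#' The package's central fit: every probe is regressed on age (plus the
#' selected covariates) by OLS, P values are Bonferroni-adjusted over the
#' probes actually tested in this tissue, and each probe is classified as
#' gain / loss / none under the dual criterion (or by effect size alone in
#' \code{effect_only} mode). Probes whose complete-case sample count falls
#' below columns + 2 are "untested" and excluded from the Bonferroni family.
#' Samples with missing age or covariates are dropped globally (logged).
#'
#' @param dataset a \code{methylation_dataset}.
#' @param criteria a \code{calling_criteria}.
#' @param covariates character vector of metadata columns to adjust for
#'   (default none).
#' @return object of class \code{admp_calls}: list with \code{table}
#'   (probe_id, slope_per_year, slope_per_decade_pct, se, p, p_bonf, n_used,
#'   class), \code{tissue}, \code{m_tested}, \code{criteria},
#'   \code{n_samples}, \code{n_dropped_samples}.
#' @export
call_admps <- function(dataset, criteria = calling_criteria(),
                       covariates = character()) {
  stopifnot(inherits(dataset, "methylation_dataset"),
            inherits(criteria, "calling_criteria"))
  if (nrow(dataset$betas) == 0) stopf("empty dataset")
  meta <- dataset$samples
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov))
    stopf("covariate column(s) not in metadata: %s",
          paste(missing_cov, collapse = ", "))
  covs <- if (length(covariates)) meta[, covariates, drop = FALSE] else NULL
  keep <- !is.na(meta$age)
  if (!is.null(covs)) keep <- keep & stats::complete.cases(covs)
  dropped <- sum(!keep)
  if (dropped > 0) {
    log_stage("call", tissue = dataset$tissue,
              dropped_samples_missing_covariates = dropped)
    meta <- meta[keep, , drop = FALSE]
    covs <- if (is.null(covs)) NULL else covs[keep, , drop = FALSE]
  }
  Y <- dataset$betas[, keep, drop = FALSE]

  X <- build_design(meta$age, covs)
  fits <- fit_probe_matrix(Y, X)
  if (!any(fits$tested)) stopf("all probes untested in tissue %s", dataset$tissue)
  m_tested <- sum(fits$tested)
  fits$p_bonf <- ifelse(fits$tested, bonferroni(fits$p, m_tested), NA_real_)

  thr <- criteria$slope_threshold_pct_per_decade
  # inclusive comparison with a small numerical tolerance so a slope that is
  # exactly at the threshold up to floating point counts as at-threshold
  tol <- 1e-9
  ge <- if (criteria$strict_inequality) function(x, t) x > t + tol else
    function(x, t) x >= t - tol
  le <- if (criteria$strict_inequality) function(x, t) x < t - tol else
    function(x, t) x <= t + tol
  sig <- if (criteria$mode == "dual") {
    !is.na(fits$p_bonf) & fits$p_bonf <= criteria$p_bonf_max
  } else rep(TRUE, nrow(fits))
  cls <- rep("none", nrow(fits))
  cls[fits$tested & sig & ge(fits$slope_per_decade_pct, thr)] <- "gain"
  cls[fits$tested & sig & le(fits$slope_per_decade_pct, -thr)] <- "loss"
  cls[!fits$tested] <- "untested"

  tab <- data.frame(probe_id = rownames(dataset$betas),
                    fits[c("slope_per_year", "slope_per_decade_pct", "se",
                           "p", "p_bonf", "n_used")],
                    class = cls, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, tissue = dataset$tissue, m_tested = m_tested,
                 criteria = criteria, n_samples = nrow(meta),
                 n_dropped_samples = dropped),
            class = "admp_calls")
}

#' Subsample every tissue to an equal size
#'
#' The equal-N power control: draws \code{n} samples without replacement per
#' tissue, deterministically per (seed, tissue label), so calling on equally
#' sized datasets removes between-tissue power differences.
#'
#' @param datasets named list of \code{methylation_dataset}.
#' @param n target sample count (every tissue must have >= n).
#' @param seed integer seed.
#' @return named list of subsampled \code{methylation_dataset}.
#' @export
subsample_equal_n <- function(datasets, n, seed = 1) {
  lapply(datasets, function(d) {
    total <- ncol(d$betas)
    if (total < n) stopf("tissue '%s' has %d samples, fewer than n = %d",
                         d$tissue, total, n)
    set.seed(derive_seed(seed, paste0("subsample:", d$tissue)))
    idx <- sort(sample.int(total, n))
    methylation_dataset(d$betas[, idx, drop = FALSE],
                        d$samples[idx, , drop = FALSE], d$tissue)
  })
}
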