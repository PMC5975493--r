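#' @export
print.admp_calls <- function(x, ...) {
  cnt <- table(factor(x$table$class, c("gain", "loss", "none", "untested")))
  cat(sprintf("aDMP calls for '%s' (%d samples, %d probes tested, mode %s)\n",
              x$tissue, x$n_samples, x$m_tested, x$criteria$mode))
  cat(sprintf("  gain %d | loss %d | none %d | untested %d\n",
              cnt["gain"], cnt["loss"], cnt["none"], cnt["untested"]))
  cat(sprintf("  criteria: |slope| %s %.3g %%/10yr",
              if (x$criteria$strict_inequality) ">" else ">=",
              x$criteria$slope_threshold_pct_per_decade))
  if (x$criteria$mode == "dual")
    cat(sprintf(", P_bonf <= %.3g (m = %d)", x$criteria$p_bonf_max, x$m_tested))
  cat("\n")
  invisible(x)
}

#' @export
summary.admp_calls <- function(object, ...) {
  tab <- object$table
  called <- tab[tab$class %in% c("gain", "loss"), , drop = FALSE]
  out <- list(tissue = object$tissue,
              n_samples = object$n_samples,
              m_tested = object$m_tested,
              n_gain = sum(tab$class == "gain"),
              n_loss = sum(tab$class == "loss"),
              n_untested = sum(tab$class == "untested"),
              slope_quartiles = if (nrow(called))
                stats::quantile(called$slope_per_decade_pct,
                                c(0.25, 0.5, 0.75)) else NULL,
              criteria = object$criteria)
  class(out) <- "summary.admp_calls"
  out
}

#' @export
print.summary.admp_calls <- function(x, ...) {
  cat(sprintf("Tissue %s: %d gain-aDMPs, %d loss-aDMPs out of %d tested probes (n = %d samples)\n",
              x$tissue, x$n_gain, x$n_loss, x$m_tested, x$n_samples))
  if (x$n_untested) cat(sprintf("  %d probes untested\n", x$n_untested))
  if (!is.null(x$slope_quartiles)) {
    cat("  called-aDMP slope quartiles (%/10yr):",
        paste(sprintf("%.2f", x$slope_quartiles), collapse = " / "), "\n")
  }
  invisible(x)
}

#' Extract per-probe age slopes
#' @param object an \code{admp_calls} fit.
#' @param ... unused.
#' @return named numeric vector of slopes in beta units per year.
#' @export
coef.admp_calls <- function(object, ...) {
  stats::setNames(object$table$slope_per_year, object$table$probe_id)
}

#' Volcano plot of an epigenome-wide age fit
#'
#' Age slope (\%/10 years) against -log10 raw P, with called aDMPs
#' highlighted and the effect-size cut-offs drawn.
#'
#' @param x an \code{admp_calls} object.
#' @param ... passed to \code{plot}.
#' @export
plot.admp_calls <- function(x, ...) {
  tab <- x$table[x$table$class != "untested", ]
  lp <- -log10(pmax(tab$p, 1e-300))
  col <- ifelse(tab$class == "gain", "#2166ac",
                ifelse(tab$class == "loss", "#762a83", "grey60"))
  graphics::plot(tab$slope_per_decade_pct, lp, pch = 16, cex = 0.4, col = col,
                 xlab = "age slope (%/10 years)", ylab = "-log10 P",
                 main = sprintf("%s: %d gain / %d loss aDMPs", x$tissue,
                                sum(tab$class == "gain"),
                                sum(tab$class == "loss")), ...)
  thr <- x$criteria$slope_threshold_pct_per_decade
  graphics::abline(v = c(-thr, thr), lty = 2, col = "grey40")
  invisible(x)
}

#' @export
as.data.frame.admp_calls <- function(x, ...) x$table
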