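# Ground-truth age effects: which probes change with age, in which tissues,
# at what rate. Placement is annotation-biased the way the real catalogue is:
# gain effects favour polycomb-bound CpG islands (CGI & EZH2), loss effects
# favour enhancer-state non-CGI probes.

#' Configuration for planting age effects
#'
#' @param n_gain,n_loss numbers of gain / loss aDMPs to plant.
#' @param sharing_gain,sharing_loss length-3 proportions
#'   (tissue-specific, k-shared, universal) per direction; must sum to 1.
#'   Defaults mirror the sharing observed in the real seven-tissue catalogue
#'   (85.2\% of gain and 97.4\% of loss aDMPs in one tissue only, with a
#'   small universal gain class standing in for the ELOVL2-type CpGs).
#' @param slope_range magnitude range of planted slopes in \%/10 years.
#' @param gain_bias_or odds ratio with which gain effects prefer CGI & EZH2
#'   probes over all others.
#' @param loss_bias_or odds ratio with which loss effects prefer
#'   enhancer-state, non-CGI probes (state taken from the effect's home
#'   tissue's segmentation).
#' @param shared_k_range range of tissue counts for the k-shared class.
#' @return list of class \code{effect_design}.
#' @export
effect_design <- function(n_gain = 500, n_loss = 300,
                          sharing_gain = c(specific = 0.852, shared = 0.146,
                                           universal = 0.002),
                          sharing_loss = c(specific = 0.974, shared = 0.026,
                                           universal = 0),
                          slope_range = c(3, 8),
                          gain_bias_or = 5, loss_bias_or = 5,
                          shared_k_range = NULL) {
  for (s in list(sharing_gain, sharing_loss)) {
    if (length(s) != 3 || abs(sum(s) - 1) > 1e-8)
      stopf("sharing proportions must be length 3 and sum to 1")
  }
  if (any(slope_range <= 0) || slope_range[1] > slope_range[2])
    stopf("slope_range must be positive and increasing (%%/10yr)")
  structure(list(n_gain = n_gain, n_loss = n_loss,
                 sharing_gain = sharing_gain, sharing_loss = sharing_loss,
                 slope_range = slope_range, gain_bias_or = gain_bias_or,
                 loss_bias_or = loss_bias_or, shared_k_range = shared_k_range),
            class = "effect_design")
}

#' Plant ground-truth age effects into a synthetic genome
#'
#' Draws the requested numbers of gain and loss effects, assigns each a
#' sharing class (tissue-specific, k-shared or universal; class counts are
#' realized exactly by largest-remainder rounding, with at least one
#' universal effect whenever its proportion is positive), a slope magnitude
#' uniform in \code{slope_range} (\%/10yr), and a probe chosen by weighted
#' sampling without replacement: gain effects with odds \code{gain_bias_or}
#' for CGI & EZH2 probes, loss effects with odds \code{loss_bias_or} for
#' enhancer-state non-CGI probes of the effect's home tissue. A universal
#' effect carries the same nonzero slope (hence the same sign) in every
#' tissue; null probes have slope exactly 0.
#'
#' @param genome a \code{synthetic_genome}.
#' @param design an \code{effect_design}.
#' @param seed integer seed.
#' @return object of class \code{effect_map}: list with \code{slopes}
#'   (probes x tissues matrix, beta units per year), \code{effects}
#'   (one row per planted effect: probe_id, direction, sharing_class,
#'   tissues, n_tissues, slope_pct_per_decade) and \code{tissues}.
#' @export
plant_effects <- function(genome, design = effect_design(), seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  n_probes <- nrow(genome$probes)
  tissues <- genome$tissues
  T_ <- length(tissues)
  if (design$n_gain + design$n_loss > n_probes)
    stopf("requested %d effects but only %d probes",
          design$n_gain + design$n_loss, n_probes)
  set.seed(derive_seed(seed, "effects"))

  cgi_class <- classify_cgi(genome$probes, genome$cgi)
  is_cgi <- cgi_class == "island"
  is_ezh2 <- probe_ezh2_flag(genome$probes, genome$ezh2)
  gain_eligible <- is_cgi & is_ezh2
  if (design$gain_bias_or > 1 && !any(gain_eligible))
    stopf("gain placement bias impossible: no CGI & EZH2 probes")

  states <- vapply(tissues, function(t) {
    assign_state(genome$probes, genome$segmentations[[t]])
  }, character(n_probes))
  if (is.null(dim(states))) states <- matrix(states, nrow = n_probes,
                                             dimnames = list(NULL, tissues))

  shared_k_range <- design$shared_k_range %||% c(2, max(2, T_ - 1))

  assign_class <- function(n, sharing) {
    counts <- apportion(n, sharing)
    # guarantee a universal effect whenever the class has positive mass
    if (sharing[3] > 0 && counts[3] == 0 && counts[1] > 0) {
      counts[3] <- 1L; counts[1] <- counts[1] - 1L
    }
    rep(c("tissue-specific", "k-shared", "universal"), counts)
  }

  slopes <- matrix(0, n_probes, T_, dimnames = list(genome$probes$probe_id,
                                                    tissues))
  taken <- logical(n_probes)
  effects <- list()

  plant_direction <- function(direction, n, sharing, bias_or, eligible_fun) {
    if (n == 0) return(invisible())
    cls <- assign_class(n, sharing)
    # member tissues per effect (home tissue = first member)
    members <- lapply(cls, function(cl) {
      if (cl == "universal") return(tissues)
      if (cl == "tissue-specific") return(sample(tissues, 1))
      k <- if (shared_k_range[1] >= shared_k_range[2]) shared_k_range[1] else
        sample(seq(shared_k_range[1], min(shared_k_range[2], T_)), 1)
      sample(tissues, min(k, T_))
    })
    home <- vapply(members, `[`, character(1), 1)
    # place effects grouped by home tissue (loss eligibility is per-tissue)
    for (t in unique(home)) {
      idx_e <- which(home == t)
      avail <- which(!taken)
      elig <- eligible_fun(t)
      if (bias_or > 1 && !any(elig[avail]))
        stopf("%s placement bias impossible in tissue %s: no eligible probes",
              direction, t)
      w <- ifelse(elig[avail], bias_or, 1)
      if (length(avail) < length(idx_e))
        stopf("not enough free probes to place %d %s effects",
              length(idx_e), direction)
      picked <- avail[sample.int(length(avail), length(idx_e), prob = w)]
      taken[picked] <<- TRUE
      mag <- stats::runif(length(idx_e), design$slope_range[1],
                          design$slope_range[2])
      sgn <- if (direction == "gain") 1 else -1
      for (j in seq_along(idx_e)) {
        e <- idx_e[j]
        slope_year <- sgn * mag[j] / 1000  # %/10yr -> beta/yr
        slopes[picked[j], members[[e]]] <<- slope_year
        effects[[length(effects) + 1]] <<- data.frame(
          probe_id = genome$probes$probe_id[picked[j]],
          direction = direction, sharing_class = cls[e],
          tissues = paste(sort(members[[e]]), collapse = ","),
          n_tissues = length(members[[e]]),
          slope_pct_per_decade = sgn * mag[j],
          stringsAsFactors = FALSE)
      }
    }
  }

  plant_direction("gain", design$n_gain, design$sharing_gain,
                  design$gain_bias_or, function(t) gain_eligible)
  plant_direction("loss", design$n_loss, design$sharing_loss,
                  design$loss_bias_or,
                  function(t) states[, t] == "Enh" & cgi_class == "non_CGI")

  structure(list(slopes = slopes,
                 effects = if (length(effects)) do.call(rbind, effects) else
                   data.frame(),
                 tissues = tissues, design = design),
            class = "effect_map")
}

#' @export
print.effect_map <- function(x, ...) {
  e <- x$effects
  cat(sprintf("effect map: %d planted effects over %d probes x %d tissues\n",
              nrow(e), nrow(x$slopes), ncol(x$slopes)))
  if (nrow(e)) print(table(e$direction, e$sharing_class))
  invisible(x)
}

#' Write the ground-truth effect map as TSV
#' @param effects an \code{effect_map}.
#' @param path output TSV path.
#' @export
write_effect_map <- function(effects, path) {
  data.table::fwrite(effects$effects, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# EZH2 flag: probe overlaps any interval of the pooled EZH2 track.
probe_ezh2_flag <- function(probes, ezh2) {
  if (!nrow(ezh2)) return(rep(FALSE, nrow(probes)))
  IRanges::overlapsAny(probes_to_granges(probes), intervals_to_granges(ezh2))
}
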