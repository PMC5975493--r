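# Cross-tissue specificity: how many tissues each aDMP (and each CGI or
# gene harbouring aDMPs) was identified in, pairwise overlap matrices, and
# the relaxed-threshold robustness checks.

# Accept either admp_calls objects or plain tables with probe_id + class.
call_table <- function(x) {
  if (inherits(x, "admp_calls")) x$table else as.data.frame(x)
}

call_set <- function(x, direction) {
  tab <- call_table(x)
  tab$probe_id[tab$class == direction]
}

#' Build the direction-stratified specificity table
#'
#' For every probe called as \code{direction} in at least one tissue, the
#' set of tissues it was called in. Gain and loss are tabulated separately;
#' a probe called gain in one tissue and loss in another appears in both
#' directions' tables and is flagged \code{discordant}. Probes untested in
#' some tissue count as "not called" there.
#'
#' @param admp_tables named list (>= 2 tissues) of \code{admp_calls} or
#'   result tables sharing a probe universe.
#' @param direction "gain" or "loss".
#' @return object of class \code{specificity_table}: data.frame with
#'   probe_id, n_tissues, tissues (comma-joined, sorted), discordant;
#'   attributes \code{direction}, \code{tissue_names} and \code{membership}
#'   (logical probes x tissues matrix).
#' @export
build_specificity <- function(admp_tables, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (length(admp_tables) < 2) stopf("need >= 2 tissues")
  if (is.null(names(admp_tables)) || anyDuplicated(names(admp_tables)))
    stopf("admp_tables must be uniquely named by tissue")
  tissues <- names(admp_tables)
  sets <- lapply(admp_tables, call_set, direction = direction)
  other <- lapply(admp_tables, call_set,
                  direction = setdiff(c("gain", "loss"), direction))
  probes <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) probes %in% s, logical(length(probes)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(probes),
                         dimnames = list(NULL, tissues))
  rownames(membership) <- probes
  n_tissues <- rowSums(membership)
  tiss_str <- apply(membership, 1, function(r)
    paste(sort(tissues[r]), collapse = ","))
  discordant <- probes %in% unique(unlist(other, use.names = FALSE))
  df <- data.frame(probe_id = probes, n_tissues = as.integer(n_tissues),
                   tissues = if (length(probes)) tiss_str else character(),
                   discordant = discordant, stringsAsFactors = FALSE)
  structure(df, direction = direction, tissue_names = tissues,
            membership = membership,
            class = c("specificity_table", "data.frame"))
}

#' Percentage of aDMPs identified in exactly one tissue
#'
#' @param table a \code{specificity_table} (or any data.frame with an
#'   \code{n_tissues} column).
#' @param digits decimals for reporting (default 1; half-up rounding).
#' @return the rounded percentage; the unrounded value is attached as
#'   attribute \code{"raw"}.
#' @export
percent_tissue_specific <- function(table, digits = 1) {
  if (nrow(table) == 0) stopf("empty specificity table")
  raw <- 100 * sum(table$n_tissues == 1) / nrow(table)
  structure(round_half_up(raw, digits), raw = raw)
}

#' Sharing histogram: aDMP counts by number of tissues
#'
#' @param table a \code{specificity_table}.
#' @param n_tissues_total histogram width (defaults to the table's tissue
#'   panel size).
#' @return named integer vector over 1..T summing to \code{nrow(table)}.
#' @export
sharing_histogram <- function(table, n_tissues_total = NULL) {
  T_ <- n_tissues_total %||% length(attr(table, "tissue_names"))
  if (is.null(T_) || T_ < 1) T_ <- max(table$n_tissues)
  h <- tabulate(table$n_tissues, nbins = T_)
  stats::setNames(as.integer(h), seq_len(T_))
}

#' Pairwise overlap matrix of per-tissue aDMP sets
#'
#' Off-diagonal (i, j): aDMPs shared by tissues i and j. Diagonal i: aDMPs
#' unique to tissue i against all other tissues. The companion percentage
#' matrix holds diagonal / tissue total x 100 on its diagonal.
#'
#' @param admp_tables named list of \code{admp_calls} or tables.
#' @param direction "gain" or "loss".
#' @return object of class \code{overlap_matrix}: list(counts, percent,
#'   totals, direction).
#' @export
overlap_matrix <- function(admp_tables, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (length(admp_tables) < 2) stopf("need >= 2 tissues")
  tissues <- names(admp_tables)
  sets <- lapply(admp_tables, call_set, direction = direction)
  T_ <- length(tissues)
  M <- matrix(0L, T_, T_, dimnames = list(tissues, tissues))
  for (i in seq_len(T_)) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    M[i, i] <- sum(!(sets[[i]] %in% others))
    for (j in seq_len(T_)) {
      if (j != i) M[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  totals <- vapply(sets, length, integer(1))
  P <- matrix(NA_real_, T_, T_, dimnames = dimnames(M))
  diag(P) <- ifelse(totals > 0, 100 * diag(M) / totals, NA_real_)
  structure(list(counts = M, percent = P, totals = totals,
                 direction = direction), class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("%s-aDMP overlap (diagonal = unique to tissue):\n", x$direction))
  print(x$counts)
  cat("percent unique:\n")
  print(round(diag(x$percent), 1))
  invisible(x)
}

#' Relaxed-threshold cross-tissue significance check
#'
#' For each aDMP and each tissue where it was \emph{not} called, tests
#' whether its raw regression P falls below \code{p_relaxed} with a slope of
#' the direction-consistent sign. Pairs where the probe was untested or
#' absent in the other tissue are skipped and counted.
#'
#' @param admps a \code{specificity_table}.
#' @param all_fits named list of \code{admp_calls}/tables for all tissues.
#' @param p_relaxed relaxed raw-P cut-off (default 0.001, strict <).
#' @return list: \code{indicator} (logical probes x tissues matrix, NA for
#'   home tissues and skipped pairs), \code{fraction} (significant pairs /
#'   evaluated pairs), \code{n_pairs}, \code{n_skipped}.
#' @export
cross_tissue_significance <- function(admps, all_fits, p_relaxed = 0.001) {
  direction <- attr(admps, "direction")
  membership <- attr(admps, "membership")
  tissues <- names(all_fits)
  sgn <- if (direction == "gain") 1 else -1
  ind <- matrix(NA, nrow(admps), length(tissues),
                dimnames = list(admps$probe_id, tissues))
  skipped <- 0L
  for (t in tissues) {
    tab <- call_table(all_fits[[t]])
    idx <- match(admps$probe_id, tab$probe_id)
    home <- if (t %in% colnames(membership))
      membership[admps$probe_id, t] else rep(FALSE, nrow(admps))
    foreign <- which(!home)
    for (i in foreign) {
      j <- idx[i]
      if (is.na(j) || is.na(tab$p[j]) ||
          (!is.null(tab$class) && tab$class[j] == "untested")) {
        skipped <- skipped + 1L
        next
      }
      ind[i, t] <- tab$p[j] < p_relaxed && sign(tab$slope_per_year[j]) == sgn
    }
  }
  n_pairs <- sum(!is.na(ind))
  list(indicator = ind,
       fraction = if (n_pairs > 0) sum(ind, na.rm = TRUE) / n_pairs else NA_real_,
       n_pairs = n_pairs, n_skipped = skipped)
}

#' Cross-tissue slope matrix for an aDMP set
#'
#' Slopes (\%/10 years) of each aDMP in every tissue's fit, the data behind
#' cross-tissue slope heatmaps. Probes missing or untested in a tissue are
#' NA (flagged distinctly from a true 0 slope).
#'
#' @param admps a \code{specificity_table}.
#' @param all_fits named list of \code{admp_calls}/tables.
#' @return numeric matrix, rows = aDMP probes, columns = tissues.
#' @export
cross_tissue_slope_matrix <- function(admps, all_fits) {
  tissues <- names(all_fits)
  M <- matrix(NA_real_, nrow(admps), length(tissues),
              dimnames = list(admps$probe_id, tissues))
  for (t in tissues) {
    tab <- call_table(all_fits[[t]])
    j <- match(admps$probe_id, tab$probe_id)
    v <- tab$slope_per_decade_pct[j]
    if (!is.null(tab$class)) v[!is.na(j) & tab$class[j] == "untested"] <- NA_real_
    M[, t] <- v
  }
  M
}

#' Aggregate probe-level specificity to CGIs or genes
#'
#' A region's tissue set is the union of its member aDMP probes' tissue
#' sets; per-(region, tissue) counts tally member probes called in that
#' tissue. Probes without a mapping are excluded (logged count).
#'
#' @param admps a \code{specificity_table}.
#' @param mapping data.frame with columns \code{probe_id} and \code{unit}
#'   (CGI id or gene id).
#' @param unit_type label for the aggregation unit ("CGI" or "gene").
#' @return object of class \code{region_specificity}: list with \code{table}
#'   (unit, n_tissues, tissues), \code{counts} (units x tissues),
#'   \code{percent_unique}, \code{n_unmapped}, \code{unit_type}.
#' @export
aggregate_to_regions <- function(admps, mapping, unit_type = "region") {
  if (nrow(mapping) == 0) stopf("empty mapping")
  stopifnot(all(c("probe_id", "unit") %in% names(mapping)))
  membership <- attr(admps, "membership")
  tissues <- colnames(membership)
  unit <- mapping$unit[match(admps$probe_id, mapping$probe_id)]
  unmapped <- sum(is.na(unit))
  if (unmapped > 0)
    log_stage("aggregate", unit = unit_type, unmapped_probes = unmapped)
  keep <- !is.na(unit)
  if (!any(keep)) stopf("no aDMP probe has a %s mapping", unit_type)
  mm <- membership[admps$probe_id[keep], , drop = FALSE]
  counts <- rowsum(mm + 0L, group = unit[keep])
  sets <- rowsum(mm + 0L, group = unit[keep]) > 0
  n_tissues <- rowSums(sets)
  tab <- data.frame(unit = rownames(sets), n_tissues = as.integer(n_tissues),
                    tissues = apply(sets, 1, function(r)
                      paste(sort(tissues[r]), collapse = ",")),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  pu <- percent_tissue_specific(tab)
  structure(list(table = tab, counts = counts, percent_unique = pu,
                 n_unmapped = unmapped, unit_type = unit_type,
                 direction = attr(admps, "direction")),
            class = "region_specificity")
}

#' @export
print.region_specificity <- function(x, ...) {
  cat(sprintf("%s-level specificity (%s-aDMPs): %d units, %.1f%% unique to one tissue (%d probes unmapped)\n",
              x$unit_type, x$direction %||% "?", nrow(x$table),
              as.numeric(x$percent_unique), x$n_unmapped))
  invisible(x)
}

#' Overlap of an aDMP catalogue with an external CpG list
#'
#' Generic set overlap against a published CpG list; the percentage is
#' reported against both possible denominators (the catalogue size and the
#' external list size).
#'
#' @param admp_probes character vector of aDMP probe ids.
#' @param external character vector of external CpG ids.
#' @return list: n_overlap, n_admps, n_external, pct_of_admps,
#'   pct_of_external (half-up, 1 decimal).
#' @export
external_overlap <- function(admp_probes, external) {
  admp_probes <- unique(admp_probes)
  external <- unique(external)
  n <- length(intersect(admp_probes, external))
  list(n_overlap = n, n_admps = length(admp_probes),
       n_external = length(external),
       pct_of_admps = round_half_up(100 * n / length(admp_probes), 1),
       pct_of_external = round_half_up(100 * n / length(external), 1))
}
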