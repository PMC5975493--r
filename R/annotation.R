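# Genomic annotation of probes (CGI geometry, chromatin states, EZH2
# binding, nearest genes) and 2x2 enrichment statistics (odds ratio +
# 1-df Pearson chi-squared). Coordinates: BED inputs are 0-based half-open;
# probe manifest positions are 1-based (array convention). Interval overlap
# runs on GenomicRanges; linear-scan equivalents live in the test suite as
# independent oracles.

#' Classify probes as CpG island, shore, or non-CGI
#'
#' Inside a (merged) island interval: \code{island}; otherwise within
#' 2000 bp of an island edge (inclusive at exactly 2000 bp): \code{shore};
#' otherwise \code{non_CGI}. Probes on chromosomes absent from the island
#' set are non_CGI (logged).
#'
#' @param probes data.frame with chrom and pos (1-based) columns.
#' @param islands island intervals (data.frame chrom/start/end, 0-based
#'   half-open); overlapping islands are merged internally.
#' @param shore_bp shore width in bp (default 2000).
#' @return factor with levels island, shore, non_CGI, one per probe.
#' @export
classify_cgi <- function(probes, islands, shore_bp = 2000) {
  out <- factor(rep("non_CGI", nrow(probes)),
                levels = c("island", "shore", "non_CGI"))
  if (nrow(islands) == 0) return(out)
  ig <- GenomicRanges::reduce(intervals_to_granges(islands))
  pg <- probes_to_granges(probes)
  off_chrom <- !(probes$chrom %in% as.character(unique(
    GenomicRanges::seqnames(ig))))
  if (any(off_chrom))
    log_stage("classify_cgi", probes_on_chrom_without_islands = sum(off_chrom))
  # warnings about disjoint seqlevels are expected when some probe
  # chromosomes carry no islands; those probes are handled as non_CGI
  inside <- suppressWarnings(IRanges::overlapsAny(pg, ig))
  d <- suppressWarnings(GenomicRanges::distanceToNearest(pg, ig))
  gap <- rep(NA_real_, nrow(probes))
  gap[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  # distanceToNearest reports the inter-range gap: a probe one base past an
  # island edge has gap 0, so "within shore_bp of the edge" is gap <= shore_bp - 1
  shore <- !inside & !is.na(gap) & gap <= shore_bp - 1
  out[shore] <- "shore"
  out[inside] <- "island"
  out
}

#' Assign each probe its chromatin state
#'
#' Segmentations tile the genome with non-overlapping, half-open state
#' intervals; each probe takes the unique covering interval's label. A probe
#' at an interval boundary belongs to the interval beginning there.
#' Uncovered probes get \code{"unassigned"} (logged) and are excluded from
#' state enrichment.
#'
#' @param probes data.frame with chrom and pos (1-based).
#' @param segmentation data.frame chrom/start/end/name with state labels
#'   from \code{chromatin_states()}.
#' @return character vector of state labels per probe.
#' @export
assign_state <- function(probes, segmentation) {
  bad <- setdiff(unique(segmentation$name), chromatin_states())
  if (length(bad))
    stopf("segmentation uses unknown state label(s): %s",
          paste(bad, collapse = ", "))
  pg <- probes_to_granges(probes)
  sg <- intervals_to_granges(segmentation)
  hits <- GenomicRanges::findOverlaps(pg, sg)
  out <- rep("unassigned", nrow(probes))
  qh <- S4Vectors::queryHits(hits)
  if (anyDuplicated(qh)) {
    warning("overlapping segmentation intervals; first hit used")
    keep <- !duplicated(qh)
    out[qh[keep]] <- segmentation$name[S4Vectors::subjectHits(hits)[keep]]
  } else {
    out[qh] <- segmentation$name[S4Vectors::subjectHits(hits)]
  }
  if (any(out == "unassigned"))
    log_stage("assign_state", uncovered_probes = sum(out == "unassigned"))
  out
}

#' 2x2 enrichment test (odds ratio + chi-squared)
#'
#' Enrichment of a probe category within an aDMP set against the
#' tested-probe background: cells a (aDMP & in category), b (aDMP & out),
#' c (background-only & in), d (background-only & out). Odds ratio
#' (a d)/(b c) with the Haldane-Anscombe +0.5 applied to all cells only when
#' some cell is zero; chi-squared is the 1-df Pearson statistic on the raw
#' counts, no continuity correction, with the upper-tail P. A category empty
#' or universal in the background is flagged degenerate.
#'
#' @param admp_probes character vector of aDMP probe ids (subset of
#'   background).
#' @param background character vector of all tested probe ids.
#' @param in_category logical vector along \code{background}, or a character
#'   vector of category probe ids.
#' @param category label for the result row.
#' @param alpha significance level for the flag.
#' @param m_tests Bonferroni factor applied before flagging (default 1).
#' @return one-row data.frame of class \code{enrichment_result}: category,
#'   a, b, c, d, odds_ratio, chi2, p, p_adj, significant, degenerate.
#' @export
enrichment_test <- function(admp_probes, background, in_category,
                            category = "category", alpha = 0.05,
                            m_tests = 1) {
  if (length(background) < 4) stopf("background must have >= 4 probes")
  if (anyDuplicated(background)) background <- unique(background)
  admp_probes <- unique(admp_probes)
  if (!all(admp_probes %in% background))
    stopf("admp_probes must be a subset of the background")
  if (is.character(in_category)) in_category <- background %in% in_category
  if (length(in_category) != length(background))
    stopf("in_category must align with background")
  is_admp <- background %in% admp_probes
  a <- sum(is_admp & in_category)
  b <- sum(is_admp & !in_category)
  c_ <- sum(!is_admp & in_category)
  d <- sum(!is_admp & !in_category)
  enrichment_from_counts(a, b, c_, d, category, alpha, m_tests)
}

# Core contingency computation shared by all enrichment entry points.
enrichment_from_counts <- function(a, b, c_, d, category = "category",
                                   alpha = 0.05, m_tests = 1) {
  a <- as.double(a); b <- as.double(b); c_ <- as.double(c_); d <- as.double(d)
  n <- a + b + c_ + d
  degenerate <- (a + c_) == 0 || (b + d) == 0 || (a + b) == 0 || (c_ + d) == 0
  if (any(c(a, b, c_, d) == 0)) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c_ + 0.5; dd <- d + 0.5
  } else {
    aa <- a; bb <- b; cc <- c_; dd <- d
  }
  or <- (aa * dd) / (bb * cc)
  if (degenerate) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    chi2 <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  p_adj <- if (is.na(p)) NA_real_ else min(1, p * m_tests)
  res <- data.frame(category = category, a = a, b = b, c = c_, d = d,
                    odds_ratio = or, chi2 = chi2, p = p, p_adj = p_adj,
                    significant = !degenerate && !is.na(p_adj) && p_adj <= alpha,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Chromatin-state enrichment profile for one tissue's aDMPs
#'
#' One enrichment test per 15-state label: category = tested probes in that
#' state, aDMP set = probes called in the requested direction, background =
#' all tested probes with an assigned state. Significance flags are
#' Bonferroni-corrected within the profile (15 tests); raw P is always
#' reported.
#'
#' @param calls an \code{admp_calls} object (or table).
#' @param direction "gain" or "loss".
#' @param states character vector of state labels along the calls table's
#'   probes (from \code{assign_state} with the tissue-matched segmentation).
#' @param alpha significance level after correction.
#' @return data.frame with one \code{enrichment_result} row per state.
#' @export
state_enrichment_profile <- function(calls, direction = c("gain", "loss"),
                                     states, alpha = 0.05) {
  direction <- match.arg(direction)
  tab <- call_table(calls)
  if (length(states) != nrow(tab))
    stopf("states must align with the calls table")
  tested <- tab$class != "untested" & states != "unassigned"
  if (sum(states == "unassigned" & tab$class != "untested") > 0)
    log_stage("state_enrichment",
              excluded_unassigned = sum(states == "unassigned"))
  bg <- tab$probe_id[tested]
  st <- states[tested]
  admps <- tab$probe_id[tested & tab$class == direction]
  res <- do.call(rbind, lapply(chromatin_states(), function(s) {
    enrichment_test(admps, bg, st == s, category = s, alpha = alpha,
                    m_tests = length(chromatin_states()))
  }))
  if (length(admps) == 0) attr(res, "empty_admp_set") <- TRUE
  res
}

#' CGI-class enrichment profile (island / shore / non-CGI)
#'
#' @inheritParams state_enrichment_profile
#' @param cgi_class factor from \code{classify_cgi} along the calls table.
#' @return data.frame with one row per CGI class (Bonferroni over 3 tests).
#' @export
cgi_enrichment_profile <- function(calls, direction = c("gain", "loss"),
                                   cgi_class, alpha = 0.05) {
  direction <- match.arg(direction)
  tab <- call_table(calls)
  tested <- tab$class != "untested"
  bg <- tab$probe_id[tested]
  cl <- as.character(cgi_class)[tested]
  admps <- tab$probe_id[tested & tab$class == direction]
  do.call(rbind, lapply(levels(factor(cl, c("island", "shore", "non_CGI"))),
                        function(s) {
    enrichment_test(admps, bg, cl == s, category = s, alpha = alpha,
                    m_tests = 3)
  }))
}

#' Joint CGI x EZH2 enrichment
#'
#' Restricts the background to probes carrying at least one of the two
#' annotations and tests whether aDMPs concentrate at probes with both,
#' compared against the CGI-only stratum, the EZH2-only stratum, and their
#' union.
#'
#' @param admp_probes character vector of aDMP probe ids.
#' @param background character vector of tested probe ids.
#' @param cgi_class factor/character along background ("island" marks CGI).
#' @param ezh2 logical along background.
#' @param alpha significance level.
#' @return data.frame with rows "both_vs_cgi_only", "both_vs_ezh2_only",
#'   "both_vs_single".
#' @export
cgi_ezh2_joint_enrichment <- function(admp_probes, background, cgi_class,
                                      ezh2, alpha = 0.05) {
  stopifnot(length(cgi_class) == length(background),
            length(ezh2) == length(background))
  is_cgi <- as.character(cgi_class) == "island"
  both <- is_cgi & ezh2
  strata <- list(both_vs_cgi_only = is_cgi & !ezh2,
                 both_vs_ezh2_only = !is_cgi & ezh2,
                 both_vs_single = xor(is_cgi, ezh2))
  res <- lapply(names(strata), function(nm) {
    keep <- both | strata[[nm]]
    if (!any(strata[[nm]]) || !any(both)) {
      r <- enrichment_from_counts(0, 0, 0, 0, category = nm, alpha = alpha)
      r$degenerate <- TRUE
      return(r)
    }
    enrichment_test(intersect(admp_probes, background[keep]),
                    background[keep], both[keep], category = nm,
                    alpha = alpha)
  })
  do.call(rbind, res)
}

#' Nearest gene for each probe
#'
#' Distance from a probe to a gene is the smaller of the distances to the
#' gene's two ends (5' and 3', defined strand-aware); a probe inside a gene
#' body is still measured to the nearer end. The gene minimising this
#' distance is assigned; ties break by smaller distance, then lexicographic
#' gene id. Probes on chromosomes without genes are unmapped (NA).
#'
#' @param probes data.frame with probe_id, chrom, pos (1-based).
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open), strand.
#' @return data.frame: probe_id, gene_id, distance (bp; NA when unmapped).
#' @export
nearest_gene <- function(probes, genes) {
  out <- data.frame(probe_id = probes$probe_id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(probes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(probes$chrom == ch)
    if (!length(gi)) next
    pos0 <- probes$pos[pi] - 1
    # strand-aware ends: + gene 5' = start, 3' = end - 1; - gene reversed.
    # The min over both ends is strand-symmetric.
    e1 <- genes$start[gi]
    e2 <- genes$end[gi] - 1
    D <- pmin(abs(outer(pos0, e1, "-")), abs(outer(pos0, e2, "-")))
    ids <- genes$gene_id[gi]
    best <- vapply(seq_along(pi), function(r) {
      dmin <- min(D[r, ])
      cand <- ids[D[r, ] == dmin]
      c(sort(cand)[1], dmin)
    }, c("", ""))
    out$gene_id[pi] <- best[1, ]
    out$distance[pi] <- as.numeric(best[2, ])
  }
  if (anyNA(out$gene_id))
    log_stage("nearest_gene", unmapped_probes = sum(is.na(out$gene_id)))
  out
}

#' Full per-probe annotation table for a synthetic genome
#'
#' CGI class, EZH2 flag, per-tissue chromatin state, CGI id (merged island
#' interval containing/near the probe, for region-level aggregation) and
#' nearest gene.
#'
#' @param genome a \code{synthetic_genome}.
#' @return data.frame: probe_id, chrom, pos, cgi_class, cgi_id (NA outside
#'   islands), ezh2, state_<tissue> columns, nearest_gene, gene_distance.
#' @export
annotate_probes <- function(genome) {
  probes <- genome$probes
  ann <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    pos = probes$pos, stringsAsFactors = FALSE)
  ann$cgi_class <- classify_cgi(probes, genome$cgi)
  ann$cgi_id <- cgi_membership(probes, genome$cgi)
  ann$ezh2 <- probe_ezh2_flag(probes, genome$ezh2)
  for (t in genome$tissues) {
    ann[[paste0("state_", t)]] <- assign_state(probes,
                                               genome$segmentations[[t]])
  }
  ng <- nearest_gene(probes, genome$genes)
  ann$nearest_gene <- ng$gene_id
  ann$gene_distance <- ng$distance
  ann
}

# Island id ("chrom:start-end" of the merged island) for probes inside one.
cgi_membership <- function(probes, islands) {
  out <- rep(NA_character_, nrow(probes))
  if (!nrow(islands)) return(out)
  red <- merge_intervals(islands)
  hits <- GenomicRanges::findOverlaps(probes_to_granges(probes),
                                      intervals_to_granges(red))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out[qh] <- sprintf("%s:%d-%d", red$chrom[sh], red$start[sh], red$end[sh])
  out
}
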