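# Synthetic annotation universe: a scaled-down 450k-like probe manifest with
# CpG islands, a pooled EZH2 binding track, per-tissue 15-state chromatin
# segmentations and gene models. Everything downstream (calling, specificity,
# enrichment) is exercised against these structures with known ground truth.

#' The Roadmap 15-state chromatin vocabulary
#'
#' Fixed label set used by all segmentations: active TSS through quiescent.
#' @export
chromatin_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF/Rpts",
    "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

# Genome-wide state frequencies used when sampling segment labels; weighted
# towards Quies/TxWk as in real somatic segmentations, with enough Enh and
# ReprPC mass that enrichment analyses have workable category sizes.
default_state_probs <- function() {
  p <- c(TssA = 0.04, TssAFlnk = 0.03, TxFlnk = 0.02, Tx = 0.06, TxWk = 0.10,
         EnhG = 0.03, Enh = 0.08, `ZNF/Rpts` = 0.02, Het = 0.05, TssBiv = 0.03,
         BivFlnk = 0.02, EnhBiv = 0.04, ReprPC = 0.08, ReprPCWk = 0.07,
         Quies = 0.33)
  stopifnot(abs(sum(p) - 1) < 1e-12)
  p
}

#' Generate a synthetic annotated genome
#'
#' Builds the full annotation universe for a simulated multi-tissue study:
#' probe manifest (strictly increasing positions per chromosome), CpG-island
#' intervals covering a configurable probe fraction (default 0.30, mimicking
#' the array's CGI bias), an EZH2 binding track enriched at CGIs, one
#' 15-state segmentation per tissue that tiles every chromosome (every probe
#' covered by exactly one state interval), and gene models with strand.
#'
#' Island membership is planted in runs of neighbouring probes, as CGIs carry
#' several array probes each; probe gaps are kept >= 60 bp so island/EZH2
#' interval padding never swallows a neighbouring probe.
#'
#' @param n_probes number of probes (>= 100).
#' @param n_genes number of gene models (>= 2).
#' @param tissues character vector of distinct tissue labels.
#' @param seed integer seed; the same seed yields a byte-identical genome.
#' @param cgi_fraction target fraction of probes inside CpG islands.
#' @param ezh2_odds odds multiplier for EZH2 binding at CGI probes relative to
#'   non-CGI probes (chance = 1).
#' @param ezh2_base_prob EZH2 binding probability for a non-CGI probe.
#' @param n_chrom number of chromosomes the probes are spread over.
#' @param mean_gap mean inter-probe spacing in bp (minimum gap 60 bp).
#' @param state_probs named probabilities over \code{chromatin_states()}.
#' @return an object of class \code{synthetic_genome}: list with elements
#'   \code{probes} (probe_id, chrom, pos; 1-based positions),
#'   \code{cgi}, \code{ezh2} (0-based half-open intervals),
#'   \code{segmentations} (per-tissue interval tables with \code{state}),
#'   \code{genes} and \code{tissues}.
#' @export
generate_genome <- function(n_probes, n_genes, tissues, seed,
                            cgi_fraction = 0.30, ezh2_odds = 4,
                            ezh2_base_prob = 0.15,
                            n_chrom = 4, mean_gap = 3000,
                            state_probs = default_state_probs()) {
  if (n_probes < 100) stopf("n_probes must be >= 100 (got %s)", n_probes)
  if (n_genes < 2) stopf("n_genes must be >= 2 (got %s)", n_genes)
  if (anyDuplicated(tissues)) stopf("duplicate tissue labels")
  if (length(tissues) < 1) stopf("need at least one tissue")
  if (cgi_fraction <= 0 || cgi_fraction >= 1) stopf("cgi_fraction in (0,1)")
  stopifnot(setequal(names(state_probs), chromatin_states()))
  set.seed(derive_seed(seed, "genome"))

  # probe manifest: n_chrom chromosomes, strictly increasing 1-based positions
  chrom_labels <- paste0("chr", seq_len(n_chrom))
  n_per <- apportion(n_probes, rep(1 / n_chrom, n_chrom))
  probes <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    gaps <- 60 + round(stats::rexp(n_per[ci], 1 / max(1, mean_gap - 60)))
    data.frame(chrom = chrom_labels[ci],
               pos = 1000 + cumsum(gaps),
               stringsAsFactors = FALSE)
  }))
  probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos")]

  # island membership in runs of consecutive probes; trimmed to the exact
  # target count so the realized fraction equals the configuration
  target <- round(cgi_fraction * n_probes)
  in_cgi <- logical(n_probes)
  while (sum(in_cgi) < target) {
    i <- sample.int(n_probes, 1)
    len <- sample(2:8, 1)
    idx <- i:min(n_probes, i + len - 1)
    idx <- idx[probes$chrom[idx] == probes$chrom[i]]
    in_cgi[idx] <- TRUE
  }
  excess <- sum(in_cgi) - target
  if (excess > 0) in_cgi[utils::tail(which(in_cgi), excess)] <- FALSE
  cgi <- runs_to_intervals(probes, in_cgi, pad = 25)

  # EZH2 binding: per-probe Bernoulli with odds tilted towards CGI probes
  odds0 <- ezh2_base_prob / (1 - ezh2_base_prob)
  p1 <- (odds0 * ezh2_odds) / (1 + odds0 * ezh2_odds)
  p_ezh2 <- ifelse(in_cgi, p1, ezh2_base_prob)
  is_ezh2 <- stats::runif(n_probes) < p_ezh2
  ezh2 <- runs_to_intervals(probes, is_ezh2, pad = 25)

  # per-tissue segmentations: tile each chromosome fully, breakpoints at
  # inter-probe midpoints, iid state labels per segment
  chrom_ends <- tapply(probes$pos, probes$chrom, max) + 1000
  segmentations <- lapply(tissues, function(t) {
    segs <- lapply(chrom_labels, function(ch) {
      pos <- probes$pos[probes$chrom == ch]
      mids <- floor((pos[-length(pos)] + pos[-1]) / 2)
      brk <- mids[stats::runif(length(mids)) < 0.3]
      bounds <- c(0, brk, chrom_ends[[ch]])
      data.frame(chrom = ch,
                 start = bounds[-length(bounds)],
                 end = bounds[-1],
                 name = sample(names(state_probs), length(bounds) - 1,
                               replace = TRUE, prob = state_probs),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, segs)
  })
  names(segmentations) <- tissues

  # gene models
  g_chrom <- sample(chrom_labels, n_genes, replace = TRUE)
  g_len <- round(stats::runif(n_genes, 5e3, 1e5))
  g_start <- vapply(seq_len(n_genes), function(i) {
    round(stats::runif(1, 0, max(1, chrom_ends[[g_chrom[i]]] - g_len[i])))
  }, numeric(1))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = g_chrom, start = g_start,
                      end = g_start + g_len,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)

  structure(list(probes = probes, cgi = cgi, ezh2 = ezh2,
                 segmentations = segmentations, genes = genes,
                 tissues = tissues,
                 params = list(cgi_fraction = cgi_fraction,
                               ezh2_odds = ezh2_odds, seed = seed)),
            class = "synthetic_genome")
}

# Convert runs of flagged consecutive probes into padded half-open intervals.
runs_to_intervals <- function(probes, flag, pad = 25) {
  out <- list()
  r <- rle(paste0(probes$chrom, "_", flag))
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  keep <- flag[starts]
  for (k in which(keep)) {
    i <- starts[k]; j <- stops[k]
    out[[length(out) + 1]] <- data.frame(
      chrom = probes$chrom[i],
      start = max(0, probes$pos[i] - 1 - pad),
      end = probes$pos[j] - 1 + pad + 1,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, method = "radix"), , drop = FALSE]
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d probes on %d chromosomes, %d genes, %d tissues\n",
              nrow(x$probes), length(unique(x$probes$chrom)),
              nrow(x$genes), length(x$tissues)))
  cat(sprintf("  CGI intervals: %d; EZH2 intervals: %d; states per segmentation: %s\n",
              nrow(x$cgi), nrow(x$ezh2),
              paste(range(vapply(x$segmentations, nrow, integer(1))),
                    collapse = "-")))
  invisible(x)
}

#' Write a synthetic genome's annotation files
#'
#' Emits the manifest TSV, CGI/EZH2 BEDs, per-tissue segmentation BEDs (state
#' label in the name column) and gene-model BED into \code{dir}.
#'
#' @param genome a \code{synthetic_genome}.
#' @param dir output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(genome$probes, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE)
  write_bed(genome$cgi, file.path(dir, "cgi.bed"))
  write_bed(genome$ezh2, file.path(dir, "ezh2.bed"))
  for (t in genome$tissues) {
    write_bed(genome$segmentations[[t]],
              file.path(dir, sprintf("segmentation_%s.bed", gsub("\\W", "_", t))))
  }
  g <- genome$genes
  write_bed(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       name = g$gene_id, strand = g$strand),
            file.path(dir, "genes.bed"))
  invisible(dir)
}
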