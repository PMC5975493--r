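# Shared fixtures and independent oracles. The oracles deliberately use
# nothing from the implementation paths they check: explicit normal
# equations for OLS, linear scans for interval queries, plain set
# operations for overlaps.

tiny_genome <- function(n_probes = 600, n_genes = 20,
                        tissues = c("brain", "liver", "kidney"), seed = 11) {
  generate_genome(n_probes, n_genes, tissues, seed = seed)
}

tiny_design <- function(tissues = c("brain", "liver", "kidney"),
                        n = 60, age_min = 20, age_max = 80, ...) {
  cohort_design(tissue = tissues, n = n, age_min = age_min,
                age_max = age_max, ...)
}

# Brute-force OLS on the age coefficient: explicit normal equations plus the
# t survival function. Complete-case on y.
ols_oracle <- function(y, age, covars = NULL) {
  ok <- !is.na(y)
  X <- cbind(1, age)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  b <- XtXinv %*% t(X) %*% y
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  tt <- b[2] / se
  list(slope = b[2], se = se, p = 2 * pt(-abs(tt), df), n = length(y))
}

# Linear-scan CGI classifier (merged islands assumed non-overlapping).
scan_cgi_oracle <- function(probes, islands, shore_bp = 2000) {
  vapply(seq_len(nrow(probes)), function(i) {
    pos0 <- probes$pos[i] - 1
    isl <- islands[islands$chrom == probes$chrom[i], , drop = FALSE]
    if (!nrow(isl)) return("non_CGI")
    inside <- any(pos0 >= isl$start & pos0 < isl$end)
    if (inside) return("island")
    gaps <- pmax(isl$start - pos0, pos0 - (isl$end - 1))
    if (min(gaps) <= shore_bp) "shore" else "non_CGI"
  }, character(1))
}

# Exhaustive all-pairs nearest-gene oracle (min distance to either end,
# ties by distance then lexicographic gene id).
scan_nearest_gene_oracle <- function(probes, genes) {
  t(vapply(seq_len(nrow(probes)), function(i) {
    g <- genes[genes$chrom == probes$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(c(NA_character_, NA_character_))
    pos0 <- probes$pos[i] - 1
    d <- pmin(abs(pos0 - g$start), abs(pos0 - (g$end - 1)))
    dmin <- min(d)
    c(sort(g$gene_id[d == dmin])[1], as.character(dmin))
  }, c("", "")))
}

# Per-probe state lookup by linear scan over segmentation rows.
scan_state_oracle <- function(probes, seg) {
  vapply(seq_len(nrow(probes)), function(i) {
    pos0 <- probes$pos[i] - 1
    hit <- which(seg$chrom == probes$chrom[i] & seg$start <= pos0 &
                   pos0 < seg$end)
    if (length(hit)) seg$name[hit[1]] else "unassigned"
  }, character(1))
}

# Minimal admp-calls-like table for set-level machinery tests.
fake_calls <- function(gain = character(), loss = character(),
                       universe = NULL) {
  universe <- universe %||% unique(c(gain, loss))
  extra <- setdiff(universe, c(gain, loss))
  data.frame(probe_id = c(gain, loss, extra),
             slope_per_year = c(rep(0.003, length(gain)),
                                rep(-0.003, length(loss)),
                                rep(0, length(extra))),
             slope_per_decade_pct = c(rep(3, length(gain)),
                                      rep(-3, length(loss)),
                                      rep(0, length(extra))),
             se = 1e-4, p = 1e-10, p_bonf = 1e-6,
             n_used = 100,
             class = c(rep("gain", length(gain)), rep("loss", length(loss)),
                       rep("none", length(extra))),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
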