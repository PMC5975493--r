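test_that("CGI classification respects the 2-kb shore geometry", {
  islands <- data.frame(chrom = "chr1", start = 10000, end = 10500)
  probes <- data.frame(
    probe_id = paste0("p", 1:6), chrom = "chr1",
    # 1-based positions: inside, start-1500, end+1, end+2000, end+2001, far
    pos = c(10250, 10001 - 1500, 10501, 10500 + 2000, 10500 + 2001, 50000),
    stringsAsFactors = FALSE)
  cls <- classify_cgi(probes, islands)
  expect_equal(as.character(cls),
               c("island", "shore", "shore", "shore", "non_CGI", "non_CGI"))
  # probe on a chromosome with no islands -> non_CGI
  p2 <- data.frame(probe_id = "q", chrom = "chrX", pos = 100)
  expect_equal(as.character(classify_cgi(p2, islands)), "non_CGI")
})

test_that("CGI classes match a brute-force linear scan on random input", {
  set.seed(17)
  n <- 10000
  probes <- data.frame(probe_id = sprintf("p%05d", 1:n),
                       chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                       pos = sample.int(2e6, n, replace = TRUE),
                       stringsAsFactors = FALSE)
  isl <- do.call(rbind, lapply(paste0("chr", 1:3), function(ch) {
    s <- sort(sample.int(2e6, 60))
    data.frame(chrom = ch, start = s, end = s + sample(200:2000, 60,
                                                       replace = TRUE))
  }))
  merged <- admpatlas:::merge_intervals(isl)
  expect_equal(as.character(classify_cgi(probes, isl)),
               scan_cgi_oracle(probes, merged))
})

test_that("state assignment is half-open at boundaries and complete", {
  seg <- data.frame(chrom = "chr1", start = c(0, 1000, 5000),
                    end = c(1000, 5000, 9000),
                    name = c("TssA", "Enh", "Quies"),
                    stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1",
                       # 1-based pos 1001 = 0-based 1000: starts the Enh interval
                       pos = c(500, 1001, 5001, 9500),
                       stringsAsFactors = FALSE)
  st <- assign_state(probes, seg)
  expect_equal(st, c("TssA", "Enh", "Quies", "unassigned"))
  expect_error(assign_state(probes, transform(seg, name = "NotAState")),
               "unknown state")

  g <- tiny_genome(n_probes = 400, seed = 43)
  for (t in g$tissues) {
    st <- assign_state(g$probes, g$segmentations[[t]])
    expect_true(all(st %in% chromatin_states()))  # full coverage, no gaps
    expect_equal(st, scan_state_oracle(g$probes, g$segmentations[[t]]))
  }
})

test_that("enrichment test reproduces the worked 2x2 example", {
  bg <- sprintf("p%03d", 1:200)
  cat30 <- c(bg[1:30], bg[101:110])       # a = 30, c = 10
  admps <- bg[1:100]                      # a+b = 100
  res <- enrichment_test(admps, bg, cat30)
  expect_equal(res$a, 30); expect_equal(res$b, 70)
  expect_equal(res$c, 10); expect_equal(res$d, 90)
  expect_equal(res$odds_ratio, 27 / 7, tolerance = 1e-12)
  expect_equal(res$chi2, 12.5, tolerance = 1e-12)
  expect_equal(res$p, 4.07e-4, tolerance = 1e-2)
})

test_that("enrichment test invariances and zero-cell handling", {
  # equal proportions -> OR 1, chi2 0
  null <- admpatlas:::enrichment_from_counts(20, 80, 40, 160)
  expect_equal(null$odds_ratio, 1)
  expect_equal(null$chi2, 0)
  # simultaneous row+column swap leaves OR and chi2 unchanged
  r1 <- admpatlas:::enrichment_from_counts(12, 34, 56, 78)
  r2 <- admpatlas:::enrichment_from_counts(78, 56, 34, 12)
  expect_equal(r1$odds_ratio, r2$odds_ratio)
  expect_equal(r1$chi2, r2$chi2)
  # column swap inverts OR
  r3 <- admpatlas:::enrichment_from_counts(34, 12, 78, 56)
  expect_equal(r3$odds_ratio, 1 / r1$odds_ratio)
  # zero cell: Haldane-Anscombe on OR, chi2 still from raw counts
  z <- admpatlas:::enrichment_from_counts(0, 50, 25, 125)
  expect_equal(z$odds_ratio, (0.5 * 125.5) / (50.5 * 25.5))
  expect_false(z$degenerate)
  # empty category is degenerate
  dg <- admpatlas:::enrichment_from_counts(0, 50, 0, 150)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
  expect_error(enrichment_test("p1", c("p1", "p2"), c(TRUE, FALSE)),
               ">= 4")
})

test_that("enrichment equals direct contingency computation on random tables", {
  set.seed(23)
  for (i in 1:200) {
    cells <- as.double(rpois(4, lambda = sample(c(2, 20, 200), 4,
                                                replace = TRUE)))
    r <- admpatlas:::enrichment_from_counts(cells[1], cells[2], cells[3],
                                            cells[4])
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    if (any(cells == 0)) {
      expect_equal(r$odds_ratio,
                   ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
    } else {
      expect_equal(r$odds_ratio, (a * d) / (b * c_))
    }
    if (!r$degenerate) {
      n <- sum(cells)
      chi2 <- n * (a * d - b * c_)^2 /
        ((a + b) * (c_ + d) * (a + c_) * (b + d))
      expect_equal(r$chi2, chi2)
      expect_equal(r$p, pchisq(chi2, 1, lower.tail = FALSE))
      # cross-check against the base chi-squared test (no correction)
      suppressWarnings(
        ct <- chisq.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         correct = FALSE))
      expect_equal(r$chi2, unname(ct$statistic), tolerance = 1e-10)
    }
  }
})

test_that("state profile partitions aDMPs and flags planted bias", {
  g <- generate_genome(6000, 30, "a", seed = 47)
  des <- cohort_design("a", n = 150, age_min = 20, age_max = 80)
  ef <- plant_effects(g, effect_design(n_gain = 120, n_loss = 80,
                                       sharing_gain = c(1, 0, 0),
                                       sharing_loss = c(1, 0, 0),
                                       gain_bias_or = 5, loss_bias_or = 5),
                      seed = 48)
  co <- simulate_cohort(g, ef, des, seed = 49)
  cc <- call_admps(co$a)
  st <- assign_state(g$probes, g$segmentations$a)
  prof <- state_enrichment_profile(cc, "loss", st)
  expect_equal(nrow(prof), 15)
  # partition conservation: cell a sums to assigned loss-aDMPs
  expect_equal(sum(prof$a),
               sum(cc$table$class == "loss" & st != "unassigned"))
  # planted enhancer bias recovered as significant enrichment
  enh <- prof[prof$category == "Enh", ]
  expect_gt(enh$odds_ratio, 1)
  expect_true(enh$significant)
  # gain bias lands at CGI & EZH2: joint enrichment significant
  ann <- annotate_probes(g)
  tested <- cc$table$class != "untested"
  joint <- cgi_ezh2_joint_enrichment(
    cc$table$probe_id[cc$table$class == "gain"],
    cc$table$probe_id[tested],
    ann$cgi_class[tested], ann$ezh2[tested])
  both_single <- joint[joint$category == "both_vs_single", ]
  expect_gt(both_single$odds_ratio, 1)
  expect_true(both_single$significant)
  # conservation within the restricted background
  expect_equal(both_single$a + both_single$b + both_single$c + both_single$d,
               sum((ann$cgi_class == "island" | ann$ezh2)[tested]))
})

test_that("joint CGI/EZH2 enrichment is near 1 under uniform placement", {
  set.seed(51)
  ors <- numeric(10)
  for (i in 1:10) {
    g <- generate_genome(3000, 10, "a", seed = 600 + i)
    ann <- annotate_probes(g)
    restricted <- ann$probe_id[ann$cgi_class == "island" | ann$ezh2]
    admps <- sample(restricted, 150)  # uniform over the union
    j <- cgi_ezh2_joint_enrichment(admps, ann$probe_id, ann$cgi_class,
                                   ann$ezh2)
    ors[i] <- j$odds_ratio[j$category == "both_vs_single"]
  }
  ci <- quantile(ors, c(0.025, 0.975))
  expect_lte(ci[1], 1)
  expect_gte(ci[2], 1)
})

test_that("nearest gene follows the nearest-end rule with ordered ties", {
  genes <- data.frame(gene_id = c("GB", "GA"), chrom = "chr1",
                      start = c(10000, 1000), end = c(20000, 2000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  # probe 100 bp upstream of GA's start; far from GB
  p1 <- data.frame(probe_id = "p1", chrom = "chr1", pos = 901)
  r1 <- nearest_gene(p1, genes)
  expect_equal(r1$gene_id, "GA")
  expect_equal(r1$distance, 100)
  # probe inside GB still measured to the nearer end
  p2 <- data.frame(probe_id = "p2", chrom = "chr1", pos = 10101)
  r2 <- nearest_gene(p2, genes)
  expect_equal(r2$gene_id, "GB")
  expect_equal(r2$distance, 100)
  # exact tie: lexicographically smaller id wins
  gt <- data.frame(gene_id = c("GB", "GA"), chrom = "chr1",
                   start = c(1499, 0), end = c(2000, 500),
                   strand = "+", stringsAsFactors = FALSE)
  pt_ <- data.frame(probe_id = "p3", chrom = "chr1", pos = 1000)
  # pos0 999: 500 bp from GA's 3' end and from GB's 5' end
  rt <- nearest_gene(pt_, gt)
  expect_equal(rt$gene_id, "GA")
  # no gene on the chromosome -> unmapped
  px <- data.frame(probe_id = "p4", chrom = "chr9", pos = 5)
  expect_true(is.na(nearest_gene(px, genes)$gene_id))
})

test_that("nearest gene matches the exhaustive all-pairs oracle", {
  set.seed(29)
  n <- 5000
  probes <- data.frame(probe_id = sprintf("p%05d", 1:n),
                       chrom = sample(paste0("chr", 1:2), n, replace = TRUE),
                       pos = sample.int(5e6, n), stringsAsFactors = FALSE)
  gs <- sort(sample.int(5e6, 200))
  genes <- data.frame(gene_id = sprintf("G%03d", 1:200),
                      chrom = sample(paste0("chr", 1:2), 200, replace = TRUE),
                      start = gs, end = gs + sample(1e3:1e5, 200,
                                                    replace = TRUE),
                      strand = sample(c("+", "-"), 200, replace = TRUE),
                      stringsAsFactors = FALSE)
  res <- nearest_gene(probes, genes)
  orc <- scan_nearest_gene_oracle(probes, genes)
  expect_equal(res$gene_id, orc[, 1])
  expect_equal(res$distance, as.numeric(orc[, 2]))
})

test_that("annotation table partitions probes across CGI classes and states", {
  g <- tiny_genome(n_probes = 500, seed = 53)
  ann <- annotate_probes(g)
  expect_equal(nrow(ann), 500)
  expect_true(all(ann$cgi_class %in% c("island", "shore", "non_CGI")))
  expect_true(all(!is.na(ann$cgi_id[ann$cgi_class == "island"])))
  expect_true(all(is.na(ann$cgi_id[ann$cgi_class != "island"])))
  for (t in g$tissues) {
    expect_true(all(ann[[paste0("state_", t)]] %in% chromatin_states()))
  }
})
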