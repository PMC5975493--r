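test_that("specificity table counts tissues per probe, direction-stratified", {
  tables <- list(
    brain = fake_calls(gain = c("p1", "p7"), universe = paste0("p", 1:10)),
    liver = fake_calls(gain = c("p2", "p7"), loss = "p3",
                       universe = paste0("p", 1:10)),
    mono = fake_calls(gain = "p7", loss = "p1", universe = paste0("p", 1:10)))
  sp <- build_specificity(tables, "gain")
  expect_setequal(sp$probe_id, c("p1", "p2", "p7"))
  expect_equal(sp$n_tissues[sp$probe_id == "p1"], 1L)
  expect_equal(sp$n_tissues[sp$probe_id == "p7"], 3L)
  # probe gain in brain, loss in mono: appears in both tables, flagged
  expect_true(sp$discordant[sp$probe_id == "p1"])
  sl <- build_specificity(tables, "loss")
  expect_setequal(sl$probe_id, c("p3", "p1"))
  expect_equal(sl$n_tissues[sl$probe_id == "p1"], 1L)

  expect_error(build_specificity(tables[1], "gain"), ">= 2")
})

test_that("percent_tissue_specific and sharing_histogram are conservative", {
  tables <- list(a = fake_calls(gain = c("x1", "x2", "s1")),
                 b = fake_calls(gain = c("x3", "s1")))
  sp <- build_specificity(tables, "gain")
  expect_equal(as.numeric(percent_tissue_specific(sp)), 75.0)
  h <- sharing_histogram(sp)
  expect_equal(sum(h), nrow(sp))
  expect_equal(unname(h), c(3L, 1L))
  # all-specific design: all mass at bin 1, 100%
  sp2 <- build_specificity(list(a = fake_calls(gain = "u1"),
                                b = fake_calls(gain = "u2")), "gain")
  expect_equal(as.numeric(percent_tissue_specific(sp2)), 100.0)
  expect_equal(unname(sharing_histogram(sp2)), c(2L, 0L))
  expect_error(percent_tissue_specific(sp2[0, ]), "empty")
})

test_that("overlap matrix equals brute-force set intersections", {
  set.seed(3)
  universe <- sprintf("cg%05d", 1:400)
  tissues <- paste0("t", 1:5)
  sets <- lapply(tissues, function(t) sample(universe, sample(20:80, 1)))
  names(sets) <- tissues
  tables <- lapply(sets, function(s) fake_calls(gain = s))
  om <- overlap_matrix(tables, "gain")
  for (i in seq_along(tissues)) {
    others <- unique(unlist(sets[-i]))
    expect_equal(om$counts[i, i], length(setdiff(sets[[i]], others)))
    for (j in seq_along(tissues)) {
      if (i != j)
        expect_equal(om$counts[i, j], length(intersect(sets[[i]], sets[[j]])))
    }
    expect_equal(om$percent[i, i],
                 100 * length(setdiff(sets[[i]], others)) / length(sets[[i]]))
  }
  expect_true(isSymmetric(unname(om$counts * 1.0)))

  # disjoint and identical edge cases
  dj <- overlap_matrix(list(a = fake_calls(gain = c("a1", "a2")),
                            b = fake_calls(gain = c("b1"))), "gain")
  expect_equal(unname(dj$counts), matrix(c(2L, 0L, 0L, 1L), 2))
  id <- overlap_matrix(list(a = fake_calls(gain = c("z1", "z2")),
                            b = fake_calls(gain = c("z1", "z2"))), "gain")
  expect_equal(diag(id$counts), c(a = 0L, b = 0L))
  expect_equal(id$counts[1, 2], 2L)
})

test_that("specificity outputs are invariant to tissue ordering", {
  set.seed(9)
  universe <- sprintf("cg%04d", 1:200)
  tabs <- list(a = fake_calls(gain = sample(universe, 30)),
               b = fake_calls(gain = sample(universe, 40)),
               c = fake_calls(gain = sample(universe, 25)))
  sp1 <- build_specificity(tabs, "gain")
  sp2 <- build_specificity(rev(tabs), "gain")
  expect_equal(sp1$probe_id, sp2$probe_id)
  expect_equal(sp1$n_tissues, sp2$n_tissues)
  expect_equal(sp1$tissues, sp2$tissues)
  expect_equal(sharing_histogram(sp1), sharing_histogram(sp2))
  om1 <- overlap_matrix(tabs, "gain")
  om2 <- overlap_matrix(rev(tabs), "gain")
  expect_equal(om1$counts, om2$counts[names(tabs), names(tabs)])
})

test_that("cross-tissue relaxed-significance indicators follow the rules", {
  tabs <- list(
    home = fake_calls(gain = "p1", universe = c("p1", "p2")),
    other = data.frame(probe_id = c("p1", "p2"),
                       slope_per_year = c(0.001, 0.001),
                       slope_per_decade_pct = c(1, 1),
                       se = 1e-4, p = c(1e-5, 0.5), p_bonf = 1,
                       n_used = 100, class = "none",
                       stringsAsFactors = FALSE),
    third = data.frame(probe_id = c("p1", "p2"),
                       slope_per_year = c(-0.001, 0),
                       slope_per_decade_pct = c(-1, 0),
                       se = 1e-4, p = c(1e-5, 0.5), p_bonf = 1,
                       n_used = 100, class = "none",
                       stringsAsFactors = FALSE))
  sp <- build_specificity(tabs, "gain")
  cs <- cross_tissue_significance(sp, tabs, p_relaxed = 0.001)
  # significant + same-sign slope in 'other', wrong sign in 'third'
  expect_true(cs$indicator["p1", "other"])
  expect_false(cs$indicator["p1", "third"])
  expect_true(is.na(cs$indicator["p1", "home"]))
  expect_equal(cs$fraction, 0.5)

  # weak shared effects raise the relaxed-significance fraction above null
  g <- tiny_genome(n_probes = 800, tissues = c("a", "b"), seed = 41)
  des <- cohort_design(c("a", "b"), n = c(400, 120), age_min = 20,
                       age_max = 80)
  slopes <- matrix(0, 800, 2, dimnames = list(g$probes$probe_id, c("a", "b")))
  idx <- 1:40
  slopes[idx, "a"] <- 0.004   # called in a
  slopes[idx, "b"] <- 0.0005  # weak shared signal in b (0.5%/10yr)
  ef <- structure(list(slopes = slopes, effects = data.frame(),
                       tissues = c("a", "b")), class = "effect_map")
  co <- simulate_cohort(g, ef, des, noise_model(residual_sd = 0.03), seed = 2)
  calls <- lapply(co, call_admps)
  sp_w <- build_specificity(calls, "gain")
  frac_weak <- cross_tissue_significance(sp_w, calls)$fraction

  ef0 <- structure(list(slopes = slopes * c(1, 0)[col(slopes)],
                        effects = data.frame(), tissues = c("a", "b")),
                   class = "effect_map")
  co0 <- simulate_cohort(g, ef0, des, noise_model(residual_sd = 0.03),
                         seed = 2)
  calls0 <- lapply(co0, call_admps)
  sp0 <- build_specificity(calls0, "gain")
  frac_null <- cross_tissue_significance(sp0, calls0)$fraction
  expect_gt(frac_weak, frac_null)
})

test_that("cross-tissue slope matrix distinguishes missing from zero", {
  tabs <- list(a = fake_calls(gain = "p1", universe = c("p1", "p2")),
               b = fake_calls(universe = "p2"))
  sp <- build_specificity(tabs, "gain")
  M <- cross_tissue_slope_matrix(sp, tabs)
  expect_equal(M["p1", "a"], 3)
  expect_true(is.na(M["p1", "b"]))  # absent from b's fits: sentinel, not 0
})

test_that("region aggregation uses union semantics over member probes", {
  tabs <- list(A = fake_calls(gain = "p1", universe = c("p1", "p2")),
               B = fake_calls(gain = "p2", universe = c("p1", "p2")))
  sp <- build_specificity(tabs, "gain")
  mapping <- data.frame(probe_id = c("p1", "p2"), unit = "cgi_1",
                        stringsAsFactors = FALSE)
  rs <- aggregate_to_regions(sp, mapping, "CGI")
  expect_equal(nrow(rs$table), 1)
  expect_equal(rs$table$n_tissues, 2L)  # shared at region level
  expect_equal(rs$table$tissues, "A,B")
  expect_equal(as.numeric(rs$percent_unique), 0)

  # a unit's n_tissues >= max over member probes' n_tissues; table smaller
  set.seed(13)
  universe <- sprintf("cg%04d", 1:300)
  tabs2 <- list(a = fake_calls(gain = sample(universe, 60)),
                b = fake_calls(gain = sample(universe, 60)),
                c = fake_calls(gain = sample(universe, 60)))
  sp2 <- build_specificity(tabs2, "gain")
  map2 <- data.frame(probe_id = universe,
                     unit = paste0("u", rep(1:60, length.out = 300)),
                     stringsAsFactors = FALSE)
  rs2 <- aggregate_to_regions(sp2, map2, "gene")
  expect_lte(nrow(rs2$table), nrow(sp2))
  expect_lte(as.numeric(rs2$percent_unique), 100)
  probe_n <- setNames(sp2$n_tissues, sp2$probe_id)
  unit_of <- setNames(map2$unit, map2$probe_id)
  for (u in rs2$table$unit) {
    members <- sp2$probe_id[unit_of[sp2$probe_id] == u]
    expect_gte(rs2$table$n_tissues[rs2$table$unit == u],
               max(probe_n[members]))
  }

  # per-(unit, tissue) counts reproduce a DIP2C-like concentrated pattern
  brain_probes <- paste0("d", 1:24)
  tabs3 <- list(brain = fake_calls(loss = brain_probes,
                                   universe = c(brain_probes, "d25")),
                buccal = fake_calls(loss = "d25",
                                    universe = c(brain_probes, "d25")))
  sp3 <- build_specificity(tabs3, "loss")
  map3 <- data.frame(probe_id = c(brain_probes, "d25"), unit = "DIP2C_like",
                     stringsAsFactors = FALSE)
  rs3 <- aggregate_to_regions(sp3, map3, "gene")
  expect_equal(unname(rs3$counts["DIP2C_like", c("brain", "buccal")]),
               c(24, 1))

  expect_error(aggregate_to_regions(sp3, map3[0, ], "gene"), "empty")
})

test_that("external catalogue overlap reports both denominators", {
  res <- external_overlap(paste0("p", 1:100), c(paste0("p", 1:8),
                                                paste0("q", 1:42)))
  expect_equal(res$n_overlap, 8)
  expect_equal(res$pct_of_admps, 8.0)
  expect_equal(res$pct_of_external, 16.0)
})
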