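test_that("normalize_ratios divides by the same-mix wild-type mean", {
  wt <- data.frame(
    strain = "WT",
    mix_id = c(1L, 1L, 2L, 2L),
    his_count = c(157L, 157L, 105L, 105L),
    leu_count = c(100L, 100L, 100L, 100L)
  )
  rec <- data.frame(
    strain = "mut", mix_id = c(1L, 2L, 1L),
    his_count = c(157L, 105L, 0L), leu_count = c(100L, 100L, 50L)
  )
  out <- normalize_ratios(rec, wt)
  expect_equal(out$value, c(1, 1, 0))
  # pooled normalized WT mean is exactly 1
  wt_norm <- normalize_ratios(wt, wt)
  expect_equal(mean(wt_norm$value), 1)
  # per-mix override path, published WT mix means
  out2 <- normalize_ratios(rec, wt_mix_means = c("1" = 1.57, "2" = 1.05))
  expect_equal(out2$value[1], 1.57 / 1.57)
  expect_error(
    normalize_ratios(rec, wt[wt$mix_id == 1L, ]),
    "no wild-type records for mix 2"
  )
})

test_that("partition_co_nco reproduces the published stability partitions", {
  wt <- partition_co_nco(rep(c("CO", "NCO"), c(41, 412)))
  expect_equal(wt$co_count, 41L)
  expect_equal(wt$co_proportion, 41 / 453, tolerance = 1e-12)
  srs2 <- partition_co_nco(rep(c("CO", "NCO"), c(86, 257)))
  expect_equal(srs2$co_proportion, 86 / 343, tolerance = 1e-12)
  expect_equal(partition_co_nco(rep("NCO", 10))$co_proportion, 0)
  expect_error(partition_co_nco(character()), "no stability calls")
})

test_that("efficiency decompositions reproduce published cells at 2 dp", {
  # mph1: repair 1.04, CO 89/462 -> CO efficiency 0.20
  e <- compute_efficiencies(1.04, 89 / 462)
  expect_equal(round(e[["co_efficiency"]], 2), 0.20)
  # srs2: 0.31 and 86/343 -> 0.08 / 0.23
  e2 <- compute_efficiencies(0.31, 86 / 343)
  expect_equal(round(unname(e2), 2), c(0.08, 0.23))
  # zero CO proportion: all efficiency is NCO
  expect_equal(unname(compute_efficiencies(0.73, 0)), c(0, 0.73))

  # class splits: WT, sgs1, mph1 srs2
  expect_equal(
    round(unname(compute_class_efficiencies(0.91, 141, 18)), 2), c(0.81, 0.10)
  )
  expect_equal(
    round(unname(compute_class_efficiencies(0.62, 136, 13)), 2), c(0.57, 0.05),
    tolerance = 0
  )
  expect_equal(
    round(unname(compute_class_efficiencies(0.39, 38, 5)), 2), c(0.34, 0.05)
  )
  expect_error(compute_class_efficiencies(0.5, 0, 0), "no hDNA-detected")
})

test_that("conservation holds exactly pre-rounding on random inputs", {
  set.seed(99)
  for (i in 1:1000) {
    eff <- runif(1, 0, 2)
    co_p <- runif(1)
    e <- compute_efficiencies(eff, co_p)
    expect_lt(abs(sum(e) - eff), 1e-12)
    uni <- sample(0:300, 1)
    bi <- sample(0:300, 1)
    if (uni + bi == 0) uni <- 1
    ce <- compute_class_efficiencies(e[["nco_efficiency"]], uni, bi)
    expect_lt(abs(sum(ce) - e[["nco_efficiency"]]), 1e-12)
  }
})

test_that("efficiencies are linear and increasing in repair efficiency", {
  co_p <- 0.2
  effs <- c(0.1, 0.5, 1.0, 1.5)
  vals <- vapply(effs, function(x) compute_efficiencies(x, co_p)[["co_efficiency"]], 0)
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, effs * co_p, tolerance = 1e-12)
})

test_that("build_efficiency_table assembles a consistent per-strain table", {
  counts <- data.frame(
    strain = c("WT", "mut"),
    repair_efficiency = c(1.00, 0.50),
    co_count = c(41L, 20L), nco_count = c(412L, 80L),
    uni_count = c(141L, 40L), bi_count = c(18L, 10L)
  )
  tab <- build_efficiency_table(counts)
  expect_equal(tab$co_proportion + tab$nco_proportion, c(1, 1))
  expect_equal(tab$co_efficiency + tab$nco_efficiency, tab$repair_efficiency,
    tolerance = 1e-12
  )
  expect_equal(tab$uni_efficiency + tab$bi_efficiency, tab$nco_efficiency,
    tolerance = 1e-12
  )
  expect_error(build_efficiency_table(counts[c(1, 1), ]), "duplicate strain")
  expect_error(
    build_efficiency_table(counts[, -2]),
    "missing columns"
  )
})

test_that("analyze_cohort recovers generator truth on an easy cohort", {
  mapd <- default_substrate()
  p <- sim_params(
    mechanism_weights = c(SDSA = 0.8, DHJ_DISSOLUTION = 0.2),
    tract_mean = 401, tract_min = 400, n_events = 400L, seed = 31L
  )
  events <- simulate_cohort(p, mapd, strain = "WT")
  tp <- transformation_sim_params(n_transformations = 12L, seed = 32L)
  trans <- simulate_transformation_counts(tp, strain = "WT")
  res <- analyze_cohort(events, trans, wt_strain = "WT", map = mapd)
  truth_uni <- sum(events$truth_mechanism == "SDSA")
  truth_bi <- sum(events$truth_mechanism %in% c("DHJ_DISSOLUTION", "DOUBLE_SDSA"))
  cc <- res$class_counts
  expect_equal(cc$unidirectional, truth_uni)
  expect_equal(cc$bidirectional, truth_bi)
  expect_equal(res$table$repair_efficiency, 1) # self-normalized WT
  expect_equal(res$table$uni_count, truth_uni)
})
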