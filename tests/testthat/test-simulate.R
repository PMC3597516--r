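map <- default_substrate()

test_that("simulated hDNA topology matches each mechanism's prediction", {
  # tract_min 400 covers every SNP on an involved side, so the observable
  # class equals the mechanism's predicted pattern deterministically
  p <- sim_params(tract_mean = 401, tract_min = 400)
  expected <- c(
    SDSA = "UNIDIRECTIONAL",
    DHJ_DISSOLUTION = "BIDIRECTIONAL",
    DOUBLE_SDSA = "BIDIRECTIONAL",
    HJ_CLEAVAGE_NCO = "CLEAVAGE_PATTERN",
    CONVERSION_ONLY = "CONVERSION_ONLY",
    NO_TRANSFER = "NO_TRANSFER"
  )
  set.seed(11)
  for (mech in names(expected)) {
    for (i in 1:50) {
      ev <- simulate_event(mech, map, p)
      expect_identical(ev$stability_call, "NCO")
      got <- classify_event(summarize_transfer(ev$plasmid, ev$chromosome, map))
      expect_identical(got, unname(expected[mech]), label = mech)
    }
  }
  co <- simulate_event("HJ_CLEAVAGE_CO", map, p)
  expect_identical(co$stability_call, "CO")
  expect_null(co$plasmid)
  expect_error(simulate_event("NOT_A_MECH", map, p), "unknown mechanism")
})

test_that("SDSA hDNA is contiguous from the gap-proximal SNP outward", {
  p <- sim_params(tract_mean = 150)
  set.seed(3)
  sides <- snp_sides(map)
  for (i in 1:200) {
    ev <- simulate_event("SDSA", map, p)
    tr <- call_tracts(ev$plasmid, map)
    expect_lte(nrow(tr), 1L) # one side, one contiguous tract (or none)
    if (nrow(tr) == 1L) {
      idx <- which(sides == tr$side)
      # tract starts at the gap-proximal SNP of its side
      proximal <- idx[which.min(snp_edge_distance(map)[idx])]
      expect_true(proximal >= tr$first_snp && proximal <= tr$last_snp)
    }
    # donor allele untouched
    expect_true(all(ev$chromosome$codes == "R"))
  }
})

test_that("undetectable-event frequency matches the tract-length CDF", {
  n <- 10000L
  tract_mean <- 60
  p <- sim_params(tract_mean = tract_mean)
  set.seed(21)
  undetected <- 0L
  for (i in seq_len(n)) {
    ev <- simulate_event("SDSA", map, p)
    if (!any(ev$plasmid$codes == "H")) undetected <- undetected + 1L
  }
  # independent route: direct CDF evaluation at the nearest-SNP distance
  p_miss <- 1 - tract_detection_prob(18, tract_mean)
  se <- sqrt(p_miss * (1 - p_miss) / n)
  expect_lt(abs(undetected / n - p_miss), 3 * se + 1e-9)
})

test_that("cohorts are seed-deterministic and draw from the stated weights", {
  p <- sim_params(
    mechanism_weights = c(NO_TRANSFER = 1), n_events = 50L, seed = 5L
  )
  a <- simulate_cohort(p, map)
  expect_equal(nrow(a), 50L)
  expect_true(all(a$truth_mechanism == "NO_TRANSFER"))
  expect_true(all(a$plasmid_calls == paste0(strrep("R", 9), "|", strrep("R", 10))))
  b <- simulate_cohort(p, map)
  expect_identical(a, b)
  p2 <- sim_params(n_events = 200L, seed = 6L)
  expect_false(identical(simulate_cohort(p2, map), simulate_cohort(
    sim_params(n_events = 200L, seed = 7L), map
  )))
})

test_that("transformation counts are centred on the configured efficiency", {
  tp <- transformation_sim_params(
    n_transformations = 36L, true_repair_efficiency = 1.0,
    leu_mean = 300, dispersion = 0.05, seed = 9L
  )
  tr <- simulate_transformation_counts(tp)
  expect_true(all(tr$leu_count > 0))
  ratios <- tr$his_count / tr$leu_count
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.0), 3 * se)

  # zero efficiency: no His+ colonies at all
  tr0 <- simulate_transformation_counts(
    transformation_sim_params(true_repair_efficiency = 0, seed = 2L)
  )
  expect_true(all(tr0$his_count == 0L))
})

test_that("dispersion -> 0 collapses ratio variance to the sampling floor", {
  n <- 200L
  leu_mean <- 400
  base <- transformation_sim_params(
    n_transformations = n, leu_mean = leu_mean, dispersion = 0, seed = 13L
  )
  over <- transformation_sim_params(
    n_transformations = n, leu_mean = leu_mean, dispersion = 0.3, seed = 13L
  )
  v0 <- stats::var(with(simulate_transformation_counts(base), his_count / leu_count))
  v1 <- stats::var(with(simulate_transformation_counts(over), his_count / leu_count))
  # closed-form floor with His | Leu Poisson: var(H/L) = E[eff / L] ~ eff/leu
  floor_var <- 1 / leu_mean
  expect_lt(v0, 3 * floor_var)
  # with dispersion d the ratio variance adds ~ eff^2 * d >> the floor
  expect_gt(v1, 10 * v0)
})
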