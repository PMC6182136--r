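test_that("archetype defaults carry the anchored kinetic values", {
  hs <- make_archetype_params("HSMAR1")
  expect_equal(hs$k_multimer_dissoc, 6e-5)   # 3 h subunit-exchange half-life
  expect_equal(1 / hs$k_unbind, 600)          # 10 min single-end dwell
  expect_lt(hs$synapsis_attenuation, 1)
  tn <- make_archetype_params("TN5_MONOMER")
  expect_gte(tn$k_unbind, 1 / 60)             # sub-minute dwell
  expect_equal(tn$synapsis_attenuation, 1)
  expect_gt(hs$k_bind, tn$k_bind)
  expect_lt(hs$k_unbind, tn$k_unbind)
  expect_error(make_archetype_params("TN7"), "arg")
  expect_identical(archetype_pathway("TN5_MONOMER")$pathway, "S_PD")
  expect_identical(archetype_pathway("HSMAR1")$pathway, "S_NEC")
})

test_that("jittered ensembles keep the rate-constant orderings", {
  tn_default <- make_archetype_params("TN5_MONOMER")
  ens <- make_archetype_params("HSMAR1", seed = 4, jitter = 3, n = 10000)
  expect_length(ens, 10000)
  kb <- vapply(ens, `[[`, numeric(1), "k_bind")
  ku <- vapply(ens, `[[`, numeric(1), "k_unbind")
  at <- vapply(ens, `[[`, numeric(1), "synapsis_attenuation")
  expect_true(all(kb > tn_default$k_bind))
  expect_true(all(ku < tn_default$k_unbind))
  expect_true(all(at < 1))
  tens <- make_archetype_params("TN5_SCD", seed = 4, jitter = 3, n = 2000)
  expect_true(all(vapply(tens, `[[`, numeric(1), "k_unbind") >= 1 / 60))
  expect_true(all(vapply(tens, `[[`, numeric(1), "synapsis_attenuation") == 1))
  # determinism
  e1 <- make_archetype_params("HSMAR1", seed = 11, jitter = 2, n = 5)
  e2 <- make_archetype_params("HSMAR1", seed = 11, jitter = 2, n = 5)
  expect_identical(e1, e2)
})

test_that("dwell-time samples are exponential and reproducible", {
  s1 <- sample_dwell_times(1 / 600, 1, seed = 3)
  s2 <- sample_dwell_times(1 / 600, 1, seed = 3)
  expect_identical(s1$times, s2$times)
  expect_gt(s1$times, 0)
  big <- sample_dwell_times(1 / 600, 10000, seed = 8)
  expect_lt(abs(mean(big$times) - 600) / 600, 0.03)
  # exponential scaling: times * c ~ rate k / c
  expect_lt(abs(mean(big$times * 3) - 1800) / 1800, 0.03)
})

test_that("dissociation-rate recovery is accurate and well calibrated", {
  for (k in c(6e-5, 1 / 600)) {
    s <- sample_dwell_times(k, 1000, seed = 12)
    fit <- fit_dissociation_rate(s)
    expect_lt(abs(fit$rate - k) / k, 0.1)
    expect_true(fit$ci[1] < fit$ci[2])
  }
  # two identical values t -> rate 1/t
  expect_equal(fit_dissociation_rate(c(50, 50))$rate, 1 / 50)
  expect_error(fit_dissociation_rate(c(5)), "two observations")
  # quick coverage check (the full 500-rep version lives in acceptance)
  hits <- vapply(1:150, function(i) {
    s <- sample_dwell_times(1 / 600, 300, seed = 1000 + i)
    ci <- fit_dissociation_rate(s)$ci
    ci[1] <= 1 / 600 && 1 / 600 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("censoring-aware recovery stays close to the truth", {
  k <- 1 / 600
  s <- sample_dwell_times(k, 2000, seed = 5)
  horizon <- 900
  cens <- s$times > horizon
  obs <- pmin(s$times, horizon)
  fit <- fit_dissociation_rate(obs, censored = cens)
  expect_lt(abs(fit$rate - k) / k, 0.1)
  expect_equal(fit$n_events, sum(!cens))
})

test_that("estimator RMSE shrinks like one over root n", {
  k <- 1 / 600
  rmse <- vapply(c(100, 1000, 10000), function(n) {
    errs <- vapply(1:40, function(i) {
      fit_dissociation_rate(sample_dwell_times(k, n, seed = n + i))$rate - k
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_gt(rmse[1] / rmse[3], 5) # expected ~10 for a 100-fold n range
})

test_that("fixture scenarios regenerate bit-identically and hold their claims", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture_run("g462d_dead", seed = 6, dir = d1)
  generate_fixture_run("g462d_dead", seed = 6, dir = d2)
  f1 <- file.path(d1, "first_passage.tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(file.path(d2, "first_passage.tsv"), "raw",
                           file.size(file.path(d2, "first_passage.tsv"))))
  golden <- read_table_tsv(f1)
  expect_true(all(golden$censored))      # zero PEC events, ever
  expect_error(generate_fixture_run("mystery"), "arg")

  d3 <- tempfile()
  generate_fixture_run("ade_single_end", seed = 1, dir = d3)
  prod <- read_table_tsv(file.path(d3, "products.tsv"))
  expect_equal(prod$fraction[prod$product == "SINGLE_END_CUT"], 1)

  d4 <- tempfile()
  generate_fixture_run("snec_basic", seed = 2, dir = d4)
  side <- jsonlite::read_json(file.path(d4, "trajectory.tsv.json"),
                              simplifyVector = TRUE)
  expect_equal(side$config$scenario, "snec_basic")
})
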