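test_that("SSA is deterministic in the seed and sensitive to it", {
  net <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 60)
  a <- simulate_ssa(net, horizon = 600, seed = 7)
  b <- simulate_ssa(net, horizon = 600, seed = 7)
  expect_identical(a$event_times, b$event_times)
  expect_identical(a$event_labels, b$event_labels)
  expect_identical(a$snapshots, b$snapshots)
  c <- simulate_ssa(net, horizon = 600, seed = 8)
  expect_false(identical(a$event_times, c$event_times))
})

test_that("zero transposase leaves the state constant to the horizon", {
  net <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 0)
  tr <- simulate_ssa(net, horizon = 100, seed = 1)
  expect_equal(tr$n_events, 0)
  expect_equal(tr$status, "exhausted")
  expect_equal(max(abs(sweep(tr$snapshots, 2, tr$snapshots[1, ]))), 0)
})

test_that("conservation laws hold along SSA snapshots and ODE solutions", {
  net <- build_network("S_PD", tn5_rates(), genome_context(4e3, n_elements = 2),
                       mono(), 40)
  tr <- simulate_ssa(net, horizon = 2000, seed = 3)
  for (w in net$conservation) {
    tot <- tr$snapshots %*% w
    expect_equal(max(abs(tot - tot[1])), 0)
  }
  mf <- integrate_mean_field(net, horizon = 2000, tol = 1e-8)
  for (w in net$conservation) {
    tot <- mf$means %*% w
    expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 1e-7)
  }
})

test_that("oracle reproduces the two-stage closed form and the SSA agrees", {
  # 1 element, 1 dimer, no unbinding, no completion:
  # MFPT = 1/(2 k1 c) + 1/k2 exactly
  rc <- rate_constants(k_bind = 1e6, k_unbind = 0, k_synapsis = 0.02,
                       k_post = 0)
  net <- build_network("S_NEC", rc, genome_context(1e3), scd(), 1)
  c1 <- count_to_concentration(1, 1e-15)
  analytic <- 1 / (2 * rc$k_bind * c1) + 1 / rc$k_synapsis
  snap <- solve_ctmc_exact(net, horizon = 200)
  expect_equal(snap$mfpt, analytic, tolerance = 1e-10)
  expect_equal(snap$absorption_prob, 1, tolerance = 1e-9)
  fp <- sample_first_passage(net, "PEC", reps = 2000, seed = 11,
                             horizon = 20 * analytic)
  expect_equal(fp$censoring_fraction, 0)
  expect_lt(abs(fp$mean - analytic) / fp$se, 3)
})

test_that("oracle distributions are normalized and DONE mass is monotone", {
  nets <- random_small_networks(3, seed = 99)
  for (net in nets) {
    snap <- solve_ctmc_exact(net, horizon = 60)
    expect_lt(abs(sum(snap$prob) - 1), 1e-9)
  }
  net <- build_network("S_NEC", tn5_rates(), genome_context(1e3), scd(), 3)
  done_mass <- vapply(c(60, 600, 6000, 60000), function(h) {
    s <- solve_ctmc_exact(net, h)
    sum(s$prob[s$states[, "DONE"] >= 1])
  }, numeric(1))
  expect_true(all(diff(done_mass) > 0))
  expect_gt(done_mass[4], 0.99)
})

test_that("the oracle refuses oversized state spaces", {
  net <- build_network("S_PD", tn5_rates(), genome_context(4e3, n_elements = 4),
                       mono(), 30)
  expect_error(solve_ctmc_exact(net, 10, state_cap = 50), "cap")
})

test_that("first-passage sampling matches a pure exponential channel", {
  # hand-place the system in the PEC state so only completion can fire
  net <- build_network("S_NEC", tn5_rates(k_post = 0.02), genome_context(1e3),
                       scd(), 0)
  net$species[] <- 0
  net$species["PEC"] <- 1
  fp <- sample_first_passage(net, "DONE", reps = 1000, seed = 5, horizon = 1e4)
  expect_lt(abs(fp$mean - 1 / 0.02) / fp$se, 3)
  expect_equal(fp$censoring_fraction, 0)
  # single replicate is reproducible
  one <- sample_first_passage(net, "DONE", reps = 1, seed = 9, horizon = 1e4)
  two <- sample_first_passage(net, "DONE", reps = 1, seed = 9, horizon = 1e4)
  expect_identical(one$times, two$times)
  expect_true(is.na(one$se))
})

test_that("an unreachable target censors every replicate without error", {
  g <- build_network("S_NEC", tn5_rates(), genome_context(4e3),
                     scd(subunit_b_interface = "G462D"), 60)
  fp <- sample_first_passage(g, "PEC", reps = 50, seed = 2, horizon = 600)
  expect_equal(fp$censoring_fraction, 1)
  expect_equal(fp$mean, NA_real_)
})

test_that("mean-field integration matches linear closed forms", {
  # pure decay: PEC -> DONE at k3
  net <- build_network("S_NEC", tn5_rates(k_post = 0.03), genome_context(1e3),
                       scd(), 0)
  net$species[] <- 0
  net$species["PEC"] <- 5
  mf <- integrate_mean_field(net, horizon = 200, grid = seq(0, 200, 20))
  expect_equal(mf$means[, "PEC"], 5 * exp(-0.03 * mf$times), tolerance = 1e-6)
  # zero transposase: constant solution
  z <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 0)
  mfz <- integrate_mean_field(z, horizon = 100)
  expect_equal(max(abs(sweep(mfz$means, 2, mfz$means[1, ]))), 0)
  # pseudo-first-order relaxation of end occupancy under excess transposase
  rc <- rate_constants(k_bind = 1e5, k_unbind = 0.02, k_synapsis = 0, k_post = 0)
  net2 <- build_network("S_PD", rc, genome_context(1e3), mono(), 10000)
  cT <- count_to_concentration(10000, 1e-15)
  kobs <- rc$k_bind * cT + rc$k_unbind
  occ_inf <- rc$k_bind * cT / kobs
  mf2 <- integrate_mean_field(net2, horizon = 300, grid = seq(0, 300, 30))
  occ <- (mf2$means[, "E_BF"] + mf2$means[, "E_FB"] +
            2 * mf2$means[, "E_BB"]) / 2
  expect_equal(occ, occ_inf * (1 - exp(-kobs * mf2$times)), tolerance = 0.01)
})

test_that("mean-field means track SSA means in the large-copy regime", {
  rc <- rate_constants(k_bind = 1e5, k_unbind = 0.05, k_synapsis = 0.01,
                       k_post = 0.005)
  net <- build_network("S_PD", rc, genome_context(1e3, n_elements = 120),
                       mono(), 300)
  horizon <- 400
  mf <- integrate_mean_field(net, horizon, grid = c(0, horizon))
  reps <- 120
  finals <- matrix(0, reps, length(net$species))
  for (r in seq_len(reps)) {
    tr <- simulate_ssa(net, horizon, seed = 1000 + r, record_grid = c(0, horizon))
    finals[r, ] <- tr$snapshots[2, ]
  }
  ssa_mean <- colMeans(finals)
  names(ssa_mean) <- names(net$species)
  for (sp in c("T", "E_FF", "E_BB", "PEC")) {
    expect_lt(abs(ssa_mean[sp] - mf$means[2, sp]) / max(ssa_mean[sp], 1), 0.05)
  }
})

test_that("S-NEC accumulates committed complexes faster than S-PD (mean field)", {
  rc <- tn5_rates(k_ns_bind = 0, k_ns_unbind = 0)
  g <- genome_context(4e3)
  nec <- build_network("S_NEC", rc, g, scd(), 60)
  spd <- build_network("S_PD", rc, g, mono(), 60)
  grid <- seq(0, 7200, length.out = 25)
  mf_nec <- integrate_mean_field(nec, 7200, grid)
  mf_spd <- integrate_mean_field(spd, 7200, grid)
  committed <- function(m) m$means[, "PEC"] + m$means[, "DONE"]
  expect_true(all(committed(mf_nec)[-1] > committed(mf_spd)[-1]))
})
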