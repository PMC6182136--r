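test_that("S-NEC network has the expected labelled channel set", {
  net <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 60)
  expect_setequal(unique(net$label),
                  c("bind-L", "bind-R", "unbind-L", "unbind-R", "capture",
                    "complete", "ns-bind", "ns-unbind"))
  expect_length(unique(net$label), 8L)
  # natural dimers additionally expose subunit dissociation
  hs <- build_network("S_NEC", hsmar1_rates(), genome_context(4e3),
                      mutant_spec("NATURAL_DIMER"), 60)
  expect_true("multimer-dissoc" %in% hs$label)
  # S-PD swaps capture for a double-occupancy synapsis channel
  sp <- build_network("S_PD", tn5_rates(), genome_context(4e3), mono(), 60)
  expect_true("synapsis" %in% sp$label)
  expect_false("capture" %in% sp$label)
})

test_that("every reaction conserves transposase subunits and elements", {
  nets <- list(
    build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 60),
    build_network("S_PD", tn5_rates(), genome_context(4e3), mono(), 60),
    build_network("S_NEC", hsmar1_rates(), genome_context(4e6, n_elements = 3),
                  mutant_spec("NATURAL_DIMER"), 10),
    build_network("DOUBLE_DIMER_SPD", tn5_rates(), genome_context(4e3),
                  scd(), 60)
  )
  for (net in nets) expect_conserved(net)
})

test_that("synapsis propensities mirror each other across pathways", {
  nec <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 10)
  spd <- build_network("S_PD", tn5_rates(), genome_context(4e3), mono(), 10)
  mk_state <- function(net, ...) {
    st <- net$species * 0
    st[names(list(...))] <- unlist(list(...))
    st
  }
  # doubly occupied element: S-NEC is blocked, S-PD can synapse
  st_bb_nec <- mk_state(nec, T = 8, E_BB = 1)
  expect_equal(sum(propensities(nec, st_bb_nec)[nec$label == "capture"]), 0)
  st_bb_spd <- mk_state(spd, T = 8, E_BB = 1)
  expect_gt(sum(propensities(spd, st_bb_spd)[spd$label == "synapsis"]), 0)
  # singly occupied element: S-NEC captures, S-PD cannot synapse
  for (single in c("E_BF", "E_FB")) {
    st1 <- mk_state(nec, T = 9); st1[single] <- 1
    expect_gt(sum(propensities(nec, st1)[nec$label == "capture"]), 0)
    st2 <- mk_state(spd, T = 9); st2[single] <- 1
    expect_equal(sum(propensities(spd, st2)[spd$label == "synapsis"]), 0)
  }
})

test_that("genome length only enters through nonspecific binding", {
  no_ns <- tn5_rates(k_ns_bind = 0, k_ns_unbind = 0)
  a <- build_network("S_NEC", no_ns, genome_context(4e3), scd(), 60)
  b <- build_network("S_NEC", no_ns, genome_context(4e9), scd(), 60)
  expect_identical(propensities(a), propensities(b))
  # cis-acting removes sequestration entirely, even with k_ns_bind > 0
  ca <- build_network("S_NEC", tn5_rates(), genome_context(4e3, cis_acting = TRUE),
                      scd(), 60)
  cb <- build_network("S_NEC", tn5_rates(), genome_context(4e9, cis_acting = TRUE),
                      scd(), 60)
  expect_identical(propensities(ca), propensities(cb))
  expect_false("NS" %in% names(ca$species))
  expect_error(build_network("S_NEC", tn5_rates(),
                             genome_context(4e3, n_elements = 2, cis_acting = TRUE),
                             scd(), 60),
               "one network per element")
})

test_that("mutants reshape the network as expected", {
  wt <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 60)
  # wild type passes through apply_mutant unchanged
  expect_identical(apply_mutant(wt, scd()), wt)
  # G462D in either subunit zeroes the capture channel
  for (side in c("subunit_a_interface", "subunit_b_interface")) {
    args <- setNames(list("G462D"), side)
    g <- build_network("S_NEC", tn5_rates(), genome_context(4e3),
                       do.call(scd, args), 60)
    expect_equal(sum(g$rate_scaled[g$label == "capture"]), 0)
  }
  # ADE leaves the channel set and rates untouched
  ade <- build_network("S_NEC", tn5_rates(), genome_context(4e3),
                       scd(subunit_a_active_site = "ADE"), 60)
  expect_identical(ade$label, wt$label)
  expect_identical(ade$rate_scaled, wt$rate_scaled)
})

test_that("invalid pathway/architecture combinations are rejected", {
  expect_error(build_network("DOUBLE_DIMER_SPD", tn5_rates(), genome_context(4e3),
                             mono(), 60), "SINGLE_CHAIN_DIMER")
  expect_error(build_network("S_NEC", tn5_rates(), genome_context(4e3),
                             mono(), 60), "multimer")
  expect_error(build_network("S_PD", tn5_rates(), genome_context(4e3),
                             scd(), 60), "monomer")
  expect_error(build_network("S_NEC", tn5_rates(), genome_context(4e3),
                             scd(), -3), "transposase_count")
})

test_that("zero transposase means zero initial propensity everywhere", {
  net <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 0)
  expect_equal(sum(propensities(net)), 0)
})

test_that("cleavage-product map follows the engaged active sites", {
  # wild type single-chain dimer: both ends cut
  wt <- predict_cleavage_products(scd(), "S_NEC")
  expect_equal(unname(wt$products["DOUBLE_END_CUT"]), 1)
  expect_equal(wt$relative_activity, 1)
  # one ADE subunit: all cutting complexes are single-end
  for (side in c("subunit_a_active_site", "subunit_b_active_site")) {
    m <- do.call(scd, setNames(list("ADE"), side))
    pr <- predict_cleavage_products(m, "S_NEC")
    expect_equal(unname(pr$products["SINGLE_END_CUT"]), 1)
    expect_equal(unname(pr$products["DOUBLE_END_CUT"]), 0)
  }
  # both ADE: no cleavage at all
  both <- predict_cleavage_products(
    scd(subunit_a_active_site = "ADE", subunit_b_active_site = "ADE"), "S_NEC")
  expect_equal(unname(both$products["UNCUT"]), 1)
  # G462D abolishes S-NEC assembly entirely
  g <- predict_cleavage_products(scd(subunit_a_interface = "G462D"), "S_NEC")
  expect_equal(g$relative_activity, 0)
})

test_that("double-dimer enumeration gives 25% for one dead interface", {
  m <- scd(subunit_a_interface = "G462D")
  dd <- predict_cleavage_products(m, "DOUBLE_DIMER_SPD", engagement_bias = 0.5)
  expect_equal(dd$relative_activity, 0.25)
  expect_lte(dd$relative_activity, 0.5)
  # wild type double-dimer is fully active; engaged subunits random
  ddwt <- predict_cleavage_products(scd(subunit_b_active_site = "ADE"),
                                    "DOUBLE_DIMER_SPD", engagement_bias = 0.5)
  expect_equal(ddwt$relative_activity, 1)
  expect_equal(unname(ddwt$products),
               c(0.25, 0.5, 0.25))
  expect_error(predict_cleavage_products(m, "DOUBLE_DIMER_SPD", 1.2),
               "engagement_bias")
  expect_error(predict_cleavage_products(mono(), "S_NEC"), "dimer")
})

test_that("network descriptions serialize round-trip through JSON", {
  net <- build_network("S_NEC", tn5_rates(), genome_context(4e3), scd(), 60)
  js <- jsonlite::toJSON(describe_network(net), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(back$pathway, "S_NEC")
  expect_length(back$reactions, length(net$label))
  expect_equal(back$species$NS, 4000)
})
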