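# Archetype parameter sets and synthetic observation generators.
#
# The literature pins only two absolute numbers for these systems -- the
# Hsmar1-like multimer subunit-exchange rate (half-life ~3 h -> 6e-5 /s)
# and the Hsmar1-like single-end dwell time (~10 min -> k_unbind = 1/600 /s)
# -- plus qualitative orderings: the eukaryotic-style (HSMAR1) enzyme has
# high k1, low k-1, an attenuated k2 and weak nonspecific binding; the
# bacterial-style (TN5) enzyme has lower k1, sub-minute dwell (k-1 >= 1/60),
# and significant nonspecific binding.  All remaining magnitudes are pinned
# here, once, so that the reference in-vitro condition (7 nM two-ended
# substrate, 100 nM transposase, 4 h at 37 C) completes synapsis well
# within the incubation.

.archetype_defaults <- list(
  # Bacterial-style monomer: modest sequence-specific association, weak
  # single-end complex (k_unbind = 0.1 /s, a decision; only "sub-minute"
  # is constrained), significant nonspecific binding (Kd,ns = 100 uM,
  # ten-fold tighter than the eukaryotic-style archetype).
  TN5_MONOMER = list(
    k_bind = 1e5, k_unbind = 0.1, k_synapsis = 0.05, k_post = 0.01,
    k_ns_bind = 1e3, k_ns_unbind = 0.1,
    k_multimer_dissoc = 0, synapsis_attenuation = 1,
    pathway = "S_PD", architecture = "MONOMER"
  ),
  # Covalent single-chain dimer of the same enzyme: identical elementary
  # constants, but the pre-formed dimer assembles via naked-end capture.
  TN5_SCD = list(
    k_bind = 1e5, k_unbind = 0.1, k_synapsis = 0.05, k_post = 0.01,
    k_ns_bind = 1e3, k_ns_unbind = 0.1,
    k_multimer_dissoc = 0, synapsis_attenuation = 1,
    pathway = "S_NEC", architecture = "SINGLE_CHAIN_DIMER"
  ),
  # Eukaryotic-style natural dimer: two HTH domains give fast specific
  # association (k1 = 1e7 /M/s), 10-min dwell (k-1 = 1/600 /s), stable
  # dimer (6e-5 /s from the 3 h exchange half-life), weak nonspecific
  # binding (Kd,ns = 1 mM), and a conformational change after single-end
  # binding that attenuates capture 10-fold.
  HSMAR1 = list(
    k_bind = 1e7, k_unbind = 1 / 600, k_synapsis = 0.05, k_post = 0.01,
    k_ns_bind = 1e2, k_ns_unbind = 0.1,
    k_multimer_dissoc = 6e-5, synapsis_attenuation = 0.1,
    pathway = "S_NEC", architecture = "NATURAL_DIMER"
  )
)

#' Default assembly pathway and architecture of an archetype
#' @param name archetype name, see [archetype_names()]
#' @return list with elements `pathway` and `architecture`
#' @export
archetype_pathway <- function(name) {
  name <- match.arg(name, archetype_names())
  d <- .archetype_defaults[[name]]
  list(pathway = d$pathway, architecture = d$architecture)
}

#' Archetype rate constants, optionally jittered into an ensemble
#'
#' Returns the pinned default [rate_constants()] for an archetype, or an
#' ensemble of `n` draws with log-normal multiplicative jitter. Draws are
#' rejected until the qualitative orderings hold: every HSMAR1 draw has
#' `k_bind` above and `k_unbind` below the TN5 defaults and an attenuation
#' `< 1`; TN5 draws keep attenuation exactly 1 and `k_unbind >= 1/60`
#' (sub-minute dwell).
#'
#' @param name archetype name
#' @param seed integer seed (used when `jitter > 1` or `n > 1`)
#' @param jitter multiplicative spread (>= 1); `1` means the exact defaults
#' @param n ensemble size; `1` returns a single `rate_constants`
#' @return a `rate_constants` object, or a list of them with attributes
#'   `archetype` and `seed` when `n > 1`
#' @examples
#' make_archetype_params("HSMAR1")$k_multimer_dissoc  # 6e-5
#' @export
make_archetype_params <- function(name, seed = 1L, jitter = 1, n = 1L) {
  name <- match.arg(name, archetype_names())
  check_number(jitter, "jitter", 1)
  check_number(n, "n", 1)
  d <- .archetype_defaults[[name]]
  base <- rate_constants(
    k_bind = d$k_bind, k_unbind = d$k_unbind, k_synapsis = d$k_synapsis,
    k_post = d$k_post, k_ns_bind = d$k_ns_bind, k_ns_unbind = d$k_ns_unbind,
    k_multimer_dissoc = d$k_multimer_dissoc,
    synapsis_attenuation = d$synapsis_attenuation
  )
  if (jitter == 1 && n == 1) return(base)

  tn5 <- .archetype_defaults$TN5_MONOMER
  sdlog <- log(jitter)
  ok <- function(rc) {
    if (name == "HSMAR1") {
      rc$k_bind > tn5$k_bind && rc$k_unbind < tn5$k_unbind &&
        rc$synapsis_attenuation < 1
    } else {
      rc$k_unbind >= 1 / 60
    }
  }
  draw_one <- function() {
    repeat {
      rc <- base
      for (nm in c("k_bind", "k_unbind", "k_synapsis", "k_post",
                   "k_ns_bind", "k_ns_unbind", "k_multimer_dissoc")) {
        if (rc[[nm]] > 0) rc[[nm]] <- rc[[nm]] * rlnorm(1, 0, sdlog)
      }
      if (name == "HSMAR1") {
        rc$synapsis_attenuation <-
          min(0.999, base$synapsis_attenuation * rlnorm(1, 0, sdlog))
      }
      if (ok(rc)) return(rc)
    }
  }
  draws <- with_local_seed(seed, replicate(n, draw_one(), simplify = FALSE))
  if (n == 1) return(draws[[1]])
  structure(draws, archetype = name, seed = as.integer(seed),
            class = "archetype_ensemble")
}

#' Sample exponential dwell times
#'
#' Draws `n` i.i.d. exponential dwell times with the given true
#' dissociation rate; the memoryless single-step unbinding model implied
#' by a single k-1.
#'
#' @param true_rate dissociation rate, per second (> 0)
#' @param n sample size (>= 1)
#' @param seed integer seed
#' @return object of class `dwell_time_sample`: list with `times`,
#'   `true_rate`, `seed`
#' @export
sample_dwell_times <- function(true_rate, n, seed = 1L) {
  check_number(true_rate, "true_rate", 0, strict = TRUE)
  check_number(n, "n", 1)
  times <- with_local_seed(seed, rexp(n, rate = true_rate))
  structure(list(times = times, true_rate = true_rate,
                 seed = as.integer(seed)),
            class = "dwell_time_sample")
}

#' Maximum-likelihood recovery of a dissociation rate from dwell times
#'
#' For uncensored exponential observations the MLE is `n / sum(t)` and the
#' exact confidence interval follows from `2 * k * sum(t) ~ chi-square(2n)`.
#' With right-censoring at a horizon, the MLE is `d / total_time` (d =
#' uncensored events) with the interval based on `chi-square(2d)` degrees of
#' freedom (the standard censored-exponential approximation).
#'
#' @param sample a `dwell_time_sample`, or a numeric vector of times
#' @param censored optional logical vector marking horizon-truncated times
#' @param conf_level confidence level, default 0.95
#' @return list with `rate`, `ci` (length-2), `n`, `n_events`
#' @export
fit_dissociation_rate <- function(sample, censored = NULL, conf_level = 0.95) {
  times <- if (inherits(sample, "dwell_time_sample")) sample$times else sample
  if (!is.numeric(times) || length(times) < 2) {
    stopf("need at least two observations")
  }
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  stopifnot(length(censored) == length(times))
  total <- sum(times)
  d <- sum(!censored)
  if (d == 0 || total <= 0) stopf("no uncensored, positive dwell times")
  rate <- d / total
  alpha <- 1 - conf_level
  ci <- c(qchisq(alpha / 2, 2 * d), qchisq(1 - alpha / 2, 2 * d)) / (2 * total)
  list(rate = rate, ci = ci, n = length(times), n_events = d)
}

#' Regenerate a packaged fixture scenario
#'
#' Writes a JSON config plus golden TSV outputs for one of the packaged
#' scenarios. Regeneration with the same seed is bit-identical, which the
#' test suite uses as its determinism contract.
#'
#' Scenarios: `snec_basic` and `spd_basic` (single SSA trajectory grids),
#' `g462d_dead` (interface mutant; zero PEC events), `ade_single_end`
#' (cleavage product map), `hsmar1_opi` and `tn5_no_opi` (dose-response
#' tables with their OPI verdicts), `invasion_plateau` (invasion summary).
#'
#' @param scenario scenario name
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return invisibly, the files written
#' @export
generate_fixture_run <- function(scenario, seed = 1L, dir = tempfile("fixtures")) {
  scenarios <- c("snec_basic", "spd_basic", "g462d_dead", "ade_single_end",
                 "hsmar1_opi", "tn5_no_opi", "invasion_plateau")
  scenario <- match.arg(scenario, scenarios)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- list(scenario = scenario, seed = as.integer(seed))
  paths <- character(0)
  p <- function(f) file.path(dir, f)

  small_net <- function(arch_name, mutant = NULL) {
    arch <- archetype_pathway(arch_name)
    if (is.null(mutant)) mutant <- mutant_spec(arch$architecture)
    build_network(arch$pathway, make_archetype_params(arch_name),
                  genome_context(4e3), mutant,
                  transposase_count = concentration_to_count(100e-9, 1e-15))
  }

  if (scenario %in% c("snec_basic", "spd_basic")) {
    arch_name <- if (scenario == "snec_basic") "TN5_SCD" else "TN5_MONOMER"
    net <- small_net(arch_name)
    traj <- simulate_ssa(net, horizon = 600, seed = seed,
                         record_grid = seq(0, 600, by = 60))
    tab <- as.data.frame(traj$snapshots)
    tab <- cbind(time = traj$snapshot_times, tab)
    paths <- write_table_tsv(tab, p("trajectory.tsv"), cfg)
  } else if (scenario == "g462d_dead") {
    mut <- mutant_spec("SINGLE_CHAIN_DIMER", subunit_a_interface = "G462D")
    net <- small_net("TN5_SCD", mut)
    fp <- sample_first_passage(net, target = "PEC", reps = 50, seed = seed,
                               horizon = 3600)
    tab <- data.frame(rep = seq_along(fp$times), time = fp$times,
                      censored = fp$censored)
    paths <- write_table_tsv(tab, p("first_passage.tsv"), cfg)
  } else if (scenario == "ade_single_end") {
    mut <- mutant_spec("SINGLE_CHAIN_DIMER", subunit_b_active_site = "ADE")
    pred <- predict_cleavage_products(mut, "S_NEC")
    tab <- data.frame(product = names(pred$products),
                      fraction = as.numeric(pred$products),
                      relative_activity = pred$relative_activity)
    paths <- write_table_tsv(tab, p("products.tsv"), cfg)
  } else if (scenario %in% c("hsmar1_opi", "tn5_no_opi")) {
    arch_name <- if (scenario == "hsmar1_opi") "HSMAR1" else "TN5_SCD"
    arch <- archetype_pathway(arch_name)
    tab <- dose_response(arch$pathway, make_archetype_params(arch_name),
                         genome_context(4e3),
                         mutant_spec(arch$architecture),
                         reps = 100, seed = seed)
    verdict <- detect_opi(tab)
    cfg$is_opi <- verdict$is_opi
    paths <- write_table_tsv(tab, p("dose_response.tsv"), cfg)
  } else if (scenario == "invasion_plateau") {
    host <- host_params(replicates = 50, seed = seed, generations = 100)
    inv <- run_invasion("S_NEC", make_archetype_params("HSMAR1"),
                        genome_context(3e9, volume_liters = 1e-12),
                        host, mutant_spec("NATURAL_DIMER"))
    tab <- summarize_invasion(inv)$table
    paths <- write_table_tsv(tab, p("invasion.tsv"), cfg)
  }
  invisible(paths)
}
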