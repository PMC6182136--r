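# Shared fixtures: all built in code, nothing on disk.

tn5_rates <- function(...) {
  mod <- list(...)
  rc <- make_archetype_params("TN5_SCD")
  for (nm in names(mod)) rc[[nm]] <- mod[[nm]]
  rc
}

hsmar1_rates <- function() make_archetype_params("HSMAR1")

scd <- function(...) mutant_spec("SINGLE_CHAIN_DIMER", ...)
mono <- function(...) mutant_spec("MONOMER", ...)

# assert that every reaction conserves transposase subunits and elements
expect_conserved <- function(net) {
  for (w in net$conservation) {
    drift <- as.numeric(t(w) %*% net$nu)
    expect_equal(max(abs(drift)), 0)
  }
}

# a first_passage_sample built from raw times (for estimator tests)
fp_sample <- function(times, censored = rep(FALSE, length(times))) {
  tt <- times[!censored]
  structure(
    list(times = times, censored = censored,
         mean = if (length(tt)) mean(tt) else NA_real_,
         median = if (length(tt)) stats::median(tt) else NA_real_,
         se = if (length(tt) > 1) stats::sd(tt) / sqrt(length(tt)) else NA_real_,
         censoring_fraction = mean(censored), n = length(times),
         target = "PEC", horizon = Inf, seed = 0L),
    class = "first_passage_sample"
  )
}
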