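# Dose-response and genome-size sweeps, rate estimation from first-passage
# samples, and over-production inhibition (OPI) detection.

#' Default transposase dose grid
#'
#' Nine logarithmic points spanning 1e-2 to 1e2 times the reference
#' end-pair concentration (7 nM, the standard two-ended substrate).
#' @param center reference concentration, molar
#' @param points number of grid points
#' @param span fold-range on each side
#' @return increasing molar concentrations
#' @export
default_dose_grid <- function(center = 7e-9, points = 9L, span = 100) {
  10^seq(log10(center / span), log10(center * span), length.out = points)
}

#' Default genome-size grid
#'
#' Seven logarithmic points from the 4 kb in-vitro plasmid to a 4 Gb
#' genome.
#' @return increasing sizes in base pairs
#' @export
default_size_grid <- function() {
  round(10^seq(log10(4e3), log10(4e9), length.out = 7))
}

#' Transposition rate from a first-passage sample
#'
#' The rate is operationalized as the reciprocal mean first-passage time,
#' `1 / mean(uncensored)`, with a delta-method standard error
#' `sd / (mean^2 * sqrt(n))`. A fully censored sample reports rate 0; a
#' single uncensored observation reports `1/t` with an undefined (NA) SE.
#'
#' @param fp a `first_passage_sample` from [sample_first_passage()]
#' @return list with `rate`, `se`, `censoring_fraction`, `n_uncensored`
#' @export
estimate_transposition_rate <- function(fp) {
  stopifnot(inherits(fp, "first_passage_sample"))
  tt <- fp$times[!fp$censored]
  n <- length(tt)
  if (n == 0) {
    return(list(rate = 0, se = NA_real_, censoring_fraction = 1,
                n_uncensored = 0L))
  }
  m <- mean(tt)
  se <- if (n > 1) sd(tt) / (m^2 * sqrt(n)) else NA_real_
  list(rate = 1 / m, se = se, censoring_fraction = fp$censoring_fraction,
       n_uncensored = as.integer(n))
}

sweep_point <- function(pathway, rates, genome, mutant, count, reps, seed,
                        horizon, target) {
  net <- build_network(pathway, rates, genome, mutant, transposase_count = count)
  fp <- sample_first_passage(net, target = target, reps = reps, seed = seed,
                             horizon = horizon)
  estimate_transposition_rate(fp)
}

#' Transposase dose-response of the transposition rate
#'
#' For each concentration on the grid, builds the network, samples
#' first-passage times to the commitment point (`PEC` by default; synapsis
#' is irreversible and commits the element) and converts them to a rate.
#' Deterministic given `seed`.
#'
#' @param pathway one of [pathway_kinds()]
#' @param rates a [rate_constants()]
#' @param genome a [genome_context()]
#' @param mutant a [mutant_spec()]
#' @param conc_grid strictly increasing molar concentrations (>= 0)
#' @param reps replicates per grid point (>= 2)
#' @param seed integer seed
#' @param horizon per-replicate horizon, seconds (default the 4 h
#'   reference incubation)
#' @param target `"PEC"` (default) or `"DONE"`
#' @return a `dose_response_table` data.frame with columns `grid_value`
#'   (molar), `mean_rate`, `se`, `reps`, `censored_fraction`
#' @export
dose_response <- function(pathway, rates, genome, mutant,
                          conc_grid = default_dose_grid(), reps = 500L,
                          seed = 1L, horizon = 14400, target = "PEC") {
  if (length(conc_grid) < 1 || any(diff(conc_grid) <= 0) || any(conc_grid < 0)) {
    stopf("'conc_grid' must be non-empty, strictly increasing and >= 0")
  }
  check_number(reps, "reps", 2)
  rows <- lapply(seq_along(conc_grid), function(i) {
    count <- concentration_to_count(conc_grid[i], genome$volume_liters)
    est <- sweep_point(pathway, rates, genome, mutant, count, reps,
                       derive_seed(seed, i), horizon, target)
    data.frame(grid_value = conc_grid[i], mean_rate = est$rate,
               se = est$se, reps = as.integer(reps),
               censored_fraction = est$censoring_fraction)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "grid") <- "transposase_concentration_M"
  attr(tab, "seed") <- as.integer(seed)
  class(tab) <- c("dose_response_table", "data.frame")
  tab
}

#' Genome-size response of the transposition rate
#'
#' Same estimator as [dose_response()], sweeping the amount of nonspecific
#' DNA at a fixed transposase concentration. With `k_ns_bind > 0`,
#' nonspecific sites sequester transposase in proportion to genome size;
#' with `cis_acting = TRUE` the sweep is flat by construction.
#'
#' @inheritParams dose_response
#' @param conc fixed transposase concentration, molar (> 0)
#' @param size_grid strictly increasing genome sizes, base pairs
#' @param cis_acting logical, passed to [genome_context()]
#' @param volume_liters reaction volume
#' @return a `genome_size_table` data.frame with columns `grid_value` (bp),
#'   `mean_rate`, `se`, `reps`, `censored_fraction`
#' @export
genome_size_response <- function(pathway, rates, conc,
                                 size_grid = default_size_grid(),
                                 mutant = mutant_spec("MONOMER"),
                                 reps = 200L, seed = 1L,
                                 cis_acting = FALSE, volume_liters = 1e-15,
                                 horizon = 14400, target = "PEC") {
  if (length(size_grid) < 1 || any(diff(size_grid) <= 0)) {
    stopf("'size_grid' must be strictly increasing")
  }
  check_number(conc, "conc", 0, strict = TRUE)
  count <- concentration_to_count(conc, volume_liters)
  rows <- lapply(seq_along(size_grid), function(i) {
    genome <- genome_context(size_grid[i], volume_liters = volume_liters,
                             cis_acting = cis_acting)
    est <- sweep_point(pathway, rates, genome, mutant, count, reps,
                       derive_seed(seed, i), horizon, target)
    data.frame(grid_value = size_grid[i], mean_rate = est$rate,
               se = est$se, reps = as.integer(reps),
               censored_fraction = est$censoring_fraction)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "grid") <- "genome_size_bp"
  attr(tab, "conc") <- conc
  attr(tab, "seed") <- as.integer(seed)
  class(tab) <- c("genome_size_table", "data.frame")
  tab
}

#' Detect over-production inhibition in a dose-response table
#'
#' OPI is called when some interior grid point's mean rate exceeds both
#' the lowest- and the highest-concentration rates by more than `z_crit`
#' pooled standard errors (quadrature pooling; an undefined SE, e.g. from
#' a fully censored point, contributes 0).
#'
#' @param table a `dose_response_table`, or any data.frame with columns
#'   `grid_value`, `mean_rate`, `se`
#' @param z_crit significance threshold in pooled-SE units, default 3
#' @return object of class `opi_verdict`: list with `is_opi`,
#'   `peak_concentration`, `peak_index`, `z_vs_first`, `z_vs_last`
#' @export
detect_opi <- function(table, z_crit = 3) {
  stopifnot(is.data.frame(table),
            all(c("grid_value", "mean_rate", "se") %in% names(table)))
  n <- nrow(table)
  if (n < 3) stopf("need at least 3 grid points to call OPI")
  r <- table$mean_rate
  s <- ifelse(is.na(table$se), 0, table$se)
  interior <- 2:(n - 1)
  peak_index <- interior[which.max(r[interior])]
  pooled <- function(i, j) sqrt(s[i]^2 + s[j]^2)
  z1 <- (r[peak_index] - r[1]) / max(pooled(peak_index, 1), .Machine$double.eps)
  z2 <- (r[peak_index] - r[n]) / max(pooled(peak_index, n), .Machine$double.eps)
  is_opi <- (r[peak_index] > r[1] && r[peak_index] > r[n] &&
               z1 > z_crit && z2 > z_crit)
  structure(
    list(is_opi = is_opi,
         peak_concentration = if (is_opi) table$grid_value[peak_index] else NA_real_,
         peak_index = peak_index, z_vs_first = z1, z_vs_last = z2,
         z_crit = z_crit),
    class = "opi_verdict"
  )
}

#' @export
print.opi_verdict <- function(x, ...) {
  cat(sprintf("<opi_verdict> is_opi=%s (peak index %d; z vs first %.2f, z vs last %.2f)\n",
              x$is_opi, x$peak_index, x$z_vs_first, x$z_vs_last))
  invisible(x)
}

#' Spearman monotonicity of a sweep table
#'
#' Rank correlation of the grid means against the grid, the package's
#' operational reading of qualitative "increases/decreases with"
#' statements.
#'
#' @param table sweep table with `grid_value` and `mean_rate`
#' @return list with `rho` and `p_value`
#' @export
monotone_trend <- function(table) {
  ct <- suppressWarnings(
    cor.test(table$grid_value, table$mean_rate, method = "spearman")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
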