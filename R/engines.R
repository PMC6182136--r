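# Execution engines: exact SSA (C++ direct method), batched first-passage
# sampling, and mean-field ODE integration (adaptive Cash-Karp RK45;
# hand-rolled because no ODE solver package is assumed).

#' Exact stochastic simulation of a reaction network
#'
#' Gillespie direct method: exponential waiting time on the total
#' propensity, channel chosen proportionally. Identical
#' `(network, horizon, seed)` triples yield bit-identical trajectories.
#' All-zero propensity is a clean termination (`status = "exhausted"`),
#' not an error; hitting `max_events` gives `status = "event_cap"`.
#'
#' @param network a `reaction_network`
#' @param horizon simulation horizon, seconds (> 0)
#' @param seed integer seed
#' @param max_events event cap (>= 1)
#' @param record_grid time points at which to snapshot the state; defaults
#'   to 101 evenly spaced points on `[0, horizon]`
#' @param max_record_events cap on the stored per-event log
#' @return object of class `ssa_trajectory`: list with `snapshot_times`,
#'   `snapshots` (matrix, species in columns), `event_times`,
#'   `event_labels`, `final_state`, `status`, `seed`, `n_events`
#' @export
simulate_ssa <- function(network, horizon, seed = 1L, max_events = 1e7,
                         record_grid = NULL, max_record_events = 1e5) {
  stopifnot(inherits(network, "reaction_network"))
  check_number(horizon, "horizon", 0, strict = TRUE)
  check_number(max_events, "max_events", 1)
  if (is.null(record_grid)) {
    record_grid <- seq(0, horizon, length.out = 101)
  }
  record_grid <- sort(record_grid[record_grid <= horizon])
  res <- cpp_ssa_trajectory(unname(network$species), network$react,
                            network$nu, network$rate_scaled,
                            horizon, as.double(seed), max_events,
                            record_grid, as.integer(max_record_events))
  snaps <- res$snapshots
  colnames(snaps) <- names(network$species)
  structure(
    list(snapshot_times = record_grid, snapshots = snaps,
         event_times = res$event_times,
         event_labels = network$label[res$event_channels],
         final_state = setNames(res$final_state, names(network$species)),
         n_events = res$n_events,
         status = c("horizon", "exhausted", "event_cap")[res$status + 1],
         seed = as.integer(seed), horizon = horizon),
    class = "ssa_trajectory"
  )
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory> %g events, status=%s, seed=%d\n",
              x$n_events, x$status, x$seed))
  cat("  final state:",
      paste(sprintf("%s=%g", names(x$final_state), x$final_state),
            collapse = ", "), "\n")
  invisible(x)
}

#' First-passage times of a species threshold under the SSA
#'
#' Runs `reps` independent exact trajectories and records the first time
#' `target` reaches `threshold` copies. Replicates that do not reach it by
#' `horizon` are censored (a reported outcome, not an error); summary
#' statistics are computed on the uncensored values.
#'
#' @param network a `reaction_network`
#' @param target species name (e.g. `"PEC"` or `"DONE"`)
#' @param reps replicate count (>= 1)
#' @param seed integer seed; replicate r uses a derived substream
#' @param horizon per-replicate horizon, seconds
#' @param threshold copies required, default 1
#' @param max_events per-replicate event cap
#' @return object of class `first_passage_sample`: list with `times`,
#'   `censored`, `mean`, `median`, `se`, `censoring_fraction`, `n`
#' @export
sample_first_passage <- function(network, target = "PEC", reps = 100L,
                                 seed = 1L, horizon = 14400,
                                 threshold = 1, max_events = 1e7) {
  stopifnot(inherits(network, "reaction_network"))
  check_number(reps, "reps", 1)
  check_number(horizon, "horizon", 0, strict = TRUE)
  ti <- match(target, names(network$species))
  if (is.na(ti)) stopf("unknown target species '%s'", target)
  res <- cpp_first_passage(unname(network$species), network$react,
                           network$nu, network$rate_scaled,
                           ti, threshold, horizon, as.integer(reps),
                           as.double(seed), max_events)
  tt <- res$times[!res$censored]
  structure(
    list(times = res$times, censored = res$censored,
         mean = if (length(tt)) mean(tt) else NA_real_,
         median = if (length(tt)) median(tt) else NA_real_,
         se = if (length(tt) > 1) sd(tt) / sqrt(length(tt)) else NA_real_,
         censoring_fraction = mean(res$censored),
         n = as.integer(reps), target = target, horizon = horizon,
         seed = as.integer(seed)),
    class = "first_passage_sample"
  )
}

#' Mean-field (deterministic) integration of a reaction network
#'
#' Integrates the mass-action ODE system over species means with an
#' adaptive Cash-Karp Runge-Kutta 4(5) scheme. Conserved totals are
#' preserved along the solution to within `10 * tol` (relative).
#'
#' @param network a `reaction_network`
#' @param horizon integration horizon, seconds (> 0)
#' @param grid output time points; defaults to 101 evenly spaced points
#' @param tol relative tolerance (> 0)
#' @return list with `times`, `means` (matrix, species in columns)
#' @export
integrate_mean_field <- function(network, horizon, grid = NULL, tol = 1e-8) {
  stopifnot(inherits(network, "reaction_network"))
  check_number(horizon, "horizon", 0, strict = TRUE)
  check_number(tol, "tol", 0, strict = TRUE)
  if (is.null(grid)) grid <- seq(0, horizon, length.out = 101)
  grid <- sort(unique(c(0, grid[grid <= horizon])))

  nu <- network$nu
  deriv <- function(x) {
    a <- propensities_mean(network, x)
    as.numeric(nu %*% a)
  }
  out <- rk45_integrate(deriv, unname(network$species), grid, tol)
  if (any(!is.finite(out))) {
    stopf("mean-field integrator failed; last state: %s",
          paste(signif(out[max(which(apply(is.finite(out), 1, all))), ], 4),
                collapse = ", "))
  }
  colnames(out) <- names(network$species)
  list(times = grid, means = out)
}

# mass-action propensity at (possibly fractional) mean counts
propensities_mean <- function(network, state) {
  a <- network$rate_scaled
  react <- network$react
  for (j in seq_along(a)) {
    idx <- which(react[, j] > 0)
    for (i in idx) a[j] <- a[j] * max(state[i], 0)^react[i, j]
  }
  a
}

# Cash-Karp RK45 with step-doubling error control; returns states at grid
rk45_integrate <- function(deriv, y0, grid, tol) {
  # Cash-Karp tableau
  b <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(3 / 10, -9 / 10, 6 / 5),
    c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
    c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
  )
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  y <- y0
  t <- grid[1]
  out <- matrix(NA_real_, length(grid), length(y0))
  out[1, ] <- y
  gi <- 2L
  scale0 <- max(sum(abs(y0)), 1)
  h <- (grid[length(grid)] - t) / 1000
  max_steps <- 2e6
  step <- 0L
  while (gi <= length(grid) && step < max_steps) {
    step <- step + 1L
    target <- grid[gi]
    h <- min(h, target - t)
    k <- matrix(0, length(y), 6)
    k[, 1] <- deriv(y)
    for (s in 2:6) {
      yi <- y + h * as.numeric(k[, 1:(s - 1), drop = FALSE] %*% b[[s - 1]])
      k[, s] <- deriv(yi)
    }
    y5 <- y + h * as.numeric(k %*% c5)
    y4 <- y + h * as.numeric(k %*% c4)
    err <- max(abs(y5 - y4)) / (tol * max(scale0, sum(abs(y5))))
    if (!is.finite(err)) {
      h <- h / 10
      if (h <= 0 || !is.finite(h)) stopf("mean-field integrator step underflow")
      next
    }
    if (err <= 1) {
      t <- t + h
      y <- pmax(y5, 0)
      while (gi <= length(grid) && t >= grid[gi] - 1e-12 * max(1, abs(t))) {
        out[gi, ] <- y
        gi <- gi + 1L
      }
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.25))
    }
    if (h < 1e-14 * max(1, abs(t))) stopf("mean-field integrator step underflow")
  }
  out
}
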