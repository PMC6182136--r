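# Generation-based simulation of a transposon invading a genome.
#
# The per-generation transposition probability of each element comes from a
# mean-field first-passage approximation of the kinetic model: the free
# transposase concentration is set by the expression model (trans-acting,
# proportional to copy number, or cis-acting and constant) discounted by
# nonspecific-DNA sequestration at equilibrium; the element-level chain
# (free/free -> single-bound -> double-bound, synapsis per pathway) is then
# solved exactly for its mean first-passage time to synapsis.

#' Host and expression parameters for an invasion run
#'
#' @param generations number of host generations to simulate (>= 1);
#'   default 200, long enough for an S-NEC invasion to reach its
#'   self-limited plateau
#' @param generation_time seconds per generation; default 86400 s (one day,
#'   a eukaryotic cell cycle)
#' @param transposase_per_copy molar transposase contributed per element
#'   copy under trans-acting expression
#' @param cis_local_concentration molar transposase seen by each element
#'   under cis-acting expression (used when the genome context is cis)
#' @param inhibitor_per_copy molar trans-acting inhibitor per element copy
#' @param inhibitor_Ki inhibition constant, molar; the synapsis rate is
#'   scaled by `1 / (1 + I / Ki)` (competitive reduction of k2)
#' @param duplication_probability probability a transposition event adds a
#'   copy (cut-and-paste gap repair from the sister), default 1
#' @param copy_cap maximum copy number (runtime bound), default 10000
#' @param initial_copies starting copy number
#' @param replicates number of independent lineages
#' @param seed integer seed
#' @param shared_end_pool logical; when TRUE (default) the S-NEC capture
#'   rate is additionally scaled by the genome-wide fraction of naked ends,
#'   modelling competition for naked ends in the nuclear pool
#' @param target `"PEC"`-equivalent commitment is always used here (the
#'   chain ends at synapsis); kept for interface symmetry
#' @return object of class `host_params`
#' @export
host_params <- function(generations = 200L, generation_time = 86400,
                        transposase_per_copy = 1e-9,
                        cis_local_concentration = 0,
                        inhibitor_per_copy = 0, inhibitor_Ki = Inf,
                        duplication_probability = 1, copy_cap = 10000L,
                        initial_copies = 1L, replicates = 200L, seed = 1L,
                        shared_end_pool = TRUE, target = "PEC") {
  check_number(generations, "generations", 1)
  check_number(generation_time, "generation_time", 0, strict = TRUE)
  check_number(transposase_per_copy, "transposase_per_copy", 0)
  check_number(cis_local_concentration, "cis_local_concentration", 0)
  check_number(inhibitor_per_copy, "inhibitor_per_copy", 0)
  if (!identical(inhibitor_Ki, Inf)) check_number(inhibitor_Ki, "inhibitor_Ki", 0, strict = TRUE)
  check_number(duplication_probability, "duplication_probability", 0)
  if (duplication_probability > 1) stopf("'duplication_probability' must be in [0, 1]")
  check_number(copy_cap, "copy_cap", 1)
  check_number(initial_copies, "initial_copies", 0)
  if (copy_cap < initial_copies) stopf("'copy_cap' must be >= initial_copies")
  check_number(replicates, "replicates", 1)
  structure(
    list(generations = as.integer(generations),
         generation_time = generation_time,
         transposase_per_copy = transposase_per_copy,
         cis_local_concentration = cis_local_concentration,
         inhibitor_per_copy = inhibitor_per_copy,
         inhibitor_Ki = inhibitor_Ki,
         duplication_probability = duplication_probability,
         copy_cap = as.integer(copy_cap),
         initial_copies = as.integer(initial_copies),
         replicates = as.integer(replicates), seed = as.integer(seed),
         shared_end_pool = isTRUE(shared_end_pool), target = target),
    class = "host_params"
  )
}

# exact MFPT of the element-level chain FF -> {S} -> BB with synapsis from
# S (S-NEC, rate s) or from BB (S-PD, rate s); b = per-end binding rate,
# u = per-end unbinding rate
element_mfpt <- function(pathway, b, u, s) {
  if (b <= 0 || s <= 0) return(Inf)
  if (pathway %in% c("S_PD", "DOUBLE_DIMER_SPD")) {
    # t_BB = 1/(2u+s) + 2u/(2u+s) t_S ; t_S = 1/(u+b) + (u t_FF + b t_BB)/(u+b)
    # t_FF = 1/(2b) + t_S
    A <- matrix(c(
      1, -1, 0,
      -u / (u + b), 1, -b / (u + b),
      0, -2 * u / (2 * u + s), 1
    ), 3, 3, byrow = TRUE)
    rhs <- c(1 / (2 * b), 1 / (u + b), 1 / (2 * u + s))
    sol <- tryCatch(solve(A, rhs), error = function(e) rep(Inf, 3))
    return(sol[1])
  }
  # S-NEC: synapsis from the single-bound state; BB is the OPI block
  if (u <= 0) return(Inf) # BB would be a dead end
  t_S <- (1 + u / (2 * b) + b / (2 * u)) / s
  1 / (2 * b) + t_S
}

#' Per-element transposition probability for one generation
#'
#' Computes the effective transposase concentration from the expression
#' model, discounts it by equilibrium nonspecific-DNA sequestration, scales
#' the synapsis rate by the competitive inhibitor factor `1/(1 + I/Ki)`
#' (and, for S-NEC with a shared end pool, by the genome-wide naked-end
#' fraction), solves the element chain for its mean first-passage time to
#' synapsis, and returns `1 - exp(-rate * generation_time)`.
#'
#' @param copies current element copy number (>= 0)
#' @param pathway one of [pathway_kinds()]
#' @param rates a [rate_constants()]
#' @param genome a [genome_context()] (its `cis_acting` flag selects the
#'   expression model)
#' @param host a [host_params()]
#' @return probability in \[0, 1\]
#' @export
per_generation_rate <- function(copies, pathway, rates, genome, host) {
  pathway <- match.arg(pathway, pathway_kinds())
  check_number(copies, "copies", 0)
  if (copies == 0) return(0)

  T_tot <- if (genome$cis_acting) host$cis_local_concentration else
    host$transposase_per_copy * copies
  if (T_tot <= 0) return(0)

  # equilibrium sequestration by nonspecific sites (site excess regime)
  T_free <- T_tot
  if (!genome$cis_acting && rates$k_ns_bind > 0 && rates$k_ns_unbind > 0) {
    s_conc <- floor(genome$genome_length_bp / genome$nonspecific_site_spacing_bp) /
      (AVOGADRO * genome$volume_liters)
    kd_ns <- rates$k_ns_unbind / rates$k_ns_bind
    T_free <- T_tot * kd_ns / (kd_ns + s_conc)
  }

  inh <- 1
  if (host$inhibitor_per_copy > 0 && is.finite(host$inhibitor_Ki)) {
    inh <- 1 / (1 + host$inhibitor_per_copy * copies / host$inhibitor_Ki)
  }

  b <- rates$k_bind * T_free
  u <- rates$k_unbind
  if (pathway == "S_NEC") {
    s <- rates$k_synapsis * rates$synapsis_attenuation * inh
    if (host$shared_end_pool && b + u > 0) s <- s * u / (u + b)
  } else {
    s <- rates$k_synapsis * inh
    if (pathway == "DOUBLE_DIMER_SPD") {
      # competence handled at network level; invasion assumes wild type
    }
  }
  mfpt <- element_mfpt(pathway, b, u, s)
  if (!is.finite(mfpt) || mfpt <= 0) return(if (mfpt <= 0) 1 else 0)
  1 - exp(-host$generation_time / mfpt)
}

#' Simulate a transposon genomic invasion
#'
#' Per generation, each element transposes independently with the
#' probability from [per_generation_rate()]; each transposition event adds
#' a copy with `duplication_probability`. Copy numbers are capped at
#' `copy_cap` (capped lineages are flagged, not an error). Stochastic and
#' seed-reproducible.
#'
#' @param pathway one of [pathway_kinds()]
#' @param rates a [rate_constants()]
#' @param genome a [genome_context()]
#' @param host a [host_params()]
#' @param mutant a [mutant_spec()]; a G462D interface mutant cannot
#'   synapse and never amplifies
#' @return object of class `invasion_trajectory`: list with `copies`
#'   (matrix, replicates x generations+1), `events` (same shape, realized
#'   transposition events per generation), `capped` (logical per
#'   replicate), plus the config echo
#' @export
run_invasion <- function(pathway, rates, genome, host,
                         mutant = mutant_spec("NATURAL_DIMER")) {
  pathway <- match.arg(pathway, pathway_kinds())
  stopifnot(inherits(rates, "rate_constants"),
            inherits(genome, "genome_context"),
            inherits(host, "host_params"),
            inherits(mutant, "mutant_spec"))
  dead <- has_g462d(mutant)
  R <- host$replicates
  G <- host$generations
  copies <- matrix(0L, R, G + 1)
  events <- matrix(0L, R, G + 1)
  copies[, 1] <- host$initial_copies
  p_cache <- new.env(hash = TRUE, parent = emptyenv())
  p_of <- function(n) {
    if (dead || n == 0) return(0)
    k <- as.character(n)
    p <- p_cache[[k]]
    if (is.null(p)) {
      p <- per_generation_rate(n, pathway, rates, genome, host)
      p_cache[[k]] <- p
    }
    p
  }
  with_local_seed(host$seed, {
    for (g in seq_len(G)) {
      cur <- copies[, g]
      for (n in unique(cur)) {
        idx <- which(cur == n)
        p <- p_of(n)
        ev <- if (p > 0) rbinom(length(idx), n, p) else integer(length(idx))
        gain <- if (host$duplication_probability >= 1) ev else
          rbinom(length(idx), ev, host$duplication_probability)
        events[idx, g + 1] <- ev
        copies[idx, g + 1] <- pmin(n + gain, host$copy_cap)
      }
    }
  })
  structure(
    list(copies = copies, events = events,
         capped = copies[, G + 1] >= host$copy_cap,
         pathway = pathway, rates = rates, genome = genome, host = host,
         mutant = mutant),
    class = "invasion_trajectory"
  )
}

#' Summarize an invasion trajectory
#'
#' Per-generation mean, SD and quantiles of copy number across replicates,
#' plus a plateau flag: the mean copy-number increment over the final 10%
#' of generations is below 10% of the peak per-generation increment of the
#' mean trajectory. A constant trajectory (zero peak increment) counts as
#' a plateau.
#'
#' @param traj an `invasion_trajectory`
#' @return list with `table` (data.frame: generation, mean_copies, sd,
#'   q05, q50, q95), `plateau` (logical), `final_mean`, `final_se`,
#'   `peak_increment`, `final_increment`
#' @export
summarize_invasion <- function(traj) {
  stopifnot(inherits(traj, "invasion_trajectory"))
  cp <- traj$copies
  G <- ncol(cp) - 1
  tab <- data.frame(
    generation = 0:G,
    mean_copies = colMeans(cp),
    sd = apply(cp, 2, sd),
    q05 = apply(cp, 2, quantile, probs = 0.05),
    q50 = apply(cp, 2, quantile, probs = 0.50),
    q95 = apply(cp, 2, quantile, probs = 0.95)
  )
  inc <- diff(tab$mean_copies)
  peak <- if (length(inc)) max(inc) else 0
  tail_n <- max(1L, floor(0.1 * G))
  final_inc <- mean(inc[(length(inc) - tail_n + 1):length(inc)])
  plateau <- if (peak <= 0) TRUE else final_inc < 0.1 * peak
  list(table = tab, plateau = plateau,
       final_mean = tab$mean_copies[G + 1],
       final_se = tab$sd[G + 1] / sqrt(nrow(cp)),
       peak_increment = peak, final_increment = final_inc)
}
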