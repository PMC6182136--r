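# Reaction-network construction for the two transpososome assembly
# pathways, plus the combinatorial mutant predictions.
#
# Species (per network):
#   T     free transposase binding unit (a dimer in S-NEC, a monomer in
#         S-PD, a single-chain dimer in the double-dimer variant)
#   TMONO inert monomer produced by natural-dimer subunit dissociation
#   E_FF / E_BF / E_FB / E_BB   elements by end occupancy (L/R)
#   PEC   synapsed paired-ends complex (commitment point)
#   DONE  completed transposition (absorbing)
#   NS    free nonspecific DNA sites; TNS  nonspecifically bound transposase
#
# In S-NEC the unit bound at one end captures the naked partner end
# (unimolecular, k2 * attenuation); a doubly occupied element (E_BB) has no
# synapsis channel and is the OPI-blocked state, exiting only by unbinding.
# In S-PD synapsis requires double occupancy: E_BB -> PEC at k2.

#' The closed enumeration of assembly pathways
#' @return character vector
#' @export
pathway_kinds <- function() c("S_NEC", "S_PD", "DOUBLE_DIMER_SPD")

#' Build the mass-action reaction network for one assembly scenario
#'
#' Constructs species, initial counts, and labelled reaction channels for
#' the chosen pathway, genome context and mutant. Bimolecular propensity
#' constants are pre-scaled by `1 / (N_A * volume)` so propensities are in
#' events per second given molecule counts.
#'
#' Channel labels for S-NEC with nonspecific binding: `bind-L`, `bind-R`,
#' `unbind-L`, `unbind-R`, `capture`, `complete`, `ns-bind`, `ns-unbind`
#' (natural dimers add `multimer-dissoc`). S-PD replaces `capture` with
#' `synapsis`, which fires only from the doubly occupied element.
#'
#' `cis_acting = TRUE` removes nonspecific sequestration from the
#' specific-binding competition (the element sees only its private, locally
#' translated pool); it requires `n_elements == 1` (one network per element).
#'
#' @param pathway one of [pathway_kinds()]
#' @param rates a [rate_constants()] object
#' @param genome a [genome_context()] object
#' @param mutant a [mutant_spec()] object
#' @param transposase_count number of free transposase binding units at t = 0
#' @return an object of class `reaction_network`
#' @examples
#' net <- build_network("S_NEC", make_archetype_params("TN5_SCD"),
#'                      genome_context(4e3), mutant_spec("SINGLE_CHAIN_DIMER"),
#'                      transposase_count = 60)
#' length(unique(net$label))  # 8 labelled channels
#' @export
build_network <- function(pathway, rates, genome, mutant, transposase_count) {
  pathway <- match.arg(pathway, pathway_kinds())
  stopifnot(inherits(rates, "rate_constants"),
            inherits(genome, "genome_context"),
            inherits(mutant, "mutant_spec"))
  check_number(transposase_count, "transposase_count", 0)

  arch <- mutant$architecture
  if (pathway == "S_NEC" && arch == "MONOMER") {
    stopf("S_NEC requires a pre-formed multimer (SINGLE_CHAIN_DIMER or NATURAL_DIMER)")
  }
  if (pathway == "S_PD" && arch != "MONOMER") {
    stopf("S_PD is the monomer pathway; use DOUBLE_DIMER_SPD for single-chain dimers")
  }
  if (pathway == "DOUBLE_DIMER_SPD" && arch != "SINGLE_CHAIN_DIMER") {
    stopf("DOUBLE_DIMER_SPD is only valid with SINGLE_CHAIN_DIMER architecture")
  }
  if (genome$cis_acting && genome$n_elements > 1) {
    stopf("cis_acting networks model a private pool: build one network per element")
  }

  vol <- genome$volume_liters
  bi <- function(k) k / (AVOGADRO * vol)
  ns_sites <- floor(genome$genome_length_bp / genome$nonspecific_site_spacing_bp)
  use_ns <- !genome$cis_acting
  natural <- pathway == "S_NEC" && arch == "NATURAL_DIMER"

  species <- c("T", "E_FF", "E_BF", "E_FB", "E_BB", "PEC", "DONE")
  init <- c(transposase_count, genome$n_elements, 0, 0, 0, 0, 0)
  if (use_ns) {
    species <- c(species, "NS", "TNS")
    init <- c(init, ns_sites, 0)
  }
  if (natural) {
    species <- c(species, "TMONO")
    init <- c(init, 0)
  }
  names(init) <- species

  rx <- list()
  add <- function(reactants, products, rate_scaled, rate_name, label) {
    rx[[length(rx) + 1L]] <<- list(reactants = reactants, products = products,
                                   rate_scaled = rate_scaled,
                                   rate_name = rate_name, label = label)
  }

  kb <- bi(rates$k_bind)
  # end binding / unbinding, kept distinct per end so the bound-unit
  # identity (left vs right) is visible in the state
  add(c(T = 1, E_FF = 1), c(E_BF = 1), kb, "k_bind", "bind-L")
  add(c(T = 1, E_FB = 1), c(E_BB = 1), kb, "k_bind", "bind-L")
  add(c(T = 1, E_FF = 1), c(E_FB = 1), kb, "k_bind", "bind-R")
  add(c(T = 1, E_BF = 1), c(E_BB = 1), kb, "k_bind", "bind-R")
  add(c(E_BF = 1), c(T = 1, E_FF = 1), rates$k_unbind, "k_unbind", "unbind-L")
  add(c(E_BB = 1), c(T = 1, E_FB = 1), rates$k_unbind, "k_unbind", "unbind-L")
  add(c(E_FB = 1), c(T = 1, E_FF = 1), rates$k_unbind, "k_unbind", "unbind-R")
  add(c(E_BB = 1), c(T = 1, E_BF = 1), rates$k_unbind, "k_unbind", "unbind-R")

  if (pathway == "S_NEC") {
    # naked-end capture: unimolecular because the partner end is tethered
    # on the same molecule; E_BB has no such channel (OPI block)
    kcap <- rates$k_synapsis * rates$synapsis_attenuation
    add(c(E_BF = 1), c(PEC = 1), kcap, "k_synapsis", "capture")
    add(c(E_FB = 1), c(PEC = 1), kcap, "k_synapsis", "capture")
  } else {
    ksyn <- rates$k_synapsis
    if (pathway == "DOUBLE_DIMER_SPD") {
      # a complex assembles only if both interface-contributing subunits
      # are functional; scale k2 by the engagement-competence probability
      ksyn <- ksyn * dd_interface_competence(mutant)
    }
    add(c(E_BB = 1), c(PEC = 1), ksyn, "k_synapsis", "synapsis")
  }
  add(c(PEC = 1), c(DONE = 1), rates$k_post, "k_post", "complete")

  if (use_ns) {
    add(c(T = 1, NS = 1), c(TNS = 1), bi(rates$k_ns_bind), "k_ns_bind", "ns-bind")
    add(c(TNS = 1), c(T = 1, NS = 1), rates$k_ns_unbind, "k_ns_unbind", "ns-unbind")
  }
  if (natural) {
    add(c(T = 1), c(TMONO = 2), rates$k_multimer_dissoc, "k_multimer_dissoc",
        "multimer-dissoc")
  }

  n_s <- length(species)
  n_r <- length(rx)
  react <- matrix(0, n_s, n_r, dimnames = list(species, NULL))
  nu <- matrix(0, n_s, n_r, dimnames = list(species, NULL))
  for (j in seq_len(n_r)) {
    r <- rx[[j]]
    react[names(r$reactants), j] <- r$reactants
    nu[names(r$reactants), j] <- nu[names(r$reactants), j] - r$reactants
    nu[names(r$products), j] <- nu[names(r$products), j] + r$products
  }

  # conservation weights: transposase subunits per species, elements per species
  unit_sub <- if (pathway == "S_PD") 1 else 2
  in_pec <- if (pathway == "S_NEC") unit_sub else 2 * unit_sub
  tw <- setNames(numeric(n_s), species)
  tw["T"] <- unit_sub
  tw[c("E_BF", "E_FB")] <- unit_sub
  tw["E_BB"] <- 2 * unit_sub
  tw["PEC"] <- in_pec
  tw["DONE"] <- in_pec
  if (use_ns) tw["TNS"] <- unit_sub
  if (natural) tw["TMONO"] <- 1
  ew <- setNames(numeric(n_s), species)
  ew[c("E_FF", "E_BF", "E_FB", "E_BB", "PEC", "DONE")] <- 1

  net <- structure(
    list(species = init, react = react, nu = nu,
         rate_scaled = vapply(rx, `[[`, numeric(1), "rate_scaled"),
         rate_name = vapply(rx, `[[`, character(1), "rate_name"),
         label = vapply(rx, `[[`, character(1), "label"),
         pathway = pathway, genome = genome, mutant = mutant, rates = rates,
         transposase_count = transposase_count,
         unit_subunits = unit_sub,
         conservation = list(transposase = tw, elements = ew)),
    class = "reaction_network"
  )
  apply_mutant(net, mutant)
}

# P(both interface-contributing subunits functional) when each end is
# engaged by one randomly chosen subunit of a separate single-chain dimer
dd_interface_competence <- function(mutant, engagement_bias = 0.5) {
  w <- engagement_bias * (mutant$subunit_a_interface == "WT") +
    (1 - engagement_bias) * (mutant$subunit_b_interface == "WT")
  w^2
}

#' Apply (or re-apply) a mutant specification to a built network
#'
#' The dimer-interface mutation G462D blocks synapsis: in an S-NEC network
#' it zeroes the capture channel, in S-PD-type networks the synapsis
#' channel. Active-site DDE->ADE mutations leave the assembly channels
#' untouched (they only change the cleavage-product map, see
#' [predict_cleavage_products()]).
#'
#' @param network a `reaction_network`
#' @param mutant a [mutant_spec()]
#' @return the modified network
#' @export
apply_mutant <- function(network, mutant) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(mutant, "mutant_spec"))
  network$mutant <- mutant
  if (has_g462d(mutant)) {
    kill <- network$label %in% c("capture", "synapsis")
    network$rate_scaled[kill] <- 0
  }
  network
}

#' Mass-action propensities of a network at a state
#' @param network a `reaction_network`
#' @param state named species counts (defaults to the initial state)
#' @return numeric vector, one propensity per reaction
#' @export
propensities <- function(network, state = network$species) {
  state <- state[rownames(network$react)]
  a <- network$rate_scaled
  for (j in seq_along(a)) {
    idx <- which(network$react[, j] > 0)
    for (i in idx) {
      m <- network$react[i, j]
      x <- state[i]
      # falling factorial for identical-reactant stoichiometry
      a[j] <- a[j] * prod(x - seq_len(m) + 1) / factorial(m)
    }
  }
  unname(pmax(a, 0))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> pathway=%s, %d species, %d reactions (%d labels)\n",
              x$pathway, length(x$species), length(x$label),
              length(unique(x$label))))
  cat("  initial state:",
      paste(sprintf("%s=%g", names(x$species), x$species), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a network description to a plain list (for JSON export)
#' @param network a `reaction_network`
#' @return a list suitable for `jsonlite::toJSON`
#' @export
describe_network <- function(network) {
  rxs <- lapply(seq_along(network$label), function(j) {
    re <- network$react[, j]
    pr <- network$nu[, j] + re
    list(label = network$label[j],
         rate_name = network$rate_name[j],
         rate_scaled = network$rate_scaled[j],
         reactants = as.list(re[re > 0]),
         products = as.list(pr[pr > 0]))
  })
  list(pathway = network$pathway,
       species = as.list(network$species),
       reactions = rxs,
       genome = unclass(network$genome),
       mutant = unclass(network$mutant),
       rates = unclass(network$rates))
}

#' Predict cleavage products and relative activity for a mutant
#'
#' Within a formed paired-ends complex each end is cut iff the subunit
#' engaged at that end carries a functional DDE active site. In the S-NEC
#' single-chain dimer the two subunits of one protein engage the two ends
#' (one each). In the hypothetical double-dimer S-PD pathway each end is
#' engaged by one randomly chosen subunit (probability `engagement_bias`
#' for subunit A) of a separate single-chain dimer, and the complex only
#' assembles if both engaged (interface-contributing) subunits are
#' wild-type at the dimer interface. Relative activity is the probability
#' of assembling an interface-competent complex.
#'
#' With one dimerization-dead (G462D) subunit and unbiased engagement the
#' double-dimer prediction is 25% relative activity, inside the classical
#' "up to 50%" upper bound.
#'
#' @param mutant a [mutant_spec()] (dimer architectures)
#' @param pathway `"S_NEC"` or `"DOUBLE_DIMER_SPD"`
#' @param engagement_bias probability that a single-chain dimer engages an
#'   end through subunit A, in \[0, 1\]
#' @return list with `products` (probabilities over `UNCUT`,
#'   `SINGLE_END_CUT`, `DOUBLE_END_CUT`, conditional on complex formation)
#'   and `relative_activity` (in \[0, 1\])
#' @examples
#' m <- mutant_spec("SINGLE_CHAIN_DIMER", subunit_a_interface = "G462D")
#' predict_cleavage_products(m, "DOUBLE_DIMER_SPD")$relative_activity  # 0.25
#' @export
predict_cleavage_products <- function(mutant, pathway = c("S_NEC", "DOUBLE_DIMER_SPD"),
                                      engagement_bias = 0.5) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(mutant, "mutant_spec"))
  if (!is.numeric(engagement_bias) || length(engagement_bias) != 1 ||
      is.na(engagement_bias) || engagement_bias < 0 || engagement_bias > 1) {
    stopf("'engagement_bias' must lie in [0, 1]")
  }
  if (mutant$architecture == "MONOMER") {
    stopf("cleavage-product prediction applies to dimer architectures")
  }
  dde <- c(A = mutant$subunit_a_active_site == "DDE",
           B = mutant$subunit_b_active_site == "DDE")
  wt_if <- c(A = mutant$subunit_a_interface == "WT",
             B = mutant$subunit_b_interface == "WT")
  products <- c(UNCUT = 0, SINGLE_END_CUT = 0, DOUBLE_END_CUT = 0)
  classify <- function(cut_l, cut_r) {
    n <- cut_l + cut_r
    c("UNCUT", "SINGLE_END_CUT", "DOUBLE_END_CUT")[n + 1]
  }

  if (pathway == "S_NEC") {
    # one protein spans the complex; subunit A at one end, B at the other
    activity <- if (any(!wt_if)) 0 else 1
    cls <- classify(dde[["A"]], dde[["B"]])
    products[cls] <- 1
  } else {
    # enumerate which subunit each of the two dimers engages with
    q <- engagement_bias
    p_sub <- c(A = q, B = 1 - q)
    activity <- 0
    for (s1 in c("A", "B")) {
      for (s2 in c("A", "B")) {
        w <- p_sub[[s1]] * p_sub[[s2]]
        if (wt_if[[s1]] && wt_if[[s2]]) {
          activity <- activity + w
          cls <- classify(dde[[s1]], dde[[s2]])
          products[cls] <- products[cls] + w
        }
      }
    }
    products <- if (activity > 0) products / activity else
      c(UNCUT = NA_real_, SINGLE_END_CUT = NA_real_, DOUBLE_END_CUT = NA_real_)
  }
  list(products = products, relative_activity = unname(activity))
}
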