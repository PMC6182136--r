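# Parameter containers and the closed-form arithmetic used throughout:
# half-life <-> first-order rate, nonspecific site excess, order-of-magnitude
# ratios, and concentration <-> molecule-count conversion.

#' Kinetic rate constants for transpososome assembly
#'
#' Houses the rate constants of the assembly model. `k_bind`/`k_unbind`
#' (the classical k1/k-1) govern transposase binding to a transposon end;
#' `k_synapsis` (k2) is the irreversible synapsis step that commits the
#' element to transposition; `k_post` (k3) lumps every step after synapsis
#' (cleavage, strand transfer) into one first-order constant. Nonspecific
#' DNA binding (`k_ns_bind`/`k_ns_unbind`) sequesters transposase in
#' proportion to genome length. `k_multimer_dissoc` is the subunit
#' dissociation rate of a natural (non-covalent) transposase dimer.
#' `synapsis_attenuation` multiplies `k_synapsis` in S-NEC networks and
#' models the conformational change by which single-end binding reduces
#' the efficiency of capturing the second end.
#'
#' @param k_bind association rate constant, per molar per second (k1)
#' @param k_unbind single-end complex dissociation rate, per second (k-1)
#' @param k_synapsis synapsis rate constant, per second (k2); unimolecular
#'   capture of the tethered partner end
#' @param k_post lumped post-synapsis rate constant, per second (k3)
#' @param k_ns_bind nonspecific DNA association rate, per molar per second
#' @param k_ns_unbind nonspecific DNA dissociation rate, per second
#' @param k_multimer_dissoc multimer subunit-dissociation rate, per second
#' @param synapsis_attenuation dimensionless factor in (0, 1]
#' @return an object of class `rate_constants`
#' @examples
#' rate_constants(k_bind = 1e6, k_unbind = 0.1, k_synapsis = 0.05, k_post = 0.01)
#' @export
rate_constants <- function(k_bind, k_unbind, k_synapsis, k_post,
                           k_ns_bind = 0, k_ns_unbind = 0,
                           k_multimer_dissoc = 0,
                           synapsis_attenuation = 1) {
  check_number(k_bind, "k_bind", 0)
  check_number(k_unbind, "k_unbind", 0)
  check_number(k_synapsis, "k_synapsis", 0)
  check_number(k_post, "k_post", 0)
  check_number(k_ns_bind, "k_ns_bind", 0)
  check_number(k_ns_unbind, "k_ns_unbind", 0)
  check_number(k_multimer_dissoc, "k_multimer_dissoc", 0)
  check_number(synapsis_attenuation, "synapsis_attenuation", 0, strict = TRUE)
  if (synapsis_attenuation > 1) {
    stopf("'synapsis_attenuation' must lie in (0, 1]")
  }
  structure(
    list(k_bind = k_bind, k_unbind = k_unbind, k_synapsis = k_synapsis,
         k_post = k_post, k_ns_bind = k_ns_bind, k_ns_unbind = k_ns_unbind,
         k_multimer_dissoc = k_multimer_dissoc,
         synapsis_attenuation = synapsis_attenuation),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Genomic context of a simulated reaction
#'
#' Describes the DNA substrate: how much nonspecific DNA competes for the
#' transposase, how many transposon copies (each with two ends) are present,
#' and the reaction volume used to convert molar concentrations to molecule
#' counts. `cis_acting = TRUE` declares that each element sees only the
#' transposase expressed from its own gene, making the effective transposase
#' concentration independent of genome size.
#'
#' @param genome_length_bp integer length of nonspecific DNA, base pairs
#' @param n_elements number of transposon copies (two ends each)
#' @param volume_liters reaction/cell volume; default 1 fL (bacterial scale)
#' @param cis_acting logical; private per-element transposase pool
#' @param nonspecific_site_spacing_bp spacing of candidate nonspecific sites
#' @return an object of class `genome_context`
#' @examples
#' genome_context(4e3)                 # the 4 kb in-vitro substrate plasmid
#' genome_context(4e6)                 # an E. coli scale genome
#' @export
genome_context <- function(genome_length_bp, n_elements = 1L,
                           volume_liters = 1e-15, cis_acting = FALSE,
                           nonspecific_site_spacing_bp = 1L) {
  check_number(genome_length_bp, "genome_length_bp", 0, strict = TRUE)
  check_number(n_elements, "n_elements", 0)
  check_number(volume_liters, "volume_liters", 0, strict = TRUE)
  check_number(nonspecific_site_spacing_bp, "nonspecific_site_spacing_bp", 1)
  stopifnot(is.logical(cis_acting), length(cis_acting) == 1L)
  if (genome_length_bp < 2 * n_elements) {
    stopf("genome_length_bp must be >= 2 * n_elements (room for the ends)")
  }
  structure(
    list(genome_length_bp = genome_length_bp,
         n_elements = as.integer(n_elements),
         volume_liters = volume_liters,
         cis_acting = cis_acting,
         nonspecific_site_spacing_bp = nonspecific_site_spacing_bp),
    class = "genome_context"
  )
}

#' Mutant specification for a transposase
#'
#' Describes the subunit composition of the transposase: the catalytic
#' motif of each active site (`DDE` functional, `ADE` catalytically dead)
#' and the dimer-interface allele (`WT`, or `G462D` which destabilizes the
#' interface and blocks synapsis). Architectures: `MONOMER` (one subunit;
#' `subunit_b_*` fields ignored), `SINGLE_CHAIN_DIMER` (two subunits fused
#' by a flexible linker), `NATURAL_DIMER` (stable non-covalent dimer).
#'
#' @param architecture one of `"MONOMER"`, `"SINGLE_CHAIN_DIMER"`,
#'   `"NATURAL_DIMER"`
#' @param subunit_a_active_site,subunit_b_active_site `"DDE"` or `"ADE"`
#' @param subunit_a_interface,subunit_b_interface `"WT"` or `"G462D"`
#' @return an object of class `mutant_spec`
#' @examples
#' mutant_spec("SINGLE_CHAIN_DIMER", subunit_b_active_site = "ADE")
#' @export
mutant_spec <- function(architecture = c("MONOMER", "SINGLE_CHAIN_DIMER",
                                         "NATURAL_DIMER"),
                        subunit_a_active_site = c("DDE", "ADE"),
                        subunit_b_active_site = c("DDE", "ADE"),
                        subunit_a_interface = c("WT", "G462D"),
                        subunit_b_interface = c("WT", "G462D")) {
  architecture <- match.arg(architecture)
  subunit_a_active_site <- match.arg(subunit_a_active_site)
  subunit_a_interface <- match.arg(subunit_a_interface)
  if (architecture == "MONOMER") {
    # MONOMER uses only subunit A; B fields are forced to NA
    subunit_b_active_site <- NA_character_
    subunit_b_interface <- NA_character_
  } else {
    subunit_b_active_site <- match.arg(subunit_b_active_site)
    subunit_b_interface <- match.arg(subunit_b_interface)
  }
  structure(
    list(architecture = architecture,
         subunit_a_active_site = subunit_a_active_site,
         subunit_b_active_site = subunit_b_active_site,
         subunit_a_interface = subunit_a_interface,
         subunit_b_interface = subunit_b_interface),
    class = "mutant_spec"
  )
}

has_g462d <- function(mutant) {
  any(c(mutant$subunit_a_interface, mutant$subunit_b_interface) == "G462D",
      na.rm = TRUE)
}

#' The closed enumeration of parameter archetypes
#' @return character vector of archetype names
#' @export
archetype_names <- function() c("TN5_MONOMER", "TN5_SCD", "HSMAR1")

#' Convert a half-life to a first-order rate constant
#'
#' Uses first-order exponential decay, k = ln(2)/t1/2. A subunit-exchange
#' half-life of 3 h (10800 s) gives 6e-5 per second at one significant
#' figure.
#'
#' @param t_half half-life, seconds (> 0)
#' @return rate constant, per second
#' @seealso [rate_to_half_life()]
#' @examples
#' half_life_to_rate(10800)   # ~6e-5 /s
#' @export
half_life_to_rate <- function(t_half) {
  check_number(t_half, "t_half", 0, strict = TRUE, len = length(t_half))
  log(2) / t_half
}

#' Convert a first-order rate constant to a half-life
#' @param rate rate constant, per second (> 0)
#' @return half-life, seconds
#' @export
rate_to_half_life <- function(rate) {
  check_number(rate, "rate", 0, strict = TRUE, len = length(rate))
  log(2) / rate
}

#' Fold excess of nonspecific DNA sites over specific transposon ends
#'
#' With sites every `spacing_bp` base pairs, a `dna_length_bp` substrate
#' carries `floor(dna_length_bp / spacing_bp)` candidate nonspecific sites;
#' the excess is that count divided by the number of specific ends. A 4 kb
#' plasmid with two ends and 1 bp spacing gives 2000-fold.
#'
#' @param dna_length_bp substrate length, base pairs
#' @param n_specific_ends number of transposon ends (>= 1)
#' @param spacing_bp site spacing, base pairs (>= 1)
#' @return dimensionless fold excess
#' @examples
#' nonspecific_site_excess(4000, 2)    # 2000
#' @export
nonspecific_site_excess <- function(dna_length_bp, n_specific_ends,
                                    spacing_bp = 1) {
  check_number(dna_length_bp, "dna_length_bp", 1)
  check_number(n_specific_ends, "n_specific_ends", 1)
  check_number(spacing_bp, "spacing_bp", 1)
  if (dna_length_bp < spacing_bp) {
    stopf("'dna_length_bp' must be >= 'spacing_bp'")
  }
  floor(dna_length_bp / spacing_bp) / n_specific_ends
}

#' Order-of-magnitude ratio of two positive quantities
#'
#' `log10(a / b)`: a 4 Mb genome holds three orders of magnitude more
#' nonspecific sites than a 4 kb plasmid; genomes span five orders of
#' magnitude (1e6 to 1e11 bp).
#'
#' @param a,b positive numbers
#' @return `log10(a/b)`
#' @export
orders_of_magnitude_ratio <- function(a, b) {
  check_number(a, "a", 0, strict = TRUE, len = length(a))
  check_number(b, "b", 0, strict = TRUE, len = length(b))
  log10(a / b)
}

#' Convert a molar concentration to a molecule count
#'
#' Rounds `conc * N_A * volume` to the nearest integer; simulation state is
#' integer molecule counts. 100 nM in 1 fL is 60 molecules.
#'
#' @param conc molar concentration (>= 0)
#' @param volume volume in liters (> 0)
#' @return molecule count (numeric, integer-valued)
#' @examples
#' concentration_to_count(100e-9, 1e-15)  # 60
#' @export
concentration_to_count <- function(conc, volume) {
  check_number(conc, "conc", 0, len = length(conc))
  check_number(volume, "volume", 0, strict = TRUE)
  round(conc * AVOGADRO * volume)
}

#' Convert a molecule count to a molar concentration
#' @param count molecule count (>= 0)
#' @param volume volume in liters (> 0)
#' @return molar concentration
#' @export
count_to_concentration <- function(count, volume) {
  check_number(count, "count", 0, len = length(count))
  check_number(volume, "volume", 0, strict = TRUE)
  count / (AVOGADRO * volume)
}
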