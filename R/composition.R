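#' Linear fit of a biomass pool against growth rate
#'
#' @param slope slope in (mg/(OD600*mL)) per (1/h).
#' @param intercept intercept in mg/(OD600*mL).
#' @return a `linear_fit` object; evaluate with [eval_fit()].
#' @export
linear_fit <- function(slope, intercept) {
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "linear_fit")
}

#' @rdname linear_fit
#' @param fit a `linear_fit`.
#' @param gr growth rate(s), 1/h.
#' @export
eval_fit <- function(fit, gr) fit$slope * gr + fit$intercept

#' Growth-rate dependence of RNA, protein and CDW content
#'
#' Bundles the three linear fits of per-OD600*mL content against growth rate.
#' The fits must stay positive over `[0, gr_max]` and CDW must exceed
#' RNA + protein throughout (the residual mass assigned to other components
#' cannot be negative).
#'
#' @param rna,protein,cdw [linear_fit()] objects (mg/(OD600*mL) vs 1/h).
#' @param gr_max maximum supported growth rate (1/h).
#' @return a `growth_rate_fits` object.
#' @export
growth_rate_fits <- function(rna, protein, cdw, gr_max = 1.4) {
  ends <- c(0, gr_max)
  for (f in list(rna = rna, protein = protein, cdw = cdw)) {
    if (any(eval_fit(f, ends) <= 0))
      stop("a content fit is nonpositive inside [0, gr_max]")
  }
  if (any(eval_fit(cdw, ends) <= eval_fit(rna, ends) + eval_fit(protein, ends)))
    stop("CDW fit must exceed RNA + protein over [0, gr_max]")
  structure(list(rna = rna, protein = protein, cdw = cdw, gr_max = gr_max),
            class = "growth_rate_fits")
}

#' Measured content fits for the modelled organism
#'
#' The package's reference parameterisation of [growth_rate_fits()]:
#' total RNA `0.05 x + 0.05`, total protein `-0.09 x + 0.38` and CDW
#' `-0.13 x + 0.64` mg/(OD600*mL) as functions of growth rate x (1/h),
#' measured across media spanning growth rates 0.28-1.38 /h.
#' @return a `growth_rate_fits` object.
#' @export
default_growth_rate_fits <- function() {
  growth_rate_fits(rna = linear_fit(0.05, 0.05),
                   protein = linear_fit(-0.09, 0.38),
                   cdw = linear_fit(-0.13, 0.64),
                   gr_max = 1.4)
}

#' Osmolyte content of biomass
#'
#' Marine bacteria balance seawater osmolarity with intracellular osmolytes;
#' here glutamate dominates (~5% of CDW), with glutamine more than tenfold
#' lower. Fractions are growth-rate independent.
#'
#' @param glutamate_fraction g/gCDW, in `[0, 0.2]`.
#' @param glutamine_fraction g/gCDW, nonnegative and below the glutamate
#'   fraction.
#' @return an `osmolyte_spec` object.
#' @export
osmolyte_spec <- function(glutamate_fraction = 0.05,
                          glutamine_fraction = 0.005) {
  if (glutamate_fraction < 0 || glutamate_fraction > 0.2)
    stop("glutamate_fraction must be in [0, 0.2]")
  if (glutamine_fraction < 0 || glutamine_fraction > 0.2)
    stop("glutamine_fraction must be in [0, 0.2]")
  if (glutamine_fraction >= glutamate_fraction)
    stop("glutamine_fraction must be below glutamate_fraction")
  structure(list(glutamate_fraction = glutamate_fraction,
                 glutamine_fraction = glutamine_fraction),
            class = "osmolyte_spec")
}

REMAINDER_COMPONENTS <- c("dna", "lps", "lipid", "murein", "inorganic_ions",
                          "soluble_pool")

#' Reference proportions of unquantified biomass components
#'
#' The components not measured directly (DNA, LPS, lipids, murein, inorganic
#' ions, soluble pools) are taken from a reference organism and later scaled
#' to fill whatever biomass fraction the measured pools leave, keeping their
#' internal proportions.
#'
#' @param components named numeric: mass fraction of each of
#'   `dna, lps, lipid, murein, inorganic_ions, soluble_pool` in the reference
#'   organism.
#' @param reference_total total mass fraction these represent in the
#'   reference; components must sum to it (tolerance 1e-9).
#' @return a `reference_remainder` object.
#' @export
reference_remainder <- function(components, reference_total = 0.20) {
  if (!setequal(names(components), REMAINDER_COMPONENTS))
    stop("components must be named exactly: ",
         paste(REMAINDER_COMPONENTS, collapse = ", "))
  components <- components[REMAINDER_COMPONENTS]
  if (any(components < 0)) stop("component fractions must be nonnegative")
  if (abs(sum(components) - reference_total) > 1e-9)
    stop("component fractions must sum to reference_total")
  structure(list(components = components, reference_total = reference_total),
            class = "reference_remainder")
}

#' E. coli-like reference remainder
#'
#' Loads the packaged "iAF1260-like" table of unquantified-component
#' proportions (rounded from the E. coli iAF1260 biomass composition and
#' normalised to a 0.20 g/gCDW total).
#' @return a `reference_remainder`.
#' @export
default_reference_remainder <- function() {
  path <- system.file("extdata", "remainder_iaf1260_like.csv",
                      package = "gemcurate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_remainder(stats::setNames(tab$mass_fraction, tab$component),
                      reference_total = 0.20)
}

#' Biomass composition at a given growth rate
#'
#' Converts the per-OD content fits into mass fractions of CDW at growth rate
#' `gr`: protein and RNA fractions come from their fits divided by the CDW
#' fit, osmolytes are fixed fractions, and the remaining mass is distributed
#' over the reference remainder components in their reference proportions.
#' Fractions sum to 1 exactly.
#'
#' @param gr growth rate (1/h), in `[0, gr_max]`.
#' @param fits a [growth_rate_fits()].
#' @param osmo an [osmolyte_spec()].
#' @param remainder a [reference_remainder()].
#' @param gam growth-associated maintenance to carry along (mmol ATP/gCDW).
#' @return a `biomass_composition`: list with `fractions` (named, sums to 1),
#'   `gam`, `growth_rate`.
#' @export
composition_at <- function(gr, fits, osmo = osmolyte_spec(),
                           remainder = default_reference_remainder(),
                           gam = 0) {
  stopifnot(inherits(fits, "growth_rate_fits"))
  if (gr < 0 || gr > fits$gr_max)
    stop("gr must lie in [0, ", fits$gr_max, "]")
  if (gam < 0) stop("gam must be nonnegative")
  cdw <- eval_fit(fits$cdw, gr)
  fr_protein <- eval_fit(fits$protein, gr) / cdw
  fr_rna <- eval_fit(fits$rna, gr) / cdw
  measured <- fr_protein + fr_rna + osmo$glutamate_fraction +
    osmo$glutamine_fraction
  resid <- 1 - measured
  if (resid < 0)
    stop("measured fractions exceed total biomass (residual ",
         signif(resid, 3), ")")
  rem <- resid * remainder$components / remainder$reference_total
  fractions <- c(protein = fr_protein, rna = fr_rna,
                 glutamate = osmo$glutamate_fraction,
                 glutamine = osmo$glutamine_fraction,
                 rem)
  # absorb roundoff so the sum is exactly 1
  fractions[["soluble_pool"]] <- fractions[["soluble_pool"]] +
    (1 - sum(fractions))
  structure(list(fractions = fractions, gam = gam, growth_rate = gr),
            class = "biomass_composition")
}

#' A monomer profile
#'
#' Molar fractions of the monomers making up one polymer class, with the mass
#' of each polymerised residue (free monomer minus one water).
#'
#' @param kind `"amino_acid"`, `"rna_nucleotide"` or `"dna_nucleotide"`.
#' @param fractions named numeric, summing to 1 (tolerance 1e-9); names are
#'   the monomer (metabolite) identifiers used in the target model.
#' @param residue_masses named numeric, g/mol, same names.
#' @return a `monomer_profile`.
#' @export
monomer_profile <- function(kind = c("amino_acid", "rna_nucleotide",
                                     "dna_nucleotide"),
                            fractions, residue_masses) {
  kind <- match.arg(kind)
  if (any(fractions < 0)) stop("monomer fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("monomer fractions must sum to 1")
  if (!all(names(fractions) %in% names(residue_masses)))
    stop("residue mass missing for: ",
         paste(setdiff(names(fractions), names(residue_masses)), collapse = ", "))
  if (any(residue_masses <= 0)) stop("residue masses must be positive")
  structure(list(kind = kind, fractions = fractions,
                 residue_masses = residue_masses[names(fractions)]),
            class = "monomer_profile")
}

# average free masses (g/mol); residues are free mass minus one water (18.02)
AA_FREE_MASS <- c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
                  E = 147.13, Q = 146.15, G = 75.07, H = 155.15, I = 131.17,
                  L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
                  S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15)
NMP_FREE_MASS <- c(AMP = 347.22, CMP = 323.20, GMP = 363.22, UMP = 324.18)
DNMP_FREE_MASS <- c(dAMP = 331.22, dCMP = 307.20, dGMP = 347.22, dTMP = 322.21)
WATER_MASS <- 18.02

extract_feature_seqs <- function(genome, annotation, types) {
  gff <- as.data.frame(rtracklayer::import(annotation))
  feats <- gff[as.character(gff$type) %in% types, , drop = FALSE]
  seqs <- character(0)
  for (i in seq_len(nrow(feats))) {
    chr <- as.character(feats$seqnames[i])
    if (!chr %in% names(genome))
      stop("annotation references unknown sequence '", chr, "'")
    s <- Biostrings::subseq(genome[[chr]], feats$start[i], feats$end[i])
    if (as.character(feats$strand[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
  }
  seqs
}

#' Amino-acid usage inferred from protein-coding genes
#'
#' Translates every CDS feature of the annotation with the standard genetic
#' code and tallies the 20 amino acids across all proteins (start methionines
#' counted, stop codons excluded, ambiguous codons skipped with a warning).
#' The tally is unweighted by expression, so long genes contribute
#' proportionally more.
#'
#' @param genome path to a genome FASTA, or a `DNAStringSet`.
#' @param annotation path to a GFF3 file with CDS features.
#' @return a `monomer_profile` of kind `"amino_acid"` with one-letter
#'   amino-acid names.
#' @export
aa_profile_from_genome <- function(genome, annotation) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- extract_feature_seqs(genome, annotation, "CDS")
  if (length(seqs) == 0L) stop("no CDS features in annotation")
  counts <- stats::setNames(numeric(length(AA_FREE_MASS)), names(AA_FREE_MASS))
  used <- 0L
  for (s in seqs) {
    if (nchar(s) %% 3 != 0) {
      warning("skipping CDS with length not divisible by 3")
      next
    }
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X")), "")[[1]]
    aa <- aa[aa != "*"]
    if (any(aa == "X")) {
      warning("skipping codons with ambiguous bases")
      aa <- aa[aa != "X"]
    }
    tab <- table(aa)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    used <- used + 1L
  }
  if (used == 0L || sum(counts) == 0) stop("no usable CDS features")
  monomer_profile("amino_acid", counts / sum(counts),
                  AA_FREE_MASS - WATER_MASS)
}

#' Nucleotide usage from rRNA genes or the whole genome
#'
#' For `region_kind = "rRNA"`, tallies AMP/CMP/GMP/UMP molar fractions over
#' the rRNA gene sequences (T counted as U); rRNA dominates total cellular
#' RNA, so its composition stands in for the RNA pool. For
#' `region_kind = "whole_genome"`, tallies dAMP/dCMP/dGMP/dTMP over both
#' strands of the genome (A pairs with T and G with C, so fractions are
#' strand-symmetric). Ambiguous bases are skipped with a warning.
#'
#' @param genome path to a genome FASTA, or a `DNAStringSet`.
#' @param annotation path to a GFF3 file (needed for `"rRNA"`).
#' @param region_kind `"rRNA"` or `"whole_genome"`.
#' @return a `monomer_profile` of the corresponding nucleotide kind.
#' @export
nt_profile_from_regions <- function(genome, annotation = NULL,
                                    region_kind = c("rRNA", "whole_genome")) {
  region_kind <- match.arg(region_kind)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (region_kind == "rRNA") {
    if (is.null(annotation)) stop("rRNA profile needs an annotation")
    seqs <- extract_feature_seqs(genome, annotation, "rRNA")
    if (length(seqs) == 0L) stop("no rRNA features in annotation")
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    keep <- chars %in% c("A", "C", "G", "T", "U")
    if (!all(keep)) warning("skipping ambiguous bases in rRNA regions")
    chars <- chars[keep]
    chars[chars == "T"] <- "U"
    tab <- table(factor(chars, levels = c("A", "C", "G", "U")))
    fr <- as.numeric(tab) / sum(tab)
    monomer_profile("rna_nucleotide",
                    stats::setNames(fr, c("AMP", "CMP", "GMP", "UMP")),
                    NMP_FREE_MASS - WATER_MASS)
  } else {
    chars <- strsplit(paste(vapply(genome, as.character, ""), collapse = ""),
                      "")[[1]]
    keep <- chars %in% c("A", "C", "G", "T")
    if (!all(keep)) warning("skipping ambiguous bases in genome")
    chars <- chars[keep]
    tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
    n <- as.numeric(tab); names(n) <- names(tab)
    tot <- 2 * sum(n)
    fr <- c(dAMP = (n[["A"]] + n[["T"]]) / tot,
            dCMP = (n[["C"]] + n[["G"]]) / tot,
            dGMP = (n[["G"]] + n[["C"]]) / tot,
            dTMP = (n[["T"]] + n[["A"]]) / tot)
    monomer_profile("dna_nucleotide", fr, DNMP_FREE_MASS - WATER_MASS)
  }
}

#' Build a biomass reaction from a composition
#'
#' Converts mass fractions into stoichiometric coefficients. For a polymer
#' class with mass fraction `f` and monomer molar fractions `phi_i` with
#' residue masses `m_i`, monomer `i` is consumed at
#' `1000 f phi_i / sum_j(phi_j m_j)` mmol/gCDW. Osmolytes and lumped
#' remainder components are consumed at `1000 f / m` using their free masses.
#' Growth-associated maintenance is appended as
#' `gam x (ATP + H2O -> ADP + Pi)`, and one unit of the biomass species is
#' produced, so the reaction's flux is the growth rate in 1/h.
#'
#' @param comp a [composition_at()] result (carries the GAM).
#' @param profiles named list with entries `protein`, `rna`, `dna`, each a
#'   [monomer_profile()] whose monomer names are metabolite ids of the target
#'   model.
#' @param lumped_species named character: metabolite id consumed for each of
#'   `glutamate`, `glutamine`, `lps`, `lipid`, `murein`, `inorganic_ions`,
#'   `soluble_pool`.
#' @param lumped_masses named numeric free masses (g/mol) for the same
#'   components; glutamate (147.13) and glutamine (146.15) default to their
#'   free amino-acid masses.
#' @param gam_species named character with entries `atp`, `h2o`, `adp`, `pi`
#'   (add e.g. `h` for models that track a proton, produced alongside ADP).
#' @param biomass_species id of the biomass metabolite produced.
#' @param id reaction id.
#' @return a [reaction()] with bounds `[0, 1000]`; attributes
#'   `component_groups` (per-component coefficient contributions, used by
#'   [sensitivity_scan()]), `gam` and `gam_species`.
#' @export
build_biomass_reaction <- function(comp, profiles, lumped_species,
                                   lumped_masses = NULL,
                                   gam_species = c(atp = "atp_c",
                                                   h2o = "h2o_c",
                                                   adp = "adp_c",
                                                   pi = "pi_c"),
                                   biomass_species = "biomass_c",
                                   id = "BIOMASS") {
  stopifnot(inherits(comp, "biomass_composition"))
  need <- c("protein", "rna", "dna")
  if (!all(need %in% names(profiles)))
    stop("profiles must cover protein, RNA and DNA")
  defaults <- c(glutamate = 147.13, glutamine = 146.15)
  lumped_masses <- c(lumped_masses,
                     defaults[setdiff(names(defaults), names(lumped_masses))])
  fr <- comp$fractions
  groups <- list()
  coef <- numeric(0)
  add_contrib <- function(coef, ids, vals) {
    for (k in seq_along(ids)) {
      coef[ids[k]] <- if (ids[k] %in% names(coef)) coef[[ids[k]]] + vals[k]
                      else vals[k]
    }
    coef
  }
  for (cls in need) {
    pr <- profiles[[cls]]
    stopifnot(inherits(pr, "monomer_profile"))
    rm_cls <- pr$residue_masses[names(pr$fractions)]
    if (any(is.na(rm_cls)))
      stop("residue mass missing for ", cls, " monomer(s): ",
           paste(names(pr$fractions)[is.na(rm_cls)], collapse = ", "))
    mbar <- sum(pr$fractions * rm_cls)
    contrib <- -1000 * fr[[cls]] * pr$fractions / mbar
    groups[[cls]] <- contrib
    coef <- add_contrib(coef, names(contrib), contrib)
  }
  lumped <- setdiff(names(fr), c(need))
  for (cls in lumped) {
    if (!cls %in% names(lumped_species))
      stop("no consuming species mapped for component '", cls, "'")
    if (!cls %in% names(lumped_masses))
      stop("no free mass given for component '", cls, "'")
    contrib <- stats::setNames(-1000 * fr[[cls]] / lumped_masses[[cls]],
                               lumped_species[[cls]])
    groups[[cls]] <- contrib
    coef <- add_contrib(coef, names(contrib), contrib)
  }
  gam <- comp$gam
  gdir <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  gsp <- gam_species[names(gam_species) %in% names(gdir)]
  gam_contrib <- stats::setNames(gam * gdir[names(gsp)], unname(gsp))
  groups[["gam"]] <- gam_contrib
  coef <- add_contrib(coef, names(gam_contrib), gam_contrib)
  coef <- add_contrib(coef, biomass_species, 1)
  rxn <- reaction(id, coef, lb = 0, ub = 1000, name = "biomass assembly")
  attr(rxn, "component_groups") <- groups
  attr(rxn, "gam") <- gam
  attr(rxn, "gam_species") <- gsp
  rxn
}

#' Sensitivity of predicted growth to reference-derived biomass coefficients
#'
#' Rescales the coefficient group of each listed biomass component by factors
#' across `factor_range` (no renormalisation of the other components — the
#' perturbation changes the total, as intended), re-solves FBA each time, and
#' reports the largest relative change of the optimal biomass flux.
#'
#' @param model a `metabolic_model` whose objective reaction was built by
#'   [build_biomass_reaction()] (it carries the `component_groups` attribute),
#'   with the reference medium already applied.
#' @param components character vector of component names to perturb.
#' @param factor_range length-2 numeric, e.g. `c(0.75, 1.25)`.
#' @param grid number of factors across the range.
#' @return list with `max_rel_change` and a data frame `detail`
#'   (component, factor, growth_rate, rel_change).
#' @export
sensitivity_scan <- function(model, components,
                             factor_range = c(0.75, 1.25), grid = 5L) {
  bio <- model$reactions[[model$objective_id]]
  groups <- attr(bio, "component_groups")
  if (is.null(groups))
    stop("objective reaction carries no component groups; build it with ",
         "build_biomass_reaction()")
  miss <- setdiff(components, names(groups))
  if (length(miss)) stop("unknown components: ", paste(miss, collapse = ", "))
  base <- fba(model)
  if (base$status != "optimal" || base$objective_value <= 0)
    stop("base model does not grow under the reference medium")
  mu0 <- base$objective_value
  factors <- seq(factor_range[1], factor_range[2], length.out = grid)
  detail <- expand.grid(component = components, factor = factors,
                        stringsAsFactors = FALSE)
  detail$growth_rate <- NA_real_
  for (i in seq_len(nrow(detail))) {
    g <- groups[[detail$component[i]]]
    pert <- bio
    delta <- (detail$factor[i] - 1) * g
    pert$stoich[names(g)] <- pert$stoich[names(g)] + delta
    m2 <- model
    m2$reactions[[model$objective_id]] <- pert
    sol <- fba(m2)
    detail$growth_rate[i] <- if (sol$status == "optimal") sol$objective_value
                             else NA_real_
  }
  detail$rel_change <- abs(detail$growth_rate - mu0) / mu0
  list(max_rel_change = max(detail$rel_change, na.rm = TRUE), detail = detail)
}
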