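ref_fits <- default_growth_rate_fits()

test_that("composition_at reproduces the printed-fit evaluations", {
  # evaluate the reference lines at 0.79/h: protein 0.3089/0.5373,
  # RNA 0.0895/0.5373, glutamate 0.05, remainder fills the rest
  comp <- composition_at(0.79, ref_fits,
                         osmo = osmolyte_spec(0.05, 0),
                         gam = 15.8)
  fr <- comp$fractions
  expect_equal(unname(fr["protein"]), (0.38 - 0.09 * 0.79) / (0.64 - 0.13 * 0.79),
               tolerance = 1e-12)
  expect_equal(unname(fr["protein"]), 0.575, tolerance = 1e-3)
  expect_equal(unname(fr["rna"]), 0.167, tolerance = 1e-2)
  expect_equal(unname(fr["glutamate"]), 0.05)
  rem <- sum(fr[c("dna", "lps", "lipid", "murein", "inorganic_ions",
                  "soluble_pool")])
  expect_equal(rem, 0.208, tolerance = 1e-2)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(comp$gam, 15.8)

  # at 0.28/h protein rises and RNA falls (slower growth, less ribosome)
  comp2 <- composition_at(0.28, ref_fits, osmo = osmolyte_spec(0.05, 0))
  expect_equal(unname(comp2$fractions["protein"]), 0.588, tolerance = 1e-2)
  expect_equal(unname(comp2$fractions["rna"]), 0.106, tolerance = 1e-2)
  expect_lt(comp2$fractions["rna"], fr["rna"])
})

test_that("zero-slope fits make the composition growth-rate independent", {
  flat <- growth_rate_fits(rna = linear_fit(0, 0.1),
                           protein = linear_fit(0, 0.3),
                           cdw = linear_fit(0, 0.6))
  a <- composition_at(0.1, flat)
  b <- composition_at(1.2, flat)
  expect_equal(a$fractions, b$fractions)
})

test_that("composition fractions sum to one across the growth-rate range", {
  set.seed(20)
  for (gr in runif(100, 0, ref_fits$gr_max)) {
    comp <- composition_at(gr, ref_fits)
    expect_equal(sum(comp$fractions), 1, tolerance = 1e-6)
    expect_true(all(comp$fractions >= 0))
  }
})

test_that("composition_at rejects out-of-range and overfull compositions", {
  expect_error(composition_at(2.0, ref_fits), "must lie in")
  # measured parts exceeding the whole
  fits <- growth_rate_fits(rna = linear_fit(0, 0.30),
                           protein = linear_fit(0, 0.35),
                           cdw = linear_fit(0, 0.66))
  expect_error(composition_at(0.5, fits, osmo = osmolyte_spec(0.05, 0.004)),
               "exceed total biomass")
})

write_genome_fixture <- function(dir, seqs, features) {
  fa <- file.path(dir, "g.fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               vapply(features, function(f)
                 paste(f$seq, "test", f$type, f$start, f$end, ".", f$strand,
                       if (f$type == "CDS") "0" else ".",
                       paste0("ID=", f$id), sep = "\t"), "")), gff)
  list(fa = fa, gff = gff)
}

test_that("amino-acid profile from a single CDS matches hand translation", {
  dir <- withr::local_tempdir()
  fx <- write_genome_fixture(dir, list(chr1 = "ATGGCTGCTTAA"),
                             list(list(seq = "chr1", type = "CDS", start = 1,
                                       end = 12, strand = "+", id = "g1")))
  pr <- aa_profile_from_genome(fx$fa, fx$gff)
  expect_s3_class(pr, "monomer_profile")
  expect_equal(unname(pr$fractions["M"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(pr$fractions["A"]), 2 / 3, tolerance = 1e-12)
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
})

test_that("minus-strand CDS are reverse-complemented before translation", {
  dir <- withr::local_tempdir()
  # reverse complement of ATGGCTGCTTAA is TTAAGCAGCCAT
  fx <- write_genome_fixture(dir, list(chr1 = "TTAAGCAGCCAT"),
                             list(list(seq = "chr1", type = "CDS", start = 1,
                                       end = 12, strand = "-", id = "g1")))
  pr <- aa_profile_from_genome(fx$fa, fx$gff)
  expect_equal(unname(pr$fractions["M"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(pr$fractions["A"]), 2 / 3, tolerance = 1e-12)
})

test_that("multi-gene profiles match an independent codon tally", {
  codon_table <- c(ATG = "M", GCT = "A", GCA = "A", AAA = "K", CGT = "R",
                   TCT = "S", GGT = "G", TAA = "*", TGA = "*")
  g1 <- "ATGGCTAAACGTTCTTAA"
  g2 <- "ATGGGTGCAGCAAAATGA"
  # brute-force per-codon tally
  tally <- table(unlist(lapply(c(g1, g2), function(s) {
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    aa <- codon_table[cods]
    aa[aa != "*"]
  })))
  dir <- withr::local_tempdir()
  fx <- write_genome_fixture(dir, list(chr1 = paste0(g1, g2)),
                             list(list(seq = "chr1", type = "CDS", start = 1,
                                       end = 18, strand = "+", id = "g1"),
                                  list(seq = "chr1", type = "CDS", start = 19,
                                       end = 36, strand = "+", id = "g2")))
  pr <- aa_profile_from_genome(fx$fa, fx$gff)
  got <- pr$fractions[pr$fractions > 0]
  expect_equal(sort(names(got)), sort(names(tally)))
  expect_equal(got[names(tally)] * sum(tally), as.numeric(tally) + got[names(tally)] * 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  # gene order must not matter
  fx2 <- write_genome_fixture(dir, list(chr1 = paste0(g2, g1)),
                              list(list(seq = "chr1", type = "CDS", start = 1,
                                        end = 18, strand = "+", id = "g2"),
                                   list(seq = "chr1", type = "CDS", start = 19,
                                        end = 36, strand = "+", id = "g1")))
  pr2 <- aa_profile_from_genome(fx2$fa, fx2$gff)
  expect_equal(pr2$fractions, pr$fractions)
})

test_that("broken CDS are skipped with a warning; none usable is an error", {
  dir <- withr::local_tempdir()
  fx <- write_genome_fixture(dir, list(chr1 = "ATGGCTGCTTAAC"),
                             list(list(seq = "chr1", type = "CDS", start = 1,
                                       end = 13, strand = "+", id = "bad")))
  expect_error(suppressWarnings(aa_profile_from_genome(fx$fa, fx$gff)),
               "no usable CDS")
  fx2 <- write_genome_fixture(dir, list(chr1 = "ATGGCTGCTTAACC"),
                              list(list(seq = "chr1", type = "CDS", start = 1,
                                        end = 13, strand = "+", id = "bad"),
                                   list(seq = "chr1", type = "CDS", start = 1,
                                        end = 12, strand = "+", id = "good")))
  expect_warning(pr <- aa_profile_from_genome(fx2$fa, fx2$gff),
                 "not divisible by 3")
  expect_equal(unname(pr$fractions["M"]), 1 / 3, tolerance = 1e-12)
})

test_that("nucleotide profiles count rRNA regions and double-stranded DNA", {
  dir <- withr::local_tempdir()
  fx <- write_genome_fixture(dir, list(chr1 = "ACGTACGTACGTACGTACGT"),
                             list(list(seq = "chr1", type = "rRNA", start = 1,
                                       end = 4, strand = "+", id = "rrn1")))
  pr <- nt_profile_from_regions(fx$fa, fx$gff, "rRNA")
  expect_equal(unname(pr$fractions), rep(0.25, 4))
  expect_equal(names(pr$fractions), c("AMP", "CMP", "GMP", "UMP"))

  # mixed two-rRNA fixture vs hand tally: AACG (A2 C1 G1) + NGGT (G2 U1,
  # ambiguous base skipped)
  fx2 <- write_genome_fixture(dir, list(chr1 = "AACGNGGT"),
                              list(list(seq = "chr1", type = "rRNA", start = 1,
                                        end = 4, strand = "+", id = "r1"),
                                   list(seq = "chr1", type = "rRNA", start = 5,
                                        end = 8, strand = "+", id = "r2")))
  pr2 <- suppressWarnings(nt_profile_from_regions(fx2$fa, fx2$gff, "rRNA"))
  expect_equal(unname(pr2$fractions[c("AMP", "CMP", "GMP", "UMP")]),
               c(2, 1, 3, 1) / 7, tolerance = 1e-12)

  # whole-genome DNA counts pair A with T and G with C
  fx3 <- write_genome_fixture(dir, list(chr1 = "AAGG"), list())
  pr3 <- nt_profile_from_regions(fx3$fa, NULL, "whole_genome")
  expect_equal(unname(pr3$fractions), rep(0.25, 4), tolerance = 1e-12)
  expect_error(nt_profile_from_regions(fx3$fa, fx$gff2, "rRNA"))
})

test_that("biomass coefficients follow the mass-fraction formula", {
  profiles <- list(
    protein = monomer_profile("amino_acid", c(aa_c = 1), c(aa_c = 100)),
    rna = monomer_profile("rna_nucleotide", c(n1 = 0.5, n2 = 0.5),
                          c(n1 = 100, n2 = 200)),
    dna = monomer_profile("dna_nucleotide", c(d1 = 1), c(d1 = 310)))
  comp <- structure(list(
    fractions = c(protein = 0.5, rna = 0.3, glutamate = 0.05, glutamine = 0.005,
                  dna = 0.045, lps = 0.02, lipid = 0.03, murein = 0.02,
                  inorganic_ions = 0.01, soluble_pool = 0.02),
    gam = 15.8, growth_rate = 0.79), class = "biomass_composition")
  rxn <- build_biomass_reaction(comp, profiles, toy_lumped_species(),
                                toy_lumped_masses())
  # single-monomer polymer: f = 0.5, residue 100 -> 5 mmol/gCDW
  expect_equal(unname(rxn$stoich["aa_c"]), -5, tolerance = 1e-12)
  # two monomers phi = (.5,.5), masses (100,200), f = 0.3 -> 1.0 each
  expect_equal(unname(rxn$stoich["n1"]), -1, tolerance = 1e-12)
  expect_equal(unname(rxn$stoich["n2"]), -1, tolerance = 1e-12)
  # GAM rides along as an ATP + H2O hydrolysis
  expect_equal(unname(rxn$stoich["atp_c"]), -15.8, tolerance = 1e-12)
  expect_equal(unname(rxn$stoich["h2o_c"]), -15.8, tolerance = 1e-12)
  expect_equal(unname(rxn$stoich["adp_c"]), 15.8, tolerance = 1e-12)
  expect_equal(unname(rxn$stoich["pi_c"]), 15.8, tolerance = 1e-12)
  # biomass product coefficient 1
  expect_equal(unname(rxn$stoich["biomass_c"]), 1)

  # mass balance: coefficients x residue masses recover 1000 f per class
  g <- attr(rxn, "component_groups")
  expect_equal(sum(-g$protein * 100), 1000 * 0.5, tolerance = 1e-9)
  expect_equal(sum(-g$rna * c(n1 = 100, n2 = 200)[names(g$rna)]),
               1000 * 0.3, tolerance = 1e-9)
  expect_equal(sum(-g$dna * 310), 1000 * 0.045, tolerance = 1e-9)

  # missing residue mass -> error
  bad <- profiles
  bad$rna <- monomer_profile("rna_nucleotide", c(n1 = 1), c(n1 = 100))
  bad$rna$residue_masses <- c(n2 = 100)
  expect_error(build_biomass_reaction(comp, bad, toy_lumped_species(),
                                      toy_lumped_masses()))
})

test_that("biomass mass balance holds for genome-derived compositions", {
  comp <- composition_at(0.79, ref_fits, gam = 15.8)
  rxn <- build_biomass_reaction(comp, toy_profiles(), toy_lumped_species(),
                                toy_lumped_masses())
  g <- attr(rxn, "component_groups")
  masses <- list(protein = c(aa_c = 100), rna = c(nt_c = 320),
                 dna = c(dnt_c = 310))
  for (cls in names(masses)) {
    expect_equal(sum(-g[[cls]] * masses[[cls]][names(g[[cls]])]),
                 1000 * comp$fractions[[cls]], tolerance = 1e-9)
  }
})

test_that("sensitivity scan is null at factor 1 and for non-limiting parts", {
  m <- toy_glc()
  s0 <- sensitivity_scan(m, c("dna", "lps", "lipid", "murein",
                              "inorganic_ions", "soluble_pool"),
                         c(1, 1), grid = 1L)
  expect_equal(s0$max_rel_change, 0, tolerance = 1e-9)

  # supply the lumped remainder species for free: perturbing any component
  # that maps to it no longer moves the optimum
  m2 <- add_metabolite(m, metabolite("rem_e", compartment = "extracellular"))
  m2 <- add_reaction(m2, reaction("EX_rem", c(rem_e = -1), -1000, 0))
  m2 <- add_reaction(m2, reaction("REMt", c(rem_e = -1, rem_c = 1), 0, 1000))
  s1 <- sensitivity_scan(m2, c("lps", "soluble_pool"), c(0.75, 1.25), grid = 5L)
  expect_lt(s1$max_rel_change, 1e-6)

  # carbon-limited components do move it, and a wider range never shrinks it
  s2 <- sensitivity_scan(m, "soluble_pool", c(0.9, 1.1), grid = 3L)
  s3 <- sensitivity_scan(m, "soluble_pool", c(0.75, 1.25), grid = 3L)
  expect_gt(s3$max_rel_change, 0)
  expect_gte(s3$max_rel_change, s2$max_rel_change)

  expect_error(sensitivity_scan(m, "nonsense", c(0.75, 1.25)), "unknown")
})
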