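bundle <- load_reference_bundle()
aa_props <- bundle$amino_acids

test_that("zygosity bands partition [0, 100] with the stated boundaries", {
  expect_identical(zygosity_from_vaf(c(65, 64.9, 40, 39.99, 20, 0, 100, NA)),
                   c("homozygous", "heterozygous", "heterozygous",
                     "subclonal_low", "subclonal_low", "subclonal_low",
                     "homozygous", "unknown"))
  expect_error(zygosity_from_vaf(120), "\\[0, 100\\]")
  expect_error(zygosity_from_vaf(-1), "\\[0, 100\\]")

  # partition property: every VAF on a fine grid gets exactly one label
  grid <- seq(0, 100, by = 0.1)
  z <- zygosity_from_vaf(grid)
  expect_true(all(z %in% c("subclonal_low", "heterozygous", "homozygous")))
})

test_that("hydrogen-bond disruption follows the donor/acceptor rule", {
  expect_true(hbond_disruption("Y", "C", aa_props))   # bonding -> none
  expect_true(hbond_disruption("K", "E", aa_props))   # donor -> acceptor
  expect_true(hbond_disruption("E", "K", aa_props))   # acceptor -> donor
  expect_false(hbond_disruption("R", "H", aa_props))  # donor -> both: kept
  expect_false(hbond_disruption("A", "G", aa_props))  # neither -> neither
  expect_false(hbond_disruption("S", "T", aa_props))  # both -> both
  expect_error(hbond_disruption("B", "C", aa_props), "nonstandard")

  # exhaustive agreement with the independently coded rule over all pairs
  pairs <- expand.grid(ref = ORACLE$aa20, alt = ORACLE$aa20,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_identical(hbond_disruption(pairs$ref, pairs$alt, aa_props),
                   unname(oracle_hbond_disrupted(pairs$ref, pairs$alt)))
})

test_that("charge/polarity change crosses classes, His placement switchable", {
  expect_true(polarity_charge_change("R", "W", aa_props))
  expect_false(polarity_charge_change("S", "T", aa_props))
  expect_true(polarity_charge_change("R", "H", aa_props))
  # under the positive-His convention R -> H stays within class
  expect_false(polarity_charge_change("R", "H", aa_props,
                                      his_class = "positive"))

  pairs <- expand.grid(ref = ORACLE$aa20, alt = ORACLE$aa20,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_identical(polarity_charge_change(pairs$ref, pairs$alt, aa_props),
                   oracle_polarity_change(pairs$ref, pairs$alt))
})

test_that("nucleotide-change features classify transitions, CpG and G:C>T:A", {
  f <- nucleotide_change_features("C", "T", context = "ACG")
  expect_identical(f$nt_change_class, "transition")
  expect_true(f$is_CpG_CtoT_transition)
  expect_false(f$is_GC_to_TA_transversion)

  f <- nucleotide_change_features("G", "T", context = "AGA")
  expect_identical(f$nt_change_class, "transversion")
  expect_false(f$is_CpG_CtoT_transition)
  expect_true(f$is_GC_to_TA_transversion)

  f <- nucleotide_change_features("A", "G")
  expect_identical(f$nt_change_class, "transition")
  expect_false(f$is_CpG_CtoT_transition)

  # reverse-strand CpG (G>A with preceding C); C>T without CG context
  expect_true(nucleotide_change_features("G", "A",
                                         context = "CGT")$is_CpG_CtoT_transition)
  expect_false(nucleotide_change_features("C", "T",
                                          context = "ACT")$is_CpG_CtoT_transition)
  # bundled position list as fallback when context is unavailable
  f <- nucleotide_change_features("C", "T", position = 1234,
                                  cpg_positions = c(1234, 999))
  expect_true(f$is_CpG_CtoT_transition)
  expect_identical(nucleotide_change_features(NA, NA)$nt_change_class, "none")
  expect_error(nucleotide_change_features("C", "C"), "must differ")
})

test_that("annotate_cohort composes the per-mutation features", {
  m <- data.frame(
    sample_id = c("R175H", "G245S", "SPLICE", "STOP"),
    kind = c("missense", "missense", "splice", "nonsense_stop"),
    ref_aa = c("R", "G", NA, "R"),
    codon = c(175L, 245L, NA, 342L),
    alt_aa = c("H", "S", NA, NA),
    vaf_percent = c(70, 45, 30, NA),
    ref_nt = c("G", "G", "C", "C"),
    alt_nt = c("A", "A", "T", "T"),
    trinucleotide_context = c("CGC", "GGC", "ACG", "ACT"),
    stringsAsFactors = FALSE)
  a <- annotate_cohort(m, bundle)

  r175 <- a[a$sample_id == "R175H", ]
  expect_identical(r175$domain, "DNA_binding")
  expect_true(r175$is_hotspot)
  expect_true(r175$is_conserved)
  expect_true(r175$in_L2L3)
  expect_true(r175$polarity_change)
  expect_identical(r175$zygosity, "homozygous")

  g245 <- a[a$sample_id == "G245S", ]
  expect_true(g245$native_glycine_substitution)
  expect_true(g245$is_hotspot)

  sp <- a[a$sample_id == "SPLICE", ]
  expect_identical(sp$domain, "unknown")
  expect_identical(sp$secondary_structure, "unknown")
  expect_false(sp$is_hotspot)
  expect_true(sp$is_CpG_CtoT_transition)   # nt features still computed

  st <- a[a$sample_id == "STOP", ]
  expect_identical(st$domain, "C_terminal")  # codon-bearing stop keeps domain
  expect_true(is.na(st$hbond_disrupted))

  expect_error(annotate_cohort(data.frame(sample_id = "B", kind = "missense",
                                          ref_aa = "R", codon = 500L,
                                          alt_aa = "H"), bundle),
               "codon outside")

  # determinism: identical input -> identical annotation
  expect_identical(a, annotate_cohort(m, bundle))
})

test_that("annotation flags agree with brute-force rule membership for every codon", {
  codons <- 1:393
  m <- data.frame(sample_id = sprintf("C%03d", codons), kind = "missense",
                  ref_aa = oracle_ref_residue(codons), codon = codons,
                  alt_aa = "A", stringsAsFactors = FALSE)
  m$alt_aa[m$ref_aa == "A"] <- "V"
  a <- annotate_cohort(m, bundle)

  expect_identical(a$domain, oracle_domain(codons))
  expect_identical(a$is_hotspot, codons %in% ORACLE$hotspots)
  expect_identical(a$is_new_hotspot, codons %in% ORACLE$new_hotspots)
  expect_identical(a$is_zinc_ligand, codons %in% ORACLE$zinc)
  expect_identical(a$is_conserved, codons %in% ORACLE$conserved)
  expect_identical(a$in_L2L3, codons %in% ORACLE$l2l3)
  expect_identical(a$native_glycine_substitution,
                   a$ref_aa == "G" & codons %in% ORACLE$glycine_sites)
})
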