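bundle <- load_reference_bundle()

annotate_one <- function(kind, ref = NA, codon = NA, alt = NA, vaf = NA) {
  annotate_cohort(data.frame(sample_id = "S", kind = kind,
                             ref_aa = ref, codon = as.integer(codon),
                             alt_aa = alt, vaf_percent = vaf,
                             stringsAsFactors = FALSE), bundle)
}

test_that("Poeta algorithm: truncating disruptive, L2-L3 polarity missense disruptive", {
  expect_identical(poeta_classify(annotate_one("nonsense_stop", "R", 306)),
                   "disruptive")
  expect_identical(poeta_classify(annotate_one("frameshift", "E", 62)),
                   "disruptive")
  expect_identical(poeta_classify(annotate_one("inframe_indel", "I", 255)),
                   "disruptive")
  expect_identical(poeta_classify(annotate_one("splice", codon = 187)),
                   "disruptive")
  # Y220C: outside L2-L3 -> nondisruptive
  expect_identical(poeta_classify(annotate_one("missense", "Y", 220, "C")),
                   "nondisruptive")
  # R175H: in 163-195 with charge-class change -> disruptive
  expect_identical(poeta_classify(annotate_one("missense", "R", 175, "H")),
                   "disruptive")
  # in L2-L3 without polarity change -> nondisruptive (S240T, both polar)
  expect_identical(poeta_classify(annotate_one("missense", "S", 240, "T")),
                   "nondisruptive")
  expect_error(poeta_classify(annotate_one("other", "P", 72, "P")),
               "unclassifiable")
})

test_that("high-risk reclassification rules fire in precedence order", {
  # Y220C heterozygous: H-bond disruption (D3)
  hr <- highrisk_classify(annotate_one("missense", "Y", 220, "C", vaf = 45))
  expect_identical(hr$highrisk_class, "high_risk")
  expect_identical(hr$fired_rules, "D3_hbond_disruption")

  # zinc ligand C176 (D2); C->S keeps no H-bond ability to lose
  hr <- highrisk_classify(annotate_one("missense", "C", 176, "S", vaf = 45))
  expect_identical(hr$highrisk_class, "high_risk")
  expect_match(hr$fired_rules, "D2_zinc_ligand")

  # homozygous VAF 70% (D1)
  hr <- highrisk_classify(annotate_one("missense", "S", 127, "T", vaf = 70))
  expect_match(hr$fired_rules, "D1_homozygous")
  expect_identical(hr$highrisk_class, "high_risk")

  # same substitution heterozygous: structured, bonding kept -> low risk (C1)
  hr <- highrisk_classify(annotate_one("missense", "S", 127, "T", vaf = 45))
  expect_identical(hr$highrisk_class, "low_risk")
  expect_identical(hr$fired_rules, "C1_structured_hbond_kept")

  # S127F in a strand loses bonding -> D3 despite assigned structure
  hr <- highrisk_classify(annotate_one("missense", "S", 127, "F", vaf = 45))
  expect_identical(hr$highrisk_class, "high_risk")
  expect_identical(hr$fired_rules, "D3_hbond_disruption")

  # unassigned secondary structure (D4): N-terminal missense
  hr <- highrisk_classify(annotate_one("missense", "A", 50, "V", vaf = 45))
  expect_identical(hr$fired_rules, "D4_unassigned_structure")

  # missing VAF never fires D1
  hr <- highrisk_classify(annotate_one("missense", "A", 50, "V"))
  expect_false(grepl("D1", hr$fired_rules))

  # truncating mutations are high risk and never downgraded
  hr <- highrisk_classify(annotate_one("nonsense_stop", "R", 306, vaf = 45))
  expect_identical(hr$highrisk_class, "high_risk")
  expect_identical(hr$fired_rules, "truncating_type")

  # subclonal VAF is not homozygous
  hr <- highrisk_classify(annotate_one("missense", "S", 127, "T", vaf = 20))
  expect_identical(hr$highrisk_class, "low_risk")
})

test_that("replaying fired rules reproduces every call", {
  cohort <- simulate_cohort(simulation_config(n_patients = 150), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  ann <- annotate_cohort(read_mutations(paths[["mutations"]]), bundle)
  calls <- classify_cohort(ann, cohort$clinical)
  mutated <- calls$fired_rules != "wild_type"
  expect_true(all(mutated == (calls$highrisk_class != "wild_type")))
  expect_identical(replay_fired_rules(calls$fired_rules),
                   calls$highrisk_class)
})

test_that("classify_cohort joins clinical samples and labels wild types", {
  m <- data.frame(
    sample_id = c("M1", "M2", "M3", "ORPHAN"),
    kind = c("missense", "missense", "nonsense_stop", "missense"),
    ref_aa = c("Y", "S", "R", "R"), codon = c(220L, 127L, 306L, 175L),
    alt_aa = c("C", "T", NA, "H"), vaf_percent = c(45, 45, 50, 45),
    stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = c("M1", "M2", "M3", "W1", "W2", "W3"),
                         os_time = 100, os_event = 1L,
                         stringsAsFactors = FALSE)
  ann <- annotate_cohort(m, bundle)
  suppressMessages(calls <- classify_cohort(ann, clinical))

  expect_identical(nrow(calls), 6L)
  counts <- table(calls$highrisk_class)
  expect_identical(as.integer(counts[["wild_type"]]), 3L)
  expect_identical(attr(calls, "unmatched"), "ORPHAN")
  # wild type in one scheme iff wild type in the other
  expect_identical(calls$poeta_class == "wild_type",
                   calls$highrisk_class == "wild_type")

  # empty mutation table -> all wild type
  calls0 <- classify_cohort(ann[0, ], clinical)
  expect_true(all(calls0$highrisk_class == "wild_type"))

  # duplicated sample rows are rejected
  expect_error(classify_cohort(rbind(ann, ann[1, ]), clinical),
               "single")
})
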