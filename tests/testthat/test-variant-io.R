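test_that("protein-change parser handles the common MAF dialects", {
  cases <- list(
    list("p.R273H", "missense", "R", 273L, "H"),
    list("R273H", "missense", "R", 273L, "H"),
    list("p.Y220C", "missense", "Y", 220L, "C"),
    list("p.Arg273His", "missense", "R", 273L, "H"),
    list("p.R306*", "nonsense_stop", "R", 306L, "*"),
    list("p.R306X", "nonsense_stop", "R", 306L, "*"),
    list("p.Arg306Ter", "nonsense_stop", "R", 306L, "*"),
    list("p.E62fs", "frameshift", "E", 62L, NA_character_),
    list("p.E62Gfs*4", "frameshift", "E", 62L, NA_character_),
    list("p.I255del", "inframe_indel", "I", 255L, NA_character_),
    list("p.K120_A123del", "inframe_indel", "K", 120L, NA_character_),
    list("p.A39_Q40insV", "inframe_indel", "A", 39L, NA_character_),
    list("p.X187_splice", "splice", NA_character_, 187L, NA_character_),
    list("_splice", "splice", NA_character_, NA_integer_, NA_character_),
    list("p.P72P", "other", "P", 72L, "P"))
  for (cs in cases) {
    p <- parse_protein_change(cs[[1]])
    expect_identical(p$kind, cs[[2]], info = cs[[1]])
    expect_identical(p$ref_aa, cs[[3]], info = cs[[1]])
    expect_identical(p$codon, cs[[4]], info = cs[[1]])
    expect_identical(p$alt_aa, cs[[5]], info = cs[[1]])
    expect_identical(p$raw, cs[[1]])
  }

  # dialect flag drops the splice codon
  expect_identical(parse_protein_change("p.X187_splice",
                                        keep_splice_codon = FALSE)$codon,
                   NA_integer_)
})

test_that("unparseable strings raise a classed error and fuzzing never crashes", {
  expect_error(parse_protein_change("p.banana"), class = "p53_parse_error")
  expect_error(parse_protein_change(""), class = "p53_parse_error")
  err <- tryCatch(parse_protein_change("p.Z999!"), condition = identity)
  expect_s3_class(err, "p53_parse_error")
  expect_identical(err$raw, "p.Z999!")

  set.seed(42)
  alphabet <- c(LETTERS, letters, 0:9, ".", "_", "*", "")
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE),
               collapse = "")
    res <- tryCatch(parse_protein_change(s), condition = identity)
    ok <- inherits(res, "p53_protein_change") ||
      inherits(res, "p53_parse_error")
    expect_true(ok, info = s)
  }
})

test_that("read_mutations filters genes, normalises VAF and maps kinds", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_fixture(tmp, c(
    "S1\tTP53\tMissense_Mutation\tp.R175H\t0.65\tG\tA\tCGC",
    "S2\tEGFR\tMissense_Mutation\tp.L858R\t0.4\tT\tG\tCTG",
    "S3\tTP53\tSplice_Site\t\t0.30\tC\tT\tACG"))
  suppressMessages(m <- read_mutations(tmp))

  expect_identical(nrow(m), 2L)
  expect_setequal(m$sample_id, c("S1", "S3"))
  expect_equal(m$vaf_percent[m$sample_id == "S1"], 65)   # fraction -> percent
  expect_identical(m$kind[m$sample_id == "S3"], "splice")
  expect_identical(m$codon[m$sample_id == "S1"], 175L)

  # explicit percent unit is left alone
  suppressMessages(m2 <- read_mutations(tmp, vaf_unit = "percent"))
  expect_equal(m2$vaf_percent[m2$sample_id == "S1"], 0.65)

  # missing required column
  writeLines("sample_id\tgene\tdna_vaf\nS1\tTP53\t0.5", tmp)
  expect_error(read_mutations(tmp), "required column")
})

test_that("single-mutation filter excludes doubles and finds wild types", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_fixture(tmp, c(
    "S1\tTP53\tMissense_Mutation\tp.R175H\t0.5\tG\tA\tCGC",
    "S1\tTP53\tNonsense_Mutation\tp.R306*\t0.4\tC\tT\tACG",
    "S2\tTP53\tMissense_Mutation\tp.Y220C\t0.6\tA\tG\tTAC"))
  suppressMessages(m <- read_mutations(tmp))
  clinical <- data.frame(sample_id = c("S1", "S2", "S3"))

  filt <- apply_single_mutation_filter(m, clinical)
  expect_identical(filt$records$sample_id, "S2")
  expect_identical(filt$exclusions$sample_id, "S1")
  expect_identical(filt$exclusions$reason, "multiple_mutations")
  expect_identical(filt$exclusions$n_mutations, 2L)
  expect_identical(filt$wild_type_samples, "S3")
})

test_that("clinical reader maps subsites to the four HNSCC subgroups", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_fixture(tmp, c(
    "S1\tTonsil\tpositive\t55\tmale\t3\tG2\tnever\tno\tno\t900\t0\t800\t0",
    "S2\tFloor of mouth\tnegative\t67\tfemale\t4\tG3\tcurrent\tyes\tyes\t400\t1\t300\t1",
    "S3\tLarynx\tnegative\t60\tmale\t2\tG2\tex_lt15y\tyes\tno\t700\t1\t600\t0",
    "S4\tNasal cavity\tunknown\t71\tmale\t1\tG1\tunknown\tunknown\tunknown\t200\t0\t150\t0"))
  expect_warning(cl <- read_clinical(tmp), "unrecognised subsite")
  expect_identical(cl$site, c("OP", "OC", "L", "other"))
  expect_identical(cl$os_event, c(0L, 1L, 1L, 0L))
})

test_that("mutation tables round-trip through write and read unchanged", {
  cohort <- simulate_cohort(simulation_config(n_patients = 60), seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)

  m <- read_mutations(paths[["mutations"]])
  expect_identical(m$sample_id, cohort$mutations$sample_id)
  expect_identical(m$protein_change_raw, cohort$mutations$protein_change)
  expect_equal(m$vaf_percent, cohort$mutations$dna_vaf * 100,
               tolerance = 1e-12)

  cl <- read_clinical(paths[["clinical"]])
  expect_identical(cl$sample_id, cohort$clinical$sample_id)
  expect_equal(cl$os_time, cohort$clinical$os_time)
  expect_identical(cl$os_event, cohort$clinical$os_event)
  expect_identical(unname(cl$site),
                   unname(p53risk:::SITE_MAP[tolower(cohort$clinical$subsite)]))
})
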