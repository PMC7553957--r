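#' Run the full annotation / classification / statistics / survival pipeline
#'
#' Chains the modules end to end: read the mutation and clinical tables,
#' keep single-mutation samples, annotate, classify under both schemes, run
#' a standard battery of cohort association tests, fit the multivariate Cox
#' models (covariates: age, gender, stage, grade, plus each risk-class
#' factor with wild type as reference) and compare them by Harrell's C,
#' AIC and BIC. All artefacts are written to \code{out_dir} together with a
#' run manifest (package version, input file hashes, configuration echo,
#' seed, timestamp).
#'
#' @param mutations_path,clinical_path input TSV paths.
#' @param out_dir output directory, created if needed.
#' @param bundle reference bundle (packaged bundle by default).
#' @param seed optional seed recorded in the manifest and set before any
#'   stochastic step (the pipeline itself is deterministic).
#' @param his_class,chi2_correction,ties configuration knobs passed through
#'   to the respective modules.
#' @return invisibly, a list of class \code{p53_run} with the output paths
#'   and the in-memory results (\code{calls}, \code{fits},
#'   \code{comparison}, \code{stats}).
#' @export
run_pipeline <- function(mutations_path, clinical_path, out_dir,
                         bundle = load_reference_bundle(), seed = NULL,
                         his_class = "polar", chi2_correction = FALSE,
                         ties = "efron") {
  if (!file.exists(mutations_path))
    stop("mutation file not found: ", mutations_path, call. = FALSE)
  if (!file.exists(clinical_path))
    stop("clinical file not found: ", clinical_path, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) set.seed(seed)

  mutations <- read_mutations(mutations_path)
  clinical <- read_clinical(clinical_path)
  filt <- apply_single_mutation_filter(mutations, clinical)
  annotated <- annotate_cohort(filt$records, bundle = bundle,
                               his_class = his_class)
  admitted <- annotated$kind != "other"
  if (any(!admitted))
    message("run_pipeline: ", sum(!admitted),
            " mutation(s) with unmapped classification excluded")
  calls <- classify_cohort(annotated[admitted, , drop = FALSE], clinical)

  paths <- c(annotated = file.path(out_dir, "annotated.tsv"),
             risk_calls = file.path(out_dir, "risk_calls.tsv"),
             exclusions = file.path(out_dir, "exclusions.tsv"),
             stats = file.path(out_dir, "stats.tsv"),
             survival_fits = file.path(out_dir, "survival_fits.tsv"),
             km = file.path(out_dir, "km_curves.tsv"),
             comparison = file.path(out_dir, "model_comparison.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write_tsv(annotated, paths["annotated"])
  write_tsv(as.data.frame(calls), paths["risk_calls"])
  write_tsv(filt$exclusions, paths["exclusions"])

  stats_tab <- cohort_association_tests(calls,
                                        correction = chi2_correction)
  write_tsv(stats_tab, paths["stats"])

  fits <- comparison <- NULL
  km_tab <- NULL
  ok <- stats::complete.cases(calls$os_time, calls$os_event)
  if (sum(calls$os_event[ok], na.rm = TRUE) >= 10) {
    fits <- risk_model_fits(calls, ties = ties)
    comparison <- compare_models(fits$poeta, fits$highrisk)
    write_tsv(rbind(cbind(model = "poeta", fits$poeta$coefficients),
                    cbind(model = "highrisk", fits$highrisk$coefficients)),
              paths["survival_fits"])
    km_tab <- km_curves(calls$os_time[ok], calls$os_event[ok],
                        calls$highrisk_class[ok])
    write_tsv(km_tab, paths["km"])
    jsonlite::write_json(unclass(comparison), paths["comparison"],
                         auto_unbox = TRUE, digits = NA)
  } else {
    message("run_pipeline: too few events for survival modelling; ",
            "survival outputs skipped")
  }

  manifest <- list(
    tool = "p53risk",
    version = as.character(utils::packageVersion("p53risk")),
    inputs = list(
      mutations = list(path = mutations_path,
                       md5 = unname(tools::md5sum(mutations_path))),
      clinical = list(path = clinical_path,
                      md5 = unname(tools::md5sum(clinical_path)))),
    config = list(his_class = his_class, chi2_correction = chi2_correction,
                  ties = ties),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       null = "null")

  invisible(structure(list(paths = paths, calls = calls, fits = fits,
                           comparison = comparison, stats = stats_tab),
                      class = "p53_run"))
}

# Standard battery of WT/MUT association tests over the classified cohort.
cohort_association_tests <- function(calls, correction = FALSE) {
  mutated <- calls$highrisk_class != "wild_type"
  rows <- list()
  add <- function(name, variable, tab) {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return()
    tr <- tryCatch(pearson_chi2(tab, correction = correction),
                   error = function(e) NULL)
    if (is.null(tr)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      test = name, variable = variable, method = tr$method,
      statistic = tr$statistic, df = tr$df, p_value = tr$p_value)
  }
  known <- function(v) !is.na(v) & !(v %in% c("unknown", ""))

  k <- known(calls$site)
  add("mutation_by_site", "site", table(mutated[k], calls$site[k]))
  k <- known(calls$hpv_status)
  add("mutation_by_hpv", "hpv_status",
      table(mutated[k], calls$hpv_status[k]))
  k <- known(calls$perineural_invasion)
  add("mutation_by_perineural", "perineural_invasion",
      table(mutated[k], calls$perineural_invasion[k]))
  k <- known(calls$smoking)
  add("mutation_by_smoking", "smoking",
      table(mutated[k], calls$smoking[k] == "never"))
  k <- known(calls$gender)
  add("mutation_by_gender", "gender", table(mutated[k], calls$gender[k]))

  if (length(rows) == 0L)
    return(data.frame(test = character(0), variable = character(0),
                      method = character(0), statistic = numeric(0),
                      df = integer(0), p_value = numeric(0)))
  do.call(rbind, rows)
}

# Cox fits with the standard covariate set plus each risk-class factor
# (wild type as reference level).
risk_model_fits <- function(calls, ties = "efron") {
  base <- data.frame(
    age = calls$age,
    gender = factor(calls$gender),
    stage = as.numeric(calls$stage),
    grade = as.numeric(factor(calls$grade,
                              levels = c("G1", "G2", "G3", "G4"))))
  fit_for <- function(class_col, levels) {
    covs <- cbind(base,
                  risk = factor(calls[[class_col]], levels = levels))
    cox_fit(calls$os_time, calls$os_event, covs, ties = ties)
  }
  list(poeta = fit_for("poeta_class",
                       c("wild_type", "nondisruptive", "disruptive")),
       highrisk = fit_for("highrisk_class",
                          c("wild_type", "low_risk", "high_risk")))
}

#' @export
print.p53_run <- function(x, ...) {
  cat("pipeline run: ", length(x$paths), " artefacts under ",
      dirname(x$paths[1]), "\n", sep = "")
  print(x$calls)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
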