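#' Simulation configuration for synthetic HNSCC cohorts
#'
#' Defaults reproduce the study cohort conditions: 415 patients, 286/415
#' mutated, mutation-type weights frameshift 51 : inframe 8 : missense 152 :
#' splice 26 : stop 49, anatomical-site weights OC 246 : OP 62 : HP 9 :
#' L 90, and observed VAF with mean 46.73\%, SD 19.33\% on the range
#' 5--97\% (the generator solves for the pre-truncation normal whose
#' truncated moments match those reported, observed moments). Missense
#' codons are drawn uniformly over the DNA-binding domain (98--292) with
#' 20\% of the mass on the nine hotspot residues. Survival is exponential
#' with hazard \code{baseline_hazard * exp(true_log_hr[class])} under
#' independent exponential censoring calibrated to the target censoring
#' fraction, plus an administrative follow-up horizon.
#'
#' @param n_patients cohort size.
#' @param seed optional RNG seed stored in the config.
#' @param site_weights named non-negative weights over OC, OP, HP, L.
#' @param p_mutated probability a patient carries one TP53 mutation.
#' @param type_weights named weights over frameshift, inframe, missense,
#'   splice, stop.
#' @param vaf_mean,vaf_sd,vaf_range target moments and support of the
#'   observed VAF distribution (percent).
#' @param vaf_missing_rate fraction of mutated samples with VAF unreported.
#' @param missense_codon_distribution \code{"uniform_dbd_weighted"}
#'   (default) or \code{"empirical_hotspot"} (all missense at hotspots).
#' @param hotspot_mass probability mass on the nine hotspot residues under
#'   the default codon distribution.
#' @param true_log_hr named log hazard ratios per generating class
#'   (\code{wild_type}, \code{low_risk}, \code{high_risk}).
#' @param baseline_hazard baseline event hazard per day.
#' @param censoring_target fraction of subjects censored (before the
#'   horizon is applied).
#' @param followup_horizon administrative censoring time, days.
#' @param confound_stage couple tumour stage to risk class (stress test for
#'   multivariate adjustment).
#' @return a validated list of class \code{p53_sim_config}.
#' @export
simulation_config <- function(n_patients = 415L,
                              seed = NULL,
                              site_weights = c(OC = 246, OP = 62, HP = 9,
                                               L = 90),
                              p_mutated = 286 / 415,
                              type_weights = c(frameshift = 51, inframe = 8,
                                               missense = 152, splice = 26,
                                               stop = 49),
                              vaf_mean = 46.73, vaf_sd = 19.33,
                              vaf_range = c(5, 97),
                              vaf_missing_rate = 15 / 286,
                              missense_codon_distribution =
                                c("uniform_dbd_weighted",
                                  "empirical_hotspot"),
                              hotspot_mass = 0.20,
                              true_log_hr = c(wild_type = 0, low_risk = 0,
                                              high_risk = log(1.8)),
                              baseline_hazard = 4e-4,
                              censoring_target = 0.6,
                              followup_horizon = 6000,
                              confound_stage = FALSE) {
  missense_codon_distribution <- match.arg(missense_codon_distribution)
  cfg <- list(n_patients = as.integer(n_patients), seed = seed,
              site_weights = site_weights, p_mutated = p_mutated,
              type_weights = type_weights, vaf_mean = vaf_mean,
              vaf_sd = vaf_sd, vaf_range = vaf_range,
              vaf_missing_rate = vaf_missing_rate,
              missense_codon_distribution = missense_codon_distribution,
              hotspot_mass = hotspot_mass, true_log_hr = true_log_hr,
              baseline_hazard = baseline_hazard,
              censoring_target = censoring_target,
              followup_horizon = followup_horizon,
              confound_stage = confound_stage)
  if (cfg$n_patients < 1L) stop("n_patients must be positive", call. = FALSE)
  if (any(cfg$site_weights < 0) || sum(cfg$site_weights) == 0)
    stop("site_weights must be non-negative with positive sum",
         call. = FALSE)
  if (any(cfg$type_weights < 0) || sum(cfg$type_weights) == 0)
    stop("type_weights must be non-negative with positive sum",
         call. = FALSE)
  if (cfg$p_mutated < 0 || cfg$p_mutated > 1)
    stop("p_mutated must lie in [0, 1]", call. = FALSE)
  if (cfg$vaf_range[1] < 0 || cfg$vaf_range[2] > 100 ||
      cfg$vaf_range[1] >= cfg$vaf_range[2])
    stop("vaf_range must be an increasing interval within [0, 100]",
         call. = FALSE)
  if (!all(c("wild_type", "low_risk", "high_risk") %in%
           names(cfg$true_log_hr)))
    stop("true_log_hr needs wild_type, low_risk and high_risk entries",
         call. = FALSE)
  class(cfg) <- "p53_sim_config"
  cfg
}

# Pre-truncation (mu, sigma) whose truncated-normal moments on [lo, hi]
# equal the target mean and sd.
solve_truncnorm <- function(mean, sd, lo, hi) {
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / z
    v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma); pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, pa, pb), mu, sigma)
}

#' Simulate a synthetic HNSCC cohort with ground truth
#'
#' Generates a mutation table and a clinical table in the exact schemas the
#' readers consume, plus a truth table carrying each sample's generating
#' risk class (obtained by applying the packaged annotation and
#' classification rules to the planted mutation) and hazard multiplier.
#' Reproducible for a fixed seed.
#'
#' @param config a \code{p53_sim_config} (default configuration if omitted).
#' @param seed RNG seed; overrides \code{config$seed}.
#' @param bundle reference bundle used to derive truth classes.
#' @return an object of class \code{p53_synthetic_cohort}: list with
#'   \code{mutations}, \code{clinical}, \code{truth} data frames and the
#'   \code{config}.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 50), seed = 1)
#' table(cohort$truth$truth_class)
#' @export
simulate_cohort <- function(config = simulation_config(), seed = NULL,
                            bundle = load_reference_bundle()) {
  stopifnot(inherits(config, "p53_sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("SYN-%05d", seq_len(n))

  ## ---- mutations ----------------------------------------------------------
  mutated <- stats::runif(n) < config$p_mutated
  n_mut <- sum(mutated)
  types <- sample(names(config$type_weights), n_mut, replace = TRUE,
                  prob = config$type_weights / sum(config$type_weights))

  hotspots <- c(HOTSPOT_CODONS, NEW_HOTSPOT_CODONS)
  draw_codon <- function(kind) {
    if (kind == "missense") {
      if (config$missense_codon_distribution == "empirical_hotspot")
        return(sample(hotspots, 1L))
      if (stats::runif(1) < config$hotspot_mass) sample(hotspots, 1L)
      else sample(DOMAIN_DNA_BINDING[1]:DOMAIN_DNA_BINDING[2], 1L)
    } else {
      sample.int(TP53_N_RESIDUES, 1L)
    }
  }
  ref_at <- function(codon) {
    known <- KNOWN_RESIDUE_IDENTITY[as.character(codon)]
    if (!is.na(known)) unname(known) else sample(AA_ONE, 1L)
  }

  tv <- solve_truncnorm(config$vaf_mean, config$vaf_sd,
                        config$vaf_range[1], config$vaf_range[2])
  vafs <- round(rtruncnorm(n_mut, tv$mu, tv$sigma,
                           config$vaf_range[1], config$vaf_range[2]), 2)
  vafs[stats::runif(n_mut) < config$vaf_missing_rate] <- NA_real_

  classification_of <- c(frameshift = "Frame_Shift_Del",
                         inframe = "In_Frame_Del",
                         missense = "Missense_Mutation",
                         splice = "Splice_Site",
                         stop = "Nonsense_Mutation")

  prot <- character(n_mut); ref_nt <- character(n_mut)
  alt_nt <- character(n_mut); ctx <- character(n_mut)
  for (i in seq_len(n_mut)) {
    codon <- draw_codon(types[i])
    ref <- ref_at(codon)
    prot[i] <- switch(types[i],
      missense = paste0("p.", ref, codon,
                        sample(setdiff(AA_ONE, ref), 1L)),
      stop = paste0("p.", ref, codon, "*"),
      frameshift = paste0("p.", ref, codon, "fs"),
      inframe = paste0("p.", ref, codon, "del"),
      splice = paste0("p.X", codon, "_splice"))
    # a plausible causal single-base change with occasional CpG context
    ref_nt[i] <- sample(c("A", "C", "G", "T"), 1L)
    alt_nt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref_nt[i]), 1L)
    ctx[i] <- if (ref_nt[i] == "C" && stats::runif(1) < 0.3)
      paste0(sample(c("A", "C", "G", "T"), 1L), "CG")
    else paste0(sample(c("A", "C", "G", "T"), 1L), ref_nt[i],
                sample(c("A", "C", "G", "T"), 1L))
  }

  mutations <- data.frame(
    sample_id = ids[mutated],
    gene = "TP53",
    variant_classification = unname(classification_of[types]),
    protein_change = prot,
    dna_vaf = vafs / 100,   # Xena-style fraction; the reader normalises
    ref_nt = ref_nt, alt_nt = alt_nt, trinucleotide_context = ctx,
    stringsAsFactors = FALSE)

  ## ---- truth classes via the packaged rules -------------------------------
  parsed <- parse_protein_changes(mutations$protein_change)
  rec <- data.frame(sample_id = mutations$sample_id, gene = "TP53",
                    variant_classification = mutations$variant_classification,
                    kind = unname(CLASSIFICATION_MAP[
                      mutations$variant_classification]),
                    ref_aa = parsed$ref_aa, codon = parsed$codon,
                    alt_aa = parsed$alt_aa,
                    protein_change_raw = mutations$protein_change,
                    vaf_percent = vafs, ref_nt = ref_nt, alt_nt = alt_nt,
                    trinucleotide_context = ctx, stringsAsFactors = FALSE)
  ann <- annotate_cohort(rec, bundle = bundle)
  hr_call <- highrisk_classify(ann)
  truth_class <- rep("wild_type", n)
  truth_class[mutated] <- hr_call$highrisk_class
  poeta_truth <- rep("wild_type", n)
  poeta_truth[mutated] <- poeta_classify(ann)

  ## ---- clinical covariates ------------------------------------------------
  site <- sample(names(config$site_weights), n, replace = TRUE,
                 prob = config$site_weights / sum(config$site_weights))
  subsite_pool <- list(
    OC = c("Oral Tongue", "Floor of mouth", "Buccal Mucosa", "Hard Palate",
           "Alveolar Ridge", "Oral Cavity", "Lip"),
    OP = c("Base of tongue", "Tonsil", "Oropharynx"),
    HP = "Hypopharynx", L = "Larynx")
  subsite <- vapply(site, function(s) sample(subsite_pool[[s]], 1L),
                    character(1))
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.08, 0.14, 0.20, 0.58))
  if (config$confound_stage) {
    hi <- truth_class == "high_risk"
    stage[hi] <- sample(1:4, sum(hi), replace = TRUE,
                        prob = c(0.03, 0.07, 0.2, 0.7))
  }
  grade <- sample(c("G1", "G2", "G3"), n, replace = TRUE,
                  prob = c(0.12, 0.60, 0.28))
  gender <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.73, 0.27))
  age <- round(pmin(pmax(stats::rnorm(n, 61, 12), 19), 90))
  smoking <- sample(c("never", "current", "ex_lt15y", "ex_ge15y", "unknown"),
                    n, replace = TRUE, prob = c(0.25, 0.30, 0.20, 0.15, 0.10))
  packs <- ifelse(smoking %in% c("never", "unknown"), NA,
                  round(stats::rlnorm(n, log(20), 0.6), 1))
  alcohol <- sample(c("yes", "no", "unknown"), n, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
  perineural <- sample(c("yes", "no", "unknown"), n, replace = TRUE,
                       prob = c(0.35, 0.45, 0.2))
  hpv <- ifelse(site == "OP",
                sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
                sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                       prob = c(0.04, 0.8, 0.16)))

  # expression: wild-type tumours express more p53 mRNA than mutated ones
  mrna <- round(ifelse(mutated, stats::rnorm(n, 3.49, 1.1),
                       stats::rnorm(n, 4.28, 1.0)), 4)
  mrna <- pmin(pmax(mrna, 0.3), 7)
  rppa <- round(stats::rnorm(n, 0, 0.91), 4)
  rppa[stats::runif(n) < 0.58] <- NA_real_

  ## ---- survival -----------------------------------------------------------
  hazard_mult <- exp(unname(config$true_log_hr[truth_class]))
  if (config$confound_stage)
    hazard_mult <- hazard_mult * exp(0.25 * (stage - mean(stage)))
  hazard <- config$baseline_hazard * hazard_mult
  cens_rate <- calibrate_censoring(hazard, config$censoring_target)
  t_event <- stats::rexp(n, hazard)
  t_cens <- stats::rexp(n, cens_rate)
  os_time <- pmin(t_event, t_cens, config$followup_horizon)
  os_event <- as.integer(t_event <= pmin(t_cens, config$followup_horizon))
  t_event2 <- stats::rexp(n, 1.4 * hazard)
  dfs_time <- pmin(t_event2, t_cens, config$followup_horizon)
  dfs_event <- as.integer(t_event2 <= pmin(t_cens, config$followup_horizon))

  clinical <- data.frame(
    sample_id = ids, subsite = subsite, hpv_status = hpv, age = age,
    gender = gender, stage = stage, grade = grade, smoking = smoking,
    packs_smoked = packs, alcohol = alcohol,
    perineural_invasion = perineural,
    os_time = round(os_time, 1), os_event = os_event,
    dfs_time = round(dfs_time, 1), dfs_event = dfs_event,
    mrna_log2fpkm1 = mrna, rppa_z = rppa, stringsAsFactors = FALSE)

  truth <- data.frame(sample_id = ids, truth_class = truth_class,
                      poeta_truth = poeta_truth,
                      hazard_multiplier = hazard_mult,
                      stringsAsFactors = FALSE)

  structure(list(mutations = mutations, clinical = clinical, truth = truth,
                 config = config),
            class = "p53_synthetic_cohort")
}

# exponential censoring rate mu with E[h / (h + mu)] = 1 - target
calibrate_censoring <- function(hazard, target) {
  f <- function(mu) mean(hazard / (hazard + mu)) - (1 - target)
  stats::uniroot(f, lower = 1e-9, upper = 10, tol = 1e-12)$root
}

#' Frequency summaries of a synthetic cohort
#'
#' @param cohort a \code{p53_synthetic_cohort}.
#' @return list with \code{n}, \code{n_mutated}, \code{type_counts},
#'   \code{site_counts}, \code{class_counts} and \code{vaf_summary}
#'   (mean, sd, n of the non-missing VAF in percent).
#' @export
spectrum_summary <- function(cohort) {
  stopifnot(inherits(cohort, "p53_synthetic_cohort"))
  kinds <- unname(CLASSIFICATION_MAP[cohort$mutations$variant_classification])
  vaf <- cohort$mutations$dna_vaf * 100
  vaf <- vaf[!is.na(vaf)]
  site <- unname(SITE_MAP[tolower(cohort$clinical$subsite)])
  list(n = nrow(cohort$clinical),
       n_mutated = nrow(cohort$mutations),
       type_counts = table(factor(kinds, levels = c("frameshift",
                                                    "inframe_indel",
                                                    "missense", "splice",
                                                    "nonsense_stop"))),
       site_counts = table(factor(site, levels = c("OC", "OP", "HP", "L"))),
       class_counts = table(factor(cohort$truth$truth_class,
                                   levels = c("wild_type", "low_risk",
                                              "high_risk"))),
       vaf_summary = c(mean = mean(vaf), sd = stats::sd(vaf),
                       n = length(vaf)))
}

#' Write a synthetic cohort to TSV files
#'
#' @param cohort a \code{p53_synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return named paths of \code{mutations.tsv}, \code{clinical.tsv},
#'   \code{truth.tsv}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "p53_synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(cohort$mutations, paths["mutations"])
  write_tsv(cohort$clinical, paths["clinical"])
  write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}

#' @export
print.p53_synthetic_cohort <- function(x, ...) {
  s <- spectrum_summary(x)
  cat("synthetic HNSCC cohort:", s$n, "patients,", s$n_mutated,
      "with a single TP53 mutation\n")
  cat("truth classes:",
      paste(names(s$class_counts), as.integer(s$class_counts),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
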