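#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit estimates per group plus the k-sample log-rank chi-square
#' test on k - 1 degrees of freedom.
#'
#' @param time follow-up time (same unit throughout, days here).
#' @param event event indicator (1 event, 0 censored).
#' @param group group labels (at least two groups).
#' @return a list with \code{curves} (data frame \code{group}, \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv}) and \code{test} (a
#'   \code{p53_test_result}).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(as.character(group))
  check_surv_input(time, event)
  if (nlevels(group) < 2L)
    stop("log-rank needs at least two groups", call. = FALSE)
  if (sum(event) == 0L)
    stop("no events: the log-rank test is undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  df <- length(sd$n) - 1L
  list(curves = km_curves(time, event, group),
       test = test_result(stat, df, stats::pchisq(stat, df,
                                                  lower.tail = FALSE),
                          "logrank"))
}

#' Kaplan-Meier curves only
#'
#' @inheritParams km_logrank
#' @return data frame with \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv}.
#' @export
km_curves <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (nlevels(group) == 1L) {
    g <- rep(levels(group), length(fit$time))
  } else {
    g <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation (Efron tie handling by default; Breslow
#' available) with Wald confidence intervals and p-values. Constant
#' covariates are rejected; a warning is issued when events are fewer than
#' covariates; likely-divergent coefficients (monotone likelihood /
#' complete separation) are reported as an error.
#'
#' @param time,event survival outcome.
#' @param covariates a data frame of covariates (factors and numerics); the
#'   model is \code{Surv(time, event) ~ .} over its columns.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return an object of class \code{p53_cox_fit}: list with
#'   \code{coefficients} (data frame \code{term}, \code{coef},
#'   \code{hazard_ratio}, \code{ci95_low}, \code{ci95_high},
#'   \code{p_value}), \code{loglik} (null and fitted), \code{n},
#'   \code{n_events}, \code{ties} and \code{model} (the underlying
#'   \code{coxph} fit).
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L)
    stop("at least one covariate is required", call. = FALSE)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("covariate '", nm, "' is constant", call. = FALSE)
  }
  if (sum(event, na.rm = TRUE) < ncol(covariates))
    warning("fewer events than covariates; estimates will be unstable",
            call. = FALSE)

  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                         data = dat[stats::complete.cases(dat), ,
                                    drop = FALSE],
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  s <- summary(fit)
  if (any(!is.finite(s$coefficients[, "coef"])) ||
      any(abs(s$coefficients[, "coef"]) > 15))
    stop("Cox fit did not converge (possible complete separation); ",
         "coefficients: ",
         paste(round(s$coefficients[, "coef"], 2), collapse = ", "),
         call. = FALSE)

  coefs <- data.frame(
    term = rownames(s$coefficients),
    coef = unname(s$coefficients[, "coef"]),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci95_low = unname(s$conf.int[, "lower .95"]),
    ci95_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)

  structure(list(coefficients = coefs, loglik = fit$loglik, n = s$n,
                 n_events = as.integer(fit$nevent), ties = ties,
                 model = fit),
            class = "p53_cox_fit")
}

#' Harrell's concordance index
#'
#' Concordance between a risk score (higher = worse prognosis) and observed
#' survival over usable pairs; pairs tied on the risk score count one half.
#'
#' @param time,event survival outcome.
#' @param risk numeric risk scores.
#' @return the concordance probability in [0, 1].
#' @export
harrell_c <- function(time, event, risk) {
  check_surv_input(time, event)
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  unname(cf$concordance)
}

#' Model metrics: Harrell's C, AIC, BIC
#'
#' AIC = -2 loglik + 2k; BIC = -2 loglik + k log(m) where m is the number
#' of events by default (the standard effective sample size for the Cox
#' partial likelihood) or the number of subjects.
#'
#' @param fit a \code{p53_cox_fit}.
#' @param bic_n \code{"events"} (default) or \code{"n"}.
#' @return list with \code{harrell_c}, \code{aic}, \code{bic}.
#' @export
model_metrics <- function(fit, bic_n = c("events", "n")) {
  bic_n <- match.arg(bic_n)
  stopifnot(inherits(fit, "p53_cox_fit"))
  ll <- fit$loglik[length(fit$loglik)]
  k <- nrow(fit$coefficients)
  m <- if (bic_n == "events") fit$n_events else fit$n
  list(harrell_c = unname(survival::concordance(fit$model)$concordance),
       aic = -2 * ll + 2 * k,
       bic = -2 * ll + k * log(m))
}

#' Compare two survival models by C, AIC and BIC
#'
#' \code{delta_bic = bic_a - bic_b} (positive favours model b), labelled by
#' the Kass-Raftery evidence bands on its magnitude: < 2 none, 2-6
#' positive, 6-10 strong, >= 10 very strong.
#'
#' @param fit_a,fit_b \code{p53_cox_fit} objects fitted to the same data, or
#'   \code{NULL} when comparing externally supplied criteria.
#' @param metrics_a,metrics_b optional precomputed metric lists (as returned
#'   by \code{\link{model_metrics}}); override the fits.
#' @param bic_n passed to \code{\link{model_metrics}}.
#' @return an object of class \code{p53_model_comparison}: list with
#'   \code{c_index_a}, \code{c_index_b}, \code{aic_a}, \code{aic_b},
#'   \code{bic_a}, \code{bic_b}, \code{delta_bic}, \code{evidence_label}.
#' @examples
#' compare_models(metrics_a = list(harrell_c = 0.54, aic = 1829.253,
#'                                 bic = 1837.290),
#'                metrics_b = list(harrell_c = 0.57, aic = 1819.828,
#'                                 bic = 1823.847))
#' @export
compare_models <- function(fit_a = NULL, fit_b = NULL, metrics_a = NULL,
                           metrics_b = NULL, bic_n = "events") {
  a <- metrics_a %||% model_metrics(fit_a, bic_n = bic_n)
  b <- metrics_b %||% model_metrics(fit_b, bic_n = bic_n)
  delta <- a$bic - b$bic
  structure(list(c_index_a = a$harrell_c, c_index_b = b$harrell_c,
                 aic_a = a$aic, aic_b = b$aic, bic_a = a$bic, bic_b = b$bic,
                 delta_bic = delta,
                 evidence_label = bic_evidence_label(delta)),
            class = "p53_model_comparison")
}

#' Kass-Raftery evidence label for a BIC difference
#'
#' @param delta_bic numeric BIC difference (magnitude is labelled).
#' @return one of \code{"none"}, \code{"positive"}, \code{"strong"},
#'   \code{"very_strong"}.
#' @export
bic_evidence_label <- function(delta_bic) {
  d <- abs(delta_bic)
  ifelse(d >= 10, "very_strong",
         ifelse(d >= 6, "strong",
                ifelse(d >= 2, "positive", "none")))
}

check_surv_input <- function(time, event) {
  if (length(time) != length(event))
    stop("time and event lengths differ", call. = FALSE)
  if (any(time < 0, na.rm = TRUE))
    stop("negative survival times", call. = FALSE)
  if (!all(event %in% c(0, 1, NA)))
    stop("event indicator must be 0/1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.p53_cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.p53_model_comparison <- function(x, ...) {
  cat(sprintf("model a: C = %.4f, AIC = %.3f, BIC = %.3f\n",
              x$c_index_a, x$aic_a, x$bic_a))
  cat(sprintf("model b: C = %.4f, AIC = %.3f, BIC = %.3f\n",
              x$c_index_b, x$aic_b, x$bic_b))
  cat(sprintf("delta BIC = %.3f (%s evidence)\n", x$delta_bic,
              gsub("_", " ", x$evidence_label)))
  invisible(x)
}
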