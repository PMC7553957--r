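#' Poeta disruptive/nondisruptive classification
#'
#' Stop, frameshift, in-frame and splice mutations are disruptive. Missense
#' mutations inside the L2-L3 loops (codons 163-195 and 236-251) with a
#' change in charge or polarity of the substituted amino acid are
#' disruptive; every other missense mutation is nondisruptive. Mutations of
#' kind \code{other} (unmapped classifications, synonymous changes) are not
#' classifiable and raise an error rather than defaulting silently.
#'
#' @param annotated a \code{p53_annotated} data frame (see
#'   \code{\link{annotate_cohort}}).
#' @return character vector over \code{\{disruptive, nondisruptive\}}, one
#'   element per row.
#' @examples
#' bundle <- load_reference_bundle()
#' m <- data.frame(sample_id = "S1", kind = "missense", ref_aa = "Y",
#'                 codon = 220L, alt_aa = "C")
#' poeta_classify(annotate_cohort(m, bundle))
#' @export
poeta_classify <- function(annotated) {
  x <- as.data.frame(annotated)
  bad <- !x$kind %in% c("missense", "nonsense_stop", "frameshift",
                        "inframe_indel", "splice")
  if (any(bad))
    stop("unclassifiable variant kind for sample(s) ",
         paste(x$sample_id[bad], collapse = ", "),
         " (kind 'other' cannot be scored)", call. = FALSE)
  ifelse(x$kind != "missense", "disruptive",
         ifelse(x$in_L2L3 & !is.na(x$polarity_change) & x$polarity_change,
                "disruptive", "nondisruptive"))
}

#' High-/low-risk-of-death classification
#'
#' Refines the Poeta classes for missense mutations using four deleterious
#' reclassification rules, applied in order before the conservative rule:
#' \describe{
#'   \item{D1}{homozygous locus (VAF 65-100\%) — missense only by default;}
#'   \item{D2}{zinc-ligand residue (C176, H179, C238, C242);}
#'   \item{D3}{hydrogen-bond disruption (donor/acceptor swap, or loss of
#'     bonding ability);}
#'   \item{D4}{residue in a non-assigned ("unknown") secondary structure;}
#'   \item{C1}{otherwise, a missense in an assigned secondary structure that
#'     keeps its hydrogen-bonding ability is low risk.}
#' }
#' Non-missense mutations (stop, frameshift, in-frame, splice) are high
#' risk and are never downgraded by C1. Missing VAF never fires D1. A
#' missense matched by none of the rules carries its Poeta class
#' (disruptive to high risk, nondisruptive to low risk).
#'
#' @param annotated a \code{p53_annotated} data frame.
#' @param homozygous_applies_to \code{"missense"} (default) or \code{"all"}:
#'   whether D1 may also upgrade non-missense mutations (sensitivity
#'   switch; with truncating mutations already high risk it only changes
#'   the recorded rules).
#' @return a data frame with columns \code{highrisk_class} (\code{high_risk}
#'   or \code{low_risk}) and \code{fired_rules} (semicolon-joined rule
#'   identifiers, in precedence order, explaining each call).
#' @examples
#' bundle <- load_reference_bundle()
#' m <- data.frame(sample_id = "S1", kind = "missense", ref_aa = "Y",
#'                 codon = 220L, alt_aa = "C", vaf_percent = 45)
#' highrisk_classify(annotate_cohort(m, bundle))
#' @export
highrisk_classify <- function(annotated,
                              homozygous_applies_to = c("missense", "all")) {
  homozygous_applies_to <- match.arg(homozygous_applies_to)
  x <- as.data.frame(annotated)
  poeta <- poeta_classify(x)
  n <- nrow(x)

  class_out <- character(n)
  rules_out <- character(n)
  miss <- x$kind == "missense"

  for (i in seq_len(n)) {
    if (!miss[i]) {
      rules <- "truncating_type"
      if (homozygous_applies_to == "all" && x$zygosity[i] == "homozygous")
        rules <- c(rules, "D1_homozygous")
      class_out[i] <- "high_risk"
      rules_out[i] <- paste(rules, collapse = ";")
      next
    }
    fired <- character(0)
    if (x$zygosity[i] == "homozygous") fired <- c(fired, "D1_homozygous")
    if (isTRUE(x$is_zinc_ligand[i])) fired <- c(fired, "D2_zinc_ligand")
    if (isTRUE(x$hbond_disrupted[i])) fired <- c(fired, "D3_hbond_disruption")
    if (x$secondary_structure[i] == "unknown")
      fired <- c(fired, "D4_unassigned_structure")
    if (length(fired) > 0L) {
      class_out[i] <- "high_risk"
    } else if (x$secondary_structure[i] %in% c("helix", "strand", "turn") &&
               !isTRUE(x$hbond_disrupted[i])) {
      fired <- "C1_structured_hbond_kept"
      class_out[i] <- "low_risk"
    } else {
      fired <- paste0("carry_poeta_", poeta[i])
      class_out[i] <- if (poeta[i] == "disruptive") "high_risk" else
        "low_risk"
    }
    rules_out[i] <- paste(fired, collapse = ";")
  }

  data.frame(highrisk_class = class_out, fired_rules = rules_out,
             stringsAsFactors = FALSE)
}

#' Classify a cohort under both schemes
#'
#' Joins the per-mutation risk calls onto the clinical table. Clinical
#' samples without an admitted mutation are wild type in both schemes;
#' mutated samples missing from the clinical table are reported (attribute
#' \code{unmatched}) and excluded from the joined table.
#'
#' @param annotated a \code{p53_annotated} data frame, one row per sample.
#' @param clinical a \code{p53_clinical} data frame.
#' @param ... passed to \code{\link{highrisk_classify}}.
#' @return a data frame of class \code{p53_risk_calls}: the clinical columns
#'   plus \code{poeta_class}, \code{highrisk_class} (each with level
#'   \code{wild_type} for mutation-free samples) and \code{fired_rules}.
#' @export
classify_cohort <- function(annotated, clinical, ...) {
  ann <- as.data.frame(annotated)
  if (anyDuplicated(ann$sample_id))
    stop("classify_cohort expects one mutation per sample; apply ",
         "apply_single_mutation_filter() first", call. = FALSE)

  calls <- data.frame(sample_id = ann$sample_id,
                      poeta_class = if (nrow(ann)) poeta_classify(ann)
                                    else character(0),
                      stringsAsFactors = FALSE)
  hr <- if (nrow(ann)) highrisk_classify(ann, ...) else
    data.frame(highrisk_class = character(0), fired_rules = character(0))
  calls <- cbind(calls, hr)

  out <- as.data.frame(clinical)
  idx <- match(out$sample_id, calls$sample_id)
  out$poeta_class <- ifelse(is.na(idx), "wild_type", calls$poeta_class[idx])
  out$highrisk_class <- ifelse(is.na(idx), "wild_type",
                               calls$highrisk_class[idx])
  out$fired_rules <- ifelse(is.na(idx), "wild_type", calls$fired_rules[idx])

  unmatched <- setdiff(calls$sample_id, out$sample_id)
  if (length(unmatched) > 0L)
    message("classify_cohort: ", length(unmatched),
            " mutated sample(s) absent from the clinical table; excluded ",
            "from the joined cohort")
  attr(out, "unmatched") <- unmatched

  rownames(out) <- NULL
  class(out) <- c("p53_risk_calls", "data.frame")
  out
}

#' Replay fired rules to reproduce a risk call
#'
#' Recomputes the high-/low-risk class from a \code{fired_rules} string
#' alone. Useful for auditing: for every classified mutation,
#' \code{replay_fired_rules(fired_rules)} equals the recorded class.
#'
#' @param fired_rules character vector of semicolon-joined rule ids.
#' @return character vector of classes.
#' @export
replay_fired_rules <- function(fired_rules) {
  vapply(strsplit(fired_rules, ";", fixed = TRUE), function(rules) {
    if (identical(rules, "wild_type")) return("wild_type")
    if (any(rules %in% c("truncating_type", "D1_homozygous",
                         "D2_zinc_ligand", "D3_hbond_disruption",
                         "D4_unassigned_structure", "carry_poeta_disruptive")))
      return("high_risk")
    if (any(rules %in% c("C1_structured_hbond_kept",
                         "carry_poeta_nondisruptive")))
      return("low_risk")
    stop("unknown rule id(s): ", paste(rules, collapse = ";"), call. = FALSE)
  }, character(1))
}

#' @export
print.p53_risk_calls <- function(x, ...) {
  cat("TP53 risk calls for", nrow(x), "samples\n")
  cat("Poeta scheme:\n")
  print(table(x$poeta_class))
  cat("high-/low-risk scheme:\n")
  print(table(x$highrisk_class))
  invisible(x)
}
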