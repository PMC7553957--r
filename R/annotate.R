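#' Zygosity call from DNA variant-allele frequency
#'
#' VAF bands: 40--64\% heterozygous, 65--100\% homozygous. VAF below 40\% is
#' given the distinct label \code{subclonal_low} (never treated as
#' homozygous by the classifier); missing VAF is \code{unknown}.
#'
#' @param vaf_percent numeric vector of VAF in percent, \code{NA} allowed.
#' @return character vector over \code{\{heterozygous, homozygous,
#'   subclonal_low, unknown\}}.
#' @examples
#' zygosity_from_vaf(c(65, 64.9, 20, NA))
#' @export
zygosity_from_vaf <- function(vaf_percent) {
  v <- as.numeric(vaf_percent)
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("VAF must lie in [0, 100] percent", call. = FALSE)
  out <- rep("unknown", length(v))
  out[!is.na(v) & v < 40] <- "subclonal_low"
  out[!is.na(v) & v >= 40 & v < 65] <- "heterozygous"
  out[!is.na(v) & v >= 65] <- "homozygous"
  out
}

aa_class <- function(aa, properties, column) {
  idx <- match(aa, properties$aa)
  if (anyNA(idx[!is.na(aa)]))
    stop("nonstandard amino-acid code: ",
         paste(unique(aa[!is.na(aa) & is.na(idx)]), collapse = ", "),
         call. = FALSE)
  properties[[column]][idx]
}

#' Hydrogen-bond disruption rule
#'
#' A substitution disrupts hydrogen bonding when it swaps a pure donor
#' (K, R, W) with a pure acceptor (E, D) in either direction, or replaces
#' any hydrogen-bonding residue (class other than \code{neither}) with a
#' non-bonding one. A donor-only residue replaced by a donor+acceptor
#' residue keeps its donation ability and is not disruptive.
#'
#' @param ref_aa,alt_aa 1-letter codes (vectorised).
#' @param properties amino-acid property table (a \code{data.frame} from the
#'   reference bundle).
#' @return logical vector.
#' @examples
#' bundle <- load_reference_bundle()
#' hbond_disruption("Y", "C", bundle$amino_acids)
#' @export
hbond_disruption <- function(ref_aa, alt_aa, properties) {
  r <- aa_class(ref_aa, properties, "hbond_class")
  a <- aa_class(alt_aa, properties, "hbond_class")
  (r == "donor_only" & a == "acceptor_only") |
    (r == "acceptor_only" & a == "donor_only") |
    (r != "neither" & a == "neither")
}

#' Charge/polarity-change rule
#'
#' True when the substitution crosses charge/polarity classes (nonpolar,
#' polar uncharged, positively charged, negatively charged). The class table
#' lives in the bundle's amino-acid properties; histidine's placement
#' (polar uncharged by default) can be changed by editing that table or via
#' \code{his_class}.
#'
#' @param ref_aa,alt_aa 1-letter codes (vectorised).
#' @param properties amino-acid property table.
#' @param his_class \code{"polar"} (default) or \code{"positive"}: overrides
#'   histidine's class for sensitivity analysis.
#' @return logical vector.
#' @export
polarity_charge_change <- function(ref_aa, alt_aa, properties,
                                   his_class = c("polar", "positive")) {
  his_class <- match.arg(his_class)
  if (his_class == "positive") {
    properties <- properties
    properties$polarity_class[properties$aa == "H"] <- "positive"
  }
  r <- aa_class(ref_aa, properties, "polarity_class")
  a <- aa_class(alt_aa, properties, "polarity_class")
  r != a
}

#' Nucleotide-change features
#'
#' Classifies a single-base substitution as transition (purine-purine or
#' pyrimidine-pyrimidine) or transversion, flags C-to-T transitions at CpG
#' dinucleotides (deamination signature; requires the trinucleotide context
#' centred on the mutated base, or membership in a supplied CpG position
#' list) and G:C-to-T:A transversions (tobacco signature: G>T or C>A).
#'
#' @param ref_nt,alt_nt single-base reference/alternate nucleotides
#'   (vectorised); \code{NA} yields class \code{none}.
#' @param context optional 3-mer context centred on the mutated base.
#' @param position optional nucleotide position, checked against
#'   \code{cpg_positions} when context is unavailable.
#' @param cpg_positions optional integer vector of CpG site positions.
#' @return a data frame with columns \code{nt_change_class} (\code{transition},
#'   \code{transversion}, \code{none}), \code{is_CpG_CtoT_transition},
#'   \code{is_GC_to_TA_transversion}.
#' @examples
#' nucleotide_change_features("C", "T", context = "ACG")
#' @export
nucleotide_change_features <- function(ref_nt, alt_nt, context = NA,
                                       position = NA, cpg_positions = NULL) {
  n <- max(length(ref_nt), length(alt_nt))
  ref <- toupper(rep_len(as.character(ref_nt), n))
  alt <- toupper(rep_len(as.character(alt_nt), n))
  ctx <- toupper(rep_len(as.character(context), n))
  pos <- rep_len(position, n)

  valid <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(valid & ref == alt))
    stop("ref and alt nucleotides must differ", call. = FALSE)

  purine <- function(x) x %in% c("A", "G")
  cls <- rep("none", n)
  cls[valid] <- ifelse(purine(ref[valid]) == purine(alt[valid]),
                       "transition", "transversion")

  # CpG deamination: C>T with the C followed by G, or G>A with the G
  # preceded by C (reverse strand); falls back to a bundled position list.
  ctx_ok <- !is.na(ctx) & nchar(ctx) == 3L
  cpg_ctx <- (ref == "C" & alt == "T" & ctx_ok &
                substr(ctx, 2L, 3L) == "CG") |
             (ref == "G" & alt == "A" & ctx_ok &
                substr(ctx, 1L, 2L) == "CG")
  cpg_list <- rep(FALSE, n)
  if (!is.null(cpg_positions))
    cpg_list <- !is.na(pos) & pos %in% cpg_positions &
      ((ref == "C" & alt == "T") | (ref == "G" & alt == "A"))
  is_cpg <- valid & cls == "transition" &
    ifelse(ctx_ok, cpg_ctx, cpg_list)

  gc_ta <- valid & ((ref == "G" & alt == "T") | (ref == "C" & alt == "A"))

  data.frame(nt_change_class = cls,
             is_CpG_CtoT_transition = is_cpg,
             is_GC_to_TA_transversion = gc_ta,
             stringsAsFactors = FALSE)
}

#' Annotate mutations with structural and biochemical features
#'
#' Computes, per mutation, every feature the classifiers consume: protein
#' domain, secondary structure, hotspot / new-hotspot / zinc-ligand /
#' conserved / native-glycine / L2-L3 flags (from the residue table, for any
#' mutation carrying a codon), hydrogen-bond classes and disruption,
#' charge/polarity change and proline substitution (missense only),
#' VAF-based zygosity, and nucleotide-change features. Mutations without a
#' codon (e.g. splice markers) get domain and secondary structure
#' \code{"unknown"} and structural flags \code{FALSE}.
#'
#' @param mutations a \code{p53_mutations} data frame (see
#'   \code{\link{read_mutations}}), already reduced to one mutation per
#'   sample.
#' @param bundle a \code{p53_reference_bundle}.
#' @param his_class histidine polarity-class override, passed to
#'   \code{\link{polarity_charge_change}}.
#' @return a data frame of class \code{p53_annotated}: the input columns
#'   plus \code{domain}, \code{secondary_structure}, \code{zygosity},
#'   \code{is_hotspot}, \code{is_new_hotspot}, \code{is_zinc_ligand},
#'   \code{is_conserved}, \code{in_L2L3}, \code{hbond_ref},
#'   \code{hbond_alt}, \code{hbond_disrupted}, \code{polarity_change},
#'   \code{proline_substitution}, \code{native_glycine_substitution},
#'   \code{nt_change_class}, \code{is_CpG_CtoT_transition},
#'   \code{is_GC_to_TA_transversion}.
#' @export
annotate_cohort <- function(mutations, bundle = load_reference_bundle(),
                            his_class = c("polar", "positive")) {
  his_class <- match.arg(his_class)
  stopifnot(inherits(bundle, "p53_reference_bundle"))
  x <- as.data.frame(mutations)
  n <- nrow(x)

  need <- c("sample_id", "kind", "codon")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L)
    stop("annotate_cohort: input lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in c("ref_aa", "alt_aa"))
    if (is.null(x[[nm]])) x[[nm]] <- NA_character_
  for (nm in c("vaf_percent"))
    if (is.null(x[[nm]])) x[[nm]] <- NA_real_
  for (nm in c("ref_nt", "alt_nt", "trinucleotide_context"))
    if (is.null(x[[nm]])) x[[nm]] <- NA_character_
  x$codon <- as.integer(x$codon)

  bad <- !is.na(x$codon) & (x$codon < 1L | x$codon > TP53_N_RESIDUES)
  if (any(bad))
    stop("codon outside 1..", TP53_N_RESIDUES, " for sample(s) ",
         paste(x$sample_id[bad], collapse = ", "), call. = FALSE)

  res <- bundle$residues
  idx <- match(x$codon, res$codon)
  has_codon <- !is.na(idx)

  pull_flag <- function(column) {
    out <- rep(FALSE, n)
    out[has_codon] <- res[[column]][idx[has_codon]] == 1L
    out
  }

  x$domain <- ifelse(has_codon, res$domain[idx], "unknown")
  x$secondary_structure <- ifelse(has_codon, res$secondary_structure[idx],
                                  "unknown")
  x$zygosity <- zygosity_from_vaf(x$vaf_percent)
  x$is_hotspot <- pull_flag("is_hotspot")
  x$is_new_hotspot <- pull_flag("is_new_hotspot")
  x$is_zinc_ligand <- pull_flag("is_zinc_ligand")
  x$is_conserved <- pull_flag("is_conserved")
  x$in_L2L3 <- pull_flag("in_L2L3")

  miss <- x$kind == "missense" & !is.na(x$ref_aa) & !is.na(x$alt_aa) &
    x$ref_aa %in% AA_ONE & x$alt_aa %in% AA_ONE
  aa <- bundle$amino_acids
  x$hbond_ref <- NA_character_
  x$hbond_alt <- NA_character_
  x$hbond_disrupted <- NA
  x$polarity_change <- NA
  x$proline_substitution <- NA
  x$native_glycine_substitution <- NA
  if (any(miss)) {
    x$hbond_ref[miss] <- aa_class(x$ref_aa[miss], aa, "hbond_class")
    x$hbond_alt[miss] <- aa_class(x$alt_aa[miss], aa, "hbond_class")
    x$hbond_disrupted[miss] <- hbond_disruption(x$ref_aa[miss],
                                                x$alt_aa[miss], aa)
    x$polarity_change[miss] <- polarity_charge_change(
      x$ref_aa[miss], x$alt_aa[miss], aa, his_class = his_class)
    x$proline_substitution[miss] <- x$alt_aa[miss] == "P"
    gly <- pull_flag("is_native_glycine_site")
    x$native_glycine_substitution[miss] <- x$ref_aa[miss] == "G" & gly[miss]
  }

  ntf <- nucleotide_change_features(x$ref_nt, x$alt_nt,
                                    context = x$trinucleotide_context,
                                    cpg_positions = bundle$cpg_positions)
  x$nt_change_class <- ntf$nt_change_class
  x$is_CpG_CtoT_transition <- ntf$is_CpG_CtoT_transition
  x$is_GC_to_TA_transversion <- ntf$is_GC_to_TA_transversion

  rownames(x) <- NULL
  class(x) <- c("p53_annotated", "data.frame")
  x
}

#' Annotate a single mutation record
#'
#' Convenience wrapper over \code{\link{annotate_cohort}} for one record.
#'
#' @param record a one-row \code{p53_mutations} data frame or a list with
#'   the same fields.
#' @param bundle a \code{p53_reference_bundle}.
#' @param ... passed to \code{\link{annotate_cohort}}.
#' @return a one-row \code{p53_annotated} data frame.
#' @export
annotate_mutation <- function(record, bundle = load_reference_bundle(), ...) {
  if (!is.data.frame(record)) record <- as.data.frame(record,
                                                      stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1L)
  annotate_cohort(record, bundle = bundle, ...)
}
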