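#' Load the TP53 reference bundle
#'
#' Reads the per-codon annotation table (domains, hotspot / zinc-ligand /
#' conserved / native-glycine flags, L2-L3 loop membership), the per-residue
#' secondary-structure map and the amino-acid hydrogen-bond and
#' charge/polarity property table. With no arguments the bundle packaged
#' under \code{inst/extdata} is returned.
#'
#' @param residue_path path to a per-codon annotation TSV, or \code{NULL} for
#'   the packaged table. The file must carry named columns \code{codon},
#'   \code{domain} and the 0/1 flag columns; \code{#} lines are comments.
#' @param structure_path path to a per-codon secondary-structure TSV
#'   (columns \code{codon}, \code{secondary_structure}), or \code{NULL}.
#' @param aa_path path to an amino-acid property TSV (columns \code{aa},
#'   \code{hbond_class}, \code{polarity_class}), or \code{NULL}.
#' @param cpg_positions optional integer vector of nucleotide positions to
#'   use as a CpG-site override when trinucleotide context is unavailable.
#' @return an object of class \code{p53_reference_bundle}: a list with
#'   elements \code{residues} (393-row data frame), \code{amino_acids}
#'   (20-row data frame), \code{cpg_positions} and \code{provenance}.
#' @examples
#' bundle <- load_reference_bundle()
#' subset(bundle$residues, is_zinc_ligand == 1)$codon
#' @export
load_reference_bundle <- function(residue_path = NULL, structure_path = NULL,
                                  aa_path = NULL, cpg_positions = NULL) {
  residue_path <- residue_path %||%
    system.file("extdata", "tp53_residue_annotation.tsv", package = "p53risk",
                mustWork = TRUE)
  structure_path <- structure_path %||%
    system.file("extdata", "tp53_secondary_structure_synthetic.tsv",
                package = "p53risk", mustWork = TRUE)
  aa_path <- aa_path %||%
    system.file("extdata", "amino_acid_properties.tsv", package = "p53risk",
                mustWork = TRUE)

  res <- read_reference_tsv(residue_path,
                            c("codon", "domain", "is_hotspot",
                              "is_new_hotspot", "is_zinc_ligand",
                              "is_conserved", "is_native_glycine_site",
                              "in_L2L3"))
  ss <- read_reference_tsv(structure_path, c("codon", "secondary_structure"))
  aa <- read_reference_tsv(aa_path, c("aa", "hbond_class", "polarity_class"))

  check_enum_column(res, "domain",
                    c("N_terminal", "DNA_binding", "C_terminal"), residue_path)
  check_enum_column(ss, "secondary_structure",
                    c("helix", "strand", "turn", "unknown"), structure_path)
  check_enum_column(aa, "hbond_class",
                    c("donor_only", "acceptor_only", "both", "neither"),
                    aa_path)
  check_enum_column(aa, "polarity_class",
                    c("nonpolar", "polar_uncharged", "positive", "negative"),
                    aa_path)

  gaps <- setdiff(seq_len(TP53_N_RESIDUES), res$codon)
  if (length(gaps) > 0L)
    stop("residue annotation table has coverage gaps at codon(s) ",
         paste(utils::head(gaps, 10L), collapse = ", "),
         if (length(gaps) > 10L) " ...", call. = FALSE)
  gaps <- setdiff(seq_len(TP53_N_RESIDUES), ss$codon)
  if (length(gaps) > 0L)
    stop("secondary-structure table has coverage gaps at codon(s) ",
         paste(utils::head(gaps, 10L), collapse = ", "), call. = FALSE)

  res <- res[order(res$codon), , drop = FALSE]
  res$secondary_structure <-
    ss$secondary_structure[match(res$codon, ss$codon)]
  rownames(res) <- NULL

  bundle <- list(
    residues = res,
    amino_acids = aa,
    cpg_positions = cpg_positions,
    provenance = paste(
      "secondary structure: synthetic reconstruction of the p53 core-domain",
      "crystal assignment collapsed to {helix,strand,turn,unknown};",
      "residues outside the crystallised core are 'unknown'"))
  class(bundle) <- "p53_reference_bundle"
  bundle
}

read_reference_tsv <- function(path, required) {
  if (!file.exists(path)) stop("reference file not found: ", path,
                               call. = FALSE)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop("reference file ", basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

check_enum_column <- function(x, column, levels, path) {
  bad <- which(!x[[column]] %in% levels)
  if (length(bad) > 0L)
    stop("reference file ", basename(path), ", row ", bad[1L],
         ": invalid ", column, " value '", x[[column]][bad[1L]], "'",
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a reference bundle against the rule-set invariants
#'
#' Report-only check of every structural invariant the classifiers rely on:
#' full 1..393 codon coverage, the domain boundaries, the hotspot / new
#' hotspot / zinc-ligand / conserved / native-glycine sets, the L2-L3 loop
#' ranges and the amino-acid hydrogen-bond classes. The packaged bundle
#' yields an empty report.
#'
#' @param bundle a \code{p53_reference_bundle}.
#' @return a data frame of class \code{p53_validation_report} with columns
#'   \code{component} and \code{message}; zero rows when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "p53_reference_bundle"))
  violations <- list()
  note <- function(component, message)
    violations[[length(violations) + 1L]] <<-
      data.frame(component = component, message = message)

  res <- bundle$residues
  aa <- bundle$amino_acids

  gaps <- setdiff(seq_len(TP53_N_RESIDUES), res$codon)
  if (length(gaps) > 0L)
    note("residues", paste("coverage gap at codons",
                           paste(gaps, collapse = ",")))
  if (anyDuplicated(res$codon))
    note("residues", "duplicated codon rows")

  expected_domain <- ifelse(res$codon <= DOMAIN_N_TERMINAL[2], "N_terminal",
                     ifelse(res$codon <= DOMAIN_DNA_BINDING[2], "DNA_binding",
                            "C_terminal"))
  bad <- res$codon[res$domain != expected_domain]
  if (length(bad) > 0L)
    note("domain", paste("domain label disagrees with boundaries at codons",
                         paste(utils::head(bad, 10L), collapse = ",")))

  check_set <- function(flag, expected, label) {
    got <- sort(res$codon[res[[flag]] == 1L])
    if (!identical(got, sort(expected)))
      note(flag, paste0(label, " set mismatch: expected {",
                        paste(sort(expected), collapse = ","), "}, got {",
                        paste(got, collapse = ","), "}"))
  }
  check_set("is_hotspot", HOTSPOT_CODONS, "hotspot")
  check_set("is_new_hotspot", NEW_HOTSPOT_CODONS, "new-hotspot")
  check_set("is_zinc_ligand", ZINC_LIGAND_CODONS, "zinc-ligand")
  check_set("is_conserved", CONSERVED_CODONS, "conserved-residue")
  check_set("is_native_glycine_site", NATIVE_GLYCINE_CODONS, "native-glycine")
  l2l3 <- sort(c(seq(L2L3_RANGES[[1]][1], L2L3_RANGES[[1]][2]),
                 seq(L2L3_RANGES[[2]][1], L2L3_RANGES[[2]][2])))
  check_set("in_L2L3", l2l3, "L2-L3 loop")

  if (!setequal(aa$aa, AA_ONE) || nrow(aa) != 20L)
    note("amino_acids", "amino-acid table must list the 20 standard residues exactly once")
  check_aa <- function(class, expected, column = "hbond_class") {
    got <- sort(aa$aa[aa[[column]] == class])
    if (!identical(got, sort(expected)))
      note("amino_acids", paste0(column, " '", class, "' mismatch: expected {",
                                 paste(sort(expected), collapse = ","),
                                 "}, got {", paste(got, collapse = ","), "}"))
  }
  check_aa("donor_only", HBOND_DONOR_ONLY)
  check_aa("acceptor_only", HBOND_ACCEPTOR_ONLY)
  check_aa("both", HBOND_BOTH)
  check_aa("neither", setdiff(AA_ONE, c(HBOND_DONOR_ONLY, HBOND_ACCEPTOR_ONLY,
                                        HBOND_BOTH)))

  report <- if (length(violations) == 0L)
    data.frame(component = character(0), message = character(0))
  else
    do.call(rbind, violations)
  class(report) <- c("p53_validation_report", "data.frame")
  report
}

#' @export
print.p53_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("reference bundle: all invariants satisfied\n")
  } else {
    cat("reference bundle:", nrow(x), "invariant violation(s)\n")
    print.data.frame(x, right = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.p53_reference_bundle <- function(x, ...) {
  cat("TP53 reference bundle:", nrow(x$residues), "codons,",
      nrow(x$amino_acids), "amino acids\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
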