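#' Read a MAF-like somatic-mutation table
#'
#' Expects a UTF-8, tab-separated file with a header row. Column names are
#' matched case-insensitively against common dialects (UCSC Xena
#' \code{mutect2_snv} exports and generic MAF): sample id
#' (\code{Sample_ID}/\code{sample}/\code{Tumor_Sample_Barcode}), gene,
#' protein change (\code{Amino_Acid_Change}/\code{HGVSp_Short}/
#' \code{protein_change}), variant classification (\code{effect}/
#' \code{Variant_Classification}), and optionally VAF (\code{dna_vaf}/
#' \code{vaf}/\code{vaf_percent}), reference/alternate nucleotides and
#' trinucleotide context. Rows for genes other than \code{gene} are dropped
#' with a message. VAF given as a fraction (whole column within [0, 1]) is
#' normalised to percent.
#'
#' @param path path to the TSV.
#' @param gene gene symbol to retain (default \code{"TP53"}).
#' @param vaf_unit \code{"auto"} (default: fractions detected when the whole
#'   column lies in [0, 1]), \code{"percent"} or \code{"fraction"}.
#' @param keep_splice_codon passed to \code{\link{parse_protein_change}}.
#' @return a data frame of class \code{p53_mutations}, one row per mutation:
#'   \code{sample_id}, \code{gene}, \code{variant_classification},
#'   \code{kind}, \code{ref_aa}, \code{codon}, \code{alt_aa},
#'   \code{protein_change_raw}, \code{vaf_percent}, \code{ref_nt},
#'   \code{alt_nt}, \code{trinucleotide_context}.
#' @export
read_mutations <- function(path, gene = "TP53",
                           vaf_unit = c("auto", "percent", "fraction"),
                           keep_splice_codon = TRUE) {
  vaf_unit <- match.arg(vaf_unit)
  if (!file.exists(path))
    stop("mutation file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", "", "."))

  col <- function(aliases, required = FALSE) {
    hit <- match(tolower(aliases), tolower(names(x)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) {
      if (required)
        stop("mutation file lacks a required column (one of: ",
             paste(aliases, collapse = ", "), ")", call. = FALSE)
      return(rep(NA, nrow(x)))
    }
    x[[hit[1L]]]
  }

  out <- data.frame(
    sample_id = as.character(col(c("sample_id", "sample",
                                   "Tumor_Sample_Barcode"), required = TRUE)),
    gene = as.character(col(c("gene", "Hugo_Symbol"), required = TRUE)),
    variant_classification =
      as.character(col(c("variant_classification", "effect"),
                       required = TRUE)),
    protein_change_raw =
      as.character(col(c("protein_change", "Amino_Acid_Change",
                         "HGVSp_Short"), required = TRUE)),
    vaf = suppressWarnings(as.numeric(col(c("dna_vaf", "vaf",
                                            "vaf_percent")))),
    ref_nt = toupper(as.character(col(c("ref_nt", "ref",
                                        "Reference_Allele")))),
    alt_nt = toupper(as.character(col(c("alt_nt", "alt",
                                        "Tumor_Seq_Allele2")))),
    trinucleotide_context =
      toupper(as.character(col(c("trinucleotide_context", "context")))),
    stringsAsFactors = FALSE)

  dropped <- sum(out$gene != gene, na.rm = TRUE) + sum(is.na(out$gene))
  if (dropped > 0L)
    message("read_mutations: dropped ", dropped, " row(s) for genes != ",
            gene)
  out <- out[!is.na(out$gene) & out$gene == gene, , drop = FALSE]

  # VAF normalisation to percent
  v <- out$vaf
  if (vaf_unit == "fraction" ||
      (vaf_unit == "auto" && length(v[!is.na(v)]) > 0L &&
       all(v[!is.na(v)] <= 1)))
    v <- v * 100
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("VAF values outside [0, 100] after unit normalisation",
         call. = FALSE)
  out$vaf_percent <- v
  out$vaf <- NULL

  parsed <- parse_protein_changes(out$protein_change_raw,
                                  keep_splice_codon = keep_splice_codon)
  mapped <- unname(CLASSIFICATION_MAP[out$variant_classification])
  # the controlled vocabulary wins where mapped; the HGVS parse fills gaps
  out$kind <- ifelse(!is.na(mapped), mapped, parsed$kind)
  out$ref_aa <- parsed$ref_aa
  out$codon <- parsed$codon
  out$alt_aa <- parsed$alt_aa

  # nucleotides only meaningful for single-base substitutions
  snv <- !is.na(out$ref_nt) & !is.na(out$alt_nt) &
    nchar(out$ref_nt) == 1L & nchar(out$alt_nt) == 1L &
    out$ref_nt %in% c("A", "C", "G", "T") & out$alt_nt %in% c("A", "C", "G", "T")
  out$ref_nt[!snv] <- NA_character_
  out$alt_nt[!snv] <- NA_character_

  dup <- duplicated(out[, c("sample_id", "protein_change_raw")])
  if (any(dup))
    warning("read_mutations: ", sum(dup),
            " duplicate (sample, protein_change) row(s) kept", call. = FALSE)

  out <- out[, c("sample_id", "gene", "variant_classification", "kind",
                 "ref_aa", "codon", "alt_aa", "protein_change_raw",
                 "vaf_percent", "ref_nt", "alt_nt", "trinucleotide_context")]
  rownames(out) <- NULL
  class(out) <- c("p53_mutations", "data.frame")
  out
}

#' Keep only samples with a single TP53 mutation
#'
#' Samples carrying two or more mutations are excluded (the cohort inclusion
#' rule) and reported; samples present only in the clinical table are
#' labelled wild type.
#'
#' @param mutations a \code{p53_mutations} data frame.
#' @param clinical optional clinical data frame with a \code{sample_id}
#'   column; its mutation-free samples populate the wild-type list.
#' @return a list with \code{records} (single-mutation rows),
#'   \code{exclusions} (data frame \code{sample_id}, \code{reason},
#'   \code{n_mutations}) and \code{wild_type_samples} (character).
#' @export
apply_single_mutation_filter <- function(mutations, clinical = NULL) {
  counts <- table(mutations$sample_id)
  multi <- names(counts)[counts >= 2L]
  single <- names(counts)[counts == 1L]

  exclusions <- data.frame(
    sample_id = multi,
    reason = rep("multiple_mutations", length(multi)),
    n_mutations = as.integer(counts[multi]),
    stringsAsFactors = FALSE)

  records <- mutations[mutations$sample_id %in% single, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- class(mutations)

  wild_type <- character(0)
  if (!is.null(clinical))
    wild_type <- setdiff(unique(clinical$sample_id), mutations$sample_id)

  list(records = records, exclusions = exclusions,
       wild_type_samples = wild_type)
}

#' Read a clinical table
#'
#' Tab-separated clinical export with one row per sample. Anatomical
#' subsites are collapsed to the four HNSCC subgroups: oral cavity (OC:
#' alveolar ridge, buccal mucosa, floor of mouth, hard palate, oral tongue,
#' oral cavity, lips), oropharynx (OP: base of tongue, oropharynx, tonsils),
#' hypopharynx (HP) and larynx (L); unrecognised subsites map to
#' \code{other} with a warning.
#'
#' @param path path to the TSV.
#' @return a data frame of class \code{p53_clinical} with columns
#'   \code{sample_id}, \code{site}, \code{subsite}, \code{hpv_status},
#'   \code{age}, \code{gender}, \code{stage}, \code{grade}, \code{smoking},
#'   \code{packs_smoked}, \code{alcohol}, \code{perineural_invasion},
#'   \code{os_time}, \code{os_event}, \code{dfs_time}, \code{dfs_event},
#'   \code{mrna_log2fpkm1}, \code{rppa_z}.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    stop("clinical file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", "", "."))
  need <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(need, tolower(names(x)))
  if (length(missing) > 0L)
    stop("clinical file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  names(x) <- tolower(names(x))

  get <- function(nm, default = NA) if (nm %in% names(x)) x[[nm]] else
    rep(default, nrow(x))

  subsite <- as.character(get("subsite", NA_character_))
  site <- unname(SITE_MAP[tolower(trimws(subsite))])
  unknown <- !is.na(subsite) & is.na(site)
  if (any(unknown)) {
    warning("read_clinical: ", sum(unknown),
            " sample(s) with unrecognised subsite mapped to 'other'",
            call. = FALSE)
    site[unknown] <- "other"
  }

  out <- data.frame(
    sample_id = as.character(x$sample_id),
    site = site,
    subsite = subsite,
    hpv_status = as.character(get("hpv_status", "unknown")),
    age = suppressWarnings(as.numeric(get("age"))),
    gender = as.character(get("gender")),
    stage = suppressWarnings(as.integer(get("stage"))),
    grade = as.character(get("grade", "unknown")),
    smoking = as.character(get("smoking", "unknown")),
    packs_smoked = suppressWarnings(as.numeric(get("packs_smoked"))),
    alcohol = as.character(get("alcohol", "unknown")),
    perineural_invasion = as.character(get("perineural_invasion", "unknown")),
    os_time = suppressWarnings(as.numeric(x$os_time)),
    os_event = suppressWarnings(as.integer(x$os_event)),
    dfs_time = suppressWarnings(as.numeric(get("dfs_time"))),
    dfs_event = suppressWarnings(as.integer(get("dfs_event"))),
    mrna_log2fpkm1 = suppressWarnings(as.numeric(get("mrna_log2fpkm1"))),
    rppa_z = suppressWarnings(as.numeric(get("rppa_z"))),
    stringsAsFactors = FALSE)

  if (any(out$os_time < 0, na.rm = TRUE))
    stop("negative survival times in clinical file", call. = FALSE)
  if (!all(out$os_event %in% c(0L, 1L, NA)))
    stop("os_event must be 0/1", call. = FALSE)

  rownames(out) <- NULL
  class(out) <- c("p53_clinical", "data.frame")
  out
}

#' Write a table as TSV
#'
#' Plain UTF-8 tab-separated output with a header row; logical columns are
#' written as 0/1 so annotated tables round-trip.
#'
#' @param x a data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) if (is.logical(x[[nm]])) x[[nm]] <- as.integer(x[[nm]])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
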