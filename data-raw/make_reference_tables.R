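# Regenerates the packaged reference TSVs under inst/extdata from the
# constants in R/constants.R. Run from the package root:
#   Rscript data-raw/make_reference_tables.R

source("R/constants.R")

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## amino-acid property table -------------------------------------------------
hb <- rep("neither", 20L)
names(hb) <- AA_ONE
hb[HBOND_DONOR_ONLY] <- "donor_only"
hb[HBOND_ACCEPTOR_ONLY] <- "acceptor_only"
hb[HBOND_BOTH] <- "both"

pol <- rep(NA_character_, 20L)
names(pol) <- AA_ONE
pol[POLARITY_NONPOLAR] <- "nonpolar"
pol[POLARITY_POLAR] <- "polar_uncharged"
pol[POLARITY_POSITIVE] <- "positive"
pol[POLARITY_NEGATIVE] <- "negative"

aa <- data.frame(aa = AA_ONE, hbond_class = unname(hb[AA_ONE]),
                 polarity_class = unname(pol[AA_ONE]))

con <- file("inst/extdata/amino_acid_properties.tsv", "w")
writeLines(c(
  "# p53risk amino-acid property table, schema_version=1",
  "# hbond_class: donor_only {K,R,W}; acceptor_only {E,D}; both {H,N,Q,S,T,Y}; neither otherwise",
  "# polarity_class: default charge/polarity partition; histidine placed polar_uncharged"),
  con)
write.table(aa, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

## secondary-structure map (synthetic reconstruction) ------------------------
# Reconstructed from published descriptions of the p53 core-domain crystal
# structure (beta-sandwich strands, loop-sheet-helix motif, H1 helix in the
# L2 loop, C-terminal H2 helix), collapsed to the four classes
# {helix, strand, turn, unknown}. Residues outside the crystallised core and
# long loop stretches carry no assignment ("unknown"). This is NOT a verbatim
# DSSP export; see the provenance column of the bundle.
ss <- rep("unknown", TP53_N_RESIDUES)
assign_range <- function(ss, ranges, class) {
  for (r in ranges) ss[r[1]:r[2]] <- class
  ss
}
ss <- assign_range(ss, list(c(110, 112), c(124, 127), c(132, 135),
                            c(141, 146), c(156, 163), c(195, 198),
                            c(203, 207), c(214, 219), c(230, 235),
                            c(251, 257), c(264, 274)), "strand")
ss <- assign_range(ss, list(c(177, 181), c(278, 289)), "helix")
ss <- assign_range(ss, list(c(113, 116), c(120, 123), c(128, 131),
                            c(136, 140), c(147, 155), c(164, 170),
                            c(182, 190), c(199, 202), c(208, 213),
                            c(220, 229), c(236, 243), c(258, 263),
                            c(275, 277), c(290, 295)), "turn")

con <- file("inst/extdata/tp53_secondary_structure_synthetic.tsv", "w")
writeLines(c(
  "# p53risk TP53 per-residue secondary structure, schema_version=1",
  "# SYNTHETIC reconstruction from published descriptions of the p53 core-domain",
  "# crystal structure, collapsed to {helix, strand, turn, unknown}; not a",
  "# verbatim DSSP export. Residues outside the crystallised core are unknown."),
  con)
write.table(data.frame(codon = seq_len(TP53_N_RESIDUES),
                       secondary_structure = ss),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

## per-codon residue annotation ----------------------------------------------
codon <- seq_len(TP53_N_RESIDUES)
domain <- ifelse(codon <= DOMAIN_N_TERMINAL[2], "N_terminal",
          ifelse(codon <= DOMAIN_DNA_BINDING[2], "DNA_binding", "C_terminal"))
in_l2l3 <- (codon >= L2L3_RANGES[[1]][1] & codon <= L2L3_RANGES[[1]][2]) |
           (codon >= L2L3_RANGES[[2]][1] & codon <= L2L3_RANGES[[2]][2])

res <- data.frame(
  codon = codon,
  domain = domain,
  is_hotspot = as.integer(codon %in% HOTSPOT_CODONS),
  is_new_hotspot = as.integer(codon %in% NEW_HOTSPOT_CODONS),
  is_zinc_ligand = as.integer(codon %in% ZINC_LIGAND_CODONS),
  is_conserved = as.integer(codon %in% CONSERVED_CODONS),
  is_native_glycine_site = as.integer(codon %in% NATIVE_GLYCINE_CODONS),
  in_L2L3 = as.integer(in_l2l3))

con <- file("inst/extdata/tp53_residue_annotation.tsv", "w")
writeLines(c(
  "# p53risk TP53 per-codon annotation table, schema_version=1",
  "# domain: N_terminal 1-97, DNA_binding 98-292, C_terminal 293-393;",
  "# flags as 0/1; L2-L3 loops are codons 163-195 and 236-251"),
  con)
write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

cat("wrote", nrow(aa), "amino acids,", nrow(res), "codons\n")
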