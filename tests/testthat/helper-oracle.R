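# Independent brute-force re-implementation of the published grouping and
# classification rules, coded directly from the printed rule statements and
# kept free of any package internals. Used to cross-check annotate_cohort(),
# poeta_classify() and highrisk_classify() by exhaustive enumeration.

ORACLE <- local({
  l <- list()
  l$donor_only <- c("K", "R", "W")
  l$acceptor_only <- c("E", "D")
  l$both <- c("H", "N", "Q", "S", "T", "Y")
  l$aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
  l$neither <- setdiff(l$aa20, c(l$donor_only, l$acceptor_only, l$both))
  l$polarity <- c(A = "np", V = "np", L = "np", I = "np", P = "np",
                  F = "np", M = "np", W = "np", G = "np", C = "np",
                  S = "pu", T = "pu", Y = "pu", N = "pu", Q = "pu", H = "pu",
                  K = "pos", R = "pos", D = "neg", E = "neg")
  l$hotspots <- c(175, 245, 248, 273, 282)
  l$new_hotspots <- c(179, 193, 196, 213)
  l$zinc <- c(176, 179, 238, 242)
  l$glycine_sites <- c(117, 154, 187, 244, 245, 262)
  l$l2l3 <- c(163:195, 236:251)
  l$conserved <- c(98, 113, 120, 121, 122, 125, 127, 130, 132, 137, 139,
                   142, 151, 152, 158, 159, 164, 172, 173, 175, 177, 178,
                   179, 196, 198, 199, 205, 208, 215, 216, 218, 219, 220,
                   221, 223, 230, 239, 240, 241, 242, 243, 244, 245, 247,
                   249, 251, 253, 257, 262, 265, 266, 267, 270, 271, 272,
                   275, 276, 277, 278, 279, 280, 281, 282)
  l
})

oracle_hbond_class <- function(aa) {
  ifelse(aa %in% ORACLE$donor_only, "donor_only",
  ifelse(aa %in% ORACLE$acceptor_only, "acceptor_only",
  ifelse(aa %in% ORACLE$both, "both", "neither")))
}

# K/R/W <-> E/D swap, or any H-bonding residue replaced by a non-bonding one
oracle_hbond_disrupted <- function(ref, alt) {
  (ref %in% ORACLE$donor_only & alt %in% ORACLE$acceptor_only) |
    (ref %in% ORACLE$acceptor_only & alt %in% ORACLE$donor_only) |
    (!(ref %in% ORACLE$neither) & alt %in% ORACLE$neither)
}

oracle_polarity_change <- function(ref, alt) {
  unname(ORACLE$polarity[ref] != ORACLE$polarity[alt])
}

oracle_domain <- function(codon) {
  ifelse(codon <= 97, "N_terminal",
         ifelse(codon <= 292, "DNA_binding", "C_terminal"))
}

oracle_zygosity <- function(vaf) {
  ifelse(is.na(vaf), "unknown",
  ifelse(vaf >= 65, "homozygous",
  ifelse(vaf >= 40, "heterozygous", "subclonal_low")))
}

# truncating kinds disruptive; missense disruptive iff in L2-L3 with a
# charge/polarity change
oracle_poeta <- function(kind, codon, ref, alt) {
  ifelse(kind != "missense", "disruptive",
         ifelse(codon %in% ORACLE$l2l3 & oracle_polarity_change(ref, alt),
                "disruptive", "nondisruptive"))
}

# deleterious reclassification rules D1-D4 before the conservative rule C1;
# truncating kinds are always high risk
oracle_highrisk <- function(kind, codon, ref, alt, zygosity, ss) {
  n <- max(length(kind), length(codon))
  kind <- rep_len(kind, n); codon <- rep_len(codon, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  zygosity <- rep_len(zygosity, n); ss <- rep_len(ss, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] != "missense") { out[i] <- "high_risk"; next }
    if (zygosity[i] == "homozygous" ||
        codon[i] %in% ORACLE$zinc ||
        oracle_hbond_disrupted(ref[i], alt[i]) ||
        ss[i] == "unknown") {
      out[i] <- "high_risk"
    } else if (ss[i] %in% c("helix", "strand", "turn")) {
      out[i] <- "low_risk"
    } else {
      out[i] <- if (oracle_poeta(kind[i], codon[i], ref[i], alt[i]) ==
                    "disruptive") "high_risk" else "low_risk"
    }
  }
  out
}

# O(n^2) pairwise Harrell's C: comparable pairs have an unambiguous event
# ordering; risk ties count one half. Fixtures use distinct times.
oracle_harrell_c <- function(time, event, risk) {
  conc <- disc <- ties <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    early <- if (time[i] < time[j]) i else j
    late <- if (time[i] < time[j]) j else i
    if (event[early] != 1) next
    if (risk[early] > risk[late]) conc <- conc + 1
    else if (risk[early] < risk[late]) disc <- disc + 1
    else ties <- ties + 1
  }
  (conc + ties / 2) / (conc + disc + ties)
}

# deterministic reference residue per codon for enumerations: the identity
# named in the published rule lists where available, else cycling over the
# 20 standard residues
oracle_ref_residue <- function(codon) {
  named <- c(`98` = "P", `113` = "F", `120` = "K", `121` = "S", `122` = "V",
             `125` = "T", `127` = "S", `130` = "L", `132` = "K", `137` = "L",
             `139` = "K", `142` = "P", `151` = "P", `152` = "P", `158` = "R",
             `159` = "A", `164` = "K", `172` = "V", `173` = "V", `175` = "R",
             `176` = "C", `177` = "P", `178` = "H", `179` = "H", `193` = "H",
             `196` = "R", `198` = "E", `199` = "G", `205` = "Y", `208` = "D",
             `213` = "R", `215` = "S", `216` = "V", `218` = "V", `219` = "P",
             `220` = "Y", `221` = "E", `223` = "P", `230` = "T", `238` = "C",
             `239` = "N", `240` = "S", `241` = "S", `242` = "C", `243` = "M",
             `244` = "G", `245` = "G", `247` = "N", `248` = "R", `249` = "R",
             `251` = "I", `253` = "T", `257` = "L", `262` = "G", `265` = "L",
             `266` = "G", `267` = "R", `270` = "F", `271` = "E", `272` = "V",
             `273` = "R", `275` = "C", `276` = "A", `277` = "C", `278` = "P",
             `279` = "G", `280` = "R", `281` = "D", `282` = "R",
             `117` = "G", `154` = "G", `187` = "G", `306` = "R")
  out <- ORACLE$aa20[(codon - 1) %% 20 + 1]
  hit <- match(as.character(codon), names(named))
  out[!is.na(hit)] <- named[hit[!is.na(hit)]]
  out
}

# small synthetic mutation + clinical fixture writers used across IO tests
write_mutation_fixture <- function(path, rows) {
  header <- "sample_id\tgene\tvariant_classification\tprotein_change\tdna_vaf\tref_nt\talt_nt\ttrinucleotide_context"
  writeLines(c(header, rows), path)
  path
}

write_clinical_fixture <- function(path, rows) {
  header <- paste("sample_id", "subsite", "hpv_status", "age", "gender",
                  "stage", "grade", "smoking", "alcohol",
                  "perineural_invasion", "os_time", "os_event", "dfs_time",
                  "dfs_event", sep = "\t")
  writeLines(c(header, rows), path)
  path
}
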