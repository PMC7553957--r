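# Constant sets behind the TP53 annotation rules. The packaged TSVs under
# inst/extdata are generated from these (data-raw/make_reference_tables.R);
# validate_bundle() re-checks loaded bundles against them so a hand-edited
# reference file cannot silently drift.

AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*")

# Hydrogen-bond donor/acceptor classes: K, R, W donate only; E, D accept
# only; H, N, Q, S, T, Y both; the remaining nine side chains neither.
HBOND_DONOR_ONLY    <- c("K", "R", "W")
HBOND_ACCEPTOR_ONLY <- c("E", "D")
HBOND_BOTH          <- c("H", "N", "Q", "S", "T", "Y")

# Charge/polarity classes used by the disruptive-missense rule. Histidine is
# placed with the polar-uncharged residues by default (configurable, see
# hbond/polarity helpers).
POLARITY_NONPOLAR  <- c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C")
POLARITY_POLAR     <- c("S", "T", "Y", "N", "Q", "H")
POLARITY_POSITIVE  <- c("K", "R")
POLARITY_NEGATIVE  <- c("D", "E")

TP53_N_RESIDUES <- 393L

# Domain boundaries on the 393-residue protein.
DOMAIN_N_TERMINAL  <- c(1L, 97L)
DOMAIN_DNA_BINDING <- c(98L, 292L)
DOMAIN_C_TERMINAL  <- c(293L, 393L)

# Canonical mutational hotspots plus the additional recurrently mutated
# residues promoted to hotspot status in this cohort.
HOTSPOT_CODONS     <- c(175L, 245L, 248L, 273L, 282L)
NEW_HOTSPOT_CODONS <- c(179L, 193L, 196L, 213L)

# Residues coordinating the structural zinc ion (C176, H179, C238, C242).
ZINC_LIGAND_CODONS <- c(176L, 179L, 238L, 242L)

# Restricted-conformation native glycines.
NATIVE_GLYCINE_CODONS <- c(117L, 154L, 187L, 244L, 245L, 262L)

# L2-L3 DNA-contact loops of the core domain.
L2L3_RANGES <- list(c(163L, 195L), c(236L, 251L))

# 63 evolutionarily conserved residues (Martin et al. residue list).
CONSERVED_RESIDUES <- c(
  P = 98L,  F = 113L, K = 120L, S = 121L, V = 122L, T = 125L, S = 127L,
  L = 130L, K = 132L, L = 137L, K = 139L, P = 142L, P = 151L, P = 152L,
  R = 158L, A = 159L, K = 164L, V = 172L, V = 173L, R = 175L, P = 177L,
  H = 178L, H = 179L, R = 196L, E = 198L, G = 199L, Y = 205L, D = 208L,
  S = 215L, V = 216L, V = 218L, P = 219L, Y = 220L, E = 221L, P = 223L,
  T = 230L, N = 239L, S = 240L, S = 241L, C = 242L, M = 243L, G = 244L,
  G = 245L, N = 247L, R = 249L, I = 251L, T = 253L, L = 257L, G = 262L,
  L = 265L, G = 266L, R = 267L, F = 270L, E = 271L, V = 272L, C = 275L,
  A = 276L, C = 277L, P = 278L, G = 279L, R = 280L, D = 281L, R = 282L)

CONSERVED_CODONS <- unname(CONSERVED_RESIDUES)

# Partial residue-identity map assembled from the named residues above plus
# hotspot/zinc/glycine identities (R175, C176, H179, H193, R196, R213, C238,
# G245, R248, G262, R273, R282, and glycines 117/154/187/244). Used by the
# simulator to plant realistic reference residues; annotation itself never
# needs it because ref/alt come from the HGVS string.
KNOWN_RESIDUE_IDENTITY <- local({
  m <- structure(names(CONSERVED_RESIDUES), names = CONSERVED_RESIDUES)
  extra <- c(`176` = "C", `193` = "H", `213` = "R", `238` = "C",
             `248` = "R", `273` = "R", `117` = "G", `154` = "G",
             `187` = "G")
  m[names(extra)] <- extra
  m
})

# MAF / Sequence-Ontology variant-classification vocabulary -> internal kind.
CLASSIFICATION_MAP <- c(
  Missense_Mutation       = "missense",
  missense_variant        = "missense",
  Nonsense_Mutation       = "nonsense_stop",
  stop_gained             = "nonsense_stop",
  Frame_Shift_Del         = "frameshift",
  Frame_Shift_Ins         = "frameshift",
  frameshift_variant      = "frameshift",
  In_Frame_Del            = "inframe_indel",
  In_Frame_Ins            = "inframe_indel",
  inframe_deletion        = "inframe_indel",
  inframe_insertion       = "inframe_indel",
  Splice_Site             = "splice",
  splice_acceptor_variant = "splice",
  splice_donor_variant    = "splice",
  splice_region_variant   = "splice")

# Anatomical-subsite names -> HNSCC subgroup.
SITE_MAP <- c(
  "alveolar ridge"     = "OC",
  "buccal mucosa"      = "OC",
  "floor of mouth"     = "OC",
  "hard palate"        = "OC",
  "oral tongue"        = "OC",
  "oral cavity"        = "OC",
  "lip"                = "OC",
  "lips"               = "OC",
  "base of tongue"     = "OP",
  "oropharynx"         = "OP",
  "tonsil"             = "OP",
  "tonsils"            = "OP",
  "hypopharynx"        = "HP",
  "larynx"             = "L")

RISK_RULE_IDS <- c("D1_homozygous", "D2_zinc_ligand", "D3_hbond_disruption",
                   "D4_unassigned_structure", "C1_structured_hbond_kept")
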