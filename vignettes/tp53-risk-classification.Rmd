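---
title: "Classifying TP53 mutations by risk of death: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TP53 mutations by risk of death: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53risk)
```

## The problem

p53 is a 393-residue tumour suppressor whose gene is mutated in roughly
two thirds of head and neck squamous cell carcinomas (HNSCC). Mutations
are heterogeneous — missense substitutions across the DNA-binding core,
truncating stops and frameshifts, splice-site disruptions — and their
prognostic weight differs. The widely used Poeta rule set separates
*disruptive* from *nondisruptive* mutations; `p53risk` implements that
scheme and a refinement that further stratifies missense mutations into
*high* and *low risk of death* using zygosity, zinc-ligand involvement,
hydrogen-bond chemistry and secondary structure. This vignette explains
the rules, the reference data behind them, the statistical and survival
machinery used to evaluate them, the synthetic-cohort generator, and the
design decisions taken where the procedure was genuinely open.

## Reference data

All rule constants ship as plain TSV files under `inst/extdata` and load
into a `p53_reference_bundle`:

* **Domains.** N-terminal 1–97, DNA-binding 98–292, C-terminal 293–393.
* **Hotspots.** The canonical residues 175, 245, 248, 273, 282, plus the
  recurrently mutated residues 179, 193, 196 and 213 promoted to hotspot
  status in the HNSCC cohort this package targets.
* **Zinc ligands.** C176, H179, C238, C242, which coordinate the
  structural zinc ion that stabilises the p53/DNA complex.
* **Conserved residues.** The 63-residue evolutionary-conservation list
  (Martin and colleagues' analysis). Note that this list contains H179 and
  C242 but *not* C176 or C238: the zinc-ligand set is deliberately not a
  subset of the conserved set, and `validate_bundle()` checks the sets
  independently.
* **L2–L3 loops.** Codons 163–195 and 236–251, the DNA-contact loops at
  the heart of the Poeta missense rule.
* **Native glycines.** Codons 117, 154, 187, 244, 245, 262, where the
  glycine backbone permits conformations other residues cannot adopt.
* **Hydrogen-bond classes.** K, R, W donate only; E, D accept only; H, N,
  Q, S, T, Y both donate and accept; the remaining nine side chains do
  neither.
* **Charge/polarity classes.** Nonpolar {A, V, L, I, P, F, M, W, G, C},
  polar uncharged {S, T, Y, N, Q, H}, positive {K, R}, negative {D, E}.

### The secondary-structure map is a synthetic reconstruction

The classification rules need a per-residue secondary-structure
assignment collapsed to four classes: helix (3/10 plus alpha), strand
(bridge plus beta strand), turn (turn plus bend) and unknown (no
assignment). The package ships
`tp53_secondary_structure_synthetic.tsv`, a reconstruction assembled from
published descriptions of the p53 core-domain crystal structure: the
beta-sandwich strands S1–S10, the H1 helix inside the L2 loop
(177–181), the C-terminal H2 helix (278–289), turn assignments on the
short connectors, and "unknown" everywhere else — in particular the
entire N-terminal (1–109) and C-terminal (296–393) regions, which are
disordered or absent in the core-domain crystals. It is *not* a verbatim
DSSP export; the file header and the bundle's `provenance` field say so,
and the map is swappable (`load_reference_bundle(structure_path = ...)`).
Because rule D4 keys on the "unknown" class, users who care about exact
boundary residues near structural elements should substitute their own
DSSP-derived table; all downstream code is agnostic to the source.

## Input handling

`read_mutations()` accepts MAF-like TSVs (UCSC Xena `mutect2_snv` exports
or generic MAF headers), keeps only the requested gene (TP53 by default),
and normalises VAF to percent — a whole-column value range within [0, 1]
is auto-detected as fractions, since Xena exports fractions while the
clinical literature reports percent. `parse_protein_change()` covers the
common HGVS protein dialects (1- and 3-letter substitutions, `*`/`X`/
`Ter` stops, `fs` frameshifts, `del`/`ins`/`dup`/`delins` in-frame
indels, `X123_splice` markers); anything else raises a classed
`p53_parse_error` carrying the raw string, never a silent drop. The
variant-classification vocabulary (both MAF terms and Sequence Ontology
terms) takes precedence over the parsed string for the *kind* of a
mutation; the parse supplies residue and codon detail. Cohort inclusion
follows the single-mutation rule: samples with two or more TP53 mutations
are excluded and reported; clinical samples with no mutation are wild
type.

## The annotation and classification rules

Per mutation, `annotate_cohort()` computes domain, secondary structure,
zygosity, the residue flags, hydrogen-bond classes and disruption,
polarity change, proline/glycine substitutions and the nucleotide-change
features. Zygosity follows the VAF bands: [40, 65) heterozygous,
[65, 100] homozygous. VAF below 40% receives the distinct label
`subclonal_low` — the source convention assigns no label there, and
calling it anything else would either silently inflate the homozygous
rule or conflate it with heterozygous; `subclonal_low` is never treated
as homozygous. Missing VAF is `unknown` and likewise never fires the
homozygosity rule.

The Poeta scheme (`poeta_classify()`): truncating kinds (stop,
frameshift, in-frame, splice) are disruptive; missense in L2–L3 with a
charge/polarity-class change is disruptive; all other missense is
nondisruptive. Kind `other` (unmapped classifications, synonymous
changes) raises an error — an unclassifiable variant must be visible, not
defaulted.

The high-/low-risk scheme (`highrisk_classify()`) evaluates, for
missense mutations, the deleterious rules in a fixed precedence order —
D1 homozygous, D2 zinc ligand, D3 hydrogen-bond disruption, D4
unassigned secondary structure — and only then the conservative rule C1
(assigned structure, bonding ability maintained). Three design choices
deserve comment:

* **Deleterious rules before C1.** The source lists the disruptive
  reclassifications first and never states a conflict-resolution policy.
  Treating "high risk if *any* deleterious criterion holds" maximises
  consistency with the scheme's stated purpose of flagging patients at
  high risk of death; a residue in a helix whose substitution destroys
  hydrogen bonding is upgraded by D3, not rescued by C1. All fired rules
  are recorded (`fired_rules`), so any alternative precedence can be
  audited after the fact, and `replay_fired_rules()` reproduces every
  call from its trace.
* **"Maintaining the ability to donate or accept hydrogen bonds"** is
  read as set containment: a donor-only residue replaced by a
  donor-and-acceptor residue keeps (indeed extends) its abilities, so
  R→H is not disruptive under D3.
* **D1 applies to missense only** by default, mirroring the scheme's
  framing around "deleterious missense substitutions"; truncating
  mutations are high risk regardless, so extending D1 to them (available
  via `homozygous_applies_to = "all"`) only changes the recorded rule
  trace.

Histidine's charge class is the one genuinely underdetermined constant:
the default places H with the polar-uncharged residues (its side chain is
mostly neutral at physiological pH), which makes R175H a
polarity-changing — hence Poeta-disruptive — substitution. The
`his_class = "positive"` switch flips this convention for sensitivity
analysis; under it R175H becomes nondisruptive under Poeta while
remaining high risk in the refined scheme (it is a homozygous-candidate
hotspot in an unassigned-structure stretch of L2).

## Statistics and survival machinery

The cohort tests wrap the standard R implementations behind the
interfaces the pipeline needs: uncorrected Pearson chi-square by default
(`pearson_chi2()`; the continuity correction is a flag, off because the
published contingency p-values match the uncorrected statistic), Fisher's
exact test for degenerate margins, Mann–Whitney / Kruskal–Wallis /
Spearman with midrank ties, Holm's step-down adjustment, and a median
split whose ties-at-the-median go to "low" (an arbitrary but fixed and
documented policy; the convention's source is silent).

Survival analysis uses the `survival` package: product-limit curves and
the log-rank test (`km_logrank()`), and Cox regression with Efron tie
handling by default (`cox_fit()`; Breslow by flag — Efron is the common
software default and the choice is immaterial for continuous simulated
times). Model quality is summarised by Harrell's C (risk-score ties count
one half), AIC = −2ℓ + 2k, and BIC = −2ℓ + k·ln(m) with m = number of
events by default — the events count is the effective sample size of the
partial likelihood; ln(n) is available, and a BIC *difference* between
models fitted to the same data is unaffected by the choice.
`compare_models()` labels ΔBIC magnitudes with the Kass–Raftery bands
(< 2 none, 2–6 positive, 6–10 strong, ≥ 10 very strong). In the pipeline
the multivariate fits use age (continuous), gender (factor), stage and
grade (ordinal-as-linear, a parsimonious default given sparse extreme
categories) plus the three-level risk factor with wild type as the
reference level.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions: 415 patients by
default, mutation probability 286/415, type weights
frameshift 51 : inframe 8 : missense 152 : splice 26 : stop 49, site
weights OC 246 : OP 62 : HP 9 : L 90, and observed VAF with mean 46.73%,
SD 19.33% on [5, 97]. Two generator details matter:

* **VAF moments.** The reported mean and SD describe the *observed*
  (range-limited) VAF. A truncated normal naively parameterised with
  μ = 46.73, σ = 19.33 has truncated moments near 47.2/18.1, so the
  generator solves numerically for the pre-truncation (μ, σ) whose
  truncated moments equal the reported ones, then samples by inverse-CDF.
* **Missense codons** are drawn uniformly over the DNA-binding domain
  (98–292) with 20% of the mass on the nine hotspot residues. This
  matches the qualitative concentration of missense mutations in the
  DBD without claiming the exact empirical codon distribution. Reference
  residues come from the identities the rule lists name (the conserved
  list, hotspots, zinc ligands, glycine sites) and are uniform elsewhere;
  the full p53 sequence is deliberately not shipped, since annotation
  reads residues from the HGVS string and never needs it.

Each sample's generating class is obtained by pushing the planted
mutation through the package's own annotation and classification; the
truth table therefore certifies *pipeline identity* (write → read →
annotate → classify returns the generating labels), while correctness of
the rules themselves is certified separately by an independently coded
brute-force oracle over all 393 × 19 substitutions × 3 zygosity bands ×
4 structure classes. Survival times are exponential with hazard
λ₀·exp(log HR of the class) (defaults: λ₀ = 4 × 10⁻⁴/day, high risk
HR 1.8, low risk HR 1.0), censoring is independent exponential with its
rate solved so the expected censored fraction hits the target (60%),
plus an administrative horizon at 6000 days. Clinical covariates are
independent of class by default (age ~ N(61, 12²) clipped to [19, 90],
73% male, stage and grade multinomials typical of HNSCC); a
`confound_stage` switch couples stage to class for stress-testing
multivariate adjustment. p53 mRNA is drawn higher in wild-type than in
mutated samples, mirroring the observed expression difference.

What the simulator does *not* model: real codon-specific mutation
spectra, HPV biology, correlated covariates (unless the confounding
switch is on), non-proportional hazards, informative censoring, or any
expression–survival coupling. Passing tests on synthetic cohorts
therefore certify the *machinery* — rule application, estimation,
calibration under a correctly specified proportional-hazards model — not
clinical validity on real data.

## Numerical choices and problem sizes

Gradient tolerance for the Cox partial likelihood is 10⁻⁹ (50 iterations
max); likely-divergent fits (|coef| > 15 or non-finite) are reported as
errors rather than returned. The moment-matching solver for the VAF
distribution runs Nelder–Mead to a 10⁻¹² relative tolerance. The test
suite and the acceptance script size their simulations as: one fixed
cohort of n = 2000 for hazard-ratio point recovery, 200 replicates of
n = 400 for 95% CI coverage (expected in [0.92, 0.98]), and one cohort of
n = 10⁴ for spectrum fidelity within three standard errors — sizes chosen
so each check has the power to fail meaningfully while the whole suite
runs in well under a minute per property.

## Known limitations

* The secondary-structure map is a reconstruction (see above); residues
  near element boundaries may differ from a DSSP export, which can flip
  individual D4/C1 calls. The classification logic is exact for whatever
  map is supplied.
* CpG C>T detection relies on the trinucleotide context column (or a
  user-supplied CpG position list); without either, the flag is false.
* Stage/grade enter the Cox model linearly by default; strongly
  non-linear stage effects would call for the categorical coding.
* The package classifies TP53 only; the constant tables are
  gene-specific by design.
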