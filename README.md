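# p53risk

Somatic TP53 mutations are the most common genomic alteration in head and
neck squamous cell carcinoma (HNSCC), but a bare wild-type/mutated split
carries limited prognostic information. `p53risk` implements, for
biostatisticians and translational researchers working with MAF-style
mutation tables and clinical exports, the full machinery needed to turn a
single TP53 mutation per patient into a prognostic class:

* **Annotation** of each mutation with the structural and biochemical
  features the classification rules consume: protein domain (N-terminal
  1–97, DNA-binding 98–292, C-terminal 293–393), per-residue secondary
  structure collapsed to {helix, strand, turn, unknown}, hotspot residues
  (175, 245, 248, 273, 282 plus 179, 193, 196, 213), zinc-ligand residues
  (C176, H179, C238, C242), the 63 evolutionarily conserved residues,
  L2–L3 loop membership (codons 163–195 and 236–251), hydrogen-bond
  donor/acceptor classes, charge/polarity changes, proline and
  native-glycine substitutions, transition/transversion spectra with CpG
  C>T and G:C>T:A flags, and VAF-based zygosity (40–64% heterozygous,
  65–100% homozygous).
* **Classification** under two schemes. The Poeta algorithm calls stop,
  frameshift, in-frame and splice mutations *disruptive*, together with
  missense mutations in the L2–L3 loops that change charge or polarity;
  everything else is *nondisruptive*. The refined high-/low-risk-of-death
  algorithm reclassifies missense mutations as *high risk* when any of four
  deleterious rules fires — D1 homozygous locus, D2 zinc ligand, D3
  hydrogen-bond disruption, D4 unassigned secondary structure — and as
  *low risk* when the residue sits in an assigned secondary structure and
  keeps its hydrogen-bonding ability (C1). Every call carries an auditable
  `fired_rules` trace.
* **Cohort statistics and survival modelling**: uncorrected Pearson
  chi-square and Fisher exact tests, Mann–Whitney/Kruskal–Wallis/Spearman
  rank tests, Holm adjustment, median expression splits, Kaplan–Meier with
  log-rank, multivariate Cox regression (covariates age, gender, stage,
  grade; Efron ties), and model comparison by Harrell's C,
  AIC = −2ℓ + 2k and BIC = −2ℓ + k·ln(events), with Kass–Raftery evidence
  labels on ΔBIC.
* **Simulation** of synthetic cohorts with the study's mutation-type
  spectrum, VAF distribution and class-dependent proportional hazards,
  with ground-truth labels for end-to-end validation.

## Worked example

```r
library(p53risk)

# a single mutation: the classic Y220C missense, heterozygous
y220c <- annotate_cohort(data.frame(sample_id = "TCGA-XX", kind = "missense",
                                    ref_aa = "Y", codon = 220L, alt_aa = "C",
                                    vaf_percent = 45))
poeta_classify(y220c)
#> [1] "nondisruptive"
highrisk_classify(y220c)
#>   highrisk_class         fired_rules
#> 1      high_risk D3_hbond_disruption
```

Y220C lies outside the L2–L3 loops, so the Poeta algorithm calls it
nondisruptive; the refined scheme upgrades it to high risk because
tyrosine hydrogen-bonds and cysteine does not (rule D3).

A full pipeline run on a simulated 415-patient cohort:

```r
cohort <- simulate_cohort(simulation_config(n_patients = 415), seed = 42)
paths  <- write_cohort(cohort, "cohort_dir")
run    <- run_pipeline(paths[["mutations"]], paths[["clinical"]], "out_dir")
run$calls
#> TP53 risk calls for 415 samples
#> Poeta scheme:
#>    disruptive nondisruptive     wild_type
#>           161           126           128
#> high-/low-risk scheme:
#> high_risk  low_risk wild_type
#>       218        69       128
run$comparison
#> model a: C = 0.5876, AIC = 1776.932, BIC = 1795.887
#> model b: C = 0.6316, AIC = 1750.593, BIC = 1769.548
#> delta BIC = 26.339 (very strong evidence)
```

Model "a" is the multivariate Cox fit (age, gender, stage, grade) with the
Poeta classes, model "b" the same fit with the high-/low-risk classes; the
lower BIC of model b, here by more than 10 points, is very strong evidence
that the refined classes order survival better on this cohort (the
simulator plants a high-risk hazard ratio of 1.8 against wild type and low
risk, so this is the expected outcome).

The output directory contains `annotated.tsv`, `risk_calls.tsv`,
`stats.tsv`, `survival_fits.tsv`, `km_curves.tsv`,
`model_comparison.json` and a `manifest.json` with input hashes for
reproducibility. A thin command-line wrapper ships at
`inst/exec/p53risk` (`p53risk simulate`, `p53risk run`).

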