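Package: p53risk
Title: TP53 Mutation Annotation and Prognostic Risk Classification for
    Head and Neck Squamous Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates somatic TP53 mutations with structural and
    biochemical features (protein domain, secondary structure, mutational
    hotspots, zinc-ligand residues, evolutionary conservation,
    hydrogen-bond donor/acceptor classes, charge/polarity changes,
    transition/transversion spectra and VAF-based zygosity), classifies
    them with the Poeta disruptive/nondisruptive algorithm and with a
    refined high-/low-risk-of-death algorithm, and provides the cohort
    statistics, Kaplan-Meier/log-rank and multivariate Cox machinery
    (Harrell's C, AIC, BIC model comparison) used to evaluate the
    classifiers, together with a synthetic-cohort simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
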