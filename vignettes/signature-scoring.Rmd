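---
title: "Scoring, checking and comparing cancer transcriptional signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, checking and comparing cancer transcriptional signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcompass)
```

## Why single-sample signature scores

A transcriptional signature is a gene set — sometimes with per-gene
weights or class labels — summarized into a score that can be computed
for one sample without refitting anything on a cohort. Such scores are
used to read off tumor phenotypes (hypoxia, proliferation, chromosomal
instability, EMT), microenvironment activity (immune infiltration,
checkpoint activity, ECM remodeling) and clinical correlates
(chemoresistance, prognosis). The same machinery applies to bulk
samples, single cells and spatial spots; what changes across
technologies is not the arithmetic but the reliability of the inputs,
which is why quality control is a first-class module here rather than an
afterthought.

`sigcompass` organizes this into: a validated catalog of signature
definitions; a scoring engine with six method families; five
reliability metrics and a filtering rule; comparison utilities
(correlation clustering, survival association, group tests); simulators
that generate data with known planted signal; and a CLI that chains the
pieces.

## The catalog and its validation rules

The packaged catalog transcribes the metadata of 47 published cancer
signatures spanning 16 topics, including their applicable tumor types
(17 entries are pan-cancer, 11 apply to ovarian tumors), authorship and
accepted input technologies. Definitions are stored as one JSON document
each plus an index — diffable and user-extensible; `load_catalog()`
accepts any directory in the same layout, so adding a signature is
writing one JSON file.

`validate_signature()` enforces the machine-checkable inclusion rules: a
non-empty gene list of well-formed official-symbol-shaped identifiers
(genes with malformed symbols are flagged and removed, mirroring the
practice of dropping genes without an official symbol), an unambiguous
scoring method, a declared input scale, and the per-family structural
requirements (finite weights for weighted sums, at least one up gene for
contrasts, a centroid matrix with two or more subtypes for consensus
subtyping, all four categories for the immunophenoscore). The
`<Topic>_<Author>` naming convention is checked *advisorily* only: the
published collection itself contains names without an author suffix
(e.g. `IPSOV`), so a hard invariant would reject the very table the
catalog transcribes.

**Provenance of the packaged gene lists.** Full gene lists ship for a
representative subset covering every method family. Two are transcribed
as published: the 12-chemokine list (`Chemokines_Messina`) and the
6-gene interferon-gamma list (`IFN_Ayers`). The others — `EMT_Cheng`
(51 genes), `Hypoxia_Buffa` (52), `ECM_Chakravarthy` (15 up / 15 down),
`IPS_Charoentong`, and the `ConsensusOV_Chen` centroid matrix — are
**synthetic stand-ins**: real HGNC symbols biologically plausible for
each topic, with list sizes matching the published ones, flagged
`genes_synthetic` and stored in `*.synthetic-genes.json` files. They
exercise the machinery faithfully but must not be used for biological
inference. The remaining 40 entries are metadata-only
(`genes_available = FALSE`): they answer catalog queries and are refused
by the scoring engine with an explicit error, never silently scored.

## Scoring: families, scales, coverage

Signatures declare the expression scale their method expects;
`compute_signature()` converts on a copy when needed. Defined conversion
paths are counts→CPM and FPKM→TPM (per-observation renormalization to
one million, zeros left at zero, all-zero observations passed through
with a warning), counts→FPKM given gene lengths, and any linear
metric→log as `log2(x + 1)`. The pseudocount of 1 and base 2 are the
dominant convention in the source literature; both are per-call
configurable. Undefined paths (log back to counts, CPM to counts) raise
an unsupported-conversion error rather than guessing.

Gene matching is case-insensitive on symbols. Coverage — genes present
divided by genes requested — is recorded in every result; below
`min_coverage` (default 5%, the boundary counts as acceptable) scoring
is refused with a coverage report. The 5% default mirrors the practice
of scoring with partial gene lists while surfacing "% genes used" as a
QC metric instead of failing silently.

Numerical choices worth knowing:

- **z-scores** use the sample standard deviation (n−1); zero-variance
  genes get z = 0 and therefore contribute nothing rather than NaN.
- **ssGSEA** is deliberately pinned to one canonical, oracle-testable
  definition, since the source literature rarely states one precisely:
  ranks are ascending with mid-ranks for ties; the walk order among tied
  ranks is lexicographic by gene ID (full determinism); in-set steps are
  weighted `rank^0.25` normalized over the set, out-of-set steps are
  uniform; the score is the sum of the running difference. It depends on
  the data only through ranks, so any strictly monotone per-observation
  transform — normalization included — leaves it unchanged. The full
  gene background is required; a set that exhausts the background is an
  error (the out-of-set ECDF would be undefined).
- **Immunophenoscore composite**: category scores are means of weighted
  subclass means of gene z-scores; a category with no genes present
  refuses the composite instead of averaging three categories as if
  they were four. The aggregate-to-composite map
  (`0 if AZ ≤ 0, min(10, 10·AZ/3)` otherwise) makes 0 and 10 hard
  endpoints, with AZ = 3 mapping to 10.
- **Consensus subtyping** is centroid correlation, not the original
  trained classifier (explicitly out of scope): per-observation Pearson
  correlation over shared genes, at least 3 shared genes required,
  zero-variance observations get missing scores, ties in the argmax go
  to the lexicographically first subtype with a warning.
- Zeros in sparse data are treated as observed values, never imputed;
  their impact is *measured* by the QC module. Imputation belongs
  upstream.
- Microarray input may contain missing values; they are excluded
  gene-wise from means. Sequencing input must be complete.

## Quality control

Five metrics per signature: (i) per-observation mean expression of the
signature genes present; (ii) per-observation % of zeros among those
genes; (iii) Pearson correlation between scores and per-observation
total counts; (iv) correlation between scores and the per-observation
% of zeros over the whole matrix; (v) % of signature genes used.
Correlations default to Pearson (the source describes the check but not
the estimator; Spearman is available by flag for rank robustness on
sparse data). For spatial data the evaluation carries a note rather
than a different formula: per-spot totals track the number and type of
captured cells, so a score/total-count correlation can be biology, not
artifact.

The filtering rule is conjunctive: a signature is dropped only when its
median % zeros exceeds 90 **and** its coverage is below 30%. The 90%
threshold is the published case-study rule; the "low percentage of
expressed signature genes" half is not quantified in the source, so 30%
is this package's explicit, documented default — change it per call if
your data warrant.

## Comparison

The score correlation matrix (pairwise-complete; zero-variance columns
dropped with a warning) is clustered with Euclidean distances *between
the rows of the correlation matrix* and complete linkage — literally
the published Methods recipe — and the number of clusters is chosen by
mean silhouette over k = 2…min(10, n−1), ties to the smallest k.
Identical signatures make silhouettes undefined (all distances zero);
that is an error path, not a silent k = 1.

Survival association dichotomizes at the median (ties to the low arm;
the source does not state its dichotomization, so the median is the
documented default, and any numeric split value is accepted) and uses
the two-sample log-rank test; arms with fewer than 2 events yield a
missing p-value with a warning. Group comparison uses Welch t-tests
(the source says only "t test"; the unequal-variance form is the safer
default) for every signature and group pair, excludes groups below 20
observations (the published cell-count rule), and adjusts
Benjamini–Hochberg across the whole table — a decision the source is
silent on, hence configurable.

## What the simulators emulate — and what they do not

`simulate_bulk()` draws gene means from a lognormal
(meanlog 1.5, sdlog 1.2 — median mean ≈ 4.5 counts with a heavy right
tail) and counts from a negative binomial with dispersion 0.4; planted
signals multiply the means of a gene set by `2^lfc` in the signal
observations. `simulate_single_cell()` adds per-entry dropout with
probability `plogis(1 − 0.8·log μ)`, logistic in the log of the
(effect-adjusted) mean, giving overall zero fractions around 60–70% and
a closed-form expected zero fraction (`expected_zero_fraction()`) that
the tests verify the realized sparsity against. `simulate_spatial()`
lays spots on an integer grid with free-text region labels and lets
planted signals target a region (e.g. a proliferation-like program in
the "tumor" region). These hyperparameters are the generator's stated
world; they were chosen once as desk-scale-realistic values and are not
tuned against test outcomes.

The simulators deliberately omit gene–gene correlation structure, batch
effects, library-size gradients, and cell-type mixtures within spots.
A green planted-signal test therefore establishes that the scoring
arithmetic recovers a multiplicative mean shift of known size under NB
noise and dropout — not that a given published signature separates real
tumor phenotypes. Truth tables are first-class outputs, so tests never
re-derive labels from the data.

## Design choices made where the design was open

- The 47 published signatures are bespoke literature recipes; this
  package normalizes them into six families and encodes each entry as
  (family, parameters). This trades recipe-exactness for a reproducible,
  oracle-testable core; exact recipes can be added later as new
  families.
- Tissue queries are case-insensitive substring matches over the
  free-text tumor-type strings, with a small alias table ("ovary" →
  "ovarian", "brain" → glioma/glioblastoma, "kidney" → renal, …);
  pan-cancer entries satisfy any tissue query unless `include_pan =
  FALSE`.
- Gene-ID translation drops unmapped genes with a logged count rather
  than erroring, and resolves many-to-one collisions by keeping the row
  with the highest total signal (summing available as an option) —
  scoring is robust to partial gene sets and QC reports the coverage.
- Whether original recipes post-process scores (e.g. cohort min–max) is
  reference-specific; defaults here are "none".
- QC correlations are computed over all observations by default;
  per-annotation strata are available by subsetting
  (`obs_subset`), since the source leaves the stratification ambiguous.

## Known limitations

- Packaged gene lists other than the two transcribed ones are synthetic
  stand-ins (see above); scoring them on real data yields syntactically
  valid but biologically meaningless numbers.
- Consensus subtyping is a centroid approximation of the original
  classifier.
- No HDF5/loom input, no on-disk matrices: datasets are dense in
  memory, which is fine at desk scale and for the sparse-triplet sizes
  the reader targets.
- Normalization method selection, imputation and embedding computation
  are upstream concerns; the package consumes their outputs.
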