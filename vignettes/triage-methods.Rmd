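---
title: "Cost-sensitive triage of imbalanced bioassays: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive triage of imbalanced bioassays: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-throughput single-concentration screens are extremely imbalanced: a
phosphatase inhibition screen may label well under 1% of several hundred
thousand compounds as active (readout: % inhibition at a fixed
concentration, thresholded at 40%). A classifier trained naively on such
data reaches excellent accuracy by predicting "inactive" everywhere and is
useless for triage. This package implements a complete, testable funnel for
that setting:

1. activity labelling at the inclusive 40% inhibition threshold
   (active = score 20, inactive = score 0);
2. 2D descriptors in three families (below), then removal of near-constant
   columns;
3. correlation-based feature-subset selection (CFS) under best-first search;
4. cost-sensitive classification with three learner families, with the
   false-negative cost escalated until the cross-validated false-positive
   rate reaches a 20% ceiling;
5. confusion-matrix/G-mean/ROC evaluation, multi-model consensus;
6. SMARTS structural-alert filtering (five alert families) and the Lipinski
   rule of five;
7. substructure-fragment enrichment between actives and inactives.

A synthetic-library generator with planted, substructure-driven signal makes
every stage testable without external data.

```{r, eval = FALSE}
library(BioassayTriage)
cfg <- runConfig(
  synthetic = librarySpec(2000, active_fraction = 0.05,
                          enriched_fragments = c("Carboxylic acid" = 8),
                          seed = 1),
  seed = 1)
res <- runPipeline(cfg)
```

# The synthetic-library generator

The generator is first-class code, not a fixture. Structures are assembled
from a bundled grammar of 21 drug-like scaffolds (benzene, pyridine,
piperazine, indole, ...) and 36 substituents (methyl through nitrate ester
and sodium carboxylate), so every emitted SMILES is valid by construction
and the fragment content of the library is known.

Activity is generated on the logit scale. Each compound receives a latent
propensity

$$\eta_i = \mu_0 + \sum_f \log(m_f)\, x_{if} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \tau^2),$$

where $x_{if}$ indicates carriage of enriched fragment $f$ (detected by
SMARTS matching against the bundled dictionary, not by bookkeeping during
assembly) and $m_f \ge 1$ is the fragment's odds multiplier. The readout is

$$y_i = 100\,\mathrm{sigmoid}(\eta_i) + e_i, \qquad e_i \sim N(0,
  \sigma^2),$$

clipped to $[-20, 120]$ — negative and >100% readouts occur in real plates.
The baseline $\mu_0$ is calibrated by root finding so that the *expected*
fraction of compounds clearing the 40% threshold equals the requested
`active_fraction`; with `noise_sd = 0` the baseline is placed between order
statistics so the count is hit exactly. If the requested fraction is below
the noise floor, the baseline is clamped with a warning.

Parameter defaults and rationale:

* `active_fraction = 0.0025` mirrors the ~1:400 imbalance of a real
  phosphatase screen; desk-scale tests use 5–10% so that every CV fold holds
  enough actives at n of a few hundred.
* `noise_sd = 5` percentage points: plate-level readout noise that makes the
  40% threshold meaningfully fuzzy without drowning the signal.
* `latent_sd = 2` on the logit scale: compounds of the same structural class
  differ in potency; this also smooths the calibration problem, which would
  otherwise be a step function over a handful of distinct fragment offsets.
* enrichment multipliers of 8 are "strong" signal; the parameter-recovery
  tests use that value, and weaker multipliers degrade gracefully.

What the generator deliberately does **not** emulate: the chemical diversity
of a real vendor library (structures come from a closed grammar), realistic
structure–activity landscapes (activity depends only on fragment carriage
plus noise), or assay artefacts such as autofluorescence. Passing tests
therefore demonstrate that the machinery recovers planted signal under known
conditions — not that these models would rank a real screening deck well.

# Descriptors

179 descriptors in three families, mirroring the classic
fingerprint/Burden/property split of 2D screening descriptors:

* **147 pharmacophore-pair bits.** Six atom features (H-bond donor,
  acceptor, aromatic, hydrophobic, positive, negative) are assigned by
  bundled SMARTS definitions (`inst/extdata/pharmacophore_features.tsv`);
  pairs of features are binned by topological (bond-count) distance into
  {1–2, 3–4, 5–6, 7+}. 21 unordered pairs × 4 bins = 84 bits, plus 6 × 10
  cumulative count bits and 3 composite bits. The bin edges and bit order
  are fixed by `pharmacophoreSchema()` and versioned with the package, so
  fingerprints are stable across releases.
* **24 Burden (BCUT-style) eigenvalues.** The Burden matrix has the atomic
  property on the diagonal and 0.1 × bond order for bonded pairs (aromatic
  bonds count 1.5), 0.001 for non-bonded pairs, following the classical
  convention. Non-bonded coupling applies within a connected component
  only, so a salt's spectrum is exactly the union of its components'
  spectra. Three weightings — atomic mass, Gasteiger partial charge,
  atomic polarizability (bundled element table) — each contribute the 4
  largest and 4 smallest eigenvalues. Molecules with fewer heavy atoms than
  slots replicate their extreme eigenvalues (single atoms warn).
* **8 properties:** MW, logP, H-bond donors/acceptors (counting heavy
  atoms, so water has one donor), rotatable bonds (all acyclic single
  heavy-atom bonds, terminal rotors included — so propane has two and
  cyclopropane none), TPSA, heavy-atom count, formal charge.

Chemistry (SMILES parsing, aromaticity, substructure matching, Gasteiger
charges, logP/TPSA) is delegated to OpenBabel through ChemmineR/ChemmineOB;
the descriptor definitions themselves are this package's own and are
intentionally open re-specifications of the same *type and cardinality* as
the classic proprietary tools — bit-level compatibility with any particular
tool is a non-goal, and downstream stages depend only on the
(binary, continuous) schema.

`removeUseless()` drops a column when its most common value covers more than
`max_identical_fraction = 0.99` of rows; constants are the fraction-1
special case. The operation is idempotent.

# Feature selection

CFS merit of a subset $S$ with $k$ features:

$$\mathrm{merit}(S) = \frac{k\,\overline{r_{cf}}}
  {\sqrt{k + k(k-1)\,\overline{r_{ff}}}},$$

with feature–class and feature–feature correlations measured by symmetric
uncertainty $2I(x;y)/(H(x)+H(y))$ on discretized attributes
(equal-frequency, at most 10 bins; deterministic and simple — MDL binning is
out of scope). Note the formula's fixed point: a perfectly redundant
duplicate ($r_{ff} = 1$, $k = 2$) collapses the merit back to $r_{cf}$ —
redundancy is never rewarded, but a pure duplicate is not strictly
penalized either.

Best-first search keeps a priority queue of evaluated subsets, expands the
best unexpanded one by single additions (forward), deletions (backward) or
both, and stops after `stale_limit = 5` consecutive expansions without
improving the global best (the cited toolkit default). Ties break
lexicographically on the sorted column-name list, making the search fully
deterministic; `stale_limit = 0` degenerates to a single expansion. On
tables of up to 12 features the search matches exhaustive enumeration on at
least 95 of 100 random tables (it is a heuristic; the miss rate is real but
small).

# Cost-sensitive classification

All three families receive cost sensitivity the same way: every active
training row carries instance weight $c_{FN}$, every inactive row weight 1.
(The alternative — minimum-expected-cost prediction — is not used; instance
reweighting applies uniformly to all three learners.)

* `naive_bayes` is implemented natively: class priors from weighted counts,
  Bernoulli likelihoods with Laplace $\alpha = 1$ for binary columns,
  Gaussian likelihoods with weighted MLE variance for continuous ones.
  Weighting with integer $c_{FN}$ is *exactly* equivalent to replicating
  each active row $c_{FN}$ times (tested).
* `random_forest` binds to ranger (200 trees, single-threaded for
  determinism) with `case.weights`.
* `svm_smo_like` is a linear-kernel SVM (e1071/libsvm) with class weights
  and a logistic calibration fitted to the decision values for scores;
  features are standardized internally. The linear kernel plus logistic
  scores mirror an SMO configuration with a degree-1 polynomial kernel and
  logistic output models.

`tuneFnCost()` evaluates the cross-validated FP rate $FP/(FP+TN)$ over an
escalating schedule — geometric doubling from 1, then bisection to a
resolution of one cost unit — and returns the largest integer cost whose CV
FP rate stays at or below the ceiling (default 20%). Two boundary rules:
if the FP rate exceeds the ceiling already at cost 1, cost 1 is returned
with a warning flag; if cost 1 leaves no false negatives at all (separable
data), escalation stops immediately, since raising the cost cannot change
the solution. Tuning is done on pooled CV counts (whether to tune per fold
is genuinely open; pooled tuning is simpler and uses all folds' errors).

# Evaluation

Sensitivity, specificity and accuracy are the usual confusion-matrix
ratios; an empty margin yields `NA`, never 0. The G-mean is
$\sqrt{Sn \cdot Sp}$ — the *geometric* mean, which is what published
G-mean values in this literature actually correspond to (e.g. $Sn = 0.52$,
$Sp = 0.798$ gives 0.64), even where the formula is typeset as a bare
product. Percentages are reported to one decimal with round-half-even.

AUC is computed by midrank Mann–Whitney, identical to trapezoidal
integration of the ROC curve with ties counted ½; the test suite checks it
against an exhaustive pairwise-concordance oracle and against pROC.

Cross-validation is stratified by class — at sub-percent prevalence
unstratified folds would regularly contain zero actives — and fold
assignment is a deterministic function of the seed. Reports include both
pooled and per-fold confusion matrices.

Consensus prediction is the plain intersection of per-model active sets.

# Structural filtering and fragments

The five bundled alert sets (PAINS, Glaxo, Oprea, Pfizer-LINT and
ALARM-NMR style) are small demonstration subsets covering each family's
canonical chemotypes; the full proprietary lists can be loaded from
user-supplied `name<TAB>SMARTS` files. A compound fails a set if any
pattern matches; per-set percentages are computed over **all** input
compounds (so they sum to more than 100% across sets), and the overall pass
list requires matching nothing anywhere. Lipinski violations use the
canonical rule-of-five thresholds with strict inequalities.

Fragment enrichment uses the class-frequency ratio

$$\mathrm{freq} = \frac{N_{\mathrm{fragment,class}} \cdot N_{\mathrm{total}}}
 {N_{\mathrm{fragment,total}} \cdot N_{\mathrm{class}}},$$

which is 1 for a fragment distributed like the library as a whole and obeys
the conservation identity $\sum_c (N_c/N)\,\mathrm{freq}_c = 1$ (tested on
every generated library). Significance is a two-sided Fisher exact test on
the 2×2 presence × class table — the natural exact choice for sparse
fragment counts; the published analyses this mirrors state only "p < 0.01"
with no named test or correction, so no multiple-testing correction is
applied by default and Benjamini–Hochberg is available behind a flag. The
bundled dictionary is a 42-entry subset of a SubFP-style named-fragment
dictionary; `Salt` uses a documented `&&` conjunction of SMARTS because a
single SMARTS cannot span disconnected components.

# Pipeline, determinism, problem sizes

`runPipeline()` executes the stages in the order above and writes a
manifest with the seed, input hashes, per-stage counts and chosen costs;
re-running an identical configuration reproduces identical outputs. Whether
SMARTS filtering precedes or follows consensus differs between published
workflows; both orders are supported
(`consensus_before_filters`). Docking and molecular-dynamics follow-up are
out of scope — the funnel ends by exporting the ranked pass list as
SMILES for external tools.

All randomness flows from a single integer seed: library assembly, CV fold
assignment and the stochastic learners (sub-seeds are derived
arithmetically and kept inside 32-bit range). Molecule handles are
session-local external pointers; persist SMILES, not objects, and use
`rebuildMols()` after reloading.

The shipped test-suite and acceptance problem sizes (libraries of 300–2,000
compounds, 4–12 feature tables for the exhaustive-search comparisons,
≤200-row ROC oracles) were chosen so the whole suite exercises every stage
in well under an hour on one CPU; they are desk-scale stand-ins for the
hundreds of thousands of compounds in a production screen, and the
imbalance used at desk scale (5–10%) is far milder than production
(0.25%), where stratification and cost escalation matter even more.

# Known limitations

* Descriptors are 2D only; no conformers, no 3D pharmacophores.
* The SMO analogue is a linear SVM with logistic calibration, not a
  re-implementation of SMO's working-set algorithm.
* Alert lists are demonstration subsets; screening decisions should load
  the full curated lists.
* Fisher p-values are unadjusted by default (by design, see above).
* The generator's activity model is fragment-additive on the logit scale;
  it cannot emulate activity cliffs or scaffold-specific SAR.
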