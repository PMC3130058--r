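---
title: "Predicting transcription-factor interactions from primary sequence: models and methods"
author: "TFIpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transcription-factor interactions from primary sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TFIpred)
```

# The problem

Transcription factors (TFs) regulate transcription initiation largely
through physical interactions with each other: regulatory complexes form in
the nucleus, and knowing which TF pairs can interact is central to
understanding combinatorial gene regulation. Experimentally confirmed TF–TF
interactions are scarce, and the usual tricks of protein–protein interaction
(PPI) prediction do not transfer well: TFs all live in the same compartment
(so cellular localisation cannot separate negatives from positives), and TF
families are full of paralogues with very similar sequences (so naive
cross-validation is easily biased by redundancy).

TFIpred implements a deliberately simple predictor that uses primary
sequence only. A TF pair is represented by a fixed-length vector of
physicochemical summary statistics, classified by quadratic discriminant
analysis (QDA), with the feature subset chosen by wrapper forward selection
under preserved cross-validation folds.

# Feature representation

## Property scales

Per-residue physicochemical scales are read from an AAIndex1 flat file
(`parseAAIndex1()`). Only scales defined for all 20 standard residues are
used (`filterComplete()`); values are kept at full printed precision and
never normalised — QDA is equivariant under affine maps of the feature
space, so per-scale rescaling cannot change a prediction. The residue order
of the `I` block is parsed from its header line rather than assumed, which
guards against dialect drift between AAIndex releases.

## Segmentation and means

A sequence of length $L$ is cut into an N-terminal, a middle and a
C-terminal segment covering roughly 20/60/20 of its length. Both terminal
segments take exactly $t = \lfloor 0.2L \rfloor$ residues and the middle
keeps the remainder: the percentages in the rule are the only constraint the
design inherits, and this rounding keeps the two termini equal-sized and
never steals terminal residues. Sequences shorter than 5 residues are
rejected (a terminal segment would be empty). For each segment and each
scale $p$ the feature is the arithmetic mean of $p$ over the segment's
residues; `X` (unknown) and `U` (selenocysteine) are excluded from both the
numerator and the denominator, and a segment consisting only of such
residues is an error rather than a silent zero. Other ambiguity codes (B, Z,
J, O) are rejected at parse time: silently mapping them to something would
change feature values without warning.

With $P$ scales a TF is a vector of $3P$ values (segment-major: N, middle,
C), and a pair is the concatenation of its two member vectors, $6P$ values.
With the classical 531 complete AAIndex scales this gives 1,593 features per
TF and 3,186 per pair. The lengths never depend on sequence length.

## Pair symmetry

An unordered pair must have exactly one representation, so the member with
the smaller molecular weight always comes first. Weight is computed from
standard average residue masses plus one water (18.0153 Da); `X` contributes
zero and `U` the selenocysteine mass. Exact ties (e.g. identical sequences)
fall back to the lexicographically smaller identifier. Only the *ordering*
matters downstream, so the mass convention is recorded in every fitted model
(`massConvention`) and checked at prediction time. `featurizePair(a, b)` and
`featurizePair(b, a)` are bitwise identical by construction.

# Training data

## Positive pairs

Known TF–TF interactions arrive as a pair table with optional PSI-MI
evidence codes. Only types that can support complex formation are kept
(`filterByMIType()`; defaults MI:0195 covalent binding, MI:0407 direct
interaction, MI:0915 physical association). Records without an evidence code
are dropped when the filter is active.

## Negative classes

Negatives are sampled as random TF pairs in three classes that differ in how
much interaction evidence exists for the members: *absolute* (neither TF has
any known partner), *partial* (exactly one does) and *ppi* (both do, but not
with each other). The classes are structurally disjoint, self-pairs are
never drawn, and no drawn pair may occur among the known positives.
`generateNegatives()` enumerates all eligible pairs and samples without
replacement, so a request beyond capacity fails with the achievable maximum
rather than looping. Pair records are stored with the lexicographically
smaller id first — a deterministic record-level canonical form; the
molecular-weight ordering that matters for features is applied at
featurization, so record order never affects a feature vector.

## Redundancy filtering

Because similar TFs tend to bind the same partners, near-duplicate positive
interactions inflate cross-validation estimates. `redundancyFilter()`
aligns every pair of TFs that share at least one positive partner
(local alignment, BLOSUM62, affine gaps open 11 / extend 1 — the BLAST
protein defaults, via `Biostrings::pairwiseAlignment`), and where identity
(identical aligned positions / alignment length) exceeds 0.8 it keeps, for
each shared partner, only the interaction whose similar member has the
lexicographically smaller id. The keep rule makes the filter deterministic,
idempotent and independent of input record order; every removal is reported
with its cause (identity and common partner) in an audit table.

# Classification

`fitQDA()` fits one Gaussian per class: sample mean, unbiased sample
covariance, empirical priors. Scores are
$-\tfrac12\log\det\Sigma_k - \tfrac12 (x-\mu_k)^\top \Sigma_k^{-1}(x-\mu_k)
+ \log\pi_k$, evaluated through Cholesky factors (triangular solves, no
explicit inverse); they match direct log-density evaluation to machine
precision, and prediction is the per-row argmax with exact ties broken
toward the earlier class label.

Cross-validation folds with many features flirt with singular covariances,
so every class covariance receives the same small relative ridge,
`ridge * tr(Sigma_pooled)/d` on the diagonal (default `ridge = 1e-6`). The
scale is shared across classes on purpose: a per-class scale would make the
large-ridge limit prefer whichever class has the smaller spread, whereas
with a shared scale the rule degrades gracefully towards
nearest-class-mean-with-prior. A covariance that is still not positive
definite (including numerically, via near-zero Cholesky pivots) raises an
error naming the class; during wrapper search such candidate fits score 0
and are logged instead of aborting the search.

# Feature selection

`makeStratifiedFolds()` deals each class's shuffled samples round-robin
across k folds, rotating the starting fold between classes so fold sizes
differ by at most one per class *and* overall. The assignment is a pure
function of (labels, k, seed) and is fingerprinted; the fingerprint is
stamped into every selection step, asserting that all candidates at all
steps were compared on the identical partition.

`forwardSelect()` is a plain greedy wrapper: at each step every unselected
candidate column is appended to the current list, scored by k-fold
cross-validated accuracy (F-measure available as an alternative criterion),
and the best mean is kept, ties breaking toward the lowest column index.
The loop supports a restricted candidate pool and a step cap (the reference
protocol stops at 150), since step $t$ costs $(|pool|-t)$ cross-validated
fits. `bestSubset()` returns the shortest prefix achieving the maximal mean
criterion. Undefined metric values (zero denominators) are carried as `NA`
and excluded from cross-fold means with a warning — coercing them to 0
would silently bias selection.

The full pipeline (`tfiPipeline()`) splits the labelled pairs into k + 1
stratified groups, runs selection with k-fold cross-validation on k of
them, refits on all k groups with the best subset, and reports
Table-style per-fold metrics plus an evaluation on the held-out
(k + 1)-th group, which never participated in selection.

# The synthetic study generator

Real training data for this problem are a snapshot of interaction databases
that cannot be redistributed or reconstructed, so the package carries its
own test bed. `genInteractionStudy()` emits exactly the artifact's input
formats (FASTA, AAIndex1, labelled pair TSV, plus a ground-truth JSON) with
a known, planted class signal:

* **Signal is planted at the composition level**, not by emitting feature
  vectors, so the whole featurization path is exercised. A designated
  subset of scales is made mutually orthogonal (Gram–Schmidt on their
  centred value vectors) and all other scales are projected out of their
  span. Members of positive pairs draw residues from a baseline composition
  shifted additively along those orthonormal directions; the shift lies in
  the informative span, sums to zero, and is therefore *exactly* null for
  every non-informative scale.
* **Effect size is calibrated.** The shift magnitude per informative scale
  is chosen so that the mid-segment pair feature moves by `effectSize`
  within-class standard deviations, where the sd is simulated from baseline
  compositions and includes the multinomial sampling noise of a typical
  middle segment. The shorter terminal segments are noisier and carry a
  somewhat smaller standardized shift. An effect the composition simplex
  cannot accommodate (frequencies would go negative) raises a feasibility
  error suggesting a smaller effect size.
* **Study conditions.** Defaults: 20 scales of which 5 informative, 200
  positive pairs, 67 negatives per class (≈400 pairs total), sequence
  lengths uniform in 600–1400 residues — typical of human TF chains, and
  long enough that a 2–3 sd composition shift stays inside the simplex.
  Baseline compositions are softmax of N(0, 0.1) logits mixed with a
  uniform floor; a 0.2% X/U sprinkle exercises the averaging skip rule.
* **Negative structure without signal leakage.** Positive pairs are drawn
  from a dedicated pool of signal-composition TFs, each used in one pair.
  Negatives come from a separate baseline-composition pool, half of which
  is flagged as interacting through decoy (non-TF) partners, so all three
  negative classes are populated while no negative pair carries planted
  signal. This mirrors the fact that training positives are a filtered
  subset of all known interactions.
* **Determinism.** All randomness flows from one root seed through named
  substreams (properties, compositions, sequences, pairing, negatives), so
  identical specifications are bitwise-identical.

What passing tests on this generator do **not** show: real TF families are
phylogenetically correlated, share domain architectures, and the true
signal (if any) is not a clean composition shift confined to orthogonal
scales; nor do real negatives avoid the positives' composition statistics.
The generator validates the machinery — featurization, canonicalisation,
fold preservation, selection, evaluation — not the biological difficulty of
the task.

# Numerical and design choices

* Segment rounding, the minimum length 5, and the rejection of B/Z/J/O are
  package decisions where the underlying protocol specifies only
  percentages and the X/U rule.
* Molecular weight uses average (not monoisotopic) masses; the convention
  tag travels with models, and `runPredict()` refuses a property table
  whose accessions *or values* (checked through a scalar fingerprint in the
  feature annotation) differ from those the model was fit on.
* Identity uses the local-alignment definition (matches / alignment length,
  including gap positions), the quantity BLAST reports; the engine is
  `Biostrings::pairwiseAlignment` with BLOSUM62 and gap costs 11 + k. An
  independent Smith–Waterman/Gotoh implementation in the test suite checks
  scores on random strings, and identities where the optimal alignment is
  unique (co-optimal alignments may legitimately differ in identity between
  engines).
* Tie-breaks are deterministic everywhere: earlier class label in
  prediction, lowest column index in selection, shortest prefix in
  `bestSubset()`, lexicographic keeper in the redundancy filter.
* Test and acceptance problem sizes (≈400 pairs, 50-column candidate
  pools, 10 selection steps, 10 + 1 groups) are chosen so the full wrapper
  loop runs in seconds at desk scale while keeping every contract
  observable; the 150-step cap and the 3,186-column space remain available
  for real runs.

# Known limitations

* The wrapper optimises cross-validated accuracy by default; with heavily
  imbalanced classes F-measure is the better criterion and is available,
  but no cost-sensitive variant is provided.
* QDA with hard labels only: no posterior calibration, no ROC analysis.
* The redundancy filter compares TFs pairwise; a cluster-level filter
  (e.g. CD-HIT-style) would scale better beyond a few thousand TFs.
* `generateNegatives()` enumerates eligible pairs, which is exact but
  quadratic in the universe size — comfortable to a few thousand TFs,
  not to proteome scale.
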