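---
title: "Benchmarking QSAR interpretation with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking QSAR interpretation with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

QSAR interpretation methods assign a contribution to each atom (or
fragment) of a molecule.  Whether those contributions are *right* cannot
be decided on real data, where the causal patterns are unknown.
`interpbench` therefore builds datasets whose activities are generated by
a known rule, giving every heavy atom a defined expected contribution,
and scores interpretation output against that ground truth.

The interpretation procedure itself is structural and model-agnostic:
for a trained predictor $f$ and molecule $M$, the contribution of an
atom set $S$ is

$$c(S) = f(M) - f(M \setminus S),$$

where $M \setminus S$ replaces the atoms of $S$ by dummy atoms (atomic
number 0) with all bonds preserved.  For binary classifiers $f$ is the
active-class probability, so $c \in [-1, 1]$.  The mechanism that makes
the masked prediction meaningful is vocabulary projection: descriptors
are vectorized against the feature universe frozen from the training
set, and the new dummy-atom descriptors created by masking never occur
there, so they are dropped and the model predicts from the remaining
substructure.  Counted fingerprints are kept *unfolded* (sparse keyed
counts) precisely so this drop is exact; binary fingerprints are folded
to 2048 bits, where a dummy feature can in principle collide with a real
bit — a known artifact of the folded representation that we keep because
the folded form is part of the benchmark design.

Any callable `(record, masked_atom_indices) -> number` satisfies the
predictor contract, so schemes that mask differently (e.g. graph
networks that delete a row of the atom-feature matrix and adjust the
connectivity table) plug into the same metrics without being implemented
here.

## The six labeling rules

Three complexity levels: simple additive atomic patterns (`N`,
`N_minus_O`, `N_plus_O`), additive local context (`amide_reg`,
`amide_class`, SMARTS `NC=O`), and a whole-molecule 3D property
(`pharmacophore`).  Details that the rules fix:

- `N_plus_O` admits only molecules with strictly equal N and O counts —
  the two patterns are perfectly correlated by construction, which is
  the point of the task (does the model split credit or prioritize one
  pattern?).  Ineligible molecules get `NA` activity.
- Amide matches are unique atom-index sets; overlapping matches (imides)
  each count toward the activity, and every atom in any match has
  expected contribution 1, because removing it destroys the pattern.
- Pharmacophore actives must show *exactly one* donor–acceptor pair at
  9–10 Å, the same two atoms in every conformer where the pattern
  occurs; molecules with several distinct pairs are `excluded` from the
  dataset to avoid ambiguous truth.  Distances use heavy-atom
  coordinates (the rule's feature points are the atoms themselves), the
  window is closed on both ends, pairs are unordered, and an amphoteric
  atom may not pair with itself.

H-bond donors and acceptors come from a fixed SMARTS table shipped with
the package (`extdata/hbond_smarts.tsv`): donors are any N–H or O–H
(amide N–H included); acceptors are N/O excluding amide nitrogen, nitro
oxygens/nitrogen, pyrrole-type aromatic N–H and quaternary N.  The table
replaces an external feature-definition dependency and is versioned so
the labeling is reproducible from the artifact alone.

Conformers are generated by distance-geometry embedding with
experimental-torsion terms (ETKDGv3), up to 25 per molecule, fixed seed,
no energy minimization — minimization would add a force-field dependency
without changing what the task tests.  Molecules that fail embedding are
flagged and excluded from the pharmacophore pool rather than raising.

## Dataset construction

Regression pools are sampled *without replacement* with weight
proportional to $\varphi((a - \mu)/\sigma)$ divided by the empirical
density of the molecule's activity bin (Freedman–Diaconis histogram), so
the drawn activities approximate a normal shape even from skewed pools.
The target $\mu, \sigma$ default to the pool median and half the
interquartile range — defaults chosen to keep every weight finite for
any pool; the generating procedure in the source work states the goal
distribution but not the weighting scheme, so the histogram reweighting
is this package's documented interpretation.  Classification datasets
draw equal numbers of actives and inactives uniformly.  Splits are
70/30; classification splits are stratified by class so the designed
balance survives in both halves (a deliberate, documented strengthening
of "random split").

`audit_bias()` reports Pearson correlations between the true-pattern
count and common element counts; `sample_regression_min_bias()` repeats
the draw over several seeds and keeps the dataset with the lowest
maximum |r|, mirroring how the benchmark datasets were originally
curated.  Zero-variance columns yield `NA`, never an error.

## The fixture pool

Tests and examples use `generate_fixture_pool()`, a deterministic
stand-in for a large public compound collection: molecules are assembled
from a fixed grammar of chain-concatenable drug-like blocks (alkyl
chains, benzene/pyridine/cyclohexane/THF rings, halogens, hydroxyl and
amino branches, amide linkers), standardized, deduplicated and filtered
to MW ≤ 500.  Three profiles reweight the grammar: `general`,
`amide_rich` (0, 1 and ≥ 2 amide matches all well represented) and
`donor_acceptor_rich` (more N/O features at varying separations).  The
pool is a pure function of `(n, seed, profile)`.

What the generator does *not* emulate: the scaffold diversity,
stereochemistry, charge states and tautomerism of real screening
collections, and any property–scaffold correlations found in curated
bioactivity data.  A green benchmark on fixture pools therefore
establishes the *machinery* — labeling, masking, metrics, the
predictivity–interpretability relationship in a controlled world — not
performance on ChEMBL-scale chemistry.

## Numerical choices

- **Atom indexing** is frozen at parse time from the canonical-SMILES
  atom order of the toolkit; truths, masks and contributions all refer
  to it.  Re-parsing the stored SMILES with the same toolkit version
  reproduces the indexing.
- **Q²** uses the standard form $1 - \sum(\hat y - y)^2 / \sum(y -
  \bar y)^2$.
- **AUC ties** use midrank (each tied positive–negative pair counts
  0.5).  **top-n ties** are broken deterministically by atom index
  (contribution descending, index ascending); an optional
  `tie_mode = "expected"` averages over random tie orders via the
  hypergeometric mean within the tied block.  The deterministic default
  makes reports byte-reproducible; the expected mode is fairer when
  many atoms tie exactly.
- **Contribution RMSE** includes molecules without true patterns (their
  expected vector is all zeros); only the AUC excludes pattern-free
  molecules.
- **Fragment enumeration** breaks only acyclic single bonds between
  heavy atoms (never ring, double, triple or aromatic bonds), up to
  three at a time; fragments are capped at 7 atoms and at 40 % of the
  molecule's heavy atoms, the bound evaluated in exact arithmetic (a
  5-atom molecule admits size-2 fragments).  Ring systems small enough
  to pass the caps are legitimate fragments, since rings are never
  broken.  Internally the enumeration walks connected subgraphs (ESU)
  and keeps those whose boundary consists of 1–3 eligible bonds, which
  is provably the same set as brute-force bond-subset deletion — the
  test suite checks exact set equality against an independent
  brute-force enumerator.
- **Failed masked predictions** are recorded as `NA` with a warning and
  excluded from metrics with a count, never imputed.
- **Masked-prediction caching:** the batched dataset path computes each
  masked form exactly once per call, so no cross-call cache is kept.

## Model harness

RF, GBM and SVM (RBF) and PLS come from the scikit-learn backend; grids
are documented defaults (RF trees {250, 500}; GBM trees {100, 300} at
depth 3, learning rate 0.1; SVM C {1, 10, 100}; PLS components
{2, 8, 16, 32}, capped by the data), searched by five-fold
cross-validation scored by RMSE (regression) or balanced accuracy
(classification), with the chosen point refit on the full training set.
The source work names the search but not the grids, so these are this
package's own, deliberately small, defaults.  PLS is regression-only
(the backend library provides no PLS classifier and the benchmark
reports PLS only on regression tasks).  All randomized learners receive
the pipeline seed; every reported number is reproducible bit-for-bit
from `(config, seed)`.

The 1-NN baseline (Tanimoto on binary fingerprints, Dice on counts) is
implemented in R and flags trivially modelable datasets: if a nearest
neighbor already predicts well, the dataset is biased toward lookup
rather than pattern learning.

Interpretation is evaluated on the **training set** by default —
prediction error is smallest there, so contribution error reflects the
interpretation method rather than model extrapolation.  `interpret_on =
"test"` is available explicitly.

## Known limitations

- On easy classification tasks boosted models can saturate the
  active-class probability to exactly 1.0, at which point removing one
  of several identical patterns leaves an exactly zero delta: every
  atom ties, per-molecule AUC⁺ collapses to 0.5 and top-n to the
  tie-break baseline $n_i/A$.  This is the known multi-pattern weakness
  of masking-based interpretation in its most extreme form, and on
  fixture pools it can break the expected monotone decay of stratified
  top-n with pattern count (the count-2 stratum can score below
  count-3, because the tie baseline grows with the number of true
  atoms).
- The pharmacophore task yields few actives from random fixture pools
  (roughly one in ten molecules); building a balanced classification
  dataset needs a large pool, and model performance on this task is
  moderate by design.
- Binary fingerprints can hash dummy features onto real bits (see
  above); counted fingerprints are immune.
- No tautomer canonicalization in standardization; duplicates are
  detected by canonical SMILES of the neutralized largest fragment.
- The harness trains no graph neural networks; they participate only
  through the generic masked-prediction contract.
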