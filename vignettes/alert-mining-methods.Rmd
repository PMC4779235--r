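---
title: "Mining structural alerts from bioactivity data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structural alerts from bioactivity data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alertminer)
```

## The problem

A structural alert is a chemical fragment whose presence in a compound is
statistically associated with a response — toxicity in an assay, inhibition of
an enzyme, permeation of a barrier. Screening candidates against alerts is a
cheap first filter in drug discovery. `alertminer` derives alerts directly
from a labelled compound collection, with no curated rule base, for two kinds
of label: dichotomous (active/inactive) and continuous (pIC50-like).

## Substructures: circular atom environments

Every substructure considered is an *atom environment*: the subgraph within
`r` bonds of a root heavy atom, for user-chosen bond radii. Radius 0 is the
atom itself; radius 1 adds its neighbours and connecting bonds; and so on. An
environment of radius `r` only exists at a root whose reachable graph distance
is at least `r`, so a lone heavy atom has only its radius-0 environment.

Identifiers are produced the way circular fingerprints produce them: each atom
starts from an invariant hashed from (element, heavy-atom degree, hydrogen
count, formal charge, ring membership), and each iteration re-hashes the
atom's previous invariant together with the sorted (bond order, neighbour
invariant) pairs. The invariant after round `r` identifies the radius-`r`
environment. The hash is 31-bit integer polynomial arithmetic, exact in
doubles, so identifiers are reproducible across machines. Two consequences
worth knowing:

- *Collisions are possible and accepted.* Distinct environments mapping to one
  identifier are treated as the same substructure, exactly as a hashed
  fingerprint would treat them. At 31 bits and the few thousand distinct
  environments of a typical training set, collisions are rare.
- *Identifiers are not portable to other toolkits.* They are stable within
  `alertminer`, which is what the frozen training basis and the alert scan
  require.

Hydrogens are kept implicit: parsing folds explicit hydrogens into a per-atom
count, which enters the initial invariant. This makes a CH2 and a CH3 carbon
distinct at radius 0, which is what chemical intuition wants, without the cost
of explicit-hydrogen graphs. Counting is presence-based where the statistics
need compound counts (a molecule with three nitro groups is *one* compound
carrying the nitro environment) and occurrence-based where fingerprints need
counts (that molecule has count 3 in the nitro column).

Molecule I/O (SMILES, SDF V2000, MOL2) and all SMILES canonicalisation go
through ChemmineR/ChemmineOB (OpenBabel). Parse failures are never fatal: they
are logged with their original record position so an activity vector supplied
in file order can be realigned. One OpenBabel-related subtlety: aromatic rings
arrive kekulized, so aromatic carbons carry alternating single/double bonds.
Because every atom of a symmetric ring sees the same sorted bond-order
multiset, symmetry still collapses correctly (benzene has exactly one
identifier per radius).

## Categorical alerts

With `n` training compounds, `m` active, a substructure in `n_S` compounds of
which `m_S_act` are active, the score is the binomial upper tail
`P(X >= m_S_act)` for `X ~ Binomial(n_S, m/n)`, computed with R's `pbinom`
(verified in the test suite against term-by-term summation to below 1e-12
relative error over all `n_S <= 25`).

The scan over a test set follows the published workflow for this statistic:

1. For each test molecule in input order, for each heavy atom, process that
   atom's environments in ascending radius.
2. Skip identifiers absent from the training index or already processed.
3. Gate before testing: `n_S >= threshold_nb_substructures` (default 5) and
   `m_S_act / n_S >= threshold_frequency` (no default; it expresses a
   domain-specific judgement about how "active-dominated" a fragment must be,
   so the caller must choose it).
4. Compute the P value; if significant, flag the identifier as an alert and
   suppress the larger-radius environments rooted at the same atom — they
   describe supersets of an already-flagged fragment and would only restate
   the same signal.

Gate comparisons are **inclusive** (`>=`): the method's own worked reading —
"if the threshold is set to 5 and only 4 compounds present the substructure,
the P value is not calculated" — forces `>=`, and both gates are read the same
way. Substructures failing a gate are also marked processed: their training
counts can never change, so re-evaluating them at later molecules could only
repeat the same skip (an optimisation with identical output).

**Multiplicity.** The Bonferroni multiplier is the number of P values actually
computed in the run, which is only known when the scan ends. The scan-time
suppression decision therefore uses raw P values against alpha, and the
reported significance flag uses the corrected values. A stricter sequential
mode (`scan_correction = "sequential"`, multiplying by the running test count
during the scan) is available for callers who want suppression itself to be
correction-aware; post-scan correction is the default because the final
multiplier is undefined mid-scan. Only enrichment is tested: the statistic is
an upper tail, so fragments *depleted* among actives are never flagged.

## Continuous alerts

For each qualifying substructure the training activities split into A
(compounds with it) and B (the rest) — both defined on the training set. The
Shapiro–Wilk test at alpha = 0.05 (the same level as the main test; the
method statement reuses one level) gates each side:

- both A and B pass → two-tailed independent two-sample *t* test. The *pooled*
  t test is the default reading of "t test for independent samples"; Welch is
  available via `welch = TRUE`.
- otherwise → two-sample two-sided Kolmogorov–Smirnov test with asymptotic
  P values (exact small-sample KS adds nothing at the sample sizes the gates
  admit, and ties from duplicated activity values would forbid it anyway).

Degenerate inputs are handled before the gate: a side with fewer than 3 values
cannot be tested by Shapiro–Wilk and produces a *skip signal* (logged, not a
result); a constant-valued side is treated as non-normal and routed to KS.
Shapiro–Wilk caps its input at 5000 values, so larger sides are judged on a
reproducible seeded subsample of 5000.

Every qualifying distinct substructure of the test set is tested exactly once,
in first-encounter order — there is no smallest-radius suppression here, since
the continuous workflow defines none. The effect size `mean(A) - mean(B)` is
reported in activity units with its direction; with large samples a trivially
small shift can reach significance, so the effect size, not the P value, is
the quantity to judge chemically.

## The synthetic study sets

The generator builds molecules from ~20 built-in drug-like scaffold SMILES,
each ending in an sp3 carbon with a free valence; carriers get the alert
fragment (default: a nitro group, absent from every scaffold) attached there
by direct SMILES concatenation, i.e. a single bond, re-parsed and resampled if
a join is chemically invalid. Labels are exact (`round(p_active * n)`
actives); fragment planting is Bernoulli per molecule given the label, so
conditional carrier frequencies match their targets within binomial sampling
error. Continuous mode draws activity as
`baseline + shift * carrier + Normal(0, noise_sd)`. Everything is driven by
one Mersenne–Twister seed and reproducible across platforms.

Default study conditions used throughout the tests mirror the validation
setting of the method: 200 training molecules, half active, fragment planted
at 0.4 | active and 0.02 | inactive, thresholds (5, 0.05, 0.7) with Bonferroni
for the categorical pipeline; 300 molecules, 20% carriers, shift 1.0, noise sd
0.3, thresholds (support 5, ratio 0.05) for the continuous pipeline. These
sizes keep a 100-replicate Monte-Carlo suite comfortably fast while leaving
the planted signal far from trivial at the gates.

What the fixtures deliberately do *not* emulate: realistic chemical-space
diversity (20 scaffolds, one fragment), activity cliffs, correlated
substructures, assay noise structure, or measurement censoring. Passing the
recovery and calibration suites therefore shows the statistics and the scan
are implemented correctly — it does not certify performance on real screening
collections, where fragment co-occurrence (see Limitations) is the dominant
complication.

## Numerical and design choices

- `pbinom(k - 1, n_S, m/n, lower.tail = FALSE)` for the tail; no naive
  summation in the production path (the summation lives in the tests as the
  independent oracle).
- Bonferroni is explicit `pmin(1, p * k)` with `k` = computed-test count; this
  equals `p.adjust(..., "bonferroni")` and is cross-checked against it.
- Keyed fingerprint columns are sorted by ascending identifier — an arbitrary
  but documented, reproducible order. Projection onto a basis drops
  substructures absent from it (with a summary message): appending novel
  columns would silently change the basis meaning between runs.
- Folding a keyed count matrix by `id mod size` reproduces the directly hashed
  count matrix exactly; binary hashed fingerprints binarize after folding (the
  indicator is the same either way).
- Fragment SMILES for an environment are rendered by extracting the subgraph
  within `r` bonds of the root (bonds reached within `r` steps) and
  canonicalising with OpenBabel; free valences fill with implicit hydrogens.
  The rendering is deterministic for a fixed index.
- Ties among radii at one root cannot occur (radii are distinct per root);
  roots are processed in atom-index order, molecules in input order, making
  the whole scan deterministic.

## Limitations

- Substructure effects are modelled as independent events. A fragment that
  merely co-occurs with a true toxicophore in the training set will be flagged
  too; no conditional or multivariate analysis is attempted.
- Hash collisions merge substructures (rarely, at 31 bits).
- Identifier stability is internal to this package, not exchangeable with
  other fingerprint implementations.
- The categorical statistic tests enrichment only.
- xlsx export requires an external writer package; CSV is the built-in,
  byte-stable output format.
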