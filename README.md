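# alertminer

Automatic derivation of **structural alerts** — substructures statistically
associated with a biological or toxicological response — from categorical
(active/inactive) or continuous (e.g. pIC50, Ki) bioactivity data sets, plus
hashed and unhashed (keyed) circular fingerprints for interpretable QSAR work.

Early toxicity triage routinely screens candidate compounds against known
toxicophores. `alertminer` derives such alerts automatically from data: it
enumerates circular (Morgan/ECFP-style) atom environments of user-chosen bond
radii in a training set, then asks, substructure by substructure, whether the
compounds carrying it respond differently from the rest.

## The statistics

**Categorical data.** For a substructure *S* present in *n_S* of *n* training
compounds, *m* of which are active and *m_S,act* of which are active *and*
carry *S*, the chance of seeing at least *m_S,act* actives among the carriers
if *S* were unrelated to activity is the binomial upper tail

```
P = sum_{i = m_S,act}^{n_S}  C(n_S, i) (m/n)^i (1 - m/n)^(n_S - i)
```

A small *P* marks *S* as a candidate alert. The scan over a test set processes
each heavy atom's environments smallest radius first, requires a minimum
training support (`threshold_nb_substructures`, default 5) and a minimum
active frequency *m_S,act*/*n_S* (`threshold_frequency`, no default) before
computing *P*, suppresses the larger-radius super-environments of a flagged
alert, and applies the Bonferroni correction (multiply by the number of
computed *P* values, clamp at 1) by default.

**Continuous data.** For each substructure the activity values split into
distribution *A* (compounds with *S*) and *B* (compounds without). Shapiro–Wilk
(alpha = 0.05) gates the test choice: both normal → two-tailed independent
two-sample *t* test; otherwise the two-sample Kolmogorov–Smirnov test. The
signed effect size `mean(A) - mean(B)` (in activity units) says whether *S*
increases or decreases activity — and whether the difference is worth caring
about, which a *P* value alone cannot.

**Fingerprints.** The same atom environments feed hashed fingerprints
(position = identifier mod size) and unhashed/keyed fingerprints (one column
per distinct substructure, optionally projected onto a frozen training basis),
in binary or count format, with a catalog mapping every column to a fragment
SMILES.

## Worked example

```r
library(alertminer)

# synthetic study set: 200 molecules, 100 active; a nitro fragment planted in
# ~40% of actives and ~2% of inactives
spec  <- fixture_spec(200, seed = 7, p_frag_given_active = 0.4,
                      p_frag_given_inactive = 0.02)
train <- generate_categorical_set(spec)
index <- label_index(extract_substructure_information(train, radii = 0:2))
cfg   <- categorical_config(threshold_frequency = 0.7, radii = 0:2)
res   <- derive_alerts_categorical(fixture_test_set(spec), index, cfg)
head(res[, c("smiles", "radius", "n_S", "m_S_act", "p_value_corrected", "significant")], 3)
```

```
       smiles radius n_S m_S_act p_value_corrected significant
3         CCN      1  77      76      7.742411e-21        TRUE
2         CCC      1  63      62      1.040834e-16        TRUE
4           N      0  84      77      3.853174e-15        TRUE
```

Reading row 1: 77 training compounds contain this radius-1 environment
(rendered `CCN` — the carbon–nitrogen attachment point of the planted nitro
group), 76 of them active; under the null the chance of that is ~1e-21 even
after multiplying by the number of tests, so it is flagged as an alert.
`depict_substructure()` draws any flagged environment highlighted inside a
molecule that contains it.

The same data flow works from the shell:

```sh
exec/alertminer fixtures --mode categorical --n 200 --seed 7 --out train.smi --labels labels.csv
exec/alertminer categorical --train train.smi --train-labels labels.csv \
    --test test.smi --radii 0,1,2 --min-frequency 0.7 --out alerts.csv
```

## Scope notes

- Substructure effects are treated as independent events; co-occurring
  fragments can confound each other (use large, diverse training sets).
- Enrichment (upper tail) only is tested in the categorical mode; depletion is
  not.
- xlsx export of result tables needs an xlsx writer package (`openxlsx` or
  `writexl`); CSV export is built in and byte-stable.
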