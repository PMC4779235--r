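test_that("binomial tail P value matches term-by-term summation", {
  # frozen spot check: n=100, m=20, n_S=10, m_S_act=8
  # C(10,8) 0.2^8 0.8^2 + C(10,9) 0.2^9 0.8 + 0.2^10 = 7.79264e-05
  expect_equal(binomial_tail_pvalue(100, 20, 10, 8), 7.79264e-05,
               tolerance = 1e-12)
  expect_equal(binomial_tail_pvalue(100, 20, 10, 8),
               binom_tail_oracle(100, 20, 10, 8), tolerance = 1e-13)

  for (nS in c(1, 5, 13)) {
    for (mfrac in c(0.2, 0.5, 0.8)) {
      for (k in 0:nS) {
        expect_equal(binomial_tail_pvalue(100, 100 * mfrac, nS, k),
                     binom_tail_oracle(100, 100 * mfrac, nS, k),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_tail_pvalue(10, 11, 5, 2), "m must")
  expect_error(binomial_tail_pvalue(10, 5, 5, 6), "m_S_act")
})

test_that("degenerate tails and monotonicity behave as probabilities demand", {
  expect_identical(binomial_tail_pvalue(50, 10, 8, 0), 1)
  expect_identical(binomial_tail_pvalue(50, 50, 8, 8), 1)
  for (nS in c(4, 9)) {
    p <- vapply(0:nS, function(k) binomial_tail_pvalue(80, 24, nS, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
  # complement identity in the oracle itself
  for (k in 0:6) {
    expect_equal(binom_tail_oracle(60, 18, 6, k) +
                   binom_lower_oracle(60, 18, 6, k - 1), 1, tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies by the test count and clamps", {
  expect_equal(bonferroni_correct(0.01), 0.01)
  expect_equal(bonferroni_correct(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1.0))
  expect_error(bonferroni_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.02, 0.04, 0.3)
  expect_equal(bonferroni_correct(p), p.adjust(p, method = "bonferroni"))
  # corrected decisions at alpha equal raw decisions at alpha/k off the clamp
  alpha <- 0.05
  expect_equal(bonferroni_correct(p) < alpha, p < alpha / length(p))
})

test_that("raw binomial significance calls are calibrated under the null", {
  set.seed(2024)
  n <- 400; m <- 160; n_S <- 50
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    m_S_act <- rbinom(1, n_S, m / n)
    if (binomial_tail_pvalue(n, m, n_S, m_S_act) < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("config validation enforces required thresholds and ranges", {
  expect_error(categorical_config(radii = 0:2), "threshold_frequency")
  expect_error(categorical_config(threshold_frequency = 0.7), "radii")
  expect_error(categorical_config(0.7, 0:2, threshold_pvalue = 1.5))
  cfg <- categorical_config(0.7, c(2, 0, 1, 1))
  expect_equal(cfg$threshold_nb_substructures, 5)
  expect_equal(cfg$threshold_pvalue, 0.05)
  expect_true(cfg$bonferroni)
  expect_equal(cfg$radii, 0:2)
})

test_that("label_index checks label alignment and counts actives", {
  ms <- molecule_set_from_smiles(c("CCO", "CCN", "CCC"), activities = c(1, 0, 1))
  idx <- extract_substructure_information(ms, 0:1)
  li <- label_index(idx)
  expect_equal(li$m, 2)
  expect_equal(li$active_mask, c(1L, 0L, 1L))
  expect_error(label_index(idx, c(1, 0)), "does not match")
  expect_error(label_index(idx, c(1, 2, 0)), "0/1")
})

test_that("a test molecule sharing nothing with the training index yields no results", {
  train <- molecule_set_from_smiles(rep(c("CCO", "CCN"), 5),
                                    activities = rep(c(1, 0), 5))
  idx <- label_index(extract_substructure_information(train, 0:1))
  test <- molecule_set_from_smiles("S")
  res <- derive_alerts_categorical(test, idx,
                                   categorical_config(0.1, 0:1))
  expect_equal(nrow(res), 0)
})

test_that("planted alerts are recovered and flagged after Bonferroni", {
  spec <- cat_spec(seed = 7)
  train <- generate_categorical_set(spec)
  idx <- label_index(extract_substructure_information(train, 0:2))
  cfg <- categorical_config(threshold_frequency = 0.7, radii = 0:2)
  res <- derive_alerts_categorical(fixture_test_set(spec), idx, cfg)
  planted <- planted_fragment_ids(train, 0:2)
  flagged <- res$identifier[res$significant]
  expect_true(any(flagged %in% planted))
  # the flagged planted substructure has an extreme oracle P value
  hit <- res[res$identifier %in% planted & res$significant, ][1, ]
  expect_lt(binom_tail_oracle(idx$n, idx$m, hit$n_S, hit$m_S_act),
            0.05 / nrow(res))
  # reported counts are consistent with the index
  ent <- idx$entries[[as.character(hit$identifier)]]
  expect_equal(hit$n_S, length(ent))
  expect_equal(hit$m_S_act, sum(idx$active_mask[ent]))
})

test_that("scan invariants: gates, suppression, uniqueness, correction", {
  for (seed in c(3, 17)) {
    spec <- cat_spec(seed = seed)
    train <- generate_categorical_set(spec)
    idx <- label_index(extract_substructure_information(train, 0:2))
    cfg <- categorical_config(threshold_frequency = 0.7, radii = 0:2)
    test <- fixture_test_set(spec, n = 8)
    res <- derive_alerts_categorical(test, idx, cfg)

    # gate correctness: every computed P value passed both gates
    expect_true(all(res$n_S >= cfg$threshold_nb_substructures))
    expect_true(all(res$frequency >= cfg$threshold_frequency))
    # each identifier reported exactly once
    expect_equal(anyDuplicated(res$identifier), 0)
    # correction is monotone, clamped, and significant rows come first
    expect_true(all(res$p_value_corrected >= res$p_value - 1e-15))
    expect_true(all(res$p_value_corrected <= 1))
    expect_equal(res$p_value_corrected,
                 pmin(1, res$p_value * nrow(res)))
    if (any(res$significant) && any(!res$significant)) {
      expect_lt(max(which(res$significant)), min(which(!res$significant)))
    }
    # suppression: once an identifier is flagged at (molecule, root, radius),
    # no larger-radius environment at that root of that molecule is reported
    flagged <- res[res$significant, , drop = FALSE]
    for (i in seq_len(nrow(flagged))) {
      worse <- res$example_molecule == flagged$example_molecule[i] &
        res$example_atom == flagged$example_atom[i] &
        res$radius > flagged$radius[i]
      expect_equal(sum(worse), 0)
    }
  }
})

test_that("radii mismatch between config and index is fatal", {
  spec <- cat_spec(seed = 2, n = 30)
  train <- generate_categorical_set(spec)
  idx <- label_index(extract_substructure_information(train, 0:2))
  cfg <- categorical_config(0.7, 0:1)
  expect_error(derive_alerts_categorical(fixture_test_set(spec), idx, cfg),
               "radii")
})
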