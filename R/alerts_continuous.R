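# Structural-alert derivation from continuous activity (e.g. pIC50). For a
# substructure S, distribution A holds the activities of training compounds
# containing S and distribution B those lacking it. Shapiro-Wilk gates the
# choice of test: if both A and B look normal, a two-tailed independent-sample
# t test; otherwise the two-sample Kolmogorov-Smirnov test. The effect size
# is mean(A) - mean(B) in activity units, its sign giving the direction.

#' Configuration for continuous alert derivation
#'
#' @param threshold_nb_substructures minimum number of training compounds with
#'   the substructure (required).
#' @param threshold_ratio minimum ratio of compounds-with-substructure to
#'   training-set size (required).
#' @param radii set of bond radii, matching the training index (required).
#' @param alpha significance level for the Shapiro-Wilk gate and the main
#'   test; default 0.05.
#' @param bonferroni apply the Bonferroni correction over all computed P
#'   values; default `TRUE`.
#' @param welch use the Welch (unequal-variance) t test instead of the pooled
#'   two-sample t test on the normal branch; default `FALSE`.
#' @return a `continuous_config` list.
#' @export
continuous_config <- function(threshold_nb_substructures, threshold_ratio,
                              radii, alpha = 0.05, bonferroni = TRUE,
                              welch = FALSE) {
  if (missing(threshold_nb_substructures)) {
    stop("threshold_nb_substructures is required")
  }
  if (missing(threshold_ratio)) stop("threshold_ratio is required")
  if (missing(radii)) stop("radii is required")
  stopifnot(alpha > 0, alpha < 1, threshold_ratio >= 0, threshold_ratio <= 1,
            threshold_nb_substructures >= 1, length(radii) >= 1)
  structure(
    list(threshold_nb_substructures = threshold_nb_substructures,
         threshold_ratio = threshold_ratio,
         alpha = alpha, bonferroni = isTRUE(bonferroni),
         welch = isTRUE(welch),
         radii = sort(unique(as.integer(radii)))),
    class = "continuous_config"
  )
}

#' Split an activity vector by substructure presence
#'
#' @param index a `substructure_index` over the training set.
#' @param activities numeric activity vector parallel to the training
#'   molecules.
#' @param id a substructure identifier known to the index.
#' @return list with components `A` (activities of compounds containing the
#'   substructure) and `B` (the rest); `length(A) + length(B)` equals the
#'   training-set size.
#' @export
split_by_substructure <- function(index, activities, id) {
  stopifnot(inherits(index, "substructure_index"))
  if (length(activities) != index$n) {
    stop(sprintf("activities length %d does not match the %d training molecules",
                 length(activities), index$n))
  }
  ent <- index$entries[[as.character(id)]]
  if (is.null(ent)) stop("unknown substructure identifier: ", id)
  list(A = activities[ent], B = activities[-ent])
}

# normality decision: TRUE when Shapiro-Wilk does not reject at `alpha`.
# Constant samples are treated as non-normal; samples above the test's size
# cap are judged on a reproducible subsample of 5000.
.looks_normal <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  if (length(x) > 5000) {
    seed_state <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(seed_state)) {
        assign(".Random.seed", seed_state, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(104729L)
    x <- sample(x, 5000)
  }
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p >= alpha
}

#' Normality-gated two-sample test of a substructure's activity effect
#'
#' Applies Shapiro-Wilk to both distributions at level `alpha`; if both pass,
#' a two-tailed independent-samples t test (pooled variance by default) is
#' used, otherwise the two-sample two-sided Kolmogorov-Smirnov test
#' (asymptotic P value). Constant-valued samples are treated as non-normal.
#' Samples with fewer than 3 values on either side cannot be gated and yield
#' a skip signal rather than a statistical result.
#'
#' @param split a list with numeric components `A` and `B`
#'   (see [split_by_substructure()]).
#' @param alpha level for the normality gate; default 0.05.
#' @param welch use the Welch t test on the normal branch; default `FALSE`.
#' @return list with `p_value`, `test_used` (`"t"` or `"ks"`), `effect_size`
#'   (`mean(A) - mean(B)`), and `skipped` (`TRUE`, with a `reason`, when the
#'   samples are too small to test).
#' @export
test_substructure_effect <- function(split, alpha = 0.05, welch = FALSE) {
  A <- split$A
  B <- split$B
  if (length(A) < 3 || length(B) < 3) {
    return(list(p_value = NA_real_, test_used = NA_character_,
                effect_size = NA_real_, skipped = TRUE,
                reason = "fewer than 3 values on one side"))
  }
  normal <- .looks_normal(A, alpha) && .looks_normal(B, alpha)
  if (normal) {
    p <- stats::t.test(A, B, var.equal = !welch, alternative = "two.sided")$p.value
    test_used <- "t"
  } else {
    p <- suppressWarnings(
      stats::ks.test(A, B, alternative = "two.sided", exact = FALSE)$p.value)
    test_used <- "ks"
  }
  list(p_value = p, test_used = test_used,
       effect_size = mean(A) - mean(B), skipped = FALSE)
}

#' Derive structural alerts from continuous activity data
#'
#' For each distinct substructure of the test set in first-encounter order
#' (molecules in input order; within a molecule, root atoms in index order,
#' radii ascending): identifiers absent from the training index or already
#' processed are skipped; the support gate (`n_A >=
#' threshold_nb_substructures`) and ratio gate (`n_A / n >= threshold_ratio`)
#' must pass before any test is computed. Unlike the categorical scan there is
#' no smallest-radius suppression: every qualifying distinct substructure is
#' tested exactly once. The Bonferroni correction (if enabled) is applied over
#' all computed P values.
#'
#' @param test_set a `molecule_set` of test/external molecules.
#' @param index a `substructure_index` over the training set, built with the
#'   same radii as `config`.
#' @param activities numeric activity vector parallel to the training
#'   molecules (taken from the index's molecule set when omitted).
#' @param config a `continuous_config`.
#' @return data frame sorted by ascending corrected P value with columns
#'   `identifier`, `smiles`, `radius`, `n_A`, `ratio`, `test_used`,
#'   `p_value`, `p_value_corrected`, `effect_size`, `direction`.
#' @export
derive_alerts_continuous <- function(test_set, index, activities = NULL,
                                     config) {
  stopifnot(inherits(test_set, "molecule_set"),
            inherits(index, "substructure_index"),
            inherits(config, "continuous_config"))
  if (is.null(activities)) {
    if (is.null(index$molset$activities) ||
        index$molset$activity_type != "continuous") {
      stop("no continuous activities available; pass `activities` or attach them")
    }
    activities <- index$molset$activities
  }
  if (length(activities) != index$n) {
    stop(sprintf("activities length %d does not match the %d training molecules",
                 length(activities), index$n))
  }
  if (!setequal(config$radii, index$radii)) {
    stop("config radii {", paste(config$radii, collapse = ","),
         "} do not match the index radii {",
         paste(index$radii, collapse = ","), "}")
  }
  radii <- config$radii
  processed <- new.env(parent = emptyenv())
  res_id <- numeric(0); res_rad <- integer(0); res_nA <- integer(0)
  res_p <- numeric(0); res_test <- character(0); res_eff <- numeric(0)

  for (t in seq_along(test_set$molecules)) {
    envs <- .env_table(test_set$molecules[[t]], max(radii))
    envs <- envs[envs$radius %in% radii, , drop = FALSE]
    envs <- envs[order(envs$root, envs$radius), , drop = FALSE]
    for (j in seq_len(nrow(envs))) {
      key <- as.character(envs$id[j])
      if (exists(key, envir = processed, inherits = FALSE)) next
      assign(key, TRUE, envir = processed)
      ent <- index$entries[[key]]
      if (is.null(ent)) next
      n_A <- length(ent)
      if (n_A < config$threshold_nb_substructures ||
          (n_A / index$n) < config$threshold_ratio) next
      split <- list(A = activities[ent], B = activities[-ent])
      tst <- test_substructure_effect(split, alpha = config$alpha,
                                      welch = config$welch)
      if (isTRUE(tst$skipped)) {
        message(sprintf("substructure %s skipped: %s", key, tst$reason))
        next
      }
      res_id <- c(res_id, envs$id[j]); res_rad <- c(res_rad, envs$radius[j])
      res_nA <- c(res_nA, n_A); res_p <- c(res_p, tst$p_value)
      res_test <- c(res_test, tst$test_used)
      res_eff <- c(res_eff, tst$effect_size)
    }
  }

  p_corr <- if (config$bonferroni) bonferroni_correct(res_p) else res_p
  smiles <- vapply(res_id, function(id) render_substructure_smiles(index, id),
                   character(1))
  out <- data.frame(
    identifier = res_id,
    smiles = smiles,
    radius = res_rad,
    n_A = res_nA,
    ratio = res_nA / index$n,
    test_used = res_test,
    p_value = res_p,
    p_value_corrected = p_corr,
    effect_size = res_eff,
    direction = ifelse(res_eff > 0, "increases", "decreases"),
    stringsAsFactors = FALSE
  )
  out[order(out$p_value_corrected, out$p_value, out$identifier), ,
      drop = FALSE]
}

#' Export an alert result table
#'
#' Writes one row per result with all fields. CSV output is byte-stable for a
#' fixed input. The xlsx format requires an xlsx writer package (openxlsx or
#' writexl), which must be installed separately.
#'
#' @param results a result data frame from [derive_alerts_categorical()] or
#'   [derive_alerts_continuous()].
#' @param path output path.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "xlsx") {
    if (requireNamespace("openxlsx", quietly = TRUE)) {
      openxlsx::write.xlsx(results, path)
      return(invisible(path))
    }
    if (requireNamespace("writexl", quietly = TRUE)) {
      writexl::write_xlsx(results, path)
      return(invisible(path))
    }
    stop("xlsx export requires the 'openxlsx' or 'writexl' package; ",
         "neither is installed. Use format = \"csv\".")
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.csv(results, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
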