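# Structural-alert derivation from dichotomous (active/inactive) activity
# data. A substructure S present in n_S of the n training compounds, m_S_act
# of them active, is scored by the binomial upper-tail probability of drawing
# at least m_S_act actives in n_S trials at the base rate m/n. The scan over
# a test set processes each heavy atom's environments smallest radius first,
# gates on training support and active frequency, and suppresses the
# larger-radius super-environments of a flagged alert.

#' Binomial upper-tail P value for substructure enrichment
#'
#' Probability of observing by chance at least `m_S_act` active compounds
#' among the `n_S` training compounds carrying a substructure, when actives
#' occur at the training base rate `m/n`:
#' `sum_{i = m_S_act}^{n_S} choose(n_S, i) (m/n)^i (1 - m/n)^(n_S - i)`,
#' i.e. `P(X >= m_S_act)` for `X ~ Binomial(n_S, m/n)`.
#'
#' @param n training-set size (>= 1).
#' @param m number of active training compounds (0 <= m <= n).
#' @param n_S number of training compounds containing the substructure.
#' @param m_S_act number of active training compounds containing it
#'   (0 <= m_S_act <= n_S).
#' @return the tail probability in `[0, 1]`.
#' @examples
#' binomial_tail_pvalue(100, 20, 10, 8)
#' @export
binomial_tail_pvalue <- function(n, m, n_S, m_S_act) {
  if (n < 1) stop("n must be >= 1")
  if (m < 0 || m > n) stop("m must satisfy 0 <= m <= n")
  if (m_S_act < 0 || m_S_act > n_S) stop("m_S_act must satisfy 0 <= m_S_act <= n_S")
  stats::pbinom(m_S_act - 1, size = n_S, prob = m / n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each P value by the number of tests (the vector length) and
#' clamps at 1.
#'
#' @param p_values numeric vector of P values in `[0, 1]`.
#' @return corrected P values.
#' @export
bonferroni_correct <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) stop("P values must lie in [0, 1]")
  pmin(1, p_values * length(p_values))
}

#' Configuration for categorical alert derivation
#'
#' @param threshold_frequency minimum active frequency `m_S_act / n_S`
#'   required to compute a P value (required, no default).
#' @param radii set of bond radii, matching the training index (required).
#' @param threshold_nb_substructures minimum number of training compounds with
#'   the substructure (`n_S`) required to compute a P value; default 5.
#' @param threshold_pvalue significance level alpha; default 0.05.
#' @param bonferroni apply the Bonferroni correction over all computed P
#'   values; default `TRUE`.
#' @param scan_correction when to correct during the scan: `"post"` (default;
#'   scan-time suppression uses raw P values, correction applied after the
#'   scan over the final number of tests) or `"sequential"` (each scan-time
#'   decision multiplies by the number of P values computed so far).
#' @return a `categorical_config` list.
#' @export
categorical_config <- function(threshold_frequency, radii,
                               threshold_nb_substructures = 5,
                               threshold_pvalue = 0.05,
                               bonferroni = TRUE,
                               scan_correction = c("post", "sequential")) {
  if (missing(threshold_frequency)) stop("threshold_frequency is required")
  if (missing(radii)) stop("radii is required")
  stopifnot(threshold_frequency >= 0, threshold_frequency <= 1,
            threshold_pvalue > 0, threshold_pvalue < 1,
            threshold_nb_substructures >= 1, length(radii) >= 1)
  structure(
    list(threshold_nb_substructures = threshold_nb_substructures,
         threshold_pvalue = threshold_pvalue,
         threshold_frequency = threshold_frequency,
         bonferroni = isTRUE(bonferroni),
         scan_correction = match.arg(scan_correction),
         radii = sort(unique(as.integer(radii)))),
    class = "categorical_config"
  )
}

#' Attach activity labels to a substructure index
#'
#' @param index a `substructure_index` built on the training set.
#' @param activities binary activity vector (1 = active) parallel to the
#'   training molecules, or omitted to use the labels already attached to the
#'   index's molecule set.
#' @return a `labeled_index`: the index plus `active_mask` and `m`.
#' @export
label_index <- function(index, activities = NULL) {
  stopifnot(inherits(index, "substructure_index"))
  if (is.null(activities)) {
    if (is.null(index$molset$activities) ||
        index$molset$activity_type != "binary") {
      stop("no binary activities available; pass `activities` or attach them")
    }
    activities <- index$molset$activities
  }
  if (length(activities) != index$n) {
    stop(sprintf("activities length %d does not match the %d training molecules",
                 length(activities), index$n))
  }
  if (!all(activities %in% c(0, 1))) stop("activities must be 0/1")
  index$active_mask <- as.integer(activities)
  index$m <- sum(index$active_mask)
  class(index) <- c("labeled_index", class(index))
  index
}

#' Derive structural alerts from categorical activity data
#'
#' Scans the test set in input order. For each heavy atom of each test
#' molecule, the atom's environments are processed in ascending radius.
#' Identifiers absent from the training index, already processed, or failing
#' the support gate (`n_S >= threshold_nb_substructures`) or the frequency
#' gate (`m_S_act / n_S >= threshold_frequency`) are skipped (and marked
#' processed, since their training counts cannot change). Otherwise the
#' binomial tail P value is computed. If it is significant at scan time, the
#' identifier is flagged, the remaining larger-radius environments rooted at
#' the same atom are suppressed (never evaluated, here or later), and the
#' identifier itself is never reconsidered. After the scan, the Bonferroni
#' correction (if enabled) multiplies every computed P value by the number of
#' P values computed in the run; the reported `significant` flag uses the
#' corrected values.
#'
#' @param test_set a `molecule_set` of test/external molecules.
#' @param index a `labeled_index` built with the same radii as `config`.
#' @param config a `categorical_config`.
#' @return data frame of all evaluated substructures, alerts first, ascending
#'   corrected P value, with columns `identifier`, `smiles`, `radius`, `n_S`,
#'   `m_S_act`, `frequency`, `p_value`, `p_value_corrected`, `significant`,
#'   `example_molecule`, `example_atom`.
#' @export
derive_alerts_categorical <- function(test_set, index, config) {
  stopifnot(inherits(test_set, "molecule_set"),
            inherits(index, "labeled_index"),
            inherits(config, "categorical_config"))
  if (length(test_set$molecules) == 0) stop("test set is empty")
  if (!setequal(config$radii, index$radii)) {
    stop("config radii {", paste(config$radii, collapse = ","),
         "} do not match the index radii {",
         paste(index$radii, collapse = ","), "}")
  }
  radii <- config$radii
  alpha <- config$threshold_pvalue
  processed <- new.env(parent = emptyenv())
  res_id <- numeric(0); res_rad <- integer(0)
  res_nS <- integer(0); res_mS <- integer(0); res_p <- numeric(0)
  res_mol <- integer(0); res_atom <- integer(0)

  for (t in seq_along(test_set$molecules)) {
    envs <- .env_table(test_set$molecules[[t]], max(radii))
    envs <- envs[envs$radius %in% radii, , drop = FALSE]
    for (root in sort(unique(envs$root))) {
      sub <- envs[envs$root == root, , drop = FALSE]
      sub <- sub[order(sub$radius), , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        key <- as.character(sub$id[j])
        if (exists(key, envir = processed, inherits = FALSE)) next
        ent <- index$entries[[key]]
        if (is.null(ent)) {
          assign(key, TRUE, envir = processed)
          next
        }
        n_S <- length(ent)
        m_S_act <- sum(index$active_mask[ent])
        if (n_S < config$threshold_nb_substructures ||
            (m_S_act / n_S) < config$threshold_frequency) {
          assign(key, TRUE, envir = processed)
          next
        }
        p <- binomial_tail_pvalue(index$n, index$m, n_S, m_S_act)
        res_id <- c(res_id, sub$id[j]); res_rad <- c(res_rad, sub$radius[j])
        res_nS <- c(res_nS, n_S); res_mS <- c(res_mS, m_S_act)
        res_p <- c(res_p, p)
        res_mol <- c(res_mol, t); res_atom <- c(res_atom, root)
        assign(key, TRUE, envir = processed)
        p_scan <- if (config$scan_correction == "sequential") {
          min(1, p * length(res_p))
        } else {
          p
        }
        if (p_scan < alpha) {
          # suppress the super-environments of the flagged alert at this root
          if (j < nrow(sub)) {
            for (k2 in (j + 1):nrow(sub)) {
              assign(as.character(sub$id[k2]), TRUE, envir = processed)
            }
          }
          break
        }
      }
    }
  }

  k <- length(res_p)
  p_corr <- if (config$bonferroni) bonferroni_correct(res_p) else res_p
  significant <- p_corr < alpha
  smiles <- vapply(res_id, function(id) render_substructure_smiles(index, id),
                   character(1))
  out <- data.frame(
    identifier = res_id,
    smiles = smiles,
    radius = res_rad,
    n_S = res_nS,
    m_S_act = res_mS,
    frequency = ifelse(res_nS > 0, res_mS / res_nS, NA_real_),
    p_value = res_p,
    p_value_corrected = p_corr,
    significant = significant,
    example_molecule = res_mol,
    example_atom = res_atom,
    stringsAsFactors = FALSE
  )
  out[order(-out$significant, out$p_value_corrected, out$p_value,
            out$identifier), , drop = FALSE]
}
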