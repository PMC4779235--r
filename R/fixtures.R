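# Synthetic molecule sets with a planted alert fragment and controlled
# activity structure. Molecules are drug-like scaffolds drawn from a built-in
# list; carriers get the fragment attached by direct SMILES concatenation
# (a single bond to the scaffold's terminal sp3 carbon). This reproduces the
# enrichment structure the alert statistics assume, without external data.

# every scaffold ends in an sp3 carbon with a free valence, and none contains
# the default nitro fragment
.AM_SCAFFOLDS <- c(
  "c1ccccc1CC",                 # ethylbenzene
  "CCOc1ccc(cc1)CC",            # ethoxyphenyl
  "CC(C)Cc1ccc(cc1)CC",         # isobutylphenyl
  "c1ccc2ccccc2c1CC",           # naphthalene
  "CN1CCN(CC1)CC",              # N-methylpiperazine
  "O=C(Nc1ccccc1)CC",           # anilide
  "COc1ccccc1OCC",              # guaiacol ether
  "c1ccncc1CC",                 # pyridine
  "Clc1ccccc1CC",               # chlorobenzene
  "Fc1ccc(cc1)CC",              # fluorophenyl
  "CC(=O)Nc1ccc(cc1)CC",        # acetanilide
  "c1ccsc1CC",                  # thiophene
  "c1cc[nH]c1CC",               # pyrrole
  "OC(=O)c1ccccc1CC",           # benzoic acid
  "CN(C)c1ccc(cc1)CC",          # dimethylaniline
  "O=S(=O)(N)c1ccc(cc1)CC",     # benzenesulfonamide
  "c1ccc(cc1)Oc1ccc(cc1)CC",    # diphenyl ether
  "CC1CCCCC1CC",                # methylcyclohexane
  "N#Cc1ccc(cc1)CC",            # benzonitrile
  "C1CCOC1CC"                   # tetrahydrofuran
)

#' Built-in scaffold SMILES used by the fixture generator
#' @return character vector of scaffold SMILES.
#' @export
alert_scaffolds <- function() .AM_SCAFFOLDS

#' Specification of a synthetic fixture set
#'
#' @param n_molecules number of molecules to generate.
#' @param seed random seed (Mersenne-Twister; reproducible across platforms).
#' @param fragment_smiles the planted alert fragment, attached to scaffolds by
#'   direct SMILES concatenation (single bond); default a nitro group.
#' @param p_active proportion of active molecules (categorical mode); the
#'   number of actives is exactly `round(p_active * n_molecules)`.
#' @param p_frag_given_active,p_frag_given_inactive per-molecule fragment
#'   planting probabilities given the label (categorical mode).
#' @param p_carrier fragment carrier fraction (continuous mode).
#' @param baseline,shift,noise_sd continuous mode: activity =
#'   `baseline + shift * carrier + Normal(0, noise_sd)`.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules, seed,
                         fragment_smiles = "N(=O)=O",
                         p_active = 0.5,
                         p_frag_given_active = NULL,
                         p_frag_given_inactive = NULL,
                         p_carrier = NULL,
                         baseline = 6.0, shift = NULL, noise_sd = NULL) {
  stopifnot(n_molecules >= 1, p_active >= 0, p_active <= 1)
  structure(
    list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
         fragment_smiles = fragment_smiles, p_active = p_active,
         p_frag_given_active = p_frag_given_active,
         p_frag_given_inactive = p_frag_given_inactive,
         p_carrier = p_carrier, baseline = baseline, shift = shift,
         noise_sd = noise_sd),
    class = "fixture_spec"
  )
}

.check_fragment <- function(fragment_smiles) {
  probe <- .parse_smiles(paste0("C", fragment_smiles))
  if (is.null(probe)) {
    stop("invalid fragment SMILES (cannot be attached): ", fragment_smiles)
  }
  invisible(TRUE)
}

# attach the fragment to a scaffold; invalid joins are resampled from the
# scaffold pool
.carrier_smiles <- function(scaffold_idx, fragment) {
  for (attempt in 1:50) {
    smi <- paste0(.AM_SCAFFOLDS[scaffold_idx], fragment)
    if (!is.null(.parse_smiles(smi))) return(smi)
    scaffold_idx <- sample.int(length(.AM_SCAFFOLDS), 1)
  }
  stop("fragment ", fragment, " could not be attached to any scaffold")
}

.seed_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

#' Generate a synthetic categorical (active/inactive) molecule set
#'
#' Exactly `round(p_active * n)` molecules are labelled active; each molecule
#' carries the planted fragment with probability `p_frag_given_active` or
#' `p_frag_given_inactive` according to its label, so the conditional carrier
#' frequencies match the spec within binomial sampling error. Fully
#' reproducible from the seed.
#'
#' @param spec a `fixture_spec` with the categorical fields set.
#' @return a `molecule_set` with binary activities and an extra logical
#'   element `carrier` flagging the molecules that contain the fragment.
#' @export
generate_categorical_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(spec$p_frag_given_active) || is.null(spec$p_frag_given_inactive)) {
    stop("categorical mode requires p_frag_given_active and p_frag_given_inactive")
  }
  .check_fragment(spec$fragment_smiles)
  .seed_rng(spec$seed)
  n <- spec$n_molecules
  n_act <- round(spec$p_active * n)
  labels <- sample(c(rep(1L, n_act), rep(0L, n - n_act)))
  p_frag <- ifelse(labels == 1, spec$p_frag_given_active,
                   spec$p_frag_given_inactive)
  carrier <- stats::rbinom(n, 1, p_frag) == 1
  scaf <- sample.int(length(.AM_SCAFFOLDS), n, replace = TRUE)
  smiles <- character(n)
  for (i in seq_len(n)) {
    smiles[i] <- if (carrier[i]) {
      .carrier_smiles(scaf[i], spec$fragment_smiles)
    } else {
      .AM_SCAFFOLDS[scaf[i]]
    }
  }
  ms <- molecule_set_from_smiles(smiles, activities = labels)
  ms$carrier <- carrier
  ms
}

#' Generate a synthetic continuous-activity molecule set
#'
#' Each molecule is a fragment carrier with probability `p_carrier`; activity
#' is `baseline + shift * carrier + Normal(0, noise_sd)`. Fully reproducible
#' from the seed.
#'
#' @param spec a `fixture_spec` with the continuous fields set
#'   (`p_carrier`, `shift`, `noise_sd`; `baseline` defaults to 6.0).
#' @return a `molecule_set` with continuous activities and an extra logical
#'   element `carrier`.
#' @export
generate_continuous_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(spec$p_carrier) || is.null(spec$shift) || is.null(spec$noise_sd)) {
    stop("continuous mode requires p_carrier, shift and noise_sd")
  }
  stopifnot(spec$noise_sd > 0)
  .check_fragment(spec$fragment_smiles)
  .seed_rng(spec$seed)
  n <- spec$n_molecules
  carrier <- stats::rbinom(n, 1, spec$p_carrier) == 1
  scaf <- sample.int(length(.AM_SCAFFOLDS), n, replace = TRUE)
  smiles <- character(n)
  for (i in seq_len(n)) {
    smiles[i] <- if (carrier[i]) {
      .carrier_smiles(scaf[i], spec$fragment_smiles)
    } else {
      .AM_SCAFFOLDS[scaf[i]]
    }
  }
  act <- spec$baseline + spec$shift * as.numeric(carrier) +
    stats::rnorm(n, 0, spec$noise_sd)
  ms <- molecule_set_from_smiles(smiles, activities = act,
                                 type = "continuous")
  ms$carrier <- carrier
  ms
}

#' Small test set of fragment-carrying molecules
#'
#' Builds one carrier molecule per scaffold (up to `n`), used as the external
#' set when validating alert recovery on fixtures.
#'
#' @param spec a `fixture_spec` (only `fragment_smiles` is used).
#' @param n number of test molecules; default 5.
#' @return a `molecule_set`.
#' @export
fixture_test_set <- function(spec, n = 5) {
  stopifnot(inherits(spec, "fixture_spec"))
  .check_fragment(spec$fragment_smiles)
  n <- min(n, length(.AM_SCAFFOLDS))
  smiles <- paste0(.AM_SCAFFOLDS[seq_len(n)], spec$fragment_smiles)
  ok <- vapply(smiles, function(s) !is.null(.parse_smiles(s)), logical(1))
  molecule_set_from_smiles(smiles[ok])
}

#' Identifiers unique to the planted fragment
#'
#' Substructure identifiers occurring in at least one carrier molecule and in
#' no non-carrier molecule of a generated fixture set: the identifiers a
#' successful alert derivation should recover.
#'
#' @param molset a fixture `molecule_set` (must have the `carrier` element).
#' @param radii bond radii to enumerate.
#' @return numeric vector of identifiers (possibly empty).
#' @export
planted_fragment_ids <- function(molset, radii) {
  stopifnot(inherits(molset, "molecule_set"), !is.null(molset$carrier))
  if (!any(molset$carrier) || all(molset$carrier)) {
    stop("fixture set must contain both carriers and non-carriers")
  }
  idx <- extract_substructure_information(molset, radii)
  carrier_idx <- which(molset$carrier)
  in_carrier <- vapply(idx$entries, function(e) any(e %in% carrier_idx),
                       logical(1))
  in_noncarrier <- vapply(idx$entries, function(e) !all(e %in% carrier_idx),
                          logical(1))
  idx$ids[in_carrier & !in_noncarrier]
}
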