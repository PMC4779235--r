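# Circular (Morgan/ECFP-style) atom environments. Each heavy atom gets an
# initial invariant hashed from (element, heavy degree, implicit+explicit H
# count, formal charge, ring membership); iterative rounds fold in the sorted
# (bond order, neighbour invariant) pairs. The invariant after round r is the
# identifier of the environment of bond radius r rooted at that atom.
# Identifiers live in [0, 2^31); the hash is plain integer-polynomial
# arithmetic on doubles (exact below 2^53), so identifiers are stable across
# runs and machines. Distinct environments may collide; collisions are
# accepted and treated as the same substructure, matching hashed-fingerprint
# semantics.

.AM_MOD <- 2147483629   # largest prime < 2^31
.AM_MULT <- 1000003

.am_hash <- function(xs) {
  h <- 0
  for (x in xs) h <- (h * .AM_MULT + x) %% .AM_MOD
  h
}

# per-atom invariants for rounds 0..max_radius; returns matrix [atom, round+1]
.morgan_invariants <- function(graph, max_radius) {
  n <- graph$n
  inv <- matrix(0, nrow = n, ncol = max_radius + 1L)
  for (a in seq_len(n)) {
    deg <- length(graph$adj[[a]])
    inv[a, 1] <- .am_hash(c(graph$Z[a], deg, graph$nH[a],
                            graph$charge[a] + 16, as.integer(graph$in_ring[a])))
  }
  if (max_radius >= 1) {
    for (r in seq_len(max_radius)) {
      prev <- inv[, r]
      for (a in seq_len(n)) {
        nb <- graph$adj[[a]]
        if (length(nb) == 0) {
          inv[a, r + 1] <- .am_hash(c(r, prev[a]))
        } else {
          pairs <- cbind(graph$adj_order[[a]], prev[nb])
          o <- order(pairs[, 1], pairs[, 2])
          inv[a, r + 1] <- .am_hash(c(r, prev[a], t(pairs[o, , drop = FALSE])))
        }
      }
    }
  }
  inv
}

# full environment table of one record up to max_radius, memoised by source
# SMILES: data.frame(root, radius, id). An environment of radius r exists at
# a root only if some atom lies at bond distance r from it (r = 0 always).
.env_table <- function(record, max_radius) {
  key <- if (!is.null(record$cache_key)) {
    paste0("env|", max_radius, "|", record$cache_key)
  } else {
    NULL
  }
  if (!is.null(key)) {
    hit <- .cache_get(key)
    if (!is.null(hit)) return(hit)
  }
  g <- record$graph
  inv <- .morgan_invariants(g, max_radius)
  d <- g$dist
  d[!is.finite(d)] <- -1
  ecc <- apply(d, 1, max)
  roots <- integer(0); radii <- integer(0); ids <- numeric(0)
  for (a in seq_len(g$n)) {
    rmax <- min(max_radius, ecc[a])
    rr <- 0:rmax
    roots <- c(roots, rep.int(a, length(rr)))
    radii <- c(radii, rr)
    ids <- c(ids, inv[a, rr + 1L])
  }
  out <- data.frame(root = roots, radius = radii, id = ids)
  if (!is.null(key)) .cache_set(key, out)
  out
}

#' Enumerate circular atom environments of a molecule
#'
#' Emits one environment per (heavy atom, radius) pair for every requested
#' radius that exists at that root (a radius cannot exceed the largest bond
#' distance reachable from the root atom). The identifier is a deterministic
#' circular-fingerprint environment identifier computed from standard
#' connectivity invariants, stable across runs and machines.
#'
#' @param record one element of `molecule_set$molecules`.
#' @param radii non-empty set of integer bond radii (>= 0).
#' @return data frame with columns `molecule_index`, `root_atom`, `radius`,
#'   `identifier`. Rows are ordered by root atom, then radius.
#' @examples
#' ms <- molecule_set_from_smiles("CCO")
#' enumerate_atom_environments(ms$molecules[[1]], radii = 0:1)
#' @export
enumerate_atom_environments <- function(record, radii) {
  if (length(radii) == 0) stop("radii must be non-empty")
  radii <- sort(unique(as.integer(radii)))
  if (any(radii < 0)) stop("radii must be >= 0")
  tab <- .env_table(record, max(radii))
  tab <- tab[tab$radius %in% radii, , drop = FALSE]
  idx <- if (!is.null(record$index)) record$index else NA_integer_
  data.frame(molecule_index = idx, root_atom = tab$root, radius = tab$radius,
             identifier = tab$id, row.names = NULL)
}

#' Build the training-set substructure index
#'
#' Maps every distinct atom-environment identifier occurring in the molecule
#' set (at the requested radii) to the sorted set of molecule indices that
#' contain it. Counting is presence-based: a molecule with several occurrences
#' of a substructure counts once. This index defines the training set for
#' alert derivation and the basis for keyed fingerprints.
#'
#' @param molset a `molecule_set`.
#' @param radii non-empty set of integer bond radii (>= 0).
#' @return a `substructure_index` with components `n` (number of training
#'   molecules), `ids` (ascending identifiers), `entries` (identifier ->
#'   sorted molecule indices, 1-based), `radius_of`, `example` (identifier ->
#'   c(molecule, root atom, radius) of the first occurrence), `radii`, and
#'   the molecule set itself (for substructure rendering).
#' @export
extract_substructure_information <- function(molset, radii) {
  stopifnot(inherits(molset, "molecule_set"))
  if (length(molset$molecules) == 0) stop("molecule set is empty")
  if (length(radii) == 0) stop("radii must be non-empty")
  radii <- sort(unique(as.integer(radii)))

  entries <- new.env(parent = emptyenv())
  radius_of <- new.env(parent = emptyenv())
  example <- new.env(parent = emptyenv())
  for (i in seq_along(molset$molecules)) {
    tab <- .env_table(molset$molecules[[i]], max(radii))
    tab <- tab[tab$radius %in% radii, , drop = FALSE]
    seen <- unique(tab$id)
    for (id in seen) {
      k <- as.character(id)
      cur <- .env_get0(entries, k)
      assign(k, c(cur, i), envir = entries)
      if (is.null(cur)) {
        first <- which(tab$id == id)[1]
        assign(k, tab$radius[first], envir = radius_of)
        assign(k, c(i, tab$root[first], tab$radius[first]), envir = example)
      }
    }
  }
  keys <- ls(entries)
  ids <- sort(as.numeric(keys))
  keys <- as.character(ids)
  structure(
    list(
      n = length(molset$molecules),
      ids = ids,
      entries = stats::setNames(lapply(keys, function(k) get(k, envir = entries)), keys),
      radius_of = stats::setNames(
        vapply(keys, function(k) get(k, envir = radius_of), numeric(1)), keys),
      example = stats::setNames(lapply(keys, function(k) get(k, envir = example)), keys),
      radii = radii,
      molset = molset,
      smiles_cache = new.env(parent = emptyenv())
    ),
    class = "substructure_index"
  )
}

.env_get0 <- function(e, k) {
  if (exists(k, envir = e, inherits = FALSE)) get(k, envir = e) else NULL
}

#' @export
print.substructure_index <- function(x, ...) {
  cat(sprintf(
    "substructure_index: %d distinct substructures over %d molecules (radii %s)\n",
    length(x$ids), x$n, paste(x$radii, collapse = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# environment subgraph extraction and SMILES rendering

# atoms within `radius` bonds of root, and the bonds reached by walking at
# most `radius` steps out of the root (i.e. both endpoints in the sphere and
# at least one endpoint strictly inside it)
.env_subgraph <- function(graph, root, radius) {
  d <- graph$dist[root, ]
  atoms <- which(is.finite(d) & d <= radius)
  b <- graph$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms &
    (d[b$a1] < radius | d[b$a2] < radius)
  list(atoms = atoms, bonds = b[keep, , drop = FALSE], dist = d)
}

# minimal V2000 molblock for a fragment (zero coordinates; OpenBabel only
# needs connectivity and charges to emit canonical SMILES)
.fragment_molblock <- function(graph, atoms, bonds) {
  remap <- stats::setNames(seq_along(atoms), atoms)
  na <- length(atoms)
  nb <- nrow(bonds)
  hdr <- c("fragment", " alertminer", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, graph$elem[atoms])
  bd <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0",
            remap[as.character(bonds$a1)], remap[as.character(bonds$a2)],
            bonds$order)
  } else {
    character(0)
  }
  chg <- which(graph$charge[atoms] != 0)
  mchg <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, graph$charge[atoms][chg]),
                   collapse = ""))
  } else {
    character(0)
  }
  paste(c(hdr, at, bd, mchg, "M  END", "$$$$"), collapse = "\n")
}

#' Render a substructure identifier as SMILES
#'
#' Extracts the atom-environment subgraph rooted at the identifier's first
#' recorded occurrence in the index and canonicalises it with OpenBabel.
#' Hydrogens are implicit, filled to default valence, so the fragment SMILES
#' shows the environment's heavy-atom skeleton. Deterministic for a fixed
#' index.
#'
#' @param index a `substructure_index`.
#' @param id a substructure identifier known to the index.
#' @return a SMILES string.
#' @export
render_substructure_smiles <- function(index, id) {
  stopifnot(inherits(index, "substructure_index"))
  k <- as.character(id)
  cached <- .env_get0(index$smiles_cache, k)
  if (!is.null(cached)) return(cached)
  ex <- index$example[[k]]
  if (is.null(ex)) stop("unknown substructure identifier: ", id)
  graph <- index$molset$molecules[[ex[1]]]$graph
  sub <- .env_subgraph(graph, ex[2], ex[3])
  blk <- .fragment_molblock(graph, sub$atoms, sub$bonds)
  smi <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste0(blk, "\n")),
    error = function(e) ""
  )
  smi <- trimws(strsplit(smi, "[\t\n]")[[1]][1])
  if (!nzchar(smi)) smi <- NA_character_
  assign(k, smi, envir = index$smiles_cache)
  smi
}
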