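# Molecule input, parse-failure tracking, and the molecular graphs that the
# atom-environment machinery works on. All format handling goes through
# ChemmineR / ChemmineOB (OpenBabel); this file only adds bookkeeping.

# atomic numbers for the elements OpenBabel is likely to hand us; anything
# else gets a deterministic code derived from the symbol so identifiers stay
# stable across machines
.Z_TABLE <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29,
  Zn = 30, As = 33, Se = 34, Br = 35, I = 53
)

.atomic_number <- function(sym) {
  z <- unname(.Z_TABLE[sym])
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- vapply(sym[miss], function(s) {
      200 + sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000
    }, numeric(1))
  }
  z
}

# default valences used to infer implicit hydrogen counts on the heavy-atom
# graph (charge-adjusted); elements not listed get 0 implicit H
.VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1,
              Br = 1, I = 1)

.implicit_h <- function(elem, charge, bond_order_sum) {
  v <- unname(.VALENCE[elem])
  v[is.na(v)] <- 0
  # charge shifts the valence of N/O-like atoms (N+ -> 4, O- -> 1, ...)
  v <- v + ifelse(elem %in% c("N", "O", "S", "P"), charge,
                  ifelse(elem %in% c("C", "B"), -abs(charge), 0))
  pmax(0L, as.integer(round(v - bond_order_sum)))
}

# ---------------------------------------------------------------------------
# graph construction from a ChemmineR SDF component

# formal charges from the raw molblock lines ("M  CHG" records); ChemmineR
# does not expose them per atom index
.charges_from_block <- function(block_lines, n_atoms) {
  charge <- integer(n_atoms)
  chg <- grep("^M  CHG", block_lines, value = TRUE)
  for (ln in chg) {
    flds <- as.integer(strsplit(trimws(substring(ln, 7)), "[ \t]+")[[1]])
    k <- flds[1]
    for (i in seq_len(k)) {
      idx <- flds[2 * i]
      if (!is.na(idx) && idx >= 1 && idx <= n_atoms) {
        charge[idx] <- flds[2 * i + 1]
      }
    }
  }
  charge
}

# atom elements/coords and bond table of one molblock. ChemmineR's SDF
# parser is used whenever the molecule has bonds; it cannot represent a
# bond-less (single heavy atom) molecule, so that case is read off the V2000
# counts/atom lines directly.
.blocks_from_molblock <- function(block_lines) {
  counts <- block_lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("malformed molblock counts line")
  if (!is.na(nb) && nb > 0) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    writeLines(c(block_lines, if (!any(grepl("^\\$\\$\\$\\$", block_lines))) "$$$$"),
               tf)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
    if (length(sdfset) < 1 || !ChemmineR::validSDF(sdfset)[1]) {
      stop("invalid SDF block")
    }
    ab <- ChemmineR::atomblock(sdfset[[1]])
    bb <- ChemmineR::bondblock(sdfset[[1]])
    list(elem = gsub("_[0-9]+$", "", rownames(ab)),
         coords = unname(ab[, 1:2, drop = FALSE]),
         bonds = cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                       as.integer(bb[, 3])))
  } else {
    at <- block_lines[5:(4 + na)]
    list(elem = trimws(substr(at, 32, 34)),
         coords = cbind(as.numeric(substr(at, 1, 10)),
                        as.numeric(substr(at, 11, 20))),
         bonds = matrix(integer(0), ncol = 3))
  }
}

# heavy-atom graph (elements, charges, implicit H, ring flags, bonds,
# all-pairs bond distances) from one molblock
.graph_from_molblock <- function(block_lines) {
  blk <- .blocks_from_molblock(block_lines)
  elem <- blk$elem
  coords <- blk$coords
  n_all <- length(elem)
  charge <- .charges_from_block(block_lines, n_all)
  b1 <- blk$bonds[, 1]; b2 <- blk$bonds[, 2]; bo <- blk$bonds[, 3]

  # fold explicit hydrogens into the heavy-atom H counts
  heavy <- elem != "H"
  n_exp_h <- integer(n_all)
  if (any(!heavy)) {
    for (k in seq_along(b1)) {
      if (!heavy[b1[k]] && heavy[b2[k]]) n_exp_h[b2[k]] <- n_exp_h[b2[k]] + 1L
      if (!heavy[b2[k]] && heavy[b1[k]]) n_exp_h[b1[k]] <- n_exp_h[b1[k]] + 1L
    }
    keep_bond <- heavy[b1] & heavy[b2]
    b1 <- b1[keep_bond]; b2 <- b2[keep_bond]; bo <- bo[keep_bond]
    remap <- cumsum(heavy)
    b1 <- remap[b1]; b2 <- remap[b2]
    elem <- elem[heavy]; charge <- charge[heavy]
    coords <- coords[heavy, , drop = FALSE]
    n_exp_h <- n_exp_h[heavy]
  }
  n <- length(elem)
  if (n == 0) stop("structure has no heavy atoms")

  # bond order sum per atom (aromatic type 4 counted as 1.5)
  ord_val <- ifelse(bo == 4, 1.5, bo)
  bos <- numeric(n)
  for (k in seq_along(b1)) {
    bos[b1[k]] <- bos[b1[k]] + ord_val[k]
    bos[b2[k]] <- bos[b2[k]] + ord_val[k]
  }
  nH <- .implicit_h(elem, charge, bos) + n_exp_h

  # adjacency, distances, ring membership
  adj <- vector("list", n)
  adj_ord <- vector("list", n)
  for (k in seq_along(b1)) {
    adj[[b1[k]]] <- c(adj[[b1[k]]], b2[k])
    adj[[b2[k]]] <- c(adj[[b2[k]]], b1[k])
    adj_ord[[b1[k]]] <- c(adj_ord[[b1[k]]], bo[k])
    adj_ord[[b2[k]]] <- c(adj_ord[[b2[k]]], bo[k])
  }
  if (length(b1) > 0) {
    g <- igraph::make_graph(rbind(b1, b2), n = n, directed = FALSE)
    dist <- igraph::distances(g)
    bridge <- igraph::bridges(g)
    in_cycle_edge <- !(seq_along(b1) %in% bridge)
    in_ring <- logical(n)
    in_ring[c(b1[in_cycle_edge], b2[in_cycle_edge])] <- TRUE
  } else {
    dist <- matrix(0, n, n)
    in_ring <- logical(n)
  }

  list(
    n = n, elem = elem, Z = .atomic_number(elem), charge = charge,
    nH = nH, in_ring = in_ring,
    bonds = data.frame(a1 = b1, a2 = b2, order = bo),
    adj = adj, adj_order = adj_ord,
    dist = dist, coords = coords
  )
}

.new_record <- function(graph, molblock, name, source, cache_key = NULL) {
  list(graph = graph, molblock = molblock, name = name, source = source,
       cache_key = cache_key)
}

# value of an SDF data field ("> <tag>" lines) in a record's source block
.sdf_tag <- function(record, tag) {
  hit <- grep(paste0("^>\\s*<", tag, ">"), record$molblock)
  if (length(hit) == 0 || hit[1] + 1 > length(record$molblock)) {
    return(NA_character_)
  }
  trimws(record$molblock[hit[1] + 1])
}

# parse one SMILES into (graph, molblock) via OpenBabel; memoised; NULL on
# failure
.parse_smiles <- function(smi) {
  key <- paste0("smi|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(if (identical(hit, "FAIL")) NULL else hit)
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, " mol\n")),
    error = function(e) ""
  )
  if (!nzchar(sdf_txt) || !grepl("M  END", sdf_txt, fixed = TRUE)) {
    .cache_set(key, "FAIL")
    return(NULL)
  }
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  g <- tryCatch(.graph_from_molblock(lines), error = function(e) NULL)
  if (is.null(g)) {
    .cache_set(key, "FAIL")
    return(NULL)
  }
  .cache_set(key, list(graph = g, molblock = lines))
}

.new_molecule_set <- function(molecules, failed, n_input) {
  structure(
    list(molecules = molecules, activities = NULL, activity_type = NULL,
         failed = failed, n_input = n_input),
    class = "molecule_set"
  )
}

.empty_failed <- function() {
  data.frame(position = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# public API

#' Read molecules from a SMILES, SDF or MOL2 file
#'
#' Parses every record of the file in order. Records that fail to parse are
#' not fatal: they are dropped, logged with one warning each, and listed in
#' the `failed` component of the result (1-based original record position and
#' reason) so that activity vectors supplied in original input order can be
#' realigned with [attach_activities()].
#'
#' The SMILES dialect is whitespace/tab delimited: first token the SMILES,
#' optional second token a name; blank lines and lines starting with `#` are
#' skipped (they do not count as record positions).
#'
#' @param path path to the molecule file.
#' @param format one of `"smiles"`, `"sdf"`, `"mol2"`. For MOL2 the whole file
#'   is converted to SDF by OpenBabel first, so per-record failure positions
#'   are only available for records OpenBabel itself retains.
#' @return a `molecule_set`: ordered parsed molecules (re-indexed
#'   contiguously), an optional parallel activity vector (initially `NULL`),
#'   and the parse-failure log.
#' @examples
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), tf)
#' ms <- read_molecules(tf, format = "smiles")
#' length(ms$molecules)
#' @export
read_molecules <- function(path, format = c("smiles", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ms <- switch(format,
    smiles = .read_smiles_file(path),
    sdf = .read_sdf_file(path),
    mol2 = .read_mol2_file(path)
  )
  if (length(ms$molecules) == 0) {
    stop("no parseable molecules in ", path)
  }
  for (i in seq_len(nrow(ms$failed))) {
    warning(sprintf("record %d failed to parse: %s",
                    ms$failed$position[i], ms$failed$reason[i]),
            call. = FALSE)
  }
  ms
}

.read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  .molecule_set_from_smiles_lines(lines)
}

.molecule_set_from_smiles_lines <- function(lines) {
  molecules <- list()
  failed_pos <- integer(0)
  failed_reason <- character(0)
  for (pos in seq_along(lines)) {
    tok <- strsplit(trimws(lines[pos]), "[ \t]+")[[1]]
    smi <- tok[1]
    nm <- if (length(tok) >= 2) tok[2] else ""
    parsed <- .parse_smiles(smi)
    if (is.null(parsed)) {
      failed_pos <- c(failed_pos, pos)
      failed_reason <- c(failed_reason, "SMILES parse error")
      next
    }
    rec <- .new_record(parsed$graph, parsed$molblock, nm, smi, cache_key = smi)
    rec$index <- length(molecules) + 1L
    molecules[[length(molecules) + 1L]] <- rec
  }
  .new_molecule_set(
    molecules,
    data.frame(position = failed_pos, reason = failed_reason,
               stringsAsFactors = FALSE),
    n_input = length(lines)
  )
}

.read_sdf_file <- function(path) {
  sdfstr <- ChemmineR::read.SDFstr(path)
  blocks <- sdfstr@a
  molecules <- list()
  failed_pos <- integer(0)
  failed_reason <- character(0)
  for (pos in seq_along(blocks)) {
    bl <- blocks[[pos]]
    rec <- tryCatch({
      g <- .graph_from_molblock(bl)
      nm <- trimws(bl[1])
      .new_record(g, bl, nm, paste(bl, collapse = "\n"))
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      failed_pos <- c(failed_pos, pos)
      failed_reason <- c(failed_reason, rec)
    } else {
      rec$index <- length(molecules) + 1L
      molecules[[length(molecules) + 1L]] <- rec
    }
  }
  .new_molecule_set(
    molecules,
    data.frame(position = failed_pos, reason = failed_reason,
               stringsAsFactors = FALSE),
    n_input = length(blocks)
  )
}

.read_mol2_file <- function(path) {
  n_in <- length(grep("@<TRIPOS>MOLECULE", readLines(path, warn = FALSE),
                      fixed = TRUE))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  ChemmineOB::convertFormatFile("MOL2", "SDF", path, tf)
  if (!file.exists(tf) || file.size(tf) == 0) {
    stop("no parseable molecules in ", path)
  }
  ms <- .read_sdf_file(tf)
  n_lost <- n_in - length(ms$molecules) - nrow(ms$failed)
  if (n_lost > 0) {
    ms$failed <- rbind(ms$failed, data.frame(
      position = rep(NA_integer_, n_lost),
      reason = rep("record dropped by OpenBabel MOL2 conversion", n_lost),
      stringsAsFactors = FALSE
    ))
  }
  ms$n_input <- n_in
  ms
}

#' Build a molecule set directly from SMILES strings
#'
#' Convenience constructor used heavily by the synthetic fixture generator.
#' Unlike [read_molecules()] it is strict: any unparseable SMILES is an error.
#'
#' @param smiles character vector of SMILES.
#' @param names optional character vector of names.
#' @param activities optional activity vector, passed to [attach_activities()].
#' @param type activity type, passed to [attach_activities()].
#' @return a `molecule_set`.
#' @export
molecule_set_from_smiles <- function(smiles, names = NULL, activities = NULL,
                                     type = "auto") {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(names)) names <- sprintf("mol%d", seq_along(smiles))
  molecules <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    parsed <- .parse_smiles(smiles[i])
    if (is.null(parsed)) stop("unparseable SMILES: ", smiles[i])
    rec <- .new_record(parsed$graph, parsed$molblock, names[i], smiles[i],
                       cache_key = smiles[i])
    rec$index <- i
    molecules[[i]] <- rec
  }
  ms <- .new_molecule_set(molecules, .empty_failed(), length(smiles))
  if (!is.null(activities)) ms <- attach_activities(ms, activities, type = type)
  ms
}

#' Attach an activity vector to a molecule set
#'
#' `values` must be parallel to the ORIGINAL input order (before parse
#' failures were removed); entries at failed positions are dropped so the
#' result is parallel to the kept molecules. Binary labels are normalised to
#' 1 = active, 0 = inactive.
#'
#' @param molset a `molecule_set`.
#' @param values activity values: numeric (continuous), 0/1 numeric, logical,
#'   or character labels (`"active"`/`"inactive"`, case-insensitive, or
#'   `"1"`/`"0"`).
#' @param type `"auto"` (default), `"binary"` or `"continuous"`. Under
#'   `"auto"`, character/logical vectors and numeric vectors containing only
#'   0 and 1 are treated as binary; any other numeric vector as continuous.
#' @return the molecule set with `activities` (and `activity_type`) set.
#' @export
attach_activities <- function(molset, values,
                              type = c("auto", "binary", "continuous")) {
  stopifnot(inherits(molset, "molecule_set"))
  type <- match.arg(type)
  if (length(values) != molset$n_input) {
    stop(sprintf("activity vector has length %d but the input had %d records",
                 length(values), molset$n_input))
  }
  keep_pos <- setdiff(seq_len(molset$n_input),
                      molset$failed$position[!is.na(molset$failed$position)])
  # failures without a recorded position (MOL2 path) cannot be realigned
  if (anyNA(molset$failed$position) &&
      length(keep_pos) != length(molset$molecules)) {
    stop("cannot realign activities: some parse failures have unknown positions")
  }
  values <- values[keep_pos]

  if (type == "auto") {
    type <- if (is.character(values) || is.logical(values) ||
                (is.numeric(values) && all(values %in% c(0, 1)))) {
      "binary"
    } else {
      "continuous"
    }
  }
  if (type == "binary") {
    if (is.character(values)) {
      v <- tolower(trimws(values))
      act <- ifelse(v %in% c("active", "1", "true", "toxic"), 1L,
                    ifelse(v %in% c("inactive", "0", "false", "nontoxic",
                                    "non-toxic"), 0L, NA_integer_))
      if (anyNA(act)) {
        stop("unrecognizable activity label(s): ",
             paste(unique(values[is.na(act)]), collapse = ", "))
      }
    } else if (is.logical(values)) {
      act <- as.integer(values)
    } else {
      if (!all(values %in% c(0, 1))) {
        stop("binary activities must be 0/1, logical, or active/inactive labels")
      }
      act <- as.integer(values)
    }
    molset$activities <- act
    molset$activity_type <- "binary"
  } else {
    if (!is.numeric(values)) stop("continuous activities must be numeric")
    molset$activities <- as.numeric(values)
    molset$activity_type <- "continuous"
  }
  molset
}

#' Write a molecule set to an SDF file
#'
#' @param molset a `molecule_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molset, path) {
  stopifnot(inherits(molset, "molecule_set"))
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  for (r in molset$molecules) {
    bl <- r$molblock
    bl <- bl[!grepl("^\\$\\$\\$\\$", bl)]
    nm <- if (nzchar(r$name)) r$name else sprintf("mol%d", r$index)
    bl[1] <- nm
    writeLines(c(bl, "$$$$"), con)
  }
  invisible(path)
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("molecule_set: %d molecules (%d input records, %d failed)\n",
              length(x$molecules), x$n_input, nrow(x$failed)))
  if (!is.null(x$activities)) {
    cat(sprintf("activities: %s", x$activity_type))
    if (x$activity_type == "binary") {
      cat(sprintf(" (%d active / %d inactive)",
                  sum(x$activities == 1), sum(x$activities == 0)))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
length.molecule_set <- function(x) length(x$molecules)
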