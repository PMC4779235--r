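# Hashed and unhashed (keyed) circular fingerprints. Counts are environment
# occurrences (number of root atoms emitting the identifier) per molecule;
# binary is the indicator of a nonzero count. Keyed columns are the distinct
# identifiers in ascending order; hashed columns are positions id mod size.

.fp_matrix <- function(values, fmt, scheme, ids = NULL, size = NULL,
                       radii = NULL) {
  structure(
    list(values = values, fmt = fmt, scheme = scheme, ids = ids, size = size,
         radii = radii),
    class = "fp_matrix"
  )
}

#' @export
print.fp_matrix <- function(x, ...) {
  cat(sprintf("fp_matrix: %d molecules x %d columns (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$scheme, x$fmt))
  invisible(x)
}

# occurrence counts of each identifier in one molecule at the given radii
.id_counts <- function(record, radii) {
  tab <- .env_table(record, max(radii))
  tab <- tab[tab$radius %in% radii, , drop = FALSE]
  if (nrow(tab) == 0) return(numeric(0))
  cnt <- table(tab$id)
  stats::setNames(as.numeric(cnt), names(cnt))
}

.mol_names <- function(molset) {
  vapply(molset$molecules, function(r) {
    if (nzchar(r$name)) r$name else sprintf("mol%d", r$index)
  }, character(1))
}

#' Hashed circular fingerprints
#'
#' Each environment identifier is mapped to the array position given by the
#' modulo of its division by the fingerprint size; colliding identifiers share
#' a position. Count format accumulates occurrence counts of all environments
#' mapping to a position; binary format is the indicator of a nonzero count.
#' Radii 0..`max_radius` are used.
#'
#' @param molset a `molecule_set`.
#' @param size fingerprint length (>= 1).
#' @param max_radius maximal bond radius.
#' @param fmt `"count"` or `"binary"`.
#' @return an `fp_matrix` (scheme `"hashed"`) with columns `pos0..pos(size-1)`.
#' @export
calculate_hashed_fps <- function(molset, size, max_radius,
                                 fmt = c("count", "binary")) {
  stopifnot(inherits(molset, "molecule_set"))
  fmt <- match.arg(fmt)
  if (size < 1) stop("size must be >= 1")
  size <- as.integer(size)
  radii <- 0:max_radius
  vals <- matrix(0, nrow = length(molset$molecules), ncol = size,
                 dimnames = list(.mol_names(molset),
                                 paste0("pos", 0:(size - 1L))))
  for (i in seq_along(molset$molecules)) {
    cnt <- .id_counts(molset$molecules[[i]], radii)
    if (length(cnt) == 0) next
    pos <- (as.numeric(names(cnt)) %% size) + 1L
    for (j in seq_along(pos)) vals[i, pos[j]] <- vals[i, pos[j]] + cnt[j]
  }
  if (fmt == "binary") vals[] <- as.numeric(vals > 0)
  .fp_matrix(vals, fmt, "hashed", size = size, radii = radii)
}

#' Unhashed (keyed) circular fingerprints
#'
#' Without a basis, columns are the distinct substructure identifiers of the
#' molecule set itself, so fingerprint length equals the number of distinct
#' substructures present. With a basis built from a training set (see
#' [extract_substructure_information()]), columns are exactly the basis
#' identifiers in ascending-identifier order, and substructures of the new
#' molecules that are absent from the basis are dropped (a summary message
#' reports how many distinct identifiers were dropped). This lets new
#' compounds be expressed on the frozen training basis.
#'
#' @param molset a `molecule_set`.
#' @param radii set of bond radii; if a basis is given it must have been built
#'   with the same radii.
#' @param basis optional `substructure_index` defining the column basis.
#' @param fmt `"count"` or `"binary"`.
#' @return list with components `fp` (an `fp_matrix`, scheme `"keyed"`) and
#'   `catalog` (named character vector: identifier -> substructure SMILES,
#'   covering every column).
#' @export
calculate_unhashed_fps <- function(molset, radii, basis = NULL,
                                   fmt = c("count", "binary")) {
  stopifnot(inherits(molset, "molecule_set"))
  fmt <- match.arg(fmt)
  if (is.null(basis)) {
    basis <- extract_substructure_information(molset, radii)
  } else {
    stopifnot(inherits(basis, "substructure_index"))
    if (length(basis$ids) == 0) stop("basis is empty")
    if (!setequal(basis$radii, as.integer(radii))) {
      stop("basis was built with radii {", paste(basis$radii, collapse = ","),
           "} but radii {", paste(sort(unique(as.integer(radii))), collapse = ","),
           "} were requested")
    }
  }
  ids <- basis$ids  # ascending
  keys <- as.character(ids)
  vals <- matrix(0, nrow = length(molset$molecules), ncol = length(ids),
                 dimnames = list(.mol_names(molset), keys))
  dropped <- character(0)
  for (i in seq_along(molset$molecules)) {
    cnt <- .id_counts(molset$molecules[[i]], basis$radii)
    if (length(cnt) == 0) next
    hit <- names(cnt) %in% keys
    dropped <- union(dropped, names(cnt)[!hit])
    if (any(hit)) vals[i, names(cnt)[hit]] <- cnt[hit]
  }
  if (length(dropped) > 0) {
    message(sprintf("%d distinct substructure identifier(s) absent from the basis were dropped",
                    length(dropped)))
  }
  if (fmt == "binary") vals[] <- as.numeric(vals > 0)
  catalog <- stats::setNames(
    vapply(ids, function(id) render_substructure_smiles(basis, id),
           character(1)),
    keys)
  list(fp = .fp_matrix(vals, fmt, "keyed", ids = ids, radii = basis$radii),
       catalog = catalog)
}

#' Fold a keyed count fingerprint matrix into a hashed one
#'
#' Column with identifier `id` contributes its counts to hashed position
#' `id mod size`. This is the bridge between the keyed and hashed schemes:
#' folding a keyed count matrix reproduces the directly hashed count matrix
#' of the same molecules and radii.
#'
#' @param fp an `fp_matrix` with scheme `"keyed"` and count format.
#' @param size hashed fingerprint length (>= 1).
#' @return an `fp_matrix` with scheme `"hashed"`, count format.
#' @export
fold_fingerprints <- function(fp, size) {
  stopifnot(inherits(fp, "fp_matrix"))
  if (fp$scheme != "keyed") stop("fold_fingerprints requires a keyed fingerprint matrix")
  if (fp$fmt != "count") stop("fold_fingerprints requires count format")
  if (size < 1) stop("size must be >= 1")
  size <- as.integer(size)
  vals <- matrix(0, nrow = nrow(fp$values), ncol = size,
                 dimnames = list(rownames(fp$values),
                                 paste0("pos", 0:(size - 1L))))
  pos <- (fp$ids %% size) + 1L
  for (j in seq_along(pos)) {
    vals[, pos[j]] <- vals[, pos[j]] + fp$values[, j]
  }
  .fp_matrix(vals, "count", "hashed", size = size, radii = fp$radii)
}

#' Export a fingerprint matrix as dense CSV
#'
#' Header names columns by identifier (keyed) or position (hashed); the first
#' column holds molecule names.
#'
#' @param fp an `fp_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fp_matrix"))
  df <- data.frame(molecule = rownames(fp$values), fp$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# depiction

#' Depict a substructure highlighted within a molecule
#'
#' Draws the molecule's 2-D structure (coordinates from the parsed file or
#' from OpenBabel's layout of SMILES input) with the atoms and bonds of the
#' identifier's environment highlighted, and writes it to a vector-graphics
#' file.
#'
#' @param record one element of `molecule_set$molecules`.
#' @param id a substructure identifier that occurs in the record.
#' @param outfile output file path.
#' @param radii radii searched for the identifier's occurrence (default 0:5).
#' @param format `"svg"` (default) or `"pdf"`.
#' @return `outfile`, invisibly.
#' @export
depict_substructure <- function(record, id, outfile, radii = 0:5,
                                format = c("svg", "pdf")) {
  format <- match.arg(format)
  tab <- .env_table(record, max(radii))
  tab <- tab[tab$radius %in% radii, , drop = FALSE]
  hit <- which(tab$id == as.numeric(id))
  if (length(hit) == 0) {
    stop("identifier ", id, " does not occur in this molecule at radii ",
         paste(range(radii), collapse = ".."))
  }
  root <- tab$root[hit[1]]
  radius <- tab$radius[hit[1]]
  g <- record$graph
  sub <- .env_subgraph(g, root, radius)

  xy <- g$coords
  # degenerate layouts (all-zero coordinates) fall back to a circle
  if (all(abs(xy) < 1e-9)) {
    th <- seq(0, 2 * pi, length.out = g$n + 1)[seq_len(g$n)]
    xy <- cbind(cos(th), sin(th))
  }
  if (format == "svg") {
    grDevices::svg(outfile, width = 6, height = 5)
  } else {
    grDevices::pdf(outfile, width = 6, height = 5)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  graphics::plot.new()
  pad <- 0.8
  graphics::plot.window(xlim = range(xy[, 1]) + c(-pad, pad),
                        ylim = range(xy[, 2]) + c(-pad, pad), asp = 1)
  b <- g$bonds
  in_env_bond <- seq_len(nrow(b)) %in% which(
    b$a1 %in% sub$atoms & b$a2 %in% sub$atoms &
      (sub$dist[b$a1] < radius | sub$dist[b$a2] < radius))
  # highlight layer first
  if (any(in_env_bond)) {
    graphics::segments(xy[b$a1[in_env_bond], 1], xy[b$a1[in_env_bond], 2],
                       xy[b$a2[in_env_bond], 1], xy[b$a2[in_env_bond], 2],
                       col = "#fdbf6f", lwd = 9, lend = 1)
  }
  graphics::points(xy[sub$atoms, 1], xy[sub$atoms, 2], pch = 16,
                   col = "#fdbf6f", cex = 3)
  # bonds (parallel offset strokes for double/triple)
  for (k in seq_len(nrow(b))) {
    p1 <- xy[b$a1[k], ]; p2 <- xy[b$a2[k], ]
    dvec <- p2 - p1
    nrm <- c(-dvec[2], dvec[1])
    len <- sqrt(sum(nrm^2))
    nrm <- if (len > 0) nrm / len * 0.07 else c(0, 0)
    offs <- switch(as.character(min(b$order[k], 3)),
                   "1" = list(c(0, 0)),
                   "2" = list(nrm, -nrm),
                   "3" = list(c(0, 0), 1.8 * nrm, -1.8 * nrm),
                   list(c(0, 0)))
    for (o in offs) {
      graphics::segments(p1[1] + o[1], p1[2] + o[2],
                         p2[1] + o[1], p2[2] + o[2], lwd = 1.6)
    }
  }
  lab <- ifelse(g$elem == "C" & g$charge == 0, "", g$elem)
  chg <- ifelse(g$charge > 0, paste0("+", g$charge),
                ifelse(g$charge < 0, as.character(g$charge), ""))
  lab <- paste0(lab, ifelse(nzchar(lab), chg, ""))
  show <- nzchar(lab)
  if (any(show)) {
    graphics::points(xy[show, 1], xy[show, 2], pch = 16, col = "white",
                     cex = 2.2)
    graphics::text(xy[show, 1], xy[show, 2], lab[show], cex = 0.9)
  }
  ttl <- if (nzchar(record$name)) record$name else record$source
  graphics::text(mean(range(xy[, 1])), max(xy[, 2]) + pad * 0.8,
                 sprintf("%s  [id %s, radius %d]", ttl, format(id, digits = 12),
                         radius), cex = 0.8)
  invisible(outfile)
}
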