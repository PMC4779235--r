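test_that("binary fingerprints are the indicator of the count matrix", {
  ms <- generate_categorical_set(cat_spec(seed = 21, n = 40))
  fc <- calculate_hashed_fps(ms, size = 256, max_radius = 2, fmt = "count")
  fb <- calculate_hashed_fps(ms, size = 256, max_radius = 2, fmt = "binary")
  expect_equal(fb$values, (fc$values > 0) * 1)
  expect_true(all(fb$values %in% c(0, 1)))

  uc <- calculate_unhashed_fps(ms, radii = 0:2, fmt = "count")
  ub <- calculate_unhashed_fps(ms, radii = 0:2, fmt = "binary")
  expect_equal(ub$fp$values, (uc$fp$values > 0) * 1)
})

test_that("keyed fingerprints: self-projection, basis columns, zero rows", {
  ms <- molecule_set_from_smiles(c("CCO", "CCN", "c1ccccc1"))
  basis <- extract_substructure_information(ms, 0:1)
  no_basis <- calculate_unhashed_fps(ms, radii = 0:1, fmt = "count")
  with_basis <- calculate_unhashed_fps(ms, radii = 0:1, basis = basis,
                                       fmt = "count")
  expect_equal(no_basis$fp$values, with_basis$fp$values)
  expect_equal(no_basis$fp$ids, with_basis$fp$ids)
  # columns are ascending identifiers
  expect_equal(with_basis$fp$ids, sort(with_basis$fp$ids))
  # number of columns = number of distinct substructures in the set
  expect_equal(ncol(no_basis$fp$values), length(basis$ids))

  # a molecule sharing no substructure with the basis gives an all-zero row
  stranger <- molecule_set_from_smiles("S")
  expect_message(
    proj <- calculate_unhashed_fps(stranger, radii = 0:1, basis = basis,
                                   fmt = "count"),
    "dropped")
  expect_equal(sum(proj$fp$values), 0)

  # basis stability: disjoint sets projected onto one basis share column
  # meaning (catalog equality)
  s1 <- molecule_set_from_smiles(c("CCO", "CCCC"))
  s2 <- molecule_set_from_smiles(c("CCN", "c1ccncc1"))
  p1 <- suppressMessages(calculate_unhashed_fps(s1, 0:1, basis, "count"))
  p2 <- suppressMessages(calculate_unhashed_fps(s2, 0:1, basis, "count"))
  expect_identical(colnames(p1$fp$values), colnames(p2$fp$values))
  expect_identical(p1$catalog, p2$catalog)
  expect_true(all(names(p1$catalog) %in% as.character(basis$ids)))
})

test_that("fold semantics follow the modulo rule", {
  mk <- alertminer:::.fp_matrix
  fp <- mk(matrix(c(3, 1), nrow = 2, dimnames = list(c("a", "b"), "5")),
           fmt = "count", scheme = "keyed", ids = 5)
  f <- fold_fingerprints(fp, 4)
  expect_equal(unname(f$values[, 2]), c(3, 1))   # 5 mod 4 = 1 -> pos1
  expect_equal(sum(f$values), 4)

  fp2 <- mk(matrix(c(2, 0, 1, 5), nrow = 2,
                   dimnames = list(c("a", "b"), c("3", "7"))),
            fmt = "count", scheme = "keyed", ids = c(3, 7))
  f2 <- fold_fingerprints(fp2, 4)
  expect_equal(unname(f2$values[, 4]), c(3, 5))  # both at pos3, counts summed

  expect_error(fold_fingerprints(f2, 4), "keyed")
  bin <- mk(matrix(1, 1, 1, dimnames = list("a", "3")), fmt = "binary",
            scheme = "keyed", ids = 3)
  expect_error(fold_fingerprints(bin, 4), "count")
})

test_that("keyed-then-fold equals directly hashed fingerprints", {
  ms <- generate_categorical_set(cat_spec(seed = 5, n = 100))
  keyed <- calculate_unhashed_fps(ms, radii = 0:2, fmt = "count")
  for (L in c(64, 1024, 4096)) {
    folded <- fold_fingerprints(keyed$fp, L)
    hashed <- calculate_hashed_fps(ms, size = L, max_radius = 2, fmt = "count")
    expect_equal(unname(folded$values), unname(hashed$values),
                 label = sprintf("fold equivalence at L=%d", L))
    # binarizing after the fold matches the directly hashed binary matrix
    hb <- calculate_hashed_fps(ms, size = L, max_radius = 2, fmt = "binary")
    expect_equal(unname((folded$values > 0) * 1), unname(hb$values))
  }
})

test_that("shuffling molecule order permutes fingerprint rows only", {
  smis <- c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "c1ccncc1")
  ms <- molecule_set_from_smiles(smis)
  set.seed(42)
  perm <- sample(length(smis))
  msp <- molecule_set_from_smiles(smis[perm])
  f1 <- calculate_hashed_fps(ms, 128, 2, "count")
  f2 <- calculate_hashed_fps(msp, 128, 2, "count")
  expect_equal(unname(f2$values), unname(f1$values[perm, ]))
})

test_that("hashed fingerprint maps identifier 0 and id+L collisions correctly", {
  # modulo identity checked through fold of synthetic columns
  mk <- alertminer:::.fp_matrix
  L <- 16
  fp <- mk(matrix(c(1, 2), nrow = 1, dimnames = list("a", c("0", "23"))),
           fmt = "count", scheme = "keyed", ids = c(0, 23))
  f <- fold_fingerprints(fp, L)
  expect_equal(unname(f$values[1, 1]), 1)        # id 0 -> pos 0
  expect_equal(unname(f$values[1, (23 %% L) + 1]), 2)
  fp2 <- mk(matrix(c(1, 2), nrow = 1, dimnames = list("a", c("7", "23"))),
            fmt = "count", scheme = "keyed", ids = c(7, 23))
  expect_equal(unname(fold_fingerprints(fp2, L)$values[1, 8]), 3)  # 7 and 7+L collide
})

test_that("substructure SMILES rendering is correct and deterministic", {
  ms <- molecule_set_from_smiles("CCO")
  idx <- extract_substructure_information(ms, 0:1)
  envs <- enumerate_atom_environments(ms$molecules[[1]], 0:1)
  # radius-0 environment of the oxygen
  o_atom <- which(ms$molecules[[1]]$graph$elem == "O")
  o_id <- envs$identifier[envs$root_atom == o_atom & envs$radius == 0]
  smi_o <- render_substructure_smiles(idx, o_id)
  expect_match(smi_o, "O")
  expect_false(grepl("C", smi_o))
  # radius-1 environment rooted at the central carbon: C, C, O fragment
  deg <- vapply(ms$molecules[[1]]$graph$adj, length, integer(1))
  c2 <- which(deg == 2)
  c2_id <- envs$identifier[envs$root_atom == c2 & envs$radius == 1]
  smi_c2 <- render_substructure_smiles(idx, c2_id)
  atoms <- gsub("[^A-Za-z]", "", smi_c2)
  expect_equal(sort(strsplit(toupper(atoms), "")[[1]]), c("C", "C", "O"))
  # determinism
  expect_identical(render_substructure_smiles(idx, c2_id),
                   render_substructure_smiles(idx, c2_id))
  expect_error(render_substructure_smiles(idx, 123456789), "unknown")
})

test_that("depiction writes a non-empty vector file and errors on absent ids", {
  ms <- molecule_set_from_smiles("CCOc1ccc(CC)cc1")
  rec <- ms$molecules[[1]]
  envs <- enumerate_atom_environments(rec, 0:2)
  id <- envs$identifier[envs$radius == 2][1]
  out <- tempfile(fileext = ".svg")
  depict_substructure(rec, id, out)
  expect_true(file.exists(out))
  expect_gt(file.size(out), 100)
  # highlight set = atoms within `radius` bonds of the root (BFS oracle)
  root <- envs$root_atom[envs$radius == 2][1]
  d <- rec$graph$dist[root, ]
  expect_setequal(alertminer:::.env_subgraph(rec$graph, root, 2)$atoms,
                  which(d <= 2))

  out2 <- tempfile(fileext = ".svg")
  expect_error(depict_substructure(rec, 424242, out2), "does not occur")
  expect_false(file.exists(out2))
})

test_that("fingerprint CSV export has identifier/position headers", {
  ms <- molecule_set_from_smiles(c("CCO", "CCN"))
  keyed <- calculate_unhashed_fps(ms, 0, fmt = "count")
  tf <- tempfile(fileext = ".csv")
  export_fingerprints(keyed$fp, tf)
  df <- read.csv(tf, check.names = FALSE)
  expect_equal(df$molecule, c("mol1", "mol2"))
  expect_setequal(names(df)[-1], as.character(keyed$fp$ids))
})
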