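test_that("a minimal PDB parses into C-alpha residues in file order", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA ", "A", 1, 9, 9, 9, elety = " CB "),  # non-CA atom
    pdb_atom_line(3, "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "SER", "A", 3, 7.6, 0, 0)))
  models <- load_structures(path)
  expect_length(models, 1)
  m <- models[[1]]
  expect_equal(m$residues$residue_name, c("GLY", "ALA", "SER"))
  expect_equal(m$residues$seq_number, 1:3)
  expect_equal(m$coordinates[, 1], c(0, 3.8, 7.6))
})

test_that("HETATM and non-amino-acid records are dropped, absence of ATOM errors", {
  path <- write_toy_pdb(c(
    sub("^ATOM  ", "HETATM", pdb_atom_line(1, "HOH", "A", 90, 1, 1, 1,
                                           elety = " O  ")),
    pdb_atom_line(2, "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "ALA", "A", 2, 3.8, 0, 0)))
  models <- load_structures(path)
  expect_equal(nrow(models[[1]]$residues), 2)

  empty <- write_toy_pdb(sub("^ATOM  ", "HETATM",
                             pdb_atom_line(1, "HOH", "A", 1, 0, 0, 0,
                                           elety = " O  ")))
  expect_error(load_structures(empty), "no amino-acid ATOM")
})

test_that("alternate locations resolve to the highest occupancy, first on tie", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "ALA", "A", 2, 1.0, 0, 0, altloc = "A", occ = 0.6),
    pdb_atom_line(3, "ALA", "A", 2, 2.0, 0, 0, altloc = "B", occ = 0.4),
    pdb_atom_line(4, "SER", "A", 3, 7.6, 0, 0)))
  m <- load_structures(path)[[1]]
  expect_equal(nrow(m$residues), 3)
  expect_equal(m$coordinates[2, 1], 1.0)

  tie <- write_toy_pdb(c(
    pdb_atom_line(1, "ALA", "A", 2, 5.0, 0, 0, altloc = "A", occ = 0.5),
    pdb_atom_line(2, "ALA", "A", 2, 6.0, 0, 0, altloc = "B", occ = 0.5)))
  expect_equal(load_structures(tie)[[1]]$coordinates[1, 1], 5.0)
})

test_that("a residue without a C-alpha atom is skipped with a warning", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "ALA", "A", 2, 1, 1, 1, elety = " CB "),
    pdb_atom_line(3, "SER", "A", 3, 7.6, 0, 0)))
  expect_warning(models <- load_structures(path), "without a C-alpha")
  expect_equal(models[[1]]$residues$seq_number, c(1L, 3L))
})

test_that("multi-MODEL files expand to one model per frame, honoring stride", {
  block <- function(x) c(pdb_atom_line(1, "GLY", "A", 1, x, 0, 0),
                         pdb_atom_line(2, "ALA", "A", 2, x + 3.8, 0, 0))
  lines <- unlist(lapply(1:4, function(i) {
    c(sprintf("MODEL     %4d", i), block(i), "ENDMDL")
  }))
  path <- write_toy_pdb(lines)
  expect_length(load_structures(path), 4)
  strided <- load_structures(path, stride = 2)
  expect_length(strided, 2)
  expect_equal(strided[[2]]$coordinates[1, 1], 3)
})

test_that("residue intersection keeps identity-matched positions in first-model order", {
  mk <- function(from, to, names = "ALA") {
    n <- to - from + 1
    mechbridge:::new_structure_model(
      paste0("m", from), toy_residues(n, start = from, names = names),
      cbind(seq(from, to) * 3.8, 0, 0))
  }
  ens <- intersect_residues(list(mk(1, 10), mk(3, 12)))
  expect_equal(ens$residues$seq_number, 3:10)
  expect_equal(nrow(ens$residues), 8)

  same <- intersect_residues(list(mk(1, 5), mk(1, 5)))
  expect_equal(nrow(same$residues), 5)

  # identity mismatch at a shared key excludes the position with a warning
  a <- mk(1, 6); b <- mk(1, 6); c3 <- mk(1, 6)
  c3$residues$residue_name[5] <- "GLY"
  expect_warning(ens2 <- intersect_residues(list(a, b, c3)),
                 "mismatch")
  expect_equal(ens2$residues$seq_number, c(1:4, 6L))

  # permuting inputs never changes membership
  e1 <- intersect_residues(list(mk(1, 10), mk(3, 12), mk(2, 8)))
  e2 <- intersect_residues(list(mk(2, 8), mk(1, 10), mk(3, 12)))
  expect_setequal(e1$residues$key, e2$residues$key)
  expect_lte(nrow(e1$residues), 7)

  expect_error(intersect_residues(list(mk(1, 5), mk(20, 25))), "common")
})

test_that("PDB serialization round-trips residues and coordinates", {
  fx <- make_hinge_ensemble(c(10, 10), max_angle = 10, noise_sd = 0.2,
                            n_members = 3, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(fx$ensemble, path)
  back <- intersect_residues(load_structures(path), "rt")
  expect_equal(back$residues$key, fx$ensemble$residues$key)
  for (m in 1:3) {
    expect_equal(back$coords[[m]], fx$ensemble$coords[[m]],
                 ignore_attr = TRUE, tolerance = 0)
  }
})

test_that("numbering maps load, validate the AxBB pattern, and reject duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("receptor_id\tchain_id\tseq_number\tgeneric_number",
               "RHO\tA\t302\t7x52",
               "RHO\tA\t135\t3x50"), path)
  map <- load_numbering_map(path)
  res <- toy_residues(1, start = 302)
  expect_equal(generic_numbers(map, "RHO", res), "7x52")

  writeLines(c("receptor_id\tchain_id\tseq_number\tgeneric_number",
               "RHO\tA\t302\t7x52",
               "RHO\tA\t302\t7x53"), path)
  expect_error(load_numbering_map(path), "duplicate")

  writeLines(c("receptor_id\tchain_id\tseq_number\tgeneric_number",
               "RHO\tA\t302\t7q52"), path)
  expect_error(load_numbering_map(path), "malformed.*line 2")
})

test_that("manifests normalize activation-state labels", {
  expect_equal(mechbridge:::normalize_state(
    c("active", "inactive", "p. active", "active (?)")),
    c("active", "inactive", "partially_active", "active"))
  expect_error(mechbridge:::normalize_state("wobbly"), "unrecognized")
})
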