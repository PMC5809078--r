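test_that("minimal and multi-model PDB files parse with correct counts", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text(), f)
  ens <- read_structure(f)
  expect_equal(n_models(ens), 1)
  m <- get_model(ens, 1)
  expect_equal(nrow(m$atom), 1)
  expect_equal(m$atom$elety, "C1'")
  expect_equal(unname(unlist(m$atom[1, c("x", "y", "z")])), c(1, 2, 3))

  f3 <- withr::local_tempfile(fileext = ".pdb")
  block <- pdb_line(1, "C1'", "DA", "A", 1, 1, 2, 3)
  writeLines(c("MODEL        1", block, "ENDMDL",
               "MODEL        2", block, "ENDMDL",
               "MODEL        3", block, "ENDMDL", "END"), f3)
  expect_equal(n_models(read_structure(f3)), 3)
})

test_that("PDB and mmCIF serialisations of one model agree to 1e-3 Angstrom", {
  m <- kinked_model()
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, fp, "pdb")
  write_structure(m, fc, "mmcif")
  mp <- get_model(read_structure(fp), 1)
  mc <- get_model(read_structure(fc), 1)
  xyz <- function(x) as.matrix(x$atom[, c("x", "y", "z")])
  expect_lt(max(abs(xyz(mp) - xyz(m))), 1e-3)
  expect_lt(max(abs(xyz(mp) - xyz(mc))), 1e-3)
  expect_equal(mp$atom$elety, m$atom$elety)
  expect_equal(mp$atom$resno, m$atom$resno)
  expect_equal(mc$atom$resid, m$atom$resid)
})

test_that("multi-model write/read round trip preserves every snapshot", {
  ens <- simulate_roll_ensemble(kinked_profile(54), roll_sd = 8,
                                n_snapshots = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, f, "pdb")
  back <- read_structure(f, trajectory = TRUE)
  expect_equal(n_models(back), 3)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)
  # a generated duplex survives the file round trip with its pairing intact
  d0 <- find_duplexes(get_model(ens, 1))[[1]]
  d1 <- find_duplexes(get_model(back, 1))[[1]]
  expect_equal(d1$sequence_I, d0$sequence_I)
  expect_equal(nrow(d1$pairs), nrow(d0$pairs))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "C1'", "DA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
               pdb_line(2, "C1'", "DA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
               pdb_line(3, "N9", "DA", "A", 1, 1, 1, 1),
               "END"), f)
  m <- get_model(read_structure(f), 1)
  c1 <- m$atom[m$atom$elety == "C1'", ]
  expect_equal(nrow(c1), 1)
  expect_equal(c1$x, 9)
})

test_that("hydrogens are dropped on read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "C1'", "DA", "A", 1, 0, 0, 0),
               pdb_line(2, "H1'", "DA", "A", 1, 1, 1, 1),
               "END"), f)
  expect_equal(get_model(read_structure(f), 1)$atom$elety, "C1'")
})

test_that("residue classification follows the screening rules and is total", {
  expect_equal(classify_residue("DA", c("N9", "C8", "C1'")), "dna_nucleotide")
  expect_equal(classify_residue("A", c("N9", "C1'", "O2'")), "rna_nucleotide")
  expect_equal(classify_residue("A", c("N9", "C1'")), "dna_nucleotide")
  expect_equal(classify_residue("U", c("N1", "C1'")), "rna_nucleotide")
  expect_equal(classify_residue("5CM", c("N1", "C2", "N3", "C4", "C5", "C6")),
               "modified_nucleotide")
  expect_equal(classify_residue("LEU", c("N", "CA", "C", "O", "CB")),
               "amino_acid")
  expect_equal(classify_residue("HOH", "O"), "other")
  expect_equal(classify_residue("XQZ", c("ZN")), "other")
})

test_that("sidechain truncation keeps backbone (+CB for ALA) untouched", {
  m <- plant_intercalator(kinked_model(), 5, "MET", depth = 2.2)
  before <- m$atom[m$atom$chain == "P" & m$atom$elety %in%
                     c("N", "CA", "C", "O", "CB"), ]
  ala <- truncate_sidechain(m, list("P", 1), "ALA")
  pa <- ala$atom[ala$atom$chain == "P", ]
  expect_setequal(pa$elety, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(pa$resid), "ALA")
  expect_equal(as.matrix(pa[order(pa$elety), c("x", "y", "z")]),
               as.matrix(before[order(before$elety), c("x", "y", "z")]),
               ignore_attr = TRUE)

  gly <- truncate_sidechain(m, list("P", 1), "GLY")
  expect_setequal(gly$atom$elety[gly$atom$chain == "P"],
                  c("N", "CA", "C", "O"))
  expect_error(truncate_sidechain(gly, list("P", 1), "ALA"), "GLY")
  expect_error(truncate_sidechain(m, list("A", 1), "ALA"), "type error")
})
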