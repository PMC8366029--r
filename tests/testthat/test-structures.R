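minimal_pdb <- paste(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
  "ATOM      3  N   GLY A   2       0.000   3.000   0.000  1.00  0.00           N",
  "ATOM      4  CA  GLY A   2       1.500   3.000   0.000  1.00  0.00           C",
  "END", sep = "\n")

test_that("parse_pdb reads a minimal two-residue structure", {
  m <- parse_pdb(minimal_pdb)
  expect_s3_class(m, "pt_structure")
  expect_equal(nrow(m$atoms), 4L)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(sort(unique(m$atoms$resnum)), c(1L, 2L))
  expect_equal(m$atoms$x[2], 1.5)
  expect_false(any(m$atoms$is_hetero))
})

test_that("parse_pdb rejects empty and malformed input", {
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM")
  bad <- sub("   1.500", "   1.5x0", minimal_pdb, fixed = TRUE)
  expect_error(parse_pdb(bad), "line 2")
})

test_that("altloc resolution keeps highest occupancy, ties toward A", {
  two_alt <- paste(
    "ATOM      1  CA BALA A   1       0.000   0.000   0.000  0.70  0.00           C",
    "ATOM      2  CA AALA A   1       9.000   0.000   0.000  0.30  0.00           C",
    "END", sep = "\n")
  m <- parse_pdb(two_alt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$altloc, "B")  # higher occupancy wins
  tie <- paste(
    "ATOM      1  CA BALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "END", sep = "\n")
  m2 <- parse_pdb(tie)
  expect_equal(m2$atoms$altloc, "A")  # tie broken toward altloc A
})

test_that("select_ligand picks copies deterministically and validates codes", {
  spec <- toy_structure_spec(n_residues = 6, pocket_members = c(2, 5), seed = 3)
  m <- parse_pdb(make_toy_structure(spec))
  lig <- select_ligand(m, "LIG")
  expect_equal(nrow(lig), 4L)
  expect_true(all(lig$element != "H"))
  expect_error(select_ligand(m, "XYZ"), "available")
  expect_error(select_ligand(m, "HOH"), "water")

  # duplicate the het group at a second residue number to make two copies
  lines <- strsplit(make_toy_structure(spec), "\n")[[1L]]
  het <- grep("^HETATM", lines, value = TRUE)
  substr(het, 23L, 26L) <- " 901"
  m2 <- parse_pdb(paste(c(lines, het, "END"), collapse = "\n"))
  expect_warning(first <- select_ligand(m2, "LIG"), "copies")
  expect_equal(unique(first$resnum), 900L)
  second <- select_ligand(m2, "LIG", copy_index = 2)
  expect_equal(unique(second$resnum), 901L)
  expect_error(select_ligand(m2, "LIG", copy_index = 3), "out of range")
})

test_that("pocket_residues applies the distance cutoff exactly", {
  # one ligand atom at the origin; residues with single CB atoms at 4.9
  # and 5.1 angstroms
  txt <- paste(
    "ATOM      1  CB  ALA A   1       4.900   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       5.100   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  LIG A  90       0.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  m <- parse_pdb(txt)
  pk <- pocket_residues(m, select_ligand(m, "LIG"), cutoff_A = 5)
  expect_equal(pk$positions, 1L)
  expect_equal(pk$provenance, "distance")
})

test_that("pocket_residues errors when the ligand is isolated", {
  spec <- toy_structure_spec(n_residues = 5, pocket_members = integer(0),
                             seed = 8)
  m <- parse_pdb(make_toy_structure(spec))
  expect_error(pocket_residues(m, select_ligand(m, "LIG"), 5), "no pocket found")
  expect_error(pocket_residues(m, select_ligand(m, "LIG")[0, ], 5), "empty ligand")
})

test_that("hydrogens are excluded on both sides of the distance test", {
  txt <- paste(
    "ATOM      1  HB  ALA A   1       2.000   0.000   0.000  1.00  0.00           H",
    "ATOM      2  CB  ALA A   1       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   2       4.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG A  90       0.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  m <- parse_pdb(txt)
  pk <- pocket_residues(m, select_ligand(m, "LIG"), 5)
  # residue 1 only reaches via its hydrogen, so only residue 2 qualifies
  expect_equal(pk$positions, 2L)
})

test_that("pocket set is monotone in the cutoff and matches the brute-force oracle", {
  for (s in 1:12) {
    spec <- toy_structure_spec(n_residues = 12,
                               pocket_members = sample(12, sample(0:5, 1)),
                               seed = s)
    m <- parse_pdb(make_toy_structure(spec))
    lig <- select_ligand(m, "LIG")
    cuts <- c(3, 5, 8, 12)
    sets <- lapply(cuts, function(cc) {
      tryCatch(pocket_residues(m, lig, cc)$positions,
               error = function(e) integer(0))
    })
    for (k in seq_along(cuts)[-1]) {
      expect_true(all(sets[[k - 1]] %in% sets[[k]]))
    }
    for (k in seq_along(cuts)) {
      expect_identical(sets[[k]], brute_force_pocket(m, lig, cuts[k]))
    }
  }
})

test_that("pocket_residues is deterministic and serializes stably", {
  spec <- toy_structure_spec(n_residues = 9, pocket_members = c(1, 4, 9),
                             seed = 21)
  run <- function() {
    m <- parse_pdb(make_toy_structure(spec))
    write_pocket_json(pocket_residues(m, select_ligand(m, "LIG"), 5))
  }
  expect_identical(run(), run())
})

test_that("pocket JSON round-trips", {
  pk <- pocket_definition("1NAA", "A", 5, "ABL",
                          positions = c(10L, 20L, 30L),
                          provenance = c("distance", "literature", "distance"))
  pk2 <- read_pocket_json(write_pocket_json(pk))
  expect_equal(pk2$positions, pk$positions)
  expect_equal(pk2$provenance, pk$provenance)
  expect_equal(pk2$cutoff_A, 5)
})

test_that("pocket definitions validate their invariants", {
  expect_error(pocket_definition("x", "A", 5, "L", integer(0)), "non-empty")
  expect_error(pocket_definition("x", "A", 5, "L", c(3L, 2L)), "increasing")
  expect_error(pocket_definition("x", "A", -1, "L", 1L), "cutoff")
})

test_that("structure_to_sequence_map densifies author numbering", {
  spec <- toy_structure_spec(n_residues = 3, pocket_members = integer(0),
                             residue_numbers = c(10L, 11L, 15L), seed = 2)
  m <- parse_pdb(make_toy_structure(spec))
  map <- structure_to_sequence_map(m, "A")
  expect_equal(map, c(`10` = 1L, `11` = 2L, `15` = 3L))
  expect_error(structure_to_sequence_map(m, "B"), "unknown chain")

  # contiguous numbering gives the identity map
  spec2 <- toy_structure_spec(n_residues = 4, pocket_members = integer(0),
                              seed = 2)
  m2 <- parse_pdb(make_toy_structure(spec2))
  expect_equal(unname(structure_to_sequence_map(m2, "A")), 1:4)
})

test_that("insertion codes get their own dense index", {
  txt <- paste(
    "ATOM      1  CA  ALA A  52       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  52A      0.000   3.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A  53       0.000   6.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  map <- structure_to_sequence_map(parse_pdb(txt), "A")
  expect_equal(map, c(`52` = 1L, `52A` = 2L, `53` = 3L))
})

test_that("metal het groups are reported as context, never as positions", {
  txt <- paste(
    "ATOM      1  CB  ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 ZN    ZN A  95       0.000   2.000   0.000  1.00  0.00          ZN",
    "HETATM    3  C1  LIG A  90       0.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  m <- parse_pdb(txt)
  pk <- pocket_residues(m, select_ligand(m, "LIG"), 5)
  expect_equal(pk$positions, 1L)
  expect_match(attr(pk, "context_het"), "ZN")
})
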