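# Structure IO and geometric primitives.

mini_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.800  -1.200  1.00 90.00           N",
  "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00 90.00           C",
  "ATOM      3  CB  ALA A   1       0.000  -1.530   0.000  1.00 90.00           C",
  "ATOM      4  N   GLY A   2       3.800   0.800  -1.200  1.00 80.00           N",
  "ATOM      5  CA  GLY A   2       3.800   0.000   0.000  1.00 80.00           C",
  "END")

mini_cif_lines <- c(
  "data_mini",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
  "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
  "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . ALA A 1 1 ? 0.000 0.800 -1.200 1.00 90.00 1 ALA A N 1",
  "ATOM 2 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 90.00 1 ALA A CA 1",
  "ATOM 3 C CB . ALA A 1 1 ? 0.000 -1.530 0.000 1.00 90.00 1 ALA A CB 1",
  "ATOM 4 N N . GLY A 1 2 ? 3.800 0.800 -1.200 1.00 80.00 2 GLY A N 1",
  "ATOM 5 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 80.00 2 GLY A CA 1")

test_that("a hand-written two-residue PDB file parses into one chain, two residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mini_pdb_lines, f)
  s <- read_structure(f)
  expect_s3_class(s, "StructureModel")
  expect_equal(unique(s$atom$chain), "A")
  expect_equal(sort(unique(s$atom$resno)), c(1, 2))
  expect_equal(nrow(s$atom), 5)
  expect_equal(s$atom$b[s$atom$elety == "CA" & s$atom$resno == 1], 90)
})

test_that("the same content read as mmCIF matches the PDB read", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(mini_pdb_lines, fp)
  writeLines(mini_cif_lines, fc)
  sp <- read_structure(fp)
  sc <- read_structure(fc)
  expect_equal(sc$atom$resno, sp$atom$resno)
  expect_equal(sc$atom$elety, sp$atom$elety)
  expect_equal(sc$atom[, c("x", "y", "z")], sp$atom[, c("x", "y", "z")])
  expect_equal(sc$source_format, "mmCIF")
})

test_that("altloc policy keeps the highest-occupancy conformer, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 50.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 50.00           C",
    "ATOM      3  CB AALA A   1       0.000  -1.530   0.000  0.50 50.00           C",
    "ATOM      4  CB BALA A   1       1.000  -1.530   0.000  0.50 50.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atom), 2)
  expect_equal(s$atom$x[s$atom$elety == "CA"], 1.0)   # higher occupancy B
  expect_equal(s$atom$x[s$atom$elety == "CB"], 0.0)   # tie -> altloc A
})

test_that("read-write-read round trip preserves coordinates to PDB precision", {
  g <- gen_complex(10, 10, 5, 90, 60, 1, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g$model, f)
  s2 <- read_structure(f, predicted = TRUE)
  expect_equal(nrow(s2$atom), nrow(g$model$atom))
  expect_lt(max(abs(s2$atom$x - g$model$atom$x)), 5.5e-4)
  expect_lt(max(abs(s2$atom$y - g$model$atom$y)), 5.5e-4)
  expect_lt(max(abs(s2$atom$z - g$model$atom$z)), 5.5e-4)
  expect_equal(s2$atom$resno, g$model$atom$resno)
})

test_that("atom_distance is Euclidean, symmetric and zero on self", {
  s <- make_ca_structure(data.frame(chain = "A", resno = 1:3,
                                    x = c(0, 3, 1), y = c(0, 4, 1),
                                    z = c(0, 0, 5)))
  a1 <- atom_address("A", 1); a2 <- atom_address("A", 2); a3 <- atom_address("A", 3)
  expect_equal(atom_distance(s, a1, a1), 0)
  expect_equal(atom_distance(s, a1, a2), 5)
  expect_equal(atom_distance(s, a2, a1), atom_distance(s, a1, a2))
})

test_that("atom_distance satisfies the triangle inequality on random triples", {
  set.seed(11)
  df <- data.frame(chain = "A", resno = 1:30,
                   x = rnorm(30, sd = 10), y = rnorm(30, sd = 10),
                   z = rnorm(30, sd = 10))
  s <- make_ca_structure(df)
  for (k in 1:25) {
    ijk <- sample(30, 3)
    d12 <- atom_distance(s, atom_address("A", ijk[1]), atom_address("A", ijk[2]))
    d23 <- atom_distance(s, atom_address("A", ijk[2]), atom_address("A", ijk[3]))
    d13 <- atom_distance(s, atom_address("A", ijk[1]), atom_address("A", ijk[3]))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("unresolvable atom addresses raise informative lookup errors", {
  s <- make_ca_structure(data.frame(chain = "A", resno = 1:2,
                                    x = 0:1, y = 0, z = 0))
  expect_error(atom_distance(s, atom_address("A", 1, "CB"), atom_address("A", 2)),
               "atoms present")
  expect_error(atom_distance(s, atom_address("Z", 1), atom_address("A", 2)),
               "no chain")
})

test_that("kabsch superposition removes rigid motions exactly", {
  g <- gen_complex(12, 8, 4, 90, 60, 0, seed = 2)
  s <- g$model
  pairing <- data.frame(chain = "A", resno = 1:12, elety = "CA")
  # identity
  fit0 <- kabsch_superpose(s, s, pairing)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  # arbitrary rigid motion
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- transform_structure(s, R, c(4, -7, 2))
  fit <- kabsch_superpose(moved, s, pairing)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches the quaternion-method oracle on random pairs", {
  set.seed(5)
  for (rep in 1:5) {
    P <- matrix(rnorm(30, sd = 5), 10, 3)
    Q <- matrix(rnorm(30, sd = 5), 10, 3)
    fit <- abcscreen:::.kabsch(P, Q)
    expect_equal(fit$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("kabsch rmsd is invariant to pre-applied rigid motion of the mobile set", {
  set.seed(6)
  P <- matrix(rnorm(45, sd = 4), 15, 3)
  Q <- P + matrix(rnorm(45, sd = 0.3), 15, 3)
  base <- abcscreen:::.kabsch(P, Q)$rmsd
  th <- 0.4
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
              byrow = TRUE)
  P2 <- P %*% t(R) + matrix(c(10, -2, 6), 15, 3, byrow = TRUE)
  expect_equal(abcscreen:::.kabsch(P2, Q)$rmsd, base, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  line <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3, byrow = TRUE)
  expect_error(abcscreen:::.kabsch(line, line), "collinear")
  expect_error(abcscreen:::.kabsch(line[1:2, ], line[1:2, ]), "at least 3")
})
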