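test_that("synthetic PDB files parse with exact coordinates and altloc A kept", {
  atoms <- rbind(
    atom_row("A", 1, "GLY", "CA", 0, 0, 0),
    atom_row("A", 2, "ALA", "CA", 1.5, 2.25, -3.125),
    atom_row("A", 2, "ALA", "CB", 2, 2, 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(atoms, path)
  s <- read_structure(path)
  expect_identical(nrow(s$atoms), 3L)
  expect_equal(unlist(s$atoms[2, c("x", "y", "z")]),
               c(x = 1.5, y = 2.25, z = -3.125))
  # alternate locations: only conformer A survives
  atoms2 <- rbind(
    atom_row("A", 1, "SER", "CA", 0, 0, 0),
    atom_row("A", 1, "SER", "OG", 1, 0, 0, elem = "O", alt = "A"),
    atom_row("A", 1, "SER", "OG", 5, 0, 0, elem = "O", alt = "B"))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(atoms2, path2)
  s2 <- read_structure(path2)
  og <- s2$atoms[s2$atoms$elety == "OG", ]
  expect_identical(nrow(og), 1L)
  expect_equal(og$x, 1)
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "parse")
})

test_that("Cbeta distances follow plane geometry and glycine falls back to CA", {
  atoms <- rbind(
    atom_row("A", 1, "ALA", "CA", -1, 0, 0),
    atom_row("A", 1, "ALA", "CB", 0, 0, 0),
    atom_row("A", 2, "ALA", "CA", 2, 3, 0),
    atom_row("A", 2, "ALA", "CB", 3, 4, 0),
    atom_row("B", 3, "GLY", "CA", 0, 0, 12))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(atoms, path)
  s <- read_structure(path)
  expect_equal(cb_cb_distance(s, "A", 1, "A", 2), 5)       # 3-4-5 triangle
  expect_equal(cb_cb_distance(s, "A", 1, "A", 1), 0)
  expect_equal(cb_cb_distance(s, "A", 1, "B", 3), 12)      # glycine CA
  expect_error(cb_cb_distance(s, "A", 9, "A", 1), "not found")
})

test_that("minimal group distances equal the exhaustive pairwise minimum", {
  set.seed(11)
  n <- 8
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    atom_row("A", i, "ALA", "CB", runif(1, -9, 9), runif(1, -9, 9),
             runif(1, -9, 9))))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(atoms, path)
  s <- read_structure(path)
  A <- 1:4; B <- 5:8
  got <- min_group_distance(s, A, B)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  brute <- min(vapply(A, function(i) min(vapply(B, function(j)
    sqrt(sum((xyz[i, ] - xyz[j, ])^2)), numeric(1))), numeric(1)))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_error(min_group_distance(s, integer(0), B), "empty")
})

test_that("a bound fluorophore's contact distance to a quencher ring is recovered", {
  # synthetic arrangement: bimane-like hetero group 3.2 A from an indole atom
  atoms <- rbind(
    atom_row("A", 72, "TRP", "CA", 0, 0, 0),
    atom_row("A", 72, "TRP", "CD1", 1.4, 1.1, 0),
    atom_row("A", 72, "TRP", "NE1", 2.2, 2.1, 0.4, elem = "N"),
    atom_row("A", 135, "CYS", "CA", 8, 0, 0),
    atom_row("A", 900, "BIM", "C1", 2.2, 2.1, 3.6, het = TRUE),
    atom_row("A", 900, "BIM", "N2", 4.0, 3.0, 4.0, elem = "N", het = TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(atoms, path)
  s <- read_structure(path)
  d <- min_group_distance(s,
                          list(chain = "A", resno = 900),
                          list(chain = "A", resno = 72,
                               elety = c("CD1", "NE1")))
  expect_equal(d, 3.2, tolerance = 1e-9)
  expect_true(classify_pair(d, quencher_rule("Trp")))
})

test_that("quenching classification uses inclusive radii of 15 and 10 Angstrom", {
  expect_true(classify_pair(14.9, quencher_rule("Trp")))
  expect_true(classify_pair(15.0, quencher_rule("Trp")))
  expect_false(classify_pair(15.1, quencher_rule("Trp")))
  expect_false(classify_pair(10.1, quencher_rule("Tyr")))
  expect_true(classify_pair(10.0, quencher_rule("Tyr")))
})

test_that("Kabsch superposition recovers rigid motions and is zero on identity", {
  base <- synthetic_structure_atoms()
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(base, p1)
  s1 <- read_structure(p1)
  self <- superpose_rmsd(s1, s1)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- apply_rigid(base, R, c(11, -4, 2.5))
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(moved, p2)
  s2 <- read_structure(p2)
  sup <- superpose_rmsd(s1, s2)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)
  expect_identical(sup$n_atoms, 6L)
  expect_error(superpose_rmsd(s1, read_structure(p2, model_id = "x"),
                              selection = "ZZ"), "3 common")
})

test_that("distances are invariant under random rigid motions", {
  base <- synthetic_structure_atoms()
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(base, p1)
  s1 <- read_structure(p1)
  d0 <- cb_cb_distance(s1, "A", 1, "A", 5)
  set.seed(3)
  for (i in 1:20) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    moved <- apply_rigid(base, R, rnorm(3, 0, 20))
    s2 <- s1
    s2$atoms[, c("x", "y", "z")] <- moved[, c("x", "y", "z")]
    expect_lt(abs(cb_cb_distance(s2, "A", 1, "A", 5) - d0), 1e-9)
    expect_lt(abs(min_group_distance(s2, 1:3, 8:10) -
                    min_group_distance(s1, 1:3, 8:10)), 1e-9)
  }
})

test_that("state-to-state pair deltas classify approach and separation", {
  closed <- synthetic_structure_atoms()
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(closed, p1)
  sA <- read_structure(p1)
  # move residue 6 two Angstrom closer to residue 1 along x
  open <- closed
  sel <- open$resno == 6
  open$x[sel] <- open$x[sel] - 2
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(open, p2)
  sB <- read_structure(p2)
  pairs <- data.frame(chainA = "A", resA = c(1, 2), chainB = "A",
                      resB = c(6, 3))
  rep <- pair_distance_delta(sA, sB, pairs)
  expect_equal(rep$delta[1], -2, tolerance = 1e-9)
  expect_identical(rep$classification[1], "approach")
  expect_identical(rep$classification[2], "unchanged")
  same <- pair_distance_delta(sA, sA, pairs)
  expect_true(all(same$classification == "unchanged"))
})
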