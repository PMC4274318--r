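test_that("PDB write/read round-trip is lossless for all modelled fields", {
  d <- make_toy_dimer(fixture_spec())
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, tf)
  d2 <- read_pdb(tf)
  expect_equal(n_atoms(d2), n_atoms(d))
  expect_equal(coords(d2), coords(d), tolerance = 1e-3)
  expect_equal(d2$atoms$name, d$atoms$name)
  expect_equal(d2$atoms$resname, d$atoms$resname)
  expect_equal(d2$atoms$segid, d$atoms$segid)
  expect_equal(d2$atoms$resid, d$atoms$resid)
  # strictly increasing serials, terminal END, no tabs
  lines <- readLines(tf)
  expect_identical(lines[length(lines)], "END")
  expect_false(any(grepl("\t", lines)))
  ser <- as.integer(substr(lines[-length(lines)], 7, 11))
  expect_true(all(diff(ser) > 0))
})

test_that("reader ignores model bookkeeping lines and drops HETATM by default", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "NUMMDL    2",
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00      A    C",
    "TER",
    "HETATM    2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00      A    O",
    "ENDMDL",
    "END"), tf)
  s <- read_pdb(tf)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$atoms$name, "CA")
  s2 <- read_pdb(tf, keep_hetatm = TRUE)
  expect_equal(n_atoms(s2), 2L)
})

test_that("SPIN dialect: fixed columns, 4-char names and resnames, segid 73-76", {
  n1 <- matrix(rnorm(30, 0, 5), 10, 3)
  conf <- lapply(seq_len(10), function(i) {
    structure(list(xyz = rbind(N1 = n1[i, ]), clash_score = 0, n1 = n1[i, ]),
              class = "label_conformer")
  })
  e <- extract_n1_ensemble(conf, resid_out = 1, segid_out = "S")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_spin_ensemble_pdb(e, tf)
  lines <- readLines(tf)
  expect_identical(lines[length(lines)], "END")
  rec <- lines[1:10]
  expect_identical(substr(rec[1], 13, 16), "N001")
  expect_identical(substr(rec[10], 13, 16), "N010")
  expect_identical(unique(substr(rec, 18, 21)), "SPIN")
  expect_identical(unique(substr(rec, 73, 76)), "S   ")
  back <- read_pdb(tf)
  expect_equal(back$atoms$name, sprintf("N%03d", 1:10))
  expect_equal(unname(coords(back)), unname(n1), tolerance = 1e-3)
})

test_that("reader and writer reject what the workflow never produces", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A", tf)   # truncated record
  expect_error(read_pdb(tf), "line 1")
  writeLines(c("REMARK nothing"), tf)
  expect_error(read_pdb(tf), "no ATOM records")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "no such file")
  writeLines(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00",
    tf)
  expect_error(read_pdb(tf), "alternate location")
  s <- make_structure("TOOLONGX", "ALA", "A", 1, matrix(0, 1, 3))
  expect_error(write_pdb(s, tf), "4 characters")
  s2 <- make_structure(c("CA", "CA"), "ALA", "A", c(1, 1), matrix(0, 2, 3))
  expect_error(write_pdb(s2, tf), "duplicate atom name")
})

test_that("segid supersedes chain and falls back to chain when blank", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00      XY",
    "ATOM      2  CA  ALA B   2       1.000   0.000   0.000  1.00  0.00",
    "END"), tf)
  s <- read_pdb(tf)
  expect_equal(s$atoms$segid, c("XY", "B"))
  expect_equal(select_atoms(s, "segid XY"), 1L)
})

test_that("selection language matches segid/resid ranges/name globs", {
  d <- make_toy_dimer(fixture_spec())
  # SPIN residues 1..3 on segid S
  n1 <- matrix(rnorm(9), 3, 3)
  for (r in 1:3) {
    conf <- list(structure(list(xyz = rbind(N1 = n1[r, ]), clash_score = 0,
                                n1 = n1[r, ]), class = "label_conformer"))
    d <- add_spin_ensemble(d, extract_n1_ensemble(conf, r, "S"))
  }
  i1 <- select_atoms(d, "segid S and resid 1")
  expect_equal(d$atoms$resid[i1], 1L)
  expect_equal(d$atoms$segid[i1], "S")
  expect_length(select_atoms(d, "segid S and name N*"), 3L)
  expect_length(select_atoms(d, "not (resid 1:999999)"), 0L)
  expect_error(select_atoms(d, "bogus CA"), "unknown field")
})

test_that("CA range selection count matches brute force on a full-length chain", {
  resid <- 4:225
  s <- make_structure(rep("CA", length(resid)), "ALA", "A", resid,
                      cbind(resid, 0, 0))
  got <- select_atoms(s, "name CA and resid 10:225 and not resid 129:136")
  want <- which(resid >= 10 & resid <= 225 & !(resid >= 129 & resid <= 136))
  expect_equal(got, want)
  expect_length(got, 216 - 8)
})

test_that("selection algebra obeys De Morgan identities on random structures", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    s <- make_structure(
      name = sample(c("CA", "CB", "N", "O"), n, TRUE),
      resname = sample(c("ALA", "PHE"), n, TRUE),
      segid = sample(c("A", "B"), n, TRUE),
      resid = sample(1:9, n, TRUE),
      xyz = random_points(n))
    a <- "segid A and resid 1:4"
    b <- "name C*"
    lhs <- select_atoms(s, sprintf("not ((%s) or (%s))", a, b))
    rhs <- select_atoms(s, sprintf("(not (%s)) and (not (%s))", a, b))
    expect_identical(lhs, rhs)
    lhs2 <- select_atoms(s, sprintf("not ((%s) and (%s))", a, b))
    rhs2 <- select_atoms(s, sprintf("(not (%s)) or (not (%s))", a, b))
    expect_identical(lhs2, rhs2)
  }
})

test_that("apply_transform moves only the selection and preserves rigidity", {
  d <- make_toy_dimer(fixture_spec())
  X0 <- coords(d)
  moved <- apply_transform(d, "segid A", translation = c(0, 100, 0))
  ia <- select_atoms(d, "segid A"); ib <- select_atoms(d, "segid B")
  expect_equal(coords(moved)[ia, 2], X0[ia, 2] + 100)
  expect_equal(coords(moved)[ib, ], X0[ib, ])
  # identity is a no-op
  expect_equal(coords(apply_transform(d, "all")), X0)
  # inverse composition returns exactly
  R <- rotation_about_axis(c(1, 2, 3), 1.1)
  fwd <- apply_transform(d, "segid A", rotation = R, translation = c(3, -4, 5))
  back <- apply_transform(fwd, "segid A", rotation = t(R),
                          translation = -as.vector(t(R) %*% c(3, -4, 5)))
  expect_lt(max(abs(coords(back) - X0)), 1e-9)
  # rigidity: intra-selection distances preserved
  pick <- sample(ia, 10)
  expect_lt(max(abs(dist(coords(fwd)[pick, ]) - dist(X0[pick, ]))), 1e-9)
  expect_error(apply_transform(d, "all", rotation = diag(3) * 2),
               "orthonormal")
})

test_that("written files agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  d <- make_toy_dimer(fixture_spec())
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d, tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ref$atom), n_atoms(d))
  expect_equal(as.numeric(ref$atom$x), d$atoms$x, tolerance = 1e-3)
  expect_equal(trimws(ref$atom$resid), d$atoms$resname)
  expect_equal(as.integer(ref$atom$resno), d$atoms$resid)
})
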