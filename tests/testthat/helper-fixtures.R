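# Shared in-code fixtures for the test suite.

# bare structure from an atom table sketch
make_structure <- function(name, resname, segid, resid, xyz,
                           chain = substr(segid, 1, 1)) {
  atoms <- data.frame(
    serial = seq_along(name), name = name, resname = resname,
    chain = chain, resid = as.integer(resid),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b = 0, segid = segid,
    element = spindock:::infer_element(name),
    stringsAsFactors = FALSE)
  spindock:::new_structure(atoms)
}

# a lone exposed poly-alanine helix with a labelling site mid-chain
exposed_helix <- function(n_res = 9) {
  spindock:::helix_chain(n_res, "A", "A", 0, 0, rep("ALA", n_res))
}

# minimal two-point-body system: two singleton SPIN ensembles at distance d
point_body_system <- function(d = 50) {
  s <- make_structure(
    name = c("N001", "N001"), resname = "SPIN",
    segid = c("S", "T"), resid = c(1L, 1L),
    xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
  groups <- list(rigid_group("a", "segid S"), rigid_group("b", "segid T"))
  restraints <- list(distance_restraint("segid S and resid 1 and name N*",
                                        "segid T and resid 1 and name N*",
                                        33, 2, 2))
  build_dock_system(s, groups, restraints)
}

# random non-degenerate point cloud
random_points <- function(n, scale = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3 * n, 0, scale), n, 3)
}

expect_rel_error <- function(got, want, tol) {
  expect_lt(max(abs(got - want)) / max(max(abs(want)), 1e-10), tol)
}
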