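## Synthetic test fixtures.
##
## Everything is generated in code: idealised helical chains (rise 1.5 A,
## ~100 degree twist) with full backbones, poly-alanine plus a few PHE/TYR/
## LEU interface residues for torsion tests; a D2-symmetric planted
## "dimer-of-dimers" assembly (the dimer's internal 2-fold about z, the
## planted tetramer 2-fold about x) so that cross-body NCS equivalence
## groups are exactly satisfiable at the truth pose; spin-label ensembles at
## chosen sites; and restraint tables computed from the truth pose with
## controllable Gaussian noise. The docking start point separates the second
## body by a large translation (default 100 A along y), optionally with a
## random rotational perturbation.

#' Fixture specification
#'
#' @param n_res residues per chain (>= 5).
#' @param segids two segment ids for the dimer chains.
#' @param interface named integer vector: residue positions carrying
#'   non-alanine side chains, named by residue type
#'   (default PHE/LEU/TYR/LEU at spread positions).
#' @param planted_rotation,planted_translation the planted inter-dimer
#'   transform (defaults: 2-fold rotation about x, zero translation, giving
#'   an exact D2 assembly).
#' @param separation start-point translation applied to the second body
#'   (default `c(0, 100, 0)`).
#' @param noise_sd restraint noise s.d. in Angstrom.
#' @param rng_seed integer seed.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_res = 30, segids = c("A", "B"),
                         interface = NULL,
                         planted_rotation = rotation_about_axis(c(1, 0, 0), pi),
                         planted_translation = c(0, 0, 0),
                         separation = c(0, 100, 0),
                         noise_sd = 0, rng_seed = 1) {
  if (n_res < 5) stop("n_res must be >= 5")
  if (!is_rotation_matrix(planted_rotation)) {
    stop("planted rotation must be a proper rotation matrix")
  }
  if (is.null(interface)) {
    q <- round(n_res * c(0.3, 0.45, 0.6, 0.75))
    interface <- stats::setNames(q, c("PHE", "LEU", "TYR", "LEU"))
  }
  structure(list(n_res = as.integer(n_res), segids = segids,
                 interface = interface,
                 planted_rotation = planted_rotation,
                 planted_translation = planted_translation,
                 separation = separation,
                 noise_sd = noise_sd, rng_seed = rng_seed),
            class = "fixture_spec")
}

## side-chain internal coordinates (bond, angle, dihedral or chi reference)
SIDECHAIN_ICS <- list(
  LEU = list(
    list(name = "CG",  refs = c("N", "CA", "CB"),  bond = 1.53, angle = 114, dih = "chi1"),
    list(name = "CD1", refs = c("CA", "CB", "CG"), bond = 1.53, angle = 111, dih = "chi2"),
    list(name = "CD2", refs = c("CA", "CB", "CG"), bond = 1.53, angle = 111, dih = "chi2+120")),
  PHE = list(
    list(name = "CG",  refs = c("N", "CA", "CB"),  bond = 1.51, angle = 114, dih = "chi1"),
    list(name = "CD1", refs = c("CA", "CB", "CG"), bond = 1.40, angle = 120, dih = "chi2"),
    list(name = "CD2", refs = c("CA", "CB", "CG"), bond = 1.40, angle = 120, dih = "chi2+180"),
    list(name = "CE1", refs = c("CB", "CG", "CD1"), bond = 1.40, angle = 120, dih = 180),
    list(name = "CE2", refs = c("CB", "CG", "CD2"), bond = 1.40, angle = 120, dih = 180),
    list(name = "CZ",  refs = c("CG", "CD1", "CE1"), bond = 1.40, angle = 120, dih = 0)),
  ALA = list()
)
SIDECHAIN_ICS$TYR <- c(SIDECHAIN_ICS$PHE,
                       list(list(name = "OH", refs = c("CD1", "CE1", "CZ"),
                                 bond = 1.36, angle = 120, dih = 180)))

build_side_chain <- function(resname, pos, chi1 = -65, chi2 = 95) {
  if (resname == "GLY") return(pos)
  ics <- SIDECHAIN_ICS[[resname]]
  if (is.null(ics)) stop("no side-chain template for ", resname)
  pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.5, 122.5)
  if (length(ics) == 0) return(pos)
  for (a in ics) {
    dih <- if (is.character(a$dih)) {
      switch(a$dih,
             "chi1" = chi1, "chi2" = chi2,
             "chi2+120" = chi2 + 120, "chi2+180" = chi2 + 180)
    } else a$dih
    pos[[a$name]] <- place_atom(pos[[a$refs[1]]], pos[[a$refs[2]]],
                                pos[[a$refs[3]]], a$bond, a$angle, dih)
  }
  pos
}

## idealised helical chain along +x, axis passing through (0, y0, z0)
helix_chain <- function(n_res, segid, chain, y0, z0, resnames) {
  r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  i <- seq_len(n_res + 2L) - 1L            # two extra for end frames
  ca <- cbind(i * rise, y0 + r * cos(i * twist), z0 + r * sin(i * twist))
  ca[, 1] <- ca[, 1] - mean(ca[, 1])       # centre the span on x = 0
  rows <- list()
  for (k in seq_len(n_res)) {
    j <- k + 1L                            # index into padded CA trace
    CA <- ca[j, ]
    N <- CA + 0.384 * (ca[j - 1L, ] - CA)
    C <- CA + 0.400 * (ca[j + 1L, ] - CA)
    radial <- c(0, C[2] - y0, C[3] - z0)
    O <- C + 1.23 * unitv(radial)
    pos <- list(N = N, CA = CA, C = C, O = O)
    resname <- resnames[k]
    pos <- build_side_chain(resname, pos)
    for (nm in names(pos)) {
      rows[[length(rows) + 1]] <- data.frame(
        serial = length(rows) + 1L, name = nm, resname = resname,
        chain = chain, resid = k,
        x = pos[[nm]][1], y = pos[[nm]][2], z = pos[[nm]][3],
        occ = 1, b = 0, segid = segid, element = infer_element(nm),
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), provenance = "toy_helix")
}

#' Generate a toy two-chain dimer
#'
#' Two antiparallel idealised helices related by an exact internal 2-fold
#' about the z axis, poly-alanine with PHE/LEU/TYR side chains at the
#' interface positions. Full backbone (N, CA, C, O) throughout.
#'
#' @param spec a `fixture_spec`.
#' @return a `pdb_structure` with chains/segids `A` and `B` (taken from
#'   `spec$segids`).
#' @export
make_toy_dimer <- function(spec = fixture_spec()) {
  resnames <- rep("ALA", spec$n_res)
  resnames[spec$interface] <- names(spec$interface)
  a <- helix_chain(spec$n_res, spec$segids[1], substr(spec$segids[1], 1, 1),
                   y0 = 7, z0 = 6, resnames)
  b <- a
  b$atoms$segid <- spec$segids[2]
  b$atoms$chain <- substr(spec$segids[2], 1, 1)
  b <- apply_transform(b, "all",
                       rotation = rotation_about_axis(c(0, 0, 1), pi))
  merge_structures(a, b)
}

#' Plant a symmetric tetramer and its docking start point
#'
#' Duplicates the dimer into segids C and D, applies the planted transform
#' to the copy (default: the 2-fold about x that completes an exact D2
#' assembly), then applies the large separation translation to create the
#' docking start point. Returns the ground truth alongside.
#'
#' @param spec a `fixture_spec`.
#' @return list with `truth` (assembled tetramer), `start` (second body
#'   separated), `truth_rotation`, `truth_translation` and the
#'   `body2_selection` string.
#' @export
plant_tetramer <- function(spec = fixture_spec()) {
  dimer <- make_toy_dimer(spec)
  copy <- dimer
  map <- stats::setNames(c("C", "D"), spec$segids)
  copy$atoms$segid <- unname(map[copy$atoms$segid])
  copy$atoms$chain <- copy$atoms$segid
  copy <- apply_transform(copy, "all", rotation = spec$planted_rotation,
                          translation = spec$planted_translation)
  truth <- merge_structures(dimer, copy)
  d2 <- cross_distances(coords(dimer), coords(copy))
  if (min(d2) < 1.0) {
    warning("planted transform causes severe initial overlap between bodies")
  }
  body2 <- "segid C or segid D"
  start <- apply_transform(truth, body2, translation = spec$separation)
  list(truth = truth, start = start,
       truth_rotation = spec$planted_rotation,
       truth_translation = spec$planted_translation,
       body2_selection = body2)
}

#' Synthesise a restraint set from a truth pose
#'
#' Computes ensemble-averaged effective distances on the ground-truth
#' structure for each selection pair, perturbs the targets with Gaussian
#' noise of s.d. `noise_sd`, and sets both bounds to
#' `max(noise_sd, 0.1)` Angstrom.
#'
#' @param truth labelled ground-truth `pdb_structure` (spin ensembles
#'   attached).
#' @param pairs data.frame with columns `sel_a`, `sel_b` (selection
#'   strings); by default all cross pairs of SPIN residues between segids
#'   S and T.
#' @param noise_sd Gaussian noise s.d. in Angstrom.
#' @param seed RNG seed for the noise draws.
#' @param averaging averaging mode (default R-3).
#' @return list of `distance_restraint`.
#' @export
synth_restraints <- function(truth, pairs = NULL, noise_sd = 0, seed = NULL,
                             averaging = "R-3") {
  a <- truth$atoms
  if (is.null(pairs)) {
    rs <- sort(unique(a$resid[a$segid == "S" & toupper(a$resname) == "SPIN"]))
    rt <- sort(unique(a$resid[a$segid == "T" & toupper(a$resname) == "SPIN"]))
    if (length(rs) == 0 || length(rt) == 0) {
      stop("truth structure carries no SPIN ensembles in segids S and T")
    }
    pairs <- expand.grid(i = rs, j = rt)
    pairs <- data.frame(
      sel_a = sprintf("segid S and resid %d and name N*", pairs$i),
      sel_b = sprintf("segid T and resid %d and name N*", pairs$j),
      stringsAsFactors = FALSE)
  }
  X <- coords(truth)
  d_true <- vapply(seq_len(nrow(pairs)), function(k) {
    ia <- select_atoms(truth, pairs$sel_a[k])
    ib <- select_atoms(truth, pairs$sel_b[k])
    effective_distance(X[ia, , drop = FALSE], X[ib, , drop = FALSE], averaging)
  }, numeric(1))
  noise <- with_seed(seed, rnorm(nrow(pairs), 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, nrow(pairs))
  bound <- max(noise_sd, 0.1)
  lapply(seq_len(nrow(pairs)), function(k) {
    distance_restraint(pairs$sel_a[k], pairs$sel_b[k],
                       target = d_true[k] + noise[k],
                       minus = bound, plus = bound,
                       label = sprintf("synthetic pair %d", k))
  })
}

## default label sites used by the planted-tetramer docking fixture
fixture_label_sites <- function(n_res) {
  pos <- round(n_res * c(0.25, 0.7))
  list(body1 = list(c("A", pos[1]), c("A", pos[2]),
                    c("B", pos[1]), c("B", pos[2])),
       body2 = list(c("C", pos[1]), c("C", pos[2]),
                    c("D", pos[1]), c("D", pos[2])))
}

#' Complete planted-tetramer docking fixture
#'
#' Builds the D2-symmetric truth assembly, attaches R1 spin ensembles at
#' standard sites on both bodies (segid `S` for body 1, `T` for body 2),
#' synthesises the restraint table from the truth pose, and creates the
#' docking start point by separating body 2 (plus an optional random
#' rotational perturbation). Also returns the rigid groups and the two
#' cross-body NCS equivalence groups.
#'
#' @param seed RNG seed controlling label sampling, restraint noise and the
#'   start perturbation.
#' @param spec a `fixture_spec`.
#' @param perturb_deg maximum random start rotation of body 2, degrees.
#' @param max_conformers,thoroughness label-sampler settings (kept small for
#'   fixture speed).
#' @return list with `start`, `truth` (both labelled), `restraints`,
#'   `groups`, `ncs`, `body2_selection`.
#' @export
dock_fixture <- function(seed = 1, spec = fixture_spec(rng_seed = seed),
                         perturb_deg = 10, max_conformers = 15,
                         thoroughness = 300) {
  pt <- plant_tetramer(spec)
  truth <- pt$truth
  sites <- fixture_label_sites(spec$n_res)
  attach_sites <- function(s, site_list, segid_out) {
    for (k in seq_along(site_list)) {
      st <- site_list[[k]]
      site <- label_site(st[1], as.integer(st[2]), "R1")
      p <- sampler_params(max_conformers = max_conformers,
                          thoroughness = thoroughness,
                          rng_seed = seed * 1000 + k +
                            if (segid_out == "T") 500 else 0)
      conf <- search_r1_conformers(s, site, p)
      s <- add_spin_ensemble(s, extract_n1_ensemble(conf, k, segid_out))
    }
    s
  }
  truth <- attach_sites(truth, sites$body1, "S")
  truth <- attach_sites(truth, sites$body2, "T")
  restraints <- synth_restraints(truth, noise_sd = spec$noise_sd,
                                 seed = seed + 77)
  body2 <- "segid C or segid D or segid T"
  start <- truth
  if (perturb_deg > 0) {
    rp <- with_seed(seed + 31, {
      ax <- rnorm(3); ang <- runif(1, 0, perturb_deg * pi / 180)
      list(ax = ax, ang = ang)
    })
    idx <- select_atoms(start, body2)
    ctr <- colMeans(coords(start)[idx, , drop = FALSE])
    R <- rotation_about_axis(rp$ax, rp$ang)
    start <- apply_transform(start, body2, rotation = R,
                             translation = ctr - as.vector(R %*% ctr))
  }
  start <- apply_transform(start, body2, translation = spec$separation)
  groups <- list(rigid_group("body1", "segid A or segid B or segid S"),
                 rigid_group("body2", body2))
  ncs <- list(
    ncs_group(list("(segid A or segid D) and name CA",
                   "(segid B or segid C) and name CA")),
    ncs_group(list("(segid A or segid C) and name CA",
                   "(segid B or segid D) and name CA")))
  list(start = start, truth = truth, restraints = restraints,
       groups = groups, ncs = ncs, body2_selection = body2)
}

#' Relative-pose recovery error
#'
#' Superposes the final body-1 CA set onto the truth body-1 CA set, applies
#' that frame correction to the final body-2 CA set, and reports the
#' residual rotation angle (degrees) and centroid displacement (Angstrom)
#' of body 2 relative to truth.
#'
#' @param final,truth `pdb_structure`s with identical atom ordering.
#' @param body1_sel,body2_sel selections of the two bodies' CA atoms.
#' @return list with `rot_deg` and `trans_A`.
#' @export
pose_recovery_error <- function(final, truth,
                                body1_sel = "(segid A or segid B) and name CA",
                                body2_sel = "(segid C or segid D) and name CA") {
  i1 <- select_atoms(truth, body1_sel)
  i2 <- select_atoms(truth, body2_sel)
  Xf <- coords(final); Xt <- coords(truth)
  f1 <- kabsch_superpose(Xt[i1, , drop = FALSE], Xf[i1, , drop = FALSE])
  b2 <- Xf[i2, , drop = FALSE] %*% t(f1$rotation) +
    matrix(f1$translation, length(i2), 3, byrow = TRUE)
  f2 <- kabsch_superpose(Xt[i2, , drop = FALSE], b2)
  list(rot_deg = rotation_angle(f2$rotation) * 180 / pi,
       trans_A = vnorm(colMeans(b2) - colMeans(Xt[i2, , drop = FALSE])))
}
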