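## Interface side-chain torsion refinement.
##
## After the rigid stages the bodies keep their internal geometry; side
## chains near the new interface are then relaxed by minimisation over their
## chi dihedrals (coordinate descent: a coarse grid scan per angle followed
## by local bisection). Backbone atoms (N, CA, C, O and their hydrogens)
## never move, residues outside the flexible ranges stay rigid, ring
## moieties of PHE/HIS/TYR/TRP rotate only as rigid units (their internal
## geometry is exactly preserved, since no intra-ring torsion is sampled)
## and PRO is fully rigid. The driving energy is the physical non-bonded
## term (repel 0: LJ + Coulomb), with electrostatics weighted to zero for
## intra-body pairs so that the term cannot dominate packing.

## chi dihedrals per residue type: the four defining atoms and the atoms
## that rotate (everything distal to the bond c-d). Ring moieties appear
## only as rigid blocks rotated by chi1/chi2.
CHI_DEFS <- list(
  SER = list(list(atoms = c("N", "CA", "CB", "OG"), moves = c("OG"))),
  CYS = list(list(atoms = c("N", "CA", "CB", "SG"), moves = c("SG"))),
  THR = list(list(atoms = c("N", "CA", "CB", "OG1"), moves = c("OG1", "CG2"))),
  VAL = list(list(atoms = c("N", "CA", "CB", "CG1"), moves = c("CG1", "CG2"))),
  ILE = list(list(atoms = c("N", "CA", "CB", "CG1"), moves = c("CG1", "CG2", "CD1")),
             list(atoms = c("CA", "CB", "CG1", "CD1"), moves = c("CD1"))),
  LEU = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "CD1", "CD2")),
             list(atoms = c("CA", "CB", "CG", "CD1"), moves = c("CD1", "CD2"))),
  ASP = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "OD1", "OD2")),
             list(atoms = c("CA", "CB", "CG", "OD1"), moves = c("OD1", "OD2"))),
  ASN = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "OD1", "ND2")),
             list(atoms = c("CA", "CB", "CG", "OD1"), moves = c("OD1", "ND2"))),
  GLU = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "CD", "OE1", "OE2")),
             list(atoms = c("CA", "CB", "CG", "CD"), moves = c("CD", "OE1", "OE2")),
             list(atoms = c("CB", "CG", "CD", "OE1"), moves = c("OE1", "OE2"))),
  GLN = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "CD", "OE1", "NE2")),
             list(atoms = c("CA", "CB", "CG", "CD"), moves = c("CD", "OE1", "NE2")),
             list(atoms = c("CB", "CG", "CD", "OE1"), moves = c("OE1", "NE2"))),
  MET = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "SD", "CE")),
             list(atoms = c("CA", "CB", "CG", "SD"), moves = c("SD", "CE")),
             list(atoms = c("CB", "CG", "SD", "CE"), moves = c("CE"))),
  LYS = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "CD", "CE", "NZ")),
             list(atoms = c("CA", "CB", "CG", "CD"), moves = c("CD", "CE", "NZ")),
             list(atoms = c("CB", "CG", "CD", "CE"), moves = c("CE", "NZ")),
             list(atoms = c("CG", "CD", "CE", "NZ"), moves = c("NZ"))),
  ARG = list(list(atoms = c("N", "CA", "CB", "CG"), moves = c("CG", "CD", "NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CA", "CB", "CG", "CD"), moves = c("CD", "NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CB", "CG", "CD", "NE"), moves = c("NE", "CZ", "NH1", "NH2")),
             list(atoms = c("CG", "CD", "NE", "CZ"), moves = c("CZ", "NH1", "NH2"))),
  PHE = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "CE1", "CE2", "CZ"))),
  TYR = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH"))),
  HIS = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "ND1", "CD2", "CE1", "NE2")),
             list(atoms = c("CA", "CB", "CG", "ND1"),
                  moves = c("ND1", "CD2", "CE1", "NE2"))),
  TRP = list(list(atoms = c("N", "CA", "CB", "CG"),
                  moves = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
             list(atoms = c("CA", "CB", "CG", "CD1"),
                  moves = c("CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))),
  PRO = list(),  # pseudo-cyclic: fully rigid
  ALA = list(),
  GLY = list()
)

#' Torsion-refinement configuration
#'
#' @param flexible named list: for each segid, an integer vector of residue
#'   numbers whose side chains may move (e.g.
#'   `list(A = c(57:84, 165:180))`). Residues not listed stay rigid.
#' @param nstep energy-evaluation budget (default 2000).
#' @param depred target energy-decrease scale per sweep, kcal/mol (stop when
#'   a full sweep improves by less); default 1.
#' @param maxe energy-evaluation budget per sweep (default 1000).
#' @param grid_step coarse chi grid spacing in degrees (default 30).
#' @return a `torsion_config`.
#' @export
torsion_config <- function(flexible, nstep = 2000, depred = 1, maxe = 1000,
                           grid_step = 30) {
  structure(list(flexible = flexible, nstep = as.integer(nstep),
                 depred = depred, maxe = as.integer(maxe),
                 grid_step = grid_step),
            class = "torsion_config")
}

residue_atom_index <- function(atoms, segid, resid) {
  idx <- which(atoms$segid == segid & atoms$resid == resid)
  stats::setNames(idx, atoms$name[idx])
}

## rotate `move_idx` atoms about the axis p1 -> p2 by angle (deg)
rotate_about_bond <- function(X, move_idx, p1, p2, angle_deg) {
  R <- rotation_about_axis(p2 - p1, angle_deg * pi / 180)
  X[move_idx, ] <- sweep(sweep(X[move_idx, , drop = FALSE], 2, p1) %*% t(R),
                         2, p1, "+")
  X
}

## local non-bonded energy of a residue's movable side chain against its
## environment (all interacting atoms outside the residue within reach)
torsion_local_energy <- function(X, move_idx, env, params, nb, elec_w) {
  xm <- X[move_idx, , drop = FALSE]
  xe <- X[env$idx, , drop = FALSE]
  d2 <- outer(rowSums(xm^2), rowSums(xe^2), "+") - 2 * xm %*% t(xe)
  inside <- d2 < nb$ctofnb^2
  if (!any(inside)) return(0)
  hit <- which(inside, arr.ind = TRUE)
  i <- move_idx[hit[, 1]]; j <- env$idx[hit[, 2]]
  pl <- data.frame(i = i, j = j, weight = 1, elec = elec_w[hit[, 2]])
  lj_coulomb_energy(pl, X, params, nb)$energy
}

#' Refine interface side-chain torsions
#'
#' Coordinate descent over the chi angles of the flexible residues: each
#' angle in turn is scanned on a coarse grid and polished locally, accepting
#' only energy-decreasing moves; sweeps repeat until the improvement falls
#' below `depred` or the evaluation budget `nstep` is spent. Backbone and
#' rigid-range atoms are fixed; ring moieties move only as rigid units; PRO
#' is never moved. Residues whose type has no chi table entry raise an
#' error.
#'
#' @param s a `pdb_structure` (post-rigid-stage coordinates).
#' @param tc a `torsion_config`.
#' @param groups list of `rigid_group` used to tell intra-body pairs
#'   (electrostatics weight 0) from inter-body pairs (full weight).
#' @param ncs,restraints,rparams carried through for the reported breakdown
#'   (side-chain torsions cannot move CA or SPIN atoms, so these terms are
#'   constant during this stage).
#' @param nb a `nonbonded_params`; evaluation uses `repel = 0`
#'   (LJ + Coulomb).
#' @return list with the refined `structure`, `pre`/`post` breakdowns and
#'   the accepted-energy `trace`.
#' @export
torsion_refine <- function(s, tc, groups = list(), ncs = list(),
                           restraints = list(),
                           rparams = restraint_params(),
                           nb = nonbonded_params()) {
  atoms <- s$atoms
  X <- coords(s)
  params <- assign_params(s)
  nb$repel <- 0

  ## body id per atom (0 = none), for the intra-body elec 0 rule
  body <- integer(nrow(atoms))
  for (g in seq_along(groups)) {
    body[select_atoms(s, groups[[g]]$members)] <- g
  }

  ## collect movable residues
  jobs <- list()
  for (segid in names(tc$flexible)) {
    for (resid in tc$flexible[[segid]]) {
      idx <- residue_atom_index(atoms, segid, resid)
      if (length(idx) == 0) next
      resname <- toupper(atoms$resname[idx[1]])
      defs <- CHI_DEFS[[resname]]
      if (is.null(defs)) {
        stop("no side-chain torsion topology for residue type ", resname,
             " at ", segid, ":", resid)
      }
      if (length(defs) == 0) next   # ALA/GLY/PRO: nothing to move
      ok <- vapply(defs, function(d) all(c(d$atoms, d$moves) %in% names(idx)),
                   logical(1))
      if (!all(ok)) next            # incomplete side chain: leave it alone
      jobs[[length(jobs) + 1]] <- list(segid = segid, resid = resid,
                                       resname = resname, idx = idx,
                                       defs = defs)
    }
  }

  ## full-system breakdown helper (reported energies)
  breakdown_at <- function(X) {
    cur <- s; coords(cur) <- X
    terms <- list()
    rows <- list()
    if (length(restraints) > 0) {
      rows <- evaluate_restraints(cur, restraints, rparams)
      terms$NOE <- sum(vapply(rows, function(x) x$energy, numeric(1)))
    }
    if (length(ncs) > 0) {
      terms$NCS <- ncs_energy(ncs, cur)$energy
    }
    if (length(groups) >= 2) {
      sysmask <- list()
      for (a in seq_along(groups)) for (b in seq_along(groups)) if (a < b) {
        sysmask[[length(sysmask) + 1]] <-
          interaction(groups[[a]]$members, groups[[b]]$members)
      }
      mask <- structure(list(entries = sysmask), class = "interaction_mask")
      pl <- build_pair_list(cur, mask, nb$cutnb, params)
      le <- lj_coulomb_energy(pl, X, params, nb)
      terms$VDW <- le$vdw
      terms$ELEC <- le$elec
    }
    new_breakdown(terms, 0, rows)
  }

  pre <- breakdown_at(X)
  if (length(jobs) == 0) {
    return(list(structure = s, pre = pre, post = pre, trace = numeric(0)))
  }

  ## movable-side-chain local energies drive acceptance
  interacting <- params$interacting
  local_env <- function(job) {
    all_move <- unique(unlist(lapply(job$defs, function(d) d$moves)))
    move_idx <- job$idx[all_move]
    in_res <- atoms$segid == job$segid & atoms$resid == job$resid
    env_idx <- which(interacting & !in_res)
    elec_w <- ifelse(body[env_idx] > 0 & body[env_idx] == body[move_idx[1]],
                     0, 1)
    list(move_idx = move_idx, env = list(idx = env_idx), elec_w = elec_w)
  }
  envs <- lapply(jobs, local_env)

  evals <- 0L
  trace <- numeric(0)
  total_local <- function(X) {
    sum(vapply(seq_along(jobs), function(k) {
      torsion_local_energy(X, envs[[k]]$move_idx, envs[[k]]$env, params, nb,
                           envs[[k]]$elec_w)
    }, numeric(1)))
  }
  e_now <- total_local(X)
  trace <- e_now
  repeat {
    e_sweep_start <- e_now
    for (k in seq_along(jobs)) {
      job <- jobs[[k]]; en <- envs[[k]]
      for (d in job$defs) {
        p1 <- X[job$idx[d$atoms[2]], ]   # axis: b -> c
        p2 <- X[job$idx[d$atoms[3]], ]
        move <- job$idx[d$moves]
        e_cur <- torsion_local_energy(X, en$move_idx, en$env, params, nb,
                                      en$elec_w)
        best <- list(ang = 0, e = e_cur)
        angles <- seq(tc$grid_step, 359, by = tc$grid_step)
        for (ang in angles) {
          Xt <- rotate_about_bond(X, move, p1, p2, ang)
          et <- torsion_local_energy(Xt, en$move_idx, en$env, params, nb,
                                     en$elec_w)
          evals <- evals + 1L
          if (et < best$e) best <- list(ang = ang, e = et)
        }
        ## local polish around the best grid point
        step <- tc$grid_step / 2
        while (step > 1) {
          for (ang in c(best$ang - step, best$ang + step)) {
            Xt <- rotate_about_bond(X, move, p1, p2, ang)
            et <- torsion_local_energy(Xt, en$move_idx, en$env, params, nb,
                                       en$elec_w)
            evals <- evals + 1L
            if (et < best$e) best <- list(ang = ang, e = et)
          }
          step <- step / 2
        }
        if (best$ang != 0 && best$e < e_cur) {
          X <- rotate_about_bond(X, move, p1, p2, best$ang)
          e_now <- e_now - (e_cur - best$e)
          trace <- c(trace, e_now)
        }
        if (evals >= tc$nstep) break
      }
      if (evals >= tc$nstep) break
    }
    if (evals >= tc$nstep || (e_sweep_start - e_now) < tc$depred) break
  }

  out <- s
  coords(out) <- X
  list(structure = out, pre = pre, post = breakdown_at(X), trace = trace)
}
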