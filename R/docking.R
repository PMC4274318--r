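## Staged rigid-body docking.
##
## Each rigid group (a protein body plus the spin ensembles riding on it)
## carries a 6-DOF pose: a unit quaternion and a translation applied about
## the group's input centroid. The staged protocol mirrors the established
## restraint-driven recipe:
##   1. NOE only, repel 1e-9, nstep 100  (bodies may pass through each other)
##   2. NOE + NCS, repel 1e-9, nstep 200
##   3. NOE + NCS + soft repulsion at repel 0.7, nstep 100
##   4. interface side-chain torsion refinement with repel 0 (LJ + Coulomb)
## Minimisation is gradient descent with backtracking line search; `drop`
## sizes the first trial step so the expected first-step decrease is about
## `drop` kcal/mol. Gradients with respect to the pose come from the chain
## rule: translation force = sum of atom forces, rotational gradient =
## torque sum (x_i - centroid) x force_i, applied as a rotation-vector
## increment (the exact equivalent of the quaternion chain rule).

#' Define a rigid group
#'
#' @param id group identifier.
#' @param members selection of the member atoms (protein segments plus their
#'   spin ensembles, e.g. `"segid A or segid B or segid S"`).
#' @return a `rigid_group`.
#' @export
rigid_group <- function(id, members) {
  structure(list(id = id, members = parse_selection(members)),
            class = "rigid_group")
}

#' Stage configuration
#'
#' @param name stage name (also used for the output PDB).
#' @param terms active energy terms, subset of `NOE`, `NCS`, `VDW`, `ELEC`.
#' @param repel repulsion scale for the VDW term (`0` = LJ + Coulomb mode).
#' @param nstep maximum minimiser iterations (>= 1).
#' @param drop initial expected energy decrease, kcal/mol (> 0), used to
#'   size the first trial step.
#' @return a `stage_config`.
#' @export
stage_config <- function(name, terms = c("NOE"), repel = 1e-9,
                         nstep = 100, drop = 10) {
  stopifnot(nstep >= 1, drop > 0)
  bad <- setdiff(terms, c("NOE", "NCS", "VDW", "ELEC"))
  if (length(bad)) stop("unknown energy terms: ", paste(bad, collapse = ", "))
  structure(list(name = name, terms = terms, repel = repel,
                 nstep = as.integer(nstep), drop = drop),
            class = "stage_config")
}

identity_pose <- function() list(q = quat_identity(), t = c(0, 0, 0))

#' Assemble a docking system
#'
#' Resolves all selections once (group membership, restraint endpoints, NCS
#' copies, the inter-group interaction mask) against the input structure and
#' caches per-atom non-bonded parameters.
#'
#' @param s input `pdb_structure` (the docking start point).
#' @param groups list of `rigid_group`; must be disjoint.
#' @param restraints list of `distance_restraint`.
#' @param ncs list of `ncs_group` (may be empty).
#' @param rparams a `restraint_params`.
#' @param nb a `nonbonded_params` (its `repel` is overridden per stage).
#' @param mask optional `interaction_mask`; by default every pair of
#'   distinct groups interacts with weight 1.
#' @return a `dock_system`.
#' @export
build_dock_system <- function(s, groups, restraints, ncs = list(),
                              rparams = restraint_params(),
                              nb = nonbonded_params(), mask = NULL) {
  X0 <- coords(s)
  g_idx <- lapply(groups, function(g) select_atoms(s, g$members))
  for (g in seq_along(groups)) {
    if (length(g_idx[[g]]) == 0) stop("empty rigid group: ", groups[[g]]$id)
  }
  all_idx <- unlist(g_idx)
  if (anyDuplicated(all_idx)) stop("rigid groups overlap")
  r_idx <- lapply(restraints, function(r) {
    ia <- select_atoms(s, r$sel_a); ib <- select_atoms(s, r$sel_b)
    if (length(ia) == 0 || length(ib) == 0) {
      stop("restraint selection matched no atoms: ", r$sel_a$text)
    }
    list(ia = ia, ib = ib)
  })
  n_idx <- lapply(ncs, function(g) {
    idx <- lapply(g$copies, function(sel) select_atoms(s, sel))
    if (length(unique(lengths(idx))) != 1 || lengths(idx)[1] == 0) {
      stop("NCS copy cardinality mismatch in group with copies: ",
           paste(vapply(g$copies, function(x) x$text, ""), collapse = " / "))
    }
    idx
  })
  params <- assign_params(s)
  if (is.null(mask)) {
    entries <- list()
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a < b) {
          entries[[length(entries) + 1]] <-
            interaction(groups[[a]]$members, groups[[b]]$members)
        }
      }
    }
    mask <- structure(list(entries = entries), class = "interaction_mask")
  }
  mask_idx <- lapply(mask$entries, function(e) {
    keep <- which(params$interacting)
    list(ia = intersect(select_atoms(s, e$sel_a), keep),
         ib = intersect(select_atoms(s, e$sel_b), keep),
         weight = e$weight, elec = e$elec)
  })
  structure(list(s = s, X0 = X0, groups = groups, g_idx = g_idx,
                 centroids = lapply(g_idx, function(i) colMeans(X0[i, , drop = FALSE])),
                 restraints = restraints, r_idx = r_idx,
                 ncs = ncs, n_idx = n_idx,
                 rparams = rparams, nb = nb, params = params,
                 mask_idx = mask_idx),
            class = "dock_system")
}

## current coordinates under a list of poses
apply_poses <- function(sys, poses) {
  X <- sys$X0
  for (g in seq_along(sys$groups)) {
    idx <- sys$g_idx[[g]]
    R <- rotation_from_quat(poses[[g]]$q)
    c0 <- sys$centroids[[g]]
    X[idx, ] <- sweep(sys$X0[idx, , drop = FALSE], 2, c0) %*% t(R) +
      matrix(c0 + poses[[g]]$t, length(idx), 3, byrow = TRUE)
  }
  X
}

## pairs within cutoff from the cached mask, at coordinates X
pairs_at <- function(sys, X, cutoff) {
  out <- list()
  for (e in sys$mask_idx) {
    if (length(e$ia) == 0 || length(e$ib) == 0) next
    d2 <- outer(rowSums(X[e$ia, , drop = FALSE]^2),
                rowSums(X[e$ib, , drop = FALSE]^2), "+") -
      2 * X[e$ia, , drop = FALSE] %*% t(X[e$ib, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[length(out) + 1]] <- data.frame(i = e$ia[hit[, 1]],
                                         j = e$ib[hit[, 2]],
                                         weight = e$weight, elec = e$elec)
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      weight = numeric(0), elec = numeric(0)))
  }
  do.call(rbind, out)
}

## NCS evaluation on bare coordinates with resolved indices
ncs_energy_X <- function(sys, X, gradient = FALSE) {
  G <- if (gradient) matrix(0, nrow(X), 3) else NULL
  per_group <- numeric(length(sys$ncs))
  for (gi in seq_along(sys$ncs)) {
    g <- sys$ncs[[gi]]
    mats <- lapply(sys$n_idx[[gi]], function(i) X[i, , drop = FALSE])
    ev <- ncs_eval_group(mats, g$weight_ncs)
    per_group[gi] <- ev$energy
    if (gradient) {
      for (c in seq_along(mats)) {
        idx <- sys$n_idx[[gi]][[c]]
        G[idx, ] <- G[idx, ] +
          2 * g$weight_ncs * (ev$Y[[c]] - ev$avg) %*% ev$rotations[[c]]
      }
    }
  }
  list(energy = sum(per_group), per_group = per_group, grad = G)
}

new_breakdown <- function(terms, grad_rms = 0, noe_rows = list()) {
  all_terms <- c(BOND = 0, ANGL = 0, DIHE = 0, IMPR = 0,
                 VDW = 0, ELEC = 0, NCS = 0, NOE = 0)
  all_terms[names(terms)] <- unlist(terms)
  structure(list(Etotal = sum(all_terms), grad = grad_rms,
                 terms = all_terms, noe_rows = noe_rows),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(format_energy_block(x), sep = "\n")
  invisible(x)
}

#' Energy and 6-DOF gradient of the current poses
#'
#' Evaluates the stage's active terms at the given poses and propagates the
#' per-atom forces to each group's six pose degrees of freedom. Spin
#' ensembles contribute only to the NOE term (they are excluded from
#' non-bonded interactions). The reported NOE energy is ceiling-capped; the
#' `objective` field carries the minimisation objective, whose NOE part
#' continues linearly beyond the cap so that heavily violated restraints
#' retain a restoring force.
#'
#' @param sys a `dock_system`.
#' @param poses list of poses (one per group), each `list(q, t)`.
#' @param stage a `stage_config`.
#' @param gradient also compute gradients?
#' @return list with `breakdown` (an `energy_breakdown`), `objective`,
#'   `atom_grad` (n x 3) and `pose_grad` (list per group of
#'   `list(rot, trans)`).
#' @export
pose_energy_gradient <- function(sys, poses, stage, gradient = TRUE) {
  X <- apply_poses(sys, poses)
  n <- nrow(X)
  G <- matrix(0, n, 3)
  terms <- list()
  objective <- 0
  noe_rows <- list()

  if ("NOE" %in% stage$terms && length(sys$restraints) > 0) {
    e_cap <- 0
    for (k in seq_along(sys$restraints)) {
      r <- sys$restraints[[k]]
      ia <- sys$r_idx[[k]]$ia; ib <- sys$r_idx[[k]]$ib
      eg <- effective_distance_grad(X[ia, , drop = FALSE],
                                    X[ib, , drop = FALSE],
                                    sys$rparams$averaging)
      row_cap <- square_well_energy(eg$r, r, sys$rparams, mode = "capped")
      row_lin <- square_well_energy(eg$r, r, sys$rparams, mode = "linear")
      e_cap <- e_cap + row_cap$energy
      objective <- objective + row_lin$energy
      noe_rows[[k]] <- row_cap
      if (gradient && row_lin$dEdr != 0) {
        G[ia, ] <- G[ia, ] + row_lin$dEdr * eg$grad_a
        G[ib, ] <- G[ib, ] + row_lin$dEdr * eg$grad_b
      }
    }
    terms$NOE <- e_cap
  }

  if ("NCS" %in% stage$terms && length(sys$ncs) > 0) {
    nc <- ncs_energy_X(sys, X, gradient = gradient)
    terms$NCS <- nc$energy
    objective <- objective + nc$energy
    if (gradient) G <- G + nc$grad
  }

  if ("VDW" %in% stage$terms) {
    nb <- sys$nb
    nb$repel <- stage$repel
    pl <- pairs_at(sys, X, nb$cutnb)
    if (stage$repel > 0) {
      re <- repel_energy(pl, X, sys$params, nb, gradient = gradient)
      terms$VDW <- re$energy
      objective <- objective + re$energy
      if (gradient) G <- G + re$grad
    } else {
      le <- lj_coulomb_energy(pl, X, sys$params, nb, gradient = gradient)
      terms$VDW <- le$vdw
      terms$ELEC <- le$elec
      objective <- objective + le$energy
      if (gradient) G <- G + le$grad
    }
  }

  pose_grad <- NULL
  grad_rms <- 0
  if (gradient) {
    pose_grad <- vector("list", length(sys$groups))
    for (g in seq_along(sys$groups)) {
      idx <- sys$g_idx[[g]]
      m <- sys$centroids[[g]] + poses[[g]]$t
      z <- sweep(X[idx, , drop = FALSE], 2, m)
      gg <- G[idx, , drop = FALSE]
      torque <- c(sum(z[, 2] * gg[, 3] - z[, 3] * gg[, 2]),
                  sum(z[, 3] * gg[, 1] - z[, 1] * gg[, 3]),
                  sum(z[, 1] * gg[, 2] - z[, 2] * gg[, 1]))
      pose_grad[[g]] <- list(rot = torque, trans = colSums(gg))
    }
    grad_rms <- sqrt(mean(rowSums(G^2)))
  }
  list(breakdown = new_breakdown(terms, grad_rms, noe_rows),
       objective = objective, atom_grad = G, pose_grad = pose_grad)
}

flatten_pose_grad <- function(pg) {
  unlist(lapply(pg, function(g) c(g$rot, g$trans)))
}

step_poses <- function(poses, pg, alpha) {
  for (g in seq_along(poses)) {
    w <- -alpha * pg[[g]]$rot
    poses[[g]]$q <- quat_normalize(quat_multiply(quat_from_rotvec(w),
                                                 poses[[g]]$q))
    poses[[g]]$t <- poses[[g]]$t - alpha * pg[[g]]$trans
  }
  poses
}

#' Rigid-body minimisation of one stage
#'
#' Gradient descent over all groups' poses with backtracking line search.
#' The first trial step is sized from `drop` (expected decrease of about
#' `drop` kcal/mol); accepted steps never increase the stage objective, and
#' iteration stops after `nstep` steps, when no decreasing step can be
#' found, or when the objective changes by less than 1e-6 kcal/mol over 5
#' consecutive iterations.
#'
#' @param sys a `dock_system`.
#' @param stage a `stage_config`.
#' @param poses starting poses; identity poses by default.
#' @return list with final `poses`, the accepted-step objective `trace`,
#'   and `pre`/`post` energy breakdowns.
#' @export
minimize_rigid <- function(sys, stage, poses = NULL) {
  if (is.null(poses)) {
    poses <- rep(list(identity_pose()), length(sys$groups))
  }
  ev <- pose_energy_gradient(sys, poses, stage)
  if (!is.finite(ev$objective)) stop("non-finite energy at start of stage ", stage$name)
  pre <- ev$breakdown
  trace <- ev$objective
  alpha <- NULL
  small <- 0L
  for (iter in seq_len(stage$nstep)) {
    gvec <- flatten_pose_grad(ev$pose_grad)
    g2 <- sum(gvec^2)
    if (g2 < 1e-20) break
    if (is.null(alpha)) alpha <- stage$drop / g2
    accepted <- FALSE
    a <- alpha
    for (ls in 1:60) {
      cand <- step_poses(poses, ev$pose_grad, a)
      ev2 <- pose_energy_gradient(sys, cand, stage)
      if (is.finite(ev2$objective) &&
          ev2$objective <= trace[length(trace)] - 1e-4 * a * g2) {
        poses <- cand
        de <- trace[length(trace)] - ev2$objective
        ev <- ev2
        trace <- c(trace, ev2$objective)
        alpha <- a * 1.5
        accepted <- TRUE
        small <- if (de < 1e-6) small + 1L else 0L
        break
      }
      a <- a / 2
    }
    if (!accepted || small >= 5L) break
  }
  list(poses = poses, trace = trace, pre = pre, post = ev$breakdown)
}

default_stages <- function() {
  list(
    stage_config("noe", terms = c("NOE", "VDW"), repel = 1e-9,
                 nstep = 100, drop = 10),
    stage_config("noencs", terms = c("NOE", "NCS", "VDW"), repel = 1e-9,
                 nstep = 200, drop = 10),
    stage_config("noencsvdw", terms = c("NOE", "NCS", "VDW"), repel = 0.7,
                 nstep = 100, drop = 10)
  )
}

#' Run the staged docking protocol
#'
#' Runs the rigid stages (NOE only; NOE + NCS; NOE + NCS + soft repulsion),
#' then, if a torsion configuration is supplied, refines interface
#' side-chain torsions with the physical non-bonded terms (repel 0).
#' After each stage the intermediate structure can be written to
#' `<outdir>/RES/<stage>.pdb` (`noe.pdb`, `noencs.pdb`, `noencsvdw.pdb`,
#' `noencsvdwdynint.pdb`).
#'
#' @param s input `pdb_structure`.
#' @param groups list of `rigid_group`.
#' @param restraints list of `distance_restraint` (or a table path).
#' @param ncs list of `ncs_group`.
#' @param rparams,nb restraint / non-bonded parameter objects.
#' @param stages list of `stage_config`; the standard three rigid stages by
#'   default.
#' @param torsion optional `torsion_config` for the final refinement stage.
#' @param outdir optional output directory (a `RES/` subfolder is created).
#' @return list with the final `structure`, final `poses`, per-stage results
#'   (`name`, `pre`, `post`, `trace`) and a `run_report`.
#' @export
run_staged_protocol <- function(s, groups, restraints, ncs = list(),
                                rparams = restraint_params(),
                                nb = nonbonded_params(),
                                stages = default_stages(),
                                torsion = NULL, outdir = NULL) {
  if (is.character(restraints)) restraints <- read_restraint_table(restraints)
  sys <- build_dock_system(s, groups, restraints, ncs, rparams, nb)
  poses <- rep(list(identity_pose()), length(groups))
  res_dir <- NULL
  if (!is.null(outdir)) {
    res_dir <- file.path(outdir, "RES")
    dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  }
  stage_results <- list()
  for (st in stages) {
    mr <- minimize_rigid(sys, st, poses)
    poses <- mr$poses
    stage_results[[st$name]] <- list(name = st$name, pre = mr$pre,
                                     post = mr$post, trace = mr$trace)
    if (!is.null(res_dir)) {
      cur <- s; coords(cur) <- apply_poses(sys, poses)
      write_pdb(cur, file.path(res_dir, paste0(st$name, ".pdb")))
    }
  }
  final <- s
  coords(final) <- apply_poses(sys, poses)
  if (!is.null(torsion)) {
    tr <- torsion_refine(final, torsion, groups = groups, ncs = ncs,
                         restraints = restraints, rparams = rparams, nb = nb)
    final <- tr$structure
    stage_results[["noencsvdwdynint"]] <-
      list(name = "noencsvdwdynint", pre = tr$pre, post = tr$post,
           trace = tr$trace)
    if (!is.null(res_dir)) {
      write_pdb(final, file.path(res_dir, "noencsvdwdynint.pdb"))
    }
  }
  report <- run_report(stage_results, rparams,
                       files = if (is.null(res_dir)) character(0) else
                         list.files(res_dir, full.names = TRUE))
  list(structure = final, poses = poses, stages = stage_results,
       report = report, system = sys)
}
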