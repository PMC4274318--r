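## Non-crystallographic symmetry (NCS) restraints.
##
## An equivalence group lists two or more "copies": selections resolving to
## equal-length, correspondingly ordered atom sets (conventionally CA atoms
## of the residues shared between chains). The energy superposes every copy
## onto the evolving copy-average by least squares, iterating to a fixed
## point, and sums weight_ncs * |y_i - mean_i|^2 over copies and atoms.
## It is therefore invariant to any global rigid motion of a whole copy and
## vanishes when the copies are identical up to rigid motion. Because the
## superpositions and the mean are at a joint stationary point, the analytic
## gradient w.r.t. the input coordinates is simply
## 2 * w * R_c^T (y_i - mean_i) mapped back through each copy's rotation.

#' Define an NCS equivalence group
#'
#' @param copies list (length >= 2) of selections, each resolving to the same
#'   number of atoms in corresponding order.
#' @param weight_ncs restraint weight (default 1).
#' @param sigb B-factor sigma, stored for config compatibility but unused
#'   (no B-factor refinement here).
#' @return an `ncs_group`.
#' @export
ncs_group <- function(copies, weight_ncs = 1, sigb = 1.0) {
  if (length(copies) < 2) stop("an NCS group needs at least two copies")
  structure(list(copies = lapply(copies, parse_selection),
                 weight_ncs = weight_ncs, sigb = sigb),
            class = "ncs_group")
}

## core evaluation on a list of coordinate matrices; returns energy, the
## superposed copies, the mean, and each copy's rotation
ncs_eval_group <- function(mats, weight, max_iter = 200, tol = 1e-12) {
  M <- length(mats)
  n <- nrow(mats[[1]])
  rots <- rep(list(diag(3)), M)
  Y <- mats
  ref <- mats[[1]]
  e_prev <- Inf
  for (iter in seq_len(max_iter)) {
    for (c in seq_len(M)) {
      fit <- kabsch_superpose(ref, mats[[c]])
      Y[[c]] <- fit$yfit
      rots[[c]] <- fit$rotation
    }
    avg <- Reduce(`+`, Y) / M
    e <- weight * sum(vapply(Y, function(y) sum((y - avg)^2), numeric(1)))
    if (abs(e_prev - e) < tol * max(1, e)) {
      ref <- avg
      break
    }
    e_prev <- e
    ref <- avg
  }
  list(energy = e, Y = Y, avg = avg, rotations = rots)
}

#' NCS restraint energy (and gradient)
#'
#' @param groups list of `ncs_group`.
#' @param s a `pdb_structure`.
#' @param gradient also return the per-atom gradient matrix?
#' @return list with `energy` (kcal/mol), `per_group` energies, `per_copy`
#'   (list per group of per-copy energies) and, if requested, `grad`
#'   (n_atoms x 3).
#' @export
ncs_energy <- function(groups, s, gradient = FALSE) {
  X <- coords(s)
  G <- if (gradient) matrix(0, nrow(X), 3) else NULL
  per_group <- numeric(length(groups))
  per_copy <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    idx <- lapply(g$copies, function(sel) select_atoms(s, sel))
    counts <- lengths(idx)
    if (length(unique(counts)) != 1 || counts[1] == 0) {
      stop(sprintf("NCS group %d: copy cardinality mismatch (%s)",
                   gi, paste(counts, collapse = " vs ")))
    }
    mats <- lapply(idx, function(i) X[i, , drop = FALSE])
    ev <- ncs_eval_group(mats, g$weight_ncs)
    per_group[gi] <- ev$energy
    per_copy[[gi]] <- vapply(ev$Y, function(y) {
      g$weight_ncs * sum((y - ev$avg)^2)
    }, numeric(1))
    if (gradient) {
      for (c in seq_along(idx)) {
        gc <- 2 * g$weight_ncs * (ev$Y[[c]] - ev$avg) %*% ev$rotations[[c]]
        G[idx[[c]], ] <- G[idx[[c]], ] + gc
      }
    }
  }
  out <- list(energy = sum(per_group), per_group = per_group,
              per_copy = per_copy)
  if (gradient) out$grad <- G
  out
}
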