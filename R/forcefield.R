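## Minimal non-bonded energetics.
##
## A deliberately small stand-in for a full force-field setup: per-atom
## radius/well-depth/charge come from a built-in per-element table (heavy
## atoms; no hydrogen building), and two interaction modes are provided:
##   * repel > 0: a purely repulsive quartic term
##       E = k * sum max(0, (repel*(rA+rB))^2 - r^2)^2
##     whose contact radii scale with `repel` (1e-9 lets bodies pass through
##     each other; 0.7 restores soft sterics);
##   * repel = 0: 12-6 Lennard-Jones (Lorentz-Berthelot combination, switched
##     over the ctonnb-ctofnb window) plus shift-truncated Coulomb
##     electrostatics, for physical evaluation snapshots.
## Absolute magnitudes are not comparable to a full CHARMM treatment; the
## staging behaviour (which is what the docking protocol relies on) is.

ELEMENT_TABLE <- data.frame(
  element = c("C", "N", "O", "S", "H", "P"),
  radius = c(1.70, 1.55, 1.52, 1.80, 1.10, 1.80),
  eps = c(0.10, 0.17, 0.12, 0.25, 0.03, 0.20),
  stringsAsFactors = FALSE
)
DEFAULT_RADIUS <- 1.70
DEFAULT_EPS <- 0.10

## electrostatic constant, kcal A / (mol e^2)
COULOMB_K <- 332.06
## quartic repulsion constant, kcal/(mol A^4)
REPEL_K <- 4.0

## simplified backbone partial charges (e); side-chain heavy atoms neutral
BACKBONE_CHARGES <- c(N = -0.47, CA = 0.07, C = 0.51, O = -0.51, OXT = -0.51)

element_vdw_radius <- function(element) {
  i <- match(element, ELEMENT_TABLE$element)
  r <- ELEMENT_TABLE$radius[i]
  r[is.na(r)] <- DEFAULT_RADIUS
  r
}

#' Non-bonded parameters
#'
#' @param repel dimensionless scale on contact-radius sums for the quartic
#'   repulsion term; `0` switches to Lennard-Jones + electrostatics.
#' @param eps_dielectric dielectric constant (default 1).
#' @param cutnb pair-list cutoff, Angstrom (default 7.5).
#' @param ctonnb,ctofnb switching window for the LJ term; the electrostatic
#'   shift function truncates at `ctofnb`. Must satisfy
#'   `ctonnb < ctofnb <= cutnb`.
#' @param e14fac,wmin stored for config compatibility; unused for rigid
#'   inter-body pairs.
#' @param repel_k repulsion constant in kcal/(mol A^4).
#' @return a `nonbonded_params`.
#' @export
nonbonded_params <- function(repel = 0.7, eps_dielectric = 1.0,
                             cutnb = 7.5, ctonnb = 6.0, ctofnb = 6.5,
                             e14fac = 0.4, wmin = 1e-8, repel_k = REPEL_K) {
  if (!(ctonnb < ctofnb && ctofnb <= cutnb)) {
    stop("need ctonnb < ctofnb <= cutnb")
  }
  if (repel < 0) stop("repel must be >= 0")
  structure(list(repel = repel, eps_dielectric = eps_dielectric,
                 cutnb = cutnb, ctonnb = ctonnb, ctofnb = ctofnb,
                 e14fac = e14fac, wmin = wmin, repel_k = repel_k),
            class = "nonbonded_params")
}

#' Assign per-atom non-bonded parameters
#'
#' Radius and well depth come from the element table; simplified partial
#' charges are placed on backbone N/CA/C/O. Atoms of SPIN pseudo-residues
#' are flagged non-interacting: a spin ensemble represents a population of
#' label conformers, so evaluating its non-bonded energy would grossly
#' overestimate the steric footprint of any single label.
#'
#' @param s a `pdb_structure`.
#' @return data.frame with one row per atom: `radius`, `eps`, `charge`,
#'   `interacting`.
#' @export
assign_params <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) {
    return(data.frame(radius = numeric(0), eps = numeric(0),
                      charge = numeric(0), interacting = logical(0)))
  }
  i <- match(a$element, ELEMENT_TABLE$element)
  charge <- BACKBONE_CHARGES[a$name]
  charge[is.na(charge)] <- 0
  data.frame(
    radius = ifelse(is.na(i), DEFAULT_RADIUS, ELEMENT_TABLE$radius[i]),
    eps = ifelse(is.na(i), DEFAULT_EPS, ELEMENT_TABLE$eps[i]),
    charge = as.numeric(charge),
    interacting = toupper(a$resname) != "SPIN"
  )
}

#' Define an interaction mask
#'
#' A list of (selection A, selection B) pairs stating which atom pairs
#' contribute to the non-bonded energy, each with an overall weight and an
#' electrostatics weight (`elec = 0` silences the Coulomb term for that
#' block, as used for intra-body side-chain packing).
#'
#' @param ... entries created with [interaction()].
#' @return an `interaction_mask`.
#' @export
interaction_mask <- function(...) {
  entries <- list(...)
  structure(list(entries = entries), class = "interaction_mask")
}

#' @rdname interaction_mask
#' @param sel_a,sel_b selections for the two sides of the block.
#' @param weight overall weight on the block (default 1).
#' @param elec weight on the electrostatic term (default 1).
#' @export
interaction <- function(sel_a, sel_b, weight = 1, elec = 1) {
  list(sel_a = parse_selection(sel_a), sel_b = parse_selection(sel_b),
       weight = weight, elec = elec)
}

#' Build the non-bonded pair list
#'
#' All inter-selection atom pairs within `cutoff`, honouring the mask and the
#' SPIN exclusion, in deterministic (i, then j) order. A pair may contribute
#' through at most one mask entry; the same pair appearing in two entries
#' with different weights is an error.
#'
#' @param s a `pdb_structure`.
#' @param mask an `interaction_mask`.
#' @param cutoff pair cutoff in Angstrom.
#' @param params per-atom parameters from [assign_params()] (computed if
#'   omitted).
#' @return data.frame with columns `i`, `j`, `weight`, `elec`.
#' @export
build_pair_list <- function(s, mask, cutoff, params = assign_params(s)) {
  X <- coords(s)
  keep <- which(params$interacting)
  out <- list()
  for (e in mask$entries) {
    ia <- intersect(select_atoms(s, e$sel_a), keep)
    ib <- intersect(select_atoms(s, e$sel_b), keep)
    if (length(ia) == 0 || length(ib) == 0 || cutoff <= 0) next
    d2 <- outer(rowSums(X[ia, , drop = FALSE]^2),
                rowSums(X[ib, , drop = FALSE]^2), "+") -
      2 * X[ia, , drop = FALSE] %*% t(X[ib, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    i <- ia[hit[, 1]]; j <- ib[hit[, 2]]
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    self <- i == j
    df <- data.frame(i = i[!self], j = j[!self],
                     weight = e$weight, elec = e$elec)
    out[[length(out) + 1]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      weight = numeric(0), elec = numeric(0)))
  }
  pairs <- do.call(rbind, out)
  key <- paste(pairs$i, pairs$j)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    sub <- pairs[key %in% dup, ]
    agg <- stats::aggregate(cbind(weight, elec) ~ i + j, sub,
                            function(v) length(unique(v)))
    if (any(agg$weight > 1) || any(agg$elec > 1)) {
      stop("overlapping interaction masks assign contradictory weights")
    }
    pairs <- pairs[!duplicated(key), ]
  }
  pairs[order(pairs$i, pairs$j), , drop = FALSE]
}

#' Quartic soft repulsion energy
#'
#' `E = k * sum_pairs w * max(0, (repel*(rA+rB))^2 - r^2)^2`. Non-negative,
#' zero beyond the scaled contact distance, monotone non-increasing in pair
#' distance and monotone non-decreasing in `repel`. With `repel = 1e-9` the
#' term is numerically zero for any physically separated atoms.
#'
#' @param pairs pair list from [build_pair_list()].
#' @param X n x 3 coordinate matrix.
#' @param params per-atom parameters ([assign_params()]).
#' @param p a `nonbonded_params` with `repel > 0`.
#' @param gradient return the analytic per-atom gradient?
#' @return list with `energy` (kcal/mol) and optionally `grad` (n x 3).
#' @export
repel_energy <- function(pairs, X, params, p, gradient = FALSE) {
  if (p$repel <= 0) stop("repel_energy requires repel > 0")
  G <- if (gradient) matrix(0, nrow(X), 3) else NULL
  if (nrow(pairs) == 0) {
    return(list(energy = 0, grad = G))
  }
  dx <- X[pairs$i, , drop = FALSE] - X[pairs$j, , drop = FALSE]
  r2 <- rowSums(dx^2)
  contact2 <- (p$repel * (params$radius[pairs$i] + params$radius[pairs$j]))^2
  u <- pmax(0, contact2 - r2)
  E <- p$repel_k * sum(pairs$weight * u^2)
  if (gradient) {
    ## dE/dxi = k*w * 2u * (-2 dx) = -4 k w u dx
    f <- -4 * p$repel_k * pairs$weight * u
    act <- which(u > 0)
    for (idx in act) {
      g <- f[idx] * dx[idx, ]
      G[pairs$i[idx], ] <- G[pairs$i[idx], ] + g
      G[pairs$j[idx], ] <- G[pairs$j[idx], ] - g
    }
  }
  list(energy = E, grad = G)
}

## LJ switching function and derivative w.r.t. r2
lj_switch <- function(r2, ron2, roff2) {
  denom <- (roff2 - ron2)^3
  sw <- ifelse(r2 <= ron2, 1,
        ifelse(r2 >= roff2, 0,
               (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / denom))
  dsw <- ifelse(r2 <= ron2 | r2 >= roff2, 0,
                (-2 * (roff2 - r2) * (roff2 + 2 * r2 - 3 * ron2) +
                   2 * (roff2 - r2)^2) / denom)
  list(sw = sw, dsw_dr2 = dsw)
}

#' Lennard-Jones + shifted-Coulomb energy
#'
#' The physical evaluation mode used when `repel = 0`: 12-6 LJ with
#' Lorentz-Berthelot combination (`rmin_ij = rA + rB`,
#' `eps_ij = sqrt(epsA*epsB)`), switched smoothly to zero over
#' `[ctonnb, ctofnb]`, plus Coulomb electrostatics damped by the shift
#' function `(1 - (r/ctofnb)^2)^2` and truncated at `ctofnb`. Per-pair
#' electrostatic weights from the mask (`elec`) are honoured.
#'
#' @inheritParams repel_energy
#' @return list with `energy`, `vdw`, `elec` components (kcal/mol) and
#'   optionally `grad`.
#' @export
lj_coulomb_energy <- function(pairs, X, params, p, gradient = FALSE) {
  G <- if (gradient) matrix(0, nrow(X), 3) else NULL
  if (nrow(pairs) == 0) {
    return(list(energy = 0, vdw = 0, elec = 0, grad = G))
  }
  dx <- X[pairs$i, , drop = FALSE] - X[pairs$j, , drop = FALSE]
  r2 <- rowSums(dx^2)
  r <- sqrt(r2)
  roff2 <- p$ctofnb^2; ron2 <- p$ctonnb^2
  inside <- r2 < roff2

  rmin <- params$radius[pairs$i] + params$radius[pairs$j]
  epsij <- sqrt(params$eps[pairs$i] * params$eps[pairs$j])
  s6 <- (rmin^2 / pmax(r2, 1e-12))^3
  ljraw <- epsij * (s6^2 - 2 * s6)
  sw <- lj_switch(r2, ron2, roff2)
  vdw_terms <- pairs$weight * ljraw * sw$sw * inside

  qq <- COULOMB_K * params$charge[pairs$i] * params$charge[pairs$j] /
    p$eps_dielectric
  shift <- (1 - r2 / roff2)^2
  elec_terms <- pairs$weight * pairs$elec * qq / pmax(r, 1e-12) * shift * inside

  E_vdw <- sum(vdw_terms)
  E_elec <- sum(elec_terms)
  if (gradient) {
    ## d(ljraw)/dr2 = eps * (12 s6^2 /r2 * (-1) ... ) computed directly:
    ## s6 = (rmin^2/r2)^3 -> ds6/dr2 = -3 s6 / r2
    ds6 <- -3 * s6 / pmax(r2, 1e-12)
    dlj_dr2 <- epsij * (2 * s6 * ds6 - 2 * ds6)
    dvdw_dr2 <- pairs$weight * (dlj_dr2 * sw$sw + ljraw * sw$dsw_dr2) * inside
    ## elec: E = qq/r * (1 - r2/roff2)^2
    ## dE/dr2 = qq * [ -1/(2 r^3) * shift + (1/r) * 2(1 - r2/roff2)(-1/roff2) ]
    delec_dr2 <- pairs$weight * pairs$elec * qq *
      (-shift / (2 * pmax(r, 1e-12)^3) -
         2 * (1 - r2 / roff2) / (roff2 * pmax(r, 1e-12))) * inside
    f <- 2 * (dvdw_dr2 + delec_dr2)   # dE/dxi = dE/dr2 * 2 dx
    act <- which(inside & abs(f) > 0)
    for (idx in act) {
      g <- f[idx] * dx[idx, ]
      G[pairs$i[idx], ] <- G[pairs$i[idx], ] + g
      G[pairs$j[idx], ] <- G[pairs$j[idx], ] - g
    }
  }
  list(energy = E_vdw + E_elec, vdw = E_vdw, elec = E_elec, grad = G)
}
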