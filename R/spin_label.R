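## Spin-label conformer ensembles.
##
## R1 (MTSL on an engineered cysteine) is modelled by an accessible-volume
## search: the label side chain is rebuilt from idealised internal
## coordinates with its five linker dihedrals drawn uniformly, and conformers
## clashing with the protein are rejected. The nitroxide-nitrogen (N1)
## positions of the survivors form the ensemble used as restraint endpoints.
##
## Rx2 (a bis-reactive label bridging two cysteines) is pseudo-cyclic, so a
## rotamer-style dihedral search is inappropriate; its nitroxide position is
## instead sampled from the geometric region satisfying the linker distance
## band to both anchor CB atoms, again with clash rejection. This is a
## documented stand-in for molecular-dynamics label placement: it reproduces
## the narrower, two-anchor-constrained character of the Rx2 ensemble, not
## any particular force-field distribution.

## idealised internal coordinates of the R1 side chain
## (bond Angstrom, angle deg); five rotatable dihedrals chi1..chi5
R1_TOPOLOGY <- list(
  list(name = "SG", refs = c("N", "CA", "CB"),  bond = 1.81, angle = 114, chi = 1),
  list(name = "SD", refs = c("CA", "CB", "SG"), bond = 2.04, angle = 104, chi = 2),
  list(name = "CE", refs = c("CB", "SG", "SD"), bond = 1.81, angle = 104, chi = 3),
  list(name = "C3", refs = c("SG", "SD", "CE"), bond = 1.51, angle = 114, chi = 4),
  ## pyrroline ring, planar, rigidly attached through chi5 about CE-C3
  list(name = "C4", refs = c("SD", "CE", "C3"), bond = 1.35, angle = 125, chi = 5),
  list(name = "C2", refs = c("C4", "CE", "C3"), bond = 1.51, angle = 125, dihedral = 180),
  list(name = "C5", refs = c("CE", "C3", "C4"), bond = 1.50, angle = 112, dihedral = 180),
  list(name = "N1", refs = c("C4", "C3", "C2"), bond = 1.47, angle = 101, dihedral = 0),
  list(name = "O1", refs = c("C3", "C2", "N1"), bond = 1.28, angle = 125, dihedral = 180)
)

## heavy atoms checked for clashes (CB/SG sit against the labelled backbone)
R1_CLASH_ATOMS <- c("SD", "CE", "C3", "C4", "C2", "C5", "N1", "O1")

#' Define a spin-label site
#'
#' @param segid segment of the labelled residue.
#' @param resid residue number of the labelled residue.
#' @param chemistry `"R1"` (single-cysteine MTSL) or `"Rx2"` (bis-label
#'   bridging two cysteines).
#' @param anchors for Rx2 only: list of two `c(segid, resid)` anchor
#'   residues; for R1 the site itself is the single anchor.
#' @param reach for Rx2: maximum anchor CB-CB distance in Angstrom
#'   (default 12).
#' @return a `label_site` object.
#' @export
label_site <- function(segid, resid, chemistry = c("R1", "Rx2"),
                       anchors = NULL, reach = 12) {
  chemistry <- match.arg(chemistry)
  if (chemistry == "R1") {
    if (!is.null(anchors) && length(anchors) != 1) {
      stop("R1 sites have exactly one anchor (the labelled residue)")
    }
    anchors <- list(c(segid, resid))
  } else {
    if (is.null(anchors) || length(anchors) != 2) {
      stop("Rx2 sites require exactly two anchor (segid, resid) pairs")
    }
  }
  structure(list(segid = as.character(segid), resid = as.integer(resid),
                 chemistry = chemistry, anchors = anchors, reach = reach),
            class = "label_site")
}

#' Sampler parameters for label-ensemble generation
#'
#' @param max_conformers maximum ensemble size returned (default 200, the
#'   customary accessible-volume search cap).
#' @param vdw_mode `"tight"` or `"loose"`; clash scale factors on
#'   element-radius sums of 0.9 and 0.75 respectively. A conformer is
#'   rejected when any checked label atom lies closer to a protein heavy atom
#'   than `scale * (r_label + r_protein)`; tight therefore rejects at longer
#'   range than loose.
#' @param thoroughness number of sampling trials (default 1000).
#' @param rng_seed integer seed; fixed seed gives bitwise-reproducible
#'   ensembles without disturbing the caller's RNG stream.
#' @return a `sampler_params` object.
#' @export
sampler_params <- function(max_conformers = 200, vdw_mode = c("tight", "loose"),
                           thoroughness = 1000, rng_seed = NULL) {
  vdw_mode <- match.arg(vdw_mode)
  if (max_conformers < 1) stop("max_conformers must be >= 1")
  structure(list(max_conformers = as.integer(max_conformers),
                 vdw_mode = vdw_mode,
                 vdw_scale = if (vdw_mode == "tight") 0.9 else 0.75,
                 thoroughness = as.integer(thoroughness),
                 rng_seed = rng_seed),
            class = "sampler_params")
}

site_backbone <- function(s, segid, resid) {
  a <- s$atoms
  pick <- function(nm) {
    i <- which(a$segid == segid & a$resid == resid & a$name == nm)
    if (length(i) != 1) {
      stop(sprintf("site %s:%d lacks a unique backbone atom %s", segid, resid, nm))
    }
    c(a$x[i], a$y[i], a$z[i])
  }
  list(N = pick("N"), CA = pick("CA"), C = pick("C"))
}

## environment used for clash rejection: protein heavy atoms excluding the
## labelled residue(s) and any SPIN pseudo-residues
clash_environment <- function(s, exclude_segres) {
  a <- s$atoms
  keep <- a$element != "H" & toupper(a$resname) != "SPIN"
  for (sr in exclude_segres) {
    keep <- keep & !(a$segid == sr[1] & a$resid == as.integer(sr[2]))
  }
  list(xyz = as.matrix(a[keep, c("x", "y", "z")]),
       radius = element_vdw_radius(a$element[keep]))
}

## build the R1 side chain for one dihedral draw; returns named matrix
build_r1_conformer <- function(bb, chis) {
  pos <- list(N = bb$N, CA = bb$CA, C = bb$C)
  ## idealised CB from the backbone frame
  pos$CB <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, 122.5)
  for (a in R1_TOPOLOGY) {
    dih <- if (!is.null(a$chi)) chis[a$chi] else a$dihedral
    pos[[a$name]] <- place_atom(pos[[a$refs[1]]], pos[[a$refs[2]]],
                                pos[[a$refs[3]]], a$bond, a$angle, dih)
  }
  do.call(rbind, pos[c("CB", names(pos)[-(1:4)])])
}

new_conformer <- function(xyz, clash_score) {
  structure(list(xyz = xyz, clash_score = clash_score,
                 n1 = xyz["N1", ]), class = "label_conformer")
}

#' Accessible-volume R1 conformer search
#'
#' Rebuilds the MTSL-cysteine (R1) side chain at the site from idealised
#' geometry, drawing the five linker dihedrals uniformly, and keeps
#' clash-free conformers until `max_conformers` are collected or the trial
#' budget is exhausted.
#'
#' @param s a `pdb_structure` containing the site backbone.
#' @param site a `label_site` with chemistry R1.
#' @param p a `sampler_params`.
#' @return list of `label_conformer` (each with full side-chain coordinates,
#'   a clash score of 0 and the N1 nitroxide-nitrogen position).
#' @export
search_r1_conformers <- function(s, site, p = sampler_params()) {
  stopifnot(inherits(site, "label_site"))
  if (site$chemistry != "R1") stop("site chemistry is not R1")
  bb <- site_backbone(s, site$segid, site$resid)
  env <- clash_environment(s, list(c(site$segid, site$resid)))
  check_el <- infer_element(R1_CLASH_ATOMS)
  r_label <- element_vdw_radius(check_el)
  ## squared contact cutoffs, label-check-atoms x environment
  cut2 <- if (nrow(env$xyz) > 0) {
    (p$vdw_scale * outer(r_label, env$radius, "+"))^2
  } else NULL

  chis <- with_seed(p$rng_seed,
                    matrix(runif(5L * p$thoroughness, 0, 360), ncol = 5))
  out <- vector("list", p$max_conformers)
  n_found <- 0L
  for (trial in seq_len(p$thoroughness)) {
    xyz <- build_r1_conformer(bb, chis[trial, ])
    if (!is.null(cut2)) {
      chk <- xyz[R1_CLASH_ATOMS, , drop = FALSE]
      d2 <- outer(rowSums(chk^2), rowSums(env$xyz^2), "+") -
        2 * chk %*% t(env$xyz)
      if (any(d2 < cut2)) next
    }
    n_found <- n_found + 1L
    out[[n_found]] <- new_conformer(xyz, 0)
    if (n_found >= p$max_conformers) break
  }
  if (n_found == 0L) {
    stop("no spin-label conformers survived the clash filter at ",
         site$segid, ":", site$resid,
         "; try increasing the thoroughness or reducing the vdW restraints ",
         "(vdw_mode = 'loose')")
  }
  out[seq_len(n_found)]
}

## distance band (Angstrom) from each anchor CB to the Rx2 nitroxide centre
RX2_DMIN <- 5.5
RX2_DMAX <- 7.0

anchor_point <- function(s, segid, resid) {
  a <- s$atoms
  i <- which(a$segid == segid & a$resid == as.integer(resid) & a$name == "CB")
  if (length(i) == 0) {
    i <- which(a$segid == segid & a$resid == as.integer(resid) & a$name == "CA")
  }
  if (length(i) == 0) stop("anchor residue ", segid, ":", resid, " not found")
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Two-anchor constrained Rx2 ensemble
#'
#' Samples nitroxide positions from the intersection of the two spherical
#' shells at linker reach from each anchor (distance band 5.5-7.0 Angstrom
#' from each anchor CB), with clash rejection against the protein. This is a
#' geometric surrogate for the pseudo-cyclic Rx2 side chain; the resulting
#' ensemble is substantially narrower than an R1 ensemble at the same site.
#'
#' @inheritParams search_r1_conformers
#' @param site a `label_site` with chemistry Rx2 and two anchors.
#' @return list of `label_conformer` (nitroxide N1 plus its oxygen).
#' @export
generate_rx2_ensemble <- function(s, site, p = sampler_params()) {
  stopifnot(inherits(site, "label_site"))
  if (site$chemistry != "Rx2") stop("site chemistry is not Rx2")
  a1 <- anchor_point(s, site$anchors[[1]][1], site$anchors[[1]][2])
  a2 <- anchor_point(s, site$anchors[[2]][1], site$anchors[[2]][2])
  d12 <- vnorm(a2 - a1)
  if (d12 > min(site$reach, 2 * RX2_DMAX)) {
    stop(sprintf("Rx2 anchors are out of reach: CB-CB distance %.1f A exceeds %.1f A",
                 d12, min(site$reach, 2 * RX2_DMAX)))
  }
  env <- clash_environment(s, site$anchors)
  r_no <- element_vdw_radius(c("N", "O"))
  cut2 <- if (nrow(env$xyz) > 0) {
    (p$vdw_scale * outer(r_no, env$radius, "+"))^2
  } else NULL

  draws <- with_seed(p$rng_seed, {
    n <- p$thoroughness
    cbind(runif(n, RX2_DMIN, RX2_DMAX),      # radius from anchor 1
          runif(n, -1, 1),                   # cos(polar)
          runif(n, 0, 2 * pi),               # azimuth
          matrix(rnorm(3 * n), ncol = 3))    # oxygen direction
  })
  out <- vector("list", p$max_conformers)
  n_found <- 0L
  for (trial in seq_len(p$thoroughness)) {
    r <- draws[trial, 1]; ct <- draws[trial, 2]; ph <- draws[trial, 3]
    st <- sqrt(max(0, 1 - ct^2))
    n1 <- a1 + r * c(st * cos(ph), st * sin(ph), ct)
    d2a <- vnorm(n1 - a2)
    if (d2a < RX2_DMIN || d2a > RX2_DMAX) next
    o_dir <- draws[trial, 4:6]
    if (vnorm(o_dir) < 1e-8) next
    o1 <- n1 + 1.28 * unitv(o_dir)
    xyz <- rbind(N1 = n1, O1 = o1)
    if (!is.null(cut2)) {
      d2 <- outer(rowSums(xyz^2), rowSums(env$xyz^2), "+") - 2 * xyz %*% t(env$xyz)
      if (any(d2 < cut2)) next
    }
    n_found <- n_found + 1L
    out[[n_found]] <- new_conformer(xyz, 0)
    if (n_found >= p$max_conformers) break
  }
  if (n_found == 0L) {
    stop("no Rx2 conformers survived the constraints at ",
         site$segid, ":", site$resid,
         "; try increasing the thoroughness or reducing the vdW restraints")
  }
  out[seq_len(n_found)]
}

#' Extract the nitroxide-nitrogen ensemble
#'
#' Keeps the first `min(n, 190)` N1 positions in conformer order (the
#' standard 190-atoms-per-residue cap) and assigns the emission atom names
#' `N001`, `N002`, ... together with the residue number and segment id under
#' which the ensemble is written.
#'
#' @param conformers list of `label_conformer`.
#' @param resid_out residue number for emission (each ensemble of a run gets
#'   its own number, increasing by 1).
#' @param segid_out emission segment id (e.g. `"S"` for body-1 labels,
#'   `"T"` for body-2 labels).
#' @param parent_body optional id of the rigid group this ensemble moves
#'   with.
#' @return a `spin_ensemble` with `n1_positions` (m x 3, m <= 190), `names`,
#'   `resid_out`, `segid_out`, `parent_body`.
#' @export
extract_n1_ensemble <- function(conformers, resid_out, segid_out,
                                parent_body = NULL) {
  if (length(conformers) == 0) stop("empty conformer list")
  n <- min(length(conformers), 190L)
  n1 <- do.call(rbind, lapply(conformers[seq_len(n)], function(cf) cf$n1))
  rownames(n1) <- NULL
  structure(list(n1_positions = n1,
                 names = sprintf("N%03d", seq_len(n)),
                 resid_out = as.integer(resid_out),
                 segid_out = as.character(segid_out),
                 parent_body = parent_body),
            class = "spin_ensemble")
}

ensemble_as_structure <- function(e) {
  n <- nrow(e$n1_positions)
  atoms <- data.frame(
    serial = seq_len(n),
    name = e$names,
    resname = "SPIN",
    chain = substr(e$segid_out, 1, 1),
    resid = e$resid_out,
    x = e$n1_positions[, 1], y = e$n1_positions[, 2], z = e$n1_positions[, 3],
    occ = 1, b = 0,
    segid = e$segid_out,
    element = "N",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, provenance = "spin_ensemble")
}

#' Write a spin ensemble as a SPIN-residue PDB file
#'
#' One ATOM record per nitroxide position, atom names `N001`...`N190`,
#' residue name `SPIN`, all sharing the ensemble's residue number and segment
#' id, terminated by `END`. The file is readable by [read_pdb()] and
#' addressable by restraint selections such as `"segid S and resid 1 and
#' name N*"`.
#'
#' @param e a `spin_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spin_ensemble_pdb <- function(e, path) {
  if (nrow(e$n1_positions) > 190) {
    stop("spin ensemble exceeds 190 positions; cap it with extract_n1_ensemble()")
  }
  write_pdb(ensemble_as_structure(e), path)
}

#' Attach a spin ensemble to a structure
#'
#' Appends the ensemble's SPIN-residue atoms to the structure so they
#' co-transform with their parent rigid body during docking.
#'
#' @param s a `pdb_structure`.
#' @param e a `spin_ensemble`.
#' @return the merged `pdb_structure`.
#' @export
add_spin_ensemble <- function(s, e) {
  merge_structures(s, ensemble_as_structure(e))
}
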