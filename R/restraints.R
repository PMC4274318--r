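## Ensemble-averaged distance restraints.
##
## A PELDOR/DEER distance is evaluated between two spin ensembles with R^-3
## averaging: r_eff = ( mean over all cross pairs of r^-3 )^(-1/3), and
## scored with a square-well potential that is zero inside
## [target - minus, target + plus] and grows as
## scale * min(ceiling, sqconstant * violation^sqexponent) outside.
## The ceiling is applied to the *unscaled* well term: a violation of
## 2.937 A under the defaults (sqconstant 1, sqexponent 2, ceiling 50,
## scale 10) scores 10 * 2.937^2 = 86.26 kcal/mol, while arbitrarily large
## violations saturate at scale * ceiling = 500 kcal/mol.
##
## For minimisation the capped plateau would leave badly violated restraints
## (violation > sqrt(ceiling) ~ 7.07 A) with no restoring force, although
## docking deliberately starts with the bodies ~100 A apart. The optimiser
## therefore uses `mode = "linear"`, which continues past the cap with the
## slope at the cap point (C1-continuous); all *reported* energies use the
## capped form.

#' Define a distance restraint between two atom selections
#'
#' @param sel_a,sel_b selections (strings or parsed) resolving to the two
#'   spin-ensemble atom sets, e.g. `"segid S and resid 1 and name N*"`.
#' @param target target distance in Angstrom.
#' @param minus,plus lower/upper half-widths of the flat well in Angstrom
#'   (the well is `[target - minus, target + plus]`).
#' @param label free-text label.
#' @return a `distance_restraint`.
#' @export
distance_restraint <- function(sel_a, sel_b, target, minus, plus, label = "") {
  if (minus < 0 || plus < 0) stop("restraint bounds must be non-negative")
  structure(list(sel_a = parse_selection(sel_a), sel_b = parse_selection(sel_b),
                 d_target = target, d_minus = minus, d_plus = plus,
                 label = label),
            class = "distance_restraint")
}

#' Restraint-class parameters
#'
#' Defaults mirror the standard EPR restraint class: R^-3 averaging,
#' square-well potential, `sqconstant` 1, `sqexponent` 2, `ceiling` 50,
#' `scale` 10.
#'
#' @param averaging `"R-3"`, `"R-6"` or `"center"`.
#' @param potential only `"square"` is implemented.
#' @param sqconstant multiplier on the violation power term.
#' @param sqexponent exponent on the violation (>= 1).
#' @param ceiling cap on the unscaled well term (> 0).
#' @param scale overall scale factor (>= 0).
#' @return a `restraint_params`.
#' @export
restraint_params <- function(averaging = c("R-3", "R-6", "center"),
                             potential = "square",
                             sqconstant = 1, sqexponent = 2,
                             ceiling = 50, scale = 10) {
  averaging <- match.arg(averaging)
  if (potential != "square") stop("only the square-well potential is implemented")
  if (sqexponent < 1) stop("sqexponent must be >= 1")
  if (ceiling <= 0) stop("ceiling must be positive")
  if (scale < 0) stop("scale must be non-negative")
  structure(list(averaging = averaging, potential = potential,
                 sqconstant = sqconstant, sqexponent = sqexponent,
                 ceiling = ceiling, scale = scale),
            class = "restraint_params")
}

cross_distances <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Ensemble-averaged effective distance
#'
#' For R^-3 averaging returns `(mean_ij r_ij^-3)^(-1/3)` over all cross
#' pairs; R^-6 analogously; `"center"` returns the centroid-centroid
#' distance. The R^-3 result always lies within
#' `[min pair distance, max pair distance]` and is weighted toward short
#' pairs.
#'
#' @param ensemble_a,ensemble_b n x 3 / m x 3 coordinate matrices.
#' @param averaging averaging mode as in [restraint_params()].
#' @return effective distance in Angstrom.
#' @examples
#' a <- matrix(c(0, 0, 0), 1, 3)
#' b <- rbind(c(10, 0, 0), c(20, 0, 0))
#' effective_distance(a, b, "R-3")  # ((10^-3 + 20^-3)/2)^(-1/3) = 12.114
#' @export
effective_distance <- function(ensemble_a, ensemble_b,
                               averaging = c("R-3", "R-6", "center")) {
  averaging <- match.arg(averaging)
  xa <- rbind(ensemble_a); xb <- rbind(ensemble_b)
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("empty ensemble")
  if (averaging == "center") {
    return(vnorm(colMeans(xa) - colMeans(xb)))
  }
  d <- cross_distances(xa, xb)
  if (any(d < 1e-9)) stop("coincident atoms across ensembles: singular average")
  p <- if (averaging == "R-3") 3 else 6
  mean(d^(-p))^(-1 / p)
}

## effective distance together with its gradient w.r.t. both ensembles
effective_distance_grad <- function(xa, xb, averaging = "R-3") {
  if (averaging == "center") {
    ca <- colMeans(xa); cb <- colMeans(xb)
    dv <- ca - cb; r <- vnorm(dv)
    if (r < 1e-9) stop("coincident ensemble centroids")
    u <- dv / r
    ga <- matrix(u, nrow(xa), 3, byrow = TRUE) / nrow(xa)
    gb <- -matrix(u, nrow(xb), 3, byrow = TRUE) / nrow(xb)
    return(list(r = r, grad_a = ga, grad_b = gb))
  }
  p <- if (averaging == "R-3") 3 else 6
  d <- cross_distances(xa, xb)
  if (any(d < 1e-9)) stop("coincident atoms across ensembles: singular average")
  S <- mean(d^(-p))
  r <- S^(-1 / p)
  ## dr/da_i = S^(-(p+1)/p) * (1/nm) * sum_j d_ij^-(p+2) (a_i - b_j)
  w <- d^(-(p + 2)) / length(d)       # n x m
  pref <- S^(-(p + 1) / p)
  ga <- pref * (w %*% xb * (-1) + xa * rowSums(w))
  gb <- pref * (t(w) %*% xa * (-1) + xb * colSums(w))
  list(r = r, grad_a = ga, grad_b = gb)
}

## violation and signed delta for a square well
well_violation <- function(r_avg, r) {
  lo <- r$d_target - r$d_minus
  hi <- r$d_target + r$d_plus
  if (r_avg > hi) {
    list(v = r_avg - hi, delta = hi - r_avg, dsign = 1)
  } else if (r_avg < lo) {
    list(v = lo - r_avg, delta = lo - r_avg, dsign = -1)
  } else {
    list(v = 0, delta = 0, dsign = 0)
  }
}

#' Square-well restraint energy
#'
#' Evaluates one restraint at a given effective distance. The signed `delta`
#' is `(nearest violated bound) - r_average`, so an overlong distance gives a
#' negative delta. `mode = "capped"` (reporting) returns
#' `scale * min(ceiling, sqconstant * v^sqexponent)`; `mode = "linear"`
#' (minimisation objective) continues past the cap point with constant slope.
#'
#' @param r_average effective distance in Angstrom.
#' @param r a `distance_restraint`.
#' @param p a `restraint_params`.
#' @param mode `"capped"` or `"linear"`.
#' @return a `restraint_row`: list with `r_average`, `d_target`, `d_minus`,
#'   `d_plus`, `delta`, `energy` (kcal/mol) and `dEdr` (gradient of the
#'   energy in this mode w.r.t. `r_average`).
#' @examples
#' r <- distance_restraint("all", "all", 33, 2, 2)
#' square_well_energy(37.937, r, restraint_params())$energy  # 86.26
#' @export
square_well_energy <- function(r_average, r, p = restraint_params(),
                               mode = c("capped", "linear")) {
  mode <- match.arg(mode)
  vv <- well_violation(r_average, r)
  k <- p$sqconstant; e <- p$sqexponent
  term <- k * vv$v^e
  if (term <= p$ceiling) {
    energy <- p$scale * term
    dEdr <- p$scale * k * e * vv$v^(e - 1) * vv$dsign
  } else if (mode == "capped") {
    energy <- p$scale * p$ceiling
    dEdr <- 0
  } else {
    v_cap <- (p$ceiling / k)^(1 / e)
    slope <- k * e * v_cap^(e - 1)
    energy <- p$scale * (p$ceiling + slope * (vv$v - v_cap))
    dEdr <- p$scale * slope * vv$dsign
  }
  structure(list(r_average = r_average, d_target = r$d_target,
                 d_minus = r$d_minus, d_plus = r$d_plus,
                 delta = vv$delta, energy = energy, dEdr = dEdr,
                 label = r$label),
            class = "restraint_row")
}

#' Summarise a set of restraint rows
#'
#' @param rows list of `restraint_row`.
#' @param violated_only compute the RMS over violated rows only? Default
#'   `FALSE` (RMS over all rows).
#' @return list with `total` energy (kcal/mol), `rms` of deltas (Angstrom),
#'   `n_violated`, `n`.
#' @export
noe_summary <- function(rows, violated_only = FALSE) {
  if (length(rows) == 0) stop("no restraint rows")
  deltas <- vapply(rows, function(x) x$delta, numeric(1))
  energies <- vapply(rows, function(x) x$energy, numeric(1))
  viol <- abs(deltas) > 0
  use <- if (violated_only) deltas[viol] else deltas
  rms <- if (length(use) == 0) 0 else sqrt(mean(use^2))
  list(total = sum(energies), rms = rms,
       n_violated = sum(viol), n = length(rows))
}

#' Read a restraint table
#'
#' Pipe-delimited text, one restraint per line:
#' `selA | selB | target | minus | plus | label`. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path table file.
#' @return list of `distance_restraint`.
#' @export
read_restraint_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws2(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no restraints in ", path)
  lapply(seq_along(lines), function(i) {
    f <- trimws2(strsplit(lines[i], "|", fixed = TRUE)[[1]])
    if (length(f) < 5) stop("malformed restraint at line ", i, " of ", path)
    distance_restraint(f[1], f[2], as.numeric(f[3]), as.numeric(f[4]),
                       as.numeric(f[5]),
                       label = if (length(f) >= 6) f[6] else "")
  })
}

#' Write a restraint table
#'
#' @param restraints list of `distance_restraint`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_restraint_table <- function(restraints, path) {
  lines <- vapply(restraints, function(r) {
    sprintf("%s | %s | %.3f | %.3f | %.3f | %s",
            r$sel_a$text, r$sel_b$text, r$d_target, r$d_minus, r$d_plus,
            r$label)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Evaluate restraints against a structure
#'
#' Resolves each restraint's selections, computes the ensemble-averaged
#' effective distance and the square-well energy.
#'
#' @param s a `pdb_structure`.
#' @param restraints list of `distance_restraint`.
#' @param p a `restraint_params`.
#' @param mode energy mode as in [square_well_energy()].
#' @return list of `restraint_row`.
#' @export
evaluate_restraints <- function(s, restraints, p = restraint_params(),
                                mode = "capped") {
  X <- coords(s)
  lapply(restraints, function(r) {
    ia <- select_atoms(s, r$sel_a); ib <- select_atoms(s, r$sel_b)
    if (length(ia) == 0 || length(ib) == 0) {
      stop("restraint selection matched no atoms: ",
           r$sel_a$text, " / ", r$sel_b$text)
    }
    r_avg <- effective_distance(X[ia, , drop = FALSE], X[ib, , drop = FALSE],
                                p$averaging)
    square_well_energy(r_avg, r, p, mode = mode)
  })
}
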