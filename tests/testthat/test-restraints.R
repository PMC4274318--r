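# Frozen oracle values:
#   R-3 of {10, 20} from a singleton: ((10^-3 + 20^-3)/2)^(-1/3) = 12.11414
#   well energy, v = 2.937: 10 * 2.937^2 = 86.25969
#   well energy, v = 2.484: 10 * 2.484^2 = 61.70256
#   RMS of (2.937, 2.937, 2.484) = 2.794172

test_that("effective distance: identity, symmetry and the two-atom oracle", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b10 <- matrix(c(10, 0, 0), 1, 3)
  for (mode in c("R-3", "R-6", "center")) {
    expect_equal(effective_distance(a, b10, mode), 10)
  }
  b <- rbind(c(10, 0, 0), c(20, 0, 0))
  expect_equal(effective_distance(a, b, "R-3"), 12.11414, tolerance = 1e-6)
  expect_equal(effective_distance(a, b, "R-3"),
               effective_distance(b, a, "R-3"))
  expect_error(effective_distance(a, a, "R-3"), "singular")
})

test_that("R-3 averaging is short-pair weighted and bracketed by pair extremes", {
  set.seed(8)
  for (rep in 1:10) {
    xa <- random_points(4) + 1
    xb <- random_points(5) + 12
    d <- as.vector(spindock:::cross_distances(xa, xb))
    r3 <- effective_distance(xa, xb, "R-3")
    expect_gte(r3, min(d) - 1e-9)
    expect_lte(r3, max(d) + 1e-9)
    # generalized-mean ordering: R-3 average <= centroid distance would need
    # convexity both ways; what always holds is R-3 <= plain mean distance
    expect_lte(r3, mean(d) + 1e-9)
  }
  # short pairs dominate: R-3 < center when one pair is much closer
  xa <- matrix(c(0, 0, 0), 1, 3)
  xb <- rbind(c(5, 0, 0), c(40, 0, 0))
  expect_lt(effective_distance(xa, xb, "R-3"),
            effective_distance(xa, xb, "center"))
})

test_that("square-well energy reproduces the worked distance-violation cases", {
  p <- restraint_params()
  r33 <- distance_restraint("all", "all", 33, 2, 2)
  row <- square_well_energy(37.937, r33, p)
  expect_equal(row$energy, 86.25969, tolerance = 1e-5)
  expect_equal(row$delta, -2.937)
  r78 <- distance_restraint("all", "all", 78, 0.1, 0.1)
  row2 <- square_well_energy(80.584, r78, p)
  expect_equal(row2$energy, 61.70256, tolerance = 1e-5)
  expect_equal(row2$delta, -2.484)
  # inside the well: zero energy, zero delta
  inwell <- square_well_energy(34.0, r33, p)
  expect_equal(inwell$energy, 0)
  expect_equal(inwell$delta, 0)
  # short-side violation has positive delta
  short <- square_well_energy(29, r33, p)
  expect_equal(short$delta, 2)
  expect_equal(short$energy, 10 * 4)
})

test_that("ceiling caps the unscaled well term at scale * ceiling", {
  p <- restraint_params()
  r33 <- distance_restraint("all", "all", 33, 2, 2)
  expect_equal(square_well_energy(1000, r33, p)$energy, 10 * 50)
  # property: never exceeds the cap, continuous, monotone in |violation|
  rs <- seq(20, 300, by = 0.5)
  es <- vapply(rs, function(r) square_well_energy(r, r33, p)$energy,
               numeric(1))
  expect_true(all(es <= 500 + 1e-12))
  expect_true(all(diff(es[rs >= 35]) >= -1e-12))
  expect_lt(max(abs(diff(es))), 80)  # no jumps: slope <= 2*scale*sqrt(ceiling)
  # linear mode agrees below the cap and is C1 through it
  vcap <- sqrt(50)
  near <- 35 + vcap
  for (r in c(36, 40, near - 1e-3)) {
    expect_equal(square_well_energy(r, r33, p, "linear")$energy,
                 square_well_energy(r, r33, p, "capped")$energy)
  }
  lin <- function(r) square_well_energy(r, r33, p, "linear")$energy
  slope_below <- (lin(near) - lin(near - 1e-4)) / 1e-4
  slope_above <- (lin(near + 1e-4) - lin(near)) / 1e-4
  expect_equal(slope_below, slope_above, tolerance = 1e-2)
})

test_that("restraint energy gradient matches central finite differences", {
  set.seed(21)
  p <- restraint_params()
  r <- distance_restraint("all", "all", 12, 1, 1)
  for (rep in 1:5) {
    xa <- random_points(4, 2)
    xb <- random_points(3, 2) + c(9, 0, 0)
    for (mode in c("capped", "linear")) {
      eg <- spindock:::effective_distance_grad(xa, xb, "R-3")
      row <- square_well_energy(eg$r, r, p, mode)
      ana <- row$dEdr * eg$grad_a
      num <- matrix(0, nrow(xa), 3)
      h <- 1e-6
      for (i in seq_len(nrow(xa))) for (k in 1:3) {
        pm <- function(sgn) {
          xp <- xa; xp[i, k] <- xp[i, k] + sgn * h
          square_well_energy(effective_distance(xp, xb, "R-3"), r, p,
                             mode)$energy
        }
        num[i, k] <- (pm(1) - pm(-1)) / (2 * h)
      }
      if (max(abs(num)) > 1e-8) expect_rel_error(ana, num, 1e-5)
    }
  }
})

test_that("NOE summary reproduces the three-row RMS / violation bookkeeping", {
  p <- restraint_params()
  r33 <- distance_restraint("all", "all", 33, 2, 2)
  r78 <- distance_restraint("all", "all", 78, 0.1, 0.1)
  rows <- list(square_well_energy(37.937, r33, p),
               square_well_energy(37.937, r33, p),
               square_well_energy(80.584, r78, p))
  sm <- noe_summary(rows)
  expect_equal(sm$rms, 2.794172, tolerance = 1e-5)
  expect_equal(sm$n_violated, 3L)
  expect_equal(sm$n, 3L)
  expect_equal(sm$total, 234.2219, tolerance = 1e-3)
  # all-satisfied set
  ok <- list(square_well_energy(33, r33, p), square_well_energy(34, r33, p),
             square_well_energy(32, r33, p))
  sm0 <- noe_summary(ok)
  expect_equal(sm0$total, 0)
  expect_equal(sm0$rms, 0)
  expect_equal(sm0$n_violated, 0L)
  # single row
  one <- square_well_energy(38, distance_restraint("all", "all", 33, 2, 2), p)
  expect_equal(noe_summary(list(one))$rms, 3.0)
  expect_error(noe_summary(list()), "no restraint rows")
})

test_that("restraint tables round-trip and evaluate against structures", {
  rs <- list(
    distance_restraint("segid S and resid 1 and name N*",
                       "segid T and resid 1 and name N*", 33, 2, 2, "pair1"),
    distance_restraint("segid S and resid 2 and name N*",
                       "segid T and resid 2 and name N*", 78, 0.1, 0.1))
  tf <- withr::local_tempfile(fileext = ".tbl")
  write_restraint_table(rs, tf)
  back <- read_restraint_table(tf)
  expect_length(back, 2L)
  expect_equal(back[[1]]$d_target, 33)
  expect_equal(back[[2]]$d_plus, 0.1)
  expect_equal(back[[1]]$sel_a$text, "segid S and resid 1 and name N*")
  s <- make_structure(
    name = rep("N001", 4), resname = "SPIN",
    segid = c("S", "T", "S", "T"), resid = c(1, 1, 2, 2),
    xyz = rbind(c(0, 0, 0), c(40, 0, 0), c(0, 10, 0), c(78, 10, 0)))
  rows <- evaluate_restraints(s, back)
  expect_equal(rows[[1]]$r_average, 40)
  expect_equal(rows[[1]]$delta, -5)
  expect_equal(rows[[2]]$energy, 0)
})

test_that("Kabsch superposition: exact cases and brute-force oracle", {
  x <- random_points(6, seed = 4)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  shifted <- x + matrix(c(5, 0, 0), 6, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(x, shifted)$rmsd, 0, tolerance = 1e-10)
  R <- rotation_about_axis(c(2, -1, 1), 1.3)
  fit <- kabsch_superpose(x, x %*% t(R) + 2)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # unit right triangle with one displaced vertex vs brute-force minimum
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tri2 <- tri; tri2[3, ] <- tri2[3, ] + c(0, 1, 0)
  got <- kabsch_superpose(tri, tri2)$rmsd
  oracle <- optim(c(0, 0, 0), function(ang) {
    R <- rotation_about_axis(c(0, 0, 1), ang[1]) %*%
      rotation_about_axis(c(0, 1, 0), ang[2]) %*%
      rotation_about_axis(c(1, 0, 0), ang[3])
    yc <- sweep(tri2, 2, colMeans(tri2)) %*% t(R)
    xc <- sweep(tri, 2, colMeans(tri))
    sqrt(mean(rowSums((yc - xc)^2)))
  }, method = "Nelder-Mead",
  control = list(maxit = 5000, reltol = 1e-14))$value
  expect_equal(got, oracle, tolerance = 1e-6)
  # collinear sets are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("NCS energy: rigid-copy zero, closed-form two-copy oracle, linearity", {
  n <- 8
  p1 <- random_points(n, seed = 10)
  R <- rotation_about_axis(c(1, 0, 2), 0.9)
  p2 <- p1 %*% t(R) + matrix(c(30, 0, 0), n, 3, byrow = TRUE)
  s <- make_structure(rep("CA", 2 * n), "ALA", rep(c("A", "B"), each = n),
                      c(1:n, 1:n), rbind(p1, p2))
  g <- ncs_group(list("segid A and name CA", "segid B and name CA"))
  expect_lt(ncs_energy(list(g), s)$energy, 1e-12)
  # displace one atom: closed form for two copies is w/2 * n * rmsd^2
  p2b <- p2; p2b[4, ] <- p2b[4, ] + c(1, 0.5, -0.3)
  s2 <- make_structure(rep("CA", 2 * n), "ALA", rep(c("A", "B"), each = n),
                       c(1:n, 1:n), rbind(p1, p2b))
  got <- ncs_energy(list(g), s2)$energy
  oracle <- 0.5 * n * kabsch_superpose(p1, p2b)$rmsd^2
  expect_equal(got, oracle, tolerance = 1e-8)
  # linear in the weight
  g2 <- ncs_group(list("segid A and name CA", "segid B and name CA"),
                  weight_ncs = 2)
  expect_equal(ncs_energy(list(g2), s2)$energy, 2 * got, tolerance = 1e-10)
  # cardinality mismatch names the group
  bad <- ncs_group(list("segid A and name CA", "segid B and resid 1:3"))
  expect_error(ncs_energy(list(bad), s2), "cardinality")
})

test_that("NCS energy is invariant under global rigid motion of one copy", {
  n <- 9
  p1 <- random_points(n, seed = 14)
  p2 <- p1 %*% t(rotation_about_axis(c(0, 1, 0), 2)) + 5
  p2[2, ] <- p2[2, ] + 0.8   # genuine asymmetry so the energy is nonzero
  build <- function(q2) {
    make_structure(rep("CA", 2 * n), "ALA", rep(c("A", "B"), each = n),
                   c(1:n, 1:n), rbind(p1, q2))
  }
  g <- list(ncs_group(list("segid A and name CA", "segid B and name CA")))
  e0 <- ncs_energy(g, build(p2))$energy
  expect_gt(e0, 1e-4)
  for (rep in 1:3) {
    set.seed(rep)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, pi))
    tr <- rnorm(3, 0, 20)
    e1 <- ncs_energy(g, build(p2 %*% t(R) +
                                matrix(tr, n, 3, byrow = TRUE)))$energy
    expect_equal(e1, e0, tolerance = 1e-8)
  }
})

test_that("NCS gradient matches finite differences at 1e-4 relative", {
  f <- dock_fixture(seed = 6, perturb_deg = 5)
  s <- f$start
  g <- ncs_energy(f$ncs, s, gradient = TRUE)
  X <- coords(s)
  set.seed(3)
  idx <- sample(select_atoms(s, "name CA"), 5)
  h <- 1e-5
  for (i in idx) for (k in 1:3) {
    Xp <- X; Xp[i, k] <- Xp[i, k] + h
    Xm <- X; Xm[i, k] <- Xm[i, k] - h
    sp <- s; coords(sp) <- Xp
    sm <- s; coords(sm) <- Xm
    fd <- (ncs_energy(f$ncs, sp)$energy - ncs_energy(f$ncs, sm)$energy) /
      (2 * h)
    if (abs(fd) > 1e-6) {
      expect_equal(g$grad[i, k], fd, tolerance = 1e-4)
    }
  }
})
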