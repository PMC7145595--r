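test_that("Kabsch superposition handles identity, translation and noise", {
  withr::with_seed(1, P <- matrix(rnorm(12, sd = 3), 4, 3))
  same <- kabsch_superpose(P, P)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  shifted <- sweep(P, 2, c(5, 0, 0), "+")
  expect_equal(kabsch_superpose(shifted, P)$rmsd, 0, tolerance = 1e-10)

  # rotated + translated copy also fits exactly, with det(R) = +1
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(P %*% t(R), 2, c(1, -2, 3), "+")
  k <- kabsch_superpose(moved, P)
  expect_equal(k$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(k$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches a brute-force rotation search on 4-point toys", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      Q <- matrix(rnorm(12, sd = 2), 4, 3)
      P <- Q
      P[1, ] <- P[1, ] + c(1, 0, 0)  # one atom displaced 1 A
      svd_rmsd <- kabsch_superpose(P, Q)$rmsd
      grid_rmsd <- brute_min_rmsd(P, Q)
      expect_lt(abs(svd_rmsd - grid_rmsd), 1e-3)
    }
  })
})

test_that("degenerate fits are rejected", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line),
               class = "allostera_degenerate_fit_error")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]),
               class = "allostera_degenerate_fit_error")
})

test_that("RMSD series separates fit and measure selections", {
  top <- bead_topology(6)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
                c(10, 0, 0), c(10, 4, 0))
  nf <- 5
  co <- array(NA_real_, dim = c(6, 3, nf))
  for (f in 1:nf) {
    fr <- base
    if (f > 1) fr[5:6, 1] <- fr[5:6, 1] + 2  # measure group drifts 2 A
    co[, , f] <- fr
  }
  trj <- trajectory(bead_topology(6), co)
  static <- rmsd_series(trj, fit = 1:4, measure = 1:4)
  expect_equal(static$rmsd, rep(0, nf), tolerance = 1e-10)
  drift <- rmsd_series(trj, fit = 1:4, measure = 5:6)
  expect_equal(drift$rmsd, c(0, rep(2, nf - 1)), tolerance = 1e-8)

  # frame-local metric: reversing frames reverses the series
  rev_trj <- trajectory(bead_topology(6), co[, , nf:1])
  rev_series <- rmsd_series(rev_trj, reference = get_frame(trj, 1),
                            fit = 1:4, measure = 5:6)
  expect_equal(rev_series$rmsd, rev(drift$rmsd), tolerance = 1e-8)
})

test_that("RMSD is invariant under joint rigid transforms", {
  withr::with_seed(3, {
    A <- matrix(rnorm(15, sd = 2), 5, 3)
    B <- A + matrix(rnorm(15, sd = 0.3), 5, 3)
  })
  base <- kabsch_superpose(A, B)$rmsd
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  t <- c(-4, 2, 7)
  moved <- kabsch_superpose(sweep(A %*% t(R), 2, t, "+"),
                            sweep(B %*% t(R), 2, t, "+"))$rmsd
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("RMSF recovers hand-built and statistical fluctuation amplitudes", {
  # static trajectory -> zero everywhere
  top <- bead_topology(5)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 4, 4))
  static <- trajectory(top, array(rep(base, 4), dim = c(5, 3, 4)))
  expect_equal(rmsf(static)$rmsf, rep(0, 5), tolerance = 1e-10)
  expect_error(rmsf(trajectory(top, base)), class = "allostera_usage_error")

  # one bead alternating +-1 A about its mean, fit on the static beads
  co <- array(rep(base, 10), dim = c(5, 3, 10))
  co[5, 1, ] <- 4 + c(-1, 1)[rep(1:2, 5)]
  alt <- trajectory(top, co)
  r <- rmsf(alt, fit = 1:4)
  expect_equal(r$rmsf[1:4], rep(0, 4), tolerance = 1e-8)
  expect_equal(r$rmsf[5], 1, tolerance = 1e-8)

  # isotropic jitter sigma = 0.5 per axis -> sigma * sqrt(3); the fit runs
  # on separate static anchors so superposition does not absorb the jitter
  top10 <- bead_topology(10)
  anchors <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  mobiles <- rbind(c(4, 4, 0), c(4, 0, 4), c(0, 4, 4), c(4, 4, 4),
                   c(2, 2, 2), c(6, 2, 2))
  withr::with_seed(5, {
    nf <- 5000
    jit <- array(rep(rbind(anchors, mobiles), nf), dim = c(10, 3, nf))
    jit[5:10, , ] <- jit[5:10, , ] +
      array(rnorm(6 * 3 * nf, sd = 0.5), dim = c(6, 3, nf))
  })
  rj <- rmsf(trajectory(top10, jit), selection = 5:10, fit = 1:4)
  expect_lt(max(abs(rj$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3))), 0.05)
})

test_that("superposition removes rigid-body rotation from RMSF", {
  top <- bead_topology(4)
  base <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1, 1, 1))
  nf <- 12
  co <- array(NA_real_, dim = c(4, 3, nf))
  for (f in 1:nf) {
    th <- 2 * pi * (f - 1) / nf
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    co[, , f] <- base %*% t(R)
  }
  r <- rmsf(trajectory(top, co))
  expect_lt(max(r$rmsf), 1e-8)
})

test_that("COM distances follow hand-computed cases and the triangle rule", {
  top <- bead_topology(5)
  fr <- rbind(c(0, 0, 0), c(3, 4, 0), c(2, 0, 0), c(1, 5, 0), c(9, 9, 9))
  expect_equal(com_distance(fr, top, 1, 2), 5)
  # equal-mass pair at (0,0,0),(2,0,0) -> COM (1,0,0); vs (1,5,0) -> 5
  expect_equal(com_distance(fr, top, c(1, 3), 4), 5)
  expect_equal(com_distance(fr, top, c(1, 3), 4),
               com_distance(fr, top, 4, c(1, 3)))
  ab <- com_distance(fr, top, 1, 2)
  bc <- com_distance(fr, top, 2, 5)
  ac <- com_distance(fr, top, 1, 5)
  expect_lte(ac, ab + bc + 1e-12)

  hvy <- topology(data.frame(id = 1:2, name = "X", element = "C",
                             resid = 1:2, mass = c(1, 3)))
  fr2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(com_distance(fr2, hvy, 1, 2), 4)  # single atoms: mass cancels
})

test_that("CV series reproduce scripted COM motions", {
  top <- bead_topology(4)
  nf <- 100
  gap <- seq(5, 15, length.out = nf)
  co <- array(0, dim = c(4, 3, nf))
  for (f in 1:nf) {
    co[, , f] <- rbind(c(0, 1, 0), c(0, -1, 0),
                       c(gap[f], 1, 0), c(gap[f], -1, 0))
  }
  trj <- trajectory(top, co)
  defs <- list(cv_definition("cv1", c(1, 2), c(3, 4)))
  cv <- cv_series(trj, defs)
  expect_equal(cv$cv1, gap, tolerance = 1e-9)
  expect_error(cv_series(trj, list(cv_definition("bad", c(1, 2), c(2, 3)))),
               class = "allostera_usage_error")
  expect_error(cv_series(trj, list(cv_definition("miss", "resid 99", 1:2))),
               class = "allostera_selection_error")
})

test_that("distance series track static and scripted separations", {
  top <- bead_topology(2)
  nf <- 50
  co <- array(0, dim = c(2, 3, nf))
  co[2, 1, ] <- 3.7
  trj <- trajectory(top, co)
  expect_equal(distance_series(trj, 1, 2)$distance, rep(3.7, nf))

  lin <- array(0, dim = c(2, 3, nf))
  lin[2, 1, ] <- seq_len(nf)
  expect_equal(distance_series(trajectory(top, lin), 1, 2)$distance,
               as.numeric(seq_len(nf)))
  expect_error(distance_series(trj, 1, 99),
               class = "allostera_selection_error")
})
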