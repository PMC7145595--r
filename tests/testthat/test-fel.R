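test_that("landscape free energies follow bin populations", {
  # flat square: interior-bin spread stays within sampling noise (edge bins
  # straddle the support boundary and are only partially covered)
  withr::with_seed(1, {
    flat <- tibble::tibble(cv1 = runif(1e5, 0, 3), cv2 = runif(1e5, 0, 3))
  })
  g <- build_fel(flat, fel_spec())
  td <- tidy(g)
  interior <- td$valid & td$cv1 > 0.3 & td$cv1 < 2.7 & td$cv2 > 0.3 & td$cv2 < 2.7
  expect_lt(diff(range(td$F[interior])), 0.15)
  expect_equal(sum(g$counts), 1e5)

  # two tight clusters 2N vs N -> dF = kT ln 2
  n <- 4000
  two <- tibble::tibble(cv1 = c(rep(1, 2 * n), rep(5, n)),
                        cv2 = c(rep(1, 2 * n), rep(5, n)))
  g2 <- build_fel(two, fel_spec())
  i1 <- which(g2$counts == 2 * n, arr.ind = TRUE)
  i2 <- which(g2$counts == n, arr.ind = TRUE)
  expect_equal(g2$F[i2] - g2$F[i1], kT(300) * log(2), tolerance = 0.05)

  # all samples in one bin: that bin at 0, everything else masked
  one <- tibble::tibble(cv1 = rep(2, 1500), cv2 = rep(2, 1500))
  g3 <- build_fel(one, fel_spec())
  expect_equal(sum(g3$valid), 1)
  expect_equal(g3$F[g3$valid], 0)

  expect_error(build_fel(flat[0, ], fel_spec()),
               class = "allostera_usage_error")
  expect_error(fel_spec(bin_size = 0), class = "allostera_parameter_error")
})

test_that("binned free energy converges to the analytic density", {
  m <- state_model(data.frame(cv1 = 5, cv2 = 5, sd = 0.5, weight = 1))
  dev_at <- function(n, seed) {
    cv <- gen_cv_series(m, n = n, seed = seed)
    g <- build_fel(cv, fel_spec())
    td <- tidy(g)
    td <- td[td$valid & abs(td$cv1 - 5) < 1 & abs(td$cv2 - 5) < 1, ]
    ana <- kT(300) * ((td$cv1 - 5)^2 + (td$cv2 - 5)^2) / (2 * 0.5^2)
    max(abs((td$F - min(td$F)) - (ana - min(ana))))
  }
  expect_lt(dev_at(1e5, 2), dev_at(1e4, 2))
})

test_that("minima detection recovers generative state centres", {
  single <- state_model(data.frame(cv1 = 6, cv2 = 7, sd = 0.4, weight = 1))
  g1 <- build_fel(gen_cv_series(single, 5e4, seed = 3), fel_spec())
  m1 <- find_minima(g1)
  expect_equal(nrow(m1), 1)
  expect_lt(abs(m1$cv1 - 6), 0.45)
  expect_lt(abs(m1$cv2 - 7), 0.45)

  two <- state_model(data.frame(cv1 = c(7.8, 11.0), cv2 = c(9.0, 8.5),
                                sd = 0.4, weight = c(0.6, 0.4)))
  g2 <- build_fel(gen_cv_series(two, 2e5, seed = 4), fel_spec())
  m2 <- find_minima(g2)
  expect_equal(nrow(m2), 2)
  expect_lt(abs(m2$cv1[1] - 7.8), 0.45)   # global at the heavier state
  expect_lt(abs(m2$cv2[1] - 9.0), 0.45)
  expect_equal(m2$population, c(0.6, 0.4), tolerance = 0.05)
  expect_equal(as.character(m2$state_label), c("closed", "cap_open"))

  # two states closer than the merge radius collapse to one minimum
  near <- state_model(data.frame(cv1 = c(5, 5.5), cv2 = c(5, 5),
                                 sd = 0.4, weight = c(0.5, 0.5)))
  g3 <- build_fel(gen_cv_series(near, 1e5, seed = 5), fel_spec())
  expect_equal(nrow(find_minima(g3, merge_radius = 0.6)), 1)
})

test_that("state classification maps exemplar coordinates and partitions frames", {
  pts <- tibble::tibble(cv1 = c(11.5, 7.8, 9.5, 11.9, 11.0),
                        cv2 = c(12.2, 9.0, 10.5, 8.5, 9.0))
  cls <- classify_states(pts)
  expect_equal(as.character(cls$state_label),
               c("fully_open", "closed", "intermediate", "cap_open", "cap_open"))
  fr <- state_fractions(cls)
  expect_equal(sum(fr$fraction), 1)
  # every frame gets exactly one label
  expect_false(anyNA(cls$state_label))

  # boundary handling: exactly at a threshold is not "open"
  edge <- classify_states(tibble::tibble(cv1 = 10, cv2 = 11))
  expect_equal(as.character(edge$state_label), "intermediate")
  expect_error(state_thresholds(cap_open = 8, closed_cv1 = 9),
               class = "allostera_parameter_error")
})

test_that("minimax barriers match brute-force path enumeration on small grids", {
  # helper: exhaustive minimax over all simple paths of a tiny grid
  brute_minimax <- function(F, a, b) {
    nr <- nrow(F); nc <- ncol(F)
    id <- function(i, j) (j - 1) * nr + i
    nbrs <- function(v) {
      i <- (v - 1) %% nr + 1; j <- (v - 1) %/% nr + 1
      out <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(F[ii, jj])) {
          out <- c(out, id(ii, jj))
        }
      }
      out
    }
    best <- Inf
    walk <- function(v, seen, mx) {
      mx <- max(mx, F[v])
      if (mx >= best) return()
      if (v == id(b[1], b[2])) { best <<- mx; return() }
      for (w in nbrs(v)) if (!w %in% seen) walk(w, c(seen, w), mx)
    }
    start <- id(a[1], a[2])
    walk(start, start, -Inf)
    best
  }
  withr::with_seed(6, {
    for (rep in 1:5) {
      F <- matrix(round(runif(25, 0, 4), 2), 5, 5)
      F[sample(25, 4)] <- NA
      F[1, 1] <- 0; F[5, 5] <- 0.5
      fel <- structure(list(
        F = F, counts = matrix(10L, 5, 5), valid = !is.na(F),
        mids1 = 1:5, mids2 = 1:5, edges1 = 0:5 + 0.5, edges2 = 0:5 + 0.5,
        n = 250, spec = fel_spec(bin_size = 1),
        cv_names = c("cv1", "cv2")), class = "fel")
      res <- tryCatch(barrier_height(fel, c(1, 1), c(5, 5)),
                      allostera_disconnected_landscape_error = function(e) NULL)
      brute <- brute_minimax(F, c(1, 1), c(5, 5))
      if (is.null(res)) {
        expect_true(is.infinite(brute))
      } else {
        expect_equal(res$saddle, brute, tolerance = 1e-10)
      }
    }
  })
})

test_that("barrier heights are endpoint-consistent and zero on identity", {
  two <- state_model(data.frame(cv1 = c(4, 6.5), cv2 = c(5, 5), sd = 0.45,
                                weight = c(0.5, 0.5)))
  g <- build_fel(gen_cv_series(two, 1e5, seed = 8), fel_spec())
  m <- find_minima(g)
  b <- barrier_height(g, m[1, ], m[2, ])
  b_rev <- barrier_height(g, m[2, ], m[1, ])
  expect_equal(b$saddle, b_rev$saddle, tolerance = 1e-10)
  expect_equal(b$barrier_from, b_rev$barrier_to, tolerance = 1e-10)
  same <- barrier_height(g, m[1, ], m[1, ])
  expect_equal(same$barrier_from, 0)
})

test_that("rigid CV shifts leave minima, fractions and barriers unchanged", {
  two <- state_model(data.frame(cv1 = c(4, 6.5), cv2 = c(4, 4), sd = 0.45,
                                weight = c(0.6, 0.4)))
  cv <- gen_cv_series(two, 1e5, seed = 9)
  g <- build_fel(cv, fel_spec())
  m <- find_minima(g)
  b <- barrier_height(g, m[1, ], m[2, ])
  shifted <- dplyr::mutate(cv, cv1 = cv1 + 2.4, cv2 = cv2 - 1.2)
  gs <- build_fel(shifted, fel_spec())
  ms <- find_minima(gs)
  bs <- barrier_height(gs, ms[1, ], ms[2, ])
  expect_equal(nrow(ms), nrow(m))
  expect_equal(ms$cv1, m$cv1 + 2.4, tolerance = 1e-9)
  expect_equal(ms$population, m$population, tolerance = 1e-9)
  expect_equal(bs$barrier_from, b$barrier_from, tolerance = 1e-9)
})

test_that("convergence reports detect stationarity and late-arriving states", {
  two <- state_model(data.frame(cv1 = c(3, 7), cv2 = c(5, 5), sd = 0.4,
                                weight = c(0.55, 0.45)), switch_prob = 0.3)
  cv <- gen_cv_series(two, 8e4, seed = 10)
  rep1 <- fel_convergence(cv)
  expect_true(rep1$converged)
  fr <- rep1$results[rep1$results$setting == "fraction", ]
  expect_true(all(fr$n_minima == 2))
  bs <- rep1$results[rep1$results$setting == "bin_size", ]
  expect_true(all(bs$n_minima == 2))  # minima count invariant across bin sizes
  expect_true(all(bs$rms_dF[abs(bs$value - 0.3) < 1e-9] < 1e-9))

  # a state visited only in the last 10% is invisible at half sampling
  a <- gen_cv_series(state_model(data.frame(cv1 = 3, cv2 = 5, sd = 0.4,
                                            weight = 1)), 45000, seed = 11)
  b <- gen_cv_series(state_model(data.frame(cv1 = 7, cv2 = 5, sd = 0.4,
                                            weight = 1)), 5000, seed = 12)
  late <- dplyr::bind_rows(a, b)
  late$frame <- seq_len(nrow(late))
  rep2 <- fel_convergence(late, fractions = c(0.5, 1))
  fr2 <- rep2$results[rep2$results$setting == "fraction", ]
  expect_equal(fr2$n_minima[fr2$value == 0.5], 1)
  expect_equal(fr2$n_minima[fr2$value == 1], 2)
  expect_false(rep2$converged)
})
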