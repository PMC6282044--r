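# Iterated-reproduction chains: perception, reproduction, convergence
# metrics, mode detection, small-integer classification.

test_that("perception with vanishing noise recovers true categories at the means", {
  sys <- ratio2_system()
  att <- perceive(c(200, 400, 800, 400), sys, s_perception = 1e-9, seed = 1)
  expect_equal(att$labels, c(1L, 2L, 3L, 2L))
  a <- perceive(c(250, 410, 790), sys, 0.025, seed = 9)
  b <- perceive(c(250, 410, 790), sys, 0.025, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$perceived_ms, b$perceived_ms)
})

test_that("misattribution between ratio-2 categories at s = 0.025 is below 1%", {
  sys <- category_system(c(200, 400), s = 0.025)
  truth <- sample_iois(sys, 1e5, seed = 21)
  att <- perceive(truth, sys, s_perception = 0.025, seed = 22)
  err <- mean(att$labels != attr(truth, "category"))
  expect_lt(err, 0.01)
})

test_that("reproduction realizes labels as scalar-timing draws", {
  sys <- ratio2_system()
  att <- perceive(c(200, 400, 800), sys, 1e-9, seed = 1)
  out <- reproduce(att, sys, s_motor = 1e-9, seed = 2)
  expect_equal(as.numeric(out), c(200, 400, 800), tolerance = 1e-6)

  labels <- rep(1:3, length.out = 3e4)
  att_big <- structure(list(labels = labels, posterior = NULL),
                       class = "category_attribution")
  big <- reproduce(att_big, sys, s_motor = 0.025, seed = 3)
  for (k in 1:3) {
    xk <- as.numeric(big)[labels == k]
    expect_lt(abs(sd(xk) / mean(xk) - 0.025) / 0.025, 0.05)
  }
  # labels survive a perceive-reproduce cycle almost always
  recovered <- map_category(big, sys)
  expect_gt(mean(recovered == labels), 0.99)
})

test_that("a one-generation chain is just the uniform seed sample", {
  sys <- ratio2_system()
  ch <- run_chain(chain_config(1, 64, rng_seed = 5), sys)
  expect_length(ch$records, 1L)
  x <- as.numeric(ch$records[[1]]$iois)
  expect_true(all(x > 100 & x < 1000))
  expect_gt(suppressWarnings(ks.test(x, "punif", 100, 1000))$p.value, 0.01)
})

test_that("identical chain configurations give bit-identical chains", {
  sys <- ratio2_system()
  cfg <- chain_config(4, 32, rng_seed = 77)
  a <- run_chain(cfg, sys)
  b <- run_chain(cfg, sys)
  for (g in seq_along(a$records)) {
    expect_identical(as.numeric(a$records[[g]]$iois),
                     as.numeric(b$records[[g]]$iois))
    expect_identical(a$records[[g]]$metrics$modes_ms,
                     b$records[[g]]$metrics$modes_ms)
  }
})

test_that("chains collapse onto the prior's mode structure generation by generation", {
  sys <- ratio2_system()
  n_rep <- 10L
  w1p <- w1m <- entro <- matrix(NA_real_, n_rep, 5)
  for (i in seq_len(n_rep)) {
    ch <- run_chain(chain_config(5, 32, rng_seed = 100 + i), sys,
                    max_modes = 1)  # distribution-level study: skip mode scan
    w1p[i, ] <- vapply(ch$records, function(g) g$metrics$w1_to_prior_ms,
                       numeric(1))
    w1m[i, ] <- vapply(ch$records, function(g) g$metrics$w1_to_modes_ms,
                       numeric(1))
    entro[i, ] <- vapply(ch$records, function(g)
      g$metrics$label_entropy_bits, numeric(1))
  }
  # the occupancy-matched distance contracts sharply at the first
  # transmission step and stays at the scalar-noise floor afterwards
  expect_lt(colMeans(w1m)[2], 0.25 * colMeans(w1m)[1])
  expect_true(all(colMeans(w1m)[-1] < 0.25 * colMeans(w1m)[1]))
  # the distance to the equal-weight prior never grows systematically:
  # category occupancies are frozen at the seed's proportions, so this
  # metric plateaus rather than shrinking (allow a few ms of noise)
  expect_true(all(diff(colMeans(w1p)) <= 4))
  # label entropy non-increasing in expectation (flat for equal weights)
  expect_true(all(diff(colMeans(entro)) <= 0.05))
})

test_that("mode detection recovers generating structure and is deterministic", {
  one <- sample_iois(category_system(400, s = 0.025), 300, seed = 31)
  m1 <- detect_modes(one)
  expect_equal(m1$mode_count, 1L)
  expect_equal(m1$modes_ms, 400, tolerance = 0.01)

  three <- sample_iois(ratio2_system(), 1000, seed = 32)
  m3 <- detect_modes(three)
  expect_equal(m3$mode_count, 3L)
  expect_equal(m3$modes_ms, c(200, 400, 800), tolerance = 0.02)

  expect_identical(detect_modes(three), m3)
  expect_error(detect_modes(as.numeric(three)[1:30]), class = "rp_domain_error")
})

test_that("nearest small-integer ratio enumerates lowest-term fractions", {
  et5 <- nearest_small_integer_ratio(2^(7 / 12), max_int = 4)
  expect_equal(c(et5$p, et5$q), c(3, 2))
  expect_equal(et5$deviation, 0.00113, tolerance = 1e-2)

  exact <- nearest_small_integer_ratio(1.0)
  expect_equal(c(exact$p, exact$q, exact$deviation), c(1, 1, 0))

  odd <- nearest_small_integer_ratio(23 / 51, max_int = 4)
  expect_gt(odd$deviation, 0.05)

  # lowest terms and tie-breaks: 2 must report 2/1, not 4/2
  two <- nearest_small_integer_ratio(2)
  expect_equal(c(two$p, two$q), c(2, 1))
  gcd <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
  set.seed(6)
  for (r in runif(50, 0.3, 4)) {
    best <- nearest_small_integer_ratio(r, max_int = 5)
    expect_equal(gcd(best$p, best$q), 1)
    # exhaustive check that nothing closer exists
    grid <- expand.grid(p = 1:5, q = 1:5)
    devs <- abs(r - grid$p / grid$q) / (grid$p / grid$q)
    expect_equal(best$deviation, min(devs), tolerance = 1e-12)
  }
})
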