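# Closed-form algebra: scalar variance law, overlap-parameterized ratios,
# mean recursion, category-count bound, intersection identity, solvers.

test_that("scalar variance law multiplies mean by the Weber fraction", {
  expect_equal(sigma_from_mu(1000, 0.025), 25)
  expect_equal(sigma_from_mu(100, 0.025), 2.5)
  expect_equal(sigma_from_mu(c(200, 400), 0.05), c(10, 20))
  expect_error(sigma_from_mu(100, 0), class = "rp_domain_error")
  expect_error(sigma_from_mu(-5, 0.025), class = "rp_domain_error")
})

test_that("overlap-implied mean ratio matches the placement identity", {
  # vanishing overlap: ratio tends to 1
  tiny <- boundary_overlap(1e-10, 1e-10)
  expect_equal(ratio_from_overlap(0.025, tiny), 1, tolerance = 1e-8)
  # jointly solved pair reproduces the target ratio to 3+ decimals
  ov <- joint_solve_overlap(0.025, 2)
  expect_equal((1 + 0.025 * ov$c_upper) / (1 - 0.025 * ov$c_lower_next), 2,
               tolerance = 1e-9)
  # the feasibility bound c_lower_next < 1/s is enforced at the boundary
  expect_error(ratio_from_overlap(0.025, boundary_overlap(2, 40)),
               class = "rp_feasibility_error")
  expect_error(boundary_overlap(-1, 2), class = "rp_domain_error")
  expect_error(boundary_overlap(2, 0), class = "rp_domain_error")
})

test_that("mean ratio is strictly increasing in both overlap parameters", {
  s <- 0.025
  base <- ratio_from_overlap(s, boundary_overlap(5, 5))
  for (d in c(0.1, 1, 5)) {
    expect_gt(ratio_from_overlap(s, boundary_overlap(5 + d, 5)), base)
    expect_gt(ratio_from_overlap(s, boundary_overlap(5, 5 + d)), base)
  }
})

test_that("mean recursion multiplies by the ratio", {
  expect_equal(next_mean(100, 2), 200)
  expect_equal(next_mean(337, 1), 337)
  expect_equal(next_mean(200, 1.5), 300)
  expect_error(next_mean(-1, 2), class = "rp_domain_error")
  expect_error(next_mean(100, 0), class = "rp_domain_error")
})

test_that("boundary x-coordinate is the mean offset by c standard deviations", {
  expect_equal(intersection_x(100, 0.025, 2.5, "upper"), 106.25)
  expect_equal(intersection_x(400, 0.025, 0, "upper"), 400)
  expect_equal(intersection_x(400, 0.025, 0, "lower"), 400)
  expect_error(intersection_x(100, 0.5, 3, "lower"), class = "rp_domain_error")
})

test_that("the two boundary parameterizations agree for joint-solved pairs", {
  set.seed(42)
  for (i in 1:50) {
    s <- runif(1, 0.01, 0.2)
    r <- runif(1, 1.2, 3)
    ov <- tryCatch(joint_solve_overlap(s, r), rp_error = function(e) NULL)
    if (is.null(ov)) next
    mu_k <- runif(1, 100, 400)
    mu_next <- next_mean(mu_k, ratio_from_overlap(s, ov))
    from_below <- intersection_x(mu_k, s, ov$c_upper, "upper")
    from_above <- intersection_x(mu_next, s, ov$c_lower_next, "lower")
    expect_equal(from_below, from_above, tolerance = 1e-9)
  }
})

test_that("mean placement identity holds on random feasible draws", {
  # mu_next - mu_k == s*c_lower_next*mu_next + s*c_upper*mu_k
  set.seed(7)
  n_ok <- 0L
  while (n_ok < 1000L) {
    s <- runif(1, 0.005, 0.3)
    cu <- runif(1, 0.01, 20)
    cl <- runif(1, 0.01, 0.999 / s)
    mu_k <- runif(1, 50, 900)
    r <- ratio_from_overlap(s, boundary_overlap(cu, cl))
    mu_next <- next_mean(mu_k, r)
    lhs <- mu_next - mu_k
    rhs <- s * cl * mu_next + s * cu * mu_k
    expect_equal(lhs, rhs, tolerance = 1e-9)
    n_ok <- n_ok + 1L
  }
})

test_that("intersection identity residual vanishes exactly at the equal-density solution", {
  c2l <- sqrt(2.5^2 - 2 * log(2))  # the worked 100/200 ms boundary
  expect_equal(
    intersection_identity_residual(boundary_overlap(2.5, c2l), 100, 200), 0,
    tolerance = 1e-12)
  # equal overlap parameters can never satisfy the identity
  res <- intersection_identity_residual(boundary_overlap(3, 3), 100, 200)
  expect_equal(res, -2 * log(2))
  expect_lt(res, 0)
  expect_error(intersection_identity_residual(boundary_overlap(2, 1), 200, 200),
               class = "rp_domain_error")
})

test_that("solve_c_lower returns the positive root of the intersection identity", {
  expect_equal(solve_c_lower(2.5, 2), 2.205381, tolerance = 1e-6)
  expect_equal(round(solve_c_lower(2.5, 2), 1), 2.2)
  expect_equal(solve_c_lower(1.7, 1), 1.7)  # ln 1 = 0, algebraic limit
  expect_error(solve_c_lower(1.0, 2), class = "rp_no_real_root")
  # round trip: solve(c, r)^2 + 2 ln r recovers c^2 to floating precision
  set.seed(11)
  for (i in 1:200) {
    r <- runif(1, 1, 4)
    c_up <- runif(1, sqrt(2 * log(r)) + 0.01, 25)
    expect_equal(solve_c_lower(c_up, r)^2 + 2 * log(r), c_up^2,
                 tolerance = 1e-12)
  }
})

test_that("joint overlap solve agrees with the scan-and-bisect oracle", {
  for (case in list(c(0.025, 2), c(0.025, 1.5), c(0.05, 2), c(0.1, 1.3))) {
    s <- case[1]; r <- case[2]
    ov <- joint_solve_overlap(s, r)
    roots <- scan_joint_roots(s, r)
    expect_true(length(roots) >= 1L)
    expect_equal(ov$c_lower_next, min(roots), tolerance = 1e-6)
    # both identities hold at the returned pair
    expect_lt(abs(ratio_from_overlap(s, ov) - r), 1e-6)
    mu2 <- next_mean(100, r)
    expect_lt(abs(intersection_identity_residual(ov, 100, mu2)), 1e-6)
  }
  # frozen values from the oracle for the canonical case
  ov <- joint_solve_overlap(0.025, 2)
  expect_equal(ov$c_lower_next, 13.31602, tolerance = 1e-5)
  expect_equal(ov$c_upper, 13.36797, tolerance = 1e-5)
})

test_that("joint solve rejects parameter pairs with no feasible root", {
  # scan oracle confirms: no sign change inside (0, 1/s) for s=0.9, r=1.5
  expect_length(scan_joint_roots(0.9, 1.5), 0L)
  expect_error(joint_solve_overlap(0.9, 1.5), class = "rp_infeasible")
  expect_error(joint_solve_overlap(0.025, 1), class = "rp_domain_error")
})

test_that("category systems are built by recursion up to the mean bound", {
  sys <- build_category_system(200, 0.025, 2)
  expect_equal(sys$means, c(200, 400, 800))
  expect_equal(sys$K, 3L)
  expect_equal(sys$sds, 0.025 * sys$means)
  expect_equal(sys$weights, rep(1 / 3, 3))

  expect_equal(build_category_system(1000, 0.025, 1.7)$K, 1L)
  sys4 <- build_category_system(200, 0.025, c(1.5, 1.5, 1.5))
  expect_equal(sys4$means, c(200, 300, 450, 675))
  expect_equal(sys4$K, 4L)

  expect_error(build_category_system(50, 0.025, 2), class = "rp_domain_error")
  expect_error(build_category_system(200, 0.025, boundary_overlap(2, 45)),
               class = "rp_feasibility_error")
})

test_that("category count bound follows the recursion", {
  expect_equal(max_categories(200, 2), 3L)
  expect_equal(max_categories(200, 10), 1L)
  expect_equal(max_categories(500, 1.5), 2L)
})

test_that("category system JSON round-trips and re-derives SDs", {
  sys <- ratio2_system()
  js <- system_to_json(sys)
  back <- system_from_json(js)
  expect_equal(back$means, sys$means)
  expect_equal(back$s, sys$s)
  expect_equal(back$sds, sys$sds)  # derived, not stored
  expect_false(grepl("sds", as.character(js)))
  expect_error(system_from_json('{"s": 0.025}'), class = "rp_domain_error")
})

test_that("infeasible overlaps are rejected everywhere, never clamped", {
  # property fuzz: any c_lower_next >= 1/s must raise, across entry points
  set.seed(99)
  for (i in 1:200) {
    s <- runif(1, 0.01, 0.5)
    cl <- 1 / s * runif(1, 1, 3)  # at or beyond the bound
    ov <- boundary_overlap(runif(1, 0.1, 10), cl)
    expect_error(ratio_from_overlap(s, ov), class = "rp_feasibility_error")
    expect_error(build_category_system(500, s, ov,
                                       scalar_timing_params(s = s)),
                 class = "rp_feasibility_error")
  }
  tab <- grid_explore(0.025, list(boundary_overlap(2, 40)), 500)
  expect_false(tab$feasible[1])
  expect_equal(tab$reason[1], "overlap_infeasible")
})
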