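# Shared fixtures and independent oracles.

# the canonical ratio-2 system: means 200/400/800 ms, s = 0.025
ratio2_system <- function(s = 0.025) {
  category_system(c(200, 400, 800), s = s)
}

# Independent oracle for the joint overlap solve: substitute the
# mean-placement identity c_upper(c_l) = (r*(1 - s*c_l) - 1)/s into the
# equal-density identity, scan c_l over (0, 1/s) at step 1e-4 for sign
# changes of the residual, and bisect each bracket. Returns all roots found.
scan_joint_roots <- function(s, r, step = 1e-4) {
  resid <- function(cl) {
    cu <- (r * (1 - s * cl) - 1) / s
    cu^2 - cl^2 - 2 * log(r)
  }
  grid <- seq(step, 1 / s - step, by = step)
  vals <- resid(grid)
  flips <- which(vals[-1] * vals[-length(vals)] < 0)
  vapply(flips, function(i)
    stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-12)$root,
    numeric(1))
}

# numeric intersection of two adjacent scaled Gaussian components:
# bisection on the density difference between the two means
numeric_intersection <- function(system, k) {
  f <- function(x)
    system$weights[k] * dnorm(x, system$means[k], system$sds[k]) -
      system$weights[k + 1] * dnorm(x, system$means[k + 1], system$sds[k + 1])
  stats::uniroot(f, c(system$means[k], system$means[k + 1]),
                 tol = 1e-12)$root
}

# classification used for chain convergence: multimodal with every
# adjacent modal ratio within `tol` (relative) of `target`
modes_near_ratio <- function(metrics, target = 2, tol = 0.05) {
  m <- metrics$modes_ms
  if (is.na(metrics$mode_count) || metrics$mode_count < 2L) return(FALSE)
  r <- m[-1] / m[-length(m)]
  all(abs(r - target) / target <= tol)
}
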