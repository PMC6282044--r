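#' Scalar-timing parameters
#'
#' Bundle of the Weber fraction `s` and the admissible range of category
#' means. Under the scalar property of interval timing, the standard
#' deviation of the internal representation of a duration is proportional to
#' that duration: `sigma = s * mu`. Empirical estimates for sub-second
#' musical timing put `s` near 0.025. Category means are conventionally
#' bounded between 200 ms (shortest perceivable rhythmic category) and
#' 1000 ms (upper edge of the sub-second range).
#'
#' @param s Weber fraction (dimensionless, > 0). Default 0.025.
#' @param mu_min Smallest admissible category mean, in ms. Default 200.
#' @param mu_max Largest admissible category mean, in ms. Default 1000.
#' @return An object of class `scalar_timing_params`.
#' @examples
#' scalar_timing_params()
#' scalar_timing_params(s = 0.05, mu_min = 100)
#' @export
scalar_timing_params <- function(s = 0.025, mu_min = 200, mu_max = 1000) {
  check_positive_scalar(s, "s")
  check_positive_scalar(mu_min, "mu_min")
  check_positive_scalar(mu_max, "mu_max")
  if (mu_min >= mu_max)
    stop_domain("`mu_min` (%g) must be smaller than `mu_max` (%g)",
                mu_min, mu_max)
  structure(list(s = s, mu_min = mu_min, mu_max = mu_max),
            class = "scalar_timing_params")
}

#' @export
print.scalar_timing_params <- function(x, ...) {
  cat(sprintf("Scalar timing: s = %g, category means in [%g, %g] ms\n",
              x$s, x$mu_min, x$mu_max))
  invisible(x)
}

#' Boundary overlap parameters for one inter-category intersection
#'
#' The boundary between two adjacent duration categories k and k+1 is the
#' point where their Gaussian densities intersect. Seen from below it lies
#' `c_upper` standard deviations above the lower category's mean; seen from
#' above it lies `c_lower_next` standard deviations below the upper
#' category's mean. Together with the Weber fraction these two dimensionless
#' numbers fix the ratio between the adjacent category means (see
#' [ratio_from_overlap()]).
#'
#' For the ratio to be defined, `c_lower_next` must be strictly below `1/s`;
#' that feasibility check is applied wherever an overlap meets a Weber
#' fraction, never silently clamped.
#'
#' @param c_upper Distance (in SD units) from the lower category's mean up
#'   to the boundary; > 0.
#' @param c_lower_next Distance (in SD units) from the upper category's mean
#'   down to the boundary; > 0.
#' @return An object of class `boundary_overlap`.
#' @examples
#' boundary_overlap(2.5, 2.2)
#' @export
boundary_overlap <- function(c_upper, c_lower_next) {
  check_positive_scalar(c_upper, "c_upper")
  check_positive_scalar(c_lower_next, "c_lower_next")
  structure(list(c_upper = c_upper, c_lower_next = c_lower_next),
            class = "boundary_overlap")
}

#' @export
print.boundary_overlap <- function(x, ...) {
  cat(sprintf("Boundary overlap: c_upper = %g, c_lower_next = %g (SD units)\n",
              x$c_upper, x$c_lower_next))
  invisible(x)
}

# shared feasibility guard: c_lower_next < 1/s
check_overlap_feasible <- function(overlap, s) {
  if (overlap$c_lower_next >= 1 / s)
    stop_feasibility(
      "infeasible overlap: c_lower_next = %g must be < 1/s = %g for the mean ratio to be defined",
      overlap$c_lower_next, 1 / s)
  invisible(overlap)
}
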