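# Closed-form algebra of scalar timing and category overlaps.
#
# Model summary. Duration categories are Gaussians N(mu_k, sigma_k) with the
# scalar tie sigma_k = s * mu_k. Adjacent categories k and k+1 intersect at a
# boundary that sits c_upper SDs above mu_k and c_lower_next SDs below
# mu_{k+1}. Two identities follow:
#   (mean placement)  r_k = mu_{k+1}/mu_k = (1 + s*c_upper)/(1 - s*c_lower_next)
#   (equal density)   c_upper^2 - c_lower_next^2 = 2 * ln(r_k)
# The first requires 0 < c_lower_next < 1/s. Solving both simultaneously
# yields the unique overlap pair consistent with a true density intersection.

#' Scalar-timing standard deviation of a duration category
#'
#' Under the scalar property, the SD of a duration category equals its mean
#' times the Weber fraction: `sigma = s * mu`.
#'
#' @param mu Category mean(s) in ms; positive.
#' @param s Weber fraction; positive.
#' @return SD(s) in ms.
#' @examples
#' sigma_from_mu(1000, 0.025)  # 25
#' @export
sigma_from_mu <- function(mu, s) {
  if (!is.numeric(mu) || length(mu) < 1L || any(!is.finite(mu)) || any(mu <= 0))
    stop_domain("`mu` must be positive and finite")
  check_positive_scalar(s, "s")
  s * mu
}

#' Ratio of adjacent category means implied by an overlap
#'
#' The mean placement identity: if the boundary between categories k and
#' k+1 is `c_upper` SDs above `mu_k` and `c_lower_next` SDs below
#' `mu_{k+1}`, scalar timing forces
#' `mu_{k+1}/mu_k = (1 + s*c_upper) / (1 - s*c_lower_next)`.
#' Defined only for `c_lower_next < 1/s`.
#'
#' @param s Weber fraction.
#' @param overlap A [boundary_overlap()].
#' @return The dimensionless ratio `mu_{k+1}/mu_k` (> 1).
#' @examples
#' ratio_from_overlap(0.025, boundary_overlap(13.368, 13.316))  # ~2
#' @export
ratio_from_overlap <- function(s, overlap) {
  check_positive_scalar(s, "s")
  if (!inherits(overlap, "boundary_overlap"))
    stop_domain("`overlap` must be a boundary_overlap object")
  check_overlap_feasible(overlap, s)
  (1 + s * overlap$c_upper) / (1 - s * overlap$c_lower_next)
}

#' Next category mean by the ratio recursion
#'
#' Category means are generated recursively: `mu_{k+1} = r_k * mu_k`.
#'
#' @param mu_k Current mean in ms; positive.
#' @param r_k Ratio to the next mean; positive.
#' @return `r_k * mu_k` in ms.
#' @examples
#' next_mean(100, 2)  # 200
#' @export
next_mean <- function(mu_k, r_k) {
  check_positive_scalar(mu_k, "mu_k")
  check_positive_scalar(r_k, "r_k")
  r_k * mu_k
}

#' x-coordinate of a category boundary seen from one category
#'
#' The boundary lies `c` SDs away from the category mean:
#' `mu + s*c*mu` from below (`side = "upper"`) or `mu - s*c*mu` from above
#' (`side = "lower"`).
#'
#' @param mu Category mean in ms.
#' @param s Weber fraction.
#' @param c_sd Distance to the boundary in SD units; >= 0.
#' @param side `"upper"` for the boundary above `mu`, `"lower"` for the one
#'   below.
#' @return Boundary location in ms.
#' @examples
#' intersection_x(100, 0.025, 2.5, "upper")  # 106.25
#' @export
intersection_x <- function(mu, s, c_sd, side = c("upper", "lower")) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(s, "s")
  side <- match.arg(side)
  if (!is.numeric(c_sd) || length(c_sd) != 1L || !is.finite(c_sd) || c_sd < 0)
    stop_domain("`c_sd` must be a single non-negative finite number")
  if (side == "upper") return(mu * (1 + s * c_sd))
  if (s * c_sd >= 1)
    stop_domain("lower-side boundary would be non-positive: s*c = %g >= 1",
                s * c_sd)
  mu * (1 - s * c_sd)
}

#' Residual of the equal-density intersection identity
#'
#' At a genuine density intersection between adjacent scalar-timing
#' Gaussians, the difference of squared overlap parameters equals twice the
#' log mean ratio: `c_upper^2 - c_lower_next^2 = 2*ln(mu_next/mu_k)`. This
#' returns the left side minus the right side; it is zero iff the two
#' category densities are equal at the boundary. Because the right side is
#' strictly positive for increasing means, `c_upper` can never equal
#' `c_lower_next` at a true intersection.
#'
#' @param overlap A [boundary_overlap()].
#' @param mu_k Lower category mean in ms.
#' @param mu_next Upper category mean in ms; must exceed `mu_k`.
#' @return Dimensionless residual.
#' @examples
#' intersection_identity_residual(boundary_overlap(2.5, 2.2054), 100, 200)
#' @export
intersection_identity_residual <- function(overlap, mu_k, mu_next) {
  if (!inherits(overlap, "boundary_overlap"))
    stop_domain("`overlap` must be a boundary_overlap object")
  check_positive_scalar(mu_k, "mu_k")
  check_positive_scalar(mu_next, "mu_next")
  if (mu_next <= mu_k)
    stop_domain("`mu_next` (%g) must exceed `mu_k` (%g)", mu_next, mu_k)
  (overlap$c_upper^2 - overlap$c_lower_next^2) - 2 * log(mu_next / mu_k)
}

#' Solve the intersection identity for the lower overlap parameter
#'
#' Given the upper overlap parameter and the ratio of adjacent means,
#' returns the unique positive root of
#' `c_lower_next = sqrt(c_upper^2 - 2*ln(r))`.
#' `r = 1` is admitted as the algebraic limit (ln 1 = 0) even though a real
#' category system requires `r > 1`.
#'
#' @param c_upper Upper overlap parameter (SD units); positive.
#' @param r Ratio of adjacent category means; >= 1.
#' @return The lower overlap parameter (SD units).
#' @examples
#' solve_c_lower(2.5, 2)  # 2.2054
#' @export
solve_c_lower <- function(c_upper, r) {
  check_positive_scalar(c_upper, "c_upper")
  check_positive_scalar(r, "r")
  if (r < 1)
    stop_domain("`r` must be >= 1 for an increasing category system")
  rad <- c_upper^2 - 2 * log(r)
  if (rad < 0)
    stop_no_real_root(
      "no real solution: c_upper^2 = %g is below 2*ln(r) = %g",
      c_upper^2, 2 * log(r))
  sqrt(rad)
}

#' Jointly solve the overlap pair for a target mean ratio
#'
#' Finds the `(c_upper, c_lower_next)` pair that simultaneously satisfies
#' the mean placement identity and the equal-density intersection identity
#' for a given Weber fraction `s` and target ratio `r`. Substituting
#' `c_upper = (r*(1 - s*c_lower) - 1)/s` into the intersection identity
#' gives a quadratic in `c_lower`:
#' `(r^2-1)*c^2 - (2*r*(r-1)/s)*c + ((r-1)^2/s^2 - 2*ln(r)) = 0`,
#' solved analytically. A root is feasible when `0 < c_lower < 1/s` and the
#' implied `c_upper` is positive; if both roots are feasible the smaller
#' `c_lower_next` (better-separated categories) is returned.
#'
#' @param s Weber fraction, in (0, 1).
#' @param r Target ratio of adjacent category means; > 1.
#' @return A [boundary_overlap()] satisfying both identities.
#' @examples
#' ov <- joint_solve_overlap(0.025, 2)
#' ratio_from_overlap(0.025, ov)                       # 2
#' intersection_identity_residual(ov, 100, 200)        # ~0
#' @export
joint_solve_overlap <- function(s, r) {
  check_positive_scalar(s, "s")
  check_positive_scalar(r, "r")
  if (s >= 1) stop_domain("`s` must be in (0, 1)")
  if (r <= 1) stop_domain("`r` must exceed 1")
  a <- r^2 - 1
  b <- -2 * r * (r - 1) / s
  c0 <- (r - 1)^2 / s^2 - 2 * log(r)
  disc <- b^2 - 4 * a * c0
  if (disc < 0)
    stop_infeasible("no real overlap pair for s = %g, r = %g", s, r)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  feasible <- roots > 0 & roots < 1 / s &
    (r * (1 - s * roots) - 1) / s > 0
  if (!any(feasible))
    stop_infeasible(
      "no overlap pair with 0 < c_lower_next < 1/s = %g exists for s = %g, r = %g (roots: %s)",
      1 / s, s, r, paste(signif(roots, 6), collapse = ", "))
  c_lower <- min(roots[feasible])
  c_upper <- (r * (1 - s * c_lower) - 1) / s
  boundary_overlap(c_upper, c_lower)
}
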