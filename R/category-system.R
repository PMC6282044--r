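#' Duration category system (scalar-timing Gaussian mixture prior)
#'
#' An ordered set of K duration categories: strictly increasing means
#' `mu_1 < ... < mu_K` (ms), SDs tied by the scalar property
#' `sigma_k = s * mu_k`, and mixture weights `phi_k` (default uniform,
#' `1/K`: no category is privileged). Means must lie within
#' `[mu_min, mu_max]`.
#'
#' SDs are always derived from `s` and the means — they are never stored or
#' set independently, so the scalar tie cannot be violated.
#'
#' @param means Strictly increasing category means in ms.
#' @param s Weber fraction.
#' @param weights Mixture weights; default uniform. Must be positive and
#'   sum to 1 (within 1e-8; renormalized).
#' @param mu_min,mu_max Admissible range for the means, in ms.
#' @return An object of class `category_system` with elements `means`,
#'   `sds`, `weights`, `s`, `K`, `mu_min`, `mu_max`.
#' @examples
#' category_system(c(200, 400, 800), s = 0.025)
#' @export
category_system <- function(means, s = 0.025, weights = NULL,
                            mu_min = 200, mu_max = 1000) {
  if (!is.numeric(means) || length(means) < 1L ||
      any(!is.finite(means)) || any(means <= 0))
    stop_domain("`means` must be positive finite durations in ms")
  if (is.unsorted(means, strictly = TRUE))
    stop_domain("`means` must be strictly increasing")
  check_positive_scalar(s, "s")
  check_positive_scalar(mu_min, "mu_min")
  check_positive_scalar(mu_max, "mu_max")
  if (mu_min >= mu_max) stop_domain("`mu_min` must be below `mu_max`")
  if (min(means) < mu_min || max(means) > mu_max)
    stop_domain("category means must lie within [%g, %g] ms", mu_min, mu_max)
  K <- length(means)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(!is.finite(weights)) || any(weights <= 0))
    stop_domain("`weights` must be %d positive numbers", K)
  if (abs(sum(weights) - 1) > 1e-8)
    stop_domain("`weights` must sum to 1 (got %g)", sum(weights))
  weights <- weights / sum(weights)
  structure(list(means = as.numeric(means), sds = s * as.numeric(means),
                 weights = weights, s = s, K = K,
                 mu_min = mu_min, mu_max = mu_max),
            class = "category_system")
}

#' @export
print.category_system <- function(x, ...) {
  cat(sprintf("Category system: K = %d, s = %g (means in [%g, %g] ms)\n",
              x$K, x$s, x$mu_min, x$mu_max))
  print(data.frame(mean_ms = x$means, sd_ms = x$sds, weight = x$weights),
        row.names = FALSE)
  if (x$K >= 2) {
    r <- x$means[-1] / x$means[-x$K]
    cat("Adjacent mean ratios:", paste(signif(r, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

# Normalize the many accepted schedule forms into a list with:
#  $kind   "ratio" or "overlap"
#  $items  list of ratios or boundary_overlap objects
#  $global TRUE when a single entry is recycled until the mean bound
normalize_schedule <- function(schedule) {
  if (inherits(schedule, "boundary_overlap"))
    return(list(kind = "overlap", items = list(schedule), global = TRUE))
  if (is.numeric(schedule)) {
    if (length(schedule) < 1L || any(!is.finite(schedule)))
      stop_domain("ratio schedule must be finite")
    if (any(schedule <= 1))
      stop_domain("every scheduled ratio must exceed 1 (means are strictly increasing)")
    return(list(kind = "ratio", items = as.list(as.numeric(schedule)),
                global = length(schedule) == 1L))
  }
  if (is.list(schedule) && length(schedule) >= 1L &&
      all(vapply(schedule, inherits, logical(1), "boundary_overlap")))
    return(list(kind = "overlap", items = schedule, global = FALSE))
  stop_domain("`schedule` must be ratio(s) > 1, a boundary_overlap, or a list of boundary_overlap")
}

#' Build a category system from a first mean and an overlap/ratio schedule
#'
#' Starting at `mu_1`, category means are generated by the recursion
#' `mu_{k+1} = r_k * mu_k`, where each `r_k` comes from the schedule: a
#' single ratio or overlap (recycled at every boundary) or a per-boundary
#' vector/list. Generation stops when the next mean would exceed
#' `bounds$mu_max` (K is the largest number of categories whose means stay
#' within the bound) or when a finite schedule is exhausted. Overlap entries
#' are converted to ratios through [ratio_from_overlap()], which enforces
#' `c_lower_next < 1/s`.
#'
#' @param mu_1 First category mean in ms; must lie within the bounds.
#' @param s Weber fraction.
#' @param schedule A ratio (> 1), a numeric vector of ratios, a
#'   [boundary_overlap()], or a list of them.
#' @param bounds A [scalar_timing_params()]; defaults to
#'   `scalar_timing_params(s = s)`.
#' @return A [category_system()].
#' @examples
#' build_category_system(200, 0.025, 2)           # means 200, 400, 800
#' build_category_system(200, 0.025, c(1.5, 1.5, 1.5))
#' @export
build_category_system <- function(mu_1, s, schedule,
                                  bounds = scalar_timing_params(s = s)) {
  check_positive_scalar(mu_1, "mu_1")
  check_positive_scalar(s, "s")
  if (!inherits(bounds, "scalar_timing_params"))
    stop_domain("`bounds` must be a scalar_timing_params object")
  if (mu_1 < bounds$mu_min || mu_1 > bounds$mu_max)
    stop_domain("`mu_1` = %g ms is outside [%g, %g] ms",
                mu_1, bounds$mu_min, bounds$mu_max)
  sch <- normalize_schedule(schedule)
  ratio_at <- function(i) {
    item <- if (sch$global) sch$items[[1L]] else sch$items[[i]]
    if (sch$kind == "ratio") item else ratio_from_overlap(s, item)
  }
  n_steps <- if (sch$global) Inf else length(sch$items)
  means <- mu_1
  i <- 1L
  while (i <= n_steps) {
    nxt <- next_mean(means[length(means)], ratio_at(i))
    if (nxt > bounds$mu_max) break
    means <- c(means, nxt)
    i <- i + 1L
  }
  category_system(means, s = s, mu_min = bounds$mu_min, mu_max = bounds$mu_max)
}

#' Number of categories admitted by the sub-second bound
#'
#' The largest K such that iterating the mean recursion from `mu_1` keeps
#' every mean at or below `mu_max`.
#'
#' @inheritParams build_category_system
#' @param mu_max Upper bound on category means, in ms.
#' @return A positive integer.
#' @examples
#' max_categories(200, 2)    # 3
#' max_categories(500, 1.5)  # 2
#' @export
max_categories <- function(mu_1, schedule, mu_max = 1000, s = 0.025) {
  bounds <- scalar_timing_params(s = s, mu_min = min(mu_1, 200),
                                 mu_max = mu_max)
  build_category_system(mu_1, s, schedule, bounds)$K
}

#' Adjacent mean ratios of a category system
#'
#' @param system A [category_system()].
#' @return Numeric vector of `K - 1` ratios `mu_{k+1}/mu_k` (empty for
#'   `K = 1`).
#' @export
system_ratios <- function(system) {
  if (!inherits(system, "category_system"))
    stop_domain("`system` must be a category_system")
  if (system$K < 2L) return(numeric(0))
  system$means[-1] / system$means[-system$K]
}

#' Serialize / deserialize a category system as JSON
#'
#' The on-disk form stores only `s`, the means, the weights and the mean
#' bounds; SDs are re-derived on load so the scalar tie cannot be violated
#' by editing the file.
#'
#' @param system A [category_system()].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `system_to_json`: the path (invisibly) or a JSON string.
#'   `system_from_json`: a [category_system()].
#' @examples
#' js <- system_to_json(category_system(c(200, 400, 800)))
#' system_from_json(js)
#' @export
system_to_json <- function(system, path = NULL) {
  if (!inherits(system, "category_system"))
    stop_domain("`system` must be a category_system")
  obj <- list(s = system$s, means_ms = system$means,
              weights = system$weights,
              mu_min_ms = system$mu_min, mu_max_ms = system$mu_max)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname system_to_json
#' @param json A file path or JSON string produced by `system_to_json`.
#' @export
system_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  req <- c("s", "means_ms", "weights", "mu_min_ms", "mu_max_ms")
  missing <- setdiff(req, names(obj))
  if (length(missing))
    stop_domain("category-system JSON lacks field(s): %s",
                paste(missing, collapse = ", "))
  category_system(obj$means_ms, s = obj$s, weights = obj$weights,
                  mu_min = obj$mu_min_ms, mu_max = obj$mu_max_ms)
}
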