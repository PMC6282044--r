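# Parameter-space exploration: which combinations of Weber fraction,
# overlap (or target ratio) and first category mean yield systems whose
# adjacent mean ratios are small integer ratios? Infeasible grid points are
# first-class rows with a reason code, so the shape of the parameter space
# is mapped rather than censored.

explore_columns <- c("s", "mu1_ms", "schedule_kind", "c_upper",
                     "c_lower_next", "K", "means_ms", "ratios",
                     "nearest_p", "nearest_q", "deviations", "all_small",
                     "feasible", "reason")

reason_from_condition <- function(e) {
  if (inherits(e, "rp_no_real_root")) "no_real_root"
  else if (inherits(e, c("rp_feasibility_error", "rp_infeasible")))
    "overlap_infeasible"
  else "domain_error"
}

join_num <- function(x) paste(signif(x, 10), collapse = ";")

explore_row <- function(s, mu1, entry, bounds, tolerance, max_int) {
  row <- list(s = s, mu1_ms = mu1,
              schedule_kind = if (inherits(entry, "boundary_overlap"))
                "overlap" else "ratio",
              c_upper = NA_real_, c_lower_next = NA_real_, K = NA_integer_,
              means_ms = NA_character_, ratios = NA_character_,
              nearest_p = NA_character_, nearest_q = NA_character_,
              deviations = NA_character_, all_small = NA,
              feasible = FALSE, reason = NA_character_)
  result <- tryCatch({
    if (mu1 < bounds$mu_min || mu1 > bounds$mu_max) {
      row$reason <- "mu1_out_of_bounds"
      return(as.data.frame(row, stringsAsFactors = FALSE))
    }
    if (inherits(entry, "boundary_overlap")) {
      row$c_upper <- entry$c_upper
      row$c_lower_next <- entry$c_lower_next
      check_overlap_feasible(entry, s)
      schedule <- entry
    } else {
      ov <- joint_solve_overlap(s, entry)
      row$c_upper <- ov$c_upper
      row$c_lower_next <- ov$c_lower_next
      schedule <- as.numeric(entry)
    }
    sys <- build_category_system(mu1, s, schedule, bounds)
    r <- system_ratios(sys)
    nearest <- lapply(r, nearest_small_integer_ratio, max_int = max_int)
    dev <- vapply(nearest, `[[`, numeric(1), "deviation")
    row$K <- sys$K
    row$means_ms <- join_num(sys$means)
    row$ratios <- join_num(r)
    row$nearest_p <- paste(vapply(nearest, `[[`, integer(1), "p"),
                           collapse = ";")
    row$nearest_q <- paste(vapply(nearest, `[[`, integer(1), "q"),
                           collapse = ";")
    row$deviations <- join_num(dev)
    row$all_small <- length(dev) > 0L && all(dev <= tolerance)
    row$feasible <- TRUE
    as.data.frame(row, stringsAsFactors = FALSE)
  }, rp_error = function(e) {
    row$reason <- reason_from_condition(e)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  result
}

#' Explore the (s, overlap/ratio, mu_1) parameter space
#'
#' For every point of the Cartesian grid, builds the category system,
#' computes its adjacent mean ratios, classifies each ratio against the
#' nearest small-integer fraction, and emits one row. Ratio entries are
#' jointly solved for their overlap pair (so the implied `c` values are
#' reported alongside); overlap entries realize their ratio through the
#' mean-placement identity. Infeasible points are kept as rows with
#' `feasible = FALSE` and a reason code (`overlap_infeasible`, `no_real_root`,
#' `mu1_out_of_bounds`).
#'
#' @param s_values Weber fractions to explore.
#' @param overlap_or_ratio_grid A list whose entries are target ratios
#'   (numbers > 1) and/or [boundary_overlap()] objects; a plain numeric
#'   vector is also accepted.
#' @param mu1_values First category means (ms) to explore.
#' @param bounds A [scalar_timing_params()] (its `s` is ignored; each grid
#'   `s` is used). Default bounds 200-1000 ms.
#' @param tolerance Relative deviation below which a ratio counts as a
#'   small integer ratio; default 0.05.
#' @param max_int Largest integer in candidate fractions; default 4.
#' @return A data.frame with stable column order: `s, mu1_ms,
#'   schedule_kind, c_upper, c_lower_next, K, means_ms, ratios, nearest_p,
#'   nearest_q, deviations, all_small, feasible, reason` (the list-valued
#'   columns are `;`-joined strings).
#' @examples
#' grid_explore(0.025, list(2), 200)
#' @export
grid_explore <- function(s_values, overlap_or_ratio_grid, mu1_values,
                         bounds = NULL, tolerance = 0.05, max_int = 4L) {
  if (is.numeric(overlap_or_ratio_grid))
    overlap_or_ratio_grid <- as.list(overlap_or_ratio_grid)
  if (length(s_values) < 1L || length(overlap_or_ratio_grid) < 1L ||
      length(mu1_values) < 1L)
    stop_domain("all exploration grids must be non-empty")
  rows <- list()
  for (s in s_values) {
    b <- if (is.null(bounds)) scalar_timing_params(s = s)
         else scalar_timing_params(s = s, mu_min = bounds$mu_min,
                                   mu_max = bounds$mu_max)
    for (entry in overlap_or_ratio_grid)
      for (mu1 in mu1_values)
        rows[[length(rows) + 1L]] <-
          explore_row(s, mu1, entry, b, tolerance, max_int)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, explore_columns]
}

#' Overlap parameters required for target ratios
#'
#' The inverse question: given a Weber fraction, which overlap pairs would
#' place adjacent category means at the target ratios? Each target is
#' jointly solved (mean-placement and equal-density identities); the
#' resulting `c` values can then be judged for psychophysical plausibility
#' (they are reported, not judged). `mu_1` fixes the concrete means the
#' recursion would produce and is echoed in the result attributes; the
#' overlap pairs themselves depend only on `s` and each ratio.
#'
#' @param mu_1 First category mean in ms.
#' @param s Weber fraction.
#' @param target_ratios Ratios > 1.
#' @return A named list of [boundary_overlap()] (names = the ratios), with
#'   attribute `means_ms` (the implied category means). Infeasible targets
#'   raise the joint-solver's error.
#' @examples
#' inverse_question(200, 0.025, c(2, 1.5))
#' @export
inverse_question <- function(mu_1, s, target_ratios) {
  check_positive_scalar(mu_1, "mu_1")
  check_positive_scalar(s, "s")
  if (length(target_ratios) < 1L || any(!is.finite(target_ratios)))
    stop_domain("`target_ratios` must be finite")
  if (any(target_ratios <= 1))
    stop_domain("every target ratio must exceed 1")
  out <- lapply(target_ratios, function(r) joint_solve_overlap(s, r))
  names(out) <- signif(target_ratios, 10)
  attr(out, "means_ms") <- cumprod(c(mu_1, target_ratios))
  out
}
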