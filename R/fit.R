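# Tied-variance mixture estimation. The free parameters are the category
# means mu_1..mu_K and ONE Weber fraction s shared by all components through
# sigma_k = s * mu_k; weights are fixed at 1/K by default. Estimation is
# expectation/conditional-maximization: responsibilities, then a closed-form
# s^2 update (responsibility-weighted mean of (x - mu_k)^2 / mu_k^2), then a
# bounded 1-D numeric maximization per category mean. The mean update has no
# closed form because mu_k enters both the squared deviation and the
# normalizer log(s*mu_k). Each conditional step increases the EM surrogate,
# so the observed log-likelihood is monotone non-decreasing.

tied_loglik <- function(x, means, s, weights) {
  ld <- vapply(seq_along(means), function(k)
    log(weights[k]) + stats::dnorm(x, means[k], s * means[k], log = TRUE),
    numeric(length(x)))
  sum(row_log_sum_exp(matrix(ld, nrow = length(x))))
}

# deterministic initializers. The tied-variance likelihood surface is
# multimodal, so the EM is started from two deterministic mean sets and the
# run ending with the higher likelihood wins:
#  (a) equal-count partition of the sorted data (robust for balanced
#      clusters),
#  (b) k-means with an internally fixed seed and multiple starts (robust
#      for unbalanced clusters).
# Both are pure functions of the data, so a fit on the same data is always
# bit-identical.
quantile_partition_init <- function(x, K) {
  xs <- sort(x)
  idx <- ceiling(seq_along(xs) * K / length(xs))
  as.numeric(tapply(xs, idx, mean))
}

kmeans_init <- function(x, K) {
  if (K == 1L) return(mean(x))
  km <- tryCatch(
    with_seed(20231108L,
              stats::kmeans(x, centers = K, nstart = 10L, iter.max = 50L)),
    error = function(e) NULL)
  if (is.null(km) || length(unique(km$centers)) < K) return(NULL)
  sort(as.numeric(km$centers))
}

# one EM run from a given set of starting means
run_tied_em <- function(x, K, means, free_weights, max_iter, tol) {
  n <- length(x)
  weights <- rep(1 / K, K)
  # initial s from the nearest-mean assignment
  assign0 <- apply(abs(outer(x, means, "-")), 1L, which.min)
  s <- sqrt(max(mean(((x - means[assign0]) / means[assign0])^2), 1e-8))

  ll <- tied_loglik(x, means, s, weights)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step
    ld <- vapply(seq_len(K), function(k)
      log(weights[k]) + stats::dnorm(x, means[k], s * means[k], log = TRUE),
      numeric(n))
    ld <- matrix(ld, nrow = n)
    gamma <- exp(ld - row_log_sum_exp(ld))
    # CM-step 1: closed-form shared Weber fraction
    s <- sqrt(max(sum(gamma * outer(x, means, "-")^2 %*% diag(1 / means^2, K)) / n,
                  1e-12))
    # CM-step 2: each mean by bounded 1-D maximization of its tied objective
    for (k in seq_len(K)) {
      g <- gamma[, k]
      if (sum(g) < 1e-12) next  # empty component: leave its mean in place
      wm <- sum(g * x) / sum(g)
      half <- 4 * s * wm
      lo <- max(wm - half, min(x) * 0.5, 1e-6)
      hi <- wm + half
      obj <- function(mu) -sum(g * stats::dnorm(x, mu, s * mu, log = TRUE))
      means[k] <- stats::optimize(obj, c(lo, hi), tol = 1e-10 * wm)$minimum
    }
    ord <- order(means)
    means <- means[ord]
    gamma <- gamma[, ord, drop = FALSE]
    if (free_weights) weights <- colMeans(gamma)
    ll_new <- tied_loglik(x, means, s, weights)
    trace <- c(trace, ll_new)
    if (is.finite(ll_new) && ll_new - ll < tol) {
      ll <- max(ll, ll_new)
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(means = means, weights = weights, s = s, loglik = ll,
       converged = converged, n_iter = iter, loglik_trace = trace)
}

#' Fit a scalar-timing (tied-variance) Gaussian mixture to IOI data
#'
#' Maximum-likelihood estimation of a K-category duration prior under the
#' scalar constraint `sigma_k = s * mu_k`: EM with the variance tie
#' re-imposed at every M-step. Weights stay fixed at `1/K` unless
#' `free_weights = TRUE`. Initial means default to a deterministic
#' equal-count partition of the sorted data, so repeated fits of the same
#' data give identical output: the EM is run from an equal-count partition
#' of the sorted data and from internally-seeded k-means centers, and the
#' run with the higher final likelihood is kept. Reported means are sorted
#' ascending (label-switching guard).
#'
#' @param iois An [ioi_sequence()] or numeric vector; needs `n >= 10 * K`.
#' @param K Number of categories.
#' @param init_means Optional starting means (length K).
#' @param free_weights Estimate mixture weights instead of fixing `1/K`?
#' @param max_iter Iteration cap per EM run.
#' @param tol Convergence threshold on the log-likelihood gain.
#' @return An object of class `scalar_mixture_fit`: the fitted
#'   [category_system()] (`$system`, mean bounds widened to cover the
#'   fitted means when they fall outside the conventional 200-1000 ms
#'   range), plus `s`, `means`, `weights`, `loglik`, `n_iter`, `converged`,
#'   `bic`, and `loglik_trace` (the per-iteration log-likelihood of the
#'   winning EM run; monotone non-decreasing).
#' @examples
#' x <- sample_iois(category_system(c(200, 400, 800)), 300, seed = 1)
#' fit_scalar_mixture(x, K = 3)
#' @export
fit_scalar_mixture <- function(iois, K, init_means = NULL,
                               free_weights = FALSE,
                               max_iter = 500L, tol = 1e-8) {
  x <- as_ioi_vector(iois)
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop_domain("`K` must be >= 1")
  K <- as.integer(K)
  n <- length(x)
  if (n < 10L * K)
    stop_domain("need n >= 10*K observations (n = %d, K = %d)", n, K)
  if (length(unique(x)) < K)
    stop_domain("degenerate data: fewer distinct values (%d) than K = %d",
                length(unique(x)), K)
  if (is.null(init_means)) {
    inits <- list(quantile_partition_init(x, K))
    km <- kmeans_init(x, K)
    if (!is.null(km) && max(abs(km - inits[[1]])) > 1e-9)
      inits <- c(inits, list(km))
  } else {
    if (length(init_means) != K || any(init_means <= 0))
      stop_domain("`init_means` must be %d positive values", K)
    inits <- list(sort(as.numeric(init_means)))
  }
  runs <- lapply(inits, function(m0)
    run_tied_em(x, K, m0, free_weights, max_iter, tol))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  means <- best$means; weights <- best$weights; s <- best$s
  ll <- best$loglik; converged <- best$converged; iter <- best$n_iter
  trace <- best$loglik_trace
  p <- K + 1L + if (free_weights) K - 1L else 0L
  bic <- -2 * ll + p * log(n)
  system <- category_system(means, s = s, weights = weights,
                            mu_min = min(200, floor(min(means))),
                            mu_max = max(1000, ceiling(max(means))))
  structure(list(system = system, s = s, means = means, weights = weights,
                 loglik = ll, n_iter = iter, converged = converged,
                 bic = bic, n = n, K = K, free_weights = free_weights,
                 loglik_trace = trace),
            class = "scalar_mixture_fit")
}

#' @export
print.scalar_mixture_fit <- function(x, ...) {
  cat(sprintf("Scalar mixture fit: K = %d, s = %.5f, loglik = %.3f, BIC = %.1f (%s in %d iterations)\n",
              x$K, x$s, x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(data.frame(mean_ms = x$means, weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' The category-system JSON plus fit diagnostics
#' (`loglik`, `n_iter`, `converged`, `bic`).
#'
#' @param fit A `scalar_mixture_fit`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  if (!inherits(fit, "scalar_mixture_fit"))
    stop_domain("`fit` must be a scalar_mixture_fit")
  obj <- c(jsonlite::fromJSON(as.character(system_to_json(fit$system))),
           list(loglik = fit$loglik, n_iter = fit$n_iter,
                converged = fit$converged, bic = fit$bic))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Choose the number of duration categories by BIC
#'
#' Fits the tied-variance mixture for `K = 1..K_max` and selects the K with
#' the lowest Bayesian information criterion. Ks whose fit is impossible
#' (e.g. too few observations or distinct values) are reported with `NA`.
#'
#' @param iois An [ioi_sequence()] or numeric vector.
#' @param K_max Largest K to try.
#' @param ... Passed to [fit_scalar_mixture()].
#' @return A list with `K` (chosen), `table` (one row per candidate K:
#'   `K`, `loglik`, `bic`, `converged`), and `fits` (the fit objects).
#' @examples
#' x <- sample_iois(category_system(c(200, 400, 800)), 400, seed = 2)
#' select_K(x, K_max = 4)$K
#' @export
select_K <- function(iois, K_max, ...) {
  x <- as_ioi_vector(iois)
  if (!is.numeric(K_max) || length(K_max) != 1L || K_max < 1)
    stop_domain("`K_max` must be >= 1")
  K_max <- as.integer(K_max)
  fits <- lapply(seq_len(K_max), function(k)
    tryCatch(fit_scalar_mixture(x, k, ...), rp_error = function(e) NULL))
  tab <- data.frame(
    K = seq_len(K_max),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik,
                    numeric(1)),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                 numeric(1)),
    converged = vapply(fits, function(f) if (is.null(f)) NA else f$converged,
                       logical(1)))
  if (all(is.na(tab$bic)))
    stop_domain("no candidate K could be fitted")
  chosen <- tab$K[which.min(tab$bic)]
  list(K = chosen, table = tab, fits = fits)
}

#' Model-implied overlap parameters of a fitted category system
#'
#' For each pair of adjacent categories, the jointly solved
#' `(c_upper, c_lower_next)` implied by the system's Weber fraction and
#' mean ratio (see [joint_solve_overlap()]). These are the overlap values a
#' perceiver with this prior would exhibit; they are model-implied, not
#' direct behavioral estimates.
#'
#' @param system A [category_system()].
#' @return A list of `K - 1` elements, each a [boundary_overlap()] or, for
#'   a boundary with no feasible solution, an `rp_infeasible_boundary`
#'   record carrying the reason. Empty list for `K = 1`.
#' @examples
#' estimate_overlaps(category_system(c(200, 400, 800), s = 0.025))
#' @export
estimate_overlaps <- function(system) {
  if (!inherits(system, "category_system"))
    stop_domain("`system` must be a category_system")
  if (system$K < 2L) return(list())
  lapply(system_ratios(system), function(r)
    tryCatch(joint_solve_overlap(system$s, r),
             rp_error = function(e)
               structure(list(ratio = r, reason = conditionMessage(e)),
                         class = "rp_infeasible_boundary")))
}
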