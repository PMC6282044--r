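# Iterated-reproduction (transmission chain) simulation. A random seed
# rhythm is perceived through scalar sensory noise, categorized under the
# duration prior, and reproduced with scalar motor noise; the reproduction
# becomes the next generation's stimulus. Because the observer's prior is
# fixed, the chain converges toward that prior by construction — the
# simulator demonstrates the mechanism linking scalar timing and
# categorical perception to small-integer-ratio rhythms, it does not
# discover it.

#' Transmission-chain configuration
#'
#' @param generations Total number of generations including the seed
#'   generation 0; >= 1.
#' @param sequence_length Number of intervals per generation.
#' @param seed_low,seed_high Bounds (ms) of the uniform distribution the
#'   seed generation is drawn from; defaults 100 and 1000.
#' @param s_perception Weber fraction of the sensory stage.
#' @param s_motor Weber fraction of the motor stage.
#' @param rng_seed Integer seed; the whole chain is a single seeded stream,
#'   so identical configurations give bit-identical chains.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(generations, sequence_length,
                         seed_low = 100, seed_high = 1000,
                         s_perception = 0.025, s_motor = 0.025,
                         rng_seed = 1L) {
  if (!is.numeric(generations) || length(generations) != 1L || generations < 1)
    stop_domain("`generations` must be >= 1")
  if (!is.numeric(sequence_length) || length(sequence_length) != 1L ||
      sequence_length < 1)
    stop_domain("`sequence_length` must be >= 1")
  check_positive_scalar(seed_low, "seed_low")
  check_positive_scalar(seed_high, "seed_high")
  if (seed_low >= seed_high) stop_domain("`seed_low` must be below `seed_high`")
  check_positive_scalar(s_perception, "s_perception")
  check_positive_scalar(s_motor, "s_motor")
  structure(list(generations = as.integer(generations),
                 sequence_length = as.integer(sequence_length),
                 seed_low = seed_low, seed_high = seed_high,
                 s_perception = s_perception, s_motor = s_motor,
                 rng_seed = as.integer(rng_seed)),
            class = "chain_config")
}

new_attribution <- function(labels, posterior, perceived_ms = NULL) {
  structure(list(labels = as.integer(labels), posterior = posterior,
                 perceived_ms = perceived_ms),
            class = "category_attribution")
}

#' @export
print.category_attribution <- function(x, ...) {
  cat(sprintf("Category attribution: %d intervals over %d categories\n",
              length(x$labels), ncol(x$posterior)))
  print(table(label = x$labels))
  invisible(x)
}

#' Perceive an IOI sequence through scalar sensory noise
#'
#' Each interval `d_i` is corrupted by Gaussian noise with SD
#' `s_perception * d_i` (scalar sensory noise; non-positive corruptions are
#' redrawn), then MAP-categorized under the prior.
#'
#' @param iois An [ioi_sequence()] or numeric vector.
#' @param system A [category_system()] (the observer's prior).
#' @param s_perception Weber fraction of the sensory stage.
#' @param seed Optional seed (caller's RNG state restored).
#' @return A `category_attribution`: MAP `labels`, the full `posterior`
#'   matrix, and the noise-corrupted `perceived_ms`.
#' @export
perceive <- function(iois, system, s_perception = 0.025, seed = NULL) {
  v <- as_ioi_vector(iois)
  check_positive_scalar(s_perception, "s_perception")
  with_seed(seed, {
    noisy <- stats::rnorm(length(v), v, s_perception * v)
    while (any(bad <- noisy <= 0))
      noisy[bad] <- stats::rnorm(sum(bad), v[bad], s_perception * v[bad])
    post <- posterior_category(noisy, system)
    new_attribution(apply(post, 1L, which.max), post, noisy)
  })
}

#' Reproduce categorized intervals with scalar motor noise
#'
#' Each category label k is realized as a draw from
#' `N(mu_k, s_motor * mu_k)` (non-positive draws redrawn): the producer
#' samples from the category's scalar-timing Gaussian rather than emitting
#' its mean.
#'
#' @param attribution A `category_attribution` (from [perceive()]).
#' @param system A [category_system()].
#' @param s_motor Weber fraction of the motor stage.
#' @param seed Optional seed.
#' @return An [ioi_sequence()].
#' @export
reproduce <- function(attribution, system, s_motor = 0.025, seed = NULL) {
  if (!inherits(attribution, "category_attribution"))
    stop_domain("`attribution` must come from perceive()")
  if (!inherits(system, "category_system"))
    stop_domain("`system` must be a category_system")
  check_positive_scalar(s_motor, "s_motor")
  k <- attribution$labels
  if (any(k < 1L | k > system$K))
    stop_domain("attribution labels outside 1..K")
  with_seed(seed, {
    x <- stats::rnorm(length(k), system$means[k], s_motor * system$means[k])
    while (any(bad <- x <= 0))
      x[bad] <- stats::rnorm(sum(bad), system$means[k[bad]],
                             s_motor * system$means[k[bad]])
    ioi_sequence(x)
  })
}

#' Shannon entropy (bits) of category labels
#'
#' @param labels Integer category labels.
#' @return Entropy in bits; 0 for a single repeated label.
#' @export
label_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  -sum(p * log2(p))
}

#' Nearest small-integer ratio
#'
#' Enumerates all fractions `p/q` with `1 <= p, q <= max_int` in lowest
#' terms and returns the one minimizing the relative deviation
#' `|r - p/q| / (p/q)`; ties go to the smaller `p + q` (then smaller `q`).
#' A ratio counts as "small-integer" when its deviation is within a
#' tolerance (0.05 by default elsewhere in the package): 1.498307 (the
#' equal-tempered fifth, 2^(7/12)) is 0.11% from 3/2, whereas 23/51 is more
#' than 5% from every small fraction.
#'
#' @param r Observed ratio; positive.
#' @param max_int Largest numerator/denominator considered; >= 2.
#' @return A list with `p`, `q`, `deviation`.
#' @examples
#' nearest_small_integer_ratio(2^(7/12))  # 3/2, deviation ~0.0011
#' @export
nearest_small_integer_ratio <- function(r, max_int = 4L) {
  check_positive_scalar(r, "r")
  if (!is.numeric(max_int) || length(max_int) != 1L || max_int < 2)
    stop_domain("`max_int` must be >= 2")
  max_int <- as.integer(max_int)
  grid <- expand.grid(p = seq_len(max_int), q = seq_len(max_int))
  gcd <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
  grid <- grid[gcd(grid$p, grid$q) == 1L, ]
  frac <- grid$p / grid$q
  dev <- abs(r - frac) / frac
  ord <- order(dev, grid$p + grid$q, grid$q)
  best <- ord[1L]
  list(p = grid$p[best], q = grid$q[best], deviation = dev[best])
}

#' Fit-based mode detection for IOI samples
#'
#' Fits scalar-timing (tied-variance) mixtures with `K = 1..max_modes`
#' components via [fit_scalar_mixture()] and selects K by BIC; the fitted
#' means, sorted ascending, are the detected modes. Mixture weights are
#' left free: the equal-weight assumption belongs to the duration prior,
#' whereas mode detection must describe a finite sample whose category
#' occupancies are never exactly equal. The candidate K range is
#' additionally capped by the fitter's own requirement of at least 10
#' observations per component. Deterministic: the fitter uses a
#' deterministic initializer, so the same data always yield the same modes.
#'
#' @param iois An [ioi_sequence()] or numeric vector.
#' @param max_modes Largest number of modes considered.
#' @param min_n Minimum number of intervals required (default 50; the chain
#'   simulator relaxes this for short experimental generations).
#' @return A list with `modes_ms`, `mode_count`, `s` (fitted Weber
#'   fraction), and the BIC `table` from [select_K()].
#' @examples
#' x <- sample_iois(category_system(c(200, 400, 800)), 200, seed = 3)
#' detect_modes(x)$modes_ms
#' @export
detect_modes <- function(iois, max_modes = 6L, min_n = 50L) {
  v <- as_ioi_vector(iois)
  if (length(v) < min_n)
    stop_domain("need at least %d intervals for mode detection (got %d)",
                min_n, length(v))
  k_cap <- max(1L, min(as.integer(max_modes), length(v) %/% 10L))
  sel <- select_K(v, K_max = k_cap, free_weights = TRUE)
  fit <- sel$fits[[sel$K]]
  list(modes_ms = fit$means, mode_count = fit$K, s = fit$s,
       table = sel$table)
}

# convergence metrics for one generation, recomputed deterministically from
# the stored sequence
generation_metrics <- function(iois, system, max_int = 4L, max_modes = 6L,
                               mode_min_n = 20L, compute_modes = TRUE) {
  v <- as_ioi_vector(iois)
  modes <- if (!compute_modes) NULL else
    tryCatch(detect_modes(v, max_modes = max_modes, min_n = mode_min_n),
             rp_error = function(e) NULL)
  if (is.null(modes)) {
    modes_ms <- numeric(0); mode_count <- NA_integer_
    ratio_dev <- data.frame(ratio = numeric(0), p = integer(0),
                            q = integer(0), deviation = numeric(0))
  } else {
    modes_ms <- modes$modes_ms
    mode_count <- modes$mode_count
    mr <- if (mode_count >= 2L) modes_ms[-1] / modes_ms[-mode_count] else numeric(0)
    nearest <- lapply(mr, nearest_small_integer_ratio, max_int = max_int)
    ratio_dev <- data.frame(
      ratio = mr,
      p = vapply(nearest, `[[`, integer(1), "p"),
      q = vapply(nearest, `[[`, integer(1), "q"),
      deviation = vapply(nearest, `[[`, numeric(1), "deviation"))
  }
  labels <- map_category(v, system)
  list(modes_ms = modes_ms, mode_count = mode_count,
       ratio_deviations = ratio_dev,
       label_entropy_bits = label_entropy(labels),
       w1_to_prior_ms = w1_to_mixture(v, system),
       w1_to_modes_ms = w1_to_occupancy_mixture(v, system))
}

#' Run an iterated-reproduction transmission chain
#'
#' Generation 0 is sampled uniformly on `(seed_low, seed_high)`; every
#' later generation is `reproduce(perceive(previous))` under the fixed
#' observer prior. All generations are retained, each with convergence
#' metrics: BIC-selected modes of the interval distribution, deviations of
#' adjacent mode ratios from the nearest small-integer ratio, the Shannon
#' entropy of the MAP category labels, and Wasserstein distances to the
#' prior mixture and to the occupancy-matched mixture (see
#' [w1_to_occupancy_mixture()]; with well-separated categories the chain
#' converges to the prior's mode structure while category occupancies stay
#' frozen at the seed generation's proportions, so the occupancy-matched
#' distance is the one that contracts). Metrics are recomputed
#' deterministically from each stored sequence (attribution without added
#' sensory noise).
#'
#' @param config A [chain_config()].
#' @param system A [category_system()] (the observer's prior).
#' @param max_int Largest integer considered by the small-ratio classifier.
#' @param max_modes Largest mode count considered.
#' @return An object of class `chain_result`: a list with `config`,
#'   `system`, and `records` — one record per generation holding
#'   `generation`, `iois`, `attribution`, `metrics`.
#' @examples
#' sys <- category_system(c(200, 400, 800))
#' ch <- run_chain(chain_config(3, 32, rng_seed = 7), sys)
#' sapply(ch$records, function(g) g$metrics$mode_count)
#' @export
run_chain <- function(config, system, max_int = 4L, max_modes = 6L) {
  if (!inherits(config, "chain_config"))
    stop_domain("`config` must be a chain_config")
  if (!inherits(system, "category_system"))
    stop_domain("`system` must be a category_system")
  with_seed(config$rng_seed, {
    records <- vector("list", config$generations)
    current <- ioi_sequence(
      stats::runif(config$sequence_length, config$seed_low, config$seed_high),
      generation = 0L)
    for (g in seq_len(config$generations) - 1L) {
      if (g > 0L) {
        att <- perceive(current, system, config$s_perception)
        current <- reproduce(att, system, config$s_motor)
        attr(current, "generation") <- g
      }
      post <- posterior_category(current, system)
      records[[g + 1L]] <- list(
        generation = g,
        iois = current,
        attribution = new_attribution(apply(post, 1L, which.max), post),
        metrics = generation_metrics(current, system, max_int = max_int,
                                     max_modes = max_modes))
    }
    structure(list(config = config, system = system, records = records),
              class = "chain_result")
  })
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("Transmission chain: %d generations x %d intervals (rng_seed %d)\n",
              x$config$generations, x$config$sequence_length,
              x$config$rng_seed))
  print(data.frame(
    generation = vapply(x$records, `[[`, integer(1), "generation"),
    mode_count = vapply(x$records, function(g) g$metrics$mode_count, integer(1)),
    entropy_bits = round(vapply(x$records, function(g)
      g$metrics$label_entropy_bits, numeric(1)), 3),
    w1_ms = round(vapply(x$records, function(g)
      g$metrics$w1_to_prior_ms, numeric(1)), 1)), row.names = FALSE)
  invisible(x)
}

#' Write a chain's sequences (CSV) and metrics (JSON)
#'
#' The CSV uses the package-wide IOI dialect
#' (`chain_id,generation,position,ioi_ms`, one row per interval); the JSON
#' holds one object per generation with `generation`, `modes_ms`,
#' `mode_count`, `ratio_deviations`, `label_entropy_bits`.
#'
#' @param chain A `chain_result`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @param chain_id Chain identifier used in the CSV.
#' @return Invisibly, the paths written.
#' @export
write_chain <- function(chain, csv_path = NULL, json_path = NULL,
                        chain_id = "chain1") {
  if (!inherits(chain, "chain_result"))
    stop_domain("`chain` must be a chain_result")
  if (!is.null(csv_path)) {
    seqs <- lapply(chain$records, function(g)
      ioi_sequence(g$iois, chain_id = chain_id, generation = g$generation))
    write_iois(seqs, csv_path)
  }
  if (!is.null(json_path)) {
    metrics <- lapply(chain$records, function(g) list(
      generation = g$generation,
      modes_ms = g$metrics$modes_ms,
      mode_count = g$metrics$mode_count,
      ratio_deviations = g$metrics$ratio_deviations$deviation,
      label_entropy_bits = g$metrics$label_entropy_bits))
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(csv = csv_path, json = json_path))
}
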