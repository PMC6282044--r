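# internal helpers: error signalling and seeded evaluation

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rp_domain_error", "rp_error")))
}

stop_feasibility <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rp_feasibility_error", "rp_error")))
}

stop_no_real_root <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rp_no_real_root", "rp_error")))
}

stop_infeasible <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rp_infeasible", "rp_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain("`%s` must be a single positive finite number", name)
  invisible(x)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
# seed = NULL means: use (and advance) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("`seed` must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# numerically stable log(sum(exp(x))) along rows of a matrix
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
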