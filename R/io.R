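# CSV input/output for IOI sequences and the synthetic fixture generator.
# Dialect: header `chain_id,generation,position,ioi_ms`, one row per
# interval, positions 0-based within a sequence, UTF-8.

ioi_header <- c("chain_id", "generation", "position", "ioi_ms")

#' Read / write IOI sequences in the package CSV dialect
#'
#' `read_iois` parses a CSV with header
#' `chain_id,generation,position,ioi_ms` into a list of [ioi_sequence()]
#' objects (one per `chain_id` x `generation`, rows ordered by `position`).
#' Malformed headers, non-numeric cells and non-positive durations are
#' rejected with the offending row numbers. An empty file yields an empty
#' list with a warning. `write_iois` is the inverse; round trips are
#' lossless to well below 1e-9 ms.
#'
#' @param path CSV file path.
#' @return `read_iois`: a list of [ioi_sequence()]. `write_iois`: the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_iois(ioi_sequence(c(200, 400.5), chain_id = "a"), f)
#' read_iois(f)
#' @export
read_iois <- function(path) {
  if (!file.exists(path)) stop_domain("input file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (!identical(names(df), ioi_header))
    stop_domain("malformed header: expected '%s', got '%s'",
                paste(ioi_header, collapse = ","),
                paste(names(df), collapse = ","))
  if (nrow(df) == 0L) {
    warning("no IOI rows in ", path)
    return(list())
  }
  ioi <- suppressWarnings(as.numeric(df$ioi_ms))
  pos <- suppressWarnings(as.numeric(df$position))
  gen <- suppressWarnings(as.numeric(df$generation))
  bad_num <- which(is.na(ioi) | is.na(pos) | is.na(gen))
  if (length(bad_num))
    stop_domain("non-numeric cells at row(s): %s",
                paste(utils::head(bad_num, 10), collapse = ", "))
  bad_pos <- which(ioi <= 0)
  if (length(bad_pos))
    stop_domain("non-positive ioi_ms at row(s): %s",
                paste(utils::head(bad_pos, 10), collapse = ", "))
  key <- paste(df$chain_id, gen, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
                  idx <- idx[order(pos[idx])]
                  ioi_sequence(ioi[idx], chain_id = df$chain_id[idx[1]],
                               generation = gen[idx[1]])
                })
  names(out) <- vapply(out, function(s)
    paste0(attr(s, "chain_id"), ".g", attr(s, "generation")), character(1))
  out
}

#' @rdname read_iois
#' @param sequences An [ioi_sequence()] or a list of them.
#' @export
write_iois <- function(sequences, path) {
  if (inherits(sequences, "ioi_sequence")) sequences <- list(sequences)
  if (!is.list(sequences) ||
      !all(vapply(sequences, inherits, logical(1), "ioi_sequence")))
    stop_domain("`sequences` must be ioi_sequence object(s)")
  rows <- lapply(sequences, function(s) data.frame(
    chain_id = attr(s, "chain_id"),
    generation = attr(s, "generation"),
    position = seq_along(s) - 1L,
    ioi_ms = format(as.numeric(s), digits = 15, scientific = FALSE,
                    trim = TRUE),
    stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Synthetic IOI fixtures emulating canonical distribution types
#'
#' Generates the four synthetic distribution shapes used throughout the
#' package's tests and examples:
#' \describe{
#'   \item{B}{uniform on (100, 1000) ms — the seed distribution of
#'     iterated-reproduction experiments;}
#'   \item{C}{a 3-centroid Gaussian mixture with centroids drawn uniformly
#'     in (200, 1000) ms and SDs drawn uniformly in (5, 80) ms,
#'     independently of the means (no scalar constraint; illustrative
#'     only);}
#'   \item{D}{3 centroids drawn as in C but with the scalar tie
#'     `sd = s * mean`;}
#'   \item{E}{the scalar-timing system with means (200, 400, 800) ms —
#'     scalar timing plus small integer ratios.}
#' }
#' All mixtures use equal weights.
#'
#' @param panel One of `"B"`, `"C"`, `"D"`, `"E"`.
#' @param n Number of intervals; default 1000.
#' @param seed Optional seed.
#' @param s Weber fraction for panels D and E.
#' @return An [ioi_sequence()] with attribute `panel` and, for mixture
#'   panels, attributes `centroids_ms` and `sds_ms`.
#' @examples
#' make_fixture("E", n = 100, seed = 1)
#' @export
make_fixture <- function(panel, n = 1000L, seed = NULL, s = 0.025) {
  if (!is.character(panel) || length(panel) != 1L ||
      !panel %in% c("B", "C", "D", "E"))
    stop_domain("`panel` must be one of 'B', 'C', 'D', 'E'")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_domain("`n` must be a positive count")
  n <- as.integer(n)
  with_seed(seed, {
    if (panel == "B") {
      out <- ioi_sequence(stats::runif(n, 100, 1000))
      attr(out, "panel") <- panel
      return(out)
    }
    if (panel == "E") {
      centroids <- c(200, 400, 800)
      sds <- s * centroids
    } else {
      centroids <- sort(stats::runif(3, 200, 1000))
      sds <- if (panel == "D") s * centroids else stats::runif(3, 5, 80)
    }
    k <- sample.int(3L, n, replace = TRUE)
    x <- stats::rnorm(n, centroids[k], sds[k])
    while (any(bad <- x <= 0))
      x[bad] <- stats::rnorm(sum(bad), centroids[k[bad]], sds[k[bad]])
    out <- ioi_sequence(x)
    attr(out, "panel") <- panel
    attr(out, "centroids_ms") <- centroids
    attr(out, "sds_ms") <- sds
    attr(out, "category") <- k
    out
  })
}
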