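#' Detect multinucleotide mutation clusters
#'
#' Within each line, events are chained into maximal clusters whenever
#' consecutive events (in circular order) are strictly less than `window`
#' nucleotides apart; chains of three or more events form a single
#' cluster.
#'
#' @param catalog mutation catalog (all event types participate).
#' @param window clustering window in nt (strict `<`).
#' @param genome_size circular genome length for wrap-around distances.
#' @return data.frame with one row per cluster: `line`, `size` (member
#'   count), `positions` (comma-separated), `span` (max pairwise circular
#'   distance).
#' @export
detect_mnm <- function(catalog, window = 50L, genome_size) {
  stopifnot(window >= 2)
  out <- list()
  for (li in unique(catalog$line)) {
    pos <- sort(unique(catalog$pos[catalog$line == li]))
    if (length(pos) < 2L) next
    gaps <- diff(pos)
    wrap <- genome_size - (pos[length(pos)] - pos[1L])
    close_gap <- gaps < window
    grp <- cumsum(c(1L, !close_gap))
    # merge first and last groups across the origin when the wrap gap
    # is short and the groups are distinct
    if (length(pos) > 1L && wrap < window && grp[1L] != grp[length(grp)]) {
      grp[grp == grp[length(grp)]] <- grp[1L]
    }
    for (g in unique(grp)) {
      members <- pos[grp == g]
      if (length(members) < 2L) next
      span <- max(outer(members, members,
                        function(a, b) circular_distance(a, b, genome_size)))
      out[[length(out) + 1L]] <- data.frame(
        line = li, size = length(members),
        positions = paste(members, collapse = ","), span = span,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(line = integer(), size = integer(),
                      positions = character(), span = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Poisson-window parameters for the MNM expectation
#'
#' The per-window rate is the observed BPS total divided by the genome
#' size and the number of MA lines, multiplied by the window length;
#' windows are non-overlapping tiles (floor division).
#'
#' @param total_bps observed BPS count across all lines.
#' @param genome_size genome length in sites.
#' @param n_lines number of MA lines.
#' @param window window length in nt.
#' @return list with `lambda`, `window`, `n_windows` and the inputs.
#' @export
mnm_params <- function(total_bps, genome_size, n_lines, window = 50L) {
  stopifnot(total_bps > 0, genome_size > 0, n_lines > 0, window > 0)
  list(lambda = total_bps / genome_size / n_lines * window,
       window = window, n_windows = genome_size %/% window,
       total_bps = total_bps, genome_size = genome_size, n_lines = n_lines)
}

#' Expected probability of at least one MNM window
#'
#' Under independent Poisson placement, the probability that at least
#' one of `n_windows` windows in a single line holds two or more
#' mutations is `1 - P(X <= 1; lambda)^n_windows`, evaluated in log
#' space for numerical stability.
#'
#' @param params an [mnm_params] list (or any list with `lambda` and
#'   `n_windows`).
#' @return probability in [0, 1].
#' @export
mnm_expected_probability <- function(params) {
  if (params$lambda <= 0) stop("lambda must be positive")
  if (params$n_windows < 1) stop("n_windows must be >= 1")
  -expm1(params$n_windows *
           stats::ppois(1, params$lambda, log.p = TRUE))
}

#' Monte-Carlo oracle for the MNM window probability
#'
#' Per replicate, scatters `total_bps / n_lines` events uniformly over
#' the genome (one simulated line) and records whether any
#' non-overlapping window of length `window` holds two or more events.
#'
#' @param params an [mnm_params] list.
#' @param reps number of replicates (>= 100).
#' @param seed integer seed.
#' @return list with `estimate`, `se` (binomial) and `reps`.
#' @export
mnm_mc_oracle <- function(params, reps = 10000L, seed = 1L) {
  stopifnot(reps >= 100)
  m <- round(params$total_bps / params$n_lines)
  with_local_seed(seed, {
    hits <- vapply(seq_len(reps), function(r) {
      pos <- sample.int(params$genome_size, m, replace = TRUE)
      win <- (pos - 1L) %/% params$window
      anyDuplicated(win) > 0L
    }, logical(1L))
    p <- mean(hits)
    list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
  })
}
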