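#' Per-line mutation rate with standard error
#'
#' The rate for one MA line is `mu = m / (n * T)`, where `m` is the
#' number of observed events, `n` the number of nucleotide sites analyzed
#' and `T` the total number of generations. Its standard error treats `m`
#' as Poisson: `se = sqrt(mu / (n * T))`, which equals `sqrt(m) / (n*T)`.
#'
#' @param m observed event count.
#' @param n analyzed sites.
#' @param T_gen generations elapsed.
#' @return list with `rate`, `se`, and the inputs `m`, `n`, `T_gen`.
#' @export
line_rate <- function(m, n, T_gen) {
  if (n <= 0 || T_gen <= 0) stop("n and T_gen must be positive")
  if (m < 0) stop("m must be non-negative")
  n <- as.numeric(n); T_gen <- as.numeric(T_gen)
  rate <- m / (n * T_gen)
  list(rate = rate, se = sqrt(rate / (n * T_gen)), m = m, n = n,
       T_gen = T_gen)
}

#' Pooled mutation rate across MA lines
#'
#' The pooled estimate is the unweighted mean of the per-line rates; its
#' standard error is `s / sqrt(N)` with `s` the sample (N-1) standard
#' deviation of the per-line rates and `N` the number of lines.
#'
#' @param lines data.frame with columns `m`, `n`, `T_gen` (one row per
#'   line), or a numeric vector of per-line rates.
#' @return list with `rate`, `se`, `s` (across-line SD), `N` and the
#'   per-line `rates`.
#' @export
pooled_rate <- function(lines) {
  rates <- if (is.numeric(lines) && is.null(dim(lines))) lines
           else lines$m / (as.numeric(lines$n) * as.numeric(lines$T_gen))
  if (length(rates) < 2L) stop("pooling requires at least 2 lines")
  s <- stats::sd(rates)
  list(rate = mean(rates), se = s / sqrt(length(rates)), s = s,
       N = length(rates), rates = rates)
}

#' Convert a per-site rate to a per-genome-replication rate
#'
#' @param rate events per site per generation.
#' @param n_effective number of sites the rate applies to (analyzed
#'   sites, reported alongside because published per-genome figures can
#'   imply a denominator below the raw genome length).
#' @return events per genome per generation.
#' @export
per_genome_rate <- function(rate, n_effective) {
  if (n_effective <= 0) stop("n_effective must be positive")
  rate * n_effective
}

#' Total generations from harmonic-mean divisions per transfer
#'
#' Generation time in a bottlenecked MA assay is accounted per transfer:
#' the divisions per transfer (log2 of colony CFU counts) are averaged by
#' their harmonic mean, then multiplied by the number of transfers.
#'
#' @param divisions_per_transfer measured cell divisions per transfer.
#' @param n_transfers number of single-colony transfers.
#' @return list with `harmonic_mean` and `generations`.
#' @export
generations_harmonic <- function(divisions_per_transfer, n_transfers = 1L) {
  if (any(divisions_per_transfer <= 0)) {
    stop("divisions per transfer must be positive")
  }
  h <- length(divisions_per_transfer) / sum(1 / divisions_per_transfer)
  list(harmonic_mean = h, generations = h * n_transfers)
}

#' Divisions per transfer from a colony CFU count
#'
#' @param cfu colony-forming units in the transferred colony.
#' @return log2(cfu), the number of doublings from a single cell.
#' @export
divisions_from_cfu <- function(cfu) {
  if (any(cfu < 1)) stop("cfu must be >= 1")
  log2(cfu)
}

#' Per-line metadata table from a catalog
#'
#' @param catalog mutation catalog.
#' @param n_lines number of lines (lines without calls get zero counts).
#' @param n_sites analyzed sites per line (scalar or per-line vector).
#' @param generations generations per line (scalar or vector).
#' @return data.frame with `line`, `T_gen`, `n`, `m_bps`, `m_indel`.
#' @export
line_metadata <- function(catalog, n_lines, n_sites, generations) {
  lines <- seq_len(n_lines)
  m_bps <- vapply(lines, function(li)
    sum(catalog$line == li & catalog$type == "BPS"), 0L)
  m_indel <- vapply(lines, function(li)
    sum(catalog$line == li & catalog$type != "BPS"), 0L)
  data.frame(line = lines, T_gen = rep_len(generations, n_lines),
             n = rep_len(n_sites, n_lines), m_bps = m_bps,
             m_indel = m_indel)
}
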