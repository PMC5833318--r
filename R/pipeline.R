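#' Run the full MA analysis pipeline
#'
#' Orchestrates data acquisition (printed-counts fixture or synthetic
#' simulation with known truth), consensus calling, rate estimation,
#' spectrum summary, genomic-context tests, MNM statistics and (when an
#' alignment is supplied) effective population size, returning one
#' structured summary. All randomness derives from `config$seed`.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `mode` (`"fixture"` or `"synthetic"`); `seed`; for synthetic mode
#'   `genome` (length, gc_content, coding_fraction) and `sim` (arguments
#'   to [sim_config()]); `thresholds` (arguments to
#'   [calling_thresholds()]); `bin_size`; `windows` (MNM window sizes);
#'   optional `alignment` (path or named sequences) and `fixture_config`.
#' @return a list of per-stage results plus a `summary` data.frame of
#'   key quantities.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% "fixture"
  seed <- config$seed %||% 1L
  bin_size <- config$bin_size %||% 50000L
  windows <- unlist(config$windows %||% c(20L, 50L, 100L))
  thr <- do.call(calling_thresholds, as.list(config$thresholds))

  genome <- NULL; truth <- NULL; recovery <- NULL
  if (mode == "fixture") {
    fx <- build_paper_fixture(config$fixture_config %||%
                                fixture_config_path())
    catalog <- fx$catalog
    meta <- fx$meta
    genome_size <- fx$genome_size
    terminus <- fx$terminus
  } else if (mode == "synthetic") {
    g <- config$genome %||% list()
    genome <- generate_reference(
      length = g$length %||% 100000L,
      gc_content = g$gc_content %||% 0.5,
      coding_fraction = g$coding_fraction %||% 0.5,
      seed = seed)
    sc <- do.call(sim_config, c(as.list(config$sim), list(seed = seed)))
    truth <- plant_mutations(genome, sc)
    sim <- simulate_counts(genome, truth, sc)
    called <- call_catalog(sim, thr)
    catalog <- called$catalog
    meta <- line_metadata(catalog, sc$n_lines, called$n_analyzed,
                          sc$generations)
    genome_size <- genome$length
    terminus <- genome$terminus
    recovery <- recovery_stats(catalog, truth, sc$n_lines, thr)
  } else {
    stop("config$mode must be 'fixture' or 'synthetic'")
  }
  if (!nrow(catalog)) stop("stage calling: no mutations in catalog")

  bps_pool <- pooled_rate(data.frame(m = meta$m_bps, n = meta$n,
                                     T_gen = meta$T_gen))
  ind_pool <- pooled_rate(data.frame(m = meta$m_indel, n = meta$n,
                                     T_gen = meta$T_gen))
  spec <- summarize_spectrum(catalog, meta)
  del_bias <- chi_square_gof(c(spec$n_deletions, spec$n_insertions))
  tstv <- ts_tv_by_line(catalog, nrow(meta))

  context <- NULL
  if (!is.null(genome) && nrow(genome$genes)) {
    bins <- bin_density(catalog, genome, bin_size)
    context <- list(
      coding = coding_distribution_test(catalog, genome),
      ns_s = ns_s_expectation_test(catalog, genome),
      bins = bins,
      terminus_incl = try_or_null(terminus_test(bins, FALSE)),
      terminus_excl = try_or_null(terminus_test(bins, TRUE)))
  }

  mnm <- lapply(windows, function(w) {
    cl <- detect_mnm(catalog, w, genome_size)
    pars <- mnm_params(spec$n_bps, genome_size, nrow(meta), w)
    list(window = w, clusters = cl, n_clustered_events = sum(cl$size),
         clustered_fraction = sum(cl$size) / nrow(catalog),
         lines_with_clusters = length(unique(cl$line)),
         params = pars, expected_probability = mnm_expected_probability(pars))
  })
  names(mnm) <- paste0("window_", windows)

  popgen <- NULL
  if (!is.null(config$alignment)) {
    pi_est <- silent_site_pi(config$alignment)
    popgen <- c(pi_est,
                list(ne = effective_population_size(pi_est$pi_s,
                                                    bps_pool$rate)))
  }

  summary <- data.frame(
    quantity = c("total_events", "n_bps", "n_indel", "mean_bps_per_line",
                 "mean_indel_per_line", "bps_rate_per_site",
                 "bps_rate_se", "indel_rate_per_site",
                 "bps_rate_per_genome", "transitions_pct", "at_ward_pct",
                 "deletions_pct_of_indels", "ts_tv_pooled",
                 "ts_tv_line_mean", "deletion_bias_chisq",
                 "mnm_clustered_fraction_w50"),
    value = c(spec$n_total, spec$n_bps, spec$n_indel,
              mean(meta$m_bps), mean(meta$m_indel),
              bps_pool$rate, bps_pool$se, ind_pool$rate,
              per_genome_rate(bps_pool$rate, meta$n[1L]),
              100 * spec$transitions / spec$n_bps,
              100 * spec$at_ward / spec$n_bps,
              100 * spec$n_deletions / spec$n_indel,
              spec$ts_tv_pooled, mean(tstv$ts_tv, na.rm = TRUE),
              del_bias$statistic,
              if ("window_50" %in% names(mnm))
                mnm$window_50$clustered_fraction else NA_real_),
    stringsAsFactors = FALSE)

  list(catalog = catalog, meta = meta, genome = genome, truth = truth,
       recovery = recovery, rates = list(bps = bps_pool, indel = ind_pool),
       spectrum = spec, deletion_bias = del_bias, ts_tv = tstv,
       context = context, mnm = mnm, popgen = popgen,
       terminus = terminus, summary = summary)
}

#' Recall and precision of the caller against planted truth
#'
#' @param catalog called catalog.
#' @param truth planted truth catalog (progenitor events shared by more
#'   than `progenitor_frac` of lines are not expected to be recovered
#'   and are excluded from the truth set).
#' @param n_lines number of lines.
#' @param thresholds a [calling_thresholds].
#' @return list with `recall`, `precision`, counts of true/called/missed
#'   and false-positive events.
#' @export
recovery_stats <- function(catalog, truth, n_lines,
                           thresholds = calling_thresholds()) {
  expected <- filter_progenitor(truth, n_lines, thresholds)
  tkey <- with(expected, paste(line, pos, type))
  ckey <- with(catalog, paste(line, pos, type))
  tp <- sum(ckey %in% tkey)
  list(recall = if (length(tkey)) tp / length(tkey) else NA_real_,
       precision = if (length(ckey)) tp / length(ckey) else NA_real_,
       n_truth = length(tkey), n_called = length(ckey),
       n_missed = sum(!tkey %in% ckey),
       n_false = sum(!ckey %in% tkey))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}
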