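#' Grid of misspecification scenarios
#'
#' Crosses multipliers on the true measurement-error SD with fractional
#' shifts of the growth curve, labelling each cell in the `ME+XX:GC+YY`
#' style: `ME-67` means the assumed SD is a 67% underestimate (multiplier
#' 0.33), `GC-5` a growth curve shifted down by 5%. The default 5 x 5 grid
#' covers under- and overestimates of both ingredients around the truth.
#'
#' @param me_factors Multipliers applied to the true sigma.
#' @param gc_shifts Fractional shifts applied to the true growth curve.
#' @return A tibble with columns `me_factor`, `gc_shift`, `scenario`.
#' @examples
#' scenario_grid()$scenario
#' @export
scenario_grid <- function(me_factors = c(0.33, 0.67, 1, 1.33, 1.67),
                          gc_shifts = c(-0.10, -0.05, 0, 0.05, 0.10)) {
  g <- tidyr::expand_grid(me_factor = me_factors, gc_shift = gc_shifts)
  dplyr::mutate(g, scenario = scenario_label(.data$me_factor, .data$gc_shift))
}

#' @rdname scenario_grid
#' @export
scenario_label <- function(me_factor, gc_shift) {
  sprintf("ME%+d:GC%+d", round(100 * (me_factor - 1)), round(100 * gc_shift))
}

# Deterministic per-replicate seed from a master seed (kept within the
# 32-bit integer range so set.seed() accepts it on any platform).
replicate_seed <- function(master_seed, replicate) {
  as.integer((as.double(master_seed) * 100003 + replicate * 7919) %% 2147483647)
}

#' Simulate replicates and fit every misspecification scenario
#'
#' The full experiment driver: simulates `n_replicates` independent
#' population histories for one species, then fits the POP pseudo-
#' likelihood to each replicate's samples under every scenario in the grid.
#' Only the assumed observation model changes between scenarios (assumed
#' sigma = `me_factor` x true sigma, assumed curve = truth shifted by
#' `gc_shift`); the data, the survival, and the maximum age stay fixed.
#' Convergence failures are recorded per fit, never raised.
#'
#' @param species A `ckmr_species` object.
#' @param n_replicates Number of simulated populations.
#' @param master_seed Integer master seed; each replicate's seed is derived
#'   from it by a fixed counter scheme so runs are reproducible.
#' @param scenarios A tibble from [scenario_grid()] (any subset of it).
#' @param years,sample_years,n_per_year,n0 Passed to
#'   [simulate_population()].
#' @param progress Print a dot per replicate.
#' @return A tibble of class `ckmr_fits` with one row per (replicate,
#'   scenario, sex): `replicate`, `scenario`, `me_factor`, `gc_shift`,
#'   `sex`, `estimate`, `se`, `lower`, `upper`, `converged`, `reason`,
#'   `N_true` (final-year adult abundance of that sex), `n_pop`,
#'   `growth_rate`, `pop_count` (true POPs in the replicate's samples).
#' @export
run_scenario_grid <- function(species, n_replicates, master_seed = 1L,
                              scenarios = scenario_grid(), years = 100L,
                              sample_years = c(99L, 100L), n_per_year = 375L,
                              n0 = 8500L, progress = FALSE) {
  stopifnot(n_replicates >= 1)
  res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_population(species, years = years,
                               sample_years = sample_years,
                               n_per_year = n_per_year, n0 = n0,
                               seed = replicate_seed(master_seed, r))
    counts <- comparison_counts(sim$samples, sim$pops)
    fin <- sim$truth[sim$truth$year == years, ]
    truth_by_sex <- c(F = fin$N_f_adult, M = fin$N_m_adult)

    rows <- purrr::pmap(scenarios, function(me_factor, gc_shift, scenario) {
      model <- age_model(vbgf_shift(species$vbgf, gc_shift),
                         me_factor * species$sigma_l, species$phi,
                         species$a_max)
      agg <- aggregate_comparisons(sim$samples, sim$pops, model, species,
                                   counts = counts)
      fit <- fit_ckmr(agg)
      tibble::tibble(
        replicate = r, scenario = scenario, me_factor = me_factor,
        gc_shift = gc_shift, sex = c("F", "M"),
        estimate = unname(fit$estimate), se = unname(fit$se),
        lower = fit$ci$lower, upper = fit$ci$upper,
        converged = fit$converged, reason = fit$failure_reason,
        N_true = unname(truth_by_sex), n_pop = fit$n_pop,
        growth_rate = sim$growth_rate, pop_count = nrow(sim$pops))
    })
    res[[r]] <- dplyr::bind_rows(rows)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(res)
  attr(out, "species") <- species$name
  class(out) <- c("ckmr_fits", class(out))
  out
}

#' Flag scenarios where fitting mostly failed
#'
#' A scenario is excluded from performance summaries when the fraction of
#' replicates whose fit did not converge exceeds `threshold` (one half by
#' default, operationalizing "most of the simulations").
#'
#' @param fits A tibble from [run_scenario_grid()].
#' @param threshold Failure fraction above which a scenario is excluded.
#' @return A tibble with `scenario`, `n_total`, `n_failed`, `excluded`.
#' @export
apply_exclusion_rule <- function(fits, threshold = 0.5) {
  per_fit <- dplyr::distinct(fits, .data$replicate, .data$scenario,
                             .data$converged)
  out <- dplyr::summarise(
    dplyr::group_by(per_fit, .data$scenario),
    n_total = dplyr::n(), n_failed = sum(!.data$converged),
    .groups = "drop")
  dplyr::mutate(out, excluded = .data$n_failed / .data$n_total > threshold)
}

#' Performance metrics per scenario and sex
#'
#' Computes, over the converged replicates of each (scenario, sex) cell,
#' the estimator-performance metrics: mean and median error
#' (`estimate - N_true`, individuals), mean and median relative error (%),
#' mean absolute error, root-mean-square error, coverage of the 95%
#' log-normal confidence intervals, the empirical standard error (the SD of
#' estimate errors across replicates -- of the errors, not the estimates,
#' since the true abundance varies between replicates), and the mean of the
#' model-estimated standard errors. Excluded scenarios (see
#' [apply_exclusion_rule()]) carry only counts.
#'
#' @param fits A tibble from [run_scenario_grid()]; `N_true` per row is the
#'   final-year adult abundance of that replicate and sex.
#' @param threshold Passed to [apply_exclusion_rule()].
#' @return A tibble of class `ckmr_metrics`, one row per (scenario, sex).
#' @export
compute_metrics <- function(fits, threshold = 0.5) {
  excl <- apply_exclusion_rule(fits, threshold)
  conv <- dplyr::filter(fits, .data$converged)
  met <- dplyr::summarise(
    dplyr::group_by(conv, .data$scenario, .data$me_factor, .data$gc_shift,
                    .data$sex),
    n_converged = dplyr::n(),
    mean_error = mean(.data$estimate - .data$N_true),
    median_error = median(.data$estimate - .data$N_true),
    mean_rel_error = mean(100 * (.data$estimate - .data$N_true) / .data$N_true),
    median_rel_error = median(100 * (.data$estimate - .data$N_true) /
                                .data$N_true),
    mae = mean(abs(.data$estimate - .data$N_true)),
    rmse = sqrt(mean((.data$estimate - .data$N_true)^2)),
    coverage = mean(.data$lower <= .data$N_true & .data$N_true <= .data$upper),
    empirical_se = sd(.data$estimate - .data$N_true),
    mean_estimated_se = mean(.data$se),
    .groups = "drop")
  out <- dplyr::left_join(
    dplyr::left_join(
      dplyr::distinct(fits, .data$scenario, .data$me_factor, .data$gc_shift,
                      .data$sex),
      met, by = c("scenario", "me_factor", "gc_shift", "sex")),
    excl[c("scenario", "n_total", "excluded")], by = "scenario")
  metric_cols <- setdiff(names(out),
                         c("scenario", "me_factor", "gc_shift", "sex",
                           "n_total", "n_converged", "excluded"))
  out <- dplyr::mutate(out, n_converged = tidyr::replace_na(.data$n_converged,
                                                            0L))
  out[out$excluded | out$n_converged < 2L, metric_cols] <- NA_real_
  class(out) <- c("ckmr_metrics", class(out))
  out
}
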