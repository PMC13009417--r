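# Patient-level bootstrap: patients are resampled with replacement (all of
# a patient's person-month rows travel together), every weight model and
# the outcome model are refit inside each replicate, and percentile
# confidence intervals are read off the replicate distribution. Replicates
# are implemented as per-patient multiplicity weights on the frozen design
# matrices, which is algebraically identical to resampling rows.

#' Patient-level bootstrap confidence intervals
#'
#' @param bundle an `ehr_bundle`, or an existing `trial_prep` /
#'   `trial_result` to avoid rebuilding the panel.
#' @param config a [run_config()]; `n_boot` and `boot_seed` control the
#'   replicates (production default 1000; scale down for exploration).
#' @param cohort_filter optional subgroup filter.
#' @return object of class `bootstrap_result`: `table` with one row per
#'   estimand (`arm`, `month`, `estimand`, `point`, `ci_low`, `ci_high`),
#'   `n_effective` converged replicates, and the point `effects`.
#' @export
bootstrap_ci <- function(bundle, config = run_config(), cohort_filter = NULL) {
  prep <- if (inherits(bundle, "trial_prep")) {
    bundle
  } else if (inherits(bundle, "trial_result")) {
    bundle$prep
  } else {
    prepare_analysis(bundle, config, cohort_filter)
  }
  config <- prep$config
  point <- fit_analysis(prep) # also seeds the warm starts for replicates
  point_vec <- fit_estimates(prep)
  n <- length(prep$pat_ids)
  B <- config$n_boot

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$boot_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, B)

  est_names <- c("mean_change", "contrast_vs_ref",
                 if (config$include_risk) c("risk5", "rr_vs_ref"))
  reps <- matrix(NA_real_, nrow = length(point_vec), ncol = B)
  failed <- 0L
  for (r in seq_len(B)) {
    set.seed(seeds[r])
    mult <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    fr <- tryCatch(fit_estimates(prep, mult = mult), error = function(e) e)
    if (inherits(fr, "error")) {
      failed <- failed + 1L
      if (failed > max(1L, ceiling(0.05 * B))) {
        stop2("more than 5% of bootstrap replicates failed; last error: ",
              conditionMessage(fr))
      }
      next
    }
    reps[, r] <- fr
  }
  ok <- colSums(is.na(reps)) < nrow(reps)
  ci <- t(apply(reps[, ok, drop = FALSE], 1L, quantile,
                probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  key <- prep$grid[prep$grid_idx]
  tab <- rbindlist(lapply(seq_along(est_names), function(j) {
    i <- (j - 1L) * nrow(key) + seq_len(nrow(key))
    data.table(arm = key$arm, month = key$month, estimand = est_names[j],
               point = point_vec[i], ci_low = ci[i, 1L], ci_high = ci[i, 2L])
  }))
  viol <- tab[!is.na(point) & (point < ci_low | point > ci_high)]
  if (nrow(viol)) {
    message(nrow(viol), " estimand(s) fall outside their percentile CI ",
            "(possible with percentile intervals; logged)")
  }
  structure(list(table = tab[], effects = point$effects,
                 n_effective = sum(ok), n_boot = B, seed = config$boot_seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$n_effective, "of", x$n_boot,
      "replicates converged\n")
  print(x$table)
  invisible(x)
}
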