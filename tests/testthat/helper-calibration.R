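# The six small-sample calibration scenarios (one-sample design, d = 4,
# standard normal marginals, no-time-effect hypothesis, MCAR) together with
# the reference type-I error rates (percent) of the three wild bootstrap
# tests, and the Monte Carlo sizes used to reproduce them.
calibration_scenarios <- function() {
  data.frame(
    cov_setting = c("AR", "AR", "CS", "TP", "TP", "AR"),
    n = c(30, 10, 20, 10, 30, 15),
    r = c(0.10, 0.10, 0.30, 0.30, 0.10, 0.30),
    wts_boot = c(5.6, 5.0, 5.4, 5.9, 4.8, 5.8),
    ats_boot = c(5.6, 5.2, 5.8, 6.0, 5.2, 5.7),
    mats_boot = c(5.7, 5.7, 6.0, 7.2, 5.4, 6.3),
    stringsAsFactors = FALSE
  )
}

calibration_nsim <- 2000
calibration_B <- 499

# run one calibration scenario and return the rate table
run_calibration_row <- function(row, seed, nsim = calibration_nsim,
                                B = calibration_B) {
  cfg <- scenario(a = 1, d = 4, n = row$n, marginal = "normal",
                  cov_setting = row$cov_setting, missing = "MCAR", r = row$r,
                  hypothesis = "time", nsim = nsim, B = B, seed = seed)
  run_type1_study(cfg)
}

# cache so the calibration and liberal-WTS checks share one set of runs
.calibration_cache <- new.env(parent = emptyenv())

calibration_results <- function() {
  if (is.null(.calibration_cache$tab)) {
    sc <- calibration_scenarios()
    .calibration_cache$tab <- lapply(seq_len(nrow(sc)), function(i) {
      run_calibration_row(sc[i, ], seed = 1000 + i)
    })
  }
  .calibration_cache$tab
}
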