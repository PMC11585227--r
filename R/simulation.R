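#' Covariance settings for the simulation designs
#'
#' Three repeated-measures dependence structures:
#' `"AR"` autoregressive, \eqn{\Sigma_{lj} = 0.6^{|l-j|}};
#' `"CS"` the identity \eqn{I_d} (independent coordinates);
#' `"TP"` linear Toeplitz, \eqn{\Sigma_{lj} = d - |l-j|}.
#'
#' @param setting `"AR"`, `"CS"` or `"TP"`.
#' @param d number of time points.
#' @param rho autoregressive parameter (default 0.6).
#' @return a `d x d` covariance matrix.
#' @examples
#' sim_covariance("TP", 3)  # Toeplitz 3,2,1
#' @export
sim_covariance <- function(setting = c("AR", "CS", "TP"), d, rho = 0.6) {
  setting <- match.arg(setting)
  stopifnot(d >= 1)
  idx <- abs(outer(seq_len(d), seq_len(d), "-"))
  switch(setting,
    AR = rho^idx,
    CS = diag(d),
    TP = d - idx
  )
}

# marginal quantile functions on the uniform scale
marginal_quantile <- function(marginal) {
  switch(marginal,
    normal = stats::qnorm,
    double_exponential = function(u)  # Laplace(0, 1)
      ifelse(u < 0.5, log(2 * u), -log(2 * (1 - u))),
    lognormal = function(u) exp(stats::qnorm(u)),
    chisq15 = function(u) stats::qchisq(u, df = 15),
    stop("unknown marginal: ", marginal)
  )
}

#' Generate continuous repeated measures via a Gaussian copula
#'
#' Draws, per subject, a multivariate normal vector with the correlation
#' matrix induced by the chosen covariance setting (the covariance is
#' diagonal-normalized, since a copula consumes a correlation and the
#' marginals fix the scale), maps coordinates to uniforms with the standard
#' normal CDF, then through the inverse CDF of the target marginal. An
#' optional location shift (for power studies) is added on the final scale.
#' Because the marginal map is strictly increasing, the pooled mid-ranks --
#' and hence every statistic in this package -- depend only on the copula
#' draw, not on the marginal choice.
#'
#' @param n vector of group sizes.
#' @param d number of time points.
#' @param marginal one of `"normal"`, `"double_exponential"`, `"lognormal"`,
#'   `"chisq15"`.
#' @param cov_setting see [sim_covariance()].
#' @param shift optional length-`d` location shift added to every subject
#'   of group 1 (the one-sample power alternatives); default none.
#' @return a complete [ifd] object (no missing values yet).
#' @export
generate_continuous <- function(n, d, marginal = "normal",
                                cov_setting = "AR", shift = NULL) {
  Sigma <- sim_covariance(cov_setting, d)
  Corr <- stats::cov2cor(Sigma)
  ch <- tryCatch(chol(Corr),
                 error = function(e) stop("correlation matrix is not ",
                                          "positive definite"))
  qf <- marginal_quantile(marginal)
  if (!is.null(shift) && length(shift) != d)
    stop("'shift' must have length d")
  values <- lapply(seq_along(n), function(i) {
    Zn <- matrix(stats::rnorm(n[i] * d), n[i], d) %*% ch
    Xm <- qf(stats::pnorm(Zn))
    if (i == 1L && !is.null(shift)) Xm <- sweep(Xm, 2L, shift, "+")
    Xm
  })
  ifd(values)
}

#' Generate four-level ordinal repeated measures
#'
#' \eqn{X_{ijk} = \lfloor 4 (c Z_{ik} + Y_{ijk}) / (c + 1) \rfloor + 1} with
#' independent uniform(0,1) variables \eqn{Z_{ik}} (shared within subject,
#' inducing a compound-symmetric dependence) and \eqn{Y_{ijk}}. Values lie in
#' \{1, 2, 3, 4\} almost surely; `c = 1` (the default) gives a triangular
#' latent marginal with \eqn{P(X = 1) = 1/8}.
#'
#' @param n vector of group sizes.
#' @param d number of time points.
#' @param c_dep positive dependence constant (default 1).
#' @return a complete [ifd] object.
#' @export
generate_ordinal <- function(n, d, c_dep = 1) {
  stopifnot(c_dep > 0)
  values <- lapply(n, function(ni) {
    Z <- stats::runif(ni)
    Y <- matrix(stats::runif(ni * d), ni, d)
    floor(4 * (c_dep * Z + Y) / (c_dep + 1)) + 1
  })
  ifd(values)
}

# redraw-until-valid wrapper shared by the missingness mechanisms:
# draw_mask(x) returns a list of 0/1 matrices; keep redrawing the whole mask
# until every cell retains >= 2 observed subjects.
apply_mask_valid <- function(x, draw_mask, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    mask <- draw_mask(x)
    ld <- t(vapply(mask, colSums, numeric(x$d)))
    if (all(ld >= 2)) {
      values <- lapply(seq_len(x$a), function(i) {
        m <- x$values[[i]]
        m[mask[[i]] == 0] <- NA
        m
      })
      out <- ifd(values, x$group_labels, x$time_labels, x$subject_ids,
                 warn_empty_subjects = FALSE)
      attr(out, "mask_tries") <- try
      return(out)
    }
  }
  stop("no valid missingness mask after ", max_tries,
       " attempts: design too small for this missing rate")
}

#' Missing completely at random
#'
#' Deletes each coordinate independently with probability `r`. The whole mask
#' is redrawn (up to `max_tries` times) if any (group, time) cell would retain
#' fewer than 2 observed subjects, so that the covariance estimators remain
#' defined.
#'
#' @param x a complete [ifd] object.
#' @param r missing probability, in \[0, 1).
#' @param max_tries redraw budget.
#' @return an [ifd] with `NA`s inserted; attribute `"mask_tries"` records the
#'   number of mask draws used.
#' @export
apply_mcar <- function(x, r, max_tries = 1000L) {
  stopifnot(inherits(x, "ifd"), r >= 0, r < 1)
  if (r == 0) return(x)
  apply_mask_valid(x, function(x) {
    lapply(x$n, function(ni) {
      matrix(as.integer(stats::runif(ni * x$d) >= r), ni, x$d)
    })
  }, max_tries)
}

# (determining, target) coordinate pairs for the MAR mechanisms
mar_pairs <- function(d) {
  if (d == 4) list(c(1L, 2L), c(3L, 4L))
  else if (d == 8) list(c(1L, 2L), c(1L, 3L), c(6L, 7L), c(6L, 8L))
  else stop("MAR mechanisms are defined for d = 4 or d = 8")
}

#' Missing at random, mechanism 1 (standard-deviation strata)
#'
#' For each (determining, target) coordinate pair -- (1,2), (3,4) for `d = 4`;
#' (1,2), (1,3), (6,7), (6,8) for `d = 8` -- subjects are stratified by the
#' determining coordinate into \eqn{(-\infty, -2\hat\sigma)},
#' \eqn{[-2\hat\sigma, 2\hat\sigma]} and \eqn{(2\hat\sigma, \infty)}, with
#' \eqn{\hat\sigma} the sample standard deviation of that coordinate. The
#' target coordinate is deleted with probability 0.15 in the outer strata and
#' 0.30 in the middle one. Determining coordinates are never deleted by their
#' own pair; for `d = 8`, coordinates 4 and 5 are never deleted at all.
#'
#' @inheritParams apply_mcar
#' @export
apply_mar1 <- function(x, max_tries = 1000L) {
  stopifnot(inherits(x, "ifd"))
  pairs <- mar_pairs(x$d)
  apply_mask_valid(x, function(x) {
    lapply(seq_len(x$a), function(i) {
      m <- matrix(1L, x$n[i], x$d)
      for (pr in pairs) {
        obs <- x$values[[i]][, pr[1]]
        sg <- stats::sd(obs)
        middle <- obs >= -2 * sg & obs <= 2 * sg
        pmiss <- ifelse(middle, 0.30, 0.15)
        del <- stats::runif(x$n[i]) < pmiss
        m[del, pr[2]] <- 0L
      }
      m
    })
  }, max_tries)
}

#' Missing at random, mechanism 2 (median strata)
#'
#' Same coordinate pairs as [apply_mar1()]; subjects at or below the median of
#' the determining coordinate lose the target with probability 0.10, subjects
#' above it with probability 0.30.
#'
#' @inheritParams apply_mcar
#' @export
apply_mar2 <- function(x, max_tries = 1000L) {
  stopifnot(inherits(x, "ifd"))
  pairs <- mar_pairs(x$d)
  apply_mask_valid(x, function(x) {
    lapply(seq_len(x$a), function(i) {
      m <- matrix(1L, x$n[i], x$d)
      for (pr in pairs) {
        obs <- x$values[[i]][, pr[1]]
        upper <- obs > stats::median(obs)
        pmiss <- ifelse(upper, 0.30, 0.10)
        del <- stats::runif(x$n[i]) < pmiss
        m[del, pr[2]] <- 0L
      }
      m
    })
  }, max_tries)
}

#' Simulation scenario configuration
#'
#' Bundles the design, distribution, dependence, missingness and study sizes
#' of one Monte Carlo scenario. Defaults follow the main simulation designs:
#' Rademacher weights, `alpha = 0.05`, four-level factorial hypotheses over
#' `hypothesis`, and location-shift alternatives added after the copula
#' transform.
#'
#' @param a,d,n design: number of groups, time points, and group sizes
#'   (recycled to length `a`).
#' @param marginal `"normal"`, `"double_exponential"`, `"lognormal"`,
#'   `"chisq15"`, or `"ordinal"`.
#' @param cov_setting `"AR"`, `"CS"` or `"TP"` (ignored for ordinal data).
#' @param missing `"none"`, `"MCAR"`, `"MAR1"` or `"MAR2"`.
#' @param r MCAR missing probability.
#' @param hypothesis hypothesis tag passed to [contrast_matrix()].
#' @param shift optional length-`d` location shift for group 1 (power).
#' @param nsim Monte Carlo repetitions.
#' @param B bootstrap replicates per repetition.
#' @param alpha nominal level.
#' @param weights bootstrap weight scheme.
#' @param seed integer seed for the whole study.
#' @return a list of class `"wr_scenario"`.
#' @export
scenario <- function(a = 1, d = 4, n = 10, marginal = "normal",
                     cov_setting = "AR", missing = "MCAR", r = 0.1,
                     hypothesis = "time", shift = NULL, nsim = 1000,
                     B = 499, alpha = 0.05, weights = "rademacher",
                     seed = NULL) {
  n <- rep(n, length.out = a)
  stopifnot(nsim >= 1, B >= 1, r >= 0, r < 1, alpha > 0, alpha < 1)
  missing <- match.arg(missing, c("none", "MCAR", "MAR1", "MAR2"))
  if (!is.null(shift) && length(shift) != d)
    stop("'shift' must have length d")
  structure(list(a = a, d = d, n = n, marginal = marginal,
                 cov_setting = cov_setting, missing = missing, r = r,
                 hypothesis = hypothesis, shift = shift, nsim = nsim, B = B,
                 alpha = alpha, weights = weights, seed = seed),
            class = "wr_scenario")
}

# one simulated dataset under a scenario
simulate_dataset <- function(cfg) {
  x <- if (identical(cfg$marginal, "ordinal"))
    generate_ordinal(cfg$n, cfg$d)
  else
    generate_continuous(cfg$n, cfg$d, cfg$marginal, cfg$cov_setting,
                        shift = cfg$shift)
  switch(cfg$missing,
    none = x,
    MCAR = apply_mcar(x, cfg$r),
    MAR1 = apply_mar1(x),
    MAR2 = apply_mar2(x)
  )
}

# fast per-dataset analysis: observed statistics, asymptotic p-values and
# bootstrap p-values for all three methods at once
analyze_dataset <- function(x, cs, B, weights) {
  meta <- design_meta(x)
  rt <- midranks(x)
  p_hat <- relative_effects(rt, meta)
  cv <- suppressWarnings(covariance_estimate(rt, meta))
  obs <- c(wts = wts(p_hat, cv, cs, meta$n_total)$statistic,
           ats = NA, mats = mats(p_hat, cv, cs, meta$n_total)$statistic)
  ares <- ats(p_hat, cv, cs, meta$n_total)
  obs["ats"] <- ares$statistic
  bs <- boot_engine(x, rt, meta, cs, weights, B)
  p_boot <- vapply(1:3, function(j) mean(bs$stats[, j] >= obs[j]), 0)
  list(
    p_asym = c(wts = stats::pchisq(obs[["wts"]], df = cs$f,
                                   lower.tail = FALSE),
               ats = ares$p_asymptotic),
    p_boot = c(wts = p_boot[1], ats = p_boot[2], mats = p_boot[3]),
    n_degenerate = bs$n_degenerate
  )
}

#' Type-I error study
#'
#' Simulates `nsim` datasets under the scenario's null configuration and
#' reports, for the asymptotic WTS and ATS tests and the three wild bootstrap
#' tests, the empirical rejection rate at level `alpha` (in percent) together
#' with its binomial Monte Carlo standard error.
#'
#' @param cfg a [scenario()] (its `shift` must be `NULL` for a genuine null).
#' @param progress print a dot every 200 repetitions.
#' @return data.frame with columns `method`, `rate` (percent), `mc_se`
#'   (percent), `nsim`; attribute `"degenerate_replicates"` tallies ATS
#'   bootstrap replicates with zero trace.
#' @export
run_type1_study <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "wr_scenario"))
  rates <- with_seed(cfg$seed, {
    rej <- matrix(0, cfg$nsim, 5,
                  dimnames = list(NULL, c("wts_asym", "ats_asym", "wts_boot",
                                          "ats_boot", "mats_boot")))
    ndeg <- 0L
    cs <- contrast_matrix(cfg$hypothesis, cfg$a, cfg$d)
    for (s in seq_len(cfg$nsim)) {
      x <- simulate_dataset(cfg)
      res <- analyze_dataset(x, cs, cfg$B, cfg$weights)
      rej[s, ] <- c(res$p_asym[["wts"]] <= cfg$alpha,
                    res$p_asym[["ats"]] <= cfg$alpha,
                    res$p_boot <= cfg$alpha)
      ndeg <- ndeg + res$n_degenerate
      if (progress && s %% 200 == 0) cat(".")
    }
    if (progress) cat("\n")
    list(rej = rej, ndeg = ndeg)
  })
  rate <- colMeans(rates$rej)
  out <- data.frame(
    method = colnames(rates$rej),
    rate = 100 * rate,
    mc_se = 100 * sqrt(rate * (1 - rate) / cfg$nsim),
    nsim = cfg$nsim,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "degenerate_replicates") <- rates$ndeg
  out
}

#' Power study over a grid of shift alternatives
#'
#' One-sample power design: for each shift magnitude `zeta`, the scenario's
#' base shift pattern (default `(0, 0, 1, 1)`, i.e. the last two coordinates
#' move together) is scaled by `zeta`, applied after the copula transform, and
#' the rejection rates of all five tests are recorded.
#'
#' @param cfg a [scenario()]; its `shift` field supplies the unit pattern
#'   (`NULL` means `c(0, 0, 1, 1)` for `d = 4`).
#' @param zeta numeric grid of shift magnitudes.
#' @param progress print progress dots.
#' @return data.frame with columns `zeta`, `method`, `rate`, `mc_se`, `nsim`.
#' @export
run_power_study <- function(cfg, zeta = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                            progress = FALSE) {
  stopifnot(inherits(cfg, "wr_scenario"))
  pattern <- if (is.null(cfg$shift)) {
    if (cfg$d != 4) stop("supply a shift pattern for d != 4")
    c(0, 0, 1, 1)
  } else cfg$shift
  out <- lapply(seq_along(zeta), function(z) {
    cz <- cfg
    cz$shift <- zeta[z] * pattern
    cz$seed <- if (is.null(cfg$seed)) NULL else cfg$seed + z - 1L
    tab <- run_type1_study(cz, progress = progress)
    cbind(zeta = zeta[z], tab)
  })
  do.call(rbind, out)
}
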