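#' Quadratic-form rank statistics
#'
#' The three statistics for the nonparametric null hypothesis
#' \eqn{H_0: CF = 0}, evaluated from the relative effect vector
#' \eqn{\hat p} and the covariance estimates:
#' \describe{
#'   \item{WTS}{\eqn{T_W = n \hat p^\top C^\top (C \hat V_n C^\top)^+ C
#'     \hat p}; asymptotically \eqn{\chi^2_f} with \eqn{f = rank(C)}.}
#'   \item{ATS}{\eqn{T_A = n \hat p^\top T \hat p / tr(T \hat V_n)} with
#'     \eqn{T = C^\top (C C^\top)^+ C}; approximated by \eqn{F(\hat f, \infty)}
#'     where the Box-type estimate is
#'     \eqn{\hat f = tr(T\hat V_n)^2 / tr(T\hat V_n T \hat V_n)}.}
#'   \item{MATS}{\eqn{T_M = n \hat p^\top C^\top (C \hat D_n C^\top)^+ C
#'     \hat p} with \eqn{\hat D_n = diag(\hat V_n)}; its limit law has unknown
#'     weights, so no asymptotic p-value is reported and calibration is by the
#'     wild bootstrap only.}
#' }
#'
#' @param p_hat relative effect vector from [relative_effects()].
#' @param cov a `"rank_cov"` from [covariance_estimate()] (WTS/ATS use `V`,
#'   MATS uses `D`).
#' @param cs a `"contrast_spec"`.
#' @param n total number of subjects (all groups).
#' @return a `"wildrank_result"`: `method`, `statistic`, `f` (WTS) or `f_hat`
#'   (ATS), `p_asymptotic` (`NA` for MATS), and placeholders `p_bootstrap`,
#'   `B`, `weight_scheme`, `seed` filled by [rank_test()].
#' @name quadratic_statistics
NULL

new_result <- function(method, statistic, p_asym = NA_real_, f = NA_real_,
                       f_hat = NA_real_) {
  structure(
    list(method = method, statistic = statistic, p_asymptotic = p_asym,
         f = f, f_hat = f_hat, p_bootstrap = NA_real_, B = NA_integer_,
         weight_scheme = NA_character_, seed = NA_integer_,
         degenerate_replicates = 0L),
    class = "wildrank_result"
  )
}

#' @rdname quadratic_statistics
#' @export
wts <- function(p_hat, cov, cs, n) {
  C <- cs$C
  Cp <- as.vector(C %*% p_hat)
  stat <- n * drop(crossprod(Cp, mp_pinv(C %*% cov$V %*% t(C)) %*% Cp))
  new_result("WTS", stat, p_asym = stats::pchisq(stat, df = cs$f,
                                                 lower.tail = FALSE),
             f = cs$f)
}

#' @rdname quadratic_statistics
#' @export
ats <- function(p_hat, cov, cs, n) {
  TV <- cs$T %*% cov$V
  tr1 <- sum(diag(TV))
  if (tr1 <= 0) stop("degenerate design: tr(T V-hat) <= 0")
  f_hat <- tr1^2 / sum(TV * t(TV))
  stat <- n * drop(crossprod(p_hat, cs$T %*% p_hat)) / tr1
  new_result("ATS", stat,
             p_asym = stats::pchisq(f_hat * stat, df = f_hat,
                                    lower.tail = FALSE),
             f_hat = f_hat)
}

#' @rdname quadratic_statistics
#' @export
mats <- function(p_hat, cov, cs, n) {
  dv <- diag(cov$D)
  if (any(dv <= 0))
    stop("MATS requires all diagonal variance estimates v_i(j,j) > 0; ",
         "a degenerate (e.g. constant) cell violates its assumptions")
  C <- cs$C
  Cp <- as.vector(C %*% p_hat)
  stat <- n * drop(crossprod(Cp, mp_pinv(C %*% cov$D %*% t(C)) %*% Cp))
  new_result("MATS", stat)
}

#' @export
print.wildrank_result <- function(x, ...) {
  df <- if (x$method == "WTS") sprintf("f = %d", x$f)
        else if (x$method == "ATS") sprintf("f-hat = %.3f", x$f_hat)
        else "bootstrap-calibrated"
  cat(sprintf("%s = %.5f (%s)\n", x$method, x$statistic, df))
  if (!is.na(x$p_asymptotic))
    cat(sprintf("  asymptotic p = %.5g\n", x$p_asymptotic))
  if (!is.na(x$p_bootstrap))
    cat(sprintf("  bootstrap  p = %.5g (B = %d, %s weights)\n",
                x$p_bootstrap, x$B, x$weight_scheme))
  invisible(x)
}

#' One-line serializations of a test result
#'
#' @param x a `"wildrank_result"`.
#' @return `result_json()` a JSON string; `result_tsv()` a single
#'   tab-separated line `method, statistic, df, p_asym, p_boot`.
#' @export
result_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname result_json
#' @export
result_tsv <- function(x) {
  df <- if (x$method == "WTS") x$f else if (x$method == "ATS") x$f_hat else NA
  paste(x$method, format(x$statistic), format(df),
        format(x$p_asymptotic), format(x$p_bootstrap), sep = "\t")
}
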