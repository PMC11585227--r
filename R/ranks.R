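#' Pooled mid-ranks of all observed values
#'
#' Ranks all \eqn{N} observed values (pooled over groups, time points and
#' subjects) with ties replaced by mid-ranks. The mid-rank equals
#' \eqn{1/2 + \sum c(X_{ijk} - X_{lms})} where the sum runs over all observed
#' values and \eqn{c(u)} is the normalized counting function (0, 1/2, 1 for
#' \eqn{u < 0}, \eqn{u = 0}, \eqn{u > 0}); computed here by sorting with
#' average-tie assignment, which is exactly equivalent.
#'
#' @param x an [ifd] object with at least one observed value.
#' @return a list of class `"rank_table"`: `R` (list of `n_i x d` mid-rank
#'   matrices, `NA` at unobserved entries), `N`, `Rbar` (a x d matrix of
#'   per-cell rank means \eqn{\bar R_{ij\cdot}}).
#' @export
midranks <- function(x) {
  stopifnot(inherits(x, "ifd"))
  pooled <- unlist(lapply(x$values, as.vector), use.names = FALSE)
  obs <- !is.na(pooled)
  N <- sum(obs)
  if (N < 1) stop("no observed values")
  r <- rep(NA_real_, length(pooled))
  r[obs] <- rank(pooled[obs], ties.method = "average")
  R <- vector("list", x$a)
  off <- 0L
  for (i in seq_len(x$a)) {
    len <- x$n[i] * x$d
    R[[i]] <- matrix(r[off + seq_len(len)], x$n[i], x$d)
    off <- off + len
  }
  Rbar <- t(vapply(R, function(m) colMeans(m, na.rm = TRUE), numeric(x$d)))
  structure(list(R = R, N = N, Rbar = Rbar, a = x$a, d = x$d, n = x$n),
            class = "rank_table")
}

#' Relative marginal effect estimates
#'
#' Estimates \eqn{p_{ij} = \int H \, dF_{ij}}, the probability that a value
#' from cell (i, j) tends to exceed a value from the weighted pooled
#' distribution \eqn{H}, by
#' \eqn{\hat p_{ij} = \lambda_{ij\cdot}^{-1} \sum_k \lambda_{ijk}
#' (R_{ijk} - 1/2)/N}. Entries are collected group-major
#' (\eqn{\hat p_{11}, \dots, \hat p_{1d}, \hat p_{21}, \dots}).
#'
#' @param rt a `"rank_table"` from [midranks()].
#' @param meta an `"ifd_meta"` from [design_meta()].
#' @return named numeric vector of length `a * d`, entries in (0, 1).
#' @export
relative_effects <- function(rt, meta) {
  stopifnot(inherits(rt, "rank_table"), inherits(meta, "ifd_meta"))
  empty <- which(meta$lambda_dot < 1, arr.ind = TRUE)
  if (nrow(empty) > 0)
    stop("empty cell(s) (group, time): ",
         paste(sprintf("(%d, %d)", empty[, 1], empty[, 2]), collapse = ", "))
  p <- as.vector(t((rt$Rbar - 0.5) / rt$N))
  names(p) <- as.vector(t(outer(seq_len(meta$a), seq_len(meta$d),
                                function(i, j) sprintf("g%d.t%d", i, j))))
  p
}

# covariance block for one group: Rmat n_i x d (NA at missing)
# returns d x d matrix V_i per the rank covariance estimator
cov_block <- function(Rmat, lamdot, Delta, N, n_i, warn = TRUE) {
  d <- ncol(Rmat)
  L <- !is.na(Rmat)
  Rbar <- colMeans(Rmat, na.rm = TRUE)
  Rc <- sweep(Rmat, 2L, Rbar)
  Rc[!L] <- 0
  V <- matrix(0, d, d)
  zeroed <- 0L
  for (j in seq_len(d)) {
    V[j, j] <- n_i * sum(Rc[, j]^2) / (N^2 * lamdot[j] * (lamdot[j] - 1))
    if (j < d) for (jp in seq((j + 1L), d)) {
      den <- N^2 * ((lamdot[j] - 1) * (lamdot[jp] - 1) + Delta[j, jp] - 1)
      if (den <= 0) {
        zeroed <- zeroed + 1L
      } else {
        V[j, jp] <- V[jp, j] <- n_i * sum(Rc[, j] * Rc[, jp]) / den
      }
    }
  }
  if (zeroed > 0 && warn)
    warning(sprintf("%d off-diagonal covariance denominator(s) <= 0; %s",
                    zeroed, "entries set to 0"))
  V
}

#' Rank covariance estimators V-hat and D-hat
#'
#' Estimates the asymptotic covariance of \eqn{\sqrt n \hat p} as the block
#' diagonal \eqn{\hat V_n = \oplus_i (n/n_i)\hat V_i}, where the per-group
#' blocks use all available pairwise-complete information:
#' \deqn{\hat v_i(j,j) = n_i \sum_k \lambda_{ijk}(R_{ijk} - \bar R_{ij\cdot})^2
#'   / \{N^2 \lambda_{ij\cdot}(\lambda_{ij\cdot} - 1)\},}
#' \deqn{\hat v_i(j,j') = n_i \sum_k \lambda_{ijk}\lambda_{ij'k}
#'   (R_{ijk} - \bar R_{ij\cdot})(R_{ij'k} - \bar R_{ij'\cdot})
#'   / [N^2 \{(\lambda_{ij\cdot}-1)(\lambda_{ij'\cdot}-1)
#'   + \Delta_{i,jj'} - 1\}].}
#' \eqn{\hat D_n} keeps only the diagonal. An off-diagonal denominator that is
#' not positive (possible for very sparse masks) zeroes that entry with a
#' warning rather than aborting.
#'
#' @param rt a `"rank_table"` from [midranks()].
#' @param meta an `"ifd_meta"` from [design_meta()]; every cell must have
#'   \eqn{\lambda_{ij\cdot} \ge 2}.
#' @return list of class `"rank_cov"`: `V` (`ad x ad` block-diagonal matrix),
#'   `D` (same size, diagonal of `V`), `blocks` (list of unscaled
#'   \eqn{\hat V_i}).
#' @export
covariance_estimate <- function(rt, meta) {
  stopifnot(inherits(rt, "rank_table"), inherits(meta, "ifd_meta"))
  if (any(meta$lambda_dot < 2))
    stop("covariance estimation needs at least 2 observed subjects per cell")
  a <- meta$a; d <- meta$d; n_total <- meta$n_total
  V <- matrix(0, a * d, a * d)
  blocks <- vector("list", a)
  for (i in seq_len(a)) {
    blocks[[i]] <- cov_block(rt$R[[i]], meta$lambda_dot[i, ], meta$delta[[i]],
                             rt$N, meta$n[i])
    idx <- (i - 1L) * d + seq_len(d)
    V[idx, idx] <- (n_total / meta$n[i]) * blocks[[i]]
  }
  structure(list(V = V, D = diag(diag(V), a * d), blocks = blocks),
            class = "rank_cov")
}
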