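#' Moore-Penrose pseudoinverse of a symmetric matrix
#'
#' Spectral pseudoinverse: eigenvalues whose magnitude falls below
#' `tol * max(|eigenvalue|)` are treated as zero. The zero matrix maps to the
#' zero matrix.
#'
#' @param M symmetric numeric matrix.
#' @param tol relative eigenvalue threshold.
#' @return matrix of the same dimension.
#' @export
mp_pinv <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  mx <- max(abs(e$values), 0)
  inv <- ifelse(abs(e$values) > tol * mx & mx > 0, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

# rank by singular values, same relative tolerance as the pseudoinverse
mat_rank <- function(M, tol = 1e-10) {
  s <- svd(M, nu = 0, nv = 0)$d
  sum(s > tol * max(s, 0))
}

#' Contrast matrices for factorial repeated-measures hypotheses
#'
#' Builds the contrast matrix \eqn{C} and projection
#' \eqn{T = C^\top (C C^\top)^+ C} for the standard hypotheses about the
#' vector \eqn{F = (F_{11}, \dots, F_{ad})^\top} of distribution functions:
#' no group effect (`"group"`, \eqn{C = P_a \otimes \frac1d J_d}), no time
#' effect (`"time"`, \eqn{C = \frac1a J_a \otimes P_d}) and no interaction
#' (`"interaction"`, \eqn{C = P_a \otimes P_d}), with
#' \eqn{P_m = I_m - \frac1m J_m} the centering matrix. All formulations with
#' the same row space yield the same projection and hence the same hypothesis
#' and test statistics.
#'
#' @param hypothesis `"group"`, `"time"` or `"interaction"`.
#' @param a number of groups; `"group"`/`"interaction"` need `a >= 2`.
#' @param d number of time points; `"time"`/`"interaction"` need `d >= 2`.
#' @return object of class `"contrast_spec"`: `C`, `T`, `f = rank(C)`,
#'   `hypothesis`.
#' @examples
#' contrast_matrix("time", a = 1, d = 4)$f  # 3
#' @export
contrast_matrix <- function(hypothesis = c("group", "time", "interaction"),
                            a, d) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(a >= 1, d >= 1)
  P <- function(m) diag(m) - matrix(1 / m, m, m)
  J <- function(m) matrix(1 / m, m, m)
  C <- switch(hypothesis,
    group = {
      if (a < 2) stop("the group hypothesis needs a >= 2 groups")
      kronecker(P(a), J(d))
    },
    time = {
      if (d < 2) stop("the time hypothesis needs d >= 2 time points")
      kronecker(J(a), P(d))
    },
    interaction = {
      if (a < 2 || d < 2)
        stop("the interaction hypothesis needs a >= 2 and d >= 2")
      kronecker(P(a), P(d))
    }
  )
  new_contrast(C, hypothesis)
}

#' Custom contrast specification
#'
#' Wraps a user-supplied contrast matrix (rows must sum to zero within
#' `1e-12`) into a `"contrast_spec"`, e.g. one read from a CSV with
#' `as.matrix(read.csv(file, header = FALSE))`.
#'
#' @param C numeric matrix with `a * d` columns and zero row sums.
#' @return a `"contrast_spec"` with `hypothesis = "custom"`.
#' @export
custom_contrast <- function(C) {
  C <- as.matrix(C)
  if (any(abs(rowSums(C)) > 1e-12))
    stop("not a contrast matrix: row sums must be 0 (|sum| <= 1e-12)")
  new_contrast(C, "custom")
}

new_contrast <- function(C, hypothesis) {
  Tm <- t(C) %*% mp_pinv(C %*% t(C)) %*% C
  Tm <- (Tm + t(Tm)) / 2
  structure(list(C = C, T = Tm, f = mat_rank(C), hypothesis = hypothesis),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("Contrast (%s): %d x %d, rank f = %d\n",
              x$hypothesis, nrow(x$C), ncol(x$C), x$f))
  invisible(x)
}
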