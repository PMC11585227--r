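#' Wild bootstrap weight schemes
#'
#' All schemes draw i.i.d. weights with mean 0 and variance 1:
#' \describe{
#'   \item{rademacher}{\eqn{P(W = -1) = P(W = 1) = 1/2} (default and
#'     recommended).}
#'   \item{mammen}{two-point: \eqn{P(W = -(\sqrt5-1)/2) = (\sqrt5+1)/(2\sqrt5)},
#'     \eqn{P(W = (\sqrt5+1)/2) = 1 - (\sqrt5+1)/(2\sqrt5)}.}
#'   \item{normal}{standard normal.}
#'   \item{poisson}{centered Poisson, \eqn{Po(1) - 1}.}
#' }
#'
#' @param scheme weight scheme tag.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_weights <- function(scheme = c("rademacher", "mammen", "normal",
                                    "poisson"), n) {
  scheme <- match.arg(scheme)
  switch(scheme,
    rademacher = sample(c(-1, 1), n, replace = TRUE),
    mammen = {
      s5 <- sqrt(5)
      sample(c(-(s5 - 1) / 2, (s5 + 1) / 2), n, replace = TRUE,
             prob = c((s5 + 1) / (2 * s5), 1 - (s5 + 1) / (2 * s5)))
    },
    normal = stats::rnorm(n),
    poisson = stats::rpois(n, 1) - 1
  )
}

#' Centered rank vectors
#'
#' \eqn{Z_{ijk} = R_{ijk} - \bar R_{ij\cdot}} wherever the observation exists;
#' unobserved entries are stored as 0 and, multiplied by their zero mask, never
#' enter any downstream sum.
#'
#' @param rt a `"rank_table"` from [midranks()].
#' @return list of `n_i x d` matrices.
#' @export
center_ranks <- function(rt) {
  stopifnot(inherits(rt, "rank_table"))
  lapply(seq_len(rt$a), function(i) {
    Z <- sweep(rt$R[[i]], 2L, rt$Rbar[i, ])
    Z[is.na(Z)] <- 0
    Z
  })
}

#' Bootstrap relative effects (reference implementation)
#'
#' \eqn{\hat p^*_{ij} = \lambda_{ij\cdot}^{-1} \sum_k \lambda_{ijk}
#' Z^*_{ijk}/N} for a single replicate \eqn{Z^*_{ik} = W_{ik} Z_{ik}} (one
#' weight per subject, shared across its time points). Centered: entries may
#' be negative, and they average to zero over replicates.
#'
#' @param Z_star list of per-group `n_i x d` weighted centered-rank matrices
#'   (0 at unobserved entries).
#' @param observed list of per-group 0/1 masks.
#' @param N total observed count.
#' @return numeric vector of length `a * d` (group-major).
#' @export
bootstrap_effects <- function(Z_star, observed, N) {
  unlist(lapply(seq_along(Z_star), function(i) {
    colSums(Z_star[[i]] * observed[[i]]) / colSums(observed[[i]]) / N
  }), use.names = FALSE)
}

#' Bootstrap covariance estimate (reference implementation)
#'
#' Same formulas as [covariance_estimate()] with ranks replaced by the
#' weighted centered ranks \eqn{Z^*} and cell means by
#' \eqn{\bar Z^*_{ij\cdot}}, recomputed per replicate.
#'
#' @inheritParams bootstrap_effects
#' @param meta an `"ifd_meta"`.
#' @return a `"rank_cov"` analogue (fields `V`, `D`, `blocks`).
#' @export
bootstrap_covariance <- function(Z_star, observed, meta) {
  a <- meta$a; d <- meta$d
  V <- matrix(0, a * d, a * d)
  blocks <- vector("list", a)
  for (i in seq_len(a)) {
    Zm <- Z_star[[i]]
    Zm[observed[[i]] == 0] <- NA  # cov_block treats NA as unobserved
    blocks[[i]] <- cov_block(Zm, meta$lambda_dot[i, ], meta$delta[[i]],
                             meta$N, meta$n[i], warn = FALSE)
    idx <- (i - 1L) * d + seq_len(d)
    V[idx, idx] <- (meta$n_total / meta$n[i]) * blocks[[i]]
  }
  structure(list(V = V, D = diag(diag(V), a * d), blocks = blocks),
            class = "rank_cov")
}

# canonical subject order within each group: lexicographic by observation
# mask then by observed values. Invariant under subject permutation and under
# strictly increasing transformations of the data, so the per-subject weight
# assignment (and hence the bootstrap p-value for a fixed seed) is too.
canonical_order <- function(x) {
  lapply(seq_len(x$a), function(i) {
    key <- cbind(x$observed[[i]],
                 ifelse(x$observed[[i]] == 1, x$values[[i]], Inf))
    do.call(order, as.data.frame(key))
  })
}

# evaluate scoped RNG: seed locally without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# shared bootstrap engine: returns B x 3 statistics (WTS, ATS, MATS) and the
# degenerate-ATS tally. Weights are drawn here, in canonical subject order.
boot_engine <- function(x, rt, meta, cs, scheme, B) {
  Z <- center_ranks(rt)
  ord <- canonical_order(x)
  W <- lapply(seq_len(x$a), function(i) {
    Wi <- matrix(draw_weights(scheme, x$n[i] * B), x$n[i], B)
    Wi[order(ord[[i]]), , drop = FALSE]  # weight stream keyed by canonical pos
  })
  L <- lapply(x$observed, function(o) {
    m <- o
    storage.mode(m) <- "double"
    m
  })
  boot_stats_cpp(Z, L, W, cs$C, cs$T, rt$N, meta$n_total, 1e-10)
}

#' Rank-based tests with wild bootstrap calibration
#'
#' The main entry point: computes the observed WTS, ATS and MATS for the
#' requested hypothesis and calibrates them by the wild bootstrap. Per
#' replicate, every subject's centered rank vector is multiplied by one
#' i.i.d. mean-0/variance-1 weight (shared across that subject's time points,
#' which preserves the within-subject dependence), the effect vector and
#' covariance estimators are recomputed from the weighted vectors, and the
#' statistic is re-evaluated with the same formula family (WTS uses
#' \eqn{\hat V^*_n}, ATS its trace functionals, MATS \eqn{\hat D^*_n}). The
#' bootstrap p-value is \eqn{B^{-1} \sum_b 1\{T^*_b \ge T\}}. A replicate with
#' \eqn{tr(T \hat V^*_n) \le 0} contributes \eqn{T^*_A = 0} (counted in the
#' result diagnostics), which can only make the ATS p-value larger.
#'
#' @param x an [ifd] object; every cell needs at least 2 observed subjects.
#' @param hypothesis `"group"`, `"time"`, `"interaction"`, or a
#'   `"contrast_spec"` (e.g. from [custom_contrast()]).
#' @param methods subset of `c("wts", "ats", "mats")`.
#' @param B number of bootstrap replicates (default 999).
#' @param weights weight scheme, see [draw_weights()].
#' @param seed optional integer seed (scoped to this call); required for
#'   reproducible p-values.
#' @param bootstrap set `FALSE` to skip the bootstrap (asymptotic p only;
#'   MATS then carries no p-value).
#' @return object of class `"wildrank_test"`: list of `"wildrank_result"`s
#'   (one per method) plus the design summary.
#' @examples
#' rank_test(demo_fixture(), "time", B = 199, seed = 1)
#' @export
rank_test <- function(x, hypothesis = "time",
                      methods = c("wts", "ats", "mats"), B = 999,
                      weights = "rademacher", seed = NULL, bootstrap = TRUE) {
  stopifnot(inherits(x, "ifd"), B >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  validate_ifd(x, min_per_cell = 2L)
  cs <- if (inherits(hypothesis, "contrast_spec")) hypothesis
        else contrast_matrix(hypothesis, x$a, x$d)
  if (ncol(cs$C) != x$a * x$d)
    stop("contrast has ", ncol(cs$C), " columns but the design needs ",
         x$a * x$d)
  meta <- design_meta(x)
  rt <- midranks(x)
  p_hat <- relative_effects(rt, meta)
  cv <- covariance_estimate(rt, meta)
  res <- list()
  if ("wts" %in% methods) res$wts <- wts(p_hat, cv, cs, meta$n_total)
  if ("ats" %in% methods) res$ats <- ats(p_hat, cv, cs, meta$n_total)
  if ("mats" %in% methods) res$mats <- mats(p_hat, cv, cs, meta$n_total)
  if (bootstrap) {
    bs <- with_seed(seed, boot_engine(x, rt, meta, cs, weights, B))
    col <- c(wts = 1L, ats = 2L, mats = 3L)
    for (m in methods) {
      res[[m]]$p_bootstrap <-
        mean(bs$stats[, col[[m]]] >= res[[m]]$statistic)
      res[[m]]$B <- as.integer(B)
      res[[m]]$weight_scheme <- weights
      res[[m]]$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
      if (m == "ats") res[[m]]$degenerate_replicates <- bs$n_degenerate
    }
  }
  structure(list(results = res, hypothesis = cs$hypothesis, a = x$a, d = x$d,
                 n = x$n, N = meta$N, p_hat = p_hat),
            class = "wildrank_test")
}

#' @export
print.wildrank_test <- function(x, ...) {
  cat(sprintf("Rank-based tests, hypothesis: no %s effect (a = %d, d = %d, N = %d)\n\n",
              x$hypothesis, x$a, x$d, x$N))
  for (r in x$results) print(r)
  invisible(x)
}

#' Tabular view of test results
#'
#' @param x a `"wildrank_test"` object.
#' @param ... unused.
#' @return data.frame with one row per method: statistic, df, asymptotic and
#'   bootstrap p-values.
#' @export
as.data.frame.wildrank_test <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(method = r$method, statistic = r$statistic,
               df = if (r$method == "WTS") r$f
                    else if (r$method == "ATS") r$f_hat else NA_real_,
               p_asymptotic = r$p_asymptotic, p_bootstrap = r$p_bootstrap,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
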