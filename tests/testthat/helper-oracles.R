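# Independent brute-force oracles used across the suite. All are O(N^2)
# implementations straight from the defining formulas (normalized counting
# function, empirical distribution sums), kept deliberately separate from the
# package's sort-based implementations.

# normalized counting function c(u) = 0, 1/2, 1 for u < 0, u = 0, u > 0
count_fn <- function(u) (sign(u) + 1) / 2

# mid-ranks by the counting-function definition over all observed values
oracle_midranks <- function(pooled) {
  obs <- pooled[!is.na(pooled)]
  vapply(pooled, function(xi) {
    if (is.na(xi)) NA_real_ else 0.5 + sum(count_fn(xi - obs))
  }, 0)
}

# relative effects via the empirical-distribution route: p_ij = mean over the
# cell's observed values of H-hat evaluated there, H-hat(x) = N^-1 sum c(x - X)
oracle_effects <- function(x) {
  pooled <- unlist(lapply(x$values, as.vector))
  obs <- pooled[!is.na(pooled)]
  N <- length(obs)
  Hhat <- function(v) sum(count_fn(v - obs)) / N
  out <- numeric(0)
  for (i in seq_len(x$a)) for (j in seq_len(x$d)) {
    cell <- x$values[[i]][, j]
    cell <- cell[!is.na(cell)]
    out <- c(out, mean(vapply(cell, Hhat, 0)))
  }
  out
}

# term-by-term covariance oracle from oracle mid-ranks
oracle_covariance <- function(x) {
  a <- x$a; d <- x$d
  pooled <- unlist(lapply(x$values, as.vector))
  r <- oracle_midranks(pooled)
  N <- sum(!is.na(pooled))
  n_total <- sum(x$n)
  R <- vector("list", a)
  off <- 0
  for (i in seq_len(a)) {
    R[[i]] <- matrix(r[off + seq_len(x$n[i] * d)], x$n[i], d)
    off <- off + x$n[i] * d
  }
  V <- matrix(0, a * d, a * d)
  for (i in seq_len(a)) {
    lam <- x$observed[[i]]
    B <- matrix(0, d, d)
    for (j in seq_len(d)) for (jp in seq_len(d)) {
      lj <- sum(lam[, j]); ljp <- sum(lam[, jp])
      Rbj <- sum(lam[, j] * ifelse(lam[, j] == 1, R[[i]][, j], 0)) / lj
      Rbjp <- sum(lam[, jp] * ifelse(lam[, jp] == 1, R[[i]][, jp], 0)) / ljp
      num <- 0
      for (k in seq_len(x$n[i])) {
        if (j == jp) {
          if (lam[, j][k] == 1) num <- num + (R[[i]][k, j] - Rbj)^2
        } else if (lam[, j][k] == 1 && lam[, jp][k] == 1) {
          num <- num + (R[[i]][k, j] - Rbj) * (R[[i]][k, jp] - Rbjp)
        }
      }
      den <- if (j == jp) N^2 * lj * (lj - 1)
      else {
        Delta <- sum(lam[, j] * lam[, jp])
        N^2 * ((lj - 1) * (ljp - 1) + Delta - 1)
      }
      B[j, jp] <- if (den > 0) x$n[i] * num / den else 0
    }
    idx <- (i - 1) * d + seq_len(d)
    V[idx, idx] <- (n_total / x$n[i]) * B
  }
  V
}

# quadratic forms via an independent pseudoinverse (full SVD route)
svd_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 0)
  dinv <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

oracle_stats <- function(p, V, C, n) {
  Tm <- t(C) %*% svd_pinv(C %*% t(C)) %*% C
  Cp <- C %*% p
  D <- diag(diag(V), length(p))
  c(wts = n * drop(t(Cp) %*% svd_pinv(C %*% V %*% t(C)) %*% Cp),
    ats = n * drop(t(p) %*% Tm %*% p) / sum(diag(Tm %*% V)),
    mats = n * drop(t(Cp) %*% svd_pinv(C %*% D %*% t(C)) %*% Cp))
}

# random incomplete dataset for property tests (every cell keeps >= 2 obs)
random_ifd <- function(a = 2, d = 3, n = c(7, 9), miss = 0.2, ties = FALSE) {
  n <- rep(n, length.out = a)
  vals <- lapply(n, function(ni) {
    m <- matrix(rnorm(ni * d), ni, d)
    if (ties) m <- round(m)  # force ties
    repeat {
      mask <- matrix(runif(ni * d) >= miss, ni, d)
      if (all(colSums(mask) >= 2) && all(rowSums(mask) >= 1)) break
    }
    m[!mask] <- NA
    m
  })
  ifd(vals)
}

# long-format CSV fixture writer
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
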