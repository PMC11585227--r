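test_that("weight schemes have the stated supports and first two moments", {
  set.seed(71)
  n <- 2e5
  for (s in c("rademacher", "mammen", "normal", "poisson")) {
    w <- draw_weights(s, n)
    expect_lt(abs(mean(w)), 4 * sd(w) / sqrt(n))
    expect_lt(abs(var(w) - 1), 0.05)
  }
  expect_true(all(draw_weights("rademacher", 1000) %in% c(-1, 1)))
  w <- draw_weights("mammen", 1e5)
  s5 <- sqrt(5)
  expect_setequal(round(unique(w), 10), round(c(-(s5 - 1) / 2, (s5 + 1) / 2), 10))
  expect_lt(abs(mean(w < 0) - (s5 + 1) / (2 * s5)), 0.01)
})

test_that("centered ranks: fixture arithmetic, zero cell sums, tied cells", {
  Z <- center_ranks(midranks(demo_fixture()))
  expect_equal(Z[[1]][, 1], c(-2.5, -1, 2.5, 1))
  expect_equal(sum(Z[[1]][, 1]), 0)  # complete cell centers to zero
  # unobserved entries are stored as zero
  expect_equal(Z[[1]][2, 2], 0)
  tied <- ifd(matrix(2, 5, 2))
  expect_true(all(unlist(center_ranks(midranks(tied))) == 0))
})

test_that("bootstrap effects: unit weights give zero, hand sum on the fixture", {
  x <- demo_fixture()
  rt <- midranks(x)
  Z <- center_ranks(rt)
  p1 <- bootstrap_effects(Z, x$observed, rt$N)  # W = +1
  expect_equal(p1[1], 0)  # complete cell
  pm <- bootstrap_effects(lapply(Z, function(z) -z), x$observed, rt$N)
  expect_equal(pm[1], 0)
  # alternating weights (1,-1,1,-1): hand summation
  W <- c(1, -1, 1, -1)
  Zs <- list(Z[[1]] * W)
  ps <- bootstrap_effects(Zs, x$observed, rt$N)
  expect_equal(ps[1], 0)          # (-2.5 + 1 + 2.5 - 1)/4/7
  expect_equal(ps[2], -2 / 9)     # ((-1/6) - 13/6*(-1)... = -14/3)/3/7
})

test_that("bootstrap covariance identities under unit and Rademacher weights", {
  set.seed(72)
  x <- random_ifd(a = 2, d = 3, n = c(7, 6), miss = 0.25)
  meta <- design_meta(x)
  rt <- midranks(x)
  Z <- center_ranks(rt)
  # W = 1 reproduces the original estimator exactly, missing data included
  expect_equal(bootstrap_covariance(Z, x$observed, meta)$V,
               covariance_estimate(rt, meta)$V, tolerance = 1e-14)
  # complete data, Rademacher weights: uncentered sums of squares are
  # preserved (W^2 = 1), so the re-centered variance cannot exceed the
  # original one (it loses the nonzero replicate mean)
  y <- ifd(matrix(rnorm(30), 10, 3))
  my <- design_meta(y)
  rty <- midranks(y)
  Zy <- center_ranks(rty)[[1]]
  for (rep in 1:5) {
    W <- draw_weights("rademacher", 10)
    Zs <- Zy * W
    expect_equal(colSums(Zs^2), colSums(Zy^2))
    vstar <- diag(bootstrap_covariance(list(Zs), y$observed, my)$V)
    vhat <- diag(covariance_estimate(rty, my)$V)
    expect_true(all(vstar <= vhat + 1e-12))
  }
  # all-tied cell gives zero bootstrap variance
  t0 <- ifd(cbind(rep(3, 6), rnorm(6)))
  m0 <- design_meta(t0)
  Z0 <- center_ranks(midranks(t0))
  Zs0 <- list(Z0[[1]] * draw_weights("rademacher", 6))
  expect_equal(bootstrap_covariance(Zs0, t0$observed, m0)$V[1, 1], 0)
})

test_that("compiled replicate path agrees with the R reference formulas", {
  set.seed(73)
  for (rep in 1:5) {
    x <- random_ifd(a = 2, d = 3, n = c(7, 9), miss = 0.2, ties = TRUE)
    meta <- design_meta(x)
    rt <- midranks(x)
    cs <- contrast_matrix(sample(c("group", "time", "interaction"), 1), 2, 3)
    Z <- center_ranks(rt)
    scheme <- sample(c("rademacher", "normal", "mammen"), 1)
    W <- lapply(x$n, function(ni) matrix(draw_weights(scheme, ni), ni, 1))
    L <- lapply(x$observed, function(o) { storage.mode(o) <- "double"; o })
    cpp <- wildrank:::boot_stats_cpp(Z, L, W, cs$C, cs$T, rt$N,
                                     meta$n_total, 1e-10)
    Zs <- lapply(1:2, function(i) Z[[i]] * W[[i]][, 1])
    ps <- bootstrap_effects(Zs, x$observed, rt$N)
    cvb <- bootstrap_covariance(Zs, x$observed, meta)
    expect_equal(as.vector(cpp$stats),
                 unname(oracle_stats(ps, cvb$V, cs$C, meta$n_total)),
                 tolerance = 1e-10)
  }
})

test_that("Rademacher replicates are sign-symmetric in the weights", {
  set.seed(74)
  x <- random_ifd(a = 1, d = 4, n = 9, miss = 0.15)
  meta <- design_meta(x)
  rt <- midranks(x)
  cs <- contrast_matrix("time", 1, 4)
  Z <- center_ranks(rt)
  L <- lapply(x$observed, function(o) { storage.mode(o) <- "double"; o })
  W <- list(matrix(draw_weights("rademacher", 9), 9, 1))
  a <- wildrank:::boot_stats_cpp(Z, L, W, cs$C, cs$T, rt$N, meta$n_total,
                                 1e-10)
  b <- wildrank:::boot_stats_cpp(Z, L, list(-W[[1]]), cs$C, cs$T, rt$N,
                                 meta$n_total, 1e-10)
  expect_equal(a$stats, b$stats, tolerance = 1e-12)
})

test_that("bootstrap effect replicates center at zero over many draws", {
  set.seed(75)
  x <- random_ifd(a = 1, d = 3, n = 12, miss = 0.2)
  meta <- design_meta(x)
  rt <- midranks(x)
  Z <- center_ranks(rt)
  B <- 4000
  W <- matrix(draw_weights("rademacher", 12 * B), 12, B)
  pbar <- rowMeans(vapply(seq_len(B), function(b) {
    bootstrap_effects(list(Z[[1]] * W[, b]), x$observed, rt$N)
  }, numeric(3)))
  expect_true(all(abs(pbar) < 4 / sqrt(B)))  # ~1/sqrt(B) rate
})

test_that("bootstrap p-values are reproducible, permutation- and monotone-stable", {
  set.seed(76)
  x <- random_ifd(a = 2, d = 3, n = c(8, 7), miss = 0.2)
  r1 <- rank_test(x, "interaction", B = 199, seed = 99)
  r2 <- rank_test(x, "interaction", B = 199, seed = 99)
  p1 <- vapply(r1$results, `[[`, 0, "p_bootstrap")
  expect_identical(p1, vapply(r2$results, `[[`, 0, "p_bootstrap"))

  # permuting subjects within groups leaves the p-values unchanged
  perm <- lapply(x$n, sample)
  xp <- ifd(lapply(seq_len(x$a),
                   function(i) x$values[[i]][perm[[i]], , drop = FALSE]))
  rp <- rank_test(xp, "interaction", B = 199, seed = 99)
  expect_identical(p1, vapply(rp$results, `[[`, 0, "p_bootstrap"))

  # strictly increasing transform leaves the p-values unchanged
  xm <- ifd(lapply(x$values, exp))
  rm_ <- rank_test(xm, "interaction", B = 199, seed = 99)
  expect_identical(p1, vapply(rm_$results, `[[`, 0, "p_bootstrap"))

  # B = 1 forces p into {0, 1}
  rb1 <- rank_test(x, "interaction", B = 1, seed = 5)
  expect_true(all(vapply(rb1$results, `[[`, 0, "p_bootstrap") %in% c(0, 1)))
})

test_that("degenerate ATS replicates are counted and scored as zero", {
  # a design where ranks barely vary: all-tied group forces tr(T V*) = 0
  x <- ifd(matrix(2, 6, 3))
  rt <- midranks(x)
  meta <- design_meta(x)
  cs <- contrast_matrix("time", 1, 3)
  Z <- center_ranks(rt)
  L <- lapply(x$observed, function(o) { storage.mode(o) <- "double"; o })
  W <- list(matrix(draw_weights("rademacher", 6 * 3), 6, 3))
  out <- wildrank:::boot_stats_cpp(Z, L, W, cs$C, cs$T, rt$N, meta$n_total,
                                   1e-10)
  expect_equal(out$n_degenerate, 3)
  expect_true(all(out$stats[, 2] == 0))
})
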