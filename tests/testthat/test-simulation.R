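test_that("covariance settings reproduce the three dependence patterns", {
  expect_equal(sim_covariance("AR", 2), matrix(c(1, 0.6, 0.6, 1), 2))
  expect_equal(sim_covariance("CS", 3), diag(3))
  expect_equal(sim_covariance("TP", 3),
               matrix(c(3, 2, 1, 2, 3, 2, 1, 2, 3), 3))
})

test_that("copula generator honours marginals and dependence", {
  set.seed(81)
  # identity setting + normal marginal: i.i.d. standard normal coordinates
  x <- generate_continuous(5000, 4, "normal", "CS")
  m <- x$values[[1]]
  expect_lt(max(abs(colMeans(m))), 3 / sqrt(5000))
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 0.05)
  expect_lt(max(abs(cor(m)[upper.tri(diag(4))])), 3 / sqrt(5000))
  # lognormal: positive, median near exp(0) = 1
  y <- generate_continuous(5000, 2, "lognormal", "CS")
  expect_true(all(y$values[[1]] > 0))
  expect_lt(abs(median(y$values[[1]][, 1]) - 1), 3 * 1.2533 / sqrt(5000) * 1)
  # AR setting: lag-1 correlation 0.6 within 3 SE
  z <- generate_continuous(5000, 4, "normal", "AR")
  l1 <- cor(z$values[[1]])[cbind(1:3, 2:4)]
  se <- (1 - 0.6^2) / sqrt(5000)
  expect_true(all(abs(l1 - 0.6) < 3 * se))
})

test_that("copula ranks are invariant to the marginal choice at a fixed seed", {
  rks <- lapply(c("normal", "lognormal", "double_exponential", "chisq15"),
                function(mar) {
    set.seed(82)
    midranks(generate_continuous(40, 3, mar, "AR"))$R
  })
  for (k in 2:4) expect_identical(rks[[k]], rks[[1]])
})

test_that("location shift is added on the final scale for power scenarios", {
  set.seed(83)
  x <- generate_continuous(3000, 4, "normal", "CS", shift = c(0, 0, 2, 2))
  mu <- colMeans(x$values[[1]])
  expect_lt(max(abs(mu - c(0, 0, 2, 2))), 4 / sqrt(3000) * 1.5)
})

test_that("MCAR deletes at rate r and keeps every cell estimable", {
  set.seed(84)
  x <- generate_continuous(2000, 4, "normal", "CS")
  expect_identical(apply_mcar(x, 0), x)  # r = 0 is the identity
  y <- apply_mcar(x, 0.3)
  frac <- mean(unlist(y$observed))
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.3 * 0.7 / 8000))
  expect_true(all(design_meta(y)$lambda_dot >= 2))
  # n_i = 2, d = 1, r = 0.5: only the all-observed mask is valid
  tiny <- ifd(matrix(rnorm(2), 2, 1))
  z <- apply_mcar(tiny, 0.5)
  expect_true(all(unlist(z$observed) == 1))
  expect_gte(attr(z, "mask_tries"), 1)
})

test_that("MAR1 stratifies by +-2 sd of the determining coordinate", {
  set.seed(85)
  # bounded data: everything falls in the middle stratum, target rate 0.30
  vals <- matrix(runif(4000 * 4, -0.5, 0.5), 4000, 4)
  x <- ifd(vals)
  y <- apply_mar1(x)
  miss2 <- mean(y$observed[[1]][, 2] == 0)
  miss4 <- mean(y$observed[[1]][, 4] == 0)
  se <- 3 * sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(miss2 - 0.30), se)
  expect_lt(abs(miss4 - 0.30), se)
  # determining coordinates are never deleted
  expect_true(all(y$observed[[1]][, c(1, 3)] == 1))
  # d = 8: only the four printed targets can go missing; 4 and 5 never do
  set.seed(86)
  w <- apply_mar1(ifd(matrix(rnorm(500 * 8), 500, 8)))
  obs_cols <- colMeans(w$observed[[1]])
  expect_true(all(obs_cols[c(1, 4, 5, 6)] == 1))
  expect_true(all(obs_cols[c(2, 3, 7, 8)] < 1))
  expect_error(apply_mar1(ifd(matrix(rnorm(50 * 3), 50, 3))), "d = 4 or d = 8")
})

test_that("MAR2 stratifies at the median with rates 0.10 and 0.30", {
  set.seed(87)
  x <- ifd(matrix(rnorm(6000 * 4), 6000, 4))
  y <- apply_mar2(x)
  det <- x$values[[1]][, 1]
  lower <- det <= median(det)
  r_low <- mean(y$observed[[1]][lower, 2] == 0)
  r_up <- mean(y$observed[[1]][!lower, 2] == 0)
  expect_lt(abs(r_low - 0.10), 3 * sqrt(0.1 * 0.9 / 3000))
  expect_lt(abs(r_up - 0.30), 3 * sqrt(0.3 * 0.7 / 3000))
  # overall rate for symmetric data is the average, 0.20
  expect_lt(abs(mean(y$observed[[1]][, 2] == 0) - 0.20),
            3 * sqrt(0.2 * 0.8 / 6000))
  # constant determining coordinate: everyone in stratum one, rate 0.10
  set.seed(88)
  z <- apply_mar2(ifd(cbind(rep(1, 5000), matrix(rnorm(15000), 5000, 3))))
  expect_lt(abs(mean(z$observed[[1]][, 2] == 0) - 0.10),
            3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("ordinal generator: support, marginal mass and within-subject dependence", {
  set.seed(89)
  x <- generate_ordinal(20000, 2, c_dep = 1)
  v <- x$values[[1]]
  expect_true(all(v %in% 1:4))
  # triangular latent marginal: P(X = 1) = P((Z+Y)/2 < 1/4) = 1/8
  expect_lt(abs(mean(v[, 1] == 1) - 1 / 8), 3 * sqrt(1 / 8 * 7 / 8 / 20000))
  # shared subject effect induces positive correlation between time points
  expect_gt(cor(v[, 1], v[, 2]), 0.2)
})

test_that("simulation studies are seed-reproducible with sane shapes", {
  cfg <- scenario(a = 1, d = 4, n = 10, missing = "MCAR", r = 0.1,
                  nsim = 8, B = 59, seed = 42)
  t1 <- run_type1_study(cfg)
  t2 <- run_type1_study(cfg)
  expect_identical(t1, t2)
  expect_setequal(t1$method, c("wts_asym", "ats_asym", "wts_boot",
                               "ats_boot", "mats_boot"))
  expect_true(all(t1$rate >= 0 & t1$rate <= 100))
  one <- run_type1_study(scenario(nsim = 1, B = 19, seed = 1))
  expect_true(all(one$rate %in% c(0, 100)))
  expect_error(scenario(nsim = 0), "nsim")
})

test_that("power grows with the shift and is near 100 at the largest shift", {
  cfg <- scenario(a = 1, d = 4, n = 15, marginal = "normal",
                  cov_setting = "CS", missing = "MCAR", r = 0.1,
                  nsim = 60, B = 119, seed = 7)
  pw <- run_power_study(cfg, zeta = c(0, 1, 3))
  ats_pw <- pw$rate[pw$method == "ats_boot"]
  expect_lt(ats_pw[1], 20)           # near the nominal level at zeta = 0
  expect_gt(ats_pw[3], 85)           # strong alternative detected
  expect_gte(ats_pw[3] + 7.5, ats_pw[2])  # monotone up to MC noise
  expect_gte(ats_pw[2] + 7.5, ats_pw[1])
})
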