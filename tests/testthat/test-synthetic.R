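test_that("the three-component design matches its printed parameters", {
  th <- design_a_params()
  expect_equal(th$k, 3)
  expect_equal(th$p, 3)
  expect_equal(unname(th$means),
               rbind(c(0, 0, 0), c(2, 6, 0), c(6, 0, 0)))
  expect_equal(th$sigmas[[1]], diag(c(2, 2, 100)), ignore_attr = TRUE)
  expect_equal(th$sigmas[[2]], diag(c(3, 1, 100)), ignore_attr = TRUE)
  expect_equal(th$sigmas[[3]], diag(c(1, 2, 100)), ignore_attr = TRUE)
  expect_equal(th$weights, c(50, 20, 20) / 90)
  th4 <- design_a_params(higher_p = TRUE)
  expect_equal(th4$p, 4)
  expect_equal(th4$sigmas[[2]], diag(c(3, 1, 100, 100)), ignore_attr = TRUE)

  d <- sim_design_a(seed = 1)
  expect_equal(dim(d), c(90L, 4L)) # 3 features + component
  expect_equal(tabulate(d$component), c(50, 20, 20))
  expect_equal(nrow(sim_design_a(higher_n = TRUE, seed = 1)), 180)
  expect_equal(ncol(sim_design_a(higher_p = TRUE, seed = 1)), 5)
})

test_that("the six-component design matches its printed parameters", {
  th <- design_b_params()
  expect_equal(th$k, 6)
  expect_equal(unname(th$means[, 1:2]),
               rbind(c(-4.5, 3.6), c(0.40, 3.6), c(-4.4, -1),
                     c(9.2, -1), c(0.4, -1), c(9.2, 3.6)))
  # same spherical in-plane scatter for every component
  for (j in 2:6) expect_equal(th$sigmas[[j]], th$sigmas[[1]])
  expect_equal(th$sigmas[[1]][1:2, 1:2], diag(2), ignore_attr = TRUE)
  d <- sim_design_b(seed = 2)
  expect_equal(nrow(d), 325) # 23 + 36 + 93 + 38 + 123 + 12
  expect_equal(ncol(d), 4)
  expect_equal(tabulate(d$component), c(23, 36, 93, 38, 123, 12))
})

test_that("mixture sampling hits exact sizes and the right moments", {
  th <- design_a_params()
  d <- sample_mixture(th, sizes = c(5, 0, 2), seed = 3)
  expect_equal(nrow(d), 7)
  expect_equal(tabulate(d$component, 3), c(5, 0, 2))
  # moment check: empirical mean and covariance of a large draw within 3
  # standard errors of the target
  big <- sample_mixture(th, sizes = c(1e5, 0, 0), seed = 4)
  X <- as.matrix(big[1:3])
  se_mean <- sqrt(diag(th$sigmas[[1]]) / 1e5)
  expect_true(all(abs(colMeans(X) - th$means[1, ]) < 3 * se_mean))
  expect_true(all(abs(cov(X) - th$sigmas[[1]]) <
                    3 * 100 / sqrt(1e5) + 0.05))
  # seeded reproducibility
  expect_identical(sample_mixture(th, n = 20, seed = 5),
                   sample_mixture(th, n = 20, seed = 5))
})

test_that("adjusted Rand index matches pair counting and survives relabels", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  # contingency table [[2,1],[1,2]]
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), ari_pairs_oracle(a, b))
  # single-cluster degenerate pairs
  expect_equal(adjusted_rand_index(c(1, 1), c(2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 1, 2)), 0)

  set.seed(81)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    a <- sample(1:3, n, TRUE)
    b <- sample(1:3, n, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pairs_oracle(a, b),
                 info = paste(a, collapse = ""), tolerance = 1e-12)
  }
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(82)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    a <- sample(1:4, n, TRUE)
    b <- sample(1:5, n, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("overlap estimates match the one-dimensional closed form", {
  z <- 1.959964
  th <- mixture_params(c(.5, .5), rbind(0, 2 * z),
                       list(matrix(1), matrix(1)))
  ov <- pairwise_overlap(th, draws = 1e5, seed = 9)
  # each directed probability is the standard normal tail beyond z (0.025)
  se <- 3 * sqrt(0.025 * 0.975 / 1e5)
  expect_lt(abs(ov$w[2, 1] - 0.025), se)
  expect_lt(abs(ov$w[1, 2] - 0.025), se)
  expect_lt(abs(ov$average - 0.05), 2 * se)
})

test_that("overlap vanishes for far-separated components and is monotone", {
  S <- diag(2)
  far <- mixture_params(c(.5, .5), rbind(c(0, 0), c(2000, 0)),
                        list(S, S))
  expect_lte(pairwise_overlap(far, draws = 1e4, seed = 1)$average, 1e-4)
  seps <- c(1, 2, 4, 8)
  avs <- vapply(seps, function(s) {
    th <- mixture_params(c(.5, .5), rbind(c(0, 0), c(s, 0)), list(S, S))
    pairwise_overlap(th, draws = 2e4, seed = 2)$average
  }, numeric(1))
  expect_true(all(diff(avs) < 0))
})

test_that("the overlap-controlled generator hits its target pattern and rate", {
  set.seed(83)
  for (case in list(list(model = "VVI", p = 3), list(model = "EEE", p = 4))) {
    th <- sim_overlap_mixture(k = 3, p = case$p, model = case$model,
                              overlap = 0.05, calib_draws = 2e4)
    lmods <- limit_models()
    row <- lmods[lmods$code == case$model, ]
    fin <- function(v, s) if (is.infinite(v)) s else v
    sp <- constraint_spec(fin(row$c_det, 100), fin(row$c_shw, 100),
                          min(fin(row$c_shb, 10),
                              shb_bound(fin(row$c_shw, 100), case$p)),
                          row$rot)
    expect_true(check_constraints(th, sp, tol = 1e-6)$satisfied)
    expect_equal(th$weights, rep(1 / 3, 3))
    ov <- pairwise_overlap(th, draws = 1e5)
    expect_lt(abs(ov$average - 0.05), 0.006) # calibration + MC tolerance
  }
})
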