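test_that("single unconstrained component recovers the sample MLE", {
  set.seed(61)
  X <- matrix(rnorm(80, sd = 2), 40, 2)
  fit <- parsmix(X, k = 1, control = parsmix_control(nstart = 2), seed = 1)
  expect_equal(as.numeric(fit$params$means), colMeans(X), tolerance = 1e-6)
  expect_equal(fit$params$sigmas[[1]], cov(X) * 39 / 40, tolerance = 1e-5)
  expect_equal(fit$loglik, mixture_loglik(X, fit$params), tolerance = 1e-10)
})

test_that("fits are reproducible under a seed and order-independent", {
  d <- sim_design_a(seed = 3)
  f1 <- parsmix(d[1:3], k = 2, c_det = 4, c_shw = 16, c_shb = 2,
                control = parsmix_control(nstart = 5), seed = 42)
  f2 <- parsmix(d[1:3], k = 2, c_det = 4, c_shw = 16, c_shb = 2,
                control = parsmix_control(nstart = 5), seed = 42)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$start_targets, f2$start_targets)
})

test_that("initialisation is seeded and ridges collinear draws", {
  X <- matrix(rnorm(60), 30, 2)
  set.seed(7); i1 <- init_params(X, 3)
  set.seed(7); i2 <- init_params(X, 3)
  expect_identical(i1$means, i2$means)
  expect_equal(i1$weights, rep(1 / 3, 3))
  # collinear data: every group covariance is singular, the ridge keeps the
  # initial parameters valid and a fit still proceeds
  Xc <- cbind(seq_len(30), 2 * seq_len(30)) + matrix(rnorm(60, sd = 1e-9), 30)
  expect_warning(ic <- init_params(Xc, 2), "ridge")
  expect_true(all(vapply(ic$sigmas, function(S) min(eigen(S)$values) > 0,
                         logical(1))))
  fit <- suppressWarnings(
    parsmix(Xc, k = 2, c_det = 4, c_shw = 4, c_shb = 2,
            control = parsmix_control(nstart = 3), seed = 1)
  )
  expect_true(is.finite(fit$loglik))
})

test_that("EM target is non-decreasing along the best run", {
  set.seed(62)
  for (i in 1:5) {
    th <- rmix(2, 2, sep = 3)
    X <- as.matrix(sample_mixture(th, n = 60)[, 1:2])
    fit <- parsmix(X, k = 2, c_det = 8, c_shw = 8, c_shb = 2,
                   control = parsmix_control(nstart = 3), seed = i)
    tr <- fit$trace[-1] # from the first constrained iterate on
    expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-1]))))
  }
})

test_that("every fit satisfies its constraint specification", {
  set.seed(63)
  d <- sim_design_a(seed = 9)
  for (sp in list(constraint_spec(1, 1, 1, "I"),
                  constraint_spec(2, 100, 2, "V"),
                  constraint_spec(4, 8, 2, "E"))) {
    fit <- parsmix(d[1:3], k = 3, spec = sp,
                   control = parsmix_control(nstart = 5), seed = 5)
    expect_true(fit$constraints$satisfied)
  }
})

test_that("hard-assignment fits are locally optimal under reassignment", {
  set.seed(64)
  d <- sim_design_a(seed = 2)
  fit <- parsmix(d[1:3], k = 3, c_det = 2, c_shw = 100, c_shb = 2,
                 mode = "cem", control = parsmix_control(nstart = 10),
                 seed = 11)
  # the returned labels are the argmax labels of the returned parameters:
  # no single-point reassignment can improve the classification likelihood
  es <- e_step(d[1:3], fit$params, mode = "cem")
  expect_equal(fit$labels, es$labels)
  expect_equal(fit$loglik,
               classification_loglik(d[1:3], fit$params, fit$labels),
               tolerance = 1e-10)
})

test_that("spherical CEM at unit constants is a constrained k-means", {
  set.seed(65)
  th <- mixture_params(rep(1 / 3, 3), rbind(c(0, 0), c(8, 0), c(0, 8)),
                       rep(list(diag(2)), 3))
  d <- sample_mixture(th, sizes = c(30, 25, 25), seed = 4)
  fit <- parsmix(d[1:2], k = 3, spec = constraint_spec(1, 1, 1, "I"),
                 mode = "cem", control = parsmix_control(nstart = 20),
                 seed = 3)
  # equal spherical covariances
  expect_equal(fit$params$sigmas[[1]], fit$params$sigmas[[3]],
               tolerance = 1e-8)
  expect_equal(fit$params$shape[, 1], rep(1, 2), tolerance = 1e-8)
  expect_true(fit$constraints$satisfied)
  expect_gte(fit$n_starts_ok, 1)
})

test_that("degenerate starts abort with a clear error", {
  # two identical points cannot support an unconstrained two-component fit
  X <- matrix(c(0, 0, 0, 0), 2, 2)
  expect_error(
    suppressWarnings(parsmix(X, k = 2, control = parsmix_control(nstart = 3),
                             seed = 1)),
    "degenerate"
  )
})

test_that("tidy accessors expose the fitted structure", {
  d <- sim_design_a(seed = 5)
  fit <- parsmix(d[1:3], k = 3, c_det = 2, c_shw = 100, c_shb = 2,
                 control = parsmix_control(nstart = 5), seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  expect_equal(sum(td$size), 90)
  expect_named(td, c("component", "weight", "size", "volume", "shape_ratio",
                     paste0("mean_", c("x1", "x2", "x3"))))
  g <- glance(fit)
  expect_equal(g$bic, -2 * fit$loglik + fit$penalty * log(90))
  au <- augment(fit)
  expect_equal(nrow(au), 90)
  expect_true(all(au$.uncertainty >= 0 & au$.uncertainty <= 1))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the achieved target grows with the constraint constants", {
  # nesting of the feasible sets: on common starts, relaxing every constant
  # can only raise the best achievable target likelihood
  d <- sim_design_a(seed = 12)
  targets <- vapply(c(1, 2, 4, 8, 16), function(cc) {
    parsmix(d[1:3], k = 3,
            spec = constraint_spec(cc, cc, min(cc, shb_bound(cc, 3)), "V"),
            control = parsmix_control(nstart = 8), seed = 99)$loglik
  }, numeric(1))
  expect_true(all(diff(targets) >= -1e-6 * (1 + abs(targets[-1]))))
})

test_that("true-ratio constraints beat the near-unconstrained fit on ARI", {
  # paired-run comparison on the noisy three-component design: constants
  # set to the generating model's own ratios against the practically
  # unconstrained surrogate 1e10, identical starts
  th0 <- design_a_params()
  r0 <- check_constraints(th0, constraint_spec())
  spC <- constraint_spec(r0$deter_ratio, max(r0$shw_ratios),
                         max(r0$shb_ratios), "V")
  spU <- constraint_spec(1e10, 1e10, shb_bound(1e10, 3), "V")
  diffs <- vapply(1:4, function(s) {
    d <- sim_design_a(seed = 200 + s)
    fc <- parsmix(d[1:3], k = 3, spec = spC,
                  control = parsmix_control(nstart = 30), seed = s)
    fu <- parsmix(d[1:3], k = 3, spec = spU,
                  control = parsmix_control(nstart = 30), seed = s)
    adjusted_rand_index(fc$labels, d$component) -
      adjusted_rand_index(fu$labels, d$component)
  }, numeric(1))
  expect_gt(mean(diffs), 0.1)
})
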