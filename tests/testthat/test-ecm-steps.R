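test_that("identical components give uniform soft weights and first-index ties", {
  S <- diag(2)
  th <- mixture_params(c(.5, .5), rbind(c(0, 0), c(0, 0)), list(S, S))
  X <- matrix(rnorm(10), 5, 2)
  es <- e_step(X, th, mode = "em")
  expect_equal(es$tau, matrix(0.5, 5, 2))
  hard <- e_step(X, th, mode = "cem")
  expect_equal(hard$labels, rep(1L, 5)) # exact tie: lowest index wins
  expect_equal(rowSums(hard$tau), rep(1, 5))
})

test_that("soft rows sum to one and hard labels equal the soft argmax", {
  set.seed(41)
  for (i in 1:10) {
    th <- rmix(3, 3)
    X <- matrix(rnorm(60, sd = 4), 20, 3)
    es <- e_step(X, th, "em")
    expect_equal(rowSums(es$tau), rep(1, 20), tolerance = 1e-12)
    expect_equal(e_step(X, th, "cem")$labels,
                 apply(es$tau, 1L, which.max))
  }
})

test_that("moment updates reproduce closed-form group statistics", {
  set.seed(42)
  X <- matrix(rnorm(40), 20, 2)
  # single component: mean and covariance with denominator n
  mm <- m_step_moments(X, matrix(1, 20, 1))
  expect_equal(as.numeric(mm$mu), colMeans(X))
  expect_equal(mm$S[[1]], cov(X) * 19 / 20)
  # hard labels: per-group statistics
  lab <- rep(1:2, each = 10)
  tau <- cbind(lab == 1, lab == 2) * 1
  mm2 <- m_step_moments(X, tau)
  expect_equal(as.numeric(mm2$mu[2, ]), colMeans(X[11:20, ]))
  expect_equal(mm2$S[[2]], cov(X[11:20, ]) * 9 / 10)
  # equal weights across components: every mean is the global mean
  mm3 <- m_step_moments(X, matrix(0.5, 20, 2))
  expect_equal(mm3$mu[1, ], mm3$mu[2, ])
  expect_equal(as.numeric(mm3$mu[1, ]), colMeans(X))
})

test_that("spherical constraint collapses every shape to the identity", {
  set.seed(43)
  mm <- rmoments(30, 4, 3)
  D <- update_shapes(mm$S, mm$n_j, d = rep(1, 3),
                     R = replicate(3, diag(4), simplify = FALSE),
                     spec = constraint_spec(1, 1, 1, rot = "I"))
  expect_equal(D, matrix(1, 4, 3), tolerance = 1e-12)
})

test_that("common-shape limit is the weighted mean of scaled diagonals", {
  set.seed(44)
  mm <- rmoments(40, 3, 3)
  d <- vapply(mm$S, function(S) det(S)^(1 / 3), numeric(1))
  D <- update_shapes(mm$S, mm$n_j, d = d,
                     R = replicate(3, diag(3), simplify = FALSE),
                     spec = constraint_spec(Inf, Inf, 1, rot = "I"),
                     iter_max = 200, tol = 1e-14)
  raw <- vapply(seq_len(3), function(j) diag(mm$S[[j]]) / d[j], numeric(3))
  m <- as.numeric(raw %*% mm$n_j) / sum(mm$n_j)
  oracle <- m / prod(m)^(1 / 3)
  expect_equal(D[, 1], oracle, tolerance = 1e-10)
  expect_equal(D[, 2], D[, 1]) # common shape
})

test_that("shape updates keep unit determinants and respect both constraints", {
  set.seed(45)
  for (i in 1:15) {
    p <- sample(2:5, 1)
    k <- sample(2:4, 1)
    mm <- rmoments(10 * k, p, k)
    cw <- exp(runif(1, 0, 4))
    cb <- runif(1, 1, shb_bound(cw, p))
    rot <- sample(c("I", "V"), 1)
    sp <- constraint_spec(Inf, cw, cb, rot)
    R <- if (rot == "V") {
      lapply(mm$S, function(S) eigen(S, symmetric = TRUE)$vectors)
    } else {
      replicate(k, diag(p), simplify = FALSE)
    }
    D <- update_shapes(mm$S, mm$n_j, d = rep(1, k), R = R, spec = sp,
                       iter_max = 100, tol = 1e-12)
    expect_equal(apply(D, 2, prod), rep(1, k), tolerance = 1e-9)
    expect_true(all(apply(D, 2, function(g) max(g) / min(g)) <=
                      cw * (1 + 1e-8)))
    Ds <- if (rot == "V") apply(D, 2, sort, decreasing = TRUE) else D
    expect_true(all(apply(Ds, 1, function(g) max(g) / min(g)) <=
                      cb * (1 + 1e-6)))
  }
})

test_that("volume updates follow the truncated trace formula", {
  set.seed(46)
  mm <- rmoments(30, 2, 3)
  Rl <- replicate(3, diag(2), simplify = FALSE)
  D <- matrix(1, 2, 3)
  nu <- vapply(mm$S, function(S) sum(diag(S)) / 2, numeric(1))
  # c_det = 1: common volume, the weighted mean of the nu_j
  d1 <- update_volumes(mm$S, mm$n_j, D, Rl, c_det = 1)
  expect_equal(d1, rep(sum(mm$n_j * nu) / sum(mm$n_j), 3), tolerance = 1e-12)
  # already feasible: unchanged
  dInf <- update_volumes(mm$S, mm$n_j, D, Rl, c_det = Inf)
  expect_equal(dInf, nu, tolerance = 1e-12)
  # k = 1 with identity shape and rotation: trace / p on a fixed matrix
  S0 <- matrix(c(4, 1, 1, 2), 2)
  expect_equal(update_volumes(list(S0), 7, matrix(1, 2, 1), list(diag(2)),
                              Inf), 3)
  # determinant ratio bound holds after truncation
  d4 <- update_volumes(mm$S, mm$n_j, D, Rl, c_det = 1.5)
  expect_lte(max(d4)^2 / min(d4)^2, 1.5 * (1 + 1e-10))
})

test_that("the common-rotation update solves the aligned eigen problem", {
  set.seed(47)
  p <- 3
  S <- rspd(p)
  ev <- eigen(S, symmetric = TRUE)
  # k = 1, spherical shape: every rotation is optimal, objective = trace/d
  res <- update_rotation_common(list(S), 5, d = 2, D = matrix(1, p, 1),
                                R_init = diag(p), iter_max = 50, tol = 1e-10)
  g <- function(R, D, d, Sl, nj) {
    sum(vapply(seq_along(Sl), function(j) {
      nj[j] / (sum(nj) * d[j]) * sum(diag(t(R) %*% Sl[[j]] %*% R) / D[, j])
    }, numeric(1)))
  }
  expect_equal(g(res$R, matrix(1, p, 1), 2, list(S), 5),
               sum(diag(S)) / 2, tolerance = 1e-10)
  # identical components with a decreasing shape: eigenvectors of S are a
  # fixed point, and a perturbed start comes back to the same objective
  D2 <- matrix(ev$values / prod(ev$values)^(1 / p), p, 2)
  d2 <- rep(prod(ev$values)^(1 / p), 2)
  fp <- update_rotation_common(list(S, S), c(4, 6), d2, D2, ev$vectors,
                               iter_max = 100, tol = 1e-12)
  expect_lt(rotation_change(ev$vectors, fp$R), 1e-10)
  th <- 0.3
  P <- diag(p)
  P[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pert <- update_rotation_common(list(S, S), c(4, 6), d2, D2,
                                 ev$vectors %*% P, iter_max = 500,
                                 tol = 1e-14)
  expect_equal(g(pert$R, D2, d2, list(S, S), c(4, 6)),
               g(ev$vectors, D2, d2, list(S, S), c(4, 6)), tolerance = 1e-8)
})

test_that("rotation iterations never worsen the complete-data objective", {
  set.seed(48)
  g <- function(R, D, d, Sl, nj) {
    sum(vapply(seq_along(Sl), function(j) {
      nj[j] / (sum(nj) * d[j]) * sum(diag(t(R) %*% Sl[[j]] %*% R) / D[, j])
    }, numeric(1)))
  }
  for (i in 1:30) {
    p <- sample(2:4, 1)
    k <- sample(1:3, 1)
    Sl <- replicate(k, rspd(p), simplify = FALSE)
    nj <- runif(k, 1, 10)
    d <- exp(runif(k, -1, 1))
    D <- vapply(seq_len(k), function(j) rshape(p, 20), numeric(p))
    D <- matrix(D, p, k)
    R0 <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
    res <- update_rotation_common(Sl, nj, d, D, R0, iter_max = 100,
                                  tol = 1e-12)
    expect_lte(g(res$R, D, d, Sl, nj), g(R0, D, d, Sl, nj) + 1e-10)
  }
})

test_that("unconstrained scatter update returns the weighted covariances", {
  set.seed(49)
  mm <- rmoments(40, 3, 2)
  res <- update_scatters(mm$S, mm$n_j, constraint_spec(Inf, Inf, Inf, "V"))
  for (j in 1:2) expect_equal(res$Sigma[[j]], mm$S[[j]], tolerance = 1e-10)
})

test_that("fully constrained axis-aligned update pools to a spherical fit", {
  set.seed(50)
  mm <- rmoments(40, 3, 2)
  res <- update_scatters(mm$S, mm$n_j, constraint_spec(1, 1, 1, "I"),
                         strict_control())
  s2 <- sum(mm$n_j * vapply(mm$S, function(S) sum(diag(S)), numeric(1))) /
    (sum(mm$n_j) * 3)
  for (j in 1:2) expect_equal(res$Sigma[[j]], s2 * diag(3), tolerance = 1e-10)
})

test_that("scatter updates satisfy an arbitrary specification", {
  set.seed(51)
  for (i in 1:10) {
    p <- sample(2:4, 1)
    k <- sample(2:4, 1)
    mm <- rmoments(12 * k, p, k)
    cw <- exp(runif(1, 0, 4))
    sp <- constraint_spec(exp(runif(1, 0, 3)), cw,
                          runif(1, 1, shb_bound(cw, p)),
                          sample(c("I", "E", "V"), 1))
    res <- update_scatters(mm$S, mm$n_j, sp, parsmix_control())
    th <- mixture_params(mm$n_j / sum(mm$n_j), matrix(0, k, p), res$Sigma,
                         rot = sp$rot)
    expect_true(check_constraints(th, sp, tol = 1e-5)$satisfied)
  }
})

test_that("relative change monitors behave as documented", {
  expect_equal(relative_change(c(1, 2), c(1, 2)), 0)
  expect_equal(relative_change(list(c(1, 0), c(0, 2)),
                               list(c(1, 0), c(0, 1))), 0.5)
  expect_equal(relative_change(0, 1), Inf)
  expect_equal(rotation_change(diag(3), diag(3)), 0)
  # 2-D rotation by pi/2 against the identity: direct formula evaluation
  a <- pi / 2
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  direct <- abs(2 - sum(diag(t(t(R) %*% diag(2)) %*% (R %*% t(diag(2)))))) / 2
  expect_equal(rotation_change(diag(2), R), direct)
  expect_equal(direct, 2) # trace(R^2) = -2 at a quarter turn
})
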