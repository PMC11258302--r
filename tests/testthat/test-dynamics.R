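test_that("expression profile evaluates the sine model", {
  p <- dyn_params(W = 1, alpha = 1, beta = 0, theta = 0, gamma = 1)
  expect_equal(profile_y(0.25, p), 1.0)
  p2 <- dyn_params(W = 1, alpha = 2, beta = 5, theta = 0, gamma = 1)
  expect_equal(profile_y(0, p2), 5.0)
  p3 <- dyn_params(W = 1, alpha = 1.3, beta = 0.2, theta = 0.4, gamma = 1)
  expect_equal(profile_y(0.1, p3), 1.3 * sin(0.2 * pi + 0.4) + 0.2)
})

test_that("drive profile solves the kinetic equation analytically", {
  set.seed(1)
  tg <- seq(0, 0.99, length.out = 100)
  for (i in 1:100) {
    p <- random_params()
    # WX(t) must equal dy/dt + gamma * y identically
    dydt <- 2 * pi * p$alpha * cos(2 * pi * tg + p$theta)
    expect_lt(max(abs(profile_wx(tg, p) - (dydt + p$gamma * profile_y(tg, p)))),
              1e-10)
  }
  # gamma -> 0+ limit: phase offset -> pi/2, drive -> derivative of y
  p <- dyn_params(W = 1, alpha = 1.4, beta = 0.3, theta = 0.5, gamma = 1e-9)
  expect_equal(profile_wx(tg, p),
               2 * pi * 1.4 * cos(2 * pi * tg + 0.5), tolerance = 1e-6)
  # hand-evaluated point: alpha=1, beta=0, gamma=2*pi, theta=0, t=0
  p <- dyn_params(W = 1, alpha = 1, beta = 0, theta = 0, gamma = 2 * pi)
  expect_equal(profile_wx(0, p), sqrt(8 * pi^2) * sin(pi / 4))
  expect_equal(profile_wx(0, p), 2 * pi)
})

test_that("latent-time assignment finds the nearest curve point", {
  set.seed(2)
  p <- random_params(1)
  p$W <- 1.5
  grid <- 200
  # a cell placed exactly on the curve at a grid time is assigned that time
  t0 <- 37 / grid
  pr <- list(X = matrix(profile_wx(t0, p) / 1.5, 1, 1), y = profile_y(t0, p))
  class(pr) <- "gene_problem"
  expect_equal(assign_latent_time(pr, p, grid = grid), t0)

  # brute-force oracle on a 10x finer grid (cells nearly equidistant
  # between the two branches of the curve may legitimately jump branch;
  # there the achieved distances must agree instead)
  for (rep in 1:5) {
    p <- random_params(1)
    p$W <- 1.5
    n <- 40
    wx <- runif(n, -3, 3); y <- runif(n, -2, 2)
    pr <- list(X = matrix(wx / 1.5, 1, n), y = y)
    class(pr) <- "gene_problem"
    t_coarse <- assign_latent_time(pr, p, grid = 100)
    tf_grid <- (0:999) / 1000
    wx_f <- profile_wx(tf_grid, p); y_f <- profile_y(tf_grid, p)
    d2_fine <- vapply(seq_len(n), function(c_)
      min((wx[c_] - wx_f)^2 + (y[c_] - y_f)^2), numeric(1))
    t_fine <- vapply(seq_len(n), function(c_) {
      tf_grid[which.min((wx[c_] - wx_f)^2 + (y[c_] - y_f)^2)]
    }, numeric(1))
    d2_coarse <- (wx - profile_wx(t_coarse, p))^2 +
      (y - profile_y(t_coarse, p))^2
    d <- pmin(abs(t_coarse - t_fine), 1 - abs(t_coarse - t_fine))
    pts <- cbind(wx_f, y_f)
    hop <- 10 * max(sqrt(rowSums((pts[-1, ] - pts[-1000, ])^2)))
    slack <- hop^2 + 2 * sqrt(d2_fine) * hop
    expect_true(all(d <= 1 / 100 + 1e-12 | d2_coarse <= d2_fine + slack))
  }

  # identical cells get identical times
  p <- random_params(1)
  pr <- list(X = matrix(c(1, 1) / p$W[1], 1, 2), y = c(0.5, 0.5))
  class(pr) <- "gene_problem"
  expect_equal(diff(assign_latent_time(pr, p)), 0)
})

test_that("phase-plane loss matches its definition and the likelihood", {
  p <- dyn_params(W = 2, alpha = 1, beta = 0.5, theta = 0.3, gamma = 2)
  t <- c(0.1, 0.4, 0.8)
  # cells exactly on the curve: zero loss
  pr <- list(X = matrix(profile_wx(t, p) / 2, 1, 3), y = profile_y(t, p))
  class(pr) <- "gene_problem"
  res <- compute_loss(pr, p, t)
  expect_equal(res$loss, 0)
  # one cell displaced by (1, 1) contributes 2
  pr$X[1, 2] <- pr$X[1, 2] + 0.5          # +1 on the W.X coordinate (W = 2)
  pr$y[2] <- pr$y[2] + 1
  expect_equal(compute_loss(pr, p, t)$loss, 2)
  # residual sign follows the y displacement
  expect_equal(sign(compute_loss(pr, p, t)$residuals), c(0, 1, 0))

  # the negative log-likelihood is -log(1/(sqrt(2 pi) sigma)) + L/(2 sigma^2)
  set.seed(3)
  g <- generate_synthetic_gene(n_cells = 80, n_tfs = 4, noise_sd = 0.1)
  fit <- velotf_fit(g$tf_trajectories, g$y_obs, n_iters = 6)
  expect_equal(as.numeric(logLik(fit)),
               log(1 / (sqrt(2 * pi) * fit$sigma)) -
                 fit$loss / (2 * fit$sigma^2))
})

test_that("bounded weight regression recovers, nulls and clips", {
  p <- dyn_params(W = 1, alpha = 1, beta = 1, theta = 0.2, gamma = 3)
  t <- (0:49) / 50
  # single TF whose trajectory is exactly the drive divided by 3
  pr <- list(X = matrix(profile_wx(t, p) / 3, 1, 50), y = profile_y(t, p))
  class(pr) <- "gene_problem"
  expect_equal(update_weights(pr, p, t), 3, tolerance = 1e-6)

  # near-zero targets give a near-zero weight vector
  p0 <- dyn_params(W = c(1, -1), alpha = 1e-6, beta = 0, theta = 0, gamma = 1)
  pr0 <- list(X = matrix(rnorm(100), 2, 50), y = rep(0, 50))
  class(pr0) <- "gene_problem"
  expect_lt(max(abs(update_weights(pr0, p0, t))), 1e-3)

  # unconstrained optimum at 50 is clipped at the +20 bound
  pr2 <- list(X = matrix(profile_wx(t, p) / 50, 1, 50), y = profile_y(t, p))
  class(pr2) <- "gene_problem"
  expect_equal(update_weights(pr2, p, t), 20)
})

test_that("shape update recovers noiseless parameters and respects bounds", {
  pT <- dyn_params(W = 1, alpha = 1.2, beta = 0.8, theta = 0.5, gamma = 2.5)
  t <- (0:199) / 200
  pr <- list(X = matrix(profile_wx(t, pT), 1, 200), y = profile_y(t, pT))
  class(pr) <- "gene_problem"
  p0 <- pT
  p0$alpha <- pT$alpha * 1.05; p0$beta <- pT$beta * 0.95
  p0$theta <- pT$theta + 0.05; p0$gamma <- pT$gamma * 1.1
  up <- update_shape_params(pr, p0, t)
  expect_equal(up$alpha, pT$alpha, tolerance = 1e-3)
  expect_equal(up$beta, pT$beta, tolerance = 1e-3)
  expect_equal(up$theta, pT$theta, tolerance = 1e-3)
  expect_equal(up$gamma, pT$gamma, tolerance = 1e-3)

  # starting at the optimum does not increase the loss
  l_opt <- compute_loss(pr, pT, t)$loss
  expect_lte(compute_loss(pr, update_shape_params(pr, pT, t), t)$loss,
             l_opt + 1e-9)

  # constraints always hold
  set.seed(4)
  for (i in 1:5) {
    p <- random_params(1)
    prr <- list(X = matrix(rnorm(60), 1, 60), y = rnorm(60))
    class(prr) <- "gene_problem"
    up <- update_shape_params(prr, p, runif(60))
    expect_gt(up$alpha, 0)
    expect_gt(up$gamma, 0)
    expect_true(up$theta > -pi && up$theta < pi)
  }
})

test_that("initialization follows rank correlation and the y range", {
  t <- seq(0.02, 0.98, length.out = 50)
  y <- 1.5 + sin(2 * pi * t * 0.4)                 # monotone piece
  X <- rbind(y * 2 + 1, 3 - y)                     # one aligned, one opposed
  pr <- structure(list(X = X, y = y), class = "gene_problem")
  inits <- init_parameters(pr, n_theta_starts = 4)
  expect_length(inits, 4)
  expect_equal(inits[[1]]$W, c(1, -1))
  # theta starts evenly spaced in (-pi, pi)
  expect_equal(vapply(inits, `[[`, numeric(1), "theta"),
               c(-3, -1, 1, 3) * pi / 4)

  y2 <- c(0.5, 1.3, 2.5, 1.1, 0.7)
  pr2 <- structure(list(X = matrix(y2, 1), y = y2), class = "gene_problem")
  i2 <- init_parameters(pr2, n_theta_starts = 1)[[1]]
  expect_equal(i2$alpha, 1.0)
  expect_equal(i2$beta, 1.5)
  expect_gt(i2$gamma, 0)
})

test_that("weight normalization scales by influence and selects strictly", {
  nw <- normalize_weights(c(2, -4, 1), c(1, 1, 1))
  expect_equal(nw$normalized, c(0.5, -1, 0.25))
  expect_equal(nw$selected, 2L)                    # 0.5 is not > 0.5
  expect_equal(max(abs(nw$normalized)), 1)

  expect_equal(abs(normalize_weights(-3, 2)$normalized), 1)
  # scaling all expressions by 10 leaves normalized weights unchanged
  nw10 <- normalize_weights(c(2, -4, 1), c(10, 10, 10))
  expect_equal(nw10$normalized, nw$normalized)

  expect_error(normalize_weights(c(0, 0), c(1, 1)), "undefined")
})
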