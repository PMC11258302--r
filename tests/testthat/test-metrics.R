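test_that("intra-class distance measures spread around type centroids", {
  # every cell at its class centroid
  pp <- phase_points(x = c(1, 1, 4, 4), y = c(2, 2, 0, 0),
                     labels = c("a", "a", "b", "b"))
  expect_equal(intra_class_distance(pp), 0)

  # one class, two cells: hand arithmetic on the stated formula
  x <- c(0, 2); y <- c(0, 1)
  pp2 <- phase_points(x, y, labels = c("a", "a"))
  manual <- sum(((x - mean(x)) / sd(x))^2 + ((y - mean(y)) / sd(y))^2)
  expect_equal(intra_class_distance(pp2), manual)

  # invariant to separate affine rescaling of the axes
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30); lb <- rep(c("a", "b", "c"), 10)
  v1 <- intra_class_distance(phase_points(x, y, lb))
  v2 <- intra_class_distance(phase_points(5 * x + 3, -2 * y + 1, lb))
  expect_equal(v1, v2)
})

test_that("inter-class distance sums ordered centroid pairs", {
  # coincident centroids
  pp <- phase_points(x = c(0, 1, 0, 1), y = c(0, 1, 0, 1),
                     labels = c("a", "a", "b", "b"))
  expect_equal(inter_class_distance(pp), 0)

  # two classes, centroids one global-sd apart on x: ordered pairs sum to 2
  s <- sqrt(0.5)                 # within-class spread making sd(x) exactly 1
  x <- c(-0.5 - s, -0.5 + s, 0.5 - s, 0.5 + s)
  pp2 <- phase_points(x, y = c(0, 1, 0, 1), labels = c("a", "a", "b", "b"))
  expect_equal(sd(x), 1)
  expect_equal(inter_class_distance(pp2), 2)

  expect_error(inter_class_distance(
    phase_points(1:3, 1:3, labels = rep("a", 3))), "two cell types")

  set.seed(42)
  x <- rnorm(30); y <- rnorm(30); lb <- rep(c("a", "b"), 15)
  expect_equal(inter_class_distance(phase_points(x, y, lb)),
               inter_class_distance(phase_points(2 * x - 7, 0.1 * y, lb)))
})

test_that("fitting error is the standardized distance to the model", {
  t <- seq(0.05, 0.95, length.out = 40)
  p <- dyn_params(W = 1, alpha = 1, beta = 0, theta = 0.3, gamma = 2)
  wx <- profile_wx(t, p); y <- profile_y(t, p)
  pp <- phase_points(wx, y, labels = rep("a", 40), model_x = wx, model_y = y)
  expect_equal(fitting_error(pp), 0)

  # one cell whose model point sits one global sd away on each axis adds 2
  ppd <- phase_points(wx, y, labels = rep("a", 40),
                      model_x = replace(wx, 7, wx[7] - sd(wx)),
                      model_y = replace(y, 7, y[7] - sd(y)))
  expect_equal(fitting_error(ppd), 2)

  expect_error(fitting_error(phase_points(wx, y, rep("a", 40))),
               "model-curve")

  # agrees with the fitter's loss once coordinates are standardized
  g <- generate_synthetic_gene(n_cells = 120, n_tfs = 4, noise_sd = 0.1,
                               seed = 43)
  fit <- velotf_fit(g$tf_trajectories, g$y_obs, n_iters = 6)
  pr <- fit$problem
  wx_o <- as.vector(crossprod(pr$X, fit$params$W))
  mod <- predict(fit)
  pp3 <- phase_points(wx_o, pr$y, labels = rep("a", fit$n_cells),
                      model_x = mod$wx, model_y = mod$y)
  manual <- sum(((wx_o - mod$wx) / sd(wx_o))^2 + ((pr$y - mod$y) / sd(pr$y))^2)
  expect_equal(fitting_error(pp3), manual)
})

test_that("cross-boundary direction correctness scores transitions", {
  # two adjacent blobs on a line, velocities of blob A point at blob B
  n <- 20
  expr <- cbind(1:20, rep(0, n))
  lab <- rep(c("A", "B"), each = 10)
  nb <- t(vapply(1:n, function(i)
    setdiff(order(abs(expr[, 1] - expr[i, 1])), i)[1:6], integer(6)))
  vel_right <- cbind(rep(1, n), rep(0, n))
  cb <- cross_boundary_direction_correctness(vel_right, expr, lab,
                                             list(c("A", "B")), nb)
  expect_equal(unname(cb["A->B"]), 1)
  cb_rev <- cross_boundary_direction_correctness(-vel_right, expr, lab,
                                                 list(c("A", "B")), nb)
  expect_equal(unname(cb_rev["A->B"]), -1)

  # random velocities average out near zero (blobs in contact so that
  # boundary cells exist)
  set.seed(44)
  n2 <- 100
  expr2 <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
                 matrix(rnorm(100, 1.2, 0.5), 50, 2))
  lab2 <- rep(c("A", "B"), each = 50)
  nb2 <- t(vapply(1:n2, function(i)
    setdiff(order(rowSums((expr2 - matrix(expr2[i, ], n2, 2,
                                          byrow = TRUE))^2)), i)[1:10],
    integer(10)))
  velr <- matrix(rnorm(2 * n2), n2, 2)
  cbr <- cross_boundary_direction_correctness(velr, expr2, lab2,
                                              list(c("A", "B")), nb2)
  expect_lt(abs(cbr["A->B"]), 0.1)

  expect_warning(
    cross_boundary_direction_correctness(velr, expr2, lab2,
                                         list(c("B", "missing")), nb2),
    "no boundary cells")
})

test_that("in-cluster coherence averages same-cluster velocity cosines", {
  n <- 6
  nb <- t(vapply(1:n, function(i) setdiff(1:n, i), integer(n - 1)))
  lab <- rep("k", n)
  # identical velocities
  expect_equal(unname(in_cluster_coherence(matrix(1, n, 2), lab, nb)["k"]), 1)
  # brute-force enumeration over all ordered neighbor pairs (unit vectors,
  # so the cosine is the plain dot product)
  brute <- function(v) {
    s <- 0; cnt <- 0
    for (i in 1:n) for (j in setdiff(1:n, i)) {
      s <- s + sum(v[i, ] * v[j, ]); cnt <- cnt + 1
    }
    s / cnt
  }
  # orthogonal pairs
  v_orth <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_equal(unname(in_cluster_coherence(v_orth, lab, nb)["k"]),
               brute(v_orth))
  # two exactly opposed halves, fully connected
  v_op <- rbind(matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE),
                matrix(rep(c(-1, 0), 3), 3, 2, byrow = TRUE))
  expect_equal(unname(in_cluster_coherence(v_op, lab, nb)["k"]), brute(v_op))
})

test_that("velocity consistency compares each cell to its neighborhood mean", {
  n <- 10
  nb <- t(vapply(1:n, function(i) setdiff(1:n, i)[1:4], integer(4)))
  expect_equal(velocity_consistency(matrix(1, n, 3), nb), rep(1, n))

  v <- matrix(1, n, 2); v[3, ] <- c(-1, -1)
  expect_equal(velocity_consistency(v, nb)[3], -1)

  set.seed(45)
  v50 <- matrix(rnorm(100), 50, 2)
  nb50 <- t(vapply(1:50, function(i) setdiff(sample(50), i)[1:7], integer(7)))
  got <- velocity_consistency(v50, nb50)
  oracle <- vapply(1:50, function(i) {
    m <- colMeans(v50[nb50[i, ], ])
    sum(v50[i, ] * m) / sqrt(sum(v50[i, ]^2) * sum(m^2))
  }, numeric(1))
  expect_equal(got, oracle)
  expect_true(all(got >= -1 & got <= 1))
})
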