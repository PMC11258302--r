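test_that("transition rows are stochastic and follow the velocity cosine", {
  set.seed(31)
  n <- 12
  expr <- cbind(seq_len(n), rep(0, n))             # cells along a line
  vel <- cbind(rep(1, n), rep(0, n))               # all pointing "right"
  nb <- cbind(pmax(seq_len(n) - 1, 1), pmin(seq_len(n) + 1, n))
  nb[1, ] <- c(2, 3); nb[n, ] <- c(n - 2, n - 1)
  T_ <- build_transition_matrix(vel, expr, nb, kernel_scale = 0.1)
  expect_equal(rowSums(T_), rep(1, n))
  expect_true(all(T_ >= 0))
  # mass goes to the right neighbor, not the left one
  for (c_ in 2:(n - 1)) expect_gt(T_[c_, c_ + 1], T_[c_, c_ - 1])
  # zero outside the neighbor graph
  expect_equal(T_[5, 9], 0)

  # equal similarities give a uniform row; zero velocity too
  vel0 <- vel; vel0[4, ] <- 0
  T0 <- build_transition_matrix(vel0, expr, nb)
  expect_equal(T0[4, nb[4, ]], c(0.5, 0.5))

  # 5-cell line against hand-computed kernel weights
  expr5 <- cbind(1:5, rep(0, 5)); vel5 <- cbind(rep(1, 5), rep(0, 5))
  nb5 <- cbind(c(2, 1, 2, 3, 4), c(3, 3, 4, 5, 3))
  T5 <- build_transition_matrix(vel5, expr5, nb5, kernel_scale = 0.1)
  w3 <- exp(c(-1, 1) / 0.1)                        # cell 3: left and right
  expect_equal(T5[3, c(2, 4)], w3 / sum(w3))
})

test_that("roots and ends are stationary states of the walk", {
  # two-state chain with absorbing second state
  T2 <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  re2 <- find_root_end_cells(T2)
  expect_equal(re2$end, 2L)
  expect_equal(re2$root, 1L)

  # 10-cell directed chain: first cell is the root, last the end
  re10 <- find_root_end_cells(chain_T(10))
  expect_equal(re10$root, 1L)
  expect_equal(re10$end, 10L)
})

test_that("pseudotime grows along the walk from the root set", {
  pt4 <- velocity_pseudotime(chain_T(4), roots = 1)
  expect_equal(pt4[1], 0)
  expect_equal(pt4[4], 1)
  expect_true(all(diff(pt4) > 0))

  # branching tree: pseudotime ranks equal breadth-first depth
  n <- 15                                          # balanced binary tree
  T_ <- matrix(0, n, n)
  for (i in 1:7) { T_[i, 2 * i] <- 0.5; T_[i, 2 * i + 1] <- 0.5 }
  for (i in 8:15) T_[i, i] <- 1
  depth <- floor(log2(1:n))
  pt <- velocity_pseudotime(T_, roots = 1)
  for (d in 0:2)
    expect_lt(max(pt[depth == d]), min(pt[depth == d + 1]))

  # permutation equivariance
  set.seed(32)
  Tr <- matrix(runif(49), 7, 7); Tr <- Tr / rowSums(Tr)
  perm <- sample(7)
  pt_a <- velocity_pseudotime(Tr, roots = 2)
  pt_b <- velocity_pseudotime(Tr[perm, perm], roots = which(perm == 2))
  expect_equal(pt_b, pt_a[perm], tolerance = 1e-8)
})

test_that("gene time normalization rotates around the blank arc", {
  # occupied arc [0.3, 0.8): rotated so order is preserved and spans [0,1]
  set.seed(33)
  t1 <- sort(runif(200, 0.3, 0.7999))
  n1 <- normalize_gene_time(t1, n_bins = 50, min_run = 3)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  expect_true(all(diff(n1) >= 0))                  # order preserved

  # times already covering the period: min-max map only
  t2 <- (0:199) / 200
  n2 <- normalize_gene_time(t2)
  expect_equal(n2, t2 / max(t2))

  # two arcs around the wrap point: the late arc comes first
  t3 <- c(runif(80, 0, 0.2), runif(80, 0.7, 0.999))
  n3 <- normalize_gene_time(t3, n_bins = 50, min_run = 3)
  expect_lt(max(n3[81:160]), min(n3[1:80]))
})

test_that("stream genes need low loss and pseudotime-aligned latent time", {
  n_cells <- 60
  pt <- (seq_len(n_cells) - 1) / (n_cells - 1)
  mk_fit <- function(t, loss) {
    structure(list(t = t, loss = loss, n_cells = n_cells,
                   low_dynamics = FALSE, kept_cell_indices = seq_len(n_cells)),
              class = "velotf_fit")
  }
  set.seed(34)
  fits <- structure(list(fits = c(
    setNames(lapply(1:10, function(i) mk_fit(pt, loss = 1)),
             paste0("aligned", 1:10)),
    setNames(lapply(1:10, function(i) mk_fit(sample(pt), loss = 60)),
             paste0("shuffled", 1:10))
  ), skipped = character()), class = "velotf_fits")
  sel <- select_stream_genes(fits, pt, alignment_threshold = 0.5)
  expect_setequal(sel, paste0("aligned", 1:10))

  # reversed-time gene is rejected even with low loss
  fits$fits$reversed <- mk_fit(rev(pt), loss = 1)
  expect_false("reversed" %in%
                 select_stream_genes(fits, pt, alignment_threshold = 0.5))
})

test_that("embedding arrows are drift-corrected weighted displacements", {
  set.seed(35)
  emb <- matrix(runif(20), 10, 2)
  nb <- t(vapply(1:10, function(i) setdiff(sample(10), i)[1:3], integer(3)))
  # uniform transition rows give zero arrows
  Tu <- matrix(0, 10, 10)
  for (i in 1:10) Tu[i, nb[i, ]] <- 1 / 3
  expect_equal(embed_velocity_stream(Tu, emb, nb), matrix(0, 10, 2),
               tolerance = 1e-12)

  # full mass on one neighbor: arrow = displacement minus uniform drift
  T1 <- matrix(0, 10, 10); T1[1, nb[1, 2]] <- 1
  for (i in 2:10) T1[i, nb[i, ]] <- 1 / 3
  a <- embed_velocity_stream(T1, emb, nb)
  disp <- emb[nb[1, ], ] - matrix(emb[1, ], 3, 2, byrow = TRUE)
  expect_equal(a[1, ], disp[2, ] - colMeans(disp))

  # two blobs with all transitions pointing at the second blob
  emb2 <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                matrix(rnorm(10, 5, 0.1), 5, 2))
  nb2 <- t(vapply(1:10, function(i) setdiff(order(rowSums((emb2 -
    matrix(emb2[i, ], 10, 2, byrow = TRUE))^2)), i)[1:4], integer(4)))
  T2 <- matrix(0, 10, 10)
  for (i in 1:5) {                                 # blob1 cells target blob2
    tgt <- nb2[i, ][nb2[i, ] > 5]
    if (!length(tgt)) tgt <- 6
    T2[i, tgt] <- 1 / length(tgt)
  }
  for (i in 6:10) T2[i, nb2[i, ]] <- 1 / 4
  a2 <- embed_velocity_stream(T2, emb2, nb2)
  to_blob2 <- colMeans(emb2[6:10, ]) - colMeans(emb2[1:5, ])
  for (i in 1:5)
    if (any(nb2[i, ] > 5) && any(nb2[i, ] <= 5))
      expect_gt(sum(a2[i, ] * to_blob2), 0)
})

test_that("trajectory wrapper produces a consistent bundle", {
  b <- generate_benchmark(n_genes = 4, n_cells = 80, n_tfs = 4,
                          noise_sd = 0.1, seed = 36, t_range = c(0, 0.75))
  fits <- fit_targets(b$dataset, b$priors, n_iters = 6)
  traj <- infer_trajectory(fits, b$dataset, n_neighbors = 10)
  expect_equal(rowSums(traj$transition), rep(1, 80), tolerance = 1e-8)
  expect_true(all(traj$pseudotime >= 0 & traj$pseudotime <= 1))
  expect_lt(mean(traj$pseudotime[traj$root]),
            mean(traj$pseudotime[traj$end]))
})
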