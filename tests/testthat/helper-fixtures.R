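# Shared fixtures. Expensive benchmark fits are computed once per test run
# and memoized here so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-conditions smoke benchmark (the CI-scale version of the full
# 200-gene study) plus its fits and the vanilla-EM ablation
smoke_bench <- function() memo("smoke_bench", {
  generate_benchmark(n_genes = 20, n_cells = 1000, n_tfs = 10, seed = 101)
})

smoke_fits <- function() memo("smoke_fits", {
  b <- smoke_bench()
  fit_targets(b$dataset, b$priors, n_iters = 20)
})

smoke_ablation <- function() memo("smoke_ablation", {
  b <- smoke_bench()
  fit_targets(b$dataset, b$priors, n_iters = 20, n_theta_starts = 1,
              update_w = FALSE)
})

noiseless_bench <- function() memo("noiseless_bench", {
  generate_benchmark(n_genes = 20, n_cells = 1000, n_tfs = 10,
                     noise_sd = 0, seed = 202)
})

noiseless_fits <- function() memo("noiseless_fits", {
  b <- noiseless_bench()
  fit_targets(b$dataset, b$priors, n_iters = 20)
})

# random valid parameter set for the dynamical model
random_params <- function(n_tf = 3) {
  dyn_params(W = runif(n_tf, -2, 2),
             alpha = runif(1, 0.3, 2),
             beta = runif(1, -1, 2),
             theta = runif(1, -pi + 0.1, pi - 0.1),
             gamma = runif(1, 0.2, 8))
}

# directed n-cell chain transition matrix with absorbing final state
chain_T <- function(n) {
  T_ <- matrix(0, n, n)
  for (i in seq_len(n - 1)) T_[i, i + 1] <- 1
  T_[n, n] <- 1
  T_
}

# write a small cells x genes CSV and return its path
write_csv_matrix <- function(mat, gene_names, path = tempfile(fileext = ".csv")) {
  df <- as.data.frame(mat)
  names(df) <- gene_names
  write.csv(df, path, row.names = FALSE)
  path
}
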