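#' Build the velocity-based cell-cell transition matrix
#'
#' For each directed neighbor-graph edge c -> j, the cosine similarity
#' between cell c's velocity vector and the expression displacement
#' `expression[j,] - expression[c,]` (both over the fitted-gene subset) is
#' passed through an exponential kernel `exp(sim / kernel_scale)`; rows are
#' restricted to the neighbor set and normalized to sum to one. A cell with
#' zero velocity gets a uniform row over its neighbors.
#'
#' @param velocity,expression cells x genes matrices of identical shape
#'   (genes restricted to those with successful fits).
#' @param neighbors cells x k matrix of neighbor indices (self excluded),
#'   e.g. from [knn_indices()].
#' @param kernel_scale kernel temperature (default 0.1).
#' @return an n x n row-stochastic matrix, zero outside the neighbor graph.
#' @export
build_transition_matrix <- function(velocity, expression, neighbors,
                                    kernel_scale = 0.1) {
  stopifnot(identical(dim(velocity), dim(expression)))
  n <- nrow(velocity)
  T_ <- matrix(0, n, n)
  for (c_ in seq_len(n)) {
    nb <- neighbors[c_, ]
    v <- velocity[c_, ]
    if (all(v == 0)) {
      T_[c_, nb] <- 1 / length(nb)
      next
    }
    disp <- expression[nb, , drop = FALSE] -
      matrix(expression[c_, ], length(nb), ncol(expression), byrow = TRUE)
    sims <- vapply(seq_along(nb),
                   function(i) cosine_sim(v, disp[i, ]), numeric(1))
    w <- exp(sims / kernel_scale)
    T_[c_, nb] <- w / sum(w)
  }
  T_
}

#' Detect root and end cells from the transition matrix
#'
#' End cells are the top quantile of the stationary distribution of the
#' forward transition matrix (left eigenvector for eigenvalue one, by power
#' iteration); root cells are obtained the same way from the transposed,
#' row-renormalized matrix (the reversed walk).
#'
#' @param T_ row-stochastic transition matrix.
#' @param quantile_top fraction of cells called root/end (default 0.02,
#'   with at least one cell).
#' @param max_iter,tol power-iteration controls.
#' @return list with integer index sets `root` and `end`.
#' @export
find_root_end_cells <- function(T_, quantile_top = 0.02, max_iter = 5000,
                                tol = 1e-6) {
  n <- nrow(T_)
  m <- max(1L, ceiling(quantile_top * n))
  pick <- function(pi_) sort(order(-pi_, seq_len(n))[seq_len(m)])
  end <- pick(stationary_distribution(T_, max_iter, tol))
  Tt <- t(T_)
  rs <- rowSums(Tt)
  zero <- rs == 0
  if (any(zero)) { Tt[zero, ] <- 1 / n; rs[zero] <- 1 }
  Tt <- Tt / rs
  root <- pick(stationary_distribution(Tt, max_iter, tol))
  list(root = root, end = end)
}

stationary_distribution <- function(T_, max_iter = 5000, tol = 1e-6) {
  n <- nrow(T_)
  pi_ <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    # half-step damping suppresses the period-2 oscillation of nearly
    # cyclic walks without moving the fixed point
    nxt <- 0.5 * pi_ + 0.5 * as.vector(pi_ %*% T_)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_)) < tol) return(nxt)
    pi_ <- nxt
  }
  # slow-mixing (nearly reducible) walks may not reach the tolerance; the
  # final iterate still ranks the high-occupancy region correctly, which is
  # all the top-quantile root/end selection needs
  warning("power iteration not fully converged after ", max_iter,
          " steps; using the final iterate")
  pi_
}

#' Velocity pseudotime from the transition matrix
#'
#' Pseudotime of a cell is the average number of steps at which the random
#' walk started from the root set occupies it: the walk's occupancy
#' distribution is propagated for `n_steps` power-iteration steps and each
#' cell's visit probabilities are averaged over the step index (cumulative
#' arrival). The result is min-max normalized to `[0, 1]`, with 0 at the
#' root set. Cells the walk essentially never reaches are assigned
#' pseudotime 1 with a warning.
#'
#' @param T_ row-stochastic transition matrix.
#' @param roots integer index set of root cells (nonempty).
#' @param n_steps number of propagation steps (default 500).
#' @return per-cell pseudotime in `[0, 1]`.
#' @export
velocity_pseudotime <- function(T_, roots, n_steps = 500) {
  stopifnot(length(roots) >= 1)
  n <- nrow(T_)
  p <- numeric(n)
  p[roots] <- 1 / length(roots)
  num <- numeric(n)
  den <- p
  for (k in seq_len(n_steps)) {
    p <- as.vector(p %*% T_)
    num <- num + k * p
    den <- den + p
  }
  reached <- den > n_steps * 1e-12
  if (!all(reached))
    warning(sum(!reached), " cells unreachable from the root set; pseudotime 1")
  depth <- ifelse(reached, num / pmax(den, .Machine$double.xmin), NA_real_)
  depth[!reached] <- max(depth[reached])
  pt <- depth - min(depth)
  if (max(pt) > 0) pt <- pt / max(pt)
  pt
}

#' Normalize gene-specific latent time for stream construction
#'
#' The sine profile is periodic, so per-gene latent times are only defined
#' up to a rotation of the circle. The occupied arc is found from a
#' histogram of latent time: if a run of at least `min_run` consecutive
#' empty bins exists (cyclically), times are rotated so the arc starts at
#' the first occupied bin after the longest empty run, then min-max mapped
#' to `[0, 1]`; otherwise only the min-max map is applied.
#'
#' @param fit a `"velotf_fit"` (or a bare numeric vector of latent times).
#' @param n_bins histogram resolution (default 50).
#' @param min_run minimum length of an empty run that triggers rotation
#'   (default 3).
#' @return per-cell normalized time in `[0, 1]`.
#' @export
normalize_gene_time <- function(fit, n_bins = 50, min_run = 3) {
  t <- if (inherits(fit, "velotf_fit")) fit$t else fit
  bin <- pmin(n_bins, 1L + floor(t * n_bins))
  occupied <- tabulate(bin, nbins = n_bins) > 0
  run <- longest_empty_run(occupied)
  if (!is.null(run) && run$length >= min_run) {
    start_bin <- run$end %% n_bins + 1L          # first occupied bin after
    start <- (start_bin - 1L) / n_bins
    t <- (t - start) %% 1
  }
  rng <- range(t)
  if (diff(rng) == 0) return(rep(0, length(t)))
  (t - rng[1]) / diff(rng)
}

# longest cyclic run of FALSE entries; returns NULL when all occupied
longest_empty_run <- function(occupied) {
  n <- length(occupied)
  if (all(occupied)) return(NULL)
  if (!any(occupied)) return(list(start = 1L, end = n, length = n))
  ext <- rep(!occupied, 2)                       # unroll the circle
  best <- NULL
  i <- 1L
  while (i <= n) {
    if (ext[i]) {
      j <- i
      while (j < 2 * n && ext[j + 1L]) j <- j + 1L
      len <- min(j - i + 1L, n)
      if (is.null(best) || len > best$length)
        best <- list(start = (i - 1L) %% n + 1L, end = (j - 1L) %% n + 1L,
                     length = len)
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

#' Select genes whose dynamics support the velocity stream
#'
#' Keeps genes whose per-cell fitting loss is in the bottom half across
#' genes and whose normalized latent time aligns with the global pseudotime
#' (Spearman correlation at or above `alignment_threshold`). Genes flagged
#' low-dynamics (flat fitted curve) are excluded up front. If the selection
#' is empty it relaxes to the ten best-aligned genes with a warning.
#'
#' @param fits a `"velotf_fits"` object.
#' @param pseudotime per-cell pseudotime over all dataset cells.
#' @param alignment_threshold Spearman cutoff (default 0.5).
#' @param n_bins passed to [normalize_gene_time()].
#' @return character vector of selected gene names.
#' @export
select_stream_genes <- function(fits, pseudotime, alignment_threshold = 0.5,
                                n_bins = 50) {
  stopifnot(inherits(fits, "velotf_fits"), length(fits$fits) >= 2)
  usable <- names(fits$fits)[!vapply(fits$fits, `[[`, TRUE, "low_dynamics")]
  loss_per_cell <- vapply(fits$fits[usable],
                          function(f) f$loss / f$n_cells, numeric(1))
  align <- vapply(usable, function(g) {
    f <- fits$fits[[g]]
    suppressWarnings(cor(normalize_gene_time(f, n_bins = n_bins),
                         pseudotime[f$kept_cell_indices],
                         method = "spearman"))
  }, numeric(1))
  align[is.na(align)] <- -Inf
  sel <- usable[loss_per_cell <= median(loss_per_cell) &
                  align >= alignment_threshold]
  if (!length(sel)) {
    warning("no gene passed stream selection; relaxing to the 10 best-aligned")
    sel <- usable[order(-align)][seq_len(min(10, length(usable)))]
  }
  sel
}

#' Project velocities onto a 2D embedding as stream arrows
#'
#' The arrow of cell c is the transition-probability-weighted mean
#' displacement to its neighbors in embedding space, minus the unweighted
#' neighbor-mean displacement (uniform-kernel drift correction), so uniform
#' transition rows yield zero arrows.
#'
#' @param T_ row-stochastic transition matrix.
#' @param embedding cells x 2 coordinate matrix.
#' @param neighbors cells x k neighbor index matrix (the graph supporting
#'   `T_`).
#' @return cells x 2 matrix of arrow vectors.
#' @export
embed_velocity_stream <- function(T_, embedding, neighbors) {
  n <- nrow(embedding)
  arrows <- matrix(0, n, 2)
  for (c_ in seq_len(n)) {
    nb <- neighbors[c_, ]
    disp <- embedding[nb, , drop = FALSE] -
      matrix(embedding[c_, ], length(nb), 2, byrow = TRUE)
    w <- T_[c_, nb]
    s <- sum(w)
    wmean <- if (s > 0) colSums(disp * (w / s)) else colMeans(disp)
    arrows[c_, ] <- wmean - colMeans(disp)
  }
  arrows
}

#' Run the whole trajectory stage on a set of fits
#'
#' Convenience wrapper: assembles the velocity and expression matrices of
#' the fitted genes, builds the transition matrix on the kNN graph,
#' detects roots and ends, and computes pseudotime.
#'
#' @param fits a `"velotf_fits"` object.
#' @param ds the [expression_dataset()] the fits came from.
#' @param n_neighbors neighborhood size for the velocity graph (default 30).
#' @param kernel_scale,quantile_top forwarded to the stage functions.
#' @return list with `transition`, `root`, `end`, `pseudotime`,
#'   `neighbors`, `velocity`, `expression` (cells x fitted-genes matrices;
#'   cells missing from a gene's fit carry zero velocity).
#' @export
infer_trajectory <- function(fits, ds, n_neighbors = 30, kernel_scale = 0.1,
                             quantile_top = 0.02) {
  stopifnot(inherits(fits, "velotf_fits"), inherits(ds, "expression_dataset"))
  if (!length(fits$fits)) stop("no fitted genes", call. = FALSE)
  genes <- names(fits$fits)
  n <- nrow(ds$matrix)
  mat <- ds$smoothed %||% ds$matrix
  expr <- mat[, match(genes, ds$gene_names), drop = FALSE]
  vel <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  for (g in genes) {
    f <- fits$fits[[g]]
    vel[f$kept_cell_indices, g] <- f$velocity * f$sd_y
  }
  nn <- ds$neighbors
  if (is.null(nn))
    nn <- knn_indices(pca_coords(log1p(mat), 30), k = min(n_neighbors, n - 1),
                      include_self = FALSE)
  else
    nn <- nn[, -1, drop = FALSE]                 # drop self for transitions
  T_ <- build_transition_matrix(vel, expr, nn, kernel_scale = kernel_scale)
  re <- find_root_end_cells(T_, quantile_top = quantile_top)
  pt <- velocity_pseudotime(T_, re$root)
  list(transition = T_, root = re$root, end = re$end, pseudotime = pt,
       neighbors = nn, velocity = vel, expression = expr)
}
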