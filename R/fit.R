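#' Fit the TF-driven velocity model for one gene
#'
#' Fits the sine-profile kinetic model by a generalized EM algorithm. Each
#' iteration runs three block updates that never increase the phase-plane
#' loss: (a) grid-search assignment of per-cell latent time
#' ([assign_latent_time()]); (b) bounded least-squares update of the TF
#' weights ([update_weights()]); (c) constrained local optimization of the
#' curve shape ([update_shape_params()]). The algorithm is run once per
#' phase start and the start with the lowest final loss is returned.
#'
#' The per-cell velocity of the fit is the defining kinetic identity
#' \eqn{v_c = W X_c - \gamma y_c}, evaluated on the observed, unit-sd-scaled
#' abundances.
#'
#' @param x a `"gene_problem"` from [assemble_gene_problem()], or an n_TF x
#'   n_cell TF abundance matrix (then `y` is required and zero-`y` cells are
#'   dropped and both sides rescaled to unit sd internally).
#' @param y target abundance vector when `x` is a matrix.
#' @param n_iters maximum EM iterations per start (default 20).
#' @param n_theta_starts number of evenly spaced phase starts (default 4).
#' @param grid latent-time grid resolution (default 1000).
#' @param weight_bound box bound on TF weights (default 20).
#' @param tol early-stopping threshold on the relative loss change
#'   (default 1e-6).
#' @param update_w set `FALSE` to skip the weight update (the vanilla-EM
#'   ablation, which also conventionally uses `n_theta_starts = 1`).
#' @return an object of class `"velotf_fit"`; see Details. Key elements:
#'   `params` (fitted [dyn_params()]), `t` (per-cell latent time),
#'   `velocity`, `loss`, `loss_trace`, `residuals`, `sigma`, `init_index`.
#' @examples
#' set.seed(1)
#' g <- generate_synthetic_gene(n_cells = 150, n_tfs = 5, noise_sd = 0.05)
#' fit <- velotf_fit(g$tf_trajectories, g$y_obs, n_iters = 10)
#' coef(fit)
#' cor(fit$velocity, g$true_velocity[fit$kept_cell_indices],
#'     method = "spearman")
#' @export
velotf_fit <- function(x, y = NULL, n_iters = 20, n_theta_starts = 4,
                       grid = 1000, weight_bound = 20, tol = 1e-6,
                       update_w = TRUE) {
  problem <- if (inherits(x, "gene_problem")) x else as_gene_problem(x, y)
  starts <- init_parameters(problem, n_theta_starts = n_theta_starts,
                            weight_bound = weight_bound)
  # phase-plane distance cannot distinguish a fit from its time-mirrored
  # twin, so both orientations are explored (odd starts run forward, even
  # starts mirrored) and the winner is chosen among runs that traverse the
  # portrait in the direction implied by the regulatory phase leads.
  # Among correctly oriented runs, forward-seeded ones are preferred (a
  # basin-crossing run scrambles the initialization-anchored part of the
  # weights); the loss breaks ties only within a preference class.
  psi_ref <- orientation_phase(problem, starts[[1]]$W)
  best <- NULL
  best_class <- Inf
  for (s in seq_along(starts)) {
    mirror <- s %% 2 == 0
    run <- em_run(problem, starts[[s]], n_iters = n_iters, grid = grid,
                  tol = tol, update_w = update_w, mirror = mirror)
    run$init_index <- s
    oriented <- run_orientation(run$t, psi_ref) >= 0
    cls <- if (oriented && !mirror) 1 else if (oriented) 2 else 3
    if (cls < best_class || (cls == best_class && run$loss < best$loss)) {
      best <- run
      best_class <- cls
    }
  }
  if (is.null(best)) skip_gene("all starts failed")
  p <- best$params
  velocity <- observed_wx(problem, p$W) - p$gamma * problem$y
  structure(list(params = p, t = best$t, velocity = velocity,
                 loss = best$loss, loss_trace = best$loss_trace,
                 residuals = best$residuals, sigma = best$sigma,
                 init_index = best$init_index,
                 low_dynamics = p$alpha < 1e-3,
                 n_cells = length(problem$y),
                 target_name = problem$target_name %||% "y",
                 tf_names = problem$tf_names %||%
                   paste0("TF", seq_along(p$W)),
                 kept_cell_indices = problem$kept_cell_indices %||%
                   seq_along(problem$y),
                 sd_y = problem$sd_y %||% 1,
                 sd_x = problem$sd_x %||% rep(1, length(p$W)),
                 problem = problem),
            class = "velotf_fit")
}

as_gene_problem <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(!is.null(y), length(y) == ncol(X))
  keep <- which(y != 0)
  if (length(keep) < 3) skip_gene("too few expressing cells")
  y <- y[keep]; X <- X[, keep, drop = FALSE]
  sd_x <- apply(X, 1, sd)
  ok <- sd_x > 0
  if (!any(ok)) skip_gene("all TFs constant")
  sd_y <- sd(y)
  if (sd_y == 0) skip_gene("constant target expression")
  structure(list(X = X[ok, , drop = FALSE] / sd_x[ok], y = y / sd_y,
                 tf_names = rownames(X)[ok], kept_cell_indices = keep,
                 sd_y = sd_y, sd_x = sd_x[ok]),
            class = "gene_problem")
}

em_run <- function(problem, p, n_iters, grid, tol, update_w = TRUE,
                   min_iters = 5, mirror = FALSE) {
  trace <- numeric(0)
  t <- NULL
  prev <- Inf
  for (it in seq_len(n_iters)) {
    if (it == 1) {
      t <- phase_warm_time(problem, p, grid = grid, mirror = mirror)
      p <- seed_first_iteration(problem, p, t, update_w = update_w)
    } else {
      t <- assign_latent_time(problem, p, grid = grid)
      if (update_w) p$W <- update_weights(problem, p, t)
      p <- update_shape_params(problem, p, t)
    }
    loss <- compute_loss(problem, p, t)$loss
    trace <- c(trace, loss)
    if (it >= min_iters && is.finite(prev) && prev > 0 &&
        abs(prev - loss) / prev < tol) break
    prev <- loss
  }
  final <- compute_loss(problem, p, t)
  list(params = p, t = t, loss = final$loss, loss_trace = trace,
       residuals = final$residuals, sigma = final$sigma)
}

# First EM iteration with a multi-start over the degradation rate. The
# steady-state initial estimate of gamma inherits the arbitrary scale of
# the correlation-based weights and regularly collapses to its positive
# floor, from where coordinate descent crawls (the loss is a long curved
# ridge in gamma). With the warm latent times fixed, each candidate rate
# gets its own weight regression and shape fit, and the lowest-loss
# configuration seeds the remaining iterations -- analogous to the phase
# multi-start.
seed_first_iteration <- function(problem, p, t, update_w = TRUE,
                                 candidates = c(0.5, 2, 2 * pi, 20)) {
  best <- NULL
  best_loss <- Inf
  for (g in unique(c(p$gamma, candidates))) {
    q <- p
    q$gamma <- g
    if (update_w) q$W <- update_weights(problem, q, t)
    q <- update_shape_params(problem, q, t)
    l <- compute_loss(problem, q, t)$loss
    if (l < best_loss) {
      best <- q
      best_loss <- l
    }
  }
  best
}

# Warm start for the first latent-time pass of each EM start. Before the
# first weight update the observed drive is too small relative to the model
# ellipse (whose drive amplitude is >= 2*pi times its y amplitude), so a
# plain nearest-point assignment collapses every cell onto the flat side of
# the ellipse and the weight regression becomes self-confirming. Instead,
# cells get the phase angle of their standardized (quadrature, y)
# coordinates; `mirror` reflects the angle to seed the time-mirrored
# orientation, which the phase-plane loss cannot distinguish from the
# forward one.
phase_warm_time <- function(problem, p, grid = 1000, mirror = FALSE) {
  psi <- warm_phase(problem, p$W)
  if (mirror) psi <- -psi
  floor((((psi - p$theta) / (2 * pi)) %% 1) * grid) / grid
}

# per-cell phase angle in the standardized (quadrature, y) plane, with the
# quadrature taken as the residual of the initial drive against y
warm_phase <- function(problem, W) {
  v <- (problem$y - mean(problem$y)) / sd(problem$y)
  u <- observed_wx(problem, W)
  su <- sd(u)
  u <- if (su > 0) (u - mean(u)) / su else rep(0, length(u))
  q <- u - sum(u * v) / sum(v * v) * v
  if (sd(q) < 1e-12) q <- v[c(length(v), seq_len(length(v) - 1))]
  q <- (q - mean(q)) / sd(q)
  atan2(v, q)
}

# orientation reference used to judge a run's traversal direction. The
# aggregate quadrature can carry a wrong sign when regulators lagging by
# more than a quarter period cancel most of it, so a confident majority
# vote of the individual regulators' leads (each oriented by the sign of
# its rank correlation with the target) overrides the aggregate's sign.
orientation_phase <- function(problem, W) {
  v <- (problem$y - mean(problem$y)) / sd(problem$y)
  u <- observed_wx(problem, W)
  su <- sd(u)
  u <- if (su > 0) (u - mean(u)) / su else rep(0, length(u))
  q <- u - sum(u * v) / sum(v * v) * v
  agg_strength <- sd(q)                  # quadrature per unit of drive sd
  if (agg_strength < 1e-12) q <- v[c(length(v), seq_len(length(v) - 1))]
  ld <- lead_direction(problem, v)
  disagree <- sum(q * ld$direction) < 0
  if (disagree && ld$confidence > agg_strength) q <- -q
  atan2(v, q)
}

# consensus lead direction: each TF's residual against y, oriented by the
# sign of its rank correlation with the target, casts one vote on which
# side of y "ahead" lies
lead_direction <- function(problem, v) {
  n_tf <- nrow(problem$X)
  vv <- sum(v * v)
  R <- matrix(0, n_tf, length(v))
  for (i in seq_len(n_tf)) {
    x <- problem$X[i, ]
    sx <- sd(x)
    if (sx == 0) next
    x <- (x - mean(x)) / sx
    r <- suppressWarnings(cor(problem$X[i, ], problem$y, method = "spearman"))
    w_sign <- if (is.na(r)) 0 else sign(r)
    R[i, ] <- (x - sum(x * v) / vv * v) * w_sign
  }
  norms <- sqrt(rowSums(R^2))
  if (max(norms) < 1e-12)
    return(list(direction = v[c(length(v), seq_len(length(v) - 1))],
                confidence = 0))
  ref <- R[which.max(norms), ]
  s <- sign(as.vector(R %*% ref))
  votes <- s[norms > 1e-12]
  if (sum(votes) < 0) ref <- -ref
  list(direction = ref, confidence = abs(sum(votes)) / length(votes))
}

# rotational sense of fitted latent times against a reference phase:
# positive when both order the cells around the portrait the same way
run_orientation <- function(t, psi_ref) {
  det(cor(cbind(sin(2 * pi * t), cos(2 * pi * t)),
          cbind(sin(psi_ref), cos(psi_ref))))
}


#' @export
print.velotf_fit <- function(x, digits = 4, ...) {
  p <- x$params
  cat(sprintf("TF-driven velocity fit for '%s' (%d TFs, %d cells)\n",
              x$target_name, length(p$W), x$n_cells))
  cat(sprintf("  alpha %.4g  beta %.4g  theta %.4g  gamma %.4g\n",
              p$alpha, p$beta, p$theta, p$gamma))
  cat(sprintf("  loss %.6g  sigma %.4g  iterations %d  start %d\n",
              x$loss, x$sigma, length(x$loss_trace), x$init_index))
  invisible(x)
}

#' @export
summary.velotf_fit <- function(object, ...) {
  mean_x <- rowMeans(object$problem$X)
  nw <- tryCatch(normalize_weights(object$params$W, mean_x),
                 error = function(e) NULL)
  out <- list(fit = object,
              weights = data.frame(tf = object$tf_names,
                                   weight = object$params$W,
                                   normalized = if (is.null(nw)) NA_real_
                                                else nw$normalized,
                                   selected = if (is.null(nw)) FALSE
                                              else seq_along(object$params$W)
                                                %in% nw$selected),
              logLik = as.numeric(logLik(object)))
  class(out) <- "summary.velotf_fit"
  out
}

#' @export
print.summary.velotf_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-likelihood %.4g\n", x$logLik))
  cat("TF weights (normalized by mean expression):\n")
  w <- x$weights[order(-abs(x$weights$normalized)), ]
  print(w, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.velotf_fit <- function(object, type = c("all", "shape", "weights"), ...) {
  type <- match.arg(type)
  p <- object$params
  shape <- c(alpha = p$alpha, beta = p$beta, theta = p$theta,
             gamma = p$gamma, omega = p$omega)
  w <- setNames(p$W, object$tf_names)
  switch(type, shape = shape, weights = w, all = c(shape, w))
}

#' Evaluate the fitted profiles
#'
#' @param object a `"velotf_fit"`.
#' @param t latent times at which to evaluate; defaults to the fitted
#'   per-cell times.
#' @param ... unused.
#' @return data.frame with columns `t`, `y` (expression profile) and `wx`
#'   (regulatory drive profile), on the unit-sd scale of the fit.
#' @export
predict.velotf_fit <- function(object, t = object$t, ...) {
  data.frame(t = t, y = profile_y(t, object$params),
             wx = profile_wx(t, object$params))
}

#' @export
fitted.velotf_fit <- function(object, ...) profile_y(object$t, object$params)

#' @export
residuals.velotf_fit <- function(object, ...) object$residuals

#' Gene-level log-likelihood of a fit
#'
#' Under the model the signed phase-plane residuals are Gaussian with
#' gene-specific scale \eqn{\sigma}, giving
#' \eqn{\log \mathcal{L} = -\log(\sqrt{2\pi}\sigma) - L / (2\sigma^2)} with
#' `L` the phase-plane loss. Used to rank genes by fit quality.
#'
#' @param object a `"velotf_fit"`.
#' @param ... unused.
#' @export
logLik.velotf_fit <- function(object, ...) {
  ll <- -log(sqrt(2 * pi) * object$sigma) -
    object$loss / (2 * object$sigma^2)
  structure(ll, df = length(object$params$W) + 4, class = "logLik")
}

#' Simulate observations from a fitted model
#'
#' Draws latent times uniformly on `[0, 1)` and returns model profiles with
#' additive Gaussian noise matched to the observed y-residual spread.
#'
#' @param object a `"velotf_fit"`.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param n number of cells per draw (defaults to the fitted cell count).
#' @param ... unused.
#' @return list of data.frames with columns `t`, `y`, `wx`.
#' @export
simulate.velotf_fit <- function(object, nsim = 1, seed = NULL,
                                n = object$n_cells, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_res <- sd(object$problem$y - fitted(object))
  lapply(seq_len(nsim), function(i) {
    t <- runif(n)
    out <- predict(object, t = t)
    out$y <- out$y + rnorm(n, 0, sd_res)
    out
  })
}

#' Phase-portrait plot of a fit
#'
#' Observed cells in the (WX, y) plane, colored by fitted latent time, with
#' the fitted model curve overlaid.
#'
#' @param x a `"velotf_fit"`.
#' @param n_curve points used to draw the model curve.
#' @param ... passed to [plot()].
#' @export
plot.velotf_fit <- function(x, n_curve = 300, ...) {
  wx_o <- observed_wx(x$problem, x$params$W)
  cols <- hcl.colors(100, "viridis")[pmin(100, 1 + floor(x$t * 100))]
  plot(wx_o, x$problem$y, col = cols, pch = 16, cex = 0.6,
       xlab = "regulatory drive (W.X)", ylab = "target abundance (y)",
       main = x$target_name, ...)
  tc <- seq(0, 1, length.out = n_curve)
  lines(profile_wx(tc, x$params), profile_y(tc, x$params), lwd = 2,
        col = "purple")
  invisible(x)
}

#' Fit all target genes of a dataset
#'
#' Assembles and fits one model per requested target, skipping genes that
#' cannot be fitted (no prior TFs present, too few expressing cells,
#' constant expression) and recording the reason.
#'
#' @param ds an [expression_dataset()] (smoothed moments are used if present).
#' @param priors prior table from [load_tf_target_priors()].
#' @param targets genes to fit; defaults to all dataset genes that appear as
#'   targets in the prior table.
#' @param min_cells minimum expressing cells per gene (default 10).
#' @param verbose print per-gene progress.
#' @param ... passed to [velotf_fit()].
#' @return an object of class `"velotf_fits"`: list with `fits` (named list
#'   of `"velotf_fit"`) and `skipped` (named character vector of reasons).
#' @export
fit_targets <- function(ds, priors, targets = NULL, min_cells = 10,
                        verbose = FALSE, ...) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(targets))
    targets <- ds$gene_names[toupper(ds$gene_names) %in%
                               unique(toupper(priors$target))]
  fits <- list()
  skipped <- character(0)
  for (g in targets) {
    res <- tryCatch({
      pr <- assemble_gene_problem(ds, priors, g, min_cells = min_cells)
      velotf_fit(pr, ...)
    }, velotf_skip = function(e) e)
    if (is_skip(res)) {
      skipped[g] <- conditionMessage(res)
      if (verbose) message("skip ", g, ": ", conditionMessage(res))
    } else {
      fits[[g]] <- res
      if (verbose) message(sprintf("fit %s: loss %.4g", g, res$loss))
    }
  }
  structure(list(fits = fits, skipped = skipped), class = "velotf_fits")
}

#' @export
print.velotf_fits <- function(x, ...) {
  cat(sprintf("<velotf_fits> %d genes fitted, %d skipped\n",
              length(x$fits), length(x$skipped)))
  invisible(x)
}

#' Per-gene parameter table of a multi-gene fit
#'
#' @param fits a `"velotf_fits"` object.
#' @return data.frame with one row per fitted gene: shape parameters, loss,
#'   residual scale, winning start and log-likelihood.
#' @export
fit_parameter_table <- function(fits) {
  stopifnot(inherits(fits, "velotf_fits"))
  do.call(rbind, lapply(names(fits$fits), function(g) {
    f <- fits$fits[[g]]
    data.frame(gene = g, alpha = f$params$alpha, beta = f$params$beta,
               theta = f$params$theta, gamma = f$params$gamma,
               loss = f$loss, sigma = f$sigma, init_index = f$init_index,
               n_cells = f$n_cells, logLik = as.numeric(logLik(f)),
               stringsAsFactors = FALSE)
  }))
}

#' Sparse TF-weight table of a multi-gene fit
#'
#' @param fits a `"velotf_fits"` object.
#' @return data.frame with columns `gene`, `tf`, `weight`,
#'   `normalized_weight`, `selected`.
#' @export
fit_weight_table <- function(fits) {
  stopifnot(inherits(fits, "velotf_fits"))
  do.call(rbind, lapply(names(fits$fits), function(g) {
    f <- fits$fits[[g]]
    s <- summary(f)$weights
    data.frame(gene = g, tf = s$tf, weight = s$weight,
               normalized_weight = s$normalized, selected = s$selected,
               stringsAsFactors = FALSE)
  }))
}
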