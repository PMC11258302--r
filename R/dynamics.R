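#' Construct the per-gene dynamical parameter set
#'
#' Parameters of the sine-profile kinetic model
#' \eqn{y(t) = \alpha \sin(\omega t + \theta) + \beta} with
#' \eqn{dy/dt = W X(t) - \gamma y(t)}. The angular frequency \eqn{\omega}
#' is fixed at \eqn{2\pi} so the profile is unimodal on one latent-time
#' period \eqn{t \in [0,1)}; it is never a free parameter.
#'
#' @param W numeric TF weight vector, each entry in `[-weight_bound, weight_bound]`.
#' @param alpha amplitude, > 0.
#' @param beta offset.
#' @param theta phase, in (-pi, pi).
#' @param gamma degradation rate, > 0.
#' @param weight_bound box bound on the weights (default 20).
#' @return an object of class `"dyn_params"`.
#' @export
dyn_params <- function(W, alpha, beta, theta, gamma, weight_bound = 20) {
  stopifnot(is.numeric(W), length(W) >= 1)
  if (!(alpha > 0)) stop("alpha must be positive", call. = FALSE)
  if (!(gamma > 0)) stop("gamma must be positive", call. = FALSE)
  if (!(theta > -pi && theta < pi)) stop("theta must lie in (-pi, pi)",
                                         call. = FALSE)
  if (any(abs(W) > weight_bound))
    stop("weights must lie within [-", weight_bound, ", ", weight_bound, "]",
         call. = FALSE)
  structure(list(W = W, alpha = alpha, beta = beta, theta = theta,
                 gamma = gamma, omega = 2 * pi, weight_bound = weight_bound),
            class = "dyn_params")
}

#' Target-gene expression profile y(t)
#'
#' @param t latent time(s) in `[0, 1)`.
#' @param p a [dyn_params()] object.
#' @return \eqn{\alpha \sin(2\pi t + \theta) + \beta}, vectorized over `t`.
#' @export
profile_y <- function(t, p) p$alpha * sin(2 * pi * t + p$theta) + p$beta

#' Regulatory-drive profile WX(t)
#'
#' The closed-form drive implied by the sine profile and the linear
#' kinetics: \eqn{WX(t) = \alpha\sqrt{4\pi^2+\gamma^2}\,
#' \sin(2\pi t + \theta + \phi) + \beta\gamma}, \eqn{\phi = \arctan(2\pi/\gamma)}.
#' It satisfies \eqn{WX(t) = y'(t) + \gamma y(t)} identically.
#'
#' @inheritParams profile_y
#' @export
profile_wx <- function(t, p) {
  phi <- atan2(2 * pi, p$gamma)
  p$alpha * sqrt(4 * pi^2 + p$gamma^2) * sin(2 * pi * t + p$theta + phi) +
    p$beta * p$gamma
}

# observed drive W.X per cell
observed_wx <- function(problem, W) as.vector(crossprod(problem$X, W))

#' Assign per-cell latent time by grid search
#'
#' For each cell, the latent time is the grid point whose model state
#' `(WX(t), y(t))` is closest (squared Euclidean distance in the phase
#' plane) to the observed state `(W.X_c, y_c)`. Ties resolve to the
#' smallest time.
#'
#' @param problem a `"gene_problem"`.
#' @param p a [dyn_params()] object.
#' @param grid number of equally spaced grid points in `[0, 1)` (default 1000).
#' @return numeric vector of per-cell times on the grid.
#' @export
assign_latent_time <- function(problem, p, grid = 1000) {
  stopifnot(grid >= 2)
  tg <- (seq_len(grid) - 1) / grid
  wx_g <- profile_wx(tg, p)
  y_g <- profile_y(tg, p)
  wx_o <- observed_wx(problem, p$W)
  # argmin_g (a_c-b_g)^2+(c_c-d_g)^2; the per-cell constant term is
  # dropped and the sign is folded in so a single matrix product feeds
  # max.col directly
  score <- cbind(2 * wx_o, 2 * problem$y, -1) %*%
    rbind(wx_g, y_g, wx_g^2 + y_g^2)
  tg[max.col(score, ties.method = "first")]
}

#' Phase-plane loss, residuals and residual scale
#'
#' The loss is the summed squared distance between each observed state and
#' its modeled target point,
#' \eqn{L = \sum_c (W X_c - WX(t_c))^2 + (y_c - y(t_c))^2}. Signed residuals
#' \eqn{e_c = \mathrm{sign}(y_c - y(t_c))\,\lVert s_c - \hat s(t_c)\rVert^2}
#' and their standard deviation \eqn{\sigma} are returned alongside.
#'
#' @inheritParams assign_latent_time
#' @param t per-cell latent time.
#' @return list with `loss`, `residuals`, `sigma`.
#' @export
compute_loss <- function(problem, p, t) {
  wx_o <- observed_wx(problem, p$W)
  dwx <- wx_o - profile_wx(t, p)
  dy <- problem$y - profile_y(t, p)
  sq <- dwx^2 + dy^2
  e <- sign(dy) * sq
  list(loss = sum(sq), residuals = e, sigma = sd(e))
}

#' Update TF weights by bounded linear least squares
#'
#' With latent times and shape parameters held fixed, the model-side drive
#' `WX(t_c)` is a constant target and the weight subproblem is a box-
#' constrained linear regression of those targets on the TF matrix:
#' minimize \eqn{\sum_c (W \cdot X_c - WX(t_c))^2} subject to
#' `|W_i| <= weight_bound`. Solved by L-BFGS-B on the exact quadratic with
#' analytic gradient, warm-started from the current weights (so the loss
#' never increases, and in rank-deficient designs the unidentified
#' component of W stays at its initialization).
#'
#' @inheritParams compute_loss
#' @return the updated weight vector.
#' @export
update_weights <- function(problem, p, t) {
  target <- profile_wx(t, p)
  if (!all(is.finite(target)) || !all(is.finite(problem$X)))
    stop("non-finite values in weight regression", call. = FALSE)
  X <- problem$X
  A <- tcrossprod(X)                     # n_TF x n_TF
  b <- as.vector(X %*% target)
  c0 <- sum(target^2)
  fn <- function(w) drop(crossprod(w, A %*% w)) - 2 * sum(w * b) + c0
  gr <- function(w) 2 * (as.vector(A %*% w) - b)
  bound <- p$weight_bound
  res <- optim(p$W, fn, gr, method = "L-BFGS-B",
               lower = -bound, upper = bound,
               control = list(maxit = 200, factr = 1e4))
  if (res$value <= fn(p$W)) res$par else p$W
}

#' Update the shape parameters (alpha, beta, theta, gamma)
#'
#' With latent times and weights fixed, locally minimizes the phase-plane
#' loss over the curve-shape parameters under the constraints
#' `alpha > 0`, `theta` in (-pi, pi), `gamma > 0`, starting from the
#' current values. If the optimizer fails or would increase the loss the
#' previous values are kept (a no-op step, which generalized EM tolerates).
#'
#' @inheritParams compute_loss
#' @return a [dyn_params()] object with updated shape parameters.
#' @export
update_shape_params <- function(problem, p, t) {
  wx_o <- observed_wx(problem, p$W)
  eps <- 1e-6
  obj <- function(par) {
    q <- p; q$alpha <- par[1]; q$beta <- par[2]; q$theta <- par[3]
    q$gamma <- par[4]
    v <- sum((wx_o - profile_wx(t, q))^2 + (problem$y - profile_y(t, q))^2)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  par0 <- c(p$alpha, p$beta, p$theta, p$gamma)
  res <- tryCatch(
    optim(par0, obj, method = "L-BFGS-B",
          lower = c(eps, -Inf, -pi + eps, eps),
          upper = c(Inf, Inf, pi - eps, Inf),
          control = list(maxit = 100)),
    error = function(e) NULL)
  if (is.null(res) || res$value > obj(par0)) {
    p$shape_step_failed <- TRUE
    return(p)
  }
  p$alpha <- res$par[1]; p$beta <- res$par[2]
  p$theta <- res$par[3]; p$gamma <- res$par[4]
  p$shape_step_failed <- FALSE
  p
}

#' Initialize the generalized EM algorithm
#'
#' Weights start at the Spearman correlation of each TF with the target;
#' \eqn{\alpha = (y_{max}-y_{min})/2} and \eqn{\beta = (y_{max}+y_{min})/2}
#' from the observed range; \eqn{\gamma} from the steady-state relation
#' \eqn{\gamma = W X / y} evaluated on the top decile of `y` (floored at a
#' small positive value); and one start per phase \eqn{\theta}, evenly
#' spaced in (-pi, pi).
#'
#' @param problem a `"gene_problem"` (already unit-sd scaled).
#' @param n_theta_starts number of phase starts (default 4).
#' @param weight_bound box bound for the weights.
#' @return list of [dyn_params()], one per theta start.
#' @export
init_parameters <- function(problem, n_theta_starts = 4, weight_bound = 20) {
  y <- problem$y
  if (sd(y) == 0) skip_gene("constant target expression")
  W0 <- apply(problem$X, 1, function(x) {
    r <- suppressWarnings(cor(x, y, method = "spearman"))
    if (is.na(r)) 0 else r
  })
  alpha <- (max(y) - min(y)) / 2
  beta <- (max(y) + min(y)) / 2
  top <- y >= quantile(y, 0.9)
  gamma <- mean(observed_wx(problem, W0)[top]) / mean(y[top])
  gamma <- max(gamma, 0.01)
  k <- n_theta_starts
  thetas <- -pi + (2 * seq_len(k) - 1) * pi / k
  lapply(thetas, function(th)
    dyn_params(W = W0, alpha = max(alpha, 1e-6), beta = beta, theta = th,
               gamma = gamma, weight_bound = weight_bound))
}

#' Normalize fitted TF weights by mean expression
#'
#' The influence of TF *i* is its weight times its mean abundance,
#' \eqn{w_i \bar x_i}; normalized weights divide by the largest absolute
#' influence so that \eqn{\max_i |\tilde w_i| = 1}. TFs with
#' \eqn{|\tilde w_i| > threshold} (strict) are flagged as selected.
#'
#' @param W fitted weight vector.
#' @param mean_tf_expression per-TF mean abundance on the same scale as the
#'   fit.
#' @param threshold selection cutoff on `|normalized weight|` (default 0.5).
#' @return list with `normalized` (max abs value exactly 1) and `selected`
#'   (integer indices).
#' @export
normalize_weights <- function(W, mean_tf_expression, threshold = 0.5) {
  infl <- W * mean_tf_expression
  m <- max(abs(infl))
  if (m == 0) stop("all TF influences are zero; normalization undefined",
                   call. = FALSE)
  w <- infl / m
  list(normalized = w, selected = which(abs(w) > threshold))
}
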