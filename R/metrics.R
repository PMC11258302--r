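#' Phase-portrait points for metric evaluation
#'
#' Bundles the two phase-plane coordinates of each cell (regulatory drive
#' W.X and target abundance y for this package's fits; unspliced/spliced
#' for splicing-based baselines), the cell-type labels, and optionally the
#' matched model-curve coordinates.
#'
#' @param x,y per-cell phase coordinates.
#' @param labels per-cell cell-type labels.
#' @param model_x,model_y optional per-cell modeled coordinates
#'   `(x(t_c), y(t_c))`.
#' @return an object of class `"phase_points"`.
#' @export
phase_points <- function(x, y, labels, model_x = NULL, model_y = NULL) {
  stopifnot(length(x) == length(y), length(labels) == length(x))
  if (sd(x) == 0 || sd(y) == 0)
    stop("phase coordinates must have positive spread", call. = FALSE)
  structure(list(x = x, y = y, labels = as.character(labels),
                 model_x = model_x, model_y = model_y),
            class = "phase_points")
}

#' Intra-class distance on the phase portrait
#'
#' Sum over cell types and member cells of the squared standardized
#' distance to the class centroid; lower values mean cells of one type
#' gather on the portrait. Coordinates are standardized by their global
#' standard deviation, making the metric invariant to separate affine
#' rescaling of each axis.
#'
#' @param pp a [phase_points()] object.
#' @return nonnegative scalar.
#' @export
intra_class_distance <- function(pp) {
  sx <- sd(pp$x); sy <- sd(pp$y)
  total <- 0
  for (k in unique(pp$labels)) {
    i <- pp$labels == k
    if (!any(i)) next
    total <- total + sum(((pp$x[i] - mean(pp$x[i])) / sx)^2 +
                           ((pp$y[i] - mean(pp$y[i])) / sy)^2)
  }
  total
}

#' Inter-class distance on the phase portrait
#'
#' Sum over ordered pairs of distinct cell types of the squared
#' standardized distance between class centroids; higher values mean types
#' separate on the portrait.
#'
#' @inheritParams intra_class_distance
#' @return nonnegative scalar.
#' @export
inter_class_distance <- function(pp) {
  classes <- unique(pp$labels)
  if (length(classes) < 2)
    stop("inter-class distance needs at least two cell types", call. = FALSE)
  sx <- sd(pp$x); sy <- sd(pp$y)
  cx <- unname(vapply(classes, function(k) mean(pp$x[pp$labels == k]),
                      numeric(1)))
  cy <- unname(vapply(classes, function(k) mean(pp$y[pp$labels == k]),
                      numeric(1)))
  total <- 0
  for (k1 in seq_along(classes)) for (k2 in seq_along(classes))
    if (k1 != k2)
      total <- total + ((cx[k1] - cx[k2]) / sx)^2 + ((cy[k1] - cy[k2]) / sy)^2
  total
}

#' Fitting error on the phase portrait
#'
#' Sum over cells of the squared standardized distance between the observed
#' point and its matched model point.
#'
#' @inheritParams intra_class_distance
#' @return nonnegative scalar.
#' @export
fitting_error <- function(pp) {
  if (is.null(pp$model_x) || is.null(pp$model_y))
    stop("fitting_error requires model-curve coordinates", call. = FALSE)
  sum(((pp$x - pp$model_x) / sd(pp$x))^2 + ((pp$y - pp$model_y) / sd(pp$y))^2)
}

#' Cross-boundary direction correctness (CBDir)
#'
#' For each annotated transition (source type -> target type), boundary
#' cells are source-type cells with at least one target-type neighbor; the
#' score of a boundary cell is the mean cosine between its velocity vector
#' and the displacement vectors to its target-type neighbors, and the
#' transition score averages over boundary cells.
#'
#' @param velocity,expression cells x genes matrices.
#' @param labels per-cell type labels.
#' @param transitions list of `c(source, target)` type pairs.
#' @param neighbors cells x k neighbor index matrix.
#' @return named numeric vector, one entry per transition (NA with a
#'   warning when a transition has no boundary cells).
#' @export
cross_boundary_direction_correctness <- function(velocity, expression,
                                                 labels, transitions,
                                                 neighbors) {
  labels <- as.character(labels)
  out <- numeric(0)
  for (tr in transitions) {
    src <- tr[1]; tgt <- tr[2]
    scores <- numeric(0)
    for (c_ in which(labels == src)) {
      nb <- neighbors[c_, ]
      nb <- nb[labels[nb] == tgt]
      if (!length(nb)) next
      disp <- expression[nb, , drop = FALSE] -
        matrix(expression[c_, ], length(nb), ncol(expression), byrow = TRUE)
      scores <- c(scores, mean(vapply(seq_along(nb), function(i)
        cosine_sim(velocity[c_, ], disp[i, ]), numeric(1))))
    }
    nm <- paste(src, tgt, sep = "->")
    if (!length(scores)) {
      warning("no boundary cells for transition ", nm)
      out[nm] <- NA_real_
    } else out[nm] <- mean(scores)
  }
  out
}

#' In-cluster velocity coherence (ICCoh)
#'
#' Mean cosine similarity between each cell's velocity and the velocities
#' of its same-cluster neighbors, averaged per cluster; measures the
#' smoothness of the velocity field within a cluster.
#'
#' @inheritParams cross_boundary_direction_correctness
#' @return named numeric vector, one entry per cluster (clusters without
#'   any same-cluster neighbor pair are omitted).
#' @export
in_cluster_coherence <- function(velocity, labels, neighbors) {
  labels <- as.character(labels)
  out <- numeric(0)
  for (k in unique(labels)) {
    scores <- numeric(0)
    for (c_ in which(labels == k)) {
      nb <- neighbors[c_, ]
      nb <- nb[labels[nb] == k]
      if (!length(nb)) next
      scores <- c(scores, vapply(nb, function(j)
        cosine_sim(velocity[c_, ], velocity[j, ]), numeric(1)))
    }
    if (length(scores)) out[k] <- mean(scores)
  }
  out
}

#' Velocity consistency across neighboring cells
#'
#' Per cell, the cosine similarity between its velocity and the mean
#' velocity of its neighbors (zero when that mean vanishes).
#'
#' @inheritParams cross_boundary_direction_correctness
#' @return per-cell numeric vector in `[-1, 1]`.
#' @export
velocity_consistency <- function(velocity, neighbors) {
  vapply(seq_len(nrow(velocity)), function(c_) {
    nb_mean <- colMeans(velocity[neighbors[c_, ], , drop = FALSE])
    cosine_sim(velocity[c_, ], nb_mean)
  }, numeric(1))
}
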