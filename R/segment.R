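#' One-dimensional K-means with stable ascending labels
#'
#' Lloyd's algorithm (via \code{stats::kmeans}) on a scalar sample, restarted
#' from \code{n_init} k-means++ draws (first centre uniform over the distinct
#' values, subsequent centres with probability proportional to squared
#' distance from the nearest chosen centre), keeping the solution with the
#' lowest within-cluster sum of squares. Clusters are relabelled by ascending
#' centroid so label 1 is always the lowest-valued class. Deterministic given
#' \code{seed}.
#'
#' @param values numeric vector (finite), with at least \code{k} distinct
#'   values.
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @param n_init number of random restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return list with \code{centroids} (ascending) and integer \code{labels}
#'   in 1..k (1 = lowest centroid).
#' @export
kmeans_1d <- function(values, k, seed = 1L, n_init = 10L, iter_max = 100L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("`values` must be finite")
  un <- unique(values)
  if (length(un) < k)
    stop(sprintf("need at least %d distinct values for k = %d clusters", k, k))
  x <- matrix(values, ncol = 1)
  kmpp_centers <- function() {
    ctr <- numeric(k)
    ctr[1] <- un[sample.int(length(un), 1L)]
    d2 <- (un - ctr[1])^2
    for (j in seq_len(k - 1L) + 1L) {
      ctr[j] <- un[sample.int(length(un), 1L, prob = d2 / sum(d2))]
      d2 <- pmin(d2, (un - ctr[j])^2)
    }
    ctr
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      centers <- matrix(kmpp_centers(), ncol = 1)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
        best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed to converge from any restart")
  ord <- order(best$centers[, 1])
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  list(centroids = as.numeric(best$centers[ord, 1]),
       labels = rank_of[best$cluster])
}

#' Two-class sound-speed segmentation (fat vs fibroglandular)
#'
#' K-means with k = 2 on the within-mask sound-speed voxel values, fitted per
#' breast. The low-centroid cluster is fat, the high-centroid cluster
#' fibroglandular (the mammographically dense tissue). A degenerate breast
#' with fewer than 2 distinct values falls back to all-fat with a warning.
#'
#' @param ss sound-speed \code{\link{image_stack}}.
#' @param breast_mask mask stack or logical array, nonempty.
#' @param seed RNG seed for the clustering restarts.
#' @return list with logical arrays \code{fat} and \code{fibroglandular}
#'   (partitioning the mask) and the two ascending \code{centroids}
#'   (\code{NA} on the degenerate fallback).
#' @export
segment_sound_speed <- function(ss, breast_mask, seed = 1L) {
  stopifnot(is_image_stack(ss))
  m <- as_mask_array(breast_mask, ss)
  if (!any(m)) stop("breast mask is empty")
  vals <- ss$data[m]
  fat <- array(FALSE, dim(ss$data)); fg <- fat
  if (length(unique(vals)) < 2L) {
    warning("fewer than 2 distinct sound-speed values: falling back to all-fat")
    fat[m] <- TRUE
    return(list(fat = fat, fibroglandular = fg, centroids = c(NA_real_, NA_real_)))
  }
  km <- kmeans_1d(vals, k = 2L, seed = seed)
  fat[m] <- km$labels == 1L
  fg[m] <- km$labels == 2L
  list(fat = fat, fibroglandular = fg, centroids = km$centroids)
}

#' Three-class stiffness segmentation (soft / intermediate / hard)
#'
#' K-means with k = 3 on the within-mask stiffness values, fitted per breast;
#' ascending centroids map to soft, intermediate and hard, in analogy to the
#' BI-RADS elasticity descriptors.
#'
#' @param S stiffness \code{\link{image_stack}} in [0, 1].
#' @param breast_mask mask stack or logical array, nonempty.
#' @param seed RNG seed for the clustering restarts.
#' @return list with logical arrays \code{soft}, \code{intermediate},
#'   \code{hard} (partitioning the mask) and the three ascending
#'   \code{centroids}.
#' @export
segment_stiffness <- function(S, breast_mask, seed = 1L) {
  stopifnot(is_image_stack(S))
  m <- as_mask_array(breast_mask, S)
  if (!any(m)) stop("breast mask is empty")
  km <- kmeans_1d(S$data[m], k = 3L, seed = seed)
  soft <- array(FALSE, dim(S$data)); int <- soft; hard <- soft
  soft[m] <- km$labels == 1L
  int[m] <- km$labels == 2L
  hard[m] <- km$labels == 3L
  list(soft = soft, intermediate = int, hard = hard, centroids = km$centroids)
}

#' Names of the six tissue components
#'
#' @return character vector naming label codes 1..6 of the six-component map:
#'   \{soft, intermediate, hard\} within fat, then within fibroglandular.
#' @export
six_component_names <- function() {
  c("soft_fat", "intermediate_fat", "hard_fat",
    "soft_fibroglandular", "intermediate_fibroglandular",
    "hard_fibroglandular")
}

#' Intersect sound-speed and stiffness masks into six components
#'
#' Crosses the 2-class sound-speed partition with the 3-class stiffness
#' partition: a voxel that is fibroglandular on sound speed and hard on
#' stiffness becomes "hard fibroglandular", and so on. Every mask voxel gets
#' exactly one of the 6 labels; voxels outside the mask are 0.
#'
#' @param ss_masks output of \code{\link{segment_sound_speed}}.
#' @param stiff_masks output of \code{\link{segment_stiffness}}.
#' @param breast_mask mask stack or logical array.
#' @param spacing,origin geometry for the returned label stack (taken from
#'   the mask if it is an \code{image_stack}).
#' @return label \code{image_stack} with values 0 (outside) and 1..6 in the
#'   order of \code{\link{six_component_names}}.
#' @export
intersect_six <- function(ss_masks, stiff_masks, breast_mask,
                          spacing = NULL, origin = NULL) {
  m <- as_mask_array(breast_mask)
  if (is_image_stack(breast_mask)) {
    if (is.null(spacing)) spacing <- breast_mask$spacing
    if (is.null(origin)) origin <- breast_mask$origin
  }
  if (is.null(spacing)) stop("`spacing` required when mask carries no geometry")
  ssc <- ss_masks$fat + 2L * ss_masks$fibroglandular
  stc <- stiff_masks$soft + 2L * stiff_masks$intermediate + 3L * stiff_masks$hard
  if (any((ssc[m] == 0L) | (stc[m] == 0L)))
    stop("masks do not cover the breast mask: not a partition")
  if (any(ss_masks$fat & ss_masks$fibroglandular) ||
      any(stiff_masks$soft & stiff_masks$intermediate) ||
      any(stiff_masks$soft & stiff_masks$hard) ||
      any(stiff_masks$intermediate & stiff_masks$hard))
    stop("masks overlap within a family: not a partition")
  lab <- array(0, dim(m))
  lab[m] <- 3L * (ssc[m] - 1L) + stc[m]
  image_stack(lab, spacing, "label", "component code", origin = origin)
}
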