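#' Build the localizer GLM design matrix
#'
#' Columns: HRF-convolved task boxcar, intercept, linear trend — the
#' standard online-localizer design. The task contrast weights the first
#' column.
#'
#' @param labels per-TR condition labels (\code{"task"}/\code{"rest"}).
#' @param tr_seconds sampling interval (s).
#' @param hrf_peak_s,hrf_undershoot_s HRF shape parameters.
#' @return numeric matrix with columns \code{task}, \code{intercept},
#'   \code{trend}.
#' @export
localizer_design_matrix <- function(labels, tr_seconds = 2.0,
                                    hrf_peak_s = 6.0, hrf_undershoot_s = 16.0) {
  n <- length(labels)
  k <- hrf_kernel(tr_seconds, hrf_peak_s, hrf_undershoot_s)
  task <- convolve_causal(as.numeric(labels == "task"), k)
  cbind(task = task, intercept = rep(1, n),
        trend = seq_len(n) - (n + 1) / 2)
}

#' Initialize a streaming GLM state
#'
#' The state carries the running cross-products needed to reproduce batch
#' least squares at any time: \eqn{X'X}, \eqn{X'y} per voxel, and the
#' per-voxel sums and sums of squares of the data. Updating is O(voxels)
#' per volume.
#'
#' @param design full design matrix (rows are presented to
#'   \code{\link{glm_update}} one at a time).
#' @param n_voxels number of voxels per volume.
#' @return an object of class \code{nfb_glm_state}.
#' @export
glm_init <- function(design, n_voxels) {
  design <- as.matrix(design)
  p <- ncol(design)
  structure(list(design = design,
                 n_volumes_seen = 0L,
                 xtx = matrix(0, p, p),
                 xty = matrix(0, p, n_voxels),
                 yty = numeric(n_voxels),
                 n_voxels = as.integer(n_voxels)),
            class = "nfb_glm_state")
}

#' Incorporate one volume into the streaming GLM
#'
#' @param state an \code{nfb_glm_state}.
#' @param volume numeric vector of per-voxel values (a flattened volume;
#'   use a consistent voxel order throughout).
#' @return the updated state.
#' @export
glm_update <- function(state, volume) {
  stopifnot(inherits(state, "nfb_glm_state"))
  volume <- as.numeric(volume)
  if (length(volume) != state$n_voxels) {
    stop(sprintf("volume has %d voxels; expected %d",
                 length(volume), state$n_voxels), call. = FALSE)
  }
  i <- state$n_volumes_seen + 1L
  if (i > nrow(state$design)) stop("more volumes than design rows", call. = FALSE)
  x <- state$design[i, ]
  state$xtx <- state$xtx + tcrossprod(x)
  state$xty <- state$xty + outer(x, volume)
  state$yty <- state$yty + volume^2
  state$n_volumes_seen <- i
  state
}

#' Per-voxel t-statistics for a contrast of the streaming GLM
#'
#' Computes \eqn{t = c'\hat\beta / \sqrt{\hat\sigma^2 c'(X'X)^{-1}c}} per
#' voxel from the running cross-products, with
#' \eqn{df = n - \mathrm{rank}(X)}. Residual variance is floored at 1e-12
#' so that noise-free synthetic fixtures yield a large finite t rather
#' than an infinity.
#'
#' @param state an \code{nfb_glm_state} with more volumes than design
#'   columns.
#' @param contrast contrast weight vector (default: the first design
#'   column, the task regressor).
#' @param grid_shape optional 3D dimensions to reshape the statistic into.
#' @return an object of class \code{nfb_stat_map}: list with \code{t}
#'   (vector, or array if \code{grid_shape} given), \code{beta} (contrast
#'   estimates), \code{df}, \code{n_volumes_seen}.
#' @export
glm_t_map <- function(state, contrast = NULL, grid_shape = NULL) {
  stopifnot(inherits(state, "nfb_glm_state"))
  p <- ncol(state$design)
  n <- state$n_volumes_seen
  if (n == 0L) stop("no volumes seen; t-map unavailable", call. = FALSE)
  if (n <= qr(state$design)$rank) {
    stop("need more volumes than design rank", call. = FALSE)
  }
  qr_x <- qr(state$xtx)
  rank <- qr_x$rank
  if (rank < p) stop("singular design; t-map unavailable", call. = FALSE)
  if (is.null(contrast)) contrast <- c(1, rep(0, p - 1))
  beta <- solve(qr_x, state$xty)                 # p x voxels
  # residual SS via the cross-product identity
  rss <- state$yty - colSums(beta * state$xty)
  rss <- pmax(rss, 0)
  df <- n - rank
  sigma2 <- pmax(rss / df, 1e-12)
  cxx <- drop(t(contrast) %*% solve(qr_x, contrast))
  cb <- drop(t(contrast) %*% beta)
  tval <- cb / sqrt(sigma2 * cxx)
  if (!is.null(grid_shape)) {
    tval <- array(tval, dim = grid_shape)
    cb <- array(cb, dim = grid_shape)
  }
  structure(list(t = tval, beta = cb, df = df, n_volumes_seen = n),
            class = "nfb_stat_map")
}

#' Run the streaming GLM over a 4D grid and return the task t-map
#'
#' Convenience wrapper: initializes the state from the design, feeds every
#' volume, and returns the t-map shaped like the grid.
#'
#' @param grid 4D array (x, y, z, time).
#' @param design design matrix from \code{\link{localizer_design_matrix}}.
#' @return an \code{nfb_stat_map} with \code{t} shaped as the grid.
#' @export
localize_grid <- function(grid, design) {
  dims <- dim(grid)
  stopifnot(length(dims) == 4L)
  n_vox <- prod(dims[1:3])
  flat <- matrix(grid, nrow = n_vox, ncol = dims[4])
  state <- glm_init(design, n_vox)
  for (i in seq_len(dims[4])) state <- glm_update(state, flat[, i])
  glm_t_map(state, grid_shape = dims[1:3])
}

#' Select the feedback ROI from a statistical map
#'
#' Thresholds the t-map, clusters suprathreshold voxels by face adjacency
#' (6-connectivity) and returns the cluster containing the global maximum
#' t — the most significant activation cluster. Ties on the peak value are
#' broken by larger cluster size, then by the lexicographically smallest
#' peak coordinate. An optional prior mask restricts the search (the
#' anatomical constraint of a real session).
#'
#' @param map an \code{nfb_stat_map} whose \code{t} is a 3D array, or a 3D
#'   array of t values.
#' @param threshold_t positive voxel-wise threshold.
#' @param prior_mask optional logical 3D array; voxels outside it are
#'   ignored.
#' @param voxel_volume_cm3 volume of one voxel in cm^3 (2 x 2 x 3 mm^3
#'   default).
#' @return an object of class \code{nfb_roi_mask}: list with \code{voxels}
#'   (n x 3 coordinate matrix), \code{mask} (logical array), \code{peak_t},
#'   \code{peak_coord}, \code{size_voxels}, \code{size_cm3}.
#' @export
select_roi <- function(map, threshold_t, prior_mask = NULL,
                       voxel_volume_cm3 = 0.012) {
  tmap <- if (inherits(map, "nfb_stat_map")) map$t else map
  if (is.null(dim(tmap)) || length(dim(tmap)) != 3L) {
    stop("t map must be a 3D array", call. = FALSE)
  }
  if (threshold_t <= 0) stop("threshold_t must be positive", call. = FALSE)
  supra <- tmap > threshold_t
  if (!is.null(prior_mask)) supra <- supra & prior_mask
  if (!any(supra)) {
    stop("no suprathreshold voxel; lower the threshold", call. = FALSE)
  }
  labels <- label_components_6(supra)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  best <- NULL
  for (id in ids) {
    in_cl <- labels == id
    peak_t <- max(tmap[in_cl])
    size <- sum(in_cl)
    coords <- which(in_cl & tmap == peak_t, arr.ind = TRUE)
    coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), , drop = FALSE]
    cand <- list(id = id, peak_t = peak_t, size = size, peak = coords[1, ])
    if (is.null(best) || cand$peak_t > best$peak_t ||
        (cand$peak_t == best$peak_t &&
         (cand$size > best$size ||
          (cand$size == best$size && coord_lt(cand$peak, best$peak))))) {
      best <- cand
    }
  }
  mask <- labels == best$id
  voxels <- which(mask, arr.ind = TRUE)
  voxels <- voxels[order(voxels[, 1], voxels[, 2], voxels[, 3]), , drop = FALSE]
  colnames(voxels) <- c("x", "y", "z")
  structure(list(voxels = voxels, mask = mask,
                 peak_t = best$peak_t,
                 peak_coord = as.integer(best$peak),
                 size_voxels = best$size,
                 size_cm3 = voxel_volume_cm3 * best$size),
            class = "nfb_roi_mask")
}

coord_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Connected components under face adjacency (6-connectivity) by flood fill.
label_components_6 <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nxt <- 0L
  todo <- which(mask)
  for (lin in todo) {
    if (labels[lin] != 0L) next
    nxt <- nxt + 1L
    queue <- lin
    labels[lin] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- lin_to_coord(cur, dims)
      for (k in seq_len(nrow(nb))) {
        cn <- cc + nb[k, ]
        if (any(cn < 1) || any(cn > dims)) next
        ln <- coord_to_lin(cn, dims)
        if (mask[ln] && labels[ln] == 0L) {
          labels[ln] <- nxt
          queue <- c(queue, ln)
        }
      }
    }
  }
  labels
}

lin_to_coord <- function(lin, dims) {
  lin <- lin - 1L
  x <- lin %% dims[1]
  y <- (lin %/% dims[1]) %% dims[2]
  z <- lin %/% (dims[1] * dims[2])
  c(x, y, z) + 1L
}

coord_to_lin <- function(coord, dims) {
  (coord[3] - 1L) * dims[1] * dims[2] + (coord[2] - 1L) * dims[1] + coord[1]
}

#' Extract the ROI-mean time series from a 4D grid
#'
#' @param grid 4D array (x, y, z, time).
#' @param roi an \code{nfb_roi_mask} (or logical 3D array).
#' @return numeric vector of per-TR ROI means.
#' @export
roi_mean_series <- function(grid, roi) {
  mask <- if (inherits(roi, "nfb_roi_mask")) roi$mask else roi
  dims <- dim(grid)
  flat <- matrix(grid, nrow = prod(dims[1:3]), ncol = dims[4])
  colMeans(flat[as.vector(mask), , drop = FALSE])
}

#' Calibrate the 100% display point from the localizer run
#'
#' For each localizer task block, the block-averaged percent signal change
#' is computed relative to the mean of the immediately preceding rest
#' block; the calibration maximum is the largest of these block means.
#' Using block means rather than a single-TR peak keeps the 100% point
#' from being set by a noise spike.
#'
#' @param series raw ROI-mean time series over the localizer run.
#' @param design the \code{\link{localizer_design}} that produced it.
#' @return a \code{\link{calibration_info}}.
#' @export
calibrate_max <- function(series, design) {
  labels <- make_localizer_design(design)
  if (length(series) != length(labels)) {
    stop("series length does not match the localizer design", call. = FALSE)
  }
  block_psc <- numeric(design$task_blocks)
  pos <- design$rest_trs
  for (b in seq_len(design$task_blocks)) {
    rest_idx <- (pos - design$rest_trs + 1):pos
    task_idx <- (pos + 1):(pos + design$task_trs)
    rest_mean <- mean(series[rest_idx])
    if (rest_mean <= 0) stop("non-positive rest baseline in localizer", call. = FALSE)
    block_psc[b] <- percent_signal_change(mean(series[task_idx]), rest_mean)
    pos <- pos + design$task_trs + design$rest_trs
  }
  mx <- max(block_psc)
  if (mx <= 0) {
    stop("non-positive localizer maximum; calibration unavailable", call. = FALSE)
  }
  calibration_info(mx)
}
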