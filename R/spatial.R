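## Spatial statistics: KDE density maps, adaptively filtered Delaunay
## graphs, fixed-radius neighborhood composition, nearest-neighbor
## proximity, and subtype ratios.  Coordinates are micrometers throughout.

#' Gaussian kernel density map with percentile clip and mask
#'
#' Fits a product-Gaussian KDE (Scott's rule bandwidth per dimension) to
#' cell centroids, evaluates the density at the cell positions to define the
#' 98th-percentile clip ceiling and 10th-percentile mask floor, then
#' evaluates the density on a regular grid, clipping and masking
#' accordingly.  Refuses fewer than 50 points.
#'
#' @param points n x 2 cell centroids (um).
#' @param grid_spacing grid step (um); default spans the data in ~128 steps.
#' @param clip_percentile,mask_percentile contrast-enhancement percentiles.
#' @param pad grid padding around the data range, in bandwidths.
#' @return object of class \code{density_map}: grid axes \code{x}, \code{y},
#'   clipped density \code{z}, raw density \code{z_raw}, logical
#'   \code{mask}, \code{clip_value}, \code{mask_value}, \code{bandwidth},
#'   \code{origin}, \code{spacing}.
#' @export
kde_map <- function(points, grid_spacing = NULL, clip_percentile = 98,
                    mask_percentile = 10, pad = 3) {
  pts <- as_coords(points)
  n <- nrow(pts)
  if (n < 50L)
    stop("insufficient cells for a density map (n = ", n, " < 50)")
  h <- apply(pts, 2, stats::sd) * n^(-1 / 6)  # Scott's rule, d = 2
  h[h <= 0] <- 1e-6
  eval_kde <- function(qx, qy) {
    # chunked evaluation keeps memory at O(chunk * n)
    out <- numeric(length(qx))
    chunk <- max(1L, floor(2e6 / n))
    for (s in seq(1L, length(qx), by = chunk)) {
      idx <- s:min(s + chunk - 1L, length(qx))
      dx <- outer(qx[idx], pts[, 1], "-") / h[1]
      dy <- outer(qy[idx], pts[, 2], "-") / h[2]
      out[idx] <- rowSums(exp(-0.5 * (dx * dx + dy * dy)))
    }
    out / (n * 2 * pi * h[1] * h[2])
  }
  dens_at_cells <- eval_kde(pts[, 1], pts[, 2])
  clip_value <- stats::quantile(dens_at_cells, clip_percentile / 100, names = FALSE)
  mask_value <- stats::quantile(dens_at_cells, mask_percentile / 100, names = FALSE)
  rx <- range(pts[, 1]) + c(-pad, pad) * h[1]
  ry <- range(pts[, 2]) + c(-pad, pad) * h[2]
  if (is.null(grid_spacing)) grid_spacing <- max(diff(rx), diff(ry)) / 128
  gx <- seq(rx[1], rx[2], by = grid_spacing)
  gy <- seq(ry[1], ry[2], by = grid_spacing)
  gg <- expand.grid(x = gx, y = gy)
  z_raw <- matrix(eval_kde(gg$x, gg$y), nrow = length(gx))
  z <- pmin(z_raw, clip_value)
  mask <- z_raw < mask_value
  structure(list(x = gx, y = gy, z = z, z_raw = z_raw, mask = mask,
                 clip_value = clip_value, mask_value = mask_value,
                 bandwidth = h, origin = c(rx[1], ry[1]),
                 spacing = grid_spacing,
                 clip_percentile = clip_percentile,
                 mask_percentile = mask_percentile),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("Gaussian KDE map:", length(x$x), "x", length(x$y), "grid, spacing",
      signif(x$spacing, 4), "um\n")
  cat("  bandwidth (Scott):", paste(signif(x$bandwidth, 4), collapse = " x "),
      "um; clip", signif(x$clip_value, 4), "; mask", signif(x$mask_value, 4), "\n")
  invisible(x)
}

#' Adaptively filtered Delaunay neighborhood graph
#'
#' Delaunay triangulation of the points with edges retained only when their
#' length does not exceed \code{filter_factor} times the smaller of the two
#' endpoint nearest-neighbor distances — keeping short-range connections
#' while dropping spurious long edges across sparse space (an edge must be
#' short on the local scale of both endpoints, so isolated far-away points
#' do not keep their long edges).
#'
#' @param points n x 2 coordinates (um).
#' @param filter_factor dimensionless edge-length multiplier (default 3).
#' @return object of class \code{spatial_graph}: \code{edges} data.frame
#'   (\code{from}, \code{to}, \code{length}), \code{n_nodes}, and the
#'   unfiltered edge count \code{n_delaunay_edges}.
#' @export
delaunay_filtered <- function(points, filter_factor = 3) {
  pts <- as_coords(points)
  n <- nrow(pts)
  empty <- function() {
    warning("need at least 3 non-collinear points for a Delaunay graph")
    structure(list(edges = data.frame(from = integer(0), to = integer(0),
                                      length = numeric(0)),
                   n_nodes = n, n_delaunay_edges = 0L),
              class = "spatial_graph")
  }
  if (n < 3L) return(empty())
  dd <- tryCatch(deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE),
                 error = function(e) NULL)
  if (is.null(dd) || nrow(dd$delsgs) == 0L) return(empty())
  es <- dd$delsgs
  len <- sqrt((es$x1 - es$x2)^2 + (es$y1 - es$y2)^2)
  nn <- rep(Inf, n)
  for (r in seq_along(len)) {
    nn[es$ind1[r]] <- min(nn[es$ind1[r]], len[r])
    nn[es$ind2[r]] <- min(nn[es$ind2[r]], len[r])
  }
  keep <- len <= filter_factor * pmin(nn[es$ind1], nn[es$ind2])
  structure(list(edges = data.frame(from = es$ind1[keep], to = es$ind2[keep],
                                    length = len[keep]),
                 n_nodes = n, n_delaunay_edges = length(len)),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("Spatial graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges (of",
      x$n_delaunay_edges, "Delaunay edges)\n")
  invisible(x)
}

#' Neighborhood composition around target cells
#'
#' A cell is a neighbor when its Euclidean distance to at least one target
#' cell is \code{<= radius} (inclusive); each neighbor is counted once
#' regardless of how many targets it is close to.
#'
#' @param targets m x 2 target coordinates (um).
#' @param others n x 2 candidate coordinates (um).
#' @param labels cell-type label per candidate.
#' @param radius neighborhood radius (um), default 50.
#' @return data.frame with \code{type}, \code{count}, \code{fraction}
#'   (fractions over all neighbors sum to 1), plus attribute
#'   \code{n_neighbors}.
#' @export
neighborhood_composition <- function(targets, others, labels, radius = 50) {
  if (radius <= 0) stop("radius must be positive")
  others <- as_coords(others)
  stopifnot(length(labels) == nrow(others))
  if (is.null(targets) || NROW(targets) == 0L) {
    warning("no target cells; empty neighborhood")
    out <- data.frame(type = character(0), count = integer(0),
                      fraction = numeric(0))
    attr(out, "n_neighbors") <- 0L
    return(out)
  }
  targets <- as_coords(targets)
  d <- FNN::knnx.dist(targets, others, k = 1)[, 1]
  nb <- d <= radius
  tab <- table(labels[nb])
  out <- data.frame(type = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / max(sum(tab), 1L),
                    stringsAsFactors = FALSE)
  attr(out, "n_neighbors") <- sum(nb)
  out
}

#' Nearest-neighbor distances between two cell populations
#'
#' For every source cell, the Euclidean distance to the closest target cell.
#' With \code{to} omitted, distances are computed within \code{from} with
#' the cell itself excluded.  The log option applies
#' \code{log(distance + 1)} (natural log, 1 um offset).
#'
#' @param from n x 2 source coordinates (um).
#' @param to m x 2 target coordinates (um); defaults to \code{from} with
#'   self-exclusion.
#' @param log log-transform the distances?
#' @return numeric vector of distances with attribute \code{mean}; NA vector
#'   (with a warning) when the target set is empty.
#' @export
nn_distances <- function(from, to = NULL, log = FALSE) {
  from <- as_coords(from)
  if (NROW(from) == 0L) stop("source set is empty")
  self <- is.null(to)
  if (!self && NROW(to) == 0L) {
    warning("empty target set; returning NA distances")
    d <- rep(NA_real_, nrow(from))
    attr(d, "mean") <- NA_real_
    return(d)
  }
  d <- if (self) {
    if (nrow(from) < 2L) stop("self nearest-neighbor distance needs >= 2 cells")
    FNN::knn.dist(from, k = 1)[, 1]
  } else {
    FNN::knnx.dist(as_coords(to), from, k = 1)[, 1]
  }
  if (log) d <- base::log(d + 1)
  attr(d, "mean") <- mean(d)
  d
}

#' Ratio of two subtype counts
#'
#' @param count_a,count_b non-negative counts.
#' @return \code{count_a / count_b}, or \code{NA} (flagged via attribute
#'   \code{undefined}) when \code{count_b} is zero — never infinity.
#' @export
subtype_ratio <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  if (count_b == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  count_a / count_b
}
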