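## Tumor boundary reconstruction and microanatomical region assignment.
##
## Tumor boundaries are reconstructed from tumor-cell centroids by DBSCAN
## clustering followed by an alpha-shape-style concave hull per cluster.
## Every cell is then assigned one region with precedence
## tumor > necrotic > perivascular > peritumoral > distal: necrotic cells
## sit inside the peritumoral band, carry DNA-debris staining and lie in a
## locally sparse neighborhood; perivascular cells sit within a fixed radius
## of a CD31+ endothelial cell.

#' Region model parameters
#'
#' @param peritumoral_band band width outside tumor polygons (um).
#' @param vessel_radius radius around CD31+ cells defining perivascular
#'   tissue (um).
#' @param necrosis_density_quantile local densities below this quantile of
#'   the field's density distribution qualify as "sparse".
#' @param dbscan_eps,dbscan_min_samples DBSCAN parameters (um, count).
#' @param boundary_alpha concavity scale of the boundary hull (um); default
#'   \code{2 * dbscan_eps}.
#' @param boundary_buffer outward dilation of reconstructed polygons (um).
#'   A concave hull of uniformly sampled points underestimates the true
#'   tissue support by about half the point spacing; the default \code{NA}
#'   buffers each polygon by half the median nearest-neighbor spacing of
#'   its cluster (0 disables the correction).
#' @param density_k neighbors used for the local k-NN density estimate.
#' @return object of class \code{region_model}.
#' @export
region_model <- function(peritumoral_band = 50, vessel_radius = 50,
                         necrosis_density_quantile = 0.2,
                         dbscan_eps = 40, dbscan_min_samples = 10,
                         boundary_alpha = 2 * dbscan_eps,
                         boundary_buffer = NA_real_, density_k = 10) {
  if (peritumoral_band <= 0 || vessel_radius <= 0)
    stop_config("band width and vessel radius must be positive")
  if (dbscan_eps <= 0) stop_config("dbscan_eps must be positive")
  if (dbscan_min_samples < 3) stop_config("dbscan_min_samples must be >= 3")
  if (necrosis_density_quantile <= 0 || necrosis_density_quantile >= 1)
    stop_config("necrosis_density_quantile must be a fraction in (0,1)")
  structure(list(peritumoral_band = peritumoral_band,
                 vessel_radius = vessel_radius,
                 necrosis_density_quantile = necrosis_density_quantile,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_samples = dbscan_min_samples,
                 boundary_alpha = boundary_alpha,
                 boundary_buffer = boundary_buffer,
                 density_k = density_k),
            class = "region_model")
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Grid-accelerated DBSCAN on 2-D points.  A point is a core point when at
#' least \code{min_samples} points (itself included) lie within \code{eps};
#' clusters are the connected components of core points under eps-adjacency;
#' a non-core point within eps of a core point joins the cluster of its
#' nearest core point (deterministic, input-order independent); remaining
#' points are noise (label 0).
#'
#' @param points n x 2 coordinate matrix (um).
#' @param eps neighborhood radius (um).
#' @param min_samples minimum neighborhood size for a core point.
#' @return integer vector of cluster labels (0 = noise), renumbered so that
#'   cluster ids are ordered by each cluster's first point index.
#' @export
cluster_dbscan <- function(points, eps, min_samples) {
  pts <- as_coords(points)
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  bx <- floor(pts[, 1] / eps); by <- floor(pts[, 2] / eps)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  nbr_keys <- function(i) {
    gx <- bx[i]; gy <- by[i]
    paste(rep(gx + (-1:1), each = 3), rep(gy + (-1:1), 3))
  }
  neighbors <- function(i) {
    cand <- unlist(buckets[nbr_keys(i)], use.names = FALSE)
    d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
    cand[d2 <= eps^2]
  }
  nbr <- lapply(seq_len(n), neighbors)
  core <- lengths(nbr) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      nb <- nbr[[j]]
      nb <- nb[core[nb] & labels[nb] == 0L]
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  # border points: nearest core neighbor decides
  for (i in which(!core)) {
    nb <- nbr[[i]]
    nb <- nb[core[nb]]
    if (!length(nb)) next
    d2 <- (pts[nb, 1] - pts[i, 1])^2 + (pts[nb, 2] - pts[i, 2])^2
    labels[i] <- labels[nb[which.min(d2)]]
  }
  labels
}

# circumradius of a triangle given 3x2 coordinate matrix
circumradius <- function(tri) {
  a <- sqrt(sum((tri[1, ] - tri[2, ])^2))
  b <- sqrt(sum((tri[2, ] - tri[3, ])^2))
  c <- sqrt(sum((tri[3, ] - tri[1, ])^2))
  area2 <- abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2]))
  if (area2 < 1e-12) return(Inf)
  a * b * c / (2 * area2)
}

#' Signed shoelace area of a polygon
#'
#' @param poly polygon vertex matrix (open ring, first vertex not repeated).
#' @param signed return the signed area (positive = counter-clockwise)?
#' @return area in the square of the coordinate unit.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_coords(poly)
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  a <- sum(x * y[i2] - x[i2] * y) / 2
  if (signed) a else abs(a)
}

# concave hull of a point cluster: triangles of the Delaunay triangulation
# with circumradius <= alpha; the outer boundary ring of their union.
# Falls back to the convex hull when the alpha complex degenerates.
alpha_hull <- function(pts, alpha) {
  pts <- unique(as_coords(pts))
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  convex <- function() pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  tl <- tryCatch(
    deldir::triang.list(deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(tl) || !length(tl)) return(convex())
  keep <- Filter(function(tr)
    circumradius(cbind(tr$x, tr$y)) <= alpha, tl)
  if (!length(keep)) return(convex())
  edges <- do.call(rbind, lapply(keep, function(tr) {
    v <- tr$ptNum
    rbind(sort(v[c(1, 2)]), sort(v[c(2, 3)]), sort(v[c(3, 1)]))
  }))
  ekey <- paste(edges[, 1], edges[, 2])
  boundary <- edges[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
  if (nrow(boundary) < 3L) return(convex())
  # walk boundary edges into closed rings; keep the largest-area ring
  adj <- split(c(boundary[, 2], boundary[, 1]), c(boundary[, 1], boundary[, 2]))
  used <- new.env(parent = emptyenv())
  edge_id <- function(i, j) paste(min(i, j), max(i, j))
  rings <- list()
  for (r in seq_len(nrow(boundary))) {
    if (!is.null(used[[edge_id(boundary[r, 1], boundary[r, 2])]])) next
    start <- boundary[r, 1]
    ring <- c(start, boundary[r, 2])
    used[[edge_id(start, boundary[r, 2])]] <- TRUE
    repeat {
      cur <- ring[length(ring)]
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[vapply(nxt, function(v) is.null(used[[edge_id(cur, v)]]), TRUE)]
      if (!length(nxt)) break
      v <- nxt[[1]]
      used[[edge_id(cur, v)]] <- TRUE
      if (v == start) break
      ring <- c(ring, v)
    }
    if (length(ring) >= 3L) rings[[length(rings) + 1L]] <- ring
  }
  if (!length(rings)) return(convex())
  polys <- lapply(rings, function(rg) pts[rg, , drop = FALSE])
  best <- polys[[which.max(vapply(polys, polygon_area, 0))]]
  if (polygon_area(best, signed = TRUE) < 0) best <- best[rev(seq_len(nrow(best))), ]
  best
}

# Dilate a CCW ring outward by d um along per-vertex normals (average of
# the adjacent edge normals).  Adequate for the small sampling-bias buffer;
# not a general polygon offsetting routine.
offset_polygon <- function(poly, d) {
  if (d == 0) return(poly)
  n <- nrow(poly)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  e1 <- poly[nxt, ] - poly
  e2 <- poly - poly[prv, ]
  nrm <- function(e) {
    len <- pmax(sqrt(rowSums(e^2)), 1e-12)
    cbind(e[, 2], -e[, 1]) / len  # outward for CCW rings
  }
  v <- nrm(e1) + nrm(e2)
  v <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
  poly + d * v
}

#' Reconstruct tumor boundary polygons
#'
#' DBSCAN on tumor-cell centroids followed by a concave-hull polygon per
#' non-noise cluster, returned largest-area first.  Each polygon is dilated
#' outward by \code{boundary_buffer} (by default half the median
#' nearest-neighbor spacing of its cluster) to correct the inward sampling
#' bias of a hull of point samples.  With fewer tumor cells than
#' \code{dbscan_min_samples} the result is an empty list (no error).
#'
#' @param tumor_cells coordinates of tumor-cell centroids (um).
#' @param model a [region_model()].
#' @return list of polygon vertex matrices (CCW, open rings).
#' @export
reconstruct_tumor_boundaries <- function(tumor_cells, model = region_model()) {
  pts <- as_coords(tumor_cells)
  if (nrow(pts) < model$dbscan_min_samples) return(list())
  labels <- cluster_dbscan(pts, model$dbscan_eps, model$dbscan_min_samples)
  polys <- list()
  for (cl in sort(unique(labels[labels > 0L]))) {
    cl_pts <- pts[labels == cl, , drop = FALSE]
    p <- alpha_hull(cl_pts, model$boundary_alpha)
    if (is.null(p)) next
    buf <- model$boundary_buffer
    if (is.na(buf))
      buf <- if (nrow(cl_pts) > 1L)
        stats::median(FNN::knn.dist(cl_pts, k = 1)[, 1]) / 2 else 0
    polys[[length(polys) + 1L]] <- offset_polygon(p, buf)
  }
  if (!length(polys)) return(list())
  polys[order(vapply(polys, polygon_area, 0), decreasing = TRUE)]
}

# 1 = inside or on boundary of any polygon
inside_any <- function(pts, polygons) {
  res <- rep(FALSE, nrow(pts))
  for (p in polygons)
    res <- res | sp::point.in.polygon(pts[, 1], pts[, 2], p[, 1], p[, 2]) > 0
  res
}

# minimum distance from each point to any polygon boundary segment
dist_to_polygons <- function(pts, polygons) {
  d <- rep(Inf, nrow(pts))
  for (p in polygons) {
    ring <- rbind(p, p[1, , drop = FALSE])
    d <- pmin(d, dist_to_path(pts, ring))
  }
  d
}

#' Local k-NN density
#'
#' Density estimate at each cell: \code{k / (pi * r_k^2)} with \code{r_k}
#' the distance to the k-th nearest neighbor.
#'
#' @param points n x 2 coordinates (um).
#' @param k neighbor count.
#' @return numeric vector, cells per um^2.
#' @export
local_knn_density <- function(points, k = 10) {
  pts <- as_coords(points)
  k <- min(k, nrow(pts) - 1L)
  if (k < 1L) return(rep(NA_real_, nrow(pts)))
  rk <- FNN::knn.dist(pts, k = k)[, k]
  k / (pi * rk^2)
}

#' Assign microanatomical regions
#'
#' Labels every cell with one region under the precedence (1) inside a tumor
#' polygon: \code{tumor}; (2) within the peritumoral band, debris-positive
#' and locally sparse: \code{necrotic}; (3) within \code{vessel_radius} of a
#' vessel (CD31+) cell: \code{perivascular}; (4) within the band:
#' \code{peritumoral}; (5) otherwise \code{distal}.
#'
#' @param cells cell table with \code{x}, \code{y} columns.
#' @param polygons tumor polygons from [reconstruct_tumor_boundaries()].
#' @param model a [region_model()].
#' @param vessel_cells coordinates of CD31+ endothelial cells (or NULL).
#' @param debris_flags logical vector (DNA-debris staining) or NULL.
#' @return \code{cells} with a \code{region} column appended.
#' @export
assign_regions <- function(cells, polygons, model = region_model(),
                           vessel_cells = NULL, debris_flags = NULL) {
  pts <- as_coords(cells)
  n <- nrow(pts)
  if (is.null(debris_flags)) debris_flags <- rep(FALSE, n)
  if (length(debris_flags) != n)
    stop("debris_flags length does not match the cell table")
  inside <- if (length(polygons)) inside_any(pts, polygons) else rep(FALSE, n)
  band <- if (length(polygons))
    !inside & dist_to_polygons(pts, polygons) <= model$peritumoral_band
  else rep(FALSE, n)
  near_vessel <- rep(FALSE, n)
  if (!is.null(vessel_cells) && NROW(vessel_cells) > 0) {
    v <- as_coords(vessel_cells)
    near_vessel <- FNN::knnx.dist(v, pts, k = 1)[, 1] <= model$vessel_radius
  }
  dens <- local_knn_density(pts, model$density_k)
  sparse <- dens < stats::quantile(dens, model$necrosis_density_quantile,
                                   na.rm = TRUE, names = FALSE)
  region <- rep("distal", n)
  region[band] <- "peritumoral"
  region[near_vessel & !inside] <- "perivascular"
  region[band & as.logical(debris_flags) & sparse] <- "necrotic"
  region[inside] <- "tumor"
  out <- as.data.frame(cells)
  out$region <- region
  out
}

#' Assign domains from annotation polygons
#'
#' @param cells cell table with \code{x}, \code{y}.
#' @param annotation_polygons named list of polygon vertex matrices.
#' @param unassigned label for cells outside every polygon.
#' @return character vector of domain ids.
#' @export
assign_domains <- function(cells, annotation_polygons, unassigned = "none") {
  pts <- as_coords(cells)
  domain <- rep(unassigned, nrow(pts))
  for (nm in names(annotation_polygons)) {
    p <- annotation_polygons[[nm]]
    hit <- sp::point.in.polygon(pts[, 1], pts[, 2], p[, 1], p[, 2]) > 0
    domain[hit & domain == unassigned] <- nm
  }
  domain
}

#' Regional composition of cell types
#'
#' For each cell type, the fraction of its cells falling in each region (or
#' domain): counts normalized to the total count of that cell type, so rows
#' sum to 1.  Cell types with zero total get an \code{NA} row.
#'
#' @param groups region or domain label per cell.
#' @param phenotypes cell-type label per cell.
#' @return matrix of fractions, cell types x groups.
#' @export
regional_composition <- function(groups, phenotypes) {
  stopifnot(length(groups) == length(phenotypes))
  tab <- table(phenotypes, groups)
  tot <- rowSums(tab)
  frac <- sweep(unclass(tab), 1, tot, "/")
  frac[tot == 0, ] <- NA_real_
  frac
}

#' Cell density within a polygon
#'
#' @param n_cells number of cells inside the polygon.
#' @param polygon polygon vertex matrix with coordinates in um.
#' @return density in cells per mm^2.
#' @export
cell_density <- function(n_cells, polygon) {
  if (n_cells < 0) stop("cell count must be non-negative")
  a <- polygon_area(polygon)
  if (!is.finite(a) || a <= 0) stop("degenerate polygon: non-positive area")
  n_cells / (a / 1e6)
}
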