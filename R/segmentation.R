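## ---- segmentation: region growing, skeleton graphs, centerlines -------------

## linear (0-based) index from 1-based (i,j,k) voxel indices
.lin0 <- function(ijk, d) {
  (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + (ijk[, 1] - 1)
}

#' Seeded region growing on a grayscale volume
#'
#' Grows the 26-connected set reachable from the seed voxels through voxels
#' whose intensity is within `tolerance` of the running mean of the accepted
#' region. Deterministic (FIFO) given identical inputs. A seed that is
#' itself out of tolerance relative to the seed mean contributes nothing;
#' if no seed is accepted an empty mask is returned with a warning.
#'
#' @param vol a `voxel_volume` of kind "grayscale".
#' @param seeds matrix of 1-based voxel indices, columns (ix, iy, iz).
#' @param tolerance intensity tolerance.
#' @return a `voxel_volume` of kind "mask" (logical data).
#' @export
region_grow <- function(vol, seeds, tolerance) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (any(seeds < 1) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed outside the volume")
  acc <- cpp_region_grow(as.numeric(vol$data), as.integer(d),
                         as.integer(.lin0(seeds, d)), tolerance)
  if (!any(acc)) warning("no seed voxel within tolerance: empty mask")
  new_voxel_volume(array(acc, dim = d), vol$voxel_size_um, vol$origin,
                   "mask", vol$label_map)
}

#' Extract a binary mask for one label of a labelled volume
#' @param vol a `voxel_volume` of kind "labels".
#' @param label label name (see `COLUMN_LABELS`).
#' @return a `voxel_volume` of kind "mask".
#' @export
label_mask <- function(vol, label = "root") {
  stopifnot(vol$kind == "labels")
  new_voxel_volume(vol$data == vol$label_map[[label]], vol$voxel_size_um,
                   vol$origin, "mask", vol$label_map)
}

## 26-connected component labels of a mask volume
.components <- function(mask_vol) {
  d <- dim(mask_vol$data)
  lab <- cpp_label_components(as.logical(mask_vol$data), as.integer(d))
  array(lab, dim = d)
}

#' Skeletonize a tubular binary mask into a skeleton graph
#'
#' Per 26-connected component, a one-voxel-wide medial path is traced by
#' (1) finding the component's geodesic diameter endpoints with a double
#' breadth-first sweep, (2) refining each endpoint to the deepest voxel
#' (maximal distance-to-background) in its neighbourhood, and (3) running a
#' shortest path between them with step costs inversely weighted by the
#' chamfer distance transform, which pins the path to the medial ridge.
#' Suited to unbranched tubes (roots, artificial pores); branch topology is
#' out of scope.
#'
#' @param mask_vol a `voxel_volume` of kind "mask" (or "labels", in which
#'   case `label` selects the structure).
#' @param label label name used when `mask_vol` is a label volume.
#' @return a `skeleton_graph`: list with `nodes` (data.frame: node, component,
#'   x_mm, y_mm, z_mm, radius_mm) and `edges` (data.frame: from, to). Nodes
#'   are ordered along each component's path.
#' @export
skeletonize <- function(mask_vol, label = "root") {
  if (mask_vol$kind == "labels") mask_vol <- label_mask(mask_vol, label)
  d <- dim(mask_vol$data)
  h <- mask_vol$voxel_size_um / 1000
  empty <- list(nodes = data.frame(node = integer(), component = integer(),
                                   x_mm = numeric(), y_mm = numeric(),
                                   z_mm = numeric(), radius_mm = numeric()),
                edges = data.frame(from = integer(), to = integer()))
  class(empty) <- "skeleton_graph"
  if (!any(mask_vol$data)) return(empty)

  comp <- .components(mask_vol)
  dt <- array(cpp_chamfer_dt(as.logical(mask_vol$data), as.integer(d), h),
              dim = d)
  ncomp <- max(comp)
  nodes <- list(); edges <- list(); offset <- 0L
  for (ci in seq_len(ncomp)) {
    idx <- which(comp == ci)
    ijk <- arrayInd(idx, d)
    g <- .voxel_graph(ijk, d, h, dt[idx])
    path <- .medial_path(g, ijk, dt[idx], h)
    np <- length(path)
    xyz <- cbind(mask_vol$origin[1] + (ijk[path, 1] - 1) * h,
                 mask_vol$origin[2] + (ijk[path, 2] - 1) * h,
                 mask_vol$origin[3] + (ijk[path, 3] - 1) * h)
    nodes[[ci]] <- data.frame(node = offset + seq_len(np), component = ci,
                              x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
                              radius_mm = dt[idx][path])
    if (np > 1)
      edges[[ci]] <- data.frame(from = offset + seq_len(np - 1),
                                to = offset + 2:np)
    offset <- offset + np
  }
  out <- list(nodes = do.call(rbind, nodes),
              edges = if (length(edges)) do.call(rbind, edges) else
                data.frame(from = integer(), to = integer()))
  class(out) <- "skeleton_graph"
  out
}

## build an igraph over the component's voxels (26-adjacency); edge weight =
## euclidean step length / mean clearance of its endpoints
.voxel_graph <- function(ijk, d, h, dtv) {
  nv <- nrow(ijk)
  lin <- .lin0(ijk, d)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0 & offs$c == 0), ]
  ## keep only "positive" half to avoid duplicate edges
  offs <- offs[offs$c > 0 | (offs$c == 0 & (offs$b > 0 |
                                              (offs$b == 0 & offs$a > 0))), ]
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    a <- offs$a[r]; b <- offs$b[r]; cc <- offs$c[r]
    nb <- cbind(ijk[, 1] + a, ijk[, 2] + b, ijk[, 3] + cc)
    okb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(okb)) next
    nlin <- .lin0(nb[okb, , drop = FALSE], d)
    j <- match(nlin, lin)
    i <- which(okb)[!is.na(j)]
    j <- j[!is.na(j)]
    if (!length(i)) next
    steplen <- h * sqrt(a^2 + b^2 + cc^2)
    ef <- c(ef, i); et <- c(et, j)
    ew <- c(ew, steplen / ((dtv[i] + dtv[j]) / 2 + h / 2))
  }
  igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew), directed = FALSE,
    vertices = data.frame(name = seq_len(nv)))
}

## medial path: double BFS (unweighted) for diameter endpoints, refine each
## endpoint to the locally deepest voxel, then DT-weighted shortest path
.medial_path <- function(g, ijk, dtv, h) {
  nv <- nrow(ijk)
  if (nv == 1) return(1L)
  far <- function(from) {
    dd <- igraph::distances(g, v = from, weights = NA)
    which.max(dd)
  }
  e1 <- far(1L)
  e2 <- far(e1)
  refine <- function(e) {
    rad <- max(2, ceiling(dtv[e] / h) + 1)
    dd <- as.numeric(igraph::distances(g, v = e, weights = NA))
    near <- which(dd <= rad)
    near[which.max(dtv[near])]
  }
  e1 <- refine(e1); e2 <- refine(e2)
  if (e1 == e2) return(e1)
  sp <- igraph::shortest_paths(g, from = e1, to = e2, weights = NULL,
                               output = "vpath")$vpath[[1]]
  as.integer(igraph::as_ids(sp))
}

#' Extract ordered centerlines from a skeleton graph
#'
#' One polyline per skeleton component: the component's medial path, ordered
#' proximal (smallest z endpoint) to distal, smoothed with a `smooth_mm`
#' moving average; radius is the mean node clearance.
#'
#' @param g a `skeleton_graph` from [skeletonize()].
#' @param smooth_mm moving-average window (mm).
#' @param min_points drop components with fewer nodes than this.
#' @return list of `root_polyline`s.
#' @export
extract_centerlines <- function(g, smooth_mm = 1, min_points = 3) {
  if (!nrow(g$nodes)) return(list())
  out <- list()
  for (ci in unique(g$nodes$component)) {
    nd <- g$nodes[g$nodes$component == ci, , drop = FALSE]
    if (nrow(nd) < min_points) next
    pts <- as.matrix(nd[, c("x_mm", "y_mm", "z_mm")])
    if (pts[1, 3] > pts[nrow(pts), 3]) pts <- pts[nrow(pts):1, , drop = FALSE]
    pts <- .moving_average_path(pts, smooth_mm)
    keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2) > 1e-12)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2) next
    out[[length(out) + 1L]] <- root_polyline(
      pts, root_id = sprintf("skel_%d", ci),
      radius_mm = max(mean(nd$radius_mm), 1e-3))
  }
  out
}

## arc-length moving average smoother
.moving_average_path <- function(pts, window_mm) {
  if (nrow(pts) < 3 || window_mm <= 0) return(pts)
  arc <- cum_arclength(pts)
  half <- window_mm / 2
  sm <- pts
  for (i in seq_len(nrow(pts))) {
    w <- which(abs(arc - arc[i]) <= half)
    sm[i, ] <- colMeans(pts[w, , drop = FALSE])
  }
  sm
}

#' Fit vertical cylinders to a pore mask
#'
#' Per 26-connected component: axis from the (x, y) centroid, z-extent from
#' the voxel range (padded half a voxel each end), radius from
#' `sqrt(volume / (pi * length))`. Components that are not vertical tubes
#' (horizontal spread large relative to the fitted radius, or too short)
#' are flagged with a warning and skipped.
#'
#' @param mask_vol a `voxel_volume` of kind "mask" (or "labels", using the
#'   "pore" label).
#' @return list of `cylinder`s.
#' @export
fit_pore_cylinders <- function(mask_vol) {
  if (mask_vol$kind == "labels") mask_vol <- label_mask(mask_vol, "pore")
  if (!any(mask_vol$data)) return(list())
  d <- dim(mask_vol$data)
  h <- mask_vol$voxel_size_um / 1000
  comp <- .components(mask_vol)
  out <- list()
  for (ci in seq_len(max(comp))) {
    idx <- which(comp == ci)
    ijk <- arrayInd(idx, d)
    x <- mask_vol$origin[1] + (ijk[, 1] - 1) * h
    y <- mask_vol$origin[2] + (ijk[, 2] - 1) * h
    z <- mask_vol$origin[3] + (ijk[, 3] - 1) * h
    len <- max(z) - min(z) + h
    vol_mm3 <- length(idx) * h^3
    radius <- sqrt(vol_mm3 / (pi * len))
    horiz_sd <- sqrt(stats::var(x) + stats::var(y))
    if (len < 4 * radius || horiz_sd > 1.5 * radius) {
      warning(sprintf("component %d is not a vertical tube; skipped", ci))
      next
    }
    out[[length(out) + 1L]] <- cylinder(
      c(mean(x), mean(y), min(z) - h / 2),
      c(mean(x), mean(y), max(z) + h / 2),
      radius_mm = radius, pore_id = sprintf("fit_P%d", length(out) + 1L))
  }
  out
}
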