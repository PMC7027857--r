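#' @useDynLib rootpore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois dpois qt pt approx optimize aov shapiro.test
#' @importFrom utils head tail write.csv read.csv
NULL

## ---- coordinate conventions -------------------------------------------------
## All coordinates are in mm. z increases downward from the soil surface
## (z = depth); x and y are centred on the column axis. Polyline points run
## proximal (seed end) to distal (tip).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector has no direction")
  v / n
}

#' Construct a root centerline polyline
#'
#' An ordered 3D polyline (proximal to distal) representing one root axis,
#' with a constant radius. Points are given in mm with z = depth.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), at least 2 rows.
#' @param root_id identifier for the root.
#' @param radius_mm root radius in mm (> 0).
#' @return an object of class `root_polyline`.
#' @export
root_polyline <- function(points, root_id = "root", radius_mm = 0.3) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z)")
  if (nrow(points) < 2) stop("a polyline needs at least 2 points")
  if (!all(is.finite(points))) stop("polyline points must be finite")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg < 1e-9)) stop("consecutive polyline points must be distinct")
  colnames(points) <- c("x", "y", "z")
  structure(list(root_id = root_id, points = points, radius_mm = radius_mm),
            class = "root_polyline")
}

#' Construct a vertical (or general) cylinder
#'
#' Cylinders model the artificial macropores: `top` is the shallow end
#' (smaller z), `bottom` the deep end.
#'
#' @param top,bottom numeric length-3 points (mm); `top[3] < bottom[3]`.
#' @param radius_mm cylinder radius in mm (> 0).
#' @param pore_id identifier.
#' @return an object of class `cylinder`.
#' @export
cylinder <- function(top, bottom, radius_mm, pore_id = "pore") {
  top <- as.numeric(top); bottom <- as.numeric(bottom)
  if (length(top) != 3 || length(bottom) != 3) stop("top/bottom must be length-3")
  if (!(top[3] < bottom[3])) stop("cylinder top must be shallower than bottom")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(pore_id = pore_id, top = top, bottom = bottom,
                 radius_mm = radius_mm),
            class = "cylinder")
}

#' Total arc length of a polyline
#'
#' @param p a `root_polyline` (or bare 3-column matrix).
#' @return total arc length in mm.
#' @export
arc_length <- function(p) {
  pts <- if (inherits(p, "root_polyline")) p$points else as.matrix(p)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

## cumulative arc length at each vertex (starts at 0)
cum_arclength <- function(pts) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a polyline at a fixed arc-length step
#'
#' Linear interpolation along the polyline at arc positions
#' `seq(0, L, by = step_mm)` plus the final vertex, so total length is
#' preserved to within one step per vertex.
#'
#' @param p a `root_polyline` or 3-column matrix.
#' @param step_mm arc-length step in mm.
#' @return list with `points` (matrix) and `arc` (arc length of each point).
#' @export
resample_polyline <- function(p, step_mm = 0.5) {
  pts <- if (inherits(p, "root_polyline")) p$points else as.matrix(p)
  arc <- cum_arclength(pts)
  L <- arc[length(arc)]
  s <- seq(0, L, by = step_mm)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  out <- cbind(
    approx(arc, pts[, 1], xout = s, ties = "ordered")$y,
    approx(arc, pts[, 2], xout = s, ties = "ordered")$y,
    approx(arc, pts[, 3], xout = s, ties = "ordered")$y
  )
  colnames(out) <- c("x", "y", "z")
  list(points = out, arc = s)
}

## point on the polyline at arc length s (clamped to [0, L])
point_at_arclength <- function(pts, s) {
  arc <- cum_arclength(pts)
  s <- min(max(s, 0), arc[length(arc)])
  c(approx(arc, pts[, 1], xout = s, ties = "ordered")$y,
    approx(arc, pts[, 2], xout = s, ties = "ordered")$y,
    approx(arc, pts[, 3], xout = s, ties = "ordered")$y)
}

#' Angle between two 3-vectors in degrees
#'
#' @param u,v numeric length-3 vectors (not necessarily unit).
#' @return angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("angle with a zero vector is undefined")
  d <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Local growth direction of a root at a given arc position
#'
#' The direction is the principal axis of a total-least-squares 3D line fit
#' to the polyline resampled at `resample_mm` within the arc-length window
#' `[s - window_mm, s]` (side `"pre"`) or `[s, s + window_mm]` (side
#' `"post"`), oriented in the direction of growth (proximal to distal).
#' Windows truncated by the ends of the root are used as long as at least
#' `min_window_mm` of arc is available; shorter windows raise a condition of
#' class `rootpore_insufficient_arc` which callers map to "indeterminate".
#'
#' @param p a `root_polyline`.
#' @param s_mm arc position of the window anchor, mm.
#' @param window_mm window length, mm (default 20, the trajectory-comparison
#'   window used throughout).
#' @param side `"pre"` (before `s_mm`) or `"post"` (after).
#' @param min_window_mm minimum usable window, mm (default 5).
#' @param resample_mm resampling step inside the window, mm.
#' @return unit length-3 vector.
#' @export
direction_at <- function(p, s_mm, window_mm = 20, side = c("pre", "post"),
                         min_window_mm = 5, resample_mm = 0.5) {
  side <- match.arg(side)
  pts <- p$points
  arc <- cum_arclength(pts)
  L <- arc[length(arc)]
  if (side == "pre") {
    lo <- max(0, s_mm - window_mm); hi <- min(s_mm, L)
  } else {
    lo <- max(0, s_mm); hi <- min(s_mm + window_mm, L)
  }
  if (hi - lo < min_window_mm - 1e-9) {
    stop(structure(
      class = c("rootpore_insufficient_arc", "error", "condition"),
      list(message = sprintf(
        "only %.2f mm of arc available on the %s side (need >= %g mm)",
        hi - lo, side, min_window_mm), call = sys.call(-1))))
  }
  s <- seq(lo, hi, by = resample_mm)
  if (s[length(s)] < hi - 1e-9) s <- c(s, hi)
  w <- cbind(approx(arc, pts[, 1], xout = s, ties = "ordered")$y,
             approx(arc, pts[, 2], xout = s, ties = "ordered")$y,
             approx(arc, pts[, 3], xout = s, ties = "ordered")$y)
  ctr <- colMeans(w)
  d <- svd(sweep(w, 2, ctr))$v[, 1]
  chord <- w[nrow(w), ] - w[1, ]
  if (sum(d * chord) < 0) d <- -d
  .unit(d)
}

## ---- point / polyline to cylinder distances --------------------------------

#' Surface separation between points and a cylinder
#'
#' Vectorized distance from each point (optionally carrying its own radius,
#' e.g. a root centerline point) to the surface of a solid cylinder, with
#' end-cap handling, floored at 0 when the surfaces touch or overlap.
#'
#' @param points 3-column matrix of points (mm).
#' @param cyl a `cylinder`.
#' @param point_radius_mm radius carried by the points (0 for bare points).
#' @return numeric vector of separations (mm, >= 0).
#' @export
cylinder_surface_distance <- function(points, cyl, point_radius_mm = 0) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  axis_xy <- cyl$top[1:2]
  radial <- sqrt((points[, 1] - axis_xy[1])^2 + (points[, 2] - axis_xy[2])^2)
  dz <- pmax(cyl$top[3] - points[, 3], points[, 3] - cyl$bottom[3], 0)
  dr <- pmax(radial - cyl$radius_mm, 0)
  dist_solid <- ifelse(dz == 0, dr, ifelse(dr == 0, dz, sqrt(dz^2 + dr^2)))
  pmax(dist_solid - point_radius_mm, 0)
}

#' Minimum surface-to-surface distance between a root and a pore
#'
#' Minimum over the whole centerline of the separation between the root
#' surface (centerline offset by the root radius) and the cylinder surface,
#' with end-cap handling; 0 iff the surfaces touch or overlap. Computed by a
#' coarse arc-length scan refined by 1D convex minimisation on the
#' bracketing sub-arcs.
#'
#' @param p a `root_polyline`.
#' @param cyl a `cylinder`.
#' @param coarse_mm coarse scan step (mm).
#' @return minimum separation in mm (>= 0).
#' @export
min_surface_distance <- function(p, cyl, coarse_mm = 0.1) {
  rs <- resample_polyline(p, coarse_mm)
  d <- cylinder_surface_distance(rs$points, cyl, p$radius_mm)
  best <- min(d)
  if (best == 0) return(0)
  ## refine around every coarse sample close to the minimum
  cand <- which(d <= best + 2 * coarse_mm)
  pts <- p$points
  arcv <- cum_arclength(pts)
  f <- function(s) {
    q <- c(approx(arcv, pts[, 1], xout = s, ties = "ordered")$y,
           approx(arcv, pts[, 2], xout = s, ties = "ordered")$y,
           approx(arcv, pts[, 3], xout = s, ties = "ordered")$y)
    cylinder_surface_distance(matrix(q, ncol = 3), cyl, p$radius_mm)
  }
  L <- arcv[length(arcv)]
  for (i in cand) {
    lo <- max(0, rs$arc[i] - coarse_mm)
    hi <- min(L, rs$arc[i] + coarse_mm)
    if (hi > lo) {
      opt <- optimize(f, c(lo, hi), tol = 1e-7)
      best <- min(best, opt$objective)
    }
  }
  max(best, 0)
}

## Rodrigues rotation of vector v about (unit) axis k by ang degrees
rotate_about_axis <- function(v, k, ang_deg) {
  k <- .unit(k)
  a <- ang_deg * pi / 180
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## a unit vector perpendicular to d, at azimuth phi (radians) within d's
## perpendicular plane
perp_at_azimuth <- function(d, phi) {
  d <- .unit(d)
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(pracma_cross(d, ref))
  e2 <- pracma_cross(d, e1)
  cos(phi) * e1 + sin(phi) * e2
}

## ---- CSV interfaces ---------------------------------------------------------

#' Write root centerlines to CSV
#'
#' Columns: column_id, root_id, point_index (0-based), x_mm, y_mm, z_mm,
#' radius_mm.
#'
#' @param roots list of `root_polyline`s.
#' @param path output file.
#' @param column_id column identifier stored with every row.
#' @export
write_centerlines_csv <- function(roots, path, column_id = "col") {
  rows <- lapply(roots, function(r) {
    n <- nrow(r$points)
    data.frame(column_id = column_id, root_id = r$root_id,
               point_index = seq_len(n) - 1L,
               x_mm = r$points[, 1], y_mm = r$points[, 2], z_mm = r$points[, 3],
               radius_mm = r$radius_mm)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read root centerlines from CSV
#'
#' @param path file written by [write_centerlines_csv()].
#' @return named list (by column_id) of lists of `root_polyline`s.
#' @export
read_centerlines_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$column_id), function(dc) {
    lapply(split(dc, dc$root_id), function(dr) {
      dr <- dr[order(dr$point_index), ]
      root_polyline(as.matrix(dr[, c("x_mm", "y_mm", "z_mm")]),
                    root_id = dr$root_id[1], radius_mm = dr$radius_mm[1])
    })
  })
  out
}

#' Write pore cylinders to CSV
#'
#' Columns: column_id, pore_id, x_mm, y_mm, z_top_mm, z_bottom_mm, radius_mm.
#'
#' @param pores list of `cylinder`s (vertical).
#' @param path output file.
#' @param column_id column identifier.
#' @export
write_pores_csv <- function(pores, path, column_id = "col") {
  d <- do.call(rbind, lapply(pores, function(p) {
    data.frame(column_id = column_id, pore_id = p$pore_id,
               x_mm = p$top[1], y_mm = p$top[2],
               z_top_mm = p$top[3], z_bottom_mm = p$bottom[3],
               radius_mm = p$radius_mm)
  }))
  write.csv(d, path, row.names = FALSE)
}

#' Read pore cylinders from CSV
#' @param path file written by [write_pores_csv()].
#' @return list of `cylinder`s.
#' @export
read_pores_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    cylinder(c(d$x_mm[i], d$y_mm[i], d$z_top_mm[i]),
             c(d$x_mm[i], d$y_mm[i], d$z_bottom_mm[i]),
             radius_mm = d$radius_mm[i], pore_id = d$pore_id[i])
  })
}
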