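## ---- mesocosm construction --------------------------------------------------

#' Label codes used in voxelized columns
#' @export
COLUMN_LABELS <- c(background = 0L, topsoil = 1L, subsoil = 2L,
                   pore = 3L, root = 4L, inner_wall = 5L)

#' Parametric description of the soil-column mesocosm
#'
#' Defaults describe the experimental design: a 64 mm x 170 mm column with a
#' 55 mm subsoil layer packed at 1.2 (loose) or 1.6 (compact) g cm-3 under
#' 1.1 g cm-3 topsoil, nine vertical macropores of 0.8 mm diameter and 45 mm
#' length leaving a 10 mm soil cap below the topsoil, a 20 mm inner guide
#' column, and seeds planted 20 mm below the soil surface.
#'
#' @param outer_diameter_mm,outer_height_mm outer column dimensions.
#' @param subsoil_height_mm thickness of the bottom (subsoil) layer.
#' @param subsoil_bulk_density_g_cm3 1.2 (loose) or 1.6 (compact).
#' @param topsoil_bulk_density_g_cm3 topsoil packing density.
#' @param inner_diameter_mm,inner_length_mm inner guide column.
#' @param pore_count number of artificial macropores.
#' @param pore_diameter_mm,pore_length_mm macropore dimensions.
#' @param pore_top_gap_mm soil cap between pore tops and the topsoil boundary.
#' @param planting_depth_mm seed depth below the soil surface.
#' @return an object of class `column_spec`.
#' @export
column_spec <- function(outer_diameter_mm = 64, outer_height_mm = 170,
                        subsoil_height_mm = 55,
                        subsoil_bulk_density_g_cm3 = 1.6,
                        topsoil_bulk_density_g_cm3 = 1.1,
                        inner_diameter_mm = 20, inner_length_mm = 120,
                        pore_count = 9, pore_diameter_mm = 0.8,
                        pore_length_mm = 45, pore_top_gap_mm = 10,
                        planting_depth_mm = 20) {
  spec <- list(outer_diameter_mm = outer_diameter_mm,
               outer_height_mm = outer_height_mm,
               subsoil_height_mm = subsoil_height_mm,
               subsoil_bulk_density_g_cm3 = subsoil_bulk_density_g_cm3,
               topsoil_bulk_density_g_cm3 = topsoil_bulk_density_g_cm3,
               inner_diameter_mm = inner_diameter_mm,
               inner_length_mm = inner_length_mm,
               pore_count = pore_count,
               pore_diameter_mm = pore_diameter_mm,
               pore_length_mm = pore_length_mm,
               pore_top_gap_mm = pore_top_gap_mm,
               planting_depth_mm = planting_depth_mm)
  if (any(unlist(spec) <= 0)) stop("all column_spec fields must be positive")
  if (pore_length_mm + pore_top_gap_mm > subsoil_height_mm)
    stop("pore_length + pore_top_gap must fit inside the subsoil layer")
  if (inner_diameter_mm >= outer_diameter_mm)
    stop("inner column must be narrower than the outer column")
  structure(spec, class = "column_spec")
}

#' Serialize / restore a column spec
#'
#' Written as a YAML mapping whose keys are exactly the `column_spec` fields.
#'
#' @param spec a `column_spec`.
#' @param path file path.
#' @export
write_column_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
}

#' @rdname write_column_spec
#' @export
read_column_spec <- function(path) {
  do.call(column_spec, yaml::read_yaml(path))
}

#' Build the artificial macropores of a column
#'
#' Vertical cylinders spanning depths `outer_height - pore_length` to
#' `outer_height` (pores are formed by a rod inserted through the base, so
#' they terminate at the column bottom). The jig layout places one axial
#' pore plus the remaining pores equally spaced on a circle of
#' `ring_radius_mm`, keeping all pores under the inner-column footprint
#' through which roots are funnelled.
#'
#' @param spec a `column_spec`.
#' @param ring_radius_mm radius of the pore ring (mm).
#' @return list of `cylinder`s.
#' @export
build_pores <- function(spec, ring_radius_mm = 8) {
  n <- spec$pore_count
  r <- spec$pore_diameter_mm / 2
  z_top <- spec$outer_height_mm - spec$pore_length_mm
  z_bot <- spec$outer_height_mm
  if (z_top < spec$outer_height_mm - spec$subsoil_height_mm)
    stop("pores would extend above the subsoil layer")
  centers <- matrix(0, nrow = n, ncol = 2)
  if (n > 1) {
    ang <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
    centers[-1, ] <- cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang))
  }
  ## feasibility: pairwise clearance and containment
  if (n > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (min(dd) <= 2 * r) stop("pore layout infeasible: pores overlap")
  }
  if (any(sqrt(rowSums(centers^2)) + r >= spec$outer_diameter_mm / 2))
    stop("pore layout infeasible: pores outside the column")
  lapply(seq_len(n), function(i) {
    cylinder(c(centers[i, ], z_top), c(centers[i, ], z_bot),
             radius_mm = r, pore_id = sprintf("P%d", i))
  })
}

## ---- voxelization -----------------------------------------------------------

new_voxel_volume <- function(data, voxel_size_um, origin, kind,
                             label_map = COLUMN_LABELS) {
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 origin = origin, kind = kind, label_map = label_map),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume (%s): %d x %d x %d voxels at %g um\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$voxel_size_um))
  invisible(x)
}

## voxel center coordinates along each axis
voxel_axes <- function(vol) {
  h <- vol$voxel_size_um / 1000
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * h,
       y = vol$origin[2] + (seq_len(d[2]) - 1) * h,
       z = vol$origin[3] + (seq_len(d[3]) - 1) * h)
}

#' Voxelize a column scene into a labelled volume
#'
#' Bulk regions (soil layers, inner wall) label a voxel by the region
#' containing its center. The thin artificial pores are rasterized
#' area-preservingly: per slice, the voxels with the largest cross-section
#' coverage are labelled until the disk area is matched, so pore volume is
#' conserved even when the voxel edge approaches the pore radius. Label
#' precedence is root > pore > inner wall > soil. The volume covers the
#' full column unless `bounds` gives an ROI as
#' `list(x = c(lo, hi), y = ..., z = ...)` in mm.
#'
#' @param spec a `column_spec`.
#' @param pores list of `cylinder`s.
#' @param roots list of `root_polyline`s (may be empty).
#' @param voxel_size_um voxel edge in micrometres (default 200; the working
#'   resolution — full columns at scan resolution are not desk-scale).
#' @param bounds optional ROI crop in mm.
#' @return a `voxel_volume` of kind "labels" (integer data).
#' @export
voxelize <- function(spec, pores, roots = list(), voxel_size_um = 200,
                     bounds = NULL) {
  h <- voxel_size_um / 1000
  R <- spec$outer_diameter_mm / 2
  if (is.null(bounds)) {
    bounds <- list(x = c(-R - h, R + h), y = c(-R - h, R + h),
                   z = c(0, spec$outer_height_mm))
  }
  nx <- max(2L, as.integer(ceiling(diff(bounds$x) / h)))
  ny <- max(2L, as.integer(ceiling(diff(bounds$y) / h)))
  nz <- max(2L, as.integer(ceiling(diff(bounds$z) / h)))
  if (as.double(nx) * ny * nz > 2e9)
    stop("requested grid exceeds 2e9 voxels; crop with `bounds` or coarsen ",
         "`voxel_size_um`")
  origin <- c(bounds$x[1] + h / 2, bounds$y[1] + h / 2, bounds$z[1] + h / 2)
  xs <- origin[1] + (seq_len(nx) - 1) * h
  ys <- origin[2] + (seq_len(ny) - 1) * h
  zs <- origin[3] + (seq_len(nz) - 1) * h

  lab <- array(COLUMN_LABELS[["background"]], dim = c(nx, ny, nz))
  rad2 <- outer(xs^2, ys^2, `+`)        # squared radius from the column axis
  in_col <- rad2 <= R^2
  subsoil_top <- spec$outer_height_mm - spec$subsoil_height_mm
  r_in <- spec$inner_diameter_mm / 2
  wall_thick <- 2                        # mm, PVC inner-column wall
  in_wall <- rad2 > r_in^2 & rad2 <= (r_in + wall_thick)^2
  inner_top <- max(0, subsoil_top - spec$inner_length_mm)

  ## area-preserving cross-sections for each (vertical) pore: identical in
  ## every slice, so compute the voxel selection once per pore
  pore_sections <- lapply(pores, function(p) {
    ix <- which(abs(xs - p$top[1]) <= p$radius_mm + h)
    iy <- which(abs(ys - p$top[2]) <= p$radius_mm + h)
    if (!length(ix) || !length(iy)) return(NULL)
    grid <- expand.grid(ix = ix, iy = iy)
    sub <- seq(-h / 2 + h / 12, h / 2 - h / 12, length.out = 6)
    cover <- vapply(seq_len(nrow(grid)), function(g) {
      cx <- xs[grid$ix[g]] - p$top[1]; cy <- ys[grid$iy[g]] - p$top[2]
      mean(outer((cx + sub)^2, (cy + sub)^2, `+`) <= p$radius_mm^2)
    }, 0)
    n_label <- min(sum(cover > 0), max(1L, round(pi * p$radius_mm^2 / h^2)))
    grid[order(-cover)[seq_len(n_label)], , drop = FALSE]
  })

  for (k in seq_len(nz)) {
    z <- zs[k]
    if (z < 0 || z > spec$outer_height_mm) next
    plane <- matrix(COLUMN_LABELS[["background"]], nx, ny)
    soil_lab <- if (z < subsoil_top) COLUMN_LABELS[["topsoil"]] else
      COLUMN_LABELS[["subsoil"]]
    plane[in_col] <- soil_lab
    if (z < subsoil_top && z >= inner_top)
      plane[in_col & in_wall] <- COLUMN_LABELS[["inner_wall"]]
    for (pidx in seq_along(pores)) {
      p <- pores[[pidx]]
      sec <- pore_sections[[pidx]]
      if (!is.null(sec) && z >= p$top[3] && z <= p$bottom[3])
        plane[cbind(sec$ix, sec$iy)] <- COLUMN_LABELS[["pore"]]
    }
    lab[, , k] <- plane
  }

  ## roots: mark voxels whose center is within radius_mm of the centerline
  for (r in roots) {
    rs <- resample_polyline(r, min(h / 2, 0.1))$points
    rad <- r$radius_mm
    nb <- ceiling(rad / h) + 1L
    for (i in seq_len(nrow(rs))) {
      q <- rs[i, ]
      ci <- round((q[1] - origin[1]) / h) + 1
      cj <- round((q[2] - origin[2]) / h) + 1
      ck <- round((q[3] - origin[3]) / h) + 1
      ii <- max(1, ci - nb):min(nx, ci + nb)
      jj <- max(1, cj - nb):min(ny, cj + nb)
      kk <- max(1, ck - nb):min(nz, ck + nb)
      if (!length(ii) || !length(jj) || !length(kk)) next
      dx2 <- (xs[ii] - q[1])^2; dy2 <- (ys[jj] - q[2])^2; dz2 <- (zs[kk] - q[3])^2
      box <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rad^2
      cur <- lab[ii, jj, kk, drop = FALSE]
      cur[box] <- COLUMN_LABELS[["root"]]
      lab[ii, jj, kk] <- cur
    }
  }
  new_voxel_volume(lab, voxel_size_um, origin, "labels")
}

#' Synthesize a grayscale CT phantom from a labelled volume
#'
#' Attenuation is piecewise constant per label: pores (air) darkest, roots
#' dark, soil brightness increasing with bulk density (subsoil default scales
#' the topsoil mean by the density ratio), plus i.i.d. Gaussian noise.
#'
#' @param labels a `voxel_volume` of kind "labels".
#' @param spec the `column_spec` (supplies the subsoil density default).
#' @param means named per-label mean intensities; defaults
#'   `pore = 0.05, root = 0.25, topsoil = 0.55,
#'   subsoil = 0.55 * density / 1.1, background = 0, inner_wall = 0.85`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed; identical seeds give bit-identical volumes.
#' @return a `voxel_volume` of kind "grayscale".
#' @export
synthesize_grayscale <- function(labels, spec = column_spec(), means = NULL,
                                 noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(labels, "voxel_volume"), labels$kind == "labels")
  if (is.null(means)) {
    means <- c(background = 0, topsoil = 0.55,
               subsoil = 0.55 * spec$subsoil_bulk_density_g_cm3 / 1.1,
               pore = 0.05, root = 0.25, inner_wall = 0.85)
  }
  g <- array(0, dim = dim(labels$data))
  for (nm in names(labels$label_map)) {
    g[labels$data == labels$label_map[[nm]]] <- means[[nm]]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    g <- g + array(rnorm(length(g), 0, noise_sd), dim = dim(g))
  }
  new_voxel_volume(g, labels$voxel_size_um, labels$origin, "grayscale",
                   labels$label_map)
}

## ---- TIFF + sidecar I/O -----------------------------------------------------

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' Pages are z slices (rows = y, columns = x); the sidecar records
#' `voxel_size_um`, `origin_mm`, `axis_order` ("zyx") and, for label
#' volumes, the label map. Label data are scaled into \[0,1\] for storage
#' and restored on read.
#'
#' @param vol a `voxel_volume`.
#' @param tiff_path,json_path output paths (sidecar defaults to
#'   `<tiff_path>.json`).
#' @export
write_volume <- function(vol, tiff_path, json_path = paste0(tiff_path, ".json")) {
  d <- dim(vol$data)
  maxlab <- max(vol$label_map)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- t(vol$data[, , k])                 # -> rows = y, cols = x
    if (vol$kind == "labels") m <- m / maxlab
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  jsonlite::write_json(
    list(voxel_size_um = vol$voxel_size_um, origin_mm = vol$origin,
         axis_order = "zyx", kind = vol$kind,
         label_map = as.list(vol$label_map)),
    json_path, auto_unbox = TRUE, digits = NA)
}

#' Read a volume written by [write_volume()]
#' @param tiff_path,json_path paths used at write time.
#' @return a `voxel_volume`.
#' @export
read_volume <- function(tiff_path, json_path = paste0(tiff_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) a[, , k] <- t(pages[[k]])
  label_map <- unlist(meta$label_map)
  if (meta$kind == "labels") {
    a <- array(as.integer(round(a * max(label_map))), dim = dim(a))
  }
  new_voxel_volume(a, meta$voxel_size_um, meta$origin_mm, meta$kind, label_map)
}
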