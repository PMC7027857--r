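## ---- interaction detection and classification -------------------------------

#' Detect root-macropore interactions
#'
#' A root-pore interaction is a contact episode where the surface-to-surface
#' separation between root and pore is at most one voxel. The centerline is
#' resampled at `sample_mm`; arc positions meeting the threshold are grouped
#' into episodes, and episodes of the same (root, pore) pair separated by
#' less than `merge_mm` of arc are merged (first contact kept).
#'
#' @param roots list of `root_polyline`s (or a `simulate_column` result).
#' @param pores list of `cylinder`s.
#' @param voxel_size_um detection threshold: one voxel, in micrometres
#'   (default 45, the scan resolution).
#' @param sample_mm centerline resampling step for detection.
#' @param merge_mm arc separation under which same-pore contacts merge.
#' @return data.frame with one row per event: `root_id`, `pore_id`,
#'   `contact_arclength_mm`, `min_separation_mm`.
#' @export
detect_interactions <- function(roots, pores, voxel_size_um = 45,
                                sample_mm = 0.05, merge_mm = 15) {
  if (!is.null(roots$roots)) roots <- roots$roots
  thr <- voxel_size_um / 1000
  out <- list()
  for (r in roots) {
    rs <- resample_polyline(r, sample_mm)
    coarse_idx <- unique(c(seq(1, nrow(rs$points), by = 20), nrow(rs$points)))
    coarse <- rs$points[coarse_idx, , drop = FALSE]
    for (p in pores) {
      ## coarse prefilter: a 1 mm-spaced scan cannot miss by more than ~0.5 mm
      if (min(cylinder_surface_distance(coarse, p, r$radius_mm)) > thr + 2)
        next
      sep <- cylinder_surface_distance(rs$points, p, r$radius_mm)
      hit <- which(sep <= thr)
      if (!length(hit)) next
      arcs <- rs$arc[hit]
      gap <- which(diff(arcs) >= merge_mm)
      starts <- c(1, gap + 1)
      ends <- c(gap, length(arcs))
      for (e in seq_along(starts)) {
        idx <- hit[starts[e]:ends[e]]
        out[[length(out) + 1L]] <- data.frame(
          root_id = r$root_id, pore_id = p$pore_id,
          contact_arclength_mm = rs$arc[idx[1]],
          min_separation_mm = min(sep[idx]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(root_id = character(), pore_id = character(),
                      contact_arclength_mm = numeric(),
                      min_separation_mm = numeric()))
  }
  do.call(rbind, out)
}

#' In-pore arc length following a contact
#'
#' Longest contiguous arc length, starting at or after the contact arc
#' position, over which the root centerline lies within the pore's radius of
#' the pore axis (and within its z-extent), measured on a 0.1 mm resampling.
#'
#' @param root a `root_polyline`.
#' @param pore a `cylinder`.
#' @param contact_arclength_mm first-contact arc position from
#'   [detect_interactions()].
#' @param sample_mm resampling step.
#' @return arc length in mm (0 if the centerline never enters the pore).
#' @export
inside_arc_length <- function(root, pore, contact_arclength_mm,
                              sample_mm = 0.1) {
  rs <- resample_polyline(root, sample_mm)
  keep <- rs$arc >= contact_arclength_mm - sample_mm
  pts <- rs$points[keep, , drop = FALSE]
  arc <- rs$arc[keep]
  if (!nrow(pts)) return(0)
  radial <- sqrt((pts[, 1] - pore$top[1])^2 + (pts[, 2] - pore$top[2])^2)
  inside <- radial <= pore$radius_mm &
    pts[, 3] >= pore$top[3] - 1e-9 & pts[, 3] <= pore$bottom[3] + 1e-9
  if (!any(inside)) return(0)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- 0
  for (i in which(runs$values)) {
    best <- max(best, arc[ends[i]] - arc[starts[i]])
  }
  best
}

#' Classify an interaction as colonization or crossing
#'
#' Colonizing means the root grew inside the pore for more than
#' `threshold_mm` (strictly) following the interaction; otherwise the root
#' crossed.
#'
#' @param inside_length_mm from [inside_arc_length()].
#' @param threshold_mm classification threshold (default 15).
#' @return `"colonize"` or `"cross"`.
#' @export
classify_colonization <- function(inside_length_mm, threshold_mm = 15) {
  if (inside_length_mm > threshold_mm) "colonize" else "cross"
}

#' Classify the trajectory outcome of an interaction
#'
#' Colonization implies a trajectory change by definition. For crossing
#' events, growth directions are fitted over `window_mm` of arc before the
#' contact and after leaving the pore (post-window origin = contact +
#' in-pore length); the trajectory changed if the angle between them
#' exceeds `angle_deg` (strictly). If either window has less than 5 mm of
#' root the event is indeterminate.
#'
#' @param root a `root_polyline`.
#' @param contact_arclength_mm,inside_length_mm event geometry.
#' @param classification `"colonize"` or `"cross"`.
#' @param window_mm direction-fit window (default 20).
#' @param angle_deg change threshold in degrees (default 3).
#' @return list with `trajectory` (`"changed"`, `"unchanged"` or
#'   `"indeterminate"`) and `deflection_deg` (measured angle; `NA` for
#'   colonizers and indeterminate events).
#' @export
classify_trajectory <- function(root, contact_arclength_mm, inside_length_mm,
                                classification, window_mm = 20,
                                angle_deg = 3) {
  if (classification == "colonize") {
    return(list(trajectory = "changed", deflection_deg = NA_real_))
  }
  res <- tryCatch({
    pre <- direction_at(root, contact_arclength_mm, window_mm, "pre")
    post <- direction_at(root, contact_arclength_mm + inside_length_mm,
                         window_mm, "post")
    ang <- angle_between(pre, post)
    list(trajectory = if (ang > angle_deg) "changed" else "unchanged",
         deflection_deg = ang)
  }, rootpore_insufficient_arc = function(e) {
    list(trajectory = "indeterminate", deflection_deg = NA_real_)
  })
  res
}

#' Detect and fully classify all interactions in a column
#'
#' Runs [detect_interactions()], [inside_arc_length()],
#' [classify_colonization()] and [classify_trajectory()] over a set of
#' centerlines, producing the events table.
#'
#' @param roots list of `root_polyline`s (or a `simulate_column` result).
#' @param pores list of `cylinder`s.
#' @param voxel_size_um detection threshold (one voxel, um).
#' @param column_id identifier attached to the rows.
#' @param ... passed to [detect_interactions()].
#' @return data.frame with columns `column_id`, `root_id`, `pore_id`,
#'   `contact_arclength_mm`, `min_separation_mm`, `inside_length_mm`,
#'   `classification`, `trajectory`, `deflection_deg`.
#' @export
classify_events <- function(roots, pores, voxel_size_um = 45,
                            column_id = "col", ...) {
  if (!is.null(roots$roots)) {
    if (!is.null(roots$column_id)) column_id <- roots$column_id
    roots <- roots$roots
  }
  ev <- detect_interactions(roots, pores, voxel_size_um, ...)
  n <- nrow(ev)
  if (!n) {
    return(data.frame(column_id = character(), root_id = character(),
                      pore_id = character(), contact_arclength_mm = numeric(),
                      min_separation_mm = numeric(),
                      inside_length_mm = numeric(),
                      classification = character(), trajectory = character(),
                      deflection_deg = numeric()))
  }
  root_map <- stats::setNames(roots, vapply(roots, `[[`, "", "root_id"))
  pore_map <- stats::setNames(pores, vapply(pores, `[[`, "", "pore_id"))
  inside <- numeric(n); cls <- character(n); trj <- character(n)
  defl <- numeric(n)
  for (i in seq_len(n)) {
    r <- root_map[[ev$root_id[i]]]
    p <- pore_map[[ev$pore_id[i]]]
    inside[i] <- inside_arc_length(r, p, ev$contact_arclength_mm[i])
    cls[i] <- classify_colonization(inside[i])
    tr <- classify_trajectory(r, ev$contact_arclength_mm[i], inside[i], cls[i])
    trj[i] <- tr$trajectory
    defl[i] <- tr$deflection_deg
  }
  data.frame(column_id = column_id, root_id = ev$root_id,
             pore_id = ev$pore_id,
             contact_arclength_mm = ev$contact_arclength_mm,
             min_separation_mm = ev$min_separation_mm,
             inside_length_mm = inside, classification = cls,
             trajectory = trj, deflection_deg = defl)
}

#' Summarise one column's interaction counts
#'
#' @param roots,pores,... as in [classify_events()].
#' @param meta optional named list/row of design labels merged into the
#'   result (e.g. genotype, treatment, block).
#' @return one-row data.frame of counts: `n_interactions`, `n_colonize`,
#'   `n_cross`, `n_changed`, `n_unchanged`, `n_indeterminate`.
#' @export
analyze_column <- function(roots, pores, meta = NULL, ...) {
  cid <- if (!is.null(roots$column_id)) roots$column_id
    else if (!is.null(meta$column_id)) meta$column_id else "col"
  ev <- classify_events(roots, pores, column_id = cid, ...)
  res <- data.frame(
    column_id = cid,
    n_interactions = nrow(ev),
    n_colonize = sum(ev$classification == "colonize"),
    n_cross = sum(ev$classification == "cross"),
    n_changed = sum(ev$trajectory == "changed"),
    n_unchanged = sum(ev$trajectory == "unchanged"),
    n_indeterminate = sum(ev$trajectory == "indeterminate"))
  if (!is.null(meta)) {
    for (nm in setdiff(names(meta), names(res))) res[[nm]] <- meta[[nm]]
  }
  res
}
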