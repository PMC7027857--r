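## ---- behaviour profiles -----------------------------------------------------

#' Per-treatment, per-genotype interaction behaviour profile
#'
#' Probabilities driving the simulator: `p_colonize` is the probability that
#' a root-pore interaction results in pore colonization; `p_change_overall`
#' is the probability that an interaction results in a trajectory change
#' (colonization always counts as a change, so
#' `p_change_overall >= p_colonize` is required).
#'
#' @param treatment `"loose_1.2"` or `"compact_1.6"`.
#' @param genotype `"Rht-B1a"`, `"Rht-B1c"` or `"combined"`.
#' @param p_colonize,p_change_overall probabilities in \[0, 1\].
#' @param interaction_rate mean root-pore interactions per column (>= 0).
#' @param max_interactions cap on interactions per column.
#' @return an object of class `behavior_profile`.
#' @export
behavior_profile <- function(treatment, genotype, p_colonize, p_change_overall,
                             interaction_rate = 1.78, max_interactions = 7L) {
  stopifnot(p_colonize >= 0, p_colonize <= 1,
            p_change_overall >= 0, p_change_overall <= 1,
            interaction_rate >= 0)
  if (p_change_overall < p_colonize)
    stop("p_change_overall must be >= p_colonize: colonization implies a ",
         "trajectory change")
  structure(list(treatment = treatment, genotype = genotype,
                 p_colonize = p_colonize,
                 p_change_overall = p_change_overall,
                 interaction_rate = interaction_rate,
                 max_interactions = as.integer(max_interactions)),
            class = "behavior_profile")
}

#' Packaged default behaviour profiles
#'
#' Observed interaction outcome rates by soil treatment and genotype:
#' colonization 80.0% (Rht-B1a) and 62.5% (Rht-B1c) in compact soil versus
#' 7.7% and 15% in loose soil; trajectory change 92.9% / 78.6% (compact)
#' and 20% / 25% (loose); combined-genotype rates 68.8% / 12.5%
#' (colonization) and 76.0% / 21.0% (change). Interaction rate 1.78 per
#' column, capped at 7.
#'
#' @return named list of `behavior_profile`s keyed `"treatment|genotype"`.
#' @export
default_profiles <- function() {
  mk <- function(trt, gen, pc, pch)
    behavior_profile(trt, gen, pc, pch)
  profs <- list(
    mk("compact_1.6", "combined", 0.688, 0.760),
    mk("loose_1.2",   "combined", 0.125, 0.210),
    mk("compact_1.6", "Rht-B1a",  0.800, 0.929),
    mk("compact_1.6", "Rht-B1c",  0.625, 0.786),
    mk("loose_1.2",   "Rht-B1a",  0.077, 0.200),
    mk("loose_1.2",   "Rht-B1c",  0.150, 0.250)
  )
  names(profs) <- vapply(profs, function(p)
    paste(p$treatment, p$genotype, sep = "|"), "")
  profs
}

#' Look up a profile for a treatment x genotype cell
#' @param profiles list from [default_profiles()] (or same shape).
#' @param treatment,genotype cell labels.
#' @export
get_profile <- function(profiles, treatment, genotype) {
  key <- paste(treatment, genotype, sep = "|")
  if (is.null(profiles[[key]]))
    stop("no behaviour profile for cell ", key)
  profiles[[key]]
}

#' Write / read behaviour profiles as a YAML config
#' @param profiles list of `behavior_profile`s.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  yaml::write_yaml(lapply(profiles, unclass), path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(behavior_profile, p))
}

#' Conditional trajectory-change probability for crossing events
#'
#' Colonization counts as a trajectory change by definition, so the overall
#' change rate decomposes as
#' `p_change_overall = p_colonize + (1 - p_colonize) * p_change_given_cross`.
#' This solves for the crossing-conditional probability, clamped to \[0, 1\].
#'
#' @param profile a `behavior_profile`.
#' @return probability a crossing event changes trajectory.
#' @export
derive_conditional_change <- function(profile) {
  pc <- profile$p_colonize; po <- profile$p_change_overall
  if (pc >= 1) {
    if (po < 1) stop("p_colonize = 1 with p_change_overall < 1 is inconsistent")
    return(1)
  }
  min(1, max(0, (po - pc) / (1 - pc)))
}

## ---- growth model -----------------------------------------------------------

#' Growth-model tuning parameters
#'
#' @param step_mm growth step (mm).
#' @param jitter_sd_deg per-step Gaussian angular jitter (degrees).
#' @param pull weight of the pull toward the current waypoint per step
#'   (direction persistence is `1 - pull`).
#' @param deflect_change_deg,deflect_nochange_deg deflection-magnitude bands
#'   (degrees) drawn uniformly for change / no-change crossing events. The
#'   defaults keep truth well away from the 3-degree decision boundary.
#' @export
growth_params <- function(step_mm = 0.5, jitter_sd_deg = 0.4, pull = 0.25,
                          deflect_change_deg = c(8, 45),
                          deflect_nochange_deg = c(0, 1.5)) {
  list(step_mm = step_mm, jitter_sd_deg = jitter_sd_deg, pull = pull,
       deflect_change_deg = deflect_change_deg,
       deflect_nochange_deg = deflect_nochange_deg)
}

## persistence walk from `from` to exactly `to`: each step blends the
## jittered previous direction with the direction to the waypoint
guided_walk <- function(from, to, dir0 = NULL, growth = growth_params()) {
  step <- growth$step_mm
  total <- sqrt(sum((to - from)^2))
  pts <- matrix(0, nrow = ceiling(total / step) * 3 + 4, ncol = 3)
  pts[1, ] <- from
  n <- 1L
  pos <- from
  dir <- if (is.null(dir0)) .unit(to - from) else .unit(dir0)
  max_steps <- nrow(pts) - 2L
  for (i in seq_len(max_steps)) {
    rest <- to - pos
    d <- sqrt(sum(rest^2))
    if (d <= step) break
    jit <- rnorm(1, 0, growth$jitter_sd_deg)
    dir_j <- rotate_about_axis(dir, perp_at_azimuth(dir, runif(1, 0, 2 * pi)),
                               jit)
    dir <- .unit((1 - growth$pull) * dir_j + growth$pull * (rest / d))
    pos <- pos + step * dir
    n <- n + 1L
    pts[n, ] <- pos
  }
  if (sqrt(sum((to - pts[n, ])^2)) > 1e-9) {
    n <- n + 1L
    pts[n, ] <- to
  }
  pts[seq_len(n), , drop = FALSE]
}

## fast approximate clearance check: min surface separation of a sampled
## point set to each pore (used for construction validation)
.min_sep_to_pores <- function(pts, pores, point_radius) {
  vapply(pores, function(p)
    min(cylinder_surface_distance(pts, p, point_radius)), 0)
}

## construct one crossing root for `pore`; returns list(points, contact_row,
## deflection) or NULL on geometric failure
.make_cross_root <- function(seed_pt, pore, deflect_deg, spec, r_root, growth) {
  R_out <- spec$outer_diameter_mm / 2
  pore_top <- pore$top[3]
  alpha <- runif(1, 8, 20) * pi / 180        # approach tilt from vertical
  phi <- runif(1, 0, 2 * pi)
  u <- c(cos(phi), sin(phi))                 # horizontal approach heading
  z_hi <- min(pore_top + 20, pore$bottom[3] - 8)
  z_c <- runif(1, pore_top + 3, max(pore_top + 4, z_hi))
  contact <- c(pore$top[1:2] - (pore$radius_mm + r_root) * u, z_c)
  d_pre <- .unit(c(sin(alpha) * u, cos(alpha)))
  L_straight <- min(45, (z_c - spec$planting_depth_mm - 12) / cos(alpha))
  if (L_straight < 26) return(NULL)
  a0 <- contact - L_straight * d_pre

  ## post direction: rotate d_pre by the drawn deflection about a random
  ## perpendicular axis, keeping growth downward and inside the column
  ok <- FALSE
  for (try in 1:25) {
    d_post <- rotate_about_axis(d_pre, perp_at_azimuth(d_pre, runif(1, 0, 2 * pi)),
                                deflect_deg)
    end_pt <- contact + 30 * d_post
    if (d_post[3] > 0.25 &&
        sqrt(sum(end_pt[1:2]^2)) < R_out - 1.5 &&
        end_pt[3] < spec$outer_height_mm - 1) { ok <- TRUE; break }
  }
  if (!ok) return(NULL)

  p1 <- guided_walk(seed_pt, a0, dir0 = c(0, 0, 1), growth = growth)
  g2 <- growth; g2$pull <- 0.35
  p2 <- guided_walk(a0, contact, dir0 = d_pre, growth = g2)
  p3 <- guided_walk(contact, end_pt, dir0 = d_post, growth = g2)
  pts <- rbind(p1, p2[-1, , drop = FALSE], p3[-1, , drop = FALSE])
  list(points = pts, contact_row = nrow(p1) + nrow(p2) - 1L,
       deflection = deflect_deg)
}

## construct one colonizing root: approach the pore mouth from above, then
## follow the pore axis to the column base
.make_colonize_root <- function(seed_pt, pore, spec, r_root, growth) {
  pore_top <- pore$top[3]
  alpha <- runif(1, 3, 10) * pi / 180
  phi <- runif(1, 0, 2 * pi)
  u <- c(cos(phi), sin(phi))
  mouth <- c(pore$top[1:2], pore_top)
  d_pre <- .unit(c(sin(alpha) * u, cos(alpha)))
  L_straight <- min(45, (pore_top - spec$planting_depth_mm - 12) / cos(alpha))
  if (L_straight < 26) return(NULL)
  a0 <- mouth - L_straight * d_pre

  p1 <- guided_walk(seed_pt, a0, dir0 = c(0, 0, 1), growth = growth)
  g2 <- growth; g2$pull <- 0.35
  p2 <- guided_walk(a0, mouth, dir0 = d_pre, growth = g2)
  ## in-pore run: down the axis with tiny confined jitter
  zin <- seq(pore_top + growth$step_mm, pore$bottom[3], by = growth$step_mm)
  if (zin[length(zin)] < pore$bottom[3] - 1e-9) zin <- c(zin, pore$bottom[3])
  off <- matrix(rnorm(2 * length(zin), 0, 0.02), ncol = 2)
  rr <- sqrt(rowSums(off^2))
  cap <- pmin(rr, 0.1) / pmax(rr, 1e-12)
  off <- off * cap
  p3 <- cbind(pore$top[1] + off[, 1], pore$top[2] + off[, 2], zin)
  pts <- rbind(p1, p2[-1, , drop = FALSE], p3)
  list(points = pts, contact_row = nrow(p1) + nrow(p2) - 1L, deflection = NA_real_)
}

## construct a filler root that avoids all pores
.make_filler_root <- function(seed_pt, pores, spec, r_root, growth) {
  R_out <- spec$outer_diameter_mm / 2
  for (try in 1:50) {
    th <- runif(1, 0, 2 * pi)
    rr <- runif(1, min(12, R_out - 8), R_out - 6)
    target <- c(rr * cos(th), rr * sin(th), spec$outer_height_mm)
    pts <- guided_walk(seed_pt, target, dir0 = c(0, 0, 1), growth = growth)
    if (min(.min_sep_to_pores(pts, pores, r_root)) > 1) return(pts)
  }
  NULL
}

## truncated-Poisson interaction count
.draw_n_interactions <- function(rate, max_n) {
  k <- 0:max_n
  p <- dpois(k, rate)
  sample(k, 1, prob = p / sum(p))
}

#' Simulate one soil column (event-driven mode)
#'
#' Draws the number of root-pore interactions from a Poisson distribution
#' with mean `profile$interaction_rate`, truncated at
#' `profile$max_interactions`, and constructs one root per interaction: the
#' root descends from the planting position with direction persistence and
#' angular jitter, approaches a uniformly chosen pore to surface contact,
#' and then either colonizes (probability `p_colonize`: enters at the pore
#' mouth and follows the axis to the pore bottom, never exiting) or crosses
#' (continues at least 20 mm past contact, deflected by an angle drawn from
#' the change / no-change bands according to the crossing-conditional change
#' probability). Non-interacting filler roots are added for realism; they
#' are constructed to stay clear (> 1 mm) of every pore. Each constructed
#' root is validated (inside the column; touches only its intended pore,
#' with > 0.5 mm clearance to all others) and rebuilt on failure, up to
#' `max_retries`.
#'
#' @param spec a `column_spec`.
#' @param pores list of `cylinder`s from [build_pores()].
#' @param profile a `behavior_profile`.
#' @param seed RNG seed for this column.
#' @param n_interactions optional forced interaction count (otherwise drawn).
#' @param n_filler number of non-interacting filler roots.
#' @param root_radius_mm root radius.
#' @param growth a [growth_params()] list.
#' @param column_id identifier attached to outputs.
#' @param max_retries construction retries per event before erroring.
#' @return list with `column_id`, `roots` (list of `root_polyline`),
#'   and `truth` (the truth-log data.frame: one row per interaction with
#'   `root_id`, `pore_id`, `contact_arclength_mm`, `outcome_colonize`,
#'   `outcome_change`, `deflection_deg`).
#' @export
simulate_column <- function(spec, pores, profile, seed = NULL,
                            n_interactions = NULL, n_filler = 2,
                            root_radius_mm = 0.3, growth = growth_params(),
                            column_id = "col1", max_retries = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_interactions))
    n_interactions <- .draw_n_interactions(profile$interaction_rate,
                                           profile$max_interactions)
  p_cross_change <- derive_conditional_change(profile)
  r_seed_max <- max(2, spec$inner_diameter_mm / 2 - 2)
  roots <- list()
  truth <- list()
  for (ev in seq_len(n_interactions)) {
    colonize <- runif(1) < profile$p_colonize
    change <- if (colonize) TRUE else runif(1) < p_cross_change
    built <- NULL
    for (try in seq_len(max_retries)) {
      th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * r_seed_max
      seed_pt <- c(rr * cos(th), rr * sin(th), spec$planting_depth_mm)
      pore_i <- sample(length(pores), 1)
      pore <- pores[[pore_i]]
      cand <- if (colonize) {
        .make_colonize_root(seed_pt, pore, spec, root_radius_mm, growth)
      } else {
        defl <- if (change) runif(1, growth$deflect_change_deg[1],
                                  growth$deflect_change_deg[2])
        else runif(1, growth$deflect_nochange_deg[1],
                   growth$deflect_nochange_deg[2])
        .make_cross_root(seed_pt, pore, defl, spec, root_radius_mm, growth)
      }
      if (is.null(cand)) next
      ## validate: inside column, clear of all non-target pores
      radial <- sqrt(cand$points[, 1]^2 + cand$points[, 2]^2)
      if (max(radial) > spec$outer_diameter_mm / 2 - 0.5) next
      if (max(cand$points[, 3]) > spec$outer_height_mm + 1e-6) next
      others <- pores[-pore_i]
      if (length(others) &&
          min(.min_sep_to_pores(cand$points, others, root_radius_mm)) <= 0.5)
        next
      built <- list(cand = cand, pore = pore)
      break
    }
    if (is.null(built))
      stop("could not construct interaction geometry after ", max_retries,
           " retries")
    root_id <- sprintf("%s_R%d", column_id, ev)
    rp <- root_polyline(built$cand$points, root_id = root_id,
                        radius_mm = root_radius_mm)
    contact_arc <- cum_arclength(rp$points)[built$cand$contact_row]
    roots[[length(roots) + 1L]] <- rp
    truth[[length(truth) + 1L]] <- data.frame(
      column_id = column_id, root_id = root_id, pore_id = built$pore$pore_id,
      contact_arclength_mm = contact_arc,
      outcome_colonize = colonize, outcome_change = change,
      deflection_deg = built$cand$deflection)
  }
  for (f in seq_len(n_filler)) {
    th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * r_seed_max
    seed_pt <- c(rr * cos(th), rr * sin(th), spec$planting_depth_mm)
    pts <- .make_filler_root(seed_pt, pores, spec, root_radius_mm, growth)
    if (!is.null(pts)) {
      roots[[length(roots) + 1L]] <-
        root_polyline(pts, root_id = sprintf("%s_F%d", column_id, f),
                      radius_mm = root_radius_mm)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    column_id = character(), root_id = character(), pore_id = character(),
    contact_arclength_mm = numeric(), outcome_colonize = logical(),
    outcome_change = logical(), deflection_deg = numeric())
  list(column_id = column_id, roots = roots, truth = truth)
}

## ---- experiment design ------------------------------------------------------

#' Randomized-block experiment design
#'
#' @param genotypes,treatments factor levels (defaults: the two near
#'   isogenic lines and the two packing densities).
#' @param replicates_per_cell columns per genotype x treatment cell.
#' @param blocks number of staggering-day blocks.
#' @param seed RNG seed for the randomized block assignment.
#' @return data.frame manifest: `column_id`, `genotype`, `treatment`,
#'   `block`, `seed` (per-column simulation seed).
#' @export
experiment_design <- function(genotypes = c("Rht-B1a", "Rht-B1c"),
                              treatments = c("loose_1.2", "compact_1.6"),
                              replicates_per_cell = 10, blocks = 6,
                              seed = 1) {
  set.seed(seed)
  d <- expand.grid(rep = seq_len(replicates_per_cell), genotype = genotypes,
                   treatment = treatments, stringsAsFactors = FALSE)
  n <- nrow(d)
  d$column_id <- sprintf("C%03d", seq_len(n))
  ## deal shuffled columns into blocks round-robin (near-equal sizes)
  ord <- sample(n)
  blk <- integer(n)
  blk[ord] <- rep_len(seq_len(blocks), n)
  d$block <- blk
  d$seed <- sample.int(.Machine$integer.max - 1, n)
  d[, c("column_id", "genotype", "treatment", "block", "seed")]
}

#' Simulate a full multi-column experiment
#'
#' One simulated column per design row, using the behaviour profile of that
#' row's genotype x treatment cell and the per-column seed from the design
#' (derived deterministically from the design's master seed).
#'
#' @param design manifest from [experiment_design()].
#' @param spec a `column_spec` (its subsoil density field is set per
#'   treatment internally; geometry is shared).
#' @param profiles profile list, e.g. [default_profiles()].
#' @param pores optional pore list (defaults to [build_pores()] on `spec`).
#' @param ... passed to [simulate_column()].
#' @return list with `design`, `columns` (list of simulate_column results)
#'   and `truth` (row-bound truth log).
#' @export
simulate_experiment <- function(design, spec = column_spec(),
                                profiles = default_profiles(),
                                pores = NULL, ...) {
  if (is.null(pores)) pores <- build_pores(spec)
  cols <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    prof <- get_profile(profiles, design$treatment[i], design$genotype[i])
    cols[[i]] <- simulate_column(spec, pores, prof, seed = design$seed[i],
                                 column_id = design$column_id[i], ...)
  }
  names(cols) <- design$column_id
  truth <- do.call(rbind, lapply(cols, `[[`, "truth"))
  rownames(truth) <- NULL
  list(design = design, columns = cols, truth = truth)
}

#' Simulate interactions until a target event count is reached
#'
#' Repeatedly simulates columns under one profile until at least
#' `n_events` interactions have been generated; used for per-arm recovery
#' runs.
#'
#' @param n_events minimum number of interaction events.
#' @param spec,pores,profile as in [simulate_column()].
#' @param seed master seed (per-column seeds derived from it).
#' @param ... passed to [simulate_column()].
#' @return list with `columns` (list), `truth` (combined truth log).
#' @export
simulate_interactions <- function(n_events, spec, pores, profile, seed = 1,
                                  ...) {
  set.seed(seed)
  max_cols <- ceiling(4 * n_events / max(profile$interaction_rate, 0.1))
  col_seeds <- sample.int(.Machine$integer.max - 1, max_cols)
  cols <- list(); total <- 0L; i <- 0L
  while (total < n_events && i < max_cols) {
    i <- i + 1L
    cid <- sprintf("A%04d", i)
    cl <- simulate_column(spec, pores, profile, seed = col_seeds[i],
                          column_id = cid, ...)
    cols[[cid]] <- cl
    total <- total + nrow(cl$truth)
  }
  truth <- do.call(rbind, lapply(cols, `[[`, "truth"))
  rownames(truth) <- NULL
  list(columns = cols, truth = truth)
}
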