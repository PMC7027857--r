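test_that("detection respects the one-voxel separation rule", {
  sc <- default_scene()
  ## root passing 5 mm clear of every pore: no events
  far <- root_polyline(cbind(20, 20, seq(20, 160, by = 1)), "far", 0.3)
  expect_equal(nrow(detect_interactions(list(far), sc$pores)), 0)

  ## root whose surface comes within 0.02 mm of a pore surface: one event
  p <- sc$pores[[1]]                       # axial pore
  x_touch <- p$radius_mm + 0.3 + 0.02
  near <- root_polyline(cbind(x_touch, 0, seq(120, 160, by = 0.5)), "near", 0.3)
  ev <- detect_interactions(list(near), sc$pores, voxel_size_um = 45)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pore_id, p$pore_id)
  expect_lte(ev$min_separation_mm, 0.045)

  ## 0.06 mm separation exceeds one 45 um voxel: no event
  x_off <- p$radius_mm + 0.3 + 0.06
  off <- root_polyline(cbind(x_off, 0, seq(120, 160, by = 0.5)), "off", 0.3)
  expect_equal(nrow(detect_interactions(list(off), sc$pores, 45)), 0)
})

test_that("same-pore contacts merge within 15 mm of arc and split beyond", {
  pore <- cylinder(c(0, 0, 10), c(0, 0, 90), 0.4, "P")
  mk_dips <- function(z_dips) {
    z <- seq(0, 80, by = 0.05)
    x <- rep(0.76, length(z))
    for (zd in z_dips) x <- pmin(x, 0.76 - 0.11 * exp(-((z - zd) / 1.5)^2))
    root_polyline(cbind(x, 0, z), "dip", 0.25)
  }
  ## dips at arcs ~40 and ~48: gap < 15 mm, one merged event (first kept)
  ev1 <- detect_interactions(list(mk_dips(c(40, 48))), list(pore), 45)
  expect_equal(nrow(ev1), 1)
  expect_lt(abs(ev1$contact_arclength_mm - 39), 2)
  ## dips at ~40 and ~60: two events
  ev2 <- detect_interactions(list(mk_dips(c(40, 60))), list(pore), 45)
  expect_equal(nrow(ev2), 2)
})

test_that("detection count is monotone in the voxel size", {
  sc <- default_scene()
  prof <- get_profile(default_profiles(), "compact_1.6", "combined")
  cl <- simulate_column(sc$spec, sc$pores, prof, seed = 91, n_interactions = 5)
  counts <- sapply(c(45, 100, 250, 500), function(v)
    nrow(detect_interactions(cl, sc$pores, voxel_size_um = v)))
  expect_true(all(diff(counts) >= 0))
})

test_that("in-pore arc length measures axial runs and chords", {
  pore <- cylinder(c(0, 0, 125), c(0, 0, 170), 0.4, "P")
  ## colonizer following the axis for 30 mm then stopping
  approach <- cbind(0, 0, seq(100, 125, by = 0.5))
  inside <- cbind(0, 0, seq(125.5, 155, by = 0.5))
  col30 <- root_polyline(rbind(approach, inside), "c30", 0.3)
  contact <- 25                              # arc where z reaches ~125
  expect_equal(inside_arc_length(col30, pore, contact), 30, tolerance = 0.2)

  ## perpendicular crosser through the 0.8 mm pore: chord <= 0.9 mm
  cross <- root_polyline(cbind(seq(-10, 10, by = 0.05), 0, 140), "x", 0.25)
  ev <- detect_interactions(list(cross), list(pore), 45)
  expect_equal(nrow(ev), 1)
  inlen <- inside_arc_length(cross, pore, ev$contact_arclength_mm)
  expect_lte(inlen, 0.9)
  expect_gt(inlen, 0)

  ## no in-pore points at all
  graze <- root_polyline(cbind(0.66, 0, seq(130, 150, 0.5)), "g", 0.25)
  expect_equal(inside_arc_length(graze, pore, 0), 0)
})

test_that("colonization threshold is strict at 15 mm", {
  expect_equal(classify_colonization(30), "colonize")
  expect_equal(classify_colonization(0.8), "cross")
  expect_equal(classify_colonization(15.0), "cross")   # "at least >15 mm"
  expect_equal(classify_colonization(15.0001), "colonize")
})

test_that("trajectory classification applies the 3-degree rule strictly", {
  mk_bend <- function(deg) {
    a <- deg * pi / 180
    pre <- cbind(0, 0, seq(0, 30, by = 0.25))
    d <- c(sin(a), 0, cos(a))
    post <- t(sapply(seq(0.25, 30, by = 0.25), function(s) c(0, 0, 30) + s * d))
    root_polyline(rbind(pre, post), "bend", 0.3)
  }
  ## straight crosser: unchanged at 0 degrees
  straight <- root_polyline(cbind(0, 0, seq(0, 60, 0.5)), "s", 0.3)
  r0 <- classify_trajectory(straight, 30, 0, "cross")
  expect_equal(r0$trajectory, "unchanged")
  expect_lt(r0$deflection_deg, 1e-6)

  r20 <- classify_trajectory(mk_bend(20), 30, 0, "cross")
  expect_equal(r20$trajectory, "changed")
  expect_equal(r20$deflection_deg, 20, tolerance = 1e-3)

  ## strict boundary: just under 3 degrees is unchanged, just over changed
  expect_equal(classify_trajectory(mk_bend(2.999), 30, 0, "cross")$trajectory,
               "unchanged")
  expect_equal(classify_trajectory(mk_bend(3.001), 30, 0, "cross")$trajectory,
               "changed")

  ## colonization is a trajectory change by definition
  rc <- classify_trajectory(straight, 30, 20, "colonize")
  expect_equal(rc$trajectory, "changed")
  expect_true(is.na(rc$deflection_deg))

  ## too little root after the pore: indeterminate
  stub <- root_polyline(cbind(0, 0, seq(0, 33, 0.5)), "stub", 0.3)
  ri <- classify_trajectory(stub, 30, 0, "cross")
  expect_equal(ri$trajectory, "indeterminate")
})

test_that("column summaries match ground truth and are label-invariant", {
  sc <- default_scene()
  ## empty column
  empty <- analyze_column(list(), sc$pores, meta = list(column_id = "E1"))
  expect_equal(empty$n_interactions, 0)
  expect_equal(empty$n_colonize + empty$n_cross, 0)

  prof <- get_profile(default_profiles(), "compact_1.6", "combined")
  cl <- simulate_column(sc$spec, sc$pores, prof, seed = 19, n_interactions = 6)
  res <- analyze_column(cl, sc$pores,
                        meta = list(genotype = "Rht-B1a",
                                    treatment = "compact_1.6"))
  expect_equal(res$n_interactions, 6)
  expect_equal(res$n_colonize, sum(cl$truth$outcome_colonize))
  expect_equal(res$n_changed, sum(cl$truth$outcome_change))
  expect_equal(res$n_colonize + res$n_cross, res$n_interactions)
  expect_equal(res$genotype, "Rht-B1a")

  ## relabeling roots leaves the counts unchanged
  rl <- cl$roots
  for (i in seq_along(rl)) rl[[i]]$root_id <- sprintf("renamed_%d", i)
  res2 <- analyze_column(rev(rl), sc$pores)
  expect_equal(res2[, c("n_interactions", "n_colonize", "n_cross",
                        "n_changed")],
               res[, c("n_interactions", "n_colonize", "n_cross",
                       "n_changed")],
               ignore_attr = TRUE)
})

test_that("compacted columns colonize more than loose ones", {
  sc <- default_scene()
  pr <- default_profiles()
  compact <- simulate_interactions(200, sc$spec, sc$pores,
                                   get_profile(pr, "compact_1.6", "combined"),
                                   seed = 23, n_filler = 0)
  loose <- simulate_interactions(200, sc$spec, sc$pores,
                                 get_profile(pr, "loose_1.2", "combined"),
                                 seed = 24, n_filler = 0)
  pct <- function(sim) {
    ev <- do.call(rbind, lapply(sim$columns, classify_events, sc$pores))
    100 * mean(ev$classification == "colonize")
  }
  expect_gt(pct(compact), pct(loose))
})
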