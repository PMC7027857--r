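test_that("region growing recovers piecewise-constant regions exactly", {
  vol <- straight_tube_volume(radius_mm = 0.6)
  g <- synthesize_grayscale(vol, column_spec(), noise_sd = 0)
  seed <- which(vol$data == COLUMN_LABELS[["root"]], arr.ind = TRUE)[1, ,
                                                                     drop = FALSE]
  m <- region_grow(g, seed, 0.05)
  expect_identical(as.vector(m$data),
                   as.vector(vol$data == COLUMN_LABELS[["root"]]))

  ## tolerance 0 on a constant region still returns that region
  m0 <- region_grow(g, seed, 0)
  expect_identical(as.vector(m0$data),
                   as.vector(vol$data == COLUMN_LABELS[["root"]]))
})

test_that("region growing survives noise at 3-sigma tolerance", {
  vol <- straight_tube_volume(radius_mm = 0.8)
  g <- synthesize_grayscale(vol, column_spec(), noise_sd = 0.03, seed = 12)
  truth <- vol$data == COLUMN_LABELS[["root"]]
  ijk <- which(truth, arr.ind = TRUE)
  ctr <- colMeans(ijk)
  seed <- ijk[which.min(rowSums(sweep(ijk, 2, ctr)^2)), , drop = FALSE]
  m <- region_grow(g, seed, 3 * 0.03)
  dice <- 2 * sum(m$data & truth) / (sum(m$data) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("an out-of-tolerance seed warns and yields an empty mask", {
  vol <- straight_tube_volume()
  g <- synthesize_grayscale(vol, column_spec(), noise_sd = 0)
  ## two seeds with very different intensities: running seed mean fits neither
  s_root <- which(vol$data == COLUMN_LABELS[["root"]], arr.ind = TRUE)[1, ]
  s_soil <- which(vol$data == COLUMN_LABELS[["topsoil"]], arr.ind = TRUE)[1, ]
  expect_warning(m <- region_grow(g, rbind(s_root, s_soil), 0.01), "empty")
  expect_false(any(m$data))
  expect_error(region_grow(g, rbind(c(0, 1, 1)), 0.1), "outside")
})

test_that("skeletons of straight tubes stay within one voxel of the axis", {
  vol <- straight_tube_volume(radius_mm = 1, x = 0.1, y = -0.2)
  sk <- skeletonize(vol, label = "root")
  expect_equal(length(unique(sk$nodes$component)), 1)
  off <- sqrt((sk$nodes$x_mm - 0.1)^2 + (sk$nodes$y_mm + 0.2)^2)
  expect_lte(sqrt(mean(off^2)), 0.2)            # 1 voxel RMS at 200 um
  ## acyclic: a path has exactly n - 1 edges
  expect_equal(nrow(sk$edges), nrow(sk$nodes) - 1)
  ## skeleton is a subset of the mask (all nodes carry positive clearance)
  expect_true(all(sk$nodes$radius_mm > 0))
})

test_that("disjoint tubes give separate skeleton components", {
  spec <- column_spec()
  r1 <- root_polyline(cbind(-5, 0, seq(60, 100, 0.5)), "a", 0.8)
  r2 <- root_polyline(cbind(5, 0, seq(60, 100, 0.5)), "b", 0.8)
  vol <- voxelize(spec, list(), list(r1, r2), voxel_size_um = 250,
                  bounds = list(x = c(-9, 9), y = c(-4, 4), z = c(56, 104)))
  sk <- skeletonize(vol, label = "root")
  expect_equal(length(unique(sk$nodes$component)), 2)
  expect_equal(nrow(sk$edges), nrow(sk$nodes) - 2)
  cls <- extract_centerlines(sk)
  expect_length(cls, 2)
})

test_that("centerline arc lengths match straight and helical truth", {
  vol <- straight_tube_volume(radius_mm = 1, z = c(60, 105))
  cl <- extract_centerlines(skeletonize(vol, label = "root"))
  expect_length(cl, 1)
  expect_lt(abs(arc_length(cl[[1]]) - 45) / 45, 0.02)
  ## proximal-to-distal ordering: z increases overall
  expect_lt(cl[[1]]$points[1, 3], cl[[1]]$points[nrow(cl[[1]]$points), 3])

  ## helix of radius 4 mm, pitch 12 mm, 2 turns
  t <- seq(0, 4 * pi, length.out = 600)
  helix <- cbind(4 * cos(t), 4 * sin(t), 70 + 12 * t / (2 * pi))
  hp <- root_polyline(helix, "h", radius_mm = 0.8)
  vol_h <- voxelize(column_spec(), list(), list(hp), voxel_size_um = 250,
                    bounds = list(x = c(-6, 6), y = c(-6, 6), z = c(66, 98)))
  cl_h <- extract_centerlines(skeletonize(vol_h, label = "root"))
  expect_length(cl_h, 1)
  true_len <- 2 * sqrt((2 * pi * 4)^2 + 12^2)
  expect_lt(abs(arc_length(cl_h[[1]]) - true_len) / true_len, 0.03)
})

test_that("empty masks give empty skeletons and centerline lists", {
  spec <- column_spec()
  vol <- voxelize(spec, list(), list(), voxel_size_um = 500,
                  bounds = list(x = c(-5, 5), y = c(-5, 5), z = c(60, 80)))
  sk <- skeletonize(vol, label = "root")
  expect_equal(nrow(sk$nodes), 0)
  expect_length(extract_centerlines(sk), 0)
  expect_length(fit_pore_cylinders(label_mask(vol, "pore")), 0)
})

test_that("pore cylinders are recovered from voxelized default pores", {
  sc <- default_scene()
  vol <- voxelize(sc$spec, sc$pores, voxel_size_um = 200,
                  bounds = list(x = c(-10, 10), y = c(-10, 10), z = c(120, 170)))
  fits <- fit_pore_cylinders(vol)
  expect_length(fits, 9)
  for (f in fits) {
    expect_lt(abs(f$radius_mm - 0.4), 0.1)
    expect_lt(abs(f$bottom[3] - f$top[3] - 45), 0.4)
    ## axis within one voxel of a true pore center
    d <- min(sapply(sc$pores, function(p)
      sqrt(sum((p$top[1:2] - f$top[1:2])^2))))
    expect_lte(d, 0.2)
  }
})

test_that("non-tubular components are flagged and skipped", {
  ## a flat slab is not a vertical tube
  spec <- column_spec()
  slab <- array(FALSE, dim = c(40, 40, 6))
  slab[5:35, 5:35, 2:5] <- TRUE
  vol <- structure(list(data = slab, voxel_size_um = 200,
                        origin = c(0, 0, 0), kind = "mask",
                        label_map = COLUMN_LABELS),
                   class = "voxel_volume")
  expect_warning(fits <- fit_pore_cylinders(vol), "not a vertical tube")
  expect_length(fits, 0)
})

test_that("classification is robust to the voxel representation", {
  ## noiseless phantoms: events classified from re-extracted centerlines match
  ## the classification from ground-truth centerlines (>= 5 voxels across the
  ## root diameter: 0.8 mm root at 150 um)
  sc <- default_scene()
  prof_col <- behavior_profile("compact_1.6", "combined", 1, 1)
  prof_chg <- behavior_profile("compact_1.6", "combined", 0, 1)
  prof_no <- behavior_profile("compact_1.6", "combined", 0, 0)
  cases <- list(col = list(prof = prof_col, seed = 61),
                chg = list(prof = prof_chg, seed = 62),
                no = list(prof = prof_no, seed = 63))
  for (nm in names(cases)) {
    cl <- simulate_column(sc$spec, sc$pores, cases[[nm]]$prof,
                          seed = cases[[nm]]$seed, n_interactions = 1,
                          n_filler = 0, root_radius_mm = 0.4)
    root <- cl$roots[[1]]
    ev_truth <- classify_events(cl, sc$pores)
    expect_equal(nrow(ev_truth), 1)

    bb <- apply(root$points, 2, range)
    bounds <- list(x = bb[, 1] + c(-2, 2), y = bb[, 2] + c(-2, 2),
                   z = c(max(0, bb[1, 3] - 2), min(170, bb[2, 3] + 2)))
    vol <- voxelize(sc$spec, sc$pores, list(root), voxel_size_um = 150,
                    bounds = bounds)
    g <- synthesize_grayscale(vol, sc$spec, noise_sd = 0)
    seed_ijk <- which(vol$data == COLUMN_LABELS[["root"]], arr.ind = TRUE)
    seed_ijk <- seed_ijk[which.min(seed_ijk[, 3]), , drop = FALSE]
    mask <- region_grow(g, seed_ijk, 0.05)
    recov <- extract_centerlines(skeletonize(mask))
    expect_length(recov, 1)
    recov[[1]]$radius_mm <- root$radius_mm
    ev_rec <- classify_events(recov, sc$pores, voxel_size_um = 150)
    expect_equal(nrow(ev_rec), 1)
    expect_equal(ev_rec$classification, ev_truth$classification)
    expect_equal(ev_rec$trajectory, ev_truth$trajectory)
  }
})
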