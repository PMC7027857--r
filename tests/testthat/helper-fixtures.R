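## shared fixtures and independent oracles

## smooth random 3D polyline (random walk with persistent direction)
random_polyline <- function(n = 100, step = 0.8, start = c(0, 0, 0),
                            dir = c(0, 0, 1), wobble = 0.15) {
  pts <- matrix(0, n, 3)
  pts[1, ] <- start
  d <- dir / sqrt(sum(dir^2))
  for (i in 2:n) {
    d <- d + rnorm(3, 0, wobble)
    d <- d / sqrt(sum(d^2))
    pts[i, ] <- pts[i - 1, ] + step * d
  }
  pts
}

## independent brute-force oracle: dense sampling of the polyline, distance
## to a vertical solid cylinder computed from first principles
brute_min_surface <- function(pts, radius_root, cyl, step = 0.01) {
  best <- Inf
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    seg <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = min(1, step / seg))
    for (t in ts) {
      q <- a + t * (b - a)
      rad <- sqrt((q[1] - cyl$top[1])^2 + (q[2] - cyl$top[2])^2)
      if (q[3] < cyl$top[3]) {
        dz <- cyl$top[3] - q[3]
      } else if (q[3] > cyl$bottom[3]) {
        dz <- q[3] - cyl$bottom[3]
      } else dz <- 0
      dr <- max(rad - cyl$radius_mm, 0)
      d <- if (dz == 0) dr else if (dr == 0) dz else sqrt(dz^2 + dr^2)
      best <- min(best, max(d - radius_root, 0))
    }
  }
  best
}

## 3D rotation matrix from axis + angle (independent of package internals)
rot_matrix <- function(axis, ang_deg) {
  k <- axis / sqrt(sum(axis^2))
  a <- ang_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

default_scene <- function() {
  spec <- column_spec()
  list(spec = spec, pores = build_pores(spec))
}

## straight-tube mask phantom: returns labelled volume containing one root
straight_tube_volume <- function(radius_mm = 1, x = 0.1, y = -0.2,
                                 z = c(60, 105), voxel_um = 200) {
  spec <- column_spec()
  root <- root_polyline(cbind(x, y, seq(z[1], z[2], by = 0.5)), "tube",
                        radius_mm = radius_mm)
  voxelize(spec, list(), list(root), voxel_size_um = voxel_um,
           bounds = list(x = c(x - 4, x + 4), y = c(y - 4, y + 4),
                         z = z + c(-4, 4)))
}
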