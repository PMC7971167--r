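test_that("Lloyd sampling: determinism, containment, uniformization", {
  p1 <- lloyd_disk_sample(250, 500, seed = 9, iterations = 25)
  p2 <- lloyd_disk_sample(250, 500, seed = 9, iterations = 25)
  expect_identical(p1$points, p2$points)
  r <- sqrt(rowSums(sweep(p1$points, 2, p1$center_um)^2))
  expect_lte(max(r), 500)
  expect_equal(nrow(unique(p1$points)), 250L)       # pairwise distinct

  # n = 1 relaxes to the disk center
  pc <- lloyd_disk_sample(1, 500, seed = 3, iterations = 40)
  expect_lt(sqrt(sum(pc$points^2)), 0.01 * 500)

  # CVT uniformization: nearest-neighbor CV drops below the random draw's
  nn_cv <- function(pts) {
    d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
    nn <- apply(d, 1, min)
    stats::sd(nn) / mean(nn)
  }
  p0 <- lloyd_disk_sample(100, 500, seed = 21, iterations = 0)
  p50 <- lloyd_disk_sample(100, 500, seed = 21, iterations = 50)
  expect_lt(nn_cv(p50$points), nn_cv(p0$points))
})

test_that("Jansonius bundles: arcuate course, disc termination, no raphe crossing", {
  # superior-temporal soma: arcs around the fovea, enters disc superiorly
  tr <- jansonius_path(c(-1, 1.5), "right")
  expect_false(tr$flagged)
  disc <- c(15, 2) * 0.286
  expect_equal(unname(tr$path_mm[nrow(tr$path_mm), ]), disc,
               tolerance = 1e-9)
  expect_gt(tr$path_mm[nrow(tr$path_mm) - 1, 2], disc[2])  # from above
  expect_gt(max(tr$path_mm[, 2]), 1.5)                     # arcs upward first

  # property sweep: finite arc length, disc termination, raphe inviolate
  u <- disc / sqrt(sum(disc^2))
  set.seed(4)
  for (i in 1:200) {
    st <- stats::runif(2, -3, 3)
    if (sqrt(sum((st - disc)^2)) < 0.5) next
    tr <- jansonius_path(st, "right")
    p <- tr$path_mm
    expect_equal(unname(p[nrow(p), ]), unname(disc), tolerance = 1e-9)
    seg <- sqrt(rowSums(diff(p)^2))
    expect_true(all(is.finite(seg)))
    # raphe: the temporal ray through the fovea; no path may cross it
    along <- p %*% u
    side <- p[, 2] * u[1] - p[, 1] * u[2]
    s <- sign(side[along < 0 & abs(side) > 1e-9])
    expect_lte(length(unique(s)), 1L)
  }
})

test_that("raphe starts take the superior branch and are flagged", {
  disc <- c(15, 2) * 0.286
  u <- disc / sqrt(sum(disc^2))
  st <- -2 * u                       # on the raphe, temporal of the fovea
  tr <- jansonius_path(st, "right")
  expect_true(tr$flagged)
  expect_gte(tr$phi0_deg, 0)
  expect_error(jansonius_path(disc, "right"), "optic disc")
})

test_that("hemifield mirror is exact under a symmetric parameterization", {
  par <- jansonius_params(disc_deg = c(15, 0), symmetric = TRUE)
  a <- jansonius_path(c(-1, 1.2), "right", params = par)
  b <- jansonius_path(c(-1, -1.2), "right", params = par)
  expect_equal(a$path_mm[, 1], b$path_mm[, 1], tolerance = 1e-8)
  expect_equal(a$path_mm[, 2], -b$path_mm[, 2], tolerance = 1e-8)
})

test_that("left-eye mirroring flips x and slope signs exactly", {
  tr_r <- jansonius_path(c(-1, 2), "right")
  tr_l <- jansonius_path(c(-1, 2), "left")
  expect_equal(tr_l$path_mm[, 1], -tr_r$path_mm[, 1])
  expect_equal(tr_l$path_mm[, 2], tr_r$path_mm[, 2])
  expect_equal(tr_l$slopes, -tr_r$slopes)
})

test_that("papillomacular bundles run straight along the disc-fovea axis", {
  # the model's degenerate (straightest) bundles hug the raphe axis between
  # disc and fovea; with the disc on the horizontal their slope is ~0
  par <- jansonius_params(disc_deg = c(15, 0))
  tr <- jansonius_path(c(2, 0.02), "right", params = par)
  sl <- tr$slopes[is.finite(tr$slopes)]
  expect_lt(max(abs(sl)), 0.15)
  # inside the inner power-law radius the course is exactly radial
  tr2 <- jansonius_path(c(3.6, 0.0), "right", params = par)
  sl2 <- tr2$slopes[is.finite(tr2$slopes)]
  expect_lt(max(abs(sl2)), 0.05)
})

test_that("3D embedding: ascent length, depth following, extension flag", {
  g <- small_patient()
  traj <- jansonius_path(c(-0.2, 0.1), "right")
  path <- embed_neuron(c(-0.2, 0.1), traj, g$retina,
                       array_center_mm = c(0, 0))
  expect_equal(attr(path, "ascent_um"), 40)       # 55 - 15
  expect_equal(as.numeric(path[1, 3]), 55)        # flat surface: s = 0
  # vertical segment truly vertical
  vert <- path[path[, 3] > 15 + 1e-9, , drop = FALSE]
  expect_lt(diff(range(vert[, 1])), 1e-9)
  # beyond the bend the axon rides the surface contour at 15 um depth
  horiz <- path[abs(path[, 3] - 15) < 1e-6, ]
  expect_gt(nrow(horiz), 100)
  # arc length covers the cable
  expect_gte(sum(sqrt(rowSums(diff(path)^2))), 3000)

  # undulating surface: axon z tracks surface + 15 within tolerance
  gu <- small_patient(height_fun = function(x, y) 20 * sin(x / 400))
  pu <- embed_neuron(c(-0.2, 0.1), traj, gu$retina,
                     array_center_mm = c(0, 0))
  in_ext <- abs(pu[, 1]) < 1400 & abs(pu[, 2]) < 1400 &
    seq_len(nrow(pu)) > 12
  zs <- surface_height(gu$retina, pu[in_ext, 1], pu[in_ext, 2])
  expect_lt(max(abs(pu[in_ext, 3] - (zs + 15))), 1.5)
})

test_that("axon slope ranges follow construction", {
  mk <- function(slope) {
    structure(list(path_mm = cbind(seq(-0.4, 0.4, 0.01),
                                   slope * seq(-0.4, 0.4, 0.01)),
                   slopes = rep(slope, 80)), class = "axon_trajectory")
  }
  flat <- axon_slope_range(list(mk(0), mk(0)), c(0, 0))
  expect_equal(flat$slope_range, c(0, 0))
  diag45 <- axon_slope_range(list(mk(1)), c(0, 0))
  expect_equal(diag45$slope_range, c(1, 1), tolerance = 1e-9)
  empty <- axon_slope_range(list(mk(0)), c(50, 50), radius_um = 10)
  expect_null(empty$slope_range)

  # qualitative sign/ordering of slopes with the electrode's vertical
  # offset from the raphe (as reported for the device's rows): inferior
  # electrodes see negative-slope overlying axons, superior ones positive
  mids <- vapply(c(-0.5, 0.5), function(y0) {
    trajs <- lapply(seq(-0.3, 0.3, length.out = 7), function(dx)
      jansonius_path(c(-0.5 + dx, y0), "right"))
    mean(axon_slope_range(trajs, c(-0.5, y0))$slope_range)
  }, numeric(1))
  expect_lt(mids[1], 0)
  expect_gt(mids[2], 0)
  expect_gt(mids[2], mids[1])
})
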