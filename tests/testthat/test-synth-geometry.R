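test_that("synthetic patients are seed-deterministic and range-respecting", {
  g1 <- generate_synthetic_patient(42)
  g2 <- generate_synthetic_patient(42)
  expect_identical(g1, g2)
  g3 <- generate_synthetic_patient(43)
  expect_false(identical(g1$retina$thickness_um, g3$retina$thickness_um))

  # gaps sampled over many seeds stay inside the declared range
  gaps <- unlist(lapply(1:100, function(s) {
    unname(electrode_retina_distances(generate_synthetic_patient(s)))
  }))
  expect_gte(min(gaps), 0)
  expect_lte(max(gaps), 300)
  rng <- synth_ranges()
  th <- unlist(lapply(1:20, function(s)
    range(generate_synthetic_patient(s)$retina$thickness_um)))
  expect_gte(min(th), rng$thickness_um[1])
  expect_lte(max(th), rng$thickness_um[2])
})

test_that("collapsed ranges give flat geometry with exact gaps", {
  g <- flat_patient(standoff_um = 50)
  expect_equal(unname(g$array$tilt_deg), c(0, 0))
  expect_true(all(abs(g$retina$thickness_um - 200) < 1e-9))
  d <- electrode_retina_distances(g)
  expect_length(d, 60)
  expect_equal(unname(d), rep(50, 60), tolerance = 1e-6)
})

test_that("invalid ranges are a configuration error", {
  expect_error(synth_ranges(gap_um = c(300, 0)), "min must be <= max")
})

test_that("tilt grades distances across rows by pitch * tan(tilt)", {
  g <- small_patient(tilt_deg = c(1, 0), standoff_um = 100)
  d <- electrode_retina_distances(g)
  lay <- electrode_layout(g$array)
  # rows A (superior, +y) vs B: one pitch apart
  dA <- mean(d[lay$label[lay$row == 1]])
  dB <- mean(d[lay$label[lay$row == 2]])
  expect_equal(abs(dA - dB), 575 * tan(1 * pi / 180), tolerance = 0.1)
})

test_that("deepening inner surface gives monotone distances across columns", {
  g <- small_patient(height_fun = function(x, y) 0.05 * (x + 1500))
  d <- electrode_retina_distances(g)
  lay <- electrode_layout(g$array)
  row1 <- d[lay$label[lay$row == 1][order(lay$col[lay$row == 1])]]
  expect_true(all(diff(row1) > 0))
})

test_that("interpenetration is a geometry error", {
  g <- small_patient(standoff_um = 0, tilt_deg = c(0, 0))
  expect_silent(electrode_retina_distances(g))
  expect_error(small_patient(standoff_um = 0, tilt_deg = c(2, 0)) |>
                 electrode_retina_distances(),
               "below the retinal surface")
})

test_that("distances are invariant under rigid in-plane translation", {
  g <- small_patient()
  g_shift <- g
  g_shift$array$center_mm <- g$array$center_mm + c(1.3, -0.7)
  g_shift$fovea_mm <- g$fovea_mm + c(1.3, -0.7)
  g_shift$optic_disc_mm <- g$optic_disc_mm + c(1.3, -0.7)
  expect_equal(electrode_retina_distances(g),
               electrode_retina_distances(g_shift))
})

test_that("geometry serializes and reloads identically", {
  g <- generate_synthetic_patient(7)
  f <- tempfile(fileext = ".json")
  write_patient_geometry(g, f)
  g2 <- read_patient_geometry(f)
  expect_equal(g, g2, tolerance = 1e-12)
})

test_that("voxelization partitions the grid and honors layer structure", {
  g <- small_patient(thickness_um = 200, standoff_um = 100)
  grid <- build_conductivity_grid(g, spacing_um = 20, margin_um = 200,
                                  z_above_um = 200, z_below_um = 100)
  lab <- grid$label
  expect_true(all(lab %in% 1:6))                  # exhaustive + disjoint
  expect_equal(prod(dim(lab)), length(lab))
  # uniform 200 um retina at 20 um spacing: exactly 10 voxels thick
  n_ret <- apply(lab == 2L, c(1, 2), sum)
  expect_true(all(n_ret == 10))
  # zero-thickness capsule: no fibrotic voxels
  expect_equal(sum(lab == 4L), 0L)
  # with a capsule, fibrotic voxels appear
  g2 <- small_patient(capsule_um = 60)
  grid2 <- build_conductivity_grid(g2, spacing_um = 20, margin_um = 200,
                                   z_above_um = 200, z_below_um = 100)
  expect_gt(sum(grid2$label == 4L), 0L)
  # every electrode has metal voxels
  expect_setequal(sort(unique(as.vector(grid$elec_id))), 0:4)
})

test_that("too-coarse spacing is a resolution error", {
  g <- small_patient(thickness_um = 120)
  expect_error(build_conductivity_grid(g, spacing_um = 150),
               "thinnest")
})
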