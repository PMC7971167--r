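test_that("closed-form helpers are exact", {
  expect_equal(analytic_disk_resistance(1.0, 100), 2500)
  expect_equal(analytic_disk_resistance(0.2715, 100), 9208.1, tolerance = 1e-4)
  expect_equal(analytic_disk_resistance(1.0, 200),
               analytic_disk_resistance(1.0, 100) / 2)
  expect_error(analytic_disk_resistance(0, 100), "must be > 0")
})

test_that("point-source solve matches I/(4 pi sigma r) in the mid-field", {
  sig <- 0.3
  g <- uniform_grid(c(800, 800, 800), spacing_um = 20, sigma = sig)
  sol <- solve_field(g, source_spec(points = matrix(0, 1, 3)),
                     tol = 1e-7, far_field = TRUE, keep_faces = TRUE)
  ctr <- sol$src_center_um
  r <- seq(5 * 20, 200, by = 20)
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 1) / sqrt(3))) {
    pts <- sweep(outer(r, dir), 2, ctr, "+")
    num <- sample_potentials(sol, pts)
    ana <- point_source_potential(sig, r)
    expect_lt(max(abs(num / ana - 1)), 0.02)
  }
  # discrete conservation: unit flux out of boxes around the source,
  # zero out of boxes that exclude it
  d <- dim(sol$phi); c0 <- (d + 1) / 2
  expect_equal(box_flux(sol, c0 - 3, c0 + 3), 1, tolerance = 1e-4)
  expect_equal(box_flux(sol, c0 - 8, c0 + 8), 1, tolerance = 1e-4)
  expect_lt(abs(box_flux(sol, c0 + 5, c0 + 10)), 1e-4)
})

test_that("solutions are linear and superpose", {
  g1 <- uniform_grid(c(600, 600, 600), 30, sigma = 0.5)
  g2 <- uniform_grid(c(600, 600, 600), 30, sigma = 1.0)
  src <- source_spec(points = matrix(c(0, 0, 0), 1))
  s1 <- solve_field(g1, src, tol = 1e-8)
  s2 <- solve_field(g2, src, tol = 1e-8)
  expect_equal(s2$phi, s1$phi / 2, tolerance = 1e-5)   # doubling sigma halves phi

  pA <- matrix(c(-90, 0, 0), 1); pB <- matrix(c(90, 30, 0), 1)
  sA <- solve_field(g1, source_spec(points = pA), tol = 1e-9)
  sB <- solve_field(g1, source_spec(points = pB), tol = 1e-9)
  sAB <- solve_field(g1, source_spec(points = rbind(pA, pB)), tol = 1e-9)
  expect_equal(sAB$phi, sA$phi + sB$phi, tolerance = 1e-5)
})

test_that("reciprocity: mutual resistance is symmetric", {
  g <- uniform_grid(c(600, 600, 400), 25, sigma = 0.4)
  pA <- c(-100, -50, 0); pB <- c(120, 60, 50)
  sA <- solve_field(g, source_spec(points = matrix(pA, 1)), tol = 1e-9)
  sB <- solve_field(g, source_spec(points = matrix(pB, 1)), tol = 1e-9)
  # evaluate each solution at the other solve's snapped source voxel
  rAB <- sample_potentials(sA, matrix(sB$src_center_um, 1))
  rBA <- sample_potentials(sB, matrix(sA$src_center_um, 1))
  expect_equal(rAB, rBA, tolerance = 1e-5)
})

test_that("terminal solves: equipotential source, impedance contract", {
  g <- disk_electrode_grid(100, 25, extent_um = c(1500, 1500, 750),
                           sigma = 1)
  sol <- solve_field(g, source_spec(electrode = "E1"), tol = 1e-8)
  # max phi on the (scaled-Dirichlet) electrode surface, all metal equal
  on_el <- g$elec_id == 1L
  expect_equal(max(sol$phi), max(sol$phi[on_el]))
  expect_lt(diff(range(sol$phi[on_el])), 1e-12)
  # Z invariant in the stimulus current used for the division
  expect_equal(compute_impedance(sol, 1), compute_impedance(sol, 2))
  # arithmetic contract: max voltage / current
  expect_equal(compute_impedance(sol), max(sol$phi) / sol$I_A)
})

test_that("floating inactive electrodes carry no net current", {
  g <- flat_patient(150, capsule_um = 0)
  grid <- build_conductivity_grid(g, 50)
  sol <- solve_field(grid, source_spec(electrode = "C5"), tol = 1e-7,
                     keep_faces = TRUE)
  # neighbor electrode C6 is floating metal: near-equipotential, ~zero net current
  e_idx <- match("C6", grid$elec_labels)
  w <- which(grid$elec_id == e_idx, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, dim(grid$label))
  expect_lt(abs(box_flux(sol, lo, hi)), 0.01 * sol$I_A)
  expect_lt(diff(range(sol$phi[grid$elec_id == e_idx])),
            1e-3 * max(sol$phi))
})

test_that("contact impedance: 0 recovers the plain solution, large blocks sclera", {
  g <- flat_patient(100, capsule_um = 0)
  mk <- function(zc) build_conductivity_grid(
    g, 50, cond = tissue_conductivities(rpe_contact_impedance_ohm_m2 = zc))
  s0 <- solve_field(mk(0), source_spec(electrode = "C5"), tol = 1e-7)
  s_tiny <- solve_field(mk(1e-9), source_spec(electrode = "C5"), tol = 1e-7)
  s_huge <- solve_field(mk(1e6), source_spec(electrode = "C5"), tol = 1e-7)
  expect_equal(s_tiny$phi, s0$phi, tolerance = 1e-4)
  # with a near-insulating RPE the scleral field is flat (no current below)
  scl <- mk(0)$label == 3L
  expect_lt(diff(range(s_huge$phi[scl])), 1e-3 * max(s_huge$phi))
  expect_gt(diff(range(s0$phi[scl])), 1e-3 * max(s0$phi))
})

test_that("interpolation is exact at nodes and linear between them", {
  g <- uniform_grid(c(300, 300, 300), 30, sigma = 1)
  sol <- solve_field(g, source_spec(points = matrix(c(0, 0, 0), 1)),
                     tol = 1e-8)
  i <- c(3L, 4L, 5L)
  node <- c(g$x[i[1]], g$y[i[2]], g$z[i[3]])
  expect_identical(sample_potentials(sol, matrix(node, 1)),
                   sol$phi[i[1], i[2], i[3]])
  nxt <- c(g$x[i[1] + 1L], node[2], node[3])
  expect_equal(sample_potentials(sol, matrix((node + nxt) / 2, 1)),
               (sol$phi[i[1], i[2], i[3]] + sol$phi[i[1] + 1L, i[2], i[3]]) / 2)
  expect_error(sample_potentials(sol, matrix(c(1e4, 0, 0), 1)),
               "outside")
})

test_that("potentials along an embedded neuron are finite and continuous", {
  g <- flat_patient(100)
  grid <- build_conductivity_grid(g, 50)
  sol <- solve_field(grid, source_spec(electrode = "C5"), tol = 1e-7)
  lay <- electrode_layout(g$array)
  e_xy <- as.numeric(lay[lay$label == "C5", c("x_um", "y_um")])
  soma_mm <- g$array$center_mm + e_xy / 1000 + c(0.05, 0.05)
  traj <- jansonius_path(soma_mm, "right")
  path <- embed_neuron(soma_mm, traj, g$retina,
                       array_center_mm = g$array$center_mm)
  chain <- build_cable(morphometry(), path)
  ve <- retistim:::sample_potentials_extended(sol, chain$centers, c(e_xy, 0))
  expect_length(ve, 3000)
  expect_true(all(is.finite(ve)))
  # continuity: no jump larger than the local field bound (V per um step)
  expect_lt(max(abs(diff(ve))), 0.05 * max(abs(ve)) + 1e-9)
})

test_that("fibrotic calibration recovers forward values and clips", {
  g <- flat_patient(150, capsule_um = 60)
  build <- function(s) build_conductivity_grid(
    g, 50, cond = tissue_conductivities(sigma_fibrotic = s))
  z_fun <- function(s) compute_impedance(
    solve_field(build(s), source_spec(electrode = "C5"), tol = 1e-7))
  z_hi <- z_fun(0.37)
  cal_clip <- calibrate_fibrotic_conductivity(build, target_Z_ohm = z_hi * 0.9,
                                              tol_sigma = 1e-3, tol = 1e-7)
  expect_true(cal_clip$out_of_range)
  expect_equal(cal_clip$sigma_f, 0.37)
  expect_true(cal_clip$monotone)
})

test_that("grid convergence report has the right shape and flags", {
  build <- function(h) disk_electrode_grid(100, h,
                                           extent_um = c(1200, 1200, 600))
  rep3 <- grid_convergence_report(build, c(25, 20, 20), "E1", tol = 1e-8)
  expect_equal(nrow(rep3), 3L)
  expect_true(is.na(rep3$dZ_rel[1]))
  expect_equal(rep3$dZ_rel[3], 0)            # identical spacings: zero change
  expect_true(rep3$converged_flag[3])
  expect_error(grid_convergence_report(build, c(20, 25, 30), "E1"),
               "non-increasing")
})
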