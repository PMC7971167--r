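# Voxelized conductivity grids: the volume-conductor representation that the
# field solver operates on. Voxels are labelled by tissue domain and carry a
# bulk conductivity; the retina/sclera interface is flagged for the contact
# impedance condition that models the thin resistive retinal pigment
# epithelium (RPE).

GRID_LABELS <- c(vitreous = 1L, retina = 2L, sclera = 3L, fibrotic = 4L,
                 electrode = 5L, insulator = 6L)

#' Bulk tissue conductivities and RPE contact impedance
#'
#' Defaults are literature-typical stand-ins (the source imaging study's
#' supplementary table is not reproduced anywhere in its text): vitreous
#' 1.28 S/m, retina 0.10 S/m, sclera 0.50 S/m, fibrotic capsule 0.2715 S/m
#' (the mid-sweep calibrated value), RPE contact impedance 0.5 Ohm m^2. All
#' are config-overridable.
#'
#' @param sigma_vitreous,sigma_retina,sigma_sclera,sigma_fibrotic bulk
#'   conductivities (S/m), all positive.
#' @param rpe_contact_impedance_ohm_m2 lumped surface resistivity of the RPE
#'   (Ohm m^2), non-negative; 0 disables the condition.
#' @return Object of class `tissue_conductivities`.
#' @export
tissue_conductivities <- function(sigma_vitreous = 1.28,
                                  sigma_retina = 0.10,
                                  sigma_sclera = 0.50,
                                  sigma_fibrotic = 0.2715,
                                  rpe_contact_impedance_ohm_m2 = 0.5) {
  s <- c(sigma_vitreous, sigma_retina, sigma_sclera, sigma_fibrotic)
  if (any(s <= 0)) stop_config("all conductivities must be > 0")
  if (rpe_contact_impedance_ohm_m2 < 0)
    stop_config("contact impedance must be >= 0")
  structure(list(sigma_vitreous = sigma_vitreous,
                 sigma_retina = sigma_retina,
                 sigma_sclera = sigma_sclera,
                 sigma_fibrotic = sigma_fibrotic,
                 rpe_contact_impedance_ohm_m2 = rpe_contact_impedance_ohm_m2),
            class = "tissue_conductivities")
}

# Low-level constructor. label/elec_id are integer arrays dim c(nx, ny, nz);
# x, y, z are voxel-center coordinates (um). `ground` names grid faces held
# at 0 V ("zmin" default: the face behind the vitreous, standing in for the
# distant extraocular return).
cond_grid <- function(label, spacing_um, origin_um = c(0, 0, 0),
                      cond = tissue_conductivities(),
                      elec_id = NULL, elec_labels = character(0),
                      ground = "zmin", sigma_metal_factor = 1e6) {
  stopifnot(is.array(label), length(dim(label)) == 3)
  storage.mode(label) <- "integer"
  dims <- dim(label)
  if (is.null(elec_id)) elec_id <- array(0L, dims)
  storage.mode(elec_id) <- "integer"
  structure(list(
    label = label, elec_id = elec_id, elec_labels = elec_labels,
    spacing_um = spacing_um,
    x = origin_um[1] + (seq_len(dims[1]) - 0.5) * spacing_um,
    y = origin_um[2] + (seq_len(dims[2]) - 0.5) * spacing_um,
    z = origin_um[3] + (seq_len(dims[3]) - 0.5) * spacing_um,
    cond = cond, ground = ground,
    sigma_metal_factor = sigma_metal_factor),
    class = "conductivity_grid")
}

#' @export
print.conductivity_grid <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<conductivity_grid> %d x %d x %d voxels at %g um (%.2g M cells)\n",
              d[1], d[2], d[3], x$spacing_um, prod(d) / 1e6))
  tab <- table(factor(x$label, levels = GRID_LABELS,
                      labels = names(GRID_LABELS)))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

# Per-voxel conductivity (S/m). Metal conductivity is a large multiple of
# the max tissue sigma (floating electrodes become near-equipotential);
# insulator is near-zero.
grid_sigma <- function(grid) {
  cd <- grid$cond
  tis <- c(cd$sigma_vitreous, cd$sigma_retina, cd$sigma_sclera,
           cd$sigma_fibrotic)
  lut <- c(tis, grid$sigma_metal_factor * max(tis), 1e-12)
  array(lut[grid$label], dim(grid$label))
}

#' Build a conductivity grid from a patient geometry
#'
#' Voxelizes the layered scene around the array: vitreous above the inner
#' retinal surface, retina of locally varying thickness, sclera below it
#' (with the retina/sclera interface subject to the RPE contact impedance),
#' the array's insulating substrate with metal electrode disks flush on its
#' retina-facing side, and a fibrotic capsule enveloping the array.
#'
#' @param g a [patient_geometry()].
#' @param spacing_um voxel edge (um); must not exceed the thinnest retinal
#'   thickness.
#' @param cond a [tissue_conductivities()].
#' @param margin_um lateral margin beyond the electrode footprint (um).
#' @param z_above_um vitreous depth included above the array (um).
#' @param z_below_um scleral depth included below the retina (um).
#' @param substrate_um array substrate (insulator) thickness (um).
#' @param electrode_um electrode metal thickness (um); snapped up to one
#'   voxel.
#' @return A `conductivity_grid`.
#' @export
build_conductivity_grid <- function(g, spacing_um,
                                    cond = tissue_conductivities(),
                                    margin_um = 500,
                                    z_above_um = 700, z_below_um = 300,
                                    substrate_um = 50, electrode_um = 20) {
  stopifnot(inherits(g, "patient_geometry"), spacing_um > 0)
  if (spacing_um > min(g$retina$thickness_um))
    stop_config("spacing (%g um) exceeds the thinnest retinal layer (%g um)",
                spacing_um, min(g$retina$thickness_um))
  lay <- electrode_layout(g$array)
  half <- g$array$diameter_um / 2
  x0 <- min(lay$x_um) - half - margin_um
  x1 <- max(lay$x_um) + half + margin_um
  y0 <- min(lay$y_um) - half - margin_um
  y1 <- max(lay$y_um) + half + margin_um
  h <- spacing_um
  x <- seq(x0 + h / 2, x1, by = h)
  y <- seq(y0 + h / 2, y1, by = h)

  zp_corners <- array_plane_z(g, c(x0, x1, x0, x1), c(y0, y0, y1, y1))
  cap_max <- max(g$capsule$thickness_um)
  z0 <- min(zp_corners) - substrate_um - cap_max - z_above_um
  z1 <- max(surface_height(g$retina, rep(x, length(y)),
                           rep(y, each = length(x))) +
            surface_thickness(g$retina, rep(x, length(y)),
                              rep(y, each = length(x)))) + z_below_um
  z <- seq(z0 + h / 2, z1, by = h)
  nx <- length(x); ny <- length(y); nz <- length(z)

  XY <- list(x = rep(x, ny), y = rep(y, each = nx))
  s_xy <- matrix(surface_height(g$retina, XY$x, XY$y), nx, ny)
  t_xy <- matrix(surface_thickness(g$retina, XY$x, XY$y), nx, ny)
  zp_xy <- matrix(array_plane_z(g, XY$x, XY$y), nx, ny)
  cap_xy <- matrix(capsule_thickness(g$capsule, XY$x, XY$y), nx, ny)

  rim <- 100  # substrate extends slightly past the outermost electrode rims
  foot <- matrix(XY$x >= min(lay$x_um) - half - rim &
                 XY$x <= max(lay$x_um) + half + rim &
                 XY$y >= min(lay$y_um) - half - rim &
                 XY$y <= max(lay$y_um) + half + rim, nx, ny)
  capm <- g$capsule$margin_um
  foot_cap <- matrix(XY$x >= min(lay$x_um) - half - rim - capm &
                     XY$x <= max(lay$x_um) + half + rim + capm &
                     XY$y >= min(lay$y_um) - half - rim - capm &
                     XY$y <= max(lay$y_um) + half + rim + capm, nx, ny)

  elec_xy <- matrix(0L, nx, ny)  # which electrode disk covers this column
  for (e in seq_len(nrow(lay))) {
    hit <- (XY$x - lay$x_um[e])^2 + (XY$y - lay$y_um[e])^2 <= half^2
    elec_xy[matrix(hit, nx, ny)] <- e
  }

  el_th <- max(electrode_um, h)
  label <- array(GRID_LABELS[["vitreous"]], c(nx, ny, nz))
  elec_id <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    zk <- z[k]
    sl <- matrix(GRID_LABELS[["vitreous"]], nx, ny)
    sl[zk >= s_xy & zk < s_xy + t_xy] <- GRID_LABELS[["retina"]]
    sl[zk >= s_xy + t_xy] <- GRID_LABELS[["sclera"]]
    capz <- sl == GRID_LABELS[["vitreous"]] & foot_cap & cap_xy > 0 &
      zk >= zp_xy - substrate_um - cap_xy & zk < zp_xy + cap_xy
    sl[capz] <- GRID_LABELS[["fibrotic"]]
    subz <- foot & zk >= zp_xy - substrate_um & zk < zp_xy
    sl[subz] <- GRID_LABELS[["insulator"]]
    elz <- elec_xy > 0 & zk >= zp_xy - el_th & zk < zp_xy
    sl[elz] <- GRID_LABELS[["electrode"]]
    elec_id[, , k][elz] <- elec_xy[elz]
    label[, , k] <- sl
  }

  for (e in seq_len(nrow(lay)))
    if (!any(elec_id == e))
      stop_config("electrode %s has no voxels at spacing %g um; refine the grid",
                  lay$label[e], h)

  cond_grid(label, h, origin_um = c(x0, y0, z0), cond = cond,
            elec_id = elec_id, elec_labels = lay$label, ground = "zmin")
}

#' Uniform (homogeneous) grid for oracle tests
#'
#' @param extent_um length-3 physical extent (um).
#' @param spacing_um voxel edge (um).
#' @param sigma bulk conductivity (S/m), assigned to every voxel (labelled
#'   vitreous).
#' @param ground grid faces held at 0 V (e.g. `"zmin"`, `"all"`, `"none"`).
#' @return A `conductivity_grid`.
#' @export
uniform_grid <- function(extent_um, spacing_um, sigma = 1,
                         ground = "all") {
  n <- pmax(2L, as.integer(round(extent_um / spacing_um)))
  label <- array(GRID_LABELS[["vitreous"]], n)
  cond_grid(label, spacing_um,
            origin_um = -n * spacing_um / 2,
            cond = tissue_conductivities(sigma_vitreous = sigma,
                                         rpe_contact_impedance_ohm_m2 = 0),
            ground = ground)
}

#' Disk electrode on a half-space (impedance oracle geometry)
#'
#' A metal disk of radius `radius_um` flush in an insulating plane at the
#' top of a homogeneous half-space of conductivity `sigma`. Its spreading
#' (access) resistance has the closed form `1/(4*sigma*a)`, which makes it
#' the standard oracle for solver impedance checks.
#'
#' @param radius_um disk radius (um).
#' @param spacing_um voxel edge (um).
#' @param extent_um length-3 domain extent (um); depth is the third entry.
#' @param sigma half-space conductivity (S/m).
#' @return A `conductivity_grid` with a single electrode labelled `"E1"`.
#' @export
disk_electrode_grid <- function(radius_um, spacing_um,
                                extent_um = c(16, 16, 8) * radius_um,
                                sigma = 1) {
  n <- pmax(4L, as.integer(round(extent_um / spacing_um)))
  label <- array(GRID_LABELS[["vitreous"]], n)
  elec_id <- array(0L, n)
  h <- spacing_um
  x <- (seq_len(n[1]) - 0.5) * h - extent_um[1] / 2
  y <- (seq_len(n[2]) - 0.5) * h - extent_um[2] / 2
  XY <- expand.grid(x = x, y = y)
  disk <- matrix(XY$x^2 + XY$y^2 <= radius_um^2, n[1], n[2])
  label[, , 1][!disk] <- GRID_LABELS[["insulator"]]
  label[, , 1][disk] <- GRID_LABELS[["electrode"]]
  elec_id[, , 1][disk] <- 1L
  cond_grid(label, h,
            origin_um = c(-extent_um[1] / 2, -extent_um[2] / 2, 0),
            cond = tissue_conductivities(sigma_vitreous = sigma,
                                         rpe_contact_impedance_ohm_m2 = 0),
            elec_id = elec_id, elec_labels = "E1",
            ground = c("xmin", "xmax", "ymin", "ymax", "zmax"))
}

#' Export a conductivity grid as legacy structured-points VTK (ASCII)
#'
#' Optional visualization output; writes voxel labels as scalars.
#'
#' @param grid a `conductivity_grid`.
#' @param path output file path.
#' @export
write_grid_vtk <- function(grid, path) {
  d <- dim(grid$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "conductivity grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", grid$x[1], grid$y[1], grid$z[1]),
               sprintf("SPACING %g %g %g", grid$spacing_um, grid$spacing_um,
                       grid$spacing_um),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$label), collapse = " "), con)
  invisible(path)
}
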