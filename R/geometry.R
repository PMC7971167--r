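# Parametric patient geometry: eye dimensions, epiretinal electrode array
# pose, retinal thickness/height fields and the fibrotic capsule that grows
# around a chronically implanted array.
#
# Coordinate conventions (stated once, used everywhere):
#   * Retinal-plane frame (mm): origin at the fovea, x temporal -> nasal
#     (mirrored for a left eye when exporting to world coordinates),
#     y inferior -> superior.
#   * Array-local frame (um): origin at the array center; x along the long
#     (column) axis, y along the short (row) axis; z increases with depth,
#     z = 0 is the reference inner-limiting-membrane plane, so the vitreous
#     (and the array) sit at z < surface height.

#' Eye-scale parameters
#'
#' Global dimensions of the implanted eye as they would be measured from
#' axial and transverse B-scan ultrasound: axial length, vitreous body
#' diameters, anterior chamber depth, and the coronal-plane angle of the
#' extraocular electronics case (EOC) that houses the current return.
#'
#' @param axial_length_mm axial length of the eye (mm).
#' @param vitreous_diameter_mm numeric length-3, vitreous body diameters
#'   along x, y, z (mm).
#' @param anterior_chamber_depth_mm anterior chamber depth (mm), must be
#'   smaller than the axial length.
#' @param eoc_angle_deg coronal-plane angle of the EOC in degrees, in
#'   \[-180, 180\].
#' @param eye_side `"left"` or `"right"`.
#' @return An object of class `eye_params`.
#' @export
eye_params <- function(axial_length_mm = 24,
                       vitreous_diameter_mm = c(22, 22, 22),
                       anterior_chamber_depth_mm = 3.2,
                       eoc_angle_deg = 0,
                       eye_side = c("left", "right")) {
  eye_side <- match.arg(eye_side)
  stopifnot(length(vitreous_diameter_mm) == 3)
  if (axial_length_mm <= 0 || any(vitreous_diameter_mm <= 0) ||
      anterior_chamber_depth_mm <= 0)
    stop_config("all eye lengths must be > 0")
  if (anterior_chamber_depth_mm >= axial_length_mm)
    stop_config("anterior chamber depth must be < axial length")
  if (abs(eoc_angle_deg) > 180)
    stop_config("EOC angle must lie in [-180, 180] degrees")
  structure(list(axial_length_mm = axial_length_mm,
                 vitreous_diameter_mm = as.numeric(vitreous_diameter_mm),
                 anterior_chamber_depth_mm = anterior_chamber_depth_mm,
                 eoc_angle_deg = eoc_angle_deg,
                 eye_side = eye_side),
            class = "eye_params")
}

#' Epiretinal electrode array
#'
#' A planar grid of disk electrodes (rows labelled A, B, ... and columns
#' 1, 2, ...; the 6 x 10 default mirrors the device layout implied by labels
#' such as A7 or C5). The array plane can be tilted about both in-plane axes
#' and stands off the retinal surface by a gap at its center.
#'
#' @param rows,cols grid dimensions (rows are lettered, columns numbered).
#' @param diameter_um electrode diameter (um), must be smaller than the pitch.
#' @param pitch_um center-to-center electrode spacing (um).
#' @param center_mm length-2 position of the array center in the
#'   retinal-plane frame (mm).
#' @param tilt_deg length-2 tilt in degrees: first about the long (column)
#'   axis, which grades the gap across rows; second about the short (row)
#'   axis, which grades it across columns.
#' @param standoff_um gap between the electrode face plane and the retinal
#'   surface at the array center (um, 0 = touching).
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(rows = 6L, cols = 10L,
                            diameter_um = 200, pitch_um = 575,
                            center_mm = c(0, 0),
                            tilt_deg = c(0, 0),
                            standoff_um = 50) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L || rows > 26L)
    stop_config("invalid array dimensions")
  if (diameter_um >= pitch_um)
    stop_config("electrode diameter must be smaller than the pitch")
  if (diameter_um <= 0 || pitch_um <= 0 || standoff_um < 0)
    stop_config("diameter and pitch must be > 0, standoff >= 0")
  stopifnot(length(center_mm) == 2, length(tilt_deg) == 2)
  structure(list(rows = rows, cols = cols,
                 diameter_um = diameter_um, pitch_um = pitch_um,
                 center_mm = as.numeric(center_mm),
                 tilt_deg = as.numeric(tilt_deg),
                 standoff_um = standoff_um),
            class = "electrode_array")
}

#' Electrode labels and in-plane positions
#'
#' @param arr an [electrode_array()].
#' @return data.frame with `label`, `row`, `col`, and array-local `x_um`,
#'   `y_um` of each electrode center (before tilt). Row A is the most
#'   superior row, column 1 the most temporal column.
#' @export
electrode_layout <- function(arr) {
  stopifnot(inherits(arr, "electrode_array"))
  g <- expand.grid(row = seq_len(arr$rows), col = seq_len(arr$cols))
  data.frame(
    label = paste0(LETTERS[g$row], g$col),
    row = g$row, col = g$col,
    x_um = (g$col - (arr$cols + 1) / 2) * arr$pitch_um,
    y_um = ((arr$rows + 1) / 2 - g$row) * arr$pitch_um,
    stringsAsFactors = FALSE)
}

#' Retinal surface descriptor
#'
#' Smooth lattice-sampled fields over (and around) the array footprint:
#' local retinal thickness and the height of the inner limiting membrane
#' relative to the reference plane. Fields are interpolated bilinearly, so
#' smoothness is bounded by the lattice resolution.
#'
#' @param x_um,y_um lattice coordinates (array-local um), strictly
#'   increasing.
#' @param thickness_um matrix `length(x_um)` x `length(y_um)` of retinal
#'   thickness (um), all positive.
#' @param height_um matrix of inner-surface height deviation from the
#'   reference plane (um, positive = deeper).
#' @return An object of class `retinal_surface`.
#' @export
retinal_surface <- function(x_um, y_um, thickness_um, height_um) {
  stopifnot(is.matrix(thickness_um), is.matrix(height_um),
            all(dim(thickness_um) == c(length(x_um), length(y_um))),
            all(dim(height_um) == dim(thickness_um)))
  if (any(thickness_um <= 0)) stop_config("retinal thickness must be > 0")
  if (is.unsorted(x_um, strictly = TRUE) || is.unsorted(y_um, strictly = TRUE))
    stop_config("surface lattice coordinates must be strictly increasing")
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 thickness_um = thickness_um, height_um = height_um),
            class = "retinal_surface")
}

#' @rdname retinal_surface
#' @param surf a `retinal_surface`.
#' @param xq,yq query coordinates (array-local um).
#' @export
surface_height <- function(surf, xq, yq)
  bilinear(surf$x_um, surf$y_um, surf$height_um, xq, yq)

#' @rdname retinal_surface
#' @export
surface_thickness <- function(surf, xq, yq)
  bilinear(surf$x_um, surf$y_um, surf$thickness_um, xq, yq)

#' Fibrotic capsule descriptor
#'
#' Thickness of the fibrotic tissue layer that envelops the implanted array
#' (a foreign-body response seen in most chronically implanted eyes),
#' sampled on the same kind of lattice as [retinal_surface()].
#'
#' @param x_um,y_um lattice coordinates (array-local um).
#' @param thickness_um capsule thickness field (um), non-negative.
#' @param margin_um lateral extent of the capsule beyond the array edge (um).
#' @return An object of class `fibrotic_capsule`.
#' @export
fibrotic_capsule <- function(x_um, y_um, thickness_um, margin_um = 200) {
  stopifnot(is.matrix(thickness_um),
            all(dim(thickness_um) == c(length(x_um), length(y_um))))
  if (any(thickness_um < 0)) stop_config("capsule thickness must be >= 0")
  if (margin_um < 0) stop_config("capsule margin must be >= 0")
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 thickness_um = thickness_um, margin_um = margin_um),
            class = "fibrotic_capsule")
}

capsule_thickness <- function(cap, xq, yq)
  bilinear(cap$x_um, cap$y_um, cap$thickness_um, xq, yq)

#' Assemble a patient geometry
#'
#' @param eye an [eye_params()].
#' @param array an [electrode_array()].
#' @param retina a [retinal_surface()].
#' @param capsule a [fibrotic_capsule()].
#' @param optic_disc_mm,fovea_mm retinal-plane positions (mm). Defaults put
#'   the optic disc 15 degrees nasal and 2 degrees superior to the fovea at
#'   0.286 mm/degree.
#' @return An object of class `patient_geometry`.
#' @export
patient_geometry <- function(eye, array, retina, capsule,
                             optic_disc_mm = c(15, 2) * 0.286,
                             fovea_mm = c(0, 0)) {
  stopifnot(inherits(eye, "eye_params"), inherits(array, "electrode_array"),
            inherits(retina, "retinal_surface"),
            inherits(capsule, "fibrotic_capsule"))
  if (isTRUE(all(abs(optic_disc_mm - fovea_mm) < 1e-9)))
    stop_config("optic disc and fovea must be distinct")
  lay <- electrode_layout(array)
  half <- array$diameter_um / 2
  if (min(lay$x_um) - half < min(retina$x_um) ||
      max(lay$x_um) + half > max(retina$x_um) ||
      min(lay$y_um) - half < min(retina$y_um) ||
      max(lay$y_um) + half > max(retina$y_um))
    stop_config("array footprint must lie inside the retinal surface extent")
  structure(list(eye = eye, array = array, retina = retina,
                 capsule = capsule,
                 optic_disc_mm = as.numeric(optic_disc_mm),
                 fovea_mm = as.numeric(fovea_mm)),
            class = "patient_geometry")
}

#' @export
print.patient_geometry <- function(x, ...) {
  d <- electrode_retina_distances(x)
  cat(sprintf(
    "<patient_geometry> %s eye, %dx%d array (pitch %g um, diameter %g um)\n",
    x$eye$eye_side, x$array$rows, x$array$cols, x$array$pitch_um,
    x$array$diameter_um))
  cat(sprintf("  electrode-retina gap: %.0f-%.0f um; retinal thickness %.0f-%.0f um\n",
              min(d), max(d), min(x$retina$thickness_um),
              max(x$retina$thickness_um)))
  invisible(x)
}

# Array plane height (array-local z, um) at in-plane position (x, y).
# Tilt about the long axis grades z across y (rows); tilt about the short
# axis grades z across x (columns).
array_plane_z <- function(g, x_um, y_um) {
  arr <- g$array
  sx <- tan(arr$tilt_deg[2] * pi / 180)
  sy <- tan(arr$tilt_deg[1] * pi / 180)
  z0 <- surface_height(g$retina, 0, 0) - arr$standoff_um
  z0 + sx * x_um + sy * y_um
}

array_plane_normal <- function(g) {
  arr <- g$array
  sx <- tan(arr$tilt_deg[2] * pi / 180)
  sy <- tan(arr$tilt_deg[1] * pi / 180)
  n <- c(-sx, -sy, 1)            # points toward the retina (+z)
  n / sqrt(sum(n^2))
}

#' Electrode-retina distances
#'
#' Distance from each electrode face center, along the array-plane normal,
#' to the inner retinal surface. Zero means touching; an electrode whose
#' center lies below the surface is a geometry error (no interpenetration).
#'
#' @param g a [patient_geometry()].
#' @return Named numeric vector (um), one entry per electrode label.
#' @export
electrode_retina_distances <- function(g) {
  stopifnot(inherits(g, "patient_geometry"))
  lay <- electrode_layout(g$array)
  n <- array_plane_normal(g)
  ze <- array_plane_z(g, lay$x_um, lay$y_um)
  # Solve z_e + t*nz = s(x_e + t*nx, y_e + t*ny) by fixed-point iteration;
  # the in-plane drift t*(nx, ny) is tiny for realistic tilts.
  t_cur <- (surface_height(g$retina, lay$x_um, lay$y_um) - ze) / n[3]
  for (it in 1:12) {
    s <- surface_height(g$retina, lay$x_um + t_cur * n[1],
                        lay$y_um + t_cur * n[2])
    t_cur <- (s - ze) / n[3]
  }
  if (any(t_cur < -1e-9))
    stop_config("electrode(s) %s project below the retinal surface",
                paste(lay$label[t_cur < -1e-9], collapse = ", "))
  stats::setNames(pmax(t_cur, 0), lay$label)
}

#' Default sampling ranges for synthetic patients
#'
#' The stated world of the generator: degenerate-retina thickness
#' 100-350 um, electrode-retina gaps 0-300 um, array tilt up to 2 degrees
#' about each in-plane axis, and a fibrotic capsule up to 100 um thick.
#'
#' @param thickness_um,gap_um,tilt_deg,capsule_um length-2 `c(min, max)`
#'   ranges.
#' @param axial_length_mm,acd_mm eye-scale ranges (mm).
#' @return A named list of ranges (class `synth_ranges`).
#' @export
synth_ranges <- function(thickness_um = c(100, 350),
                         gap_um = c(0, 300),
                         tilt_deg = c(-2, 2),
                         capsule_um = c(0, 100),
                         axial_length_mm = c(22, 26),
                         acd_mm = c(2.6, 3.8)) {
  r <- list(thickness_um = thickness_um, gap_um = gap_um,
            tilt_deg = tilt_deg, capsule_um = capsule_um,
            axial_length_mm = axial_length_mm, acd_mm = acd_mm)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2])
      stop_config("invalid range for %s: min must be <= max", nm)
  }
  structure(r, class = "synth_ranges")
}

#' Generate a synthetic patient geometry
#'
#' Draws a plausible implanted-eye geometry: smooth retinal thickness and
#' surface-height fields, an array pose (tilt + standoff) whose
#' electrode-retina gaps all fall inside the requested range, and a smooth
#' fibrotic capsule. Deterministic for a fixed seed. This stands in for the
#' imaging-derived geometry of a real patient; it is a sampler over stated
#' ranges, not a reconstruction.
#'
#' @param seed integer seed.
#' @param ranges a [synth_ranges()].
#' @param array_center_mm array center in the retinal-plane frame (mm).
#' @param eye_side `"left"` or `"right"` (default left).
#' @param lattice_n lattice resolution per axis of the sampled fields.
#' @param height_amp_um amplitude of the retinal surface undulation (um).
#' @return A [patient_geometry()].
#' @export
generate_synthetic_patient <- function(seed,
                                       ranges = synth_ranges(),
                                       array_center_mm = c(-0.3, 0.6),
                                       eye_side = "left",
                                       lattice_n = 25L,
                                       height_amp_um = 25) {
  if (!inherits(ranges, "synth_ranges")) ranges <- do.call(synth_ranges, ranges)
  with_seed(seed, {
    arr0 <- electrode_array(center_mm = array_center_mm)
    lay <- electrode_layout(arr0)
    margin <- 700
    x_um <- seq(min(lay$x_um) - margin, max(lay$x_um) + margin,
                length.out = lattice_n)
    y_um <- seq(min(lay$y_um) - margin, max(lay$y_um) + margin,
                length.out = lattice_n)

    tr <- ranges$thickness_um
    thick <- tr[1] + (tr[2] - tr[1]) *
      (0.5 + 0.5 * smooth_random_field(x_um, y_um)) *
      stats::runif(1, 0.6, 1)
    thick <- pmin(pmax(thick, tr[1]), tr[2])
    height <- height_amp_um * smooth_random_field(x_um, y_um)
    surf <- retinal_surface(x_um, y_um, thick, height)

    cr <- ranges$capsule_um
    cap_t <- cr[1] + (cr[2] - cr[1]) *
      (0.5 + 0.5 * smooth_random_field(x_um, y_um)) * stats::runif(1, 0.5, 1)
    cap <- fibrotic_capsule(x_um, y_um, pmin(pmax(cap_t, cr[1]), cr[2]))

    eye <- eye_params(
      axial_length_mm = stats::runif(1, ranges$axial_length_mm[1],
                                     ranges$axial_length_mm[2]),
      vitreous_diameter_mm = stats::runif(3, 20, 24),
      anterior_chamber_depth_mm = stats::runif(1, ranges$acd_mm[1],
                                               ranges$acd_mm[2]),
      eoc_angle_deg = stats::runif(1, -45, 45),
      eye_side = eye_side)

    # Pose: draw tilt, then place the array plane so every electrode gap is
    # inside the stated range. If the tilt-induced gap span exceeds the
    # range width, the tilt draw is shrunk (the range is the contract).
    gr <- ranges$gap_um
    tilt <- stats::runif(2, ranges$tilt_deg[1], ranges$tilt_deg[2])
    for (try in 1:20) {
      arr <- electrode_array(center_mm = array_center_mm, tilt_deg = tilt,
                             standoff_um = max(gr[1], 1))
      gtry <- patient_geometry(eye, arr, surf, cap)
      d <- tryCatch(electrode_retina_distances(gtry), error = function(e) NULL)
      if (is.null(d)) {  # interpenetration at minimal standoff: lift first
        arr <- electrode_array(center_mm = array_center_mm, tilt_deg = tilt,
                               standoff_um = gr[2])
        gtry <- patient_geometry(eye, arr, surf, cap)
        d <- electrode_retina_distances(gtry)
        d <- d - gr[2] + max(gr[1], 1)
      }
      span <- max(d) - min(d)
      if (span <= (gr[2] - gr[1]) * 0.999) break
      tilt <- tilt * 0.6
    }
    if (span > gr[2] - gr[1]) span <- gr[2] - gr[1]  # width-saturated fallback
    target_min <- stats::runif(1, gr[1], gr[2] - span)
    standoff <- max(0, max(gr[1], 1) + (target_min - min(d)))
    # the gap-vs-standoff relation is affine only to first order (tilted
    # normals, curved surface); nudge the plane up if rounding lands an
    # electrode fractionally below the surface
    for (bump in c(0, 0.5, 1, 2, 5)) {
      arr <- electrode_array(center_mm = array_center_mm, tilt_deg = tilt,
                             standoff_um = standoff + bump)
      g_out <- patient_geometry(eye, arr, surf, cap)
      d_out <- tryCatch(electrode_retina_distances(g_out),
                        error = function(e) NULL)
      if (!is.null(d_out)) break
    }
    if (max(d_out) > gr[2]) {
      # clamped standoff pushed the top out: lower it, but never past the
      # interpenetration limit (the smallest current gap)
      red <- min(max(d_out) - gr[2], max(min(d_out) - 0.5, 0))
      arr <- electrode_array(center_mm = array_center_mm, tilt_deg = tilt,
                             standoff_um = max(0, standoff - red))
      g_out <- patient_geometry(eye, arr, surf, cap)
    }
    g_out
  })
}

#' Serialize / restore a patient geometry (JSON)
#'
#' Plain-text round trip: `write_patient_geometry()` then
#' `read_patient_geometry()` reproduces the object.
#'
#' @param g a [patient_geometry()].
#' @param path file path.
#' @return `read_patient_geometry()` returns a [patient_geometry()].
#' @export
write_patient_geometry <- function(g, path) {
  stopifnot(inherits(g, "patient_geometry"))
  enc <- list(
    eye = unclass(g$eye),
    array = unclass(g$array),
    retina = list(x_um = g$retina$x_um, y_um = g$retina$y_um,
                  thickness_um = g$retina$thickness_um,
                  height_um = g$retina$height_um),
    capsule = list(x_um = g$capsule$x_um, y_um = g$capsule$y_um,
                   thickness_um = g$capsule$thickness_um,
                   margin_um = g$capsule$margin_um),
    optic_disc_mm = g$optic_disc_mm, fovea_mm = g$fovea_mm)
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patient_geometry
#' @export
read_patient_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  eye <- do.call(eye_params, j$eye)
  arr <- do.call(electrode_array, j$array)
  surf <- retinal_surface(j$retina$x_um, j$retina$y_um,
                          as.matrix(j$retina$thickness_um),
                          as.matrix(j$retina$height_um))
  cap <- fibrotic_capsule(j$capsule$x_um, j$capsule$y_um,
                          as.matrix(j$capsule$thickness_um),
                          j$capsule$margin_um)
  patient_geometry(eye, arr, surf, cap,
                   optic_disc_mm = j$optic_disc_mm, fovea_mm = j$fovea_mm)
}
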