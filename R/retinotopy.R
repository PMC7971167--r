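# Population placement and axon routing. Cell bodies are spread uniformly
# under each electrode by Lloyd's algorithm (centroidal Voronoi relaxation
# clipped to the sampling disk); axons leave each soma along the nerve-fiber
# bundle trajectories of the Jansonius model (a modified-polar power-law
# spiral around the optic nerve head, with separate published fits for the
# superior and inferior hemifields) and run to the optic disc without
# crossing the horizontal raphe.

#' Lloyd (centroidal Voronoi) sampling of a disk
#'
#' Seeds `n` points uniformly at random in the disk, then relaxes them by
#' Lloyd iterations toward a centroidal Voronoi configuration. Centroids
#' are estimated against a fixed, deterministic sunflower lattice covering
#' the disk, so the output is fully determined by the seed.
#'
#' @param n number of points.
#' @param radius_um disk radius (um).
#' @param seed integer seed.
#' @param iterations Lloyd iterations (default 50).
#' @param center_um length-2 disk center (um).
#' @return Object of class `soma_placement`: `points` (n x 2, um),
#'   `radius_um`, `center_um`, `seed`, `iterations`.
#' @export
lloyd_disk_sample <- function(n, radius_um, seed, iterations = 50L,
                              center_um = c(0, 0)) {
  stopifnot(n >= 1, radius_um > 0, iterations >= 0)
  m <- max(4000L, 40L * n)
  k <- seq_len(m)                      # sunflower reference lattice
  rr <- radius_um * sqrt((k - 0.5) / m)
  th <- k * pi * (3 - sqrt(5))
  ref <- cbind(rr * cos(th), rr * sin(th))

  pts <- with_seed(seed, {
    r0 <- radius_um * sqrt(stats::runif(n))
    a0 <- stats::runif(n, 0, 2 * pi)
    cbind(r0 * cos(a0), r0 * sin(a0))
  })
  for (it in seq_len(iterations)) {
    d2 <- outer(ref[, 1], pts[, 1], "-")^2 + outer(ref[, 2], pts[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    for (j in seq_len(n)) {
      sel <- nearest == j
      if (any(sel)) pts[j, ] <- colMeans(ref[sel, , drop = FALSE])
    }
  }
  # clip (Lloyd against a disk lattice keeps points inside, but be strict)
  rad <- sqrt(rowSums(pts^2))
  out <- rad > radius_um
  if (any(out)) pts[out, ] <- pts[out, ] * (radius_um / rad[out])
  structure(list(points = sweep(pts, 2, center_um, "+"),
                 radius_um = radius_um, center_um = as.numeric(center_um),
                 seed = seed, iterations = iterations),
            class = "soma_placement")
}

#' Jansonius trajectory model parameters
#'
#' Published power-law fits per hemifield: the bundle leaving the optic
#' nerve head at angle `phi0` follows `phi(r) = phi0 + b (r - r0)^c` in
#' disc-centered polar coordinates (degrees of visual angle), with `b` and
#' `c` smooth functions of `phi0`. `phi0 = 0` points temporally (toward
#' the raphe region), `phi0 = 180` nasally, positive angles superior.
#'
#' @param disc_deg optic-disc center relative to the fovea (degrees,
#'   nasal x, superior y).
#' @param r0_deg inner radius of the power-law regime (degrees).
#' @param mm_per_deg retinal scale (mm per degree of visual angle);
#'   0.286 mm/deg is the standard emmetropic conversion.
#' @param sup,inf named coefficient vectors `(beta0, beta1, c0, c1, mu, s)`
#'   for the superior / inferior hemifields:
#'   `b = +-exp(beta0 + beta1 tanh(+-(mu - |phi0|)/s))`,
#'   `c = c0 + c1 tanh((|phi0| - mu)/s)`.
#' @param symmetric if `TRUE`, the inferior hemifield mirrors the superior
#'   fit exactly (useful for symmetry tests); the published fits differ.
#' @return List of class `jansonius_params`.
#' @export
jansonius_params <- function(disc_deg = c(15, 2), r0_deg = 4,
                             mm_per_deg = 0.286,
                             sup = c(beta0 = -1.9, beta1 = 3.9,
                                     c0 = 1.9, c1 = 1.4, mu = 121, s = 14),
                             inf = c(beta0 = 0.7, beta1 = 1.5,
                                     c0 = 1.0, c1 = 0.5, mu = 90, s = 25),
                             symmetric = FALSE) {
  structure(list(disc_deg = disc_deg, r0_deg = r0_deg,
                 mm_per_deg = mm_per_deg, sup = sup, inf = inf,
                 symmetric = symmetric),
            class = "jansonius_params")
}

# b and c of the power law for a bundle angle phi0 (degrees, signed).
jansonius_bc <- function(phi0, par) {
  if (phi0 >= 0) {
    p <- par$sup
    b <- exp(p[["beta0"]] + p[["beta1"]] * tanh((p[["mu"]] - phi0) / p[["s"]]))
    cc <- p[["c0"]] + p[["c1"]] * tanh((phi0 - p[["mu"]]) / p[["s"]])
  } else if (par$symmetric) {
    bc <- jansonius_bc(-phi0, par)
    b <- -bc$b; cc <- bc$c
  } else {
    p <- par$inf  # published inferior fit, phi0 in (-180, 0)
    b <- -exp(p[["beta0"]] + p[["beta1"]] * tanh((phi0 + p[["mu"]]) / p[["s"]]))
    cc <- p[["c0"]] + p[["c1"]] * tanh((-phi0 - p[["mu"]]) / p[["s"]])
  }
  list(b = b, c = cc)
}

# Disc-centered polar coordinates of a fovea-frame point (internal frame:
# x nasal, y superior, degrees). The reference axis (phi = 0) points
# nasally (away from the fovea); phi > 0 is superior. The temporal ray
# phi = +-180 passes through the fovea and onward along the raphe, which
# trajectories approach asymptotically but never cross: bundles leaving
# the disc nearly temporally (phi0 -> +-180) are the almost-straight
# papillomacular/raphe fibers (b -> 0), bundles leaving superiorly arc
# around the macula toward the raphe (phi increasing with r).
raphe_axes <- function(par) {
  u <- par$disc_deg / sqrt(sum(par$disc_deg^2))   # fovea -> disc (nasal)
  v <- c(-u[2], u[1])                             # superior-positive normal
  list(u = u, v = v)
}

to_disc_polar <- function(p_deg, par) {
  ax <- raphe_axes(par)
  d <- p_deg - par$disc_deg
  r <- sqrt(sum(d^2))
  phi <- atan2(sum(d * ax$v), sum(d * ax$u)) * 180 / pi
  list(r = r, phi = wrap180(phi))
}

from_disc_polar <- function(r, phi, par) {
  ax <- raphe_axes(par)
  a <- phi * pi / 180
  par$disc_deg + r * (cos(a) * ax$u + sin(a) * ax$v)
}

#' Route an axon along a Jansonius nerve-fiber trajectory
#'
#' Finds the bundle passing through the soma (root-solving the power law
#' for the disc-exit angle `phi0`), then traces it from the soma to the
#' optic disc. Starts inside the nasal wedge that the published fits do
#' not cover reuse the nearest admissible bundle shape, rigidly offset in
#' angle to pass through the soma, and are flagged; raphe starts are
#' assigned to the superior branch (declared tie-break) and flagged.
#'
#' @param start_mm soma position, retinal-plane frame (mm, fovea origin;
#'   internal right-eye convention: +x nasal, +y superior).
#' @param eye_side `"right"` or `"left"`; a left eye mirrors the x axis of
#'   the returned world-frame polyline (slope signs flip exactly).
#' @param params a [jansonius_params()].
#' @param step_deg radial tracing step (degrees).
#' @return Object of class `axon_trajectory`: `path_mm` (polyline from the
#'   soma to the disc center, world frame), `slopes` (dy/dx per segment),
#'   `phi0_deg`, `offset_deg` (0 unless wedge fallback), `flagged`.
#' @export
jansonius_path <- function(start_mm, eye_side = "right",
                           params = jansonius_params(), step_deg = 0.1) {
  par <- params
  mirror <- identical(eye_side, "left")
  p_deg <- as.numeric(start_mm) / par$mm_per_deg
  pol <- to_disc_polar(p_deg, par)
  r_s <- pol$r; phi_s <- pol$phi
  disc_radius_deg <- 0.9
  if (r_s <= disc_radius_deg)
    stop_config("start position lies inside the optic disc")

  on_raphe <- (180 - abs(phi_s)) < 1e-9
  hemi_sign <- if (phi_s >= 0) 1 else -1  # raphe (phi = 180) wraps superior
  flagged <- on_raphe
  offset <- 0
  phi0 <- NA_real_

  if (r_s <= par$r0_deg) {
    # inside the power-law inner radius: straight radial course
    path_pol <- cbind(r = c(r_s, 0), phi = c(phi_s, phi_s))
  } else {
    dr <- (r_s - par$r0_deg)
    gfun <- function(p0) {
      bc <- jansonius_bc(p0, par)
      p0 + bc$b * dr^bc$c - phi_s
    }
    grid0 <- hemi_sign * seq(0.05, 179.5, by = 0.5)
    gv <- vapply(grid0, gfun, numeric(1))
    root <- NA_real_
    sgn <- sign(gv)
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flip)) {
      # root nearest to phi_s in bundle angle
      i <- flip[which.min(abs(grid0[flip] - phi_s))]
      root <- stats::uniroot(gfun, c(grid0[i], grid0[i + 1]),
                             tol = 1e-8)$root
    }
    if (is.na(root)) {
      # raphe wedge: nearest admissible bundle, rigid angular offset
      i <- which.min(abs(gv))
      root <- grid0[i]
      offset <- phi_s - (root + {
        bc <- jansonius_bc(root, par); bc$b * dr^bc$c
      })
      flagged <- TRUE
    }
    phi0 <- root
    bc <- jansonius_bc(phi0, par)
    rs <- seq(r_s, par$r0_deg, by = -step_deg)
    if (rs[length(rs)] > par$r0_deg) rs <- c(rs, par$r0_deg)
    phis <- phi0 + bc$b * (rs - par$r0_deg)^bc$c + offset
    # the raphe (phi = +-180) is inviolate: clip any overshoot onto it
    phis <- if (hemi_sign > 0) pmin(phis, 180) else pmax(phis, -180)
    path_pol <- cbind(r = c(rs, 0), phi = c(phis, phis[length(phis)]))
  }

  xy_deg <- t(apply(path_pol, 1, function(rp)
    from_disc_polar(rp[1], rp[2], par)))
  path_mm <- xy_deg * par$mm_per_deg
  path_mm[1, ] <- as.numeric(start_mm)   # exact start at the soma
  if (mirror) path_mm[, 1] <- -path_mm[, 1]
  dx <- diff(path_mm[, 1]); dy <- diff(path_mm[, 2])
  slopes <- ifelse(abs(dx) < 1e-12, NA_real_, dy / dx)
  structure(list(path_mm = path_mm, slopes = slopes,
                 phi0_deg = if (mirror && !is.na(phi0)) phi0 else phi0,
                 offset_deg = offset, flagged = flagged,
                 eye_side = eye_side, params = par),
            class = "axon_trajectory")
}

#' Embed a neuron in 3D below the retinal surface
#'
#' Builds the 3D cable path: a vertical descent-to-ascent segment from the
#' soma depth (55 um) to the nerve-fiber-layer depth (15 um) -- exactly
#' `soma_depth - axon_depth` long -- followed by a 90-degree bend onto the
#' Jansonius trajectory, which then follows the retinal surface contour at
#' the axon depth. If the trajectory ends (at the disc) before the cable
#' length is exhausted, the path continues along the final tangent and is
#' flagged.
#'
#' @param soma_mm soma position (retinal-plane frame, mm).
#' @param traj an [jansonius_path()] trajectory starting at the soma.
#' @param surface a [retinal_surface()] (array-local frame).
#' @param array_center_mm array center (mm) linking the two frames.
#' @param depths_um named `c(soma = 55, axon = 15)` depths below the inner
#'   surface.
#' @param min_length_um minimum path arc length (um).
#' @param step_um resampling step along the trajectory (um).
#' @return Matrix (k x 3) polyline in array-local um, with attributes
#'   `ascent_um` and `extended` (logical).
#' @export
embed_neuron <- function(soma_mm, traj, surface, array_center_mm = c(0, 0),
                         depths_um = c(soma = 55, axon = 15),
                         min_length_um = 3000, step_um = 5) {
  stopifnot(inherits(traj, "axon_trajectory"),
            inherits(surface, "retinal_surface"))
  local_um <- function(p_mm)
    cbind((p_mm[, 1] - array_center_mm[1]) * 1000,
          (p_mm[, 2] - array_center_mm[2]) * 1000)
  p2 <- local_um(traj$path_mm)
  seg <- sqrt(rowSums((p2[-1, , drop = FALSE] - p2[-nrow(p2), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  need <- min_length_um + 4 * step_um
  extended <- FALSE
  if (arc[length(arc)] < need) {
    tang <- p2[nrow(p2), ] - p2[nrow(p2) - 1, ]
    tang <- tang / sqrt(sum(tang^2))
    extra <- need - arc[length(arc)]
    p2 <- rbind(p2, p2[nrow(p2), ] + tang * extra)
    seg <- c(seg, extra)
    arc <- c(arc, arc[length(arc) - 1] + extra)
    arc <- c(0, cumsum(seg))
    extended <- TRUE
  }
  s_grid <- seq(0, arc[length(arc)], by = step_um)
  xs <- stats::approx(arc, p2[, 1], xout = s_grid)$y
  ys <- stats::approx(arc, p2[, 2], xout = s_grid)$y

  in_extent <- xs >= surface$x_um[1] & xs <= surface$x_um[length(surface$x_um)] &
    ys >= surface$y_um[1] & ys <= surface$y_um[length(surface$y_um)]
  sz <- numeric(length(xs))
  sz[in_extent] <- surface_height(surface, xs[in_extent], ys[in_extent])
  # outside the described surface, the reference plane (height 0) is used

  x0 <- xs[1]; y0 <- ys[1]
  s0 <- surface_height(surface, x0, y0)
  ascent <- depths_um[["soma"]] - depths_um[["axon"]]
  vert <- cbind(x0, y0, s0 + seq(depths_um[["soma"]], depths_um[["axon"]],
                                 length.out = max(2, ceiling(ascent / step_um) + 1)))
  horiz <- cbind(xs, ys, sz + depths_um[["axon"]])
  path <- rbind(vert, horiz[-1, , drop = FALSE])
  attr(path, "ascent_um") <- ascent
  attr(path, "extended") <- extended
  path
}

#' Axonal slope range under an electrode
#'
#' Min/max of dy/dx over trajectory segments whose midpoint falls within
#' the electrode's sampling disk (coronal-plane convention: sagittal y,
#' transverse x).
#'
#' @param trajs list of [jansonius_path()] trajectories (or any objects
#'   with `path_mm`).
#' @param center_mm electrode center (retinal-plane mm).
#' @param radius_um sampling-disk radius (um).
#' @return List `slope_range` (length-2, or `NULL` when no segment passes
#'   under the footprint), `n_segments`.
#' @export
axon_slope_range <- function(trajs, center_mm, radius_um = 500) {
  sl <- unlist(lapply(trajs, function(tr) {
    p <- tr$path_mm
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    d2 <- (mid[, 1] - center_mm[1])^2 + (mid[, 2] - center_mm[2])^2
    s <- tr$slopes[d2 <= (radius_um / 1000)^2]
    s[is.finite(s)]
  }))
  if (!length(sl)) return(list(slope_range = NULL, n_segments = 0L))
  list(slope_range = c(min(sl), max(sl)), n_segments = length(sl))
}
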