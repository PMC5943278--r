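#' Detector geometry
#'
#' Describes a single flat detector panel in the standard small-angle
#' laboratory frame: the beam travels along +z, the detector fast axis is
#' horizontal (+x) and the slow axis vertical (+y). Pixel indices are 0-based
#' with pixel centers at integer + 0.5 offsets from the panel corner, so a
#' beam center of `c(64, 64)` sits on the shared corner of four pixels while
#' `c(64.5, 64.5)` sits on the center of pixel (64, 64).
#'
#' The wavelength is derived from the photon energy as
#' lambda\[A\] = 12.3984 / E\[keV\].
#'
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param n_fast,n_slow Number of pixels along the fast (horizontal) and slow
#'   (vertical) axes.
#' @param distance_mm Sample-to-detector distance in millimetres.
#' @param beam_center_px Length-2 numeric, beam center in pixel units
#'   `(fast, slow)`. May lie off the panel.
#' @param photon_energy_kev Photon energy in keV.
#' @param polarization_deg Angle of the (linear) polarization axis in the
#'   detector plane, degrees from the fast axis. XFELs are horizontally
#'   polarized, so the default is 0.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(110, 1516, 1516, 85, c(758, 758), 8)
#' geom$wavelength_A
#' @export
detector_geometry <- function(pixel_size_um, n_fast, n_slow, distance_mm,
                              beam_center_px, photon_energy_kev,
                              polarization_deg = 0) {
  stopifnot(length(beam_center_px) == 2)
  if (!is.numeric(distance_mm) || distance_mm <= 0)
    stop("sample-detector distance must be > 0", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (photon_energy_kev <= 0) stop("photon_energy_kev must be > 0", call. = FALSE)
  n_fast <- as.integer(n_fast); n_slow <- as.integer(n_slow)
  stopifnot(n_fast > 0, n_slow > 0)
  bc <- as.numeric(beam_center_px)
  if (bc[1] < -n_fast || bc[1] > 2 * n_fast ||
      bc[2] < -n_slow || bc[2] > 2 * n_slow)
    stop("beam_center_px is implausibly far off-panel", call. = FALSE)
  wl <- 12.3984 / photon_energy_kev
  structure(
    list(
      pixel_size_um = as.numeric(pixel_size_um),
      n_fast = n_fast, n_slow = n_slow,
      distance_mm = as.numeric(distance_mm),
      beam_center_px = bc,
      photon_energy_kev = as.numeric(photon_energy_kev),
      wavelength_A = wl,
      polarization_deg = as.numeric(polarization_deg)
    ),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %d x %d px, %.1f um, D = %.2f mm, E = %.4f keV (lambda = %.5f A)\n",
    x$n_fast, x$n_slow, x$pixel_size_um, x$distance_mm,
    x$photon_energy_kev, x$wavelength_A))
  cat(sprintf("  beam center (fast, slow) = (%.3f, %.3f) px, polarization %g deg\n",
              x$beam_center_px[1], x$beam_center_px[2], x$polarization_deg))
  invisible(x)
}

#' Demonstration geometries
#'
#' `cspad_geometry()` is the experiment-scale default: a 1516 x 1516 pixel
#' assembled frame (about 2.3 million pixels) of 110 um pixels at 85 mm and
#' 8 keV. `demo_geometry()` is the package's working scale for simulation and
#' tests: 512 x 512 pixels of 150 um at the same distance and energy, which
#' reaches about 3.7 A at the center edge and samples one TMV layer-line
#' spacing with about 13 pixels.
#'
#' @param polarization_deg Polarization axis angle, degrees from horizontal.
#' @return A [detector_geometry()].
#' @export
cspad_geometry <- function(polarization_deg = 0) {
  detector_geometry(110, 1516, 1516, 85, c(758, 758), 8, polarization_deg)
}

#' @rdname cspad_geometry
#' @export
demo_geometry <- function(polarization_deg = 0) {
  detector_geometry(150, 512, 512, 85, c(256, 256), 8, polarization_deg)
}

#' Fiber orientation of one frame
#'
#' @param phi In-plane rotation of the fiber axis about the beam, degrees.
#'   The fiber axis is unsigned, so phi is reduced to `[0, 180)`.
#' @param beta Out-of-plane tilt of the fiber axis away from the plane normal
#'   to the beam, degrees in `[-90, 90]`.
#' @return An object of class `fiber_orientation`.
#' @export
orientation <- function(phi = 0, beta = 0) {
  phi <- as.numeric(phi) %% 180
  beta <- as.numeric(beta)
  if (abs(beta) > 90) stop("beta must lie in [-90, 90] degrees", call. = FALSE)
  structure(list(phi = phi, beta = beta), class = "fiber_orientation")
}

#' @export
print.fiber_orientation <- function(x, ...) {
  cat(sprintf("<orientation> phi = %.4f deg, beta = %.4f deg\n", x$phi, x$beta))
  invisible(x)
}

# Unit vector of the fiber axis and its in-plane normal, from (phi, beta).
# phi = 0 puts the fiber along detector vertical; the beam is +z.
# Returns list(f = fiber axis, e = normalize(f x beam), g = f x e).
fiber_basis <- function(orient) {
  phi <- orient$phi * pi / 180
  beta <- orient$beta * pi / 180
  f <- c(-sin(phi) * cos(beta), cos(phi) * cos(beta), sin(beta))
  e <- c(cos(phi), sin(phi), 0)        # normalize(f x z), right of meridian
  g <- c(f[2] * e[3] - f[3] * e[2],
         f[3] * e[1] - f[1] * e[3],
         f[1] * e[2] - f[2] * e[1])    # f x e, completes the frame
  list(f = f, e = e, g = g)
}

#' Per-pixel scattering vectors for a geometry
#'
#' Maps every pixel center onto the Ewald sphere. For a pixel at laboratory
#' position (x, y, D) the outgoing unit vector is k_out = (x, y, D)/|(x,y,D)|
#' and the scattering vector is q = (k_out - k_in)/lambda with k_in = (0,0,1),
#' i.e. the crystallographic convention |q| = 2 sin(theta)/lambda without a
#' factor 2 pi. Resolution is d = 1/|q| (infinite on the beam axis). The
#' polarization factor is P = 1 - (k_out . p)^2 for the linear polarization
#' direction p.
#'
#' @param geom A [detector_geometry()].
#' @return An object of class `qmap`: matrices (`n_slow` rows x `n_fast`
#'   columns) `qx`, `qy`, `qz`, `q`, `d`, `pol`, plus the geometry.
#' @examples
#' qm <- build_qmap(detector_geometry(110, 64, 64, 85, c(32.5, 32.5), 8))
#' min(qm$q)  # 0 at the beam-center pixel
#' @export
build_qmap <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  px_mm <- geom$pixel_size_um / 1000
  fast <- (seq_len(geom$n_fast) - 0.5 - geom$beam_center_px[1]) * px_mm
  slow <- (seq_len(geom$n_slow) - 0.5 - geom$beam_center_px[2]) * px_mm
  x <- matrix(fast, nrow = geom$n_slow, ncol = geom$n_fast, byrow = TRUE)
  y <- matrix(slow, nrow = geom$n_slow, ncol = geom$n_fast)
  D <- geom$distance_mm
  nrm <- sqrt(x^2 + y^2 + D^2)
  kx <- x / nrm; ky <- y / nrm; kz <- D / nrm
  wl <- geom$wavelength_A
  qx <- kx / wl; qy <- ky / wl; qz <- (kz - 1) / wl
  q <- sqrt(qx^2 + qy^2 + qz^2)
  d <- ifelse(q > 0, 1 / q, Inf)
  pa <- geom$polarization_deg * pi / 180
  kp <- kx * cos(pa) + ky * sin(pa)
  pol <- 1 - kp^2
  structure(list(qx = qx, qy = qy, qz = qz, q = q, d = d, pol = pol,
                 geom = geom),
            class = "qmap")
}

#' @export
print.qmap <- function(x, ...) {
  cat(sprintf("<qmap> %d x %d px, |q| up to %.4f 1/A (d_min = %.3f A)\n",
              x$geom$n_fast, x$geom$n_slow, max(x$q), 1 / max(x$q)))
  invisible(x)
}

#' Signed cylindrical fiber coordinates of every pixel
#'
#' Projects the per-pixel scattering vectors onto the fiber frame of one
#' orientation. The fiber axis f is the detector-vertical unit vector rotated
#' by phi about the beam and tilted by beta out of the plane normal to the
#' beam. Then Z = q . f and R = sign(q . e) * sqrt(|q|^2 - Z^2) with
#' e = normalize(f x beam); positive R is "right of the meridian". The
#' identity R^2 + Z^2 = |q|^2 holds for every pixel.
#'
#' @param qmap A [build_qmap()] result.
#' @param orient An [orientation()].
#' @param psi If `TRUE`, also return the azimuth of q about the fiber axis
#'   (radians; needed for oriented single-rotation intensities).
#' @return List of matrices `R` and `Z` (1/A), and `psi` when requested.
#' @export
fiber_frame_coords <- function(qmap, orient, psi = FALSE) {
  stopifnot(inherits(qmap, "qmap"), inherits(orient, "fiber_orientation"))
  b <- fiber_basis(orient)
  Z <- qmap$qx * b$f[1] + qmap$qy * b$f[2] + qmap$qz * b$f[3]
  qe <- qmap$qx * b$e[1] + qmap$qy * b$e[2] + qmap$qz * b$e[3]
  rsq <- qmap$q^2 - Z^2
  bad <- rsq < -1e-9 * qmap$q^2
  if (any(bad))
    stop("internal consistency error: |Z| exceeds |q|", call. = FALSE)
  R <- sign(qe) * sqrt(pmax(rsq, 0))
  out <- list(R = R, Z = Z)
  if (psi) {
    qg <- qmap$qx * b$g[1] + qmap$qy * b$g[2] + qmap$qz * b$g[3]
    out$psi <- atan2(qg, qe)
  }
  out
}

#' Azimuthal rotation range that covers a helix's unique data
#'
#' Diffraction from a u_t helix (u subunits in t turns per repeat) is
#' invariant under rotation by 360 t / u degrees about its axis, so a tilt
#' series spanning that range samples all unique reciprocal space. For TMV
#' (u = 49, t = 3) this is about 22 degrees.
#'
#' @param u,t Coprime positive integers: subunits and turns per repeat.
#' @return Rotation range in degrees.
#' @examples
#' rotation_range_for_helix(49, 3)  # 22.04
#' @export
rotation_range_for_helix <- function(u, t) {
  if (length(u) != 1 || length(t) != 1 || u < 1 || t < 1 ||
      u != round(u) || t != round(t))
    stop("u and t must be positive integers", call. = FALSE)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  if (g(u, t) != 1) stop("u and t must be coprime", call. = FALSE)
  360 * t / u
}

#' Resolution at the detector corner farthest from the beam center
#'
#' @param geom A [detector_geometry()].
#' @return d-spacing in Angstrom at the farthest corner.
#' @export
corner_resolution <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  px_mm <- geom$pixel_size_um / 1000
  cx <- c(0, geom$n_fast) - geom$beam_center_px[1]
  cy <- c(0, geom$n_slow) - geom$beam_center_px[2]
  r <- max(outer(cx^2, cy^2, "+"))  # squared corner distances, px^2
  r_mm <- sqrt(r) * px_mm
  tth <- atan2(r_mm, geom$distance_mm)
  q <- 2 * sin(tth / 2) / geom$wavelength_A
  if (q == 0) Inf else 1 / q
}

# ---- geometry file round trip -------------------------------------------

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%.1f", v)
    else sprintf("%.17g", v)
  }, character(1))
}

#' Read or write a geometry file
#'
#' Flat key:value YAML with keys `pixel_size_um`, `n_fast`, `n_slow`,
#' `distance_mm`, `beam_center_px` (two numbers), `photon_energy_keV`,
#' `polarization_deg`. Values are written with 17 significant digits so a
#' write/read cycle reproduces the geometry bit-exactly.
#'
#' @param path File path.
#' @param geom A [detector_geometry()].
#' @return `read_geometry()` returns a [detector_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("pixel_size_um", "n_fast", "n_slow", "distance_mm",
            "beam_center_px", "photon_energy_keV")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("geometry file missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  detector_geometry(y$pixel_size_um, y$n_fast, y$n_slow, y$distance_mm,
                    as.numeric(y$beam_center_px), y$photon_energy_keV,
                    if (is.null(y$polarization_deg)) 0 else y$polarization_deg)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "detector_geometry"))
  lines <- c(
    paste0("pixel_size_um: ", fmt_num(geom$pixel_size_um)),
    paste0("n_fast: ", geom$n_fast),
    paste0("n_slow: ", geom$n_slow),
    paste0("distance_mm: ", fmt_num(geom$distance_mm)),
    paste0("beam_center_px: [", fmt_num(geom$beam_center_px[1]), ", ",
           fmt_num(geom$beam_center_px[2]), "]"),
    paste0("photon_energy_keV: ", fmt_num(geom$photon_energy_kev)),
    paste0("polarization_deg: ", fmt_num(geom$polarization_deg))
  )
  writeLines(lines, path)
  invisible(path)
}
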