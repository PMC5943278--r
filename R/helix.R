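#' Helical diffraction model
#'
#' A discrete helix with `u` subunits in `t` turns per crystallographic
#' repeat `c`. Each subunit is a set of pseudo-atoms given in cylindrical
#' coordinates (radius r in Angstrom, azimuth psi in radians, axial offset z
#' in Angstrom) with scattering weights f. Diffraction from such a helix is
#' confined to layer lines Z = l/c, and on layer line l only Bessel orders n
#' satisfying the selection rule l = t n + u m (integer m) contribute.
#'
#' @param u,t Coprime positive integers: subunits and turns per repeat.
#' @param c_A Axial repeat in Angstrom.
#' @param atoms Data frame with columns `r`, `psi`, `z`, `f` (one row per
#'   pseudo-atom of the asymmetric subunit).
#' @param length_A Filament length in Angstrom; controls the axial width of
#'   layer lines (Gaussian sigma_Z = 1/(2 L)).
#' @param n_max Highest Bessel order retained in layer-line sums.
#' @return An object of class `helix_model`.
#' @seealso [tmv_model()] for the tobacco mosaic virus preset.
#' @export
helix_model <- function(u, t, c_A, atoms, length_A = 1000, n_max = 55) {
  rotation_range_for_helix(u, t)  # validates coprimality/positivity
  stopifnot(is.data.frame(atoms),
            all(c("r", "psi", "z", "f") %in% names(atoms)))
  if (c_A <= 0) stop("axial repeat c_A must be > 0", call. = FALSE)
  if (any(atoms$r < 0)) stop("atom radii must be >= 0", call. = FALSE)
  if (length_A <= c_A) stop("length_A must exceed the repeat c_A", call. = FALSE)
  structure(list(u = as.integer(u), t = as.integer(t), c_A = as.numeric(c_A),
                 atoms = tibble::as_tibble(atoms),
                 length_A = as.numeric(length_A), n_max = as.integer(n_max)),
            class = c("helix_model"))
}

#' Tobacco mosaic virus helix preset
#'
#' TMV is a 49_3 helix (49 coat-protein subunits in 3 turns) with an axial
#' repeat of 68.7 A. The subunit is represented by four pseudo-atom shells
#' spanning the 20-90 A radial extent of the virion, which populates the
#' near-meridional layer lines l = 3k (lowest Bessel order n = k) strongly
#' and the remaining lines (|n| >= 14) away from the meridian, as observed
#' for real TMV.
#'
#' @param length_A Filament length (A); graphene-deposited rod fragments are
#'   shorter than the 3000 A virion, default 1000 A.
#' @param n_max Highest Bessel order retained; at least 50 + lowest order is
#'   needed for two orders to coexist on a line (the source of left/right
#'   asymmetry in oriented patterns).
#' @return A [helix_model()].
#' @export
tmv_model <- function(length_A = 1000, n_max = 55) {
  atoms <- tibble::tibble(
    r = c(25, 40, 70, 85),
    psi = c(4.0, 0.0, 0.8, 2.1),
    z = c(5.0, 0.0, 10.5, 20.0),
    f = c(0.6, 1.0, 1.2, 0.8)
  )
  helix_model(49, 3, 68.7, atoms, length_A = length_A, n_max = n_max)
}

# Bessel function of the first kind, integer order, safe for negative n.
# base::besselJ handles negative nu by the reflection formula, whose
# sin(nu*pi)*Y_nu term is numerically disastrous for large |n| at small x.
bessel_jn <- function(n, x) {
  stopifnot(n == round(n))
  j <- besselJ(x, abs(n))
  if (n < 0 && abs(n) %% 2 == 1) -j else j
}

#' Bessel orders allowed on a layer line
#'
#' The helix selection rule l = t n + u m restricts the Bessel orders n that
#' contribute to layer line l. Returns all n with |n| <= n_max such that
#' (l - t n) is divisible by u, ordered by increasing |n|.
#'
#' @param l Layer-line index (integer, may be negative).
#' @param u,t Helix symmetry (coprime positive integers).
#' @param n_max Highest order considered.
#' @return Integer vector of allowed orders.
#' @examples
#' allowed_bessel_orders(1, 49, 3, 20)  # -16
#' allowed_bessel_orders(3, 49, 3, 55)  # 1, -48 (and 50 if n_max >= 50)
#' @export
allowed_bessel_orders <- function(l, u, t, n_max) {
  rotation_range_for_helix(u, t)
  stopifnot(n_max >= 0, l == round(l))
  n <- seq.int(-n_max, n_max)
  n <- n[(l - t * n) %% u == 0]
  n[order(abs(n), n)]
}

# Complex layer-line structure factor G_{n,l}(R) for one Bessel order,
# from the asymmetric subunit's atoms (selection-rule u-fold sum applied
# by the caller as a factor u).
ccv_gnl <- function(model, n, l, R) {
  a <- model$atoms
  out <- complex(length.out = length(R))
  for (j in seq_len(nrow(a))) {
    ph <- -n * a$psi[j] + 2 * pi * l * a$z[j] / model$c_A
    out <- out + a$f[j] * bessel_jn(n, 2 * pi * R * a$r[j]) *
      complex(real = cos(ph), imaginary = sin(ph))
  }
  out
}

#' Layer-line intensity of a helix
#'
#' Evaluates the Cochran-Crick-Vand intensity on layer line `l` at radial
#' coordinate R. With `cylindrical_average = TRUE` (many filaments with
#' random axial rotations) the intensity is the incoherent sum
#' sum_n |G_{n,l}(R)|^2 over allowed orders. Otherwise the oriented
#' (single axial rotation `psi0`) intensity
#' |sum_n G_{n,l}(R) exp(i n (psi + pi/2))|^2 is returned, with
#' psi = psi0 + the azimuth of the scattering vector about the fiber axis
#' (`psi_q`, 0 on the right half of a flat section).
#'
#' Intensities include the u^2 factor from the subunit sum, so they match
#' [atomistic_oracle()] divided by n_repeats^2 on layer planes.
#'
#' @param model A [helix_model()].
#' @param l Layer-line index.
#' @param R Radial reciprocal coordinate(s), 1/A, non-negative.
#' @param psi0 Axial rotation of the filament, radians.
#' @param psi_q Azimuth of q about the fiber axis (same length as R or
#'   scalar), radians.
#' @param cylindrical_average Average over psi0?
#' @return Numeric vector of intensities.
#' @export
layerline_intensity <- function(model, l, R, psi0 = 0, psi_q = 0,
                                cylindrical_average = FALSE) {
  stopifnot(inherits(model, "helix_model"), all(R >= 0))
  orders <- allowed_bessel_orders(l, model$u, model$t, model$n_max)
  if (!length(orders)) return(numeric(length(R)))
  if (cylindrical_average) {
    out <- numeric(length(R))
    for (n in orders) out <- out + Mod(ccv_gnl(model, n, l, R))^2
    return(model$u^2 * out)
  }
  psi <- psi0 + psi_q + pi / 2
  amp <- complex(length.out = length(R))
  for (n in orders) {
    if (length(psi) == 1) {
      rot <- complex(real = cos(n * psi), imaginary = sin(n * psi))
    } else {
      rot <- complex(real = cos(n * psi), imaginary = sin(n * psi))
    }
    amp <- amp + ccv_gnl(model, n, l, R) * rot
  }
  model$u^2 * Mod(amp)^2
}

#' Brute-force atomistic diffraction oracle
#'
#' Builds explicit atom coordinates for `n_repeats` helical repeats (subunit
#' s places atom j at azimuth 2 pi s t / u + psi_j and height s c / u + z_j)
#' and evaluates |sum f exp(2 pi i q . r)|^2 by direct summation. Slow and
#' simple; used to validate the layer-line expressions.
#'
#' @param model A [helix_model()].
#' @param n_repeats Number of axial repeats to build.
#' @param q Length-3 scattering vector in the fiber frame (1/A), fiber along
#'   the third axis.
#' @return Intensity (single number).
#' @export
atomistic_oracle <- function(model, n_repeats, q) {
  stopifnot(inherits(model, "helix_model"), n_repeats >= 1, length(q) == 3)
  u <- model$u; t <- model$t; c_A <- model$c_A; a <- model$atoms
  s <- seq_len(u * n_repeats) - 1
  th <- 2 * pi * s * t / u
  zz <- s * c_A / u
  re <- 0; im <- 0
  for (j in seq_len(nrow(a))) {
    x <- a$r[j] * cos(th + a$psi[j])
    y <- a$r[j] * sin(th + a$psi[j])
    z <- zz + a$z[j]
    ph <- 2 * pi * (q[1] * x + q[2] * y + q[3] * z)
    re <- re + a$f[j] * sum(cos(ph))
    im <- im + a$f[j] * sum(sin(ph))
  }
  re^2 + im^2
}

# Expected helix intensity at signed fiber coordinates (vectorized over
# pixels). Layer lines have Gaussian axial profile sigma_Z = 1/(2L).
# psi_q: per-pixel azimuth about the fiber axis (from Ewald curvature);
# psi0: the filament's axial rotation; cylindrical_average switches to the
# psi-averaged pattern. footprint: rms half-extent of one detector pixel in
# q; axial profiles narrower than the sampling are widened to it with the
# integrated flux preserved (pixel-area integration proxy).
helix_intensity_rz <- function(model, R, Z, psi_q = NULL, psi0 = 0,
                               cylindrical_average = TRUE, footprint = 0) {
  sigma_z <- 1 / (2 * model$length_A)
  sig_eff <- sqrt(sigma_z^2 + footprint^2)
  flux <- sigma_z / sig_eff
  sigma_z <- sig_eff
  out <- numeric(length(R))
  l_near <- round(Z * model$c_A)
  l_max <- max(abs(l_near))
  absR <- abs(R)
  for (l in -l_max:l_max) {
    dz <- Z - l / model$c_A
    sel <- which(abs(dz) < 4 * sigma_z & l_near == l)
    if (!length(sel)) next
    if (cylindrical_average) {
      prof <- layerline_intensity(model, l, absR[sel],
                                  cylindrical_average = TRUE)
    } else {
      pq <- if (is.null(psi_q)) ifelse(R[sel] >= 0, 0, pi) else psi_q[sel]
      prof <- layerline_intensity(model, l, absR[sel], psi0 = psi0,
                                  psi_q = pq)
    }
    out[sel] <- out[sel] + flux * prof * exp(-dz[sel]^2 / (2 * sigma_z^2))
  }
  out
}
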