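#' Detector background model
#'
#' Circularly symmetric diffuse background (silicon frame, residual chamber
#' scattering) modelled as a constant plus a power-law term in |q|, scaled so
#' the realized mean over the unmasked detector — after the polarization
#' factor when `apply_polarization` — equals `mean_photons` per pixel. The
#' experiment's sample-free average is about 0.050 photons/pixel.
#'
#' @param mean_photons Target mean photons per unmasked pixel.
#' @param power_frac Fraction of the (pre-normalization) profile carried by
#'   the power-law term.
#' @param exponent Power-law exponent alpha in q^(-alpha).
#' @param q_floor Small-q clamp for the power law, 1/A.
#' @param apply_polarization Modulate by the polarization factor?
#' @return An object of class `background_model`.
#' @export
background_model <- function(mean_photons = 0.05, power_frac = 0.5,
                             exponent = 1, q_floor = 0.01,
                             apply_polarization = TRUE) {
  stopifnot(mean_photons >= 0, power_frac >= 0, power_frac <= 1, q_floor > 0)
  structure(list(mean_photons = mean_photons, power_frac = power_frac,
                 exponent = exponent, q_floor = q_floor,
                 apply_polarization = apply_polarization),
            class = "background_model")
}

# Expected background photons per pixel on a qmap (normalized to the target
# mean over unmasked pixels).
background_expected <- function(bg, qmap, mask = NULL) {
  stopifnot(inherits(bg, "background_model"), inherits(qmap, "qmap"))
  qq <- pmax(qmap$q, bg$q_floor)
  shape <- (1 - bg$power_frac) + bg$power_frac * (qq / bg$q_floor)^(-bg$exponent)
  if (bg$apply_polarization) shape <- shape * qmap$pol
  ok <- if (is.null(mask)) rep(TRUE, length(shape)) else as.vector(mask)
  m <- mean(shape[ok])
  if (m <= 0) return(shape * 0)
  shape * (bg$mean_photons / m)
}

#' Simulation configuration
#'
#' @param fluence Photons per unit model intensity per unit reciprocal-space
#'   area (1/A^2); the expected count in a pixel is fluence x intensity x the
#'   pixel's reciprocal-space area, so the photon budget does not depend on
#'   detector sampling.
#' @param disorientation_deg Gaussian angular spread (degrees) of the fiber
#'   axis within one exposure; implemented as a deterministic average over
#'   `n_disorient` orientations on a Gaussian quadrature grid.
#' @param n_disorient Number of grid orientations used when
#'   `disorientation_deg > 0` (odd).
#' @param seed RNG seed; identical configuration implies identical frames.
#' @param noiseless If `TRUE`, return expected intensities instead of Poisson
#'   draws.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fluence = 1, disorientation_deg = 0.3,
                       n_disorient = 11, seed = 1, noiseless = FALSE) {
  stopifnot(fluence >= 0, disorientation_deg >= 0, n_disorient >= 1)
  structure(list(fluence = fluence,
                 disorientation_deg = disorientation_deg,
                 n_disorient = as.integer(n_disorient),
                 seed = as.integer(seed), noiseless = isTRUE(noiseless)),
            class = "sim_config")
}

# default beamstop/gap mask: TRUE = usable pixel
default_mask <- function(geom, beamstop_px = 6) {
  fast <- (seq_len(geom$n_fast) - 0.5 - geom$beam_center_px[1])
  slow <- (seq_len(geom$n_slow) - 0.5 - geom$beam_center_px[2])
  x <- matrix(fast, nrow = geom$n_slow, ncol = geom$n_fast, byrow = TRUE)
  y <- matrix(slow, nrow = geom$n_slow, ncol = geom$n_fast)
  sqrt(x^2 + y^2) > beamstop_px
}

# Expected photon map for a set of filaments (list of list(model, orient,
# psi0)) on a qmap: sum of filament intensities evaluated at each pixel's
# (R, Z), disorientation-averaged, plus background, times polarization.
expected_frame <- function(filaments, qmap, bg, cfg, mask = NULL,
                           cylindrical_average = FALSE) {
  expd <- matrix(0, nrow(qmap$q), ncol(qmap$q))
  footprint <- pixel_q_step(qmap$geom) / sqrt(12)  # rms width of one pixel
  for (fil in filaments) {
    or <- fil$orient
    psi0 <- if (is.null(fil$psi0)) 0 else fil$psi0
    if (cfg$disorientation_deg > 0 && cfg$n_disorient > 1) {
      n <- cfg$n_disorient
      # Gauss-Hermite-like grid: equally spaced in probability
      p <- (seq_len(n) - 0.5) / n
      dphi <- stats::qnorm(p, sd = cfg$disorientation_deg)
      w <- rep(1 / n, n)
    } else {
      dphi <- 0; w <- 1
    }
    acc <- 0
    for (k in seq_along(dphi)) {
      ork <- orientation(or$phi + dphi[k], or$beta)
      fc <- fiber_frame_coords(qmap, ork, psi = !cylindrical_average)
      ii <- model_intensity_rz(fil$model, fc$R, fc$Z, psi_q = fc$psi,
                               psi0 = psi0,
                               cylindrical_average = cylindrical_average,
                               footprint = footprint)
      acc <- acc + w[k] * ii
    }
    expd <- expd + matrix(acc, nrow(expd), ncol(expd))
  }
  # photons per pixel = fluence x intensity x pixel area in reciprocal space
  # (so the photon budget is independent of detector sampling), attenuated by
  # polarization; background_expected() already carries the polarization
  # modulation (and is normalized with it) and is specified per pixel
  dq2 <- pixel_q_step(qmap$geom)^2
  expd <- expd * cfg$fluence * dq2 * qmap$pol
  if (!is.null(bg)) expd <- expd + background_expected(bg, qmap, mask)
  if (!is.null(mask)) expd[!mask] <- 0
  expd
}

#' Simulate one diffraction frame
#'
#' Expected intensity is the sum over filaments of the model intensity at
#' each pixel's fiber coordinates (averaged over the disorientation spread),
#' plus the background, multiplied by the polarization factor, then
#' Poisson-sampled into integer photon counts (unless `noiseless`).
#'
#' @param filaments List of filaments; each is a list with elements `model`
#'   (a [helix_model()] or [cross_beta_model()]), `orient` (an
#'   [orientation()]), and optionally `psi0` (axial rotation, radians).
#'   May be empty (background-only frame).
#' @param geom A [detector_geometry()].
#' @param bg A [background_model()] or `NULL`.
#' @param cfg A [sim_config()].
#' @param qmap Optional precomputed [build_qmap()] for `geom`.
#' @param mask Optional logical matrix, `TRUE` = usable pixel; defaults to a
#'   small central beamstop disk.
#' @param cylindrical_average Simulate the psi-averaged (many mutually
#'   rotated filaments) pattern instead of oriented single rotations.
#' @return Integer photon-count matrix with attributes `mask` and `expected`.
#' @export
simulate_frame <- function(filaments, geom, bg = background_model(),
                           cfg = sim_config(), qmap = NULL, mask = NULL,
                           cylindrical_average = FALSE) {
  stopifnot(inherits(geom, "detector_geometry"), inherits(cfg, "sim_config"))
  if (is.null(qmap)) qmap <- build_qmap(geom)
  if (is.null(mask)) mask <- default_mask(geom)
  expd <- expected_frame(filaments, qmap, bg, cfg, mask,
                         cylindrical_average = cylindrical_average)
  if (cfg$noiseless) {
    out <- expd
  } else {
    out <- withr::with_seed(cfg$seed, {
      matrix(stats::rpois(length(expd), lambda = as.vector(expd)),
             nrow(expd), ncol(expd))
    })
    storage.mode(out) <- "integer"
  }
  attr(out, "mask") <- mask
  out
}

#' Simulate a labeled frame set
#'
#' Generates a ground-truth-labeled population of beam-off frames (dark
#' detector, a stray photon or two), sample-free frames (background only) and
#' hits (background plus filament diffraction at random orientations).
#'
#' @param n_beam_off,n_sample_free,n_hit Frame counts per class.
#' @param model Filament model used for hits.
#' @param geom A [detector_geometry()].
#' @param bg A [background_model()].
#' @param cfg A [sim_config()]; the seed controls orientations and photon
#'   noise for the whole set.
#' @param beta_range Hits draw beta uniformly in `[-beta_range, beta_range]`
#'   degrees (graphene buckling keeps the tilt small); phi is uniform in
#'   `[0, 180)`.
#' @param n_filaments Filaments per hit frame (all share one orientation
#'   family, mutually rotated in psi0).
#' @return A `frame_set`: list with `data` (n_slow x n_fast x n integer
#'   array), `mask`, `geom`, and `meta` tibble (frame_id, label, phi, beta,
#'   psi0).
#' @export
simulate_frameset <- function(n_beam_off, n_sample_free, n_hit,
                              model = bombesin_model(),
                              geom = demo_geometry(),
                              bg = background_model(),
                              cfg = sim_config(),
                              beta_range = 5, n_filaments = 1) {
  stopifnot(n_beam_off >= 0, n_sample_free >= 0, n_hit >= 0)
  n <- n_beam_off + n_sample_free + n_hit
  if (n == 0) stop("empty frame set requested", call. = FALSE)
  qmap <- build_qmap(geom)
  mask <- default_mask(geom)
  labels <- c(rep("beam_off", n_beam_off), rep("sample_free", n_sample_free),
              rep("hit", n_hit))
  pars <- withr::with_seed(cfg$seed, {
    tibble::tibble(
      frame_id = seq_len(n) - 1L,
      label = labels,
      phi = ifelse(labels == "hit", stats::runif(n, 0, 180), NA_real_),
      beta = ifelse(labels == "hit",
                    stats::runif(n, -beta_range, beta_range), NA_real_),
      psi0 = ifelse(labels == "hit", stats::runif(n, 0, 2 * pi), NA_real_),
      frame_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  data <- array(0L, dim = c(geom$n_slow, geom$n_fast, n))
  bg_expected <- background_expected(bg, qmap, mask)
  bg_expected[!mask] <- 0
  for (i in seq_len(n)) {
    lab <- pars$label[i]
    fseed <- pars$frame_seed[i]
    if (lab == "beam_off") {
      fr <- withr::with_seed(fseed, {
        m <- matrix(stats::rpois(length(mask), 1e-6), nrow(mask), ncol(mask))
        m[!mask] <- 0L
        m
      })
    } else if (lab == "sample_free") {
      fr <- withr::with_seed(fseed, {
        matrix(stats::rpois(length(bg_expected), as.vector(bg_expected)),
               nrow(bg_expected), ncol(bg_expected))
      })
    } else {
      fils <- lapply(seq_len(n_filaments), function(k) {
        list(model = model,
             orient = orientation(pars$phi[i], pars$beta[i]),
             psi0 = pars$psi0[i] + (k - 1) * 2 * pi / max(1, n_filaments))
      })
      fcfg <- cfg; fcfg$seed <- fseed
      fr <- simulate_frame(fils, geom, bg, fcfg, qmap = qmap, mask = mask)
    }
    storage.mode(fr) <- "integer"
    data[, , i] <- fr
  }
  structure(list(data = data, mask = mask, geom = geom, meta = pars),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of %d x %d px\n",
              dim(x$data)[3], dim(x$data)[2], dim(x$data)[1]))
  if (!is.null(x$meta$label)) print(table(x$meta$label))
  invisible(x)
}

# number of frames
n_frames <- function(fs) dim(fs$data)[3]
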