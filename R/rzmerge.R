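#' Signed (R, Z) accumulation grid
#'
#' Regular grid of bin centers symmetric about R = 0 and Z = 0 (a center bin
#' sits exactly on each axis), the target of frame merging.
#'
#' @param r_max,z_max Grid half-extents, 1/A.
#' @param dr,dz Bin widths, 1/A.
#' @return An empty `rz_map`: bin centers `R`, `Z`, matrices `intensity`
#'   (mean per bin) and `weight` (contributing pixels per bin), and a
#'   `provenance` tibble.
#' @export
rz_grid <- function(r_max, z_max, dr, dz = dr) {
  stopifnot(dr > 0, dz > 0, r_max > 0, z_max > 0)
  nr <- ceiling(r_max / dr)
  nz <- ceiling(z_max / dz)
  R <- seq(-nr, nr) * dr
  Z <- seq(-nz, nz) * dz
  structure(list(
    R = R, Z = Z, dr = dr, dz = dz,
    intensity = matrix(0, length(Z), length(R)),
    weight = matrix(0, length(Z), length(R)),
    provenance = tibble::tibble(frame_id = integer(), phi = numeric(),
                                beta = numeric(), scale = numeric())),
    class = "rz_map")
}

#' @export
print.rz_map <- function(x, ...) {
  cat(sprintf("<rz_map> %d x %d bins (dR = %.2e, dZ = %.2e 1/A), %d frame(s), %.3g photons\n",
              ncol(x$intensity), nrow(x$intensity), x$dr, x$dz,
              nrow(x$provenance), sum(x$intensity * x$weight)))
  invisible(x)
}

# default grid matched to a geometry: bin = one central pixel, extent = |q|max
default_grid <- function(qmap) {
  step <- pixel_q_step(qmap$geom)
  qmax <- max(qmap$q)
  rz_grid(qmax, qmax, step, step)
}

#' Orientation search configuration
#'
#' @param phi_step Coarse in-plane search step, degrees.
#' @param beta_range,beta_step Tilt search half-range and step, degrees. The
#'   fiber tilt on graphene varies only within a small range; default +-15.
#' @param refine_factor Fine-stage step reduction factor.
#' @param z_bin Z-profile bin width for scoring, 1/A (`NULL`: one central
#'   pixel).
#' @param mask_halfwidth_sigma Layer-line exclusion half-width for background
#'   subtraction, in units of the fitted axial line width.
#' @param bg_bin Radial background bin width, 1/A (`NULL`: 2 pixels).
#' @return A list of class `merge_config`.
#' @export
merge_config <- function(phi_step = 2, beta_range = 15, beta_step = 2,
                         refine_factor = 8, z_bin = NULL,
                         mask_halfwidth_sigma = 3, bg_bin = NULL) {
  stopifnot(phi_step > 0, beta_step > 0, beta_range >= 0)
  structure(list(phi_step = phi_step, beta_range = beta_range,
                 beta_step = beta_step, refine_factor = refine_factor,
                 z_bin = z_bin, mask_halfwidth_sigma = mask_halfwidth_sigma,
                 bg_bin = bg_bin),
            class = "merge_config")
}

# parabolic refinement of a grid maximum; returns the refined x
parabolic_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[2] - x[1])
}

#' Estimate the fiber orientation of one frame
#'
#' The in-plane rotation phi maximizes the sharpness of the Z-marginal photon
#' profile (layer lines are sharp only at the true phi), via a coarse grid, a
#' fine grid and a three-point parabolic refinement. The tilt beta is then
#' estimated from the equator-bend criterion — at a wrong tilt the computed Z
#' of equator photons bends quadratically with |q| through the Ewald
#' curvature, so regressing Z on dZ/dbeta gives the correction in closed
#' form (iterated with a shrinking background-trimming tube); a sharpness
#' grid over beta serves as fallback for photon-starved frames. Both angles
#' are then polished once more. Deterministic.
#'
#' @param frame Integer photon matrix (optionally with a `mask` attribute).
#' @param qmap A [build_qmap()] result.
#' @param cfg A [merge_config()].
#' @param mask Optional logical matrix.
#' @return List with `orient` (an [orientation()]), `score`, and
#'   `confidence` (`"ok"` or `"low"` when the score landscape is flat).
#' @export
estimate_orientation <- function(frame, qmap, cfg = merge_config(),
                                 mask = NULL) {
  pp <- photon_pixels(frame, qmap, mask)
  z_bin <- if (is.null(cfg$z_bin)) pixel_q_step(qmap$geom) else cfg$z_bin
  n_bins <- ceiling(max(qmap$q) / z_bin)
  if (length(pp$w) < 10)
    return(list(orient = orientation(0, 0), score = 0, confidence = "low"))
  sc <- function(phi, beta)
    z_marginal_score(pp$qx, pp$qy, pp$qz, pp$w, phi, beta, z_bin, n_bins)

  # Tilt from the equator-bend criterion ("layer lines are horizontal"): for
  # photons near the equator, a tilt error delta displaces the computed Z by
  # delta * dZ/dbeta pixelwise (the Ewald-curvature bend, ~ -|q|^2 lambda/2),
  # so regressing Z on dZ/dbeta yields the correction in closed form.
  # Iterating with a shrinking tube around the current equator curve trims
  # the flat background that would otherwise attenuate the slope.
  beta_regress <- function(phi, beta0 = 0, tubes = c(0.012, 0.006, 0.003,
                                                     0.002, 0.002)) {
    phr <- phi * pi / 180
    beta <- beta0
    used <- 0
    for (tube in tubes) {
      b <- fiber_basis(orientation(phi, beta))
      Z <- pp$qx * b$f[1] + pp$qy * b$f[2] + pp$qz * b$f[3]
      br <- beta * pi / 180
      g <- sin(br) * (pp$qx * sin(phr) - pp$qy * cos(phr)) +
        pp$qz * cos(br)
      sel <- abs(Z) < tube
      used <- sum(sel)
      if (used < 50) break
      w <- pp$w[sel]
      s <- sum(w * Z[sel] * g[sel]) / sum(w * g[sel]^2)
      beta <- beta - s * 180 / pi
      if (abs(beta) > cfg$beta_range) {
        beta <- max(min(beta, cfg$beta_range), -cfg$beta_range)
      }
    }
    list(beta = beta, n = used)
  }

  refine_phi <- function(phi_c, beta) {
    fstep <- cfg$phi_step / cfg$refine_factor
    phif <- seq(phi_c - cfg$phi_step, phi_c + cfg$phi_step, by = fstep)
    s <- vapply(phif, sc, numeric(1), beta = beta)
    parabolic_peak(phif, s, which.max(s))
  }
  refine_beta <- function(phi, beta_c) {
    bstep <- cfg$beta_step / cfg$refine_factor
    betaf <- seq(max(-cfg$beta_range, beta_c - cfg$beta_step),
                 min(cfg$beta_range, beta_c + cfg$beta_step), by = bstep)
    s <- vapply(betaf, sc, numeric(1), phi = phi)
    parabolic_peak(betaf, s, which.max(s))
  }

  # phi is well determined even at beta = 0 (the tilt enters only through
  # the Ewald curvature), while beta is meaningful only near the true phi:
  # so refine phi first, then estimate beta, then polish.
  phis <- seq(0, 180 - cfg$phi_step, by = cfg$phi_step)
  s_phi <- vapply(phis, sc, numeric(1), beta = 0)
  phi1 <- refine_phi(phis[which.max(s_phi)], 0)

  br <- beta_regress(phi1)
  if (br$n >= 50) {
    beta1 <- br$beta
  } else {
    # photon-starved equator: fall back to the sharpness grid
    betas <- seq(-cfg$beta_range, cfg$beta_range, by = cfg$beta_step)
    s_beta <- vapply(betas, sc, numeric(1), phi = phi1)
    beta1 <- refine_beta(phi1, betas[which.max(s_beta)])
  }
  phi2 <- refine_phi(phi1, beta1)
  beta2 <- beta_regress(phi2, beta1, tubes = c(0.003, 0.002))$beta

  score <- sc(phi2, beta2)
  conf <- if (score < 2 * stats::median(s_phi)) "low" else "ok"
  list(orient = orientation(phi2, beta2), score = score, confidence = conf)
}

#' Map a frame onto the signed (R, Z) grid
#'
#' Every unmasked pixel's photons are added to the bin containing its signed
#' fiber coordinates; the weight accumulator counts contributing pixels. By
#' default each pixel is divided by its polarization factor before
#' accumulation, so that the residual detector background in (R, Z) is
#' circularly symmetric. Photons are conserved: the sum of intensity x weight
#' over bins equals the (corrected) photon sum over in-grid pixels.
#'
#' @param frame Integer photon matrix.
#' @param qmap A [build_qmap()] result.
#' @param orient An [orientation()].
#' @param grid An [rz_grid()] (its accumulated content is ignored; a fresh
#'   map on the same grid is returned). `NULL` for a geometry-matched grid.
#' @param mask Optional logical matrix.
#' @param polarization_correct Divide pixel counts by the polarization
#'   factor before accumulation.
#' @param frame_id Recorded in provenance.
#' @return An `rz_map` holding this single frame.
#' @export
map_to_rz <- function(frame, qmap, orient, grid = NULL, mask = NULL,
                      polarization_correct = TRUE, frame_id = 0L) {
  if (is.null(grid)) grid <- default_grid(qmap)
  if (is.null(mask)) mask <- attr(frame, "mask")
  if (is.null(mask)) mask <- array(TRUE, dim(frame))
  fc <- fiber_frame_coords(qmap, orient)
  nr <- (length(grid$R) - 1) / 2
  nz <- (length(grid$Z) - 1) / 2
  iR <- round(fc$R / grid$dr) + nr + 1
  iZ <- round(fc$Z / grid$dz) + nz + 1
  ok <- mask & iR >= 1 & iR <= length(grid$R) & iZ >= 1 & iZ <= length(grid$Z)
  if (!any(ok)) stop("grid too small: no pixel falls inside", call. = FALSE)
  lin <- (iR[ok] - 1) * length(grid$Z) + iZ[ok]
  w <- frame[ok]
  if (polarization_correct) w <- w / qmap$pol[ok]
  nbin <- length(grid$Z) * length(grid$R)
  isum <- numeric(nbin)
  t1 <- tapply(w, lin, sum)
  isum[as.integer(names(t1))] <- t1
  wsum <- tabulate(lin, nbin)
  out <- grid
  out$weight <- matrix(wsum, length(grid$Z), length(grid$R))
  out$intensity <- matrix(ifelse(wsum > 0, isum / pmax(wsum, 1), 0),
                          length(grid$Z), length(grid$R))
  out$provenance <- tibble::tibble(frame_id = as.integer(frame_id),
                                   phi = orient$phi, beta = orient$beta,
                                   scale = 1)
  out
}

# total photons represented by a map
rz_photons <- function(m) sum(m$intensity * m$weight)

#' Scale and merge (R, Z) maps
#'
#' The reference is the map with the most photons. Each map k gets a
#' least-squares overlap scale s_k = sum(I_k M) / sum(I_k^2) over bins where
#' both it and the running merge have weight; the merged intensity is the
#' weight-weighted mean of the scaled maps, with one refinement pass of the
#' scales against the first merge.
#'
#' @param maps List of `rz_map`s on identical grids.
#' @param refine Number of scale refinement passes.
#' @return Merged `rz_map` with per-frame scales in `provenance`.
#' @export
merge_rzmaps <- function(maps, refine = 1) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$R, g$R)) || !isTRUE(all.equal(m$Z, g$Z)))
      stop("maps are on different grids", call. = FALSE)
  if (length(maps) == 1) return(maps[[1]])
  ref <- which.max(vapply(maps, rz_photons, numeric(1)))
  M <- maps[[ref]]$intensity
  Mw <- maps[[ref]]$weight
  scales <- rep(1, length(maps))
  compute_scales <- function(M, Mw) {
    vapply(seq_along(maps), function(k) {
      ov <- maps[[k]]$weight > 0 & Mw > 0
      if (!any(ov)) {
        id <- maps[[k]]$provenance$frame_id[1]
        stop(sprintf("frame %s has no overlap with the merge reference", id),
             call. = FALSE)
      }
      den <- sum(maps[[k]]$intensity[ov]^2)
      if (den == 0) 1 else sum(maps[[k]]$intensity[ov] * M[ov]) / den
    }, numeric(1))
  }
  do_merge <- function(scales) {
    num <- 0; den <- 0
    for (k in seq_along(maps)) {
      num <- num + maps[[k]]$intensity * scales[k] * maps[[k]]$weight
      den <- den + maps[[k]]$weight
    }
    out <- maps[[1]]
    out$weight <- den
    out$intensity <- ifelse(den > 0, num / pmax(den, 1), 0)
    out
  }
  scales <- compute_scales(M, Mw)
  merged <- do_merge(scales)
  for (r in seq_len(refine)) {
    scales <- compute_scales(merged$intensity, merged$weight)
    merged <- do_merge(scales)
  }
  merged$provenance <- dplyr::bind_rows(lapply(seq_along(maps), function(k) {
    p <- maps[[k]]$provenance
    if (!nrow(p))
      p <- tibble::tibble(frame_id = NA_integer_, phi = NA_real_,
                          beta = NA_real_, scale = 1)
    p$scale <- scales[k]
    p
  }))
  merged
}

#' Four-quadrant symmetrization
#'
#' Replaces each bin by the weight-weighted mean of its up-to-four mirror
#' bins (+-R, +-Z). Bins empty in all four quadrants stay empty; the result
#' is symmetric under R -> -R and Z -> -Z and the operation is idempotent.
#'
#' @param rzmap An `rz_map` on a grid symmetric about both axes.
#' @return Symmetrized `rz_map`.
#' @export
symmetrize_quadrants <- function(rzmap) {
  I <- rzmap$intensity; W <- rzmap$weight
  rev2 <- function(m, rows, cols) {
    if (rows) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (cols) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }
  num <- I * W
  nsum <- num + rev2(num, TRUE, FALSE) + rev2(num, FALSE, TRUE) +
    rev2(num, TRUE, TRUE)
  wsum <- W + rev2(W, TRUE, FALSE) + rev2(W, FALSE, TRUE) +
    rev2(W, TRUE, TRUE)
  out <- rzmap
  out$intensity <- ifelse(wsum > 0, nsum / pmax(wsum, 1), 0)
  out$weight <- wsum / 4
  out
}

#' Subtract the circularly symmetric background
#'
#' The detector background is circularly symmetric once the polarization
#' factor has been divided out (which [map_to_rz()] does by default). Since
#' the signal is confined to layer lines, the radial background profile
#' b(|q|) is estimated as the median of bin intensities over annuli,
#' excluding bins within `halfwidth` of any layer-line Z, and subtracted
#' everywhere. Negative results are clipped at zero; the unclipped map is
#' kept in `$intensity_raw` and the profile in `$background`.
#'
#' @param rzmap An `rz_map`.
#' @param layerline_z Z positions (1/A) of the layer lines to exclude,
#'   including the equator (0). Alternatively a single number interpreted as
#'   an axial repeat c (A), expanding to multiples of 1/c over the grid.
#' @param halfwidth Exclusion half-width in Z, 1/A.
#' @param bg_bin Radial bin width, 1/A; default two grid steps.
#' @return The background-subtracted `rz_map`.
#' @export
subtract_circular_background <- function(rzmap, layerline_z, halfwidth,
                                         bg_bin = NULL) {
  if (is.null(bg_bin)) bg_bin <- 2 * rzmap$dr
  if (length(layerline_z) == 1 && layerline_z > 1) {
    c_A <- layerline_z
    lmax <- floor(max(abs(rzmap$Z)) * c_A) + 1
    layerline_z <- (-lmax:lmax) / c_A
  }
  qmat <- sqrt(outer(rzmap$Z^2, rzmap$R^2, "+"))
  nearline <- vapply(rzmap$Z, function(z)
    any(abs(z - layerline_z) < halfwidth), logical(1))
  est <- rzmap$weight > 0 & !matrix(nearline, length(rzmap$Z),
                                    length(rzmap$R))
  if (!any(est))
    stop("layer-line mask too wide: no bins left for the background",
         call. = FALSE)
  rbin <- floor(qmat / bg_bin)
  med <- tapply(rzmap$intensity[est], rbin[est], stats::median)
  qq <- (as.numeric(names(med)) + 0.5) * bg_bin
  bfun <- stats::approx(qq, as.numeric(med), xout = as.vector(qmat),
                        rule = 2)$y
  bmat <- matrix(bfun, length(rzmap$Z), length(rzmap$R))
  raw <- rzmap$intensity - bmat
  raw[rzmap$weight == 0] <- 0
  out <- rzmap
  out$intensity_raw <- raw
  out$background <- bmat
  out$intensity <- pmax(raw, 0)
  out
}
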