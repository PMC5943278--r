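test_that("mapping to (R, Z) conserves photons and places deltas correctly", {
  geom <- micro_geom()
  qm <- build_qmap(geom)
  or <- orientation(41, 3)
  fr <- withr::with_seed(4, matrix(rpois(64 * 64, 0.5), 64, 64))
  mask <- serialfiber:::default_mask(geom = geom)

  # exact integer conservation without the polarization correction
  m <- map_to_rz(fr, qm, or, mask = mask, polarization_correct = FALSE)
  expect_equal(sum(m$intensity * m$weight), sum(as.numeric(fr[mask])),
               tolerance = 1e-12)
  # with the correction, the corrected photon sum is conserved
  m2 <- map_to_rz(fr, qm, or, mask = mask)
  expect_equal(sum(m2$intensity * m2$weight), sum(fr[mask] / qm$pol[mask]),
               tolerance = 1e-12)

  # single bright pixel -> exactly one nonzero bin at its fiber coordinates
  one <- matrix(0L, 64, 64); one[20, 45] <- 7L
  m1 <- map_to_rz(one, qm, or, mask = matrix(TRUE, 64, 64),
                  polarization_correct = FALSE)
  filled <- which(m1$intensity > 0, arr.ind = TRUE)
  expect_equal(nrow(filled), 1)
  fc <- fiber_frame_coords(qm, or)
  expect_lt(abs(m1$R[filled[1, 2]] - fc$R[20, 45]), m1$dr / 2 + 1e-12)
  expect_lt(abs(m1$Z[filled[1, 1]] - fc$Z[20, 45]), m1$dz / 2 + 1e-12)
  expect_equal(sum(m1$intensity * m1$weight), 7)

  # uniform frame at beta = 0: the Z-marginal intensity is uniform to < 2%
  ones <- matrix(1L, 64, 64)
  mu <- map_to_rz(ones, qm, orientation(90, 0), mask = matrix(TRUE, 64, 64),
                  polarization_correct = FALSE)
  marg <- rowSums(mu$intensity * mu$weight) / pmax(rowSums(mu$weight), 1)
  inner <- abs(mu$Z) < 0.7 * max(mu$Z)
  have <- inner & rowSums(mu$weight) > 0
  expect_lt(max(abs(marg[have] - 1)), 0.02)

  expect_error(map_to_rz(fr, qm, or, grid = rz_grid(1e-9, 1e-9, 1e-9)),
               "grid too small")
})

test_that("merging scales least-squares and is permutation invariant", {
  base <- toy_rzmap(8, 8, fill = function(R, Z) 1 + 10 * exp(-Z^2 / 2e-4))
  # two identical maps: scale 1, merge equals input
  mg <- merge_rzmaps(list(base, base))
  expect_equal(mg$intensity, base$intensity, tolerance = 1e-12)
  expect_equal(mg$provenance$scale, c(1, 1), tolerance = 1e-12)

  # a map and its doubled copy merge back to the reference (most photons =
  # the doubled copy); the merge is proportional to the input with the
  # non-reference frame scaled by the intensity ratio
  dbl <- base; dbl$intensity <- 2 * base$intensity
  mg2 <- merge_rzmaps(list(base, dbl))
  expect_equal(mg2$intensity / 2, base$intensity, tolerance = 1e-12)
  expect_equal(mg2$provenance$scale, c(2, 1), tolerance = 1e-12)

  # permutation invariance given the same (most-photon) reference
  a <- toy_rzmap(8, 8, fill = function(R, Z) 3 + exp(-(Z - 0.02)^2 / 1e-4))
  b <- toy_rzmap(8, 8, fill = function(R, Z) 1.7 * (3 + exp(-(Z - 0.02)^2 / 1e-4)))
  c3 <- toy_rzmap(8, 8, fill = function(R, Z) 0.4 * (3 + exp(-(Z - 0.02)^2 / 1e-4)))
  m_abc <- merge_rzmaps(list(a, b, c3))
  m_cba <- merge_rzmaps(list(c3, b, a))
  expect_equal(m_abc$intensity, m_cba$intensity, tolerance = 1e-10)

  # disjoint coverage raises an error naming the frame
  left <- toy_rzmap(8, 8, fill = function(R, Z) 1 + 0 * R)
  left$weight[, 1:9] <- 0
  right <- toy_rzmap(8, 8, fill = function(R, Z) 1 + 0 * R)
  right$weight[, 9:17] <- 0
  right$provenance <- tibble::tibble(frame_id = 99L, phi = 0, beta = 0,
                                     scale = 1)
  expect_error(merge_rzmaps(list(left, right)), "99")
})

test_that("four-quadrant symmetrization is a weighted mirror average and idempotent", {
  set.seed(11)
  m <- toy_rzmap(6, 7, fill = function(R, Z) matrix(runif(length(R)), nrow(R)),
                 weight = 1)
  m$weight <- matrix(rpois(length(m$weight), 3), nrow(m$weight))
  s <- symmetrize_quadrants(m)
  # independent brute-force reference over the four mirrored maps
  flipR <- function(x) x[, rev(seq_len(ncol(x)))]
  flipZ <- function(x) x[rev(seq_len(nrow(x))), ]
  num <- m$intensity * m$weight
  ref_num <- num + flipR(num) + flipZ(num) + flipZ(flipR(num))
  ref_w <- m$weight + flipR(m$weight) + flipZ(m$weight) +
    flipZ(flipR(m$weight))
  ref <- ifelse(ref_w > 0, ref_num / pmax(ref_w, 1), 0)
  expect_equal(s$intensity, ref, tolerance = 1e-12)
  # symmetric output, idempotent operation
  expect_equal(s$intensity, flipR(s$intensity), tolerance = 1e-12)
  expect_equal(s$intensity, flipZ(s$intensity), tolerance = 1e-12)
  s2 <- symmetrize_quadrants(s)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(s2$weight, s$weight, tolerance = 1e-12)

  # one filled quadrant propagates to all four
  oneq <- toy_rzmap(6, 7, fill = function(R, Z) (R > 0) * (Z > 0) * 5,
                    weight = 0)
  oneq$weight <- (oneq$intensity > 0) * 1
  sq <- symmetrize_quadrants(oneq)
  expect_equal(sum(sq$weight > 0), 4 * sum(oneq$weight > 0))
  # already symmetric map is unchanged
  sym <- toy_rzmap(6, 7, fill = function(R, Z) exp(-(R^2 + Z^2) / 1e-3))
  expect_equal(symmetrize_quadrants(sym)$intensity, sym$intensity,
               tolerance = 1e-12)
})

test_that("circular background subtraction removes the isotropic part and
          preserves layer-line peaks", {
  dr <- 0.002
  # pure isotropic background: residual per radial bin is ~0
  iso <- toy_rzmap(60, 60, dr = dr, dz = dr,
                   fill = function(R, Z) 2 + 5 * sqrt(R^2 + Z^2))
  sub <- subtract_circular_background(iso, layerline_z = c(0, 0.05),
                                      halfwidth = 3 * dr)
  have <- sub$weight > 0
  expect_lt(mean(abs(sub$intensity_raw[have])), 0.02)

  # background + two synthetic layer lines: line peaks preserved within 5%,
  # inter-line residual near zero
  zl <- c(0, 0.04, -0.04)
  fill <- function(R, Z) {
    bgp <- 1 + 20 * exp(-(R^2 + Z^2) / 5e-3)
    sig <- 0
    for (z0 in zl) sig <- sig + 30 * exp(-(Z - z0)^2 / (2 * (dr)^2)) *
      exp(-R^2 / 2e-3)
    bgp + sig
  }
  m <- toy_rzmap(60, 60, dr = dr, dz = dr, fill = fill)
  s2 <- subtract_circular_background(m, layerline_z = zl, halfwidth = 4 * dr)
  iz <- which.min(abs(m$Z - 0.04)); ir <- which.min(abs(m$R))
  truth_peak <- 30
  expect_equal(s2$intensity[iz, ir], truth_peak, tolerance = 0.05)
  between <- abs(abs(m$Z) - 0.02) < 2 * dr
  expect_lt(mean(abs(s2$intensity_raw[between, ])), 0.05 * truth_peak)

  # zero map stays zero; over-wide mask errors out
  z0 <- toy_rzmap(10, 10, fill = function(R, Z) 0 * R)
  sz <- subtract_circular_background(z0, 0, halfwidth = 2 * z0$dz)
  expect_true(all(sz$intensity == 0))
  expect_error(subtract_circular_background(z0, 0, halfwidth = 10),
               "mask too wide")
})

test_that("orientation estimation recovers simulated truth and is equivariant", {
  geom <- demo_geometry()
  qm <- build_qmap(geom)
  cfg <- merge_config(phi_step = 3, beta_range = 8, beta_step = 2)
  mk <- function(phi, beta, seed = 1) {
    simulate_frame(list(list(model = tmv_model(), orient = orientation(phi, beta),
                             psi0 = 0.9)),
                   geom, bg = background_model(0.05),
                   cfg = sim_config(fluence = 5.5e3, seed = seed,
                                    disorientation_deg = 0),
                   qmap = qm)
  }
  f1 <- mk(37, 4)
  e1 <- estimate_orientation(f1, qm, cfg)
  expect_lt(abs(e1$orient$phi - 37), 0.5)
  expect_lt(abs(e1$orient$beta - 4), 0.5)
  expect_equal(e1$confidence, "ok")

  # equivariance: the same filament rotated in-plane by 10 degrees
  f2 <- mk(47, 4)
  e2 <- estimate_orientation(f2, qm, cfg)
  expect_lt(abs((e2$orient$phi - e1$orient$phi) - 10), cfg$phi_step)

  # horizontal-guide criterion at the optimum: Z centroids of detected lines
  # are constant along R within one bin
  m <- map_to_rz(f1, qm, e1$orient)
  lines <- detect_layer_lines(m)
  strong <- lines[abs(lines$l) %in% c(3, 6) & !is.na(lines$l), ]
  expect_gte(nrow(strong), 1)
  for (k in seq_len(nrow(strong))) {
    rows <- abs(m$Z - strong$Z[k]) <= 2 * m$dz
    # centroid in Z computed separately for inner and outer |R|
    w <- m$intensity[rows, ] * m$weight[rows, ]
    absR <- abs(m$R)
    inner <- absR <= stats::median(absR)
    zc_in <- sum(w[, inner] * m$Z[rows]) / sum(w[, inner])
    zc_out <- sum(w[, !inner] * m$Z[rows]) / sum(w[, !inner])
    expect_lt(abs(zc_in - zc_out), m$dz)
  }

  # featureless frame: low-confidence flag, no exception
  flat <- simulate_frame(list(), geom, bg = background_model(0.05),
                         cfg = sim_config(seed = 5), qmap = qm)
  ef <- estimate_orientation(flat, qm, cfg)
  expect_equal(ef$confidence, "low")
})

test_that("end-to-end merge of simulated amyloid frames matches the model", {
  geom <- tiny_geom()
  qm <- build_qmap(geom)
  model <- bombesin_model()
  n <- 10
  fs <- simulate_frameset(0, 0, n, model = model, geom = geom,
                          cfg = sim_config(fluence = 2e7, seed = 31),
                          beta_range = 4)
  grid <- serialfiber:::default_grid(qm)
  maps <- lapply(seq_len(n), function(i) {
    map_to_rz(fs$data[, , i], qm,
              orientation(fs$meta$phi[i], fs$meta$beta[i]),
              grid, mask = fs$mask, frame_id = i)
  })
  merged <- merge_rzmaps(maps)
  symm <- symmetrize_quadrants(merged)
  sub <- subtract_circular_background(
    symm, layerline_z = c(0, 1 / 4.8, -1 / 4.8, 1 / 2.4, -1 / 2.4),
    halfwidth = 4 * symm$dz)
  # merged, subtracted map correlates with the (pixel-sampled) noiseless
  # model intensity on covered bins
  RR <- matrix(sub$R, length(sub$Z), length(sub$R), byrow = TRUE)
  ZZ <- matrix(sub$Z, length(sub$Z), length(sub$R))
  fp <- serialfiber:::pixel_q_step(geom) / sqrt(12)
  truth <- cross_beta_intensity(model, RR, ZZ, footprint = fp)
  have <- sub$weight > 0
  expect_gt(stats::cor(sub$intensity[have], truth[have]), 0.9)

  # merging suppresses the off-peak residual noise of the equatorial profile
  # (sqrt-N trend, measured on unclipped residuals) and raises the SNR
  prof_stats <- function(m) {
    mr <- m; mr$intensity <- m$intensity_raw
    p <- equatorial_profile(mr, band_width_px = 8)
    c(peak = max(p$intensity[p$R > 0.08 & p$R < 0.11], na.rm = TRUE),
      noise = stats::sd(p$intensity[p$R > 0.15], na.rm = TRUE))
  }
  s1 <- subtract_circular_background(
    symmetrize_quadrants(maps[[1]]),
    layerline_z = c(0, 1 / 4.8, -1 / 4.8, 1 / 2.4, -1 / 2.4),
    halfwidth = 4 * symm$dz)
  ps_m <- prof_stats(sub); ps_1 <- prof_stats(s1)
  expect_lt(ps_m["noise"], ps_1["noise"] / 2)
  expect_gt(ps_m["peak"] / ps_m["noise"], ps_1["peak"] / ps_1["noise"])
})
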