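test_that("allowed Bessel orders agree with brute force over the selection rule", {
  brute <- function(l, u, t, n_max) {
    hits <- integer()
    for (n in -n_max:n_max) for (m in -200:200)
      if (l == t * n + u * m) hits <- c(hits, n)
    unique(hits)
  }
  cases <- list(c(0, 49, 3, 50), c(1, 49, 3, 20), c(3, 49, 3, 55),
                c(5, 7, 2, 15), c(-4, 8, 3, 12))
  for (cs in cases) {
    got <- allowed_bessel_orders(cs[1], cs[2], cs[3], cs[4])
    expect_setequal(got, brute(cs[1], cs[2], cs[3], cs[4]))
  }
  expect_equal(allowed_bessel_orders(1, 49, 3, 20), -16L)
  expect_setequal(allowed_bessel_orders(0, 49, 3, 50), c(0L, -49L, 49L))
  # u = 1 imposes no selection: every order is allowed
  expect_setequal(allowed_bessel_orders(1, 1, 1, 3), -3:3)
})

test_that("layer-line intensity equals the atomistic oracle on layer planes", {
  # TMV preset (high n_max so truncation is below the tolerance) plus
  # random low-symmetry helices
  models <- c(list(tmv_model(n_max = 120)),
              lapply(c(101, 202, 303), random_helix))
  n_rep <- 16
  for (m in models) {
    Rmax <- if (m$u == 49) 0.12 else 0.2
    for (l in c(0, 1, 3)) for (R in c(0.25, 0.6, 1) * Rmax)
      for (psi in c(0, 1.1)) {
        q <- c(R * cos(psi), R * sin(psi), l / m$c_A)
        oracle <- atomistic_oracle(m, n_rep, q) / n_rep^2
        ccv <- layerline_intensity(m, l, R, psi_q = psi)
        expect_equal(ccv, oracle, tolerance = 1e-6)
      }
  }
})

test_that("oracle limits: zero frequency, destructive interference, convergence", {
  m <- toy_helix()
  fsum <- sum(m$atoms$f)
  for (n_rep in c(1, 4)) {
    expect_equal(atomistic_oracle(m, n_rep, c(0, 0, 0)),
                 fsum^2 * n_rep^2 * m$u^2, tolerance = 1e-12)
  }
  # q strictly between layer planes: intensity / n_rep^2 -> 0
  # (incommensurate offset so the finite-lattice sum is not already zero)
  q_mid <- c(0.05, 0, 0.37 / m$c_A)
  vals <- sapply(c(4, 16, 64), function(nr)
    atomistic_oracle(m, nr, q_mid) / nr^2)
  expect_lt(vals[3], vals[1] / 10 + 1e-12)
  expect_lt(vals[3], 1e-2 * atomistic_oracle(m, 1, c(0, 0, 0)))
  # on-plane convergence at n_repeats = 64 (oriented form)
  q_on <- c(0.08, 0.03, 2 / m$c_A)
  o64 <- atomistic_oracle(m, 64, q_on) / 64^2
  ccv <- layerline_intensity(m, 2, sqrt(0.08^2 + 0.03^2),
                             psi_q = atan2(0.03, 0.08))
  expect_equal(ccv, o64, tolerance = 1e-6)
})

test_that("meridian selection rule and point-scatterer closed form", {
  m <- toy_helix()  # u = 7: l = 1 not a multiple of u
  expect_equal(layerline_intensity(m, 1, 0), 0)
  expect_equal(layerline_intensity(m, 1, 0, cylindrical_average = TRUE), 0)
  expect_gt(layerline_intensity(m, 0, 0), 0)

  pt <- helix_model(1, 1, 20, tibble::tibble(r = 6, psi = 0, z = 0, f = 1.3),
                    length_A = 100, n_max = 0)
  R <- c(0.02, 0.07, 0.15)
  expect_equal(layerline_intensity(pt, 0, R, cylindrical_average = TRUE),
               1.3^2 * besselJ(2 * pi * R * 6, 0)^2, tolerance = 1e-12)
})

test_that("cylindrical average equals the psi-quadrature of oriented intensity", {
  for (m in list(toy_helix(), random_helix(404))) {
    psis <- 2 * pi * (seq_len(256) - 1) / 256
    for (l in c(0, 2)) for (R in c(0.05, 0.15)) {
      quad <- mean(sapply(psis, function(p)
        layerline_intensity(m, l, R, psi0 = p)))
      cyl <- layerline_intensity(m, l, R, cylindrical_average = TRUE)
      expect_equal(quad, cyl, tolerance = 1e-8)
    }
  }
})

test_that("cross-beta intensity peaks at the configured spacings", {
  m <- bombesin_model()
  # equatorial band maxima at R = 1/34.5, 1/23.8, 1/10.6
  R <- seq(0.005, 0.2, by = 1e-4)
  eq <- cross_beta_intensity(m, R, rep(0, length(R)))
  for (d in m$equatorial_peaks$d) {
    win <- abs(R - 1 / d) < 0.006
    expect_equal(R[win][which.max(eq[win])], 1 / d, tolerance = 2e-3)
  }
  # meridional maxima at Z = 1/4.8 and 1/2.4
  Z <- seq(0.02, 0.5, by = 1e-4)
  mer <- cross_beta_intensity(m, rep(0, length(Z)), Z)
  i1 <- which.max(mer)
  expect_equal(Z[i1], 1 / 4.8, tolerance = 1e-3)
  win2 <- abs(Z - 1 / 2.4) < 0.05
  expect_equal(Z[win2][which.max(mer[win2])], 1 / 2.4, tolerance = 1e-3)
  # off layer lines the intensity decays essentially to zero
  far <- cross_beta_intensity(m, c(0.05, 0.1), c(0.1, 0.15))
  expect_lt(max(far), 1e-6 * max(mer))
})

test_that("simulated background realizes the configured mean within 5%", {
  geom <- tiny_geom()
  cfg <- sim_config(seed = 3)
  fr <- simulate_frame(list(), geom, bg = background_model(0.05), cfg = cfg)
  mask <- attr(fr, "mask")
  expect_equal(mean(fr[mask]), 0.05, tolerance = 0.05)
  # noiseless: the expected map itself realizes the target
  fr0 <- simulate_frame(list(), geom, bg = background_model(0.05),
                        cfg = sim_config(noiseless = TRUE))
  expect_equal(mean(fr0[mask]), 0.05, tolerance = 0.051)
  expect_true(all(fr0 >= 0))
})

test_that("noiseless frames are exact expectations and scale with fluence", {
  geom <- micro_geom()
  fil <- list(list(model = bombesin_model(), orient = orientation(30, 2)))
  f1 <- simulate_frame(fil, geom, bg = NULL,
                       cfg = sim_config(fluence = 1, noiseless = TRUE,
                                        disorientation_deg = 0))
  f2 <- simulate_frame(fil, geom, bg = NULL,
                       cfg = sim_config(fluence = 2, noiseless = TRUE,
                                        disorientation_deg = 0))
  expect_equal(2 * as.vector(f1), as.vector(f2), tolerance = 1e-12)
  expect_gt(sum(f1), 0)
})

test_that("Poisson sampling is seeded, reproducible, and unbiased", {
  geom <- micro_geom()
  fil <- list(list(model = bombesin_model(), orient = orientation(140, -3)))
  cfg <- sim_config(fluence = 2e6, seed = 42)
  a <- simulate_frame(fil, geom, cfg = cfg)
  b <- simulate_frame(fil, geom, cfg = cfg)
  expect_identical(a, b)
  expect_true(is.integer(a) && all(a >= 0))

  # mean over 200 seeded frames matches the expectation within 3 sigma in
  # coarse intensity bins (law of large numbers)
  expd <- simulate_frame(fil, geom, cfg = sim_config(fluence = 2e6,
                                                     noiseless = TRUE))
  n <- 200
  acc <- 0
  for (s in seq_len(n)) {
    acc <- acc + simulate_frame(fil, geom,
                                cfg = sim_config(fluence = 2e6, seed = s))
  }
  mask <- attr(expd, "mask")
  bins <- cut(expd[mask], breaks = c(-1e-9, 0.01, 0.1, 1, Inf))
  mean_obs <- tapply((acc / n)[mask], bins, mean)
  mean_exp <- tapply(expd[mask], bins, mean)
  npix <- tapply(expd[mask], bins, length)
  se <- sqrt(mean_exp / (n * npix))   # Poisson SE of the bin mean
  ok <- is.finite(se) & se > 0
  expect_true(all(abs(mean_obs[ok] - mean_exp[ok]) < 3 * se[ok]))
})

test_that("frame sets carry exact population bookkeeping and determinism", {
  geom <- micro_geom()
  fs <- simulate_frameset(10, 10, 10, model = bombesin_model(), geom = geom,
                          cfg = sim_config(fluence = 2e6, seed = 5))
  expect_equal(dim(fs$data)[3], 30)
  expect_equal(as.vector(table(fs$meta$label)[c("beam_off", "sample_free", "hit")]),
               c(10L, 10L, 10L))
  expect_equal(mean(fs$meta$label == "hit"), 1 / 3)  # hit fraction exact
  expect_true(all(fs$meta$phi[fs$meta$label == "hit"] >= 0 &
                    fs$meta$phi[fs$meta$label == "hit"] < 180))
  fs2 <- simulate_frameset(10, 10, 10, model = bombesin_model(), geom = geom,
                           cfg = sim_config(fluence = 2e6, seed = 5))
  expect_identical(fs$data, fs2$data)
  # beam-off frames are dark
  expect_lt(max(apply(fs$data[, , fs$meta$label == "beam_off"], 3, sum)), 5)
})

test_that("oriented single-rotation patterns break mirror symmetry; the
          cylindrical average does not", {
  m <- tmv_model()
  # layer line l = 3 carries orders n = 1 and n = -48; where both contribute,
  # the oriented intensity differs left/right of the meridian
  R <- seq(0.05, 0.25, by = 0.005)
  right <- layerline_intensity(m, 3, R, psi0 = 0.7, psi_q = 0)
  left <- layerline_intensity(m, 3, R, psi0 = 0.7, psi_q = pi)
  expect_gt(max(abs(right - left) / pmax(right + left, 1e-12)), 0.01)
  cyl_r <- layerline_intensity(m, 3, R, cylindrical_average = TRUE)
  expect_equal(cyl_r, layerline_intensity(m, 3, R, cylindrical_average = TRUE))
  # cylindrical average is manifestly psi-independent (same call), and the
  # psi-quadrature of the oriented asymmetry vanishes
  psis <- 2 * pi * (seq_len(128) - 1) / 128
  quad_r <- rowMeans(sapply(psis, function(p)
    layerline_intensity(m, 3, R, psi0 = p, psi_q = 0)))
  quad_l <- rowMeans(sapply(psis, function(p)
    layerline_intensity(m, 3, R, psi0 = p, psi_q = pi)))
  expect_equal(quad_r, quad_l, tolerance = 1e-8)
})
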