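# Shared fixtures: small geometries and models sized for fast tests.

# 128 x 128 px of 600 um at 85 mm / 8 keV: same q coverage as demo_geometry()
# at 1/16 the pixel count.
tiny_geom <- function() detector_geometry(600, 128, 128, 85, c(64, 64), 8)

# 64 x 64 px, coarse; for statistics-only tests
micro_geom <- function() detector_geometry(1200, 64, 64, 85, c(32, 32), 8)

# two-atom low-symmetry helix for oracle comparisons
toy_helix <- function(u = 7, t = 2, n_max = 40) {
  helix_model(u, t, c_A = 30,
              atoms = tibble::tibble(r = c(3, 7), psi = c(0.4, 2.0),
                                     z = c(1.2, 4.0), f = c(1, 0.7)),
              length_A = 200, n_max = n_max)
}

# random helix with coprime (u, t) from a fixed table
random_helix <- function(seed) {
  ut <- list(c(5, 1), c(7, 2), c(8, 3), c(9, 4), c(11, 3), c(12, 5))
  withr::with_seed(seed, {
    p <- ut[[sample.int(length(ut), 1)]]
    k <- sample(2:4, 1)
    helix_model(p[1], p[2], c_A = stats::runif(1, 20, 60),
                atoms = tibble::tibble(
                  r = stats::runif(k, 1, 10),
                  psi = stats::runif(k, 0, 2 * pi),
                  z = stats::runif(k, 0, 10),
                  f = stats::runif(k, 0.5, 1.5)),
                length_A = 300, n_max = 40)
  })
}

# an rz_map with prescribed intensity/weight for plumbing tests
toy_rzmap <- function(nr = 10, nz = 12, dr = 0.01, dz = 0.01,
                      fill = function(R, Z) 0 * R, weight = 1) {
  g <- rz_grid(nr * dr, nz * dz, dr, dz)
  RR <- matrix(g$R, length(g$Z), length(g$R), byrow = TRUE)
  ZZ <- matrix(g$Z, length(g$Z), length(g$R))
  g$intensity <- fill(RR, ZZ)
  g$weight <- matrix(weight, length(g$Z), length(g$R))
  g
}
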