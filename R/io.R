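#' Write / read frames in CXI-style HDF5
#'
#' Frames are stored as `/entry_1/data_1/data` (photon counts), with the
#' detector mask at `/entry_1/data_1/mask`, a geometry echo under
#' `/entry_1/instrument_1/detector_1`, and, for synthetic sets, ground-truth
#' labels and orientations under `/ground_truth`. Reading tolerates dialect
#' differences: the data are looked up at `/entry_1/data_1/data` and then at
#' `/data`.
#'
#' @param frames A `frame_set` (see [simulate_frameset()]).
#' @param path HDF5 file path.
#' @return `write_frames()` returns `path` invisibly; `read_frames()` returns
#'   a `frame_set`.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "entry_1")
  rhdf5::h5createGroup(path, "entry_1/data_1")
  rhdf5::h5write(frames$data, path, "entry_1/data_1/data")
  rhdf5::h5write(frames$mask * 1L, path, "entry_1/data_1/mask")
  g <- frames$geom
  rhdf5::h5createGroup(path, "entry_1/instrument_1")
  rhdf5::h5createGroup(path, "entry_1/instrument_1/detector_1")
  rhdf5::h5write(g$distance_mm / 1000, path,
                 "entry_1/instrument_1/detector_1/distance")
  rhdf5::h5write(g$pixel_size_um * 1e-6, path,
                 "entry_1/instrument_1/detector_1/x_pixel_size")
  rhdf5::h5write(g$photon_energy_kev * 1000, path,
                 "entry_1/instrument_1/detector_1/photon_energy_ev")
  rhdf5::h5write(g$beam_center_px, path,
                 "entry_1/instrument_1/detector_1/beam_center_px")
  if (!is.null(frames$meta)) {
    rhdf5::h5createGroup(path, "ground_truth")
    rhdf5::h5write(frames$meta$frame_id, path, "ground_truth/frame_id")
    if (!is.null(frames$meta$label))
      rhdf5::h5write(frames$meta$label, path, "ground_truth/label")
    for (col in c("phi", "beta", "psi0"))
      if (!is.null(frames$meta[[col]]))
        rhdf5::h5write(ifelse(is.na(frames$meta[[col]]), -9999,
                              frames$meta[[col]]),
                       path, paste0("ground_truth/", col))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @param geom Optional [detector_geometry()] to attach when the file lacks a
#'   usable geometry echo.
#' @rdname write_frames
#' @export
read_frames <- function(path, geom = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  paths <- file.path(ls$group, ls$name)
  paths <- sub("^/", "", sub("^//", "/", paths))
  dataset <- if ("entry_1/data_1/data" %in% paths) "entry_1/data_1/data"
  else if ("data" %in% paths) "data"
  else stop("not a CXI-style file: expected /entry_1/data_1/data (or /data) in ",
            path, call. = FALSE)
  data <- rhdf5::h5read(path, dataset)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1)
  storage.mode(data) <- "integer"
  mask <- if ("entry_1/data_1/mask" %in% paths)
    rhdf5::h5read(path, "entry_1/data_1/mask") == 1
  else array(TRUE, dim(data)[1:2])
  meta <- tibble::tibble(frame_id = seq_len(dim(data)[3]) - 1L)
  if ("ground_truth/frame_id" %in% paths) {
    meta$frame_id <- as.integer(rhdf5::h5read(path, "ground_truth/frame_id"))
    for (col in c("label", "phi", "beta", "psi0")) {
      p <- paste0("ground_truth/", col)
      if (p %in% paths) {
        v <- rhdf5::h5read(path, p)
        if (is.numeric(v)) v[v == -9999] <- NA
        meta[[col]] <- as.vector(v)
      }
    }
  }
  if (is.null(geom) &&
      "entry_1/instrument_1/detector_1/distance" %in% paths) {
    geom <- detector_geometry(
      pixel_size_um = as.numeric(rhdf5::h5read(
        path, "entry_1/instrument_1/detector_1/x_pixel_size")) * 1e6,
      n_fast = dim(data)[2], n_slow = dim(data)[1],
      distance_mm = as.numeric(rhdf5::h5read(
        path, "entry_1/instrument_1/detector_1/distance")) * 1000,
      beam_center_px = as.numeric(rhdf5::h5read(
        path, "entry_1/instrument_1/detector_1/beam_center_px")),
      photon_energy_kev = as.numeric(rhdf5::h5read(
        path, "entry_1/instrument_1/detector_1/photon_energy_ev")) / 1000)
  }
  rhdf5::h5closeAll()
  structure(list(data = data, mask = mask, geom = geom, meta = meta),
            class = "frame_set")
}

#' Write / read an (R, Z) map in HDF5
#'
#' Layout: `/rz/intensity`, `/rz/weight`, `/rz/R`, `/rz/Z` (axes in 1/A) and
#' `/rz/provenance` (frame ids, phi, beta, scales).
#'
#' @param rzmap An `rz_map`.
#' @param path File path.
#' @return `write_rzmap()` returns `path` invisibly; `read_rzmap()` an
#'   `rz_map`.
#' @export
write_rzmap <- function(rzmap, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "rz")
  rhdf5::h5write(rzmap$intensity, path, "rz/intensity")
  rhdf5::h5write(rzmap$weight, path, "rz/weight")
  rhdf5::h5write(rzmap$R, path, "rz/R")
  rhdf5::h5write(rzmap$Z, path, "rz/Z")
  rhdf5::h5write(as.data.frame(rzmap$provenance), path, "rz/provenance")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_rzmap
#' @export
read_rzmap <- function(path) {
  R <- as.numeric(rhdf5::h5read(path, "rz/R"))
  Z <- as.numeric(rhdf5::h5read(path, "rz/Z"))
  out <- structure(list(
    R = R, Z = Z, dr = R[2] - R[1], dz = Z[2] - Z[1],
    intensity = as.matrix(rhdf5::h5read(path, "rz/intensity")),
    weight = as.matrix(rhdf5::h5read(path, "rz/weight")),
    provenance = tibble::as_tibble(lapply(
      rhdf5::h5read(path, "rz/provenance"), as.vector))),
    class = "rz_map")
  rhdf5::h5closeAll()
  out
}

#' Fixed-target chip layout
#'
#' Hole count and positions of a holey-silicon fixed target: a square frame
#' carrying `windows_fast` x `windows_slow` thinned windows, each with
#' `holes_per_window` holes on a hexagonal lattice. The experiment's chip had
#' 12 x 13 windows of 81 holes each — 12,636 holes over 2.54 x 2.54 cm.
#'
#' @param windows_fast,windows_slow Window grid dimensions.
#' @param holes_per_window Holes per window (a hexagonal-lattice patch).
#' @param window_mm Window edge length, mm.
#' @param frame_mm Chip edge length, mm.
#' @param pitch_um Hole pitch within a window, micrometres.
#' @return List with `n_holes` and a `positions` tibble (window indices and
#'   hole centers `x_mm`, `y_mm` on the chip).
#' @export
layout_model <- function(windows_fast = 12, windows_slow = 13,
                         holes_per_window = 81, window_mm = 0.9,
                         frame_mm = 25.4, pitch_um = 60) {
  stopifnot(windows_fast >= 1, windows_slow >= 1, holes_per_window >= 1)
  n_holes <- as.integer(windows_fast) * as.integer(windows_slow) *
    as.integer(holes_per_window)
  # hexagonal patch: rows of alternating length around a square-ish block
  n_side <- ceiling(sqrt(holes_per_window))
  pitch <- pitch_um / 1000
  hx <- hy <- numeric(0)
  k <- 0; row <- 0
  while (k < holes_per_window) {
    take <- min(n_side, holes_per_window - k)
    xs <- (seq_len(take) - (take + 1) / 2) * pitch +
      (row %% 2) * pitch / 2
    hx <- c(hx, xs)
    hy <- c(hy, rep((row - (n_side - 1) / 2) * pitch * sqrt(3) / 2, take))
    k <- k + take; row <- row + 1
  }
  wx <- (seq_len(windows_fast) - (windows_fast + 1) / 2) *
    (frame_mm / (windows_fast + 1))
  wy <- (seq_len(windows_slow) - (windows_slow + 1) / 2) *
    (frame_mm / (windows_slow + 1))
  pos <- tidyr::expand_grid(wi = seq_len(windows_fast),
                            wj = seq_len(windows_slow),
                            hole = seq_len(holes_per_window))
  pos$x_mm <- wx[pos$wi] + hx[pos$hole]
  pos$y_mm <- wy[pos$wj] + hy[pos$hole]
  list(n_holes = n_holes, positions = pos,
       window_mm = window_mm, frame_mm = frame_mm)
}

# ---- run configuration ----------------------------------------------------

run_config_keys <- c("geometry", "seed", "out_dir", "simulate", "hits",
                     "merge", "profiles", "log_level")

#' Read a pipeline run configuration
#'
#' YAML with top-level keys `geometry` (path to a geometry file, or `demo`),
#' `seed`, `out_dir`, and per-stage blocks `simulate`, `hits`, `merge`,
#' `profiles`. Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(y, class = "run_config")
}

#' Default demonstration configuration
#'
#' A synthetic 40-hit bombesin run at the demonstration geometry (85 mm,
#' 8 keV) with the study's background level (0.050 photons/pixel).
#'
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param preset `"bombesin"`, `"beta_endorphin"` or `"tmv"`.
#' @return A `run_config`.
#' @export
demo_config <- function(out_dir = tempfile("sfrun"), seed = 1,
                        preset = "bombesin") {
  structure(list(
    geometry = "demo",
    seed = seed,
    out_dir = out_dir,
    simulate = list(preset = preset, n_beam_off = 5, n_sample_free = 15,
                    n_hit = 40, fluence = NULL),
    hits = list(beam_off_threshold = 100),
    merge = list(phi_step = 2, beta_range = 8, beta_step = 2),
    profiles = list(band_width_px = if (preset == "beta_endorphin") 22 else 8)
  ), class = "run_config")
}

model_from_preset <- function(preset) {
  switch(preset,
         bombesin = bombesin_model(),
         beta_endorphin = beta_endorphin_model(),
         tmv = tmv_model(),
         stop("unknown preset: ", preset, call. = FALSE))
}

# default fluence per preset: photon budgets chosen so single hits carry
# a few 1e4 signal photons above the 0.05 ph/px background (see vignette)
default_fluence <- function(preset) {
  switch(preset, bombesin = 2e7, beta_endorphin = 2e7, tmv = 5.5e3)
}

#' Run the full reduction pipeline
#'
#' simulate (optional) -> classify -> orient -> map/merge -> symmetrize ->
#' subtract background -> profiles/peaks. Every stage writes its artifact
#' into `out_dir` together with a JSON provenance record; a rerun with the
#' same configuration reproduces all artifacts bit-exactly.
#'
#' @param config A `run_config` (see [read_run_config()], [demo_config()]).
#' @param frames Optional `frame_set` to analyze instead of simulating.
#' @return Invisibly, a list with the classification, orientations tibble,
#'   merged/symmetrized/subtracted maps, layer lines, profile and peak table,
#'   plus `out_dir`.
#' @export
run_pipeline <- function(config, frames = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  out_dir <- config$out_dir %||% tempfile("sfrun")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  geom <- if (identical(config$geometry, "demo") || is.null(config$geometry))
    demo_geometry() else read_geometry(config$geometry)

  preset <- config$simulate$preset %||% "bombesin"
  model <- model_from_preset(preset)
  if (is.null(frames)) {
    sim <- config$simulate
    fl <- sim$fluence %||% default_fluence(preset)
    frames <- simulate_frameset(
      sim$n_beam_off %||% 5, sim$n_sample_free %||% 15, sim$n_hit %||% 40,
      model = model, geom = geom,
      bg = background_model(sim$bg_mean %||% 0.05),
      cfg = sim_config(fluence = fl, seed = seed),
      beta_range = sim$beta_range %||% 5)
    write_frames(frames, file.path(out_dir, "frames.cxi"))
  }
  geom <- frames$geom %||% geom
  qmap <- build_qmap(geom)

  regions <- default_regions(qmap)
  stats <- frame_stats(frames, regions$signal, regions$empty)
  cls <- classify_frames(stats,
                         config$hits$beam_off_threshold %||% 100)
  readr::write_csv(cls, file.path(out_dir, "classification.csv"))

  mc <- merge_config(phi_step = config$merge$phi_step %||% 2,
                     beta_range = config$merge$beta_range %||% 15,
                     beta_step = config$merge$beta_step %||% 2)
  hit_idx <- which(cls$label == "hit")
  grid <- default_grid(qmap)
  maps <- list(); orients <- list()
  for (i in hit_idx) {
    fr <- frames$data[, , i]
    est <- estimate_orientation(fr, qmap, mc, mask = frames$mask)
    orients[[length(orients) + 1]] <- tibble::tibble(
      frame_id = cls$frame_id[i], phi = est$orient$phi,
      beta = est$orient$beta, score = est$score,
      confidence = est$confidence)
    maps[[length(maps) + 1]] <- map_to_rz(fr, qmap, est$orient, grid,
                                          mask = frames$mask,
                                          frame_id = cls$frame_id[i])
  }
  orients <- dplyr::bind_rows(orients)
  readr::write_csv(orients, file.path(out_dir, "orientations.csv"))
  if (!length(maps)) stop("pipeline stage 'orient': no hit frames",
                          call. = FALSE)

  merged <- merge_rzmaps(maps)
  symm <- symmetrize_quadrants(merged)
  lines0 <- detect_layer_lines(symm)
  zl <- if (nrow(lines0)) lines0$Z else 0
  hw <- if (nrow(lines0)) {
    mc$mask_halfwidth_sigma * stats::median(lines0$width)
  } else 3 * symm$dz
  sub <- subtract_circular_background(symm, zl, hw)
  write_rzmap(sub, file.path(out_dir, "merged_rz.h5"))

  lines <- detect_layer_lines(sub)
  readr::write_csv(lines, file.path(out_dir, "layer_lines.csv"))
  bw <- config$profiles$band_width_px %||% 8
  prof <- equatorial_profile(sub, band_width_px = bw)
  readr::write_tsv(dplyr::transmute(prof, d_A = .data$d,
                                    intensity = .data$intensity),
                   file.path(out_dir, "equatorial_profile.tsv"))
  peaks <- find_profile_peaks(prof)
  readr::write_csv(peaks, file.path(out_dir, "peaks.csv"))

  prov <- list(
    stages = c("simulate", "classify", "orient", "merge", "symmetrize",
               "subtract_bg", "profiles"),
    seed = seed, preset = preset,
    geometry = list(n_fast = geom$n_fast, n_slow = geom$n_slow,
                    pixel_size_um = geom$pixel_size_um,
                    distance_mm = geom$distance_mm,
                    photon_energy_kev = geom$photon_energy_kev),
    n_frames = dim(frames$data)[3], n_hits = length(hit_idx),
    package_version = as.character(utils::packageVersion("serialfiber")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(classification = cls, orientations = orients,
                 merged = merged, symmetrized = symm, subtracted = sub,
                 lines = lines, profile = prof, peaks = peaks,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
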