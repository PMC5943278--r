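# Weighted Z-marginal of an rz_map: mean intensity per Z row over bins with
# weight, plus its trend-flattened residual.
z_marginal <- function(rzmap, k_trend = 15) {
  num <- rowSums(rzmap$intensity * rzmap$weight)
  den <- rowSums(rzmap$weight)
  marg <- ifelse(den > 0, num / pmax(den, 1), 0)
  k <- min(k_trend, 2 * floor((length(marg) - 1) / 2) + 1)
  flat <- marg - stats::runmed(marg, k)
  # approximate sampling error of each row mean: counting statistics give
  # var(marginal) ~ marginal / weight; the floor guards empty/low rows
  floor_m <- stats::median(marg[marg > 0])
  if (!is.finite(floor_m) || floor_m <= 0) floor_m <- 1e-12
  se <- sqrt(pmax(marg, 0.2 * floor_m) / pmax(den, 1))
  tibble::tibble(Z = rzmap$Z, marginal = marg, flattened = flat,
                 zstat = ifelse(den > 0, flat / se, 0),
                 covered = den > 0)
}

#' Detect layer lines in an (R, Z) map
#'
#' Finds peaks of the background-flattened Z-marginal intensity above a
#' significance threshold, computes each line's Z centroid by local center of
#' mass, and assigns signed integer indices outward from the equator assuming
#' no missing orders between detected lines.
#'
#' @param rzmap An `rz_map` (oriented; merged or single-frame).
#' @param n_sigma Significance threshold: a line must exceed its
#'   counting-statistics standard error by this factor after trend
#'   flattening.
#' @param k_trend Running-median window (bins) used to flatten the marginal.
#' @param centroid_halfwidth Bins on each side of a peak used for the
#'   center-of-mass centroid and width.
#' @param min_separation Minimum peak separation in bins; closer maxima are
#'   merged into the stronger one.
#' @return Tibble with columns `l`, `Z`, `Z_se`, `width`, `height`; zero rows
#'   when nothing is found.
#' @export
detect_layer_lines <- function(rzmap, n_sigma = 6, k_trend = 15,
                               centroid_halfwidth = 3, min_separation = 4) {
  zm <- z_marginal(rzmap, k_trend)
  y <- zm$flattened
  n <- length(y)
  if (!any(zm$covered)) return(empty_lines())
  # criterion: counting-statistics significance of the flattened excess
  # (a MAD-based empirical threshold would be inflated by the lines
  # themselves when they occupy many rows, and degenerates without
  # background)
  is_peak <- which(y > 0 & zm$zstat > n_sigma &
                     y >= c(-Inf, y[-n]) &
                     y >= c(y[-1], -Inf))
  if (!length(is_peak)) return(empty_lines())
  # merge near-coincident maxima
  is_peak <- is_peak[order(-y[is_peak])]
  keep <- integer()
  for (i in is_peak) {
    if (!length(keep) || all(abs(keep - i) >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  dz <- rzmap$dz
  rows <- lapply(keep, function(i) {
    j <- max(1, i - centroid_halfwidth):min(n, i + centroid_halfwidth)
    w <- pmax(y[j], 0)
    if (sum(w) == 0) return(NULL)
    zc <- sum(w * zm$Z[j]) / sum(w)
    width <- sqrt(pmax(sum(w * (zm$Z[j] - zc)^2) / sum(w), (dz / 4)^2))
    se <- width / sqrt(sum(w) / max(y[j]))
    tibble::tibble(Z = zc, Z_se = se, width = width, height = y[i])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_lines())
  out <- dplyr::arrange(out, .data$Z)
  # index assignment: equator = line nearest 0 (within 1 bin); the
  # fundamental spacing 1/c is the smallest adjacent-line spacing (cluster
  # median, so low orders may be absent without collapsing the indexing)
  eq <- abs(out$Z) < dz
  if (nrow(out) >= 2) {
    gaps <- diff(sort(out$Z))
    d1 <- stats::median(gaps[gaps < 1.45 * min(gaps)])
    l <- ifelse(eq, 0L, as.integer(round(out$Z / d1)))
  } else l <- ifelse(eq, 0L, NA_integer_)
  out$l <- l
  dplyr::select(out, "l", "Z", "Z_se", "width", "height")
}

empty_lines <- function() {
  tibble::tibble(l = integer(), Z = numeric(), Z_se = numeric(),
                 width = numeric(), height = numeric())
}

#' Axial repeat from layer-line spacing
#'
#' Weighted least-squares fit of Z_l = l / c through the origin over the
#' non-equatorial detected lines; returns c = 1/slope and its standard error
#' from the fit residuals.
#'
#' @param lines Tibble from [detect_layer_lines()] (columns `l`, `Z`,
#'   optionally `Z_se` used as inverse-variance weights).
#' @return List with `c_A` (repeat, Angstrom), `stderr`, `n_lines`.
#' @export
estimate_axial_repeat <- function(lines) {
  d <- lines[!is.na(lines$l) & lines$l != 0, ]
  if (nrow(d) < 2)
    stop("need at least 2 non-equatorial layer lines", call. = FALSE)
  w <- if ("Z_se" %in% names(d) && all(is.finite(d$Z_se)) && all(d$Z_se > 0))
    1 / d$Z_se^2 else rep(1, nrow(d))
  slope <- sum(w * d$l * d$Z) / sum(w * d$l^2)
  res <- d$Z - slope * d$l
  s2 <- sum(w * res^2) / max(nrow(d) - 1, 1)
  se_slope <- sqrt(s2 / sum(w * d$l^2))
  list(c_A = 1 / slope, stderr = se_slope / slope^2, n_lines = nrow(d))
}

#' Equatorial band profile
#'
#' Mean intensity of the (symmetrized) map over a band centered on the
#' equator, as a function of the radial coordinate, reported against both R
#' (1/A) and resolution d = 1/R (A). The band width may be given in
#' pixel-equivalent bins (the default grid uses one central-pixel bin), which
#' matches the published settings of 8 pixels (bombesin) and 22 pixels
#' (beta-endorphin).
#'
#' @param rzmap An `rz_map`.
#' @param band_width_px Band full width in pixel-equivalent Z bins.
#' @param band_width Band full width in 1/A (overrides `band_width_px`).
#' @return Tibble with columns `R`, `d`, `intensity` (folded over +-R).
#' @export
equatorial_profile <- function(rzmap, band_width_px = 8, band_width = NULL) {
  if (is.null(band_width)) band_width <- band_width_px * rzmap$dz
  half <- band_width / 2
  if (half > max(rzmap$Z))
    stop("band exceeds the map's Z extent", call. = FALSE)
  rows <- abs(rzmap$Z) <= half
  nr <- (length(rzmap$R) - 1) / 2
  num <- colSums(rzmap$intensity[rows, , drop = FALSE] *
                   rzmap$weight[rows, , drop = FALSE])
  den <- colSums(rzmap$weight[rows, , drop = FALSE])
  # fold signed R onto |R|
  iplus <- (nr + 1):(2 * nr + 1)
  iminus <- (nr + 1):1
  fnum <- num[iplus] + num[iminus] - ifelse(seq_along(iplus) == 1, num[nr + 1], 0)
  fden <- den[iplus] + den[iminus] - ifelse(seq_along(iplus) == 1, den[nr + 1], 0)
  R <- rzmap$R[iplus]
  tibble::tibble(R = R,
                 d = ifelse(R > 0, 1 / R, Inf),
                 intensity = ifelse(fden > 0, fnum / pmax(fden, 1), NA_real_))
}

# Topographic prominence of local maxima of y at indices pk.
peak_prominence <- function(y, pk) {
  vapply(pk, function(i) {
    h <- y[i]
    # walk left until terrain exceeds h; the key col is the minimum en route
    lmin <- h
    j <- i - 1
    while (j >= 1 && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1 }
    left <- if (j >= 1) lmin else min(y[1:i])
    rmin <- h
    j <- i + 1
    while (j <= length(y) && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1 }
    right <- if (j <= length(y)) rmin else min(y[i:length(y)])
    h - max(left, right)
  }, numeric(1))
}

#' Find peaks in an equatorial (or any) profile
#'
#' Local maxima of the smoothed profile, filtered by topographic prominence,
#' with positions refined by a three-point parabola and qualitative intensity
#' labels (s / w / vw) assigned by prominence terciles.
#'
#' @param profile Tibble with columns `R` and `intensity` (as from
#'   [equatorial_profile()]); `NA` intensities are dropped.
#' @param smooth_k Running-mean window (odd number of bins).
#' @param min_prominence Minimum prominence; default 5% of the profile's
#'   dynamic range.
#' @return A peak-table tibble: `axis`, `d` (A), `recip` (1/A), `intensity`
#'   (label), `prominence`, `height`, sorted by decreasing prominence.
#' @export
find_profile_peaks <- function(profile, smooth_k = 5, min_prominence = NULL) {
  d <- profile[is.finite(profile$intensity) & profile$R > 0, ]
  if (nrow(d) < 5) stop("profile needs at least 5 points", call. = FALSE)
  y <- as.numeric(stats::filter(d$intensity, rep(1 / smooth_k, smooth_k),
                                sides = 2))
  ed <- (smooth_k - 1) / 2
  n <- nrow(d)
  y[seq_len(ed)] <- y[ed + 1]
  y[(n - ed + 1):n] <- y[n - ed]
  if (is.null(min_prominence))
    min_prominence <- 0.05 * diff(range(y))
  pk <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  pk <- pk[pk > 1 & pk < n]
  if (!length(pk)) return(empty_peak_table())
  prom <- peak_prominence(y, pk)
  sel <- prom >= min_prominence & prom > 0
  pk <- pk[sel]; prom <- prom[sel]
  if (!length(pk)) return(empty_peak_table())
  Rpk <- vapply(seq_along(pk), function(k) {
    parabolic_peak(d$R, y, pk[k])
  }, numeric(1))
  label <- rep("s", length(pk))
  if (length(pk) >= 2) {
    ter <- cut(rank(prom, ties.method = "first"),
               breaks = stats::quantile(rank(prom, ties.method = "first"),
                                        probs = c(0, 1/3, 2/3, 1)),
               labels = c("vw", "w", "s"), include.lowest = TRUE)
    label <- as.character(ter)
  }
  out <- tibble::tibble(axis = "R", d = 1 / Rpk, recip = Rpk,
                        intensity = label, prominence = prom,
                        height = y[pk])
  dplyr::arrange(out, dplyr::desc(.data$prominence))
}

empty_peak_table <- function() {
  tibble::tibble(axis = character(), d = numeric(), recip = numeric(),
                 intensity = character(), prominence = numeric(),
                 height = numeric())
}

#' Check reciprocal consistency of a peak table
#'
#' Verifies that the `recip` column equals 1/`d` within one unit in the last
#' printed decimal of `recip` (tolerant to printed truncation as well as
#' rounding).
#'
#' @param table Tibble with columns `d` and `recip`.
#' @return The table with columns `recip_expected` and `consistent`.
#' @export
check_reciprocal_consistency <- function(table) {
  digits <- vapply(table$recip, function(v) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(v, scientific = FALSE)))
    nchar(s)
  }, integer(1))
  expected <- 1 / table$d
  tol <- 10^(-digits)
  dplyr::mutate(table,
                recip_expected = expected,
                consistent = abs(expected - .data$recip) <= tol + 1e-12)
}

#' Left/right layer-line asymmetry
#'
#' For each detected layer line, compares the intensity profile right of the
#' meridian with the mirrored left profile over bins covered on both sides:
#' the normalized L1 difference A = sum|I(R) - I(-R)| / sum(I(R) + I(-R))
#' (0 for identical profiles, at most 1), the Pearson correlation of the
#' mirrored profiles, and a Poisson null band for A from weight-matched
#' resampling of the pooled counts.
#'
#' @param rzmap An un-symmetrized `rz_map`.
#' @param lines Tibble from [detect_layer_lines()].
#' @param halfwidth Band half-width in Z around each line, 1/A; default 3
#'   grid steps.
#' @param n_null Number of Poisson resamples for the null band.
#' @param seed Seed for the resampling.
#' @return Tibble with columns `l`, `Z`, `A`, `pearson`, `A_null99`,
#'   `n_bins`. Lines with one-sided coverage are skipped with a message.
#' @export
asymmetry <- function(rzmap, lines, halfwidth = NULL, n_null = 200,
                      seed = 1) {
  if (is.null(halfwidth)) halfwidth <- 3 * rzmap$dz
  nr <- (length(rzmap$R) - 1) / 2
  ip <- (nr + 2):(2 * nr + 1)   # R > 0
  im <- nr:1                    # mirrored R < 0
  rows_of <- function(zc) which(abs(rzmap$Z - zc) <= halfwidth)
  out <- lapply(seq_len(nrow(lines)), function(k) {
    rows <- rows_of(lines$Z[k])
    wp <- colSums(rzmap$weight[rows, ip, drop = FALSE])
    wm <- colSums(rzmap$weight[rows, im, drop = FALSE])
    np <- colSums((rzmap$intensity * rzmap$weight)[rows, ip, drop = FALSE])
    nm <- colSums((rzmap$intensity * rzmap$weight)[rows, im, drop = FALSE])
    both <- wp > 0 & wm > 0
    if (sum(both) < 3) {
      message(sprintf("layer line l = %s skipped: one-sided coverage",
                      lines$l[k]))
      return(NULL)
    }
    Ip <- np[both] / wp[both]
    Im <- nm[both] / wm[both]
    denom <- sum(Ip + Im)
    A <- if (denom > 0) sum(abs(Ip - Im)) / denom else 0
    r <- suppressWarnings(stats::cor(Ip, Im))
    pooled <- (np[both] + nm[both]) / 2
    A_null <- withr::with_seed(seed + k, {
      vapply(seq_len(n_null), function(b) {
        ap <- stats::rpois(length(pooled), pooled) / wp[both]
        am <- stats::rpois(length(pooled), pooled) / wm[both]
        dn <- sum(ap + am)
        if (dn > 0) sum(abs(ap - am)) / dn else 0
      }, numeric(1))
    })
    tibble::tibble(l = lines$l[k], Z = lines$Z[k], A = A, pearson = r,
                   A_null99 = stats::quantile(A_null, 0.99, names = FALSE),
                   n_bins = sum(both))
  })
  dplyr::bind_rows(out)
}
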