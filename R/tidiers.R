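#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an (R, Z) map into a long tibble
#'
#' @param x An `rz_map`.
#' @param drop_empty Drop bins with zero weight.
#' @param ... Unused.
#' @return Tibble with columns `R`, `Z`, `intensity`, `weight`.
#' @method tidy rz_map
#' @export
tidy.rz_map <- function(x, drop_empty = TRUE, ...) {
  out <- tibble::tibble(
    R = rep(x$R, each = length(x$Z)),
    Z = rep(x$Z, times = length(x$R)),
    intensity = as.vector(x$intensity),
    weight = as.vector(x$weight))
  if (drop_empty) out <- out[out$weight > 0, ]
  out
}

#' @method glance rz_map
#' @export
glance.rz_map <- function(x, ...) {
  tibble::tibble(
    n_bins = length(x$intensity),
    n_filled = sum(x$weight > 0),
    photons = sum(x$intensity * x$weight),
    n_frames = nrow(x$provenance),
    dr = x$dr, dz = x$dz,
    r_max = max(x$R), z_max = max(x$Z))
}

#' @method tidy frame_set
#' @export
tidy.frame_set <- function(x, ...) x$meta

#' Plot an (R, Z) map
#'
#' @param object An `rz_map`.
#' @param trans Intensity transform for display (`"log1p"` or `"identity"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rz_map
#' @export
autoplot.rz_map <- function(object, trans = "log1p", ...) {
  df <- tidy(object)
  df$shown <- if (trans == "log1p") log1p(df$intensity) else df$intensity
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$Z,
                                   fill = .data$shown)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "log1p")
      "log(1+I)" else "I") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(R ~ (ring(A)^-1)),
                  y = expression(Z ~ (ring(A)^-1)))
}

#' Plot an equatorial profile with its peak table
#'
#' @param profile Tibble from [equatorial_profile()].
#' @param peaks Optional peak table from [find_profile_peaks()].
#' @return A ggplot of intensity against resolution d = 1/R.
#' @export
plot_equatorial_profile <- function(profile, peaks = NULL) {
  df <- profile[is.finite(profile$intensity) & profile$R > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(R ~ (ring(A)^-1)), y = "mean intensity")
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks$recip,
                                 linetype = "dashed", colour = "red") +
      ggplot2::annotate("text", x = peaks$recip,
                        y = max(df$intensity, na.rm = TRUE),
                        label = sprintf("%.1f Å", peaks$d),
                        angle = 90, vjust = -0.4, size = 3)
  }
  p
}

#' Plot per-frame classification
#'
#' @param object A `frame_classification` tibble.
#' @param ... Unused.
#' @return A ggplot of signal-region photons per frame, coloured by class.
#' @method autoplot frame_classification
#' @export
autoplot.frame_classification <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_total,
                                       y = .data$n_signal,
                                       colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "photons per frame", y = "photons in signal region",
                  colour = NULL)
}
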