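# Base-graphics diagnostic plots for the main result objects.

#' @export
plot.implied_timescales <- function(x, ...) {
  lags <- sort(unique(x$lag))
  procs <- sort(unique(x$process))
  ts <- sapply(procs, function(p) {
    vapply(lags, function(l) {
      v <- x$timescale[x$lag == l & x$process == p]
      if (length(v)) v else NA_real_
    }, numeric(1))
  })
  graphics::matplot(lags, ts, type = "b", pch = 19, log = "y",
                    xlab = "lag (frames)",
                    ylab = "implied timescale (frames)", ...)
  graphics::lines(lags, lags, lty = 2)  # resolution limit t = tau
  invisible(x)
}

#' @export
plot.dos_spectrum <- function(x, ...) {
  graphics::plot(x$frequencies, x$intensity, type = "l",
                 xlab = "frequency (1/ps)",
                 ylab = "density of states I(nu) (ps)", ...)
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  n <- nrow(x$probabilities)
  graphics::image(seq_len(n), seq_len(n), x$probabilities,
                  xlab = "residue", ylab = "residue",
                  zlim = c(0, 1), useRaster = TRUE, ...)
  invisible(x)
}

#' Plot a free-energy landscape as a filled image
#'
#' @param landscape output of [free_energy_landscape()].
#' @param ... passed to [graphics::image()].
#' @export
plot_free_energy <- function(landscape, ...) {
  graphics::image(landscape$x, landscape$y, landscape$free_energy,
                  xlab = "latent 1", ylab = "latent 2", useRaster = TRUE,
                  ...)
  invisible(landscape)
}
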