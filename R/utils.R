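# Physical constants in the MD unit system used throughout the package:
# length nm, time ps, mass amu (g/mol), energy kJ/mol = amu nm^2 ps^-2.
#' Physical constants (MD units)
#'
#' Boltzmann constant in kJ mol^-1 K^-1 (numerically equal to the molar gas
#' constant R in these units), Planck's constant in amu nm^2 ps^-1, and the
#' molar gas constant in J mol^-1 K^-1.
#'
#' @format Named list with elements `kB`, `h`, `R_gas`.
#' @export
idpens_constants <- list(
  kB    = 0.008314462618,  # kJ mol^-1 K^-1 == amu nm^2 ps^-2 K^-1
  h     = 0.399031002,     # amu nm^2 ps^-1
  R_gas = 8.314462618      # J mol^-1 K^-1
)

#' Derive a child random seed from a master seed
#'
#' Every stochastic stage draws its RNG stream from a per-purpose child seed so
#' that stages are individually reproducible and mutually independent. The
#' expansion is a small deterministic integer hash of (master seed, purpose
#' string), kept below 2^31.
#'
#' @param master integer master seed.
#' @param purpose character tag naming the consumer of the stream.
#' @return integer seed.
#' @export
child_seed <- function(master, purpose) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(purpose))
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(purpose)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483587) + 1L
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector/matrix of angles in radians.
#' @return angles wrapped to (-pi, pi], same shape as `x`.
#' @export
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor(x / (2 * pi) + 0.5)
  # floor convention puts -pi in the output range; fold it to +pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# Shortest wrapped absolute difference between two angle arrays.
wrapped_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Assert a row-stochastic matrix.
check_stochastic <- function(T, tol = 1e-10) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    stop("transition matrix must be square")
  }
  if (any(T < -tol)) stop("transition matrix has negative entries")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > max(tol, 1e-8))) {
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  invisible(TRUE)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(T) {
  check_stochastic(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
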