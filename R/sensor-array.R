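#' Construct a hemispheric sensor array
#'
#' Lays out `n_channels` sensors on a spherical-cap patch (head radius
#' ~75 mm) using a Fibonacci lattice, scaled so that the typical
#' nearest-neighbour (centre-to-centre) distance matches `spacing`.
#' The layout emulates a hemispheric gradiometer array positioned over
#' one sensorimotor cortex; only sensor count and pitch are
#' controllable, the exact geometry is a package choice.
#'
#' @param n_channels number of sensors (>= 2).
#' @param spacing target nearest-neighbour distance in mm.
#' @param radius sphere radius in mm.
#' @param seed unused; accepted for interface stability (the lattice is
#'   deterministic).
#' @return An object of class `sensor_array`: a list with `sensor_id`
#'   (character), `position` (n x 3 matrix, mm) and `M_Eu` (symmetric
#'   matrix of pairwise Euclidean distances, mm).
#' @examples
#' arr <- make_sensor_array(76, 13)
#' dim(arr$M_Eu)
#' @export
make_sensor_array <- function(n_channels, spacing = 13, radius = 75,
                              seed = NULL) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 2 || n_channels != round(n_channels)) {
    stop("`n_channels` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a positive scalar (mm)", call. = FALSE)
  }
  n <- as.integer(n_channels)

  if (n == 2L) {
    # two sensors exactly one pitch apart on the cap surface
    pos <- rbind(c(-spacing / 2, 0, radius),
                 c( spacing / 2, 0, radius))
  } else {
    # cap solid angle sized so the realised Fibonacci-lattice pitch
    # matches the target spacing (the lattice packs ~13% tighter than
    # ideal hexagonal, hence the 1.11 area coefficient)
    area <- n * 1.11 * spacing^2
    cos_theta_max <- 1 - area / (2 * pi * radius^2)
    if (cos_theta_max < 0) cos_theta_max <- 0 # never beyond a hemisphere
    i <- seq_len(n) - 0.5
    z <- 1 - (i / n) * (1 - cos_theta_max)   # cos(theta), descending cap fill
    golden <- pi * (3 - sqrt(5))
    phi <- golden * (seq_len(n) - 1)
    sin_theta <- sqrt(pmax(0, 1 - z^2))
    pos <- radius * cbind(sin_theta * cos(phi), sin_theta * sin(phi), z)
  }
  ids <- sprintf("ch%02d", seq_len(n))
  dimnames(pos) <- list(ids, c("x_mm", "y_mm", "z_mm"))
  m_eu <- as.matrix(stats::dist(pos))
  dimnames(m_eu) <- list(ids, ids)
  structure(list(sensor_id = ids, position = pos, M_Eu = m_eu),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  nn <- nn_distances(x)
  cat(sprintf("<sensor_array> %d sensors, median nearest-neighbour %.2f mm\n",
              length(x$sensor_id), stats::median(nn)))
  invisible(x)
}

#' Nearest-neighbour distances of a sensor array
#'
#' @param arr a `sensor_array`.
#' @return numeric vector, one nearest-neighbour distance per sensor (mm).
#' @export
nn_distances <- function(arr) {
  stopifnot(inherits(arr, "sensor_array"))
  d <- arr$M_Eu
  diag(d) <- Inf
  apply(d, 1L, min)
}
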