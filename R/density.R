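# Density simulation from atomic models and map utilities.
#
# Each atom contributes an isotropic Gaussian whose full width at half
# maximum equals the stated resolution (sigma = resolution / (2 sqrt(2 ln 2))
# ~ resolution / 2.355); conventions differ across packages, so this one is
# stated once and tested. Kernels are truncated at 4 sigma (< 0.01% mass).

GAUSS_FWHM <- 2 * sqrt(2 * log(2))
GAUSS_RCUT <- 4

# Rough electron counts for the handful of elements backbone models carry.
ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Density-simulation parameters
#'
#' @param resolution target resolution in Å, interpreted as the FWHM of the
#'   atomic Gaussian; must be at least twice the voxel size.
#' @param voxel_size voxel edge in Å.
#' @param padding margin added around the model bounding box in Å.
#' @param weight_mode `"unit"` (every atom weight 1; the default, suited to
#'   backbone-only models) or `"atomic_number"`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(resolution, voxel_size, padding = 8,
                              weight_mode = c("unit", "atomic_number")) {
  weight_mode <- match.arg(weight_mode)
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 * voxel_size (sampling)", call. = FALSE)
  if (padding < 0) stop("padding must be >= 0", call. = FALSE)
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 padding = padding, weight_mode = weight_mode),
            class = "simulation_params")
}

atom_weights <- function(model, weight_mode) {
  if (weight_mode == "unit") rep(1, nrow(model))
  else {
    z <- ATOMIC_NUMBERS[toupper(model$element)]
    z[is.na(z)] <- 6
    as.numeric(z)
  }
}

#' Simulate a density map from an atomic model
#'
#' The grid spans the model bounding box plus `padding` unless an explicit
#' `grid` (list with `dim` and `origin`) is given. The discrete integral
#' (sum times voxel volume) equals `sum(weights) * (2 pi sigma^2)^(3/2)`
#' within the truncation tolerance.
#'
#' @param model an [atomic_model].
#' @param params a [simulation_params].
#' @param grid optional list(dim = integer(3), origin = numeric(3)) forcing
#'   grid geometry (used when simulating into an existing map frame).
#' @return A [density_map].
#' @export
simulate_map <- function(model, params, grid = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!inherits(model, "atomic_model") || nrow(model) == 0L)
    stop("model must be a non-empty atomic_model", call. = FALSE)
  xyz <- coords_of(model)
  sigma <- params$resolution / GAUSS_FWHM
  vox <- params$voxel_size
  if (is.null(grid)) {
    lo <- apply(xyz, 2, min) - params$padding
    hi <- apply(xyz, 2, max) + params$padding
    origin <- floor(lo / vox) * vox
    dim <- pmax(1L, as.integer(ceiling((hi - origin) / vox)) + 1L)
  } else {
    dim <- as.integer(grid$dim)
    origin <- as.numeric(grid$origin)
  }
  w <- atom_weights(model, params$weight_mode)
  vals <- cpp_splat(xyz, w, dim, origin, vox, sigma, GAUSS_RCUT)
  density_map(array(vals, dim), vox, origin)
}

#' Threshold a map into a boolean mask
#'
#' @param map a [density_map].
#' @param mode `"fraction_of_max"` (threshold at `level * max`, mask is
#'   `values >= threshold`) or `"sd_above_mean"` (threshold at
#'   `mean + level * sd`, mask is `values > threshold`).
#' @param level positive threshold level.
#' @return A logical array of the map's dimensions.
#' @export
auto_mask <- function(map, mode = c("fraction_of_max", "sd_above_mean"),
                      level = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "density_map"))
  if (level <= 0) stop("level must be > 0", call. = FALSE)
  v <- map$values
  if (mode == "fraction_of_max") {
    mx <- max(v)
    if (mx <= 0) {
      warning("map maximum is <= 0; mask is empty", call. = FALSE)
      return(array(FALSE, dim(v)))
    }
    v >= level * mx
  } else {
    v > mean(v) + level * sd(as.vector(v))
  }
}

#' Add white Gaussian noise to a map
#'
#' @param map a [density_map].
#' @param noise_sd_rel noise standard deviation relative to `sd(map)`.
#' @param seed RNG seed; the result is a pure function of map + arguments.
#' @return A [density_map].
#' @export
add_noise <- function(map, noise_sd_rel, seed = 1) {
  stopifnot(inherits(map, "density_map"))
  if (noise_sd_rel < 0) stop("noise_sd_rel must be >= 0", call. = FALSE)
  if (noise_sd_rel == 0) return(map)
  s <- sd(as.vector(map$values)) * noise_sd_rel
  vals <- with_seed(seed, map$values + array(rnorm(length(map$values), sd = s),
                                             dim(map$values)))
  density_map(vals, map$voxel_size, map$origin)
}
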