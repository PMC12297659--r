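#' Construct a density map
#'
#' A `density_map` is a 3-D grid of finite scalars with an isotropic
#' physical voxel size and an origin giving the physical position of the
#' centre of grid index (1,1,1) (0-based index (0,0,0)). Axis order is
#' x-fastest: `values[i, j, k]` indexes (x, y, z).
#'
#' @param values 3-D numeric array of finite values.
#' @param voxel_size voxel edge length (Å for structure maps; the axoneme
#'   statistics module works in nm and says so where it does).
#' @param origin numeric length-3, physical position of the centre of the
#'   first voxel, in the same unit as `voxel_size`.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("density values must all be finite", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 vector", call. = FALSE)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, voxel %.4g, origin (%.4g, %.4g, %.4g)\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an atomic model
#'
#' Flat atom table: one row per atom with element, chain id, residue index,
#' residue name, atom name, Cartesian coordinates in Å, occupancy and
#' B-factor. `(chain, resno, atom)` must be unique.
#'
#' @param atoms data frame with columns `element`, `chain`, `resno`,
#'   `resname`, `atom`, `x`, `y`, `z`, `occupancy`, `b`.
#' @return An object of class `atomic_model` (a data frame).
#' @export
atomic_model <- function(atoms) {
  req <- c("element", "chain", "resno", "resname", "atom",
           "x", "y", "z", "occupancy", "b")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("missing atom columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(atoms) < 1L) stop("model contains no atoms", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) records", call. = FALSE)
  atoms <- atoms[, req]
  class(atoms) <- c("atomic_model", "data.frame")
  atoms
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

coords_of <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Construct a PAE matrix
#'
#' Square matrix of predicted aligned errors in Å with a cap `max_pae`.
#' The matrix need not be symmetric; the diagonal must be at most 1 Å.
#'
#' @param values square numeric matrix of expected position errors (Å).
#' @param max_pae scalar cap in Å (AlphaFold convention default 31.75).
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(values, max_pae = 31.75) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("PAE must be a square matrix", call. = FALSE)
  if (!all(is.finite(values))) stop("PAE entries must be finite", call. = FALSE)
  if (any(values < 0) || any(values > max_pae + 1e-9))
    stop("PAE entries must lie in [0, max_pae]", call. = FALSE)
  if (any(diag(values) > 1 + 1e-9))
    stop("PAE diagonal must be <= 1 Angstrom", call. = FALSE)
  structure(unname(values), max_pae = as.numeric(max_pae),
            class = c("pae_matrix", "matrix"))
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, max_pae %.4g, mean %.3g\n",
              nrow(x), ncol(x), attr(x, "max_pae"), mean(x)))
  invisible(x)
}

particle_cols <- c("filament_id", "arc_nm", "x_nm", "y_nm", "z_nm",
                   "tilt_deg", "psi_deg")

#' Construct a filament particle table
#'
#' One row per picked particle: filament id, arc position along the
#' filament (nm, non-negative and sorted within each filament), coordinates
#' (nm), tilt and psi orientation angles (degrees, in \[-180, 180\]), and an
#' optional class label.
#'
#' @param df data frame with columns `filament_id`, `arc_nm`, `x_nm`,
#'   `y_nm`, `z_nm`, `tilt_deg`, `psi_deg` and optionally `class`.
#' @param warn_unsorted warn (rather than silently fix) when arc positions
#'   need re-sorting within a filament.
#' @return An object of class `particle_table` (a data frame).
#' @export
particle_table <- function(df, warn_unsorted = TRUE) {
  miss <- setdiff(particle_cols, names(df))
  if (length(miss))
    stop("missing particle column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- c(particle_cols, intersect("class", names(df)))
  df <- as.data.frame(df)[, keep]
  if (any(df$arc_nm < 0)) stop("arc positions must be >= 0", call. = FALSE)
  ang <- c(df$tilt_deg, df$psi_deg)
  if (any(ang < -180 - 1e-9 | ang > 180 + 1e-9))
    stop("angles must lie in [-180, 180] degrees", call. = FALSE)
  o <- order(df$filament_id, df$arc_nm)
  if (is.unsorted(o) || any(o != seq_len(nrow(df)))) {
    if (any(tapply(df$arc_nm, df$filament_id, is.unsorted))) {
      if (warn_unsorted)
        warning("arc positions re-sorted within filament(s)", call. = FALSE)
    }
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("particle_table", "data.frame")
  df
}
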