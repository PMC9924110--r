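#' Regular 3-D voxel grid
#'
#' The common container for CT phantoms (Hounsfield units), relative
#' stopping-power maps, dose distributions, and structure masks.  Values are
#' stored in an R array with `dim = c(nx, ny, nz)` (x varies fastest, the
#' column-major convention); the world coordinate of voxel index
#' `(i, j, k)` (1-based) is `origin + (index - 0.5) * spacing` along each
#' axis, i.e. `origin` is the corner of the grid and voxel centers sit half
#' a voxel inside.  All lengths are millimetres.
#'
#' @param values numeric or logical 3-D array, `dim = c(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel size in mm per axis (x, y, z).
#' @param origin numeric length-3, world position (mm) of the grid corner.
#' @param kind what the voxel values represent: `"hu"` (CT numbers),
#'   `"rsp"` (relative stopping power), `"dose"`, or `"mask"` (logical).
#' @return An object of class `vox_grid`.
#' @examples
#' g <- vox_grid(array(0, c(10, 10, 5)), spacing = c(2, 2, 2))
#' dim(g$values)
#' @export
vox_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     kind = c("hu", "rsp", "dose", "mask")) {
  kind <- match.arg(kind)
  pw_check(is.array(values) && length(dim(values)) == 3L,
           "`values` must be a 3-D array")
  pw_check(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
           "`spacing` must be 3 positive finite numbers")
  pw_check(length(origin) == 3L && all(is.finite(origin)),
           "`origin` must be 3 finite numbers")
  if (kind == "mask") {
    storage.mode(values) <- "logical"
  } else {
    pw_check(all(is.finite(values)), "grid values must be finite")
    storage.mode(values) <- "double"
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vox_grid [%s]> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$kind, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  if (x$kind == "mask") {
    cat(sprintf("  %d voxels in mask\n", sum(x$values)))
  } else {
    cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

grid_dim <- function(grid) dim(grid$values)

# world extent: lower corner = origin, upper corner = origin + n * spacing
grid_upper <- function(grid) grid$origin + grid_dim(grid) * grid$spacing

same_grid_geometry <- function(a, b, tol = 1e-9) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "mask") {
  if (!same_grid_geometry(a, b)) {
    pw_abort(sprintf("%s geometry (dim/spacing/origin) does not match the phantom grid",
                     what),
             "protonWET_shape_error")
  }
  invisible(TRUE)
}

# voxel centers along one axis (world mm)
axis_centers <- function(grid, axis) {
  n <- grid_dim(grid)[axis]
  grid$origin[axis] + (seq_len(n) - 0.5) * grid$spacing[axis]
}

# world point (matrix n x 3) -> 1-based voxel index matrix (NA outside grid)
world_to_index <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- matrix(NA_integer_, nrow(pts), 3)
  d <- grid_dim(grid)
  for (a in 1:3) {
    i <- floor((pts[, a] - grid$origin[a]) / grid$spacing[a]) + 1
    i[i < 1 | i > d[a]] <- NA_integer_
    idx[, a] <- as.integer(i)
  }
  idx
}

#' Convert a CT phantom to a relative stopping-power grid
#'
#' Applies the two-stage calibration (HU to mass density to relative stopping
#' power) voxel-wise, producing the stopping-power map the planning-system
#' side of the pipeline works in.
#'
#' @param phantom a `vox_grid` of kind `"hu"`.
#' @param curve a [calibration_curve()].
#' @return A `vox_grid` of kind `"rsp"` on the same geometry.
#' @export
phantom_rsp <- function(phantom, curve) {
  pw_check(inherits(phantom, "vox_grid") && phantom$kind == "hu",
           "`phantom` must be a vox_grid of kind 'hu'")
  v <- phantom$values
  v[] <- hu_to_rsp(as.vector(v), curve)
  vox_grid(v, phantom$spacing, phantom$origin, kind = "rsp")
}

# coerce phantom-or-rsp input used by ray tracing / dose code
as_rsp_grid <- function(phantom, curve = NULL) {
  pw_check(inherits(phantom, "vox_grid"), "`phantom` must be a vox_grid")
  if (phantom$kind == "rsp") return(phantom)
  if (phantom$kind == "hu") {
    pw_check(!is.null(curve), "a calibration curve is required for an HU phantom")
    return(phantom_rsp(phantom, curve))
  }
  pw_abort("phantom must be of kind 'hu' or 'rsp'", "protonWET_validation_error")
}
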