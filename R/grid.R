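#' Regular voxel grid in Leksell stereotactic coordinates
#'
#' A `grid_spec` describes a regular 3D voxel lattice in stereotactic
#' millimetre coordinates (Leksell convention: the unit focus is at
#' (100, 100, 100) mm). `origin` is the coordinate of the *center* of the
#' voxel with index (1, 1, 1); indices are stored 1-based as is natural in R.
#'
#' @param shape integer vector of length 3, voxel counts per axis (x, y, z).
#' @param spacing numeric vector of length 3, mm per voxel per axis.
#'   A scalar is recycled.
#' @param origin numeric vector of length 3, stereotactic mm coordinate of
#'   the center of the first voxel.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(41, 41, 41), 0.5, origin = c(90, 90, 90))
#' grid_axis(g, 3)[1:3]
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite mm coordinates")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param grid a [grid_spec()].
#' @param axis axis index 1..3 or one of `"x"`, `"y"`, `"z"`.
#' @return Numeric vector of voxel-center mm coordinates.
#' @export
grid_axis <- function(grid, axis) {
  stopifnot(inherits(grid, "grid_spec"))
  a <- axis_index(axis)
  grid$origin[a] + (seq_len(grid$shape[a]) - 1L) * grid$spacing[a]
}

axis_index <- function(axis) {
  if (is.character(axis)) {
    a <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(a)) stop("'axis' must be one of \"x\", \"y\", \"z\"")
    return(a)
  }
  a <- as.integer(axis)
  if (is.na(a) || a < 1L || a > 3L) stop("'axis' must be 1, 2 or 3")
  a
}

#' Grid extent (outer voxel edges) per axis
#'
#' @param grid a [grid_spec()].
#' @return 2 x 3 matrix of lower/upper mm bounds.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing + grid$spacing / 2
  rbind(lower = lo, upper = hi)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}
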