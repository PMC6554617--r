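#' Define a regular image lattice
#'
#' A grid specification records the voxel counts and the voxel spacing of the
#' periodic lattice on which all images, basis functions, velocity fields and
#' deformations in this package live.  Two- and three-dimensional lattices are
#' supported.
#'
#' @param dims Integer vector of length 2 or 3: voxels per axis (each >= 4).
#' @param voxel_size Numeric vector of per-axis spacings in mm (each > 0);
#'   recycled to `length(dims)` if scalar.
#' @return An object of class `grid_spec` with elements `dims`, `voxel_size`
#'   and `d` (the dimensionality).
#' @examples
#' g <- grid_spec(c(32, 32))
#' g3 <- grid_spec(c(8, 8, 8), voxel_size = 2)
#' @export
grid_spec <- function(dims, voxel_size = 1) {
  dims <- as.integer(dims)
  if (!(length(dims) %in% c(2L, 3L)))
    stop("grid must be 2D or 3D, got length(dims) = ", length(dims))
  if (any(is.na(dims)) || any(dims < 4L))
    stop("all grid dimensions must be integers >= 4")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, length(dims))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != length(dims) || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be positive and match the number of dimensions")
  structure(list(dims = dims, voxel_size = voxel_size, d = length(dims)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels, spacing %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

nvox <- function(grid) prod(grid$dims)

## Internal checks that a field array conforms to a grid.
## ncomp = NULL accepts either a bare scalar field or any channel count.
check_field <- function(field, grid, ncomp = NULL, what = "field") {
  dm <- dim(field)
  if (is.null(dm)) stop(what, " must be an array")
  d <- grid$d
  if (is.null(ncomp)) {
    ok <- (length(dm) == d && all(dm == grid$dims)) ||
      (length(dm) == d + 1L && all(dm[seq_len(d)] == grid$dims))
  } else if (ncomp == 1L) {
    ok <- (length(dm) == d && all(dm == grid$dims)) ||
      (length(dm) == d + 1L && all(dm[seq_len(d)] == grid$dims) &&
         dm[d + 1L] == 1L)
  } else {
    ok <- length(dm) == d + 1L && all(dm[seq_len(d)] == grid$dims) &&
      dm[d + 1L] == ncomp
  }
  if (!ok) stop(what, " has dimensions [", paste(dm, collapse = ","),
                "] which do not match the grid [",
                paste(grid$dims, collapse = ","), "]")
  invisible(TRUE)
}

## Number of trailing channels of a field on `grid` (1 for a bare array).
n_channels <- function(field, grid) {
  dm <- dim(field)
  if (length(dm) == grid$d) 1L else dm[grid$d + 1L]
}

## Extract channel k of a possibly multi-channel field as a bare array.
get_channel <- function(field, grid, k) {
  if (length(dim(field)) == grid$d) return(field)
  M <- nvox(grid)
  array(field[(k - 1L) * M + seq_len(M)], dim = grid$dims)
}

set_channel <- function(field, grid, k, value) {
  M <- nvox(grid)
  field[(k - 1L) * M + seq_len(M)] <- value
  field
}

zero_field <- function(grid, ncomp = 1L) {
  if (ncomp == 1L) array(0, dim = grid$dims)
  else array(0, dim = c(grid$dims, ncomp))
}
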