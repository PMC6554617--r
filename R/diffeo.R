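## Diffeomorphic deformations by Euler-integrated geodesic shooting, and the
## resampling operations pull (interpolation) and push (its exact adjoint,
## "splatting").
##
## Conventions:
##  * Coordinates are 0-based voxel units; the identity map at voxel x has
##    value x.  Deformation maps are stored unwrapped (identity plus a smooth
##    periodic displacement); wrapping happens only when indexing.
##  * pull(image, psi) samples `image` at psi(x) with (bi/tri)linear
##    interpolation and periodic wrap, so the warped reconstruction is
##    a' = pull(mu + Wa z, psi).
##  * push is the transpose of the interpolation matrix: identical weights,
##    accumulated instead of read.  NaN source values contribute nothing to
##    push; NaN propagates conservatively through pull.

## Identity deformations are pure functions of the grid; cache them.
id_def_cache <- new.env(parent = emptyenv())

#' Identity deformation
#'
#' @param grid A [grid_spec()].
#' @return A `deformation` whose map is the identity grid (0-based voxel
#'   coordinates) and whose Jacobian determinant is 1 everywhere.
#' @export
identity_deformation <- function(grid) {
  key <- paste(c(grid$dims, signif(grid$voxel_size, 10)), collapse = "x")
  def <- id_def_cache[[key]]
  if (!is.null(def)) return(def)
  d <- grid$d
  map <- zero_field(grid, d)
  for (j in seq_len(d))
    map <- set_channel(map, grid, j,
                       per_axis_array(seq_len(grid$dims[j]) - 1, grid, j))
  def <- structure(list(grid = grid, map = map,
                        jac_det = array(1, grid$dims),
                        min_jac = 1, ok = TRUE),
                   class = "deformation")
  def$plan <- interp_plan(map, grid)
  id_def_cache[[key]] <- def
  def
}

identity_map <- function(grid) identity_deformation(grid)$map

#' @export
print.deformation <- function(x, ...) {
  cat(sprintf("<deformation> on %s grid, min |Dpsi| = %.4f%s\n",
              paste(x$grid$dims, collapse = "x"), x$min_jac,
              if (isTRUE(x$ok)) "" else " (NOT diffeomorphic)"))
  invisible(x)
}

as_deformation <- function(map, grid) {
  jd <- det_from_tensor(jacobian_tensor(map, grid), grid)
  mj <- min(jd)
  def <- structure(list(grid = grid, map = map, jac_det = jd, min_jac = mj,
                        ok = mj > 0),
                   class = "deformation")
  def$plan <- interp_plan(map, grid)
  def
}

def_plan <- function(deformation) {
  if (!is.null(deformation$plan)) deformation$plan
  else interp_plan(deformation$map, deformation$grid)
}

## Interpolation plan: corner linear indices and weights for sampling at the
## (arbitrary, periodic) coordinates in `map`.  Returns idx (M x 2^d) and
## w (M x 2^d).  Weights are non-negative and sum to 1 per row.
interp_plan <- function(map, grid) {
  M <- nvox(grid)
  cpp_interp_plan(matrix(as.numeric(map), M, grid$d), grid$dims)
}

## Sample one scalar channel with a precomputed plan.  0 * NaN = NaN, so any
## corner holding NaN makes the output voxel NaN (conservative).
pull_channel <- function(values, plan) {
  cpp_pull_channel(as.numeric(values), plan$idx, plan$w)
}

## Adjoint of pull_channel: splat `values` (at output voxels) back onto the
## source lattice with the same weights.  NaN entries contribute nothing.
push_channel <- function(values, plan) {
  cpp_push_channel(as.numeric(values), plan$idx, plan$w)
}

#' Resample an image along a deformation (pull)
#'
#' Linear interpolation of `image` at the deformed coordinates, with periodic
#' wrap.  Interpolation weights are non-negative and sum to one per output
#' voxel, so constants are reproduced exactly.  `NaN` voxels in the source
#' propagate to every output voxel whose interpolation support touches them
#' with positive weight.
#'
#' @param image Array on the deformation's grid, optionally with trailing
#'   channels.
#' @param deformation A `deformation`.
#' @return The warped image, same shape as `image`.
#' @export
pull <- function(image, deformation) {
  grid <- deformation$grid
  check_field(image, grid, what = "image")
  plan <- def_plan(deformation)
  nc <- n_channels(image, grid)
  if (nc == 1L && length(dim(image)) == grid$d)
    return(array(pull_channel(as.numeric(image), plan), dim = grid$dims))
  out <- image
  for (c in seq_len(nc))
    out <- set_channel(out, grid, c,
                       pull_channel(as.numeric(get_channel(image, grid, c)),
                                    plan))
  out
}

#' Adjoint resampling (push / splatting)
#'
#' The exact transpose of [pull()] with identical interpolation weights, so
#' that `sum(pull(a, psi) * f) == sum(a * push(f, psi))` for all `a`, `f`.
#' `NaN` entries of `image` are skipped (contribute nothing).
#'
#' @inheritParams pull
#' @return The splatted image, same shape as `image`.
#' @export
push <- function(image, deformation) {
  grid <- deformation$grid
  check_field(image, grid, what = "image")
  plan <- def_plan(deformation)
  nc <- n_channels(image, grid)
  if (nc == 1L && length(dim(image)) == grid$d)
    return(array(push_channel(as.numeric(image), plan), dim = grid$dims))
  out <- image
  for (c in seq_len(nc))
    out <- set_channel(out, grid, c,
                       push_channel(as.numeric(get_channel(image, grid, c)),
                                    plan))
  out
}

## Central-difference partial derivative of a periodic scalar array along
## axis j, in voxel units.
central_diff <- function(x, grid, j) {
  n <- grid$dims[j]
  ip <- c(2:n, 1L)
  im <- c(n, 1:(n - 1L))
  d <- grid$d
  if (d == 2L) {
    if (j == 1L) (x[ip, , drop = FALSE] - x[im, , drop = FALSE]) / 2
    else (x[, ip, drop = FALSE] - x[, im, drop = FALSE]) / 2
  } else {
    if (j == 1L) (x[ip, , , drop = FALSE] - x[im, , , drop = FALSE]) / 2
    else if (j == 2L) (x[, ip, , drop = FALSE] - x[, im, , drop = FALSE]) / 2
    else (x[, , ip, drop = FALSE] - x[, , im, drop = FALSE]) / 2
  }
}

## Jacobian tensor of a deformation map: J[, , i, j] = d psi_i / d x_j,
## computed on the displacement so that periodic wrap is harmless.
jacobian_tensor <- function(map, grid, id = identity_map(grid)) {
  d <- grid$d
  J <- array(0, dim = c(grid$dims, d, d))
  M <- nvox(grid)
  for (i in seq_len(d)) {
    disp_i <- get_channel(map, grid, i) - get_channel(id, grid, i)
    for (j in seq_len(d)) {
      block <- central_diff(disp_i, grid, j)
      if (i == j) block <- block + 1
      J[(((j - 1L) * d + (i - 1L)) * M) + seq_len(M)] <- block
    }
  }
  J
}

det_from_tensor <- function(J, grid) {
  d <- grid$d
  M <- nvox(grid)
  jc <- function(i, j) array(J[(((j - 1L) * d + (i - 1L)) * M) + seq_len(M)],
                             dim = grid$dims)
  if (d == 2L) {
    jc(1, 1) * jc(2, 2) - jc(1, 2) * jc(2, 1)
  } else {
    jc(1, 1) * (jc(2, 2) * jc(3, 3) - jc(2, 3) * jc(3, 2)) -
      jc(1, 2) * (jc(2, 1) * jc(3, 3) - jc(2, 3) * jc(3, 1)) +
      jc(1, 3) * (jc(2, 1) * jc(3, 2) - jc(2, 2) * jc(3, 1))
  }
}

jacobian_determinant_map <- function(map, grid) {
  det_from_tensor(jacobian_tensor(map, grid), grid)
}

#' Jacobian determinant field of a deformation
#'
#' Central finite differences with periodic boundaries; positivity of the
#' determinant everywhere certifies local invertibility.
#'
#' @param deformation A `deformation`.
#' @return Array of per-voxel determinants on the grid.
#' @export
jacobian_determinant <- function(deformation) {
  jacobian_determinant_map(deformation$map, deformation$grid)
}

#' Geodesic shooting of an initial velocity field
#'
#' Integrates the EPDiff momentum-conservation equations by Euler steps: the
#' initial momentum is `u0 = L v`; at each step the velocity is recovered by
#' the Green's function `v_t = L^{-1} u_t`, the map is updated by one Euler
#' step of the inverse flow, and the momentum is transported as
#' `u_t = |Dpsi| (Dpsi)^T (u0 o psi)`.  The returned deformation is the one
#' used to resample template-space images into subject space.
#'
#' @param v Initial velocity: array `c(dims, d)` in voxel units.
#' @param op A strictly invertible velocity-kind `linear_operator`.
#' @param n_steps Number of Euler steps (>= 1).
#' @return A `deformation` with the Jacobian determinant field populated and
#'   `ok = FALSE` (with a warning) if `min |Dpsi| <= 0`.
#' @export
geodesic_shoot <- function(v, op, n_steps = 8L) {
  grid <- op$grid
  if (op$kind != "velocity") stop("geodesic_shoot needs a velocity operator")
  check_field(v, grid, ncomp = grid$d, what = "velocity field")
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1L)
  d <- grid$d
  M <- nvox(grid)
  dt <- 1 / n_steps
  id <- identity_map(grid)
  u0 <- matrix(as.numeric(apply_operator(op, v)), M, d)
  u <- u0
  disp <- matrix(0, M, d)
  for (step in seq_len(n_steps)) {
    vt <- if (step == 1L) matrix(as.numeric(v), M, d) else
      matrix(as.numeric(apply_inverse_operator(op, array(u, c(grid$dims, d)))),
             M, d)
    if (any(!is.finite(vt)))
      stop("geodesic_shoot: non-finite velocity at Euler step ", step)
    ## psi <- psi o (id - dt v):  disp(x) <- -dt v(x) + disp(x - dt v(x))
    disp <- cpp_compose_disp(disp, vt, grid$dims, dt)
    if (any(!is.finite(disp)))
      stop("geodesic_shoot: non-finite map at Euler step ", step)
    ## transport the momentum by the current map (not needed after the last)
    if (step < n_steps)
      u <- cpp_transport_momentum(disp, u0, grid$dims)
  }
  def <- as_deformation(id + array(disp, c(grid$dims, d)), grid)
  if (!def$ok)
    warning(sprintf("geodesic_shoot: min |Dpsi| = %.4f <= 0; deformation is folded",
                    def$min_jac))
  def
}

## Spatial gradient of a (multi-channel) template-space image by central
## differences, in voxel units: array c(dims, C, d) (C dropped if 1).
spatial_gradient <- function(image, grid) {
  d <- grid$d
  nc <- n_channels(image, grid)
  out <- array(0, dim = c(grid$dims, nc, d))
  M <- nvox(grid)
  for (c in seq_len(nc)) {
    ch <- get_channel(image, grid, c)
    for (j in seq_len(d))
      out[(((j - 1L) * nc + (c - 1L)) * M) + seq_len(M)] <-
        central_diff(ch, grid, j)
  }
  out
}
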