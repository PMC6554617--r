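## Sobolev regularisation operators on a periodic lattice.
##
## Every operator here is a circulant (translation-invariant) matrix, so it is
## diagonalised exactly by the discrete Fourier transform.  Scalar operators
## have a real per-frequency transfer value alpha(theta); vector (velocity)
## operators have a d x d transfer matrix of the form
##     A(theta) = alpha(theta) I + beta s(theta) s(theta)^T
## where s_j(theta) = sin(theta_j)/h_j is the symbol of the central first
## difference along axis j.  The rank-one coupling comes from the
## linear-elastic and divergence penalties; its inverse is available in closed
## form (Sherman-Morrison), which makes the Green's function a per-frequency
## division.
##
## Discretisation: first derivatives by central differences, the Laplacian by
## the standard second-difference stencil, all scaled by the voxel size.
## Boundary conditions are periodic throughout.

## Per-axis frequency angles broadcast to full arrays on the grid.
theta_arrays <- function(grid) {
  lapply(seq_len(grid$d), function(j) {
    th <- 2 * pi * (seq_len(grid$dims[j]) - 1) / grid$dims[j]
    per_axis_array(th, grid, j)
  })
}

## Broadcast a per-axis vector into a full array varying along axis j.
per_axis_array <- function(v, grid, j) {
  d <- grid$d
  perm <- seq_len(d)
  perm[c(1L, j)] <- perm[c(j, 1L)]
  a <- array(v, dim = grid$dims[perm])
  if (j != 1L) a <- aperm(a, order(perm))
  array(a, dim = grid$dims)
}

op_spectrum_parts <- function(grid) {
  th <- theta_arrays(grid)
  h <- grid$voxel_size
  s <- lapply(seq_len(grid$d), function(j) sin(th[[j]]) / h[j])
  membrane <- Reduce(`+`, lapply(s, function(x) x^2))
  lap <- Reduce(`+`, lapply(seq_len(grid$d), function(j)
    (2 - 2 * cos(th[[j]])) / h[j]^2))
  list(s = s, membrane = membrane, bending = lap^2)
}

#' Build the velocity regularisation operator
#'
#' Discretises the Sobolev quadratic form on vector fields combining five
#' penalties: absolute displacement (`w0`), membrane energy (`w1`), bending
#' energy (`w2`), the symmetric part of the Jacobian, i.e. linear elasticity
#' (`w3`), and divergence (`w4`).  The operator acts on `d`-component vector
#' fields on a periodic lattice and is self-adjoint and positive
#' semi-definite; it is strictly positive definite whenever `w0 > 0`.
#'
#' @param grid A [grid_spec()].
#' @param weights Numeric vector of length 5, all non-negative, at least one
#'   positive: `c(w0, w1, w2, w3, w4)`.
#' @return A `linear_operator` object of kind `"velocity"`.
#' @examples
#' op <- build_velocity_operator(grid_spec(c(8, 8)), c(1e-3, 0, 8, 0.25, 0.5))
#' @export
build_velocity_operator <- function(grid, weights) {
  stopifnot(inherits(grid, "grid_spec"))
  weights <- as.numeric(weights)
  if (length(weights) != 5L || any(!is.finite(weights)) || any(weights < 0))
    stop("velocity weights must be 5 non-negative finite numbers")
  if (all(weights == 0))
    stop("all-zero regularisation weights give a singular operator")
  parts <- op_spectrum_parts(grid)
  alpha <- weights[1] + weights[2] * parts$membrane +
    weights[3] * parts$bending + (weights[4] / 2) * parts$membrane
  beta <- weights[4] / 2 + weights[5]
  structure(list(grid = grid, kind = "velocity", alpha = alpha, beta = beta,
                 s = parts$s, smag2 = parts$membrane, weights = weights),
            class = "linear_operator")
}

#' Build a scalar-field regularisation operator
#'
#' Discretises the Sobolev quadratic form on scalar fields with absolute
#' (`w0`), membrane (`w1`) and bending (`w2`) penalties.  Used both for the
#' appearance basis functions and for the mean template; applied
#' channel-by-channel to multi-channel fields.
#'
#' @param grid A [grid_spec()].
#' @param weights Numeric vector `c(w0, w1, w2)`, all non-negative.
#' @return A `linear_operator` object of kind `"scalar"`.
#' @export
build_scalar_operator <- function(grid, weights) {
  stopifnot(inherits(grid, "grid_spec"))
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0))
    stop("scalar weights must be 3 non-negative finite numbers")
  if (all(weights == 0))
    stop("all-zero regularisation weights give a singular operator")
  parts <- op_spectrum_parts(grid)
  alpha <- weights[1] + weights[2] * parts$membrane + weights[3] * parts$bending
  structure(list(grid = grid, kind = "scalar", alpha = alpha, beta = 0,
                 s = NULL, smag2 = parts$membrane, weights = weights),
            class = "linear_operator")
}

#' @export
print.linear_operator <- function(x, ...) {
  cat(sprintf("<linear_operator> kind=%s on %s grid, weights=(%s)\n",
              x$kind, paste(x$grid$dims, collapse = "x"),
              paste(signif(x$weights, 4), collapse = ", ")))
  invisible(x)
}

fftn <- function(x) stats::fft(x)
ifftn_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## Forward application to one scalar channel (complex-capable).
scalar_channel_apply <- function(op, x, scale) {
  ifftn_re((scale * op$alpha) * fftn(x))
}

#' Apply a regularisation operator (momentum from a field)
#'
#' Computes `L f` exactly, i.e. the same result as multiplying by the dense
#' finite-difference matrix that the operator discretises.  Scalar operators
#' act channel-by-channel on multi-channel fields; velocity operators couple
#' the `d` components through the elastic and divergence terms.
#'
#' @param op A `linear_operator`.
#' @param field For scalar kind an array on the grid (optionally with a
#'   trailing channel dimension); for velocity kind an array with trailing
#'   dimension `d`.
#' @param scale Optional positive scalar multiplying the operator.
#' @return The momentum `scale * L field`, same shape as `field`.
#' @export
apply_operator <- function(op, field, scale = 1) {
  grid <- op$grid
  if (op$kind == "velocity") {
    check_field(field, grid, ncomp = grid$d, what = "velocity field")
    d <- grid$d
    vhat <- lapply(seq_len(d), function(j) fftn(get_channel(field, grid, j)))
    sdot <- Reduce(`+`, lapply(seq_len(d), function(j) op$s[[j]] * vhat[[j]]))
    out <- zero_field(grid, d)
    for (j in seq_len(d)) {
      yj <- scale * (op$alpha * vhat[[j]] + op$beta * op$s[[j]] * sdot)
      out <- set_channel(out, grid, j, ifftn_re(yj))
    }
    out
  } else {
    check_field(field, grid, what = "scalar field")
    nc <- n_channels(field, grid)
    if (nc == 1L && length(dim(field)) == grid$d)
      return(scalar_channel_apply(op, field, scale))
    out <- field
    for (c in seq_len(nc))
      out <- set_channel(out, grid, c,
                         scalar_channel_apply(op, get_channel(field, grid, c),
                                              scale))
    out
  }
}

## Inverse with an optional uniform diagonal shift:  (shift I + scale L)^{-1}.
## The shift is how solve_regularized builds its preconditioner.
apply_inverse_shifted <- function(op, mom, scale = 1, shift = 0) {
  grid <- op$grid
  alpha <- scale * op$alpha + shift
  if (min(alpha) <= 0)
    stop("singular operator: the transfer function is not strictly positive ",
         "(set w0 > 0 for an invertible operator)")
  if (op$kind == "velocity") {
    check_field(mom, grid, ncomp = grid$d, what = "momentum field")
    d <- grid$d
    beta <- scale * op$beta
    bhat <- lapply(seq_len(d), function(j) fftn(get_channel(mom, grid, j)))
    sdot <- Reduce(`+`, lapply(seq_len(d), function(j) op$s[[j]] * bhat[[j]]))
    denom <- alpha * (alpha + beta * op$smag2)
    out <- zero_field(grid, d)
    for (j in seq_len(d)) {
      xj <- bhat[[j]] / alpha - (beta * sdot / denom) * op$s[[j]]
      out <- set_channel(out, grid, j, ifftn_re(xj))
    }
    out
  } else {
    check_field(mom, grid, what = "momentum field")
    nc <- n_channels(mom, grid)
    if (nc == 1L && length(dim(mom)) == grid$d)
      return(ifftn_re(fftn(mom) / alpha))
    out <- mom
    for (c in seq_len(nc))
      out <- set_channel(out, grid, c,
                         ifftn_re(fftn(get_channel(mom, grid, c)) / alpha))
    out
  }
}

#' Apply the inverse of a regularisation operator (Green's function)
#'
#' Solves `L x = momentum` by per-frequency division (scalar kind) or a
#' closed-form per-frequency rank-one solve (velocity kind).  Requires a
#' strictly positive definite operator, i.e. `w0 > 0`.
#'
#' @inheritParams apply_operator
#' @param momentum Field conformable with the operator.
#' @return The field `x` with `apply_operator(op, x) = momentum`.
#' @export
apply_inverse_operator <- function(op, momentum, scale = 1) {
  apply_inverse_shifted(op, momentum, scale = scale, shift = 0)
}

#' Quadratic form of a regularisation operator
#'
#' Computes the (non-negative) Sobolev energy `<field, L field>`.
#'
#' @inheritParams apply_operator
#' @return A single non-negative number.
#' @export
quad_form <- function(op, field, scale = 1) {
  sum(field * apply_operator(op, field, scale = scale))
}

## Apply a per-voxel Hessian field H to a field x.
## H may be NULL (zero), an array matching x (independent diagonal entries),
## or an array c(dims, C, C) of per-voxel symmetric matrices acting on the
## C trailing channels of x.
apply_hessian_field <- function(H, x, grid) {
  if (is.null(H)) return(x * 0)
  dH <- dim(H)
  dx <- dim(x)
  if (length(dH) == length(dx) && all(dH == dx)) return(H * x)
  d <- grid$d
  if (length(dH) != d + 2L)
    stop("unrecognised Hessian field layout")
  C <- dH[d + 1L]
  M <- nvox(grid)
  Hm <- matrix(H, nrow = M)            # columns indexed by (i-1) + C*(j-1) + 1
  xm <- matrix(x, nrow = M)
  out <- matrix(0, M, C)
  for (i in seq_len(C))
    for (j in seq_len(C))
      out[, i] <- out[, i] + Hm[, (i - 1L) + C * (j - 1L) + 1L] * xm[, j]
  array(out, dim = dx)
}

## Mean diagonal entry of a Hessian field, used for the preconditioner shift.
hessian_mean_diag <- function(H, grid, ncomp) {
  if (is.null(H)) return(0)
  dH <- dim(H)
  d <- grid$d
  if (length(dH) == d + 2L) {
    C <- dH[d + 1L]
    M <- nvox(grid)
    Hm <- matrix(H, nrow = M)
    mean(vapply(seq_len(C), function(i)
      mean(Hm[, (i - 1L) + C * (i - 1L) + 1L]), numeric(1)))
  } else {
    mean(H)
  }
}

#' Solve a regularised Gauss-Newton linear system
#'
#' Solves `(H + scale * L) x = g` where `H` is a field of per-voxel
#' non-negative diagonal entries or small symmetric PSD matrices and `L` is a
#' regularisation operator, by preconditioned conjugate gradients with the
#' spectral inverse of `shift + scale * L` as preconditioner (`shift` being
#' the mean diagonal of `H`).
#'
#' @param h_field `NULL`, an array matching `g_field` (diagonal), or an array
#'   `c(dims, C, C)` of per-voxel matrices.
#' @param op A `linear_operator`.
#' @param g_field Right-hand side, conformable with the operator kind.
#' @param scale Positive scalar multiplying the operator.
#' @param tol Relative residual tolerance.
#' @param maxit Iteration budget; exceeding it is an error reporting the
#'   final residual.
#' @return List with elements `x`, `rel_residual` and `iterations`.
#' @export
solve_regularized <- function(h_field, op, g_field, scale = 1,
                              tol = 1e-6, maxit = 1000L) {
  grid <- op$grid
  ncomp <- if (op$kind == "velocity") grid$d else n_channels(g_field, grid)
  shift <- hessian_mean_diag(h_field, grid, ncomp)
  amul <- function(x)
    apply_hessian_field(h_field, x, grid) + apply_operator(op, x, scale = scale)
  pinv <- function(r) apply_inverse_shifted(op, r, scale = scale, shift = shift)

  gnorm <- sqrt(sum(g_field^2))
  if (gnorm == 0)
    return(list(x = g_field * 0, rel_residual = 0, iterations = 0L))
  x <- g_field * 0
  r <- g_field
  z <- pinv(r)
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    rel <- sqrt(sum(r^2)) / gnorm
    if (rel < tol) break
    if (it >= maxit)
      stop(sprintf(
        "solve_regularized did not converge in %d iterations (relative residual %.3e)",
        maxit, rel))
    Ap <- amul(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- pinv(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(x = x, rel_residual = sqrt(sum(r^2)) / gnorm, iterations = it)
}
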