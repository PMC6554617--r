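## Independent dense finite-difference oracle for the regularisation
## operators, assembled coefficient-by-coefficient from the penalty
## definitions (central first differences, second-difference Laplacian,
## periodic wrap).  Kept deliberately naive: explicit circulant shift
## matrices and quadratic forms D' D, never the FFT.

## M x M matrix shifting a vectorised field by one voxel along axis j:
## (S u)(x) = u(x + e_j), periodic.
shift_matrix <- function(grid, j) {
  dims <- grid$dims
  M <- prod(dims)
  coords <- arrayInd(seq_len(M), dims)
  to <- coords
  to[, j] <- (to[, j] %% dims[j]) + 1L   # x + e_j with wrap
  lin <- as.integer((to - 1) %*% cumprod(c(1, dims[-length(dims)]))) + 1L
  S <- matrix(0, M, M)
  S[cbind(seq_len(M), lin)] <- 1
  S
}

## Central first difference and Laplacian as dense matrices.
dense_diff <- function(grid, j) {
  S <- shift_matrix(grid, j)
  (S - t(S)) / (2 * grid$voxel_size[j])
}

dense_laplacian <- function(grid) {
  out <- 0
  for (j in seq_len(grid$d)) {
    S <- shift_matrix(grid, j)
    out <- out + (S + t(S) - 2 * diag(nrow(S))) / grid$voxel_size[j]^2
  }
  out
}

## Dense scalar operator: w0 I + w1 sum_j D_j' D_j + w2 Lap' Lap.
dense_scalar_operator <- function(grid, w) {
  M <- prod(grid$dims)
  out <- w[1] * diag(M)
  if (w[2] != 0)
    for (j in seq_len(grid$d)) {
      D <- dense_diff(grid, j)
      out <- out + w[2] * crossprod(D)
    }
  if (w[3] != 0) {
    L <- dense_laplacian(grid)
    out <- out + w[3] * crossprod(L)
  }
  out
}

## Dense velocity operator on stacked components (comp 1 first), containing
## absolute, membrane, bending, linear-elastic (symmetrised Jacobian) and
## divergence terms.
dense_velocity_operator <- function(grid, w) {
  d <- grid$d
  M <- prod(grid$dims)
  D <- lapply(seq_len(d), function(j) dense_diff(grid, j))
  comp <- function(i) {          # selector P_i: M x dM
    P <- matrix(0, M, d * M)
    P[, (i - 1) * M + seq_len(M)] <- diag(M)
    P
  }
  out <- w[1] * diag(d * M)
  if (w[2] != 0 || w[3] != 0) {
    mem <- 0
    for (j in seq_len(d)) mem <- mem + crossprod(D[[j]])
    bend <- if (w[3] != 0) crossprod(dense_laplacian(grid)) else 0
    for (i in seq_len(d)) {
      blk <- (i - 1) * M + seq_len(M)
      out[blk, blk] <- out[blk, blk] + w[2] * mem + w[3] * bend
    }
  }
  if (w[4] != 0) {
    for (i in seq_len(d))
      for (j in seq_len(d)) {
        Sij <- D[[j]] %*% comp(i) + D[[i]] %*% comp(j)
        out <- out + (w[4] / 4) * crossprod(Sij)
      }
  }
  if (w[5] != 0) {
    R <- 0
    for (i in seq_len(d)) R <- R + D[[i]] %*% comp(i)
    out <- out + w[5] * crossprod(R)
  }
  out
}

## Apply a package operator to every canonical basis field -> dense matrix.
dense_from_operator <- function(op) {
  grid <- op$grid
  d <- grid$d
  M <- prod(grid$dims)
  ncomp <- if (op$kind == "velocity") d else 1L
  n <- ncomp * M
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- array(0, dim = if (ncomp == 1L) grid$dims else c(grid$dims, ncomp))
    e[j] <- 1
    out[, j] <- as.numeric(apply_operator(op, e))
  }
  out
}

## Explicit interpolation matrix of a deformation (for adjointness and
## Hessian-majorisation checks): row x gives the pull weights of voxel x.
dense_interp_matrix <- function(def) {
  grid <- def$grid
  M <- prod(grid$dims)
  Psi <- matrix(0, M, M)
  for (j in seq_len(M)) {
    e <- array(0, dim = grid$dims)
    e[j] <- 1
    Psi[, j] <- as.numeric(pull(e, def))
  }
  Psi
}

## Smooth random velocity with a chosen peak displacement, for shooting and
## warping tests.
random_smooth_velocity <- function(grid, op, peak = 2) {
  v <- array(stats::rnorm(prod(grid$dims) * grid$d), c(grid$dims, grid$d))
  v <- apply_inverse_operator(op, v)
  v <- v - mean(v)
  v * (peak / max(abs(v)))
}

default_vel_op <- function(grid) {
  build_velocity_operator(grid, c(1e-3, 0, 8, 0.25, 0.5))
}

## Tiny rendered ground-truth dataset shared by several tests.
tiny_synthetic <- function(dims = c(24, 24), K = 2, N = 12,
                           noise = "gaussian", noise_level = 0.05,
                           missing_frac = 0, seed = 7) {
  set.seed(seed)
  g <- grid_spec(dims)
  gt <- make_ground_truth_model(g, K = K, noise = noise)
  ds <- render_dataset(gt, N = N, noise_level = noise_level,
                       missing_frac = missing_frac)
  list(grid = g, gt = gt, ds = ds)
}
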