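## Energies (negative log-likelihoods) and their template-space derivatives
## for the three noise models.  Energies are accumulated in subject space over
## observed voxels only (NaN marks missing data and is simply ignored);
## gradients and diagonalised Hessians are returned already pushed through the
## adjoint of the resampling, since every consumer of these quantities (the
## template, basis and latent updates) needs them in template space.

#' Wrap an array as an observed image
#'
#' @param data Array on the grid; `NaN` encodes missing voxels.  For the
#'   categorical model the trailing dimension indexes the `C` classes.
#' @param model One of `"gaussian"`, `"bernoulli"`, `"categorical"`.
#' @param grid A [grid_spec()]; defaults to a unit-spacing grid matching
#'   `data`.
#' @return An `observed_image` with a per-voxel observed mask derived from
#'   `NaN` (a voxel with any missing channel counts as missing).
#' @export
observed_image <- function(data, model = c("gaussian", "bernoulli", "categorical"),
                           grid = NULL) {
  model <- match.arg(model)
  if (is.null(dim(data))) stop("data must be an array")
  if (is.null(grid)) {
    dm <- dim(data)
    gd <- if (model == "categorical") dm[-length(dm)] else dm
    grid <- grid_spec(gd)
  }
  if (model == "categorical") {
    check_field(data, grid, what = "categorical image")
    if (n_channels(data, grid) < 2L)
      stop("categorical images need at least 2 channels")
  } else {
    check_field(data, grid, ncomp = 1L, what = "image")
  }
  nc <- n_channels(data, grid)
  obs <- array(TRUE, dim = grid$dims)
  for (c in seq_len(nc)) obs <- obs & !is.na(get_channel(data, grid, c))
  vals <- data[!is.na(data)]
  if (model %in% c("bernoulli", "categorical") &&
      length(vals) && (min(vals) < -1e-6 || max(vals) > 1 + 1e-6))
    stop(model, " data must lie in [0, 1] where observed")
  structure(list(data = data, mask = obs, model = model, grid = grid),
            class = "observed_image")
}

#' @export
print.observed_image <- function(x, ...) {
  cat(sprintf("<observed_image> %s, %s grid, %.1f%% observed\n",
              x$model, paste(x$grid$dims, collapse = "x"),
              100 * mean(x$mask)))
  invisible(x)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Stable per-voxel softmax over the channel dimension of an M x C matrix.
softmax_rows <- function(A) {
  mx <- do.call(pmax, c(as.data.frame(A), na.rm = FALSE))
  E <- exp(A - mx)
  s <- rowSums(E)
  list(s = E / s, lse = mx + log(s))
}

#' Energy, gradient and Hessian of a noise model
#'
#' Warps the template-space appearance `a` by `deformation`, evaluates the
#' negative log-likelihood of `f` over its observed voxels, and returns the
#' gradient and a diagonally-majorised Hessian with respect to `a`, both
#' already pushed back to template space.  For the categorical model the
#' Hessian is a per-voxel `C x C` matrix field; otherwise a non-negative
#' per-voxel diagonal.
#'
#' @param f An [observed_image()].
#' @param a Template-space appearance (same channels as `f`).
#' @param deformation A `deformation` (use [identity_deformation()] for
#'   unwarped evaluation).
#' @param sigma2 Noise variance (Gaussian model only, > 0).
#' @param want_derivs If `FALSE`, only the energy (cheaper line-search path).
#' @return List with `energy`, `grad`, `hess`, `n_obs`, and for the Gaussian
#'   model `resid_ss` (sum of squared observed residuals).
#' @export
energy_derivs <- function(f, a, deformation, sigma2 = NULL,
                          want_derivs = TRUE) {
  stopifnot(inherits(f, "observed_image"))
  grid <- f$grid
  check_field(a, grid, what = "appearance")
  plan <- def_plan(deformation)
  M <- nvox(grid)
  obs <- as.numeric(f$mask)
  switch(f$model,
    gaussian = {
      if (is.null(sigma2) || sigma2 <= 0)
        stop("gaussian model needs sigma2 > 0")
      ap <- pull_channel(as.numeric(a), plan)
      r <- ap - as.numeric(f$data)
      r[obs == 0] <- 0
      r[is.na(r)] <- 0
      n_obs <- sum(obs)
      energy <- 0.5 * sum(r^2) / sigma2 +
        0.5 * n_obs * (log(sigma2) + log(2 * pi))
      if (!want_derivs)
        return(list(energy = energy, n_obs = n_obs, resid_ss = sum(r^2)))
      grad <- array(push_channel(r / sigma2, plan), dim = grid$dims)
      hess <- array(push_channel(obs / sigma2, plan), dim = grid$dims)
      list(energy = energy, grad = grad, hess = hess, n_obs = n_obs,
           resid_ss = sum(r^2))
    },
    bernoulli = {
      ap <- pull_channel(as.numeric(a), plan)
      fv <- as.numeric(f$data)
      keep <- obs == 1 & !is.na(ap)
      n_obs <- sum(keep)
      energy <- sum(softplus(ap[keep]) - fv[keep] * ap[keep])
      if (!want_derivs) return(list(energy = energy, n_obs = n_obs))
      s <- stats::plogis(ap)
      g <- s - fv
      g[!keep] <- 0
      h <- s * (1 - s)
      h[!keep] <- 0
      list(energy = energy,
           grad = array(push_channel(g, plan), dim = grid$dims),
           hess = array(push_channel(h, plan), dim = grid$dims),
           n_obs = n_obs)
    },
    categorical = {
      C <- n_channels(f$data, grid)
      A <- matrix(NA_real_, M, C)
      Fm <- matrix(as.numeric(f$data), M, C)
      for (c in seq_len(C))
        A[, c] <- pull_channel(as.numeric(get_channel(a, grid, c)), plan)
      keep <- obs == 1 & rowSums(is.na(A)) == 0
      n_obs <- sum(keep)
      sm <- softmax_rows(A)
      energy <- sum(sm$lse[keep]) - sum((A * Fm)[keep, , drop = FALSE])
      if (!want_derivs) return(list(energy = energy, n_obs = n_obs))
      grad <- array(0, dim = c(grid$dims, C))
      for (c in seq_len(C)) {
        g <- sm$s[, c] - Fm[, c]
        g[!keep] <- 0
        grad <- set_channel(grad, grid, c, push_channel(g, plan))
      }
      hess <- array(0, dim = c(grid$dims, C, C))
      for (i in seq_len(C))
        for (j in seq_len(i)) {
          h <- if (i == j) sm$s[, i] * (1 - sm$s[, i]) else
            -sm$s[, i] * sm$s[, j]
          h[!keep] <- 0
          hp <- push_channel(h, plan)
          hess[(((j - 1L) * C + (i - 1L)) * M) + seq_len(M)] <- hp
          if (i != j)
            hess[(((i - 1L) * C + (j - 1L)) * M) + seq_len(M)] <- hp
        }
      list(energy = energy, grad = grad, hess = hess, n_obs = n_obs)
    })
}

#' Maximum-likelihood update of the Gaussian noise variance
#'
#' @param resid_ss Total sum of squared observed residuals over all images.
#' @param n_obs Total observed voxel count.
#' @param floor Lower bound kept to avoid degenerate likelihoods on noiseless
#'   data.
#' @return The updated variance.
#' @export
update_sigma2 <- function(resid_ss, n_obs, floor = 1e-6) {
  if (n_obs <= 0) return(floor)
  max(resid_ss / n_obs, floor)
}

## Expected data image for a given warped linear predictor, per noise model.
mean_function <- function(ap, model, grid) {
  switch(model,
    gaussian = ap,
    bernoulli = stats::plogis(ap),
    categorical = {
      C <- n_channels(ap, grid)
      M <- nvox(grid)
      A <- matrix(as.numeric(ap), M, C)
      array(softmax_rows(A)$s, dim = c(grid$dims, C))
    })
}

## Per-voxel predictive log-likelihood of `truth` under predictor `ap`
## (subject-space linear predictor), restricted to voxels in `sel` (logical).
predictive_loglik <- function(ap, truth, model, grid, sel, sigma2 = NULL) {
  M <- nvox(grid)
  sel <- as.logical(sel)
  switch(model,
    gaussian = {
      r <- (as.numeric(truth) - as.numeric(ap))[sel]
      sum(-0.5 * log(2 * pi * sigma2) - r^2 / (2 * sigma2))
    },
    bernoulli = {
      av <- as.numeric(ap)[sel]
      fv <- as.numeric(truth)[sel]
      sum(fv * av - softplus(av))
    },
    categorical = {
      C <- n_channels(truth, grid)
      A <- matrix(as.numeric(ap), M, C)[sel, , drop = FALSE]
      Fm <- matrix(as.numeric(truth), M, C)[sel, , drop = FALSE]
      sm <- softmax_rows(A)
      sum(rowSums(A * Fm) - sm$lse)
    })
}
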