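## The shape-and-appearance model and its fitting algorithm.
##
## Each image f_n is modelled by a latent K-vector z_n through
##   a_n  = mu + W^a z_n          (appearance in template space)
##   v_n  = W^v z_n               (initial velocity)
##   f_n ~ noise(pull(a_n, shoot(v_n)))
## with z_n ~ N(0, A^{-1}) and A given a Wishart prior.  Fitting alternates
## single line-searched Gauss-Newton updates of mu, the appearance basis and
## the velocity basis with latent updates (plus Laplace covariances), a
## variational update of the expected precision A-hat, and an
## orthogonalisation step that keeps the rows of Z orthogonal so that the
## per-column (block-Jacobi) basis updates remain well conditioned.

#' Fitting configuration
#'
#' @param K Number of latent modes in `"shared"` mode (each latent drives
#'   both shape and appearance).
#' @param K_a,K_v Numbers of appearance and shape modes in `"split"` mode
#'   (separate latents; either may be 0 for shape-only / appearance-only
#'   models).  The full latent dimension is then `K_a + K_v`.
#' @param mode `"shared"` or `"split"`.
#' @param lambda Length-2 non-negative weights `c(lambda1, lambda2)` of the
#'   two regularisation strategies (Wishart-governed latent prior vs
#'   smoothness of the reconstructions); their sum must be positive.
#' @param n_iter Outer iterations.
#' @param n_shoot Euler steps for geodesic shooting.
#' @param omega_v Velocity operator weights (length 5).
#' @param omega_a Appearance operator weights (length 3).
#' @param omega_mu Mean operator weights (length 3); scaled by `N` when
#'   `scale_mu_by_N` is `TRUE`.
#' @param noise `"gaussian"`, `"bernoulli"` or `"categorical"`.
#' @param n_latent_iter Gauss-Newton iterations per image in each latent
#'   update stage.
#' @param scale_prior_by_N Scale the basis-function priors by `N` (pushes the
#'   latents towards unit variance); toggleable.
#' @param scale_mu_by_N Scale the mean penalty by `N`.
#' @param nu0 Wishart prior degrees of freedom (default `K`, the least
#'   informative normalisable choice).
#' @param seed Seed for the latent initialisation (the only source of
#'   randomness in fitting).
#' @return A `fit_config` list.
#' @export
fit_config <- function(K = NULL, K_a = NULL, K_v = NULL,
                       mode = c("shared", "split"),
                       lambda = c(0.9, 0.1), n_iter = 8L, n_shoot = 8L,
                       omega_v = c(1e-3, 0, 8, 0.25, 0.5),
                       omega_a = c(0.01, 1, 4),
                       omega_mu = c(1e-4, 0.01, 0.1),
                       noise = c("gaussian", "bernoulli", "categorical"),
                       n_latent_iter = 3L, scale_prior_by_N = TRUE,
                       scale_mu_by_N = TRUE, nu0 = NULL, seed = 1L) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  if (mode == "shared") {
    if (is.null(K)) stop("shared mode needs K")
    K_a <- K_v <- K
  } else {
    if (is.null(K_a) || is.null(K_v)) stop("split mode needs K_a and K_v")
    K <- K_a + K_v
    if (K < 1L) stop("split mode needs K_a + K_v >= 1")
  }
  lambda <- as.numeric(lambda)
  if (length(lambda) != 2L || any(lambda < 0) || sum(lambda) <= 0)
    stop("lambda must be two non-negative weights with positive sum")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  structure(list(K = as.integer(K), K_a = as.integer(K_a),
                 K_v = as.integer(K_v), mode = mode, lambda = lambda,
                 n_iter = as.integer(n_iter), n_shoot = as.integer(n_shoot),
                 omega_v = as.numeric(omega_v), omega_a = as.numeric(omega_a),
                 omega_mu = as.numeric(omega_mu),
                 noise = noise, n_latent_iter = as.integer(n_latent_iter),
                 scale_prior_by_N = isTRUE(scale_prior_by_N),
                 scale_mu_by_N = isTRUE(scale_mu_by_N),
                 nu0 = if (is.null(nu0)) NULL else as.numeric(nu0),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Bundle images into a training dataset
#'
#' @param images List of arrays (NaN marks missing voxels) or
#'   [observed_image()] objects, all on the same grid.
#' @param noise Noise model tag applied to bare arrays.
#' @param grid Optional [grid_spec()].
#' @return A `sam_dataset`.
#' @export
as_dataset <- function(images, noise = c("gaussian", "bernoulli", "categorical"),
                       grid = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.list(images), length(images) >= 1L)
  images <- lapply(images, function(im) {
    if (inherits(im, "observed_image")) im else observed_image(im, noise, grid)
  })
  g <- images[[1]]$grid
  for (im in images)
    if (!identical(im$grid$dims, g$dims))
      stop("all images must share one grid")
  structure(list(images = images, grid = g, noise = images[[1]]$model,
                 N = length(images)),
            class = "sam_dataset")
}

## ---- latent bookkeeping -------------------------------------------------

appearance_index <- function(model) {
  if (model$mode == "shared") seq_len(model$K) else seq_len(model$Ka)
}
shape_index <- function(model) {
  if (model$mode == "shared") seq_len(model$K)
  else model$Ka + seq_len(model$Kv)
}

#' Random latent initialisation with exactly orthogonal rows
#'
#' Draws a K x N matrix whose rows are orthogonal with `Z %*% t(Z) = N * I`
#' exactly (QR of a Gaussian draw, rescaled), which breaks the symmetry of
#' the zero-initialised bases.
#'
#' @param N Number of images (must be >= K).
#' @param K Latent dimension.
#' @return K x N matrix.
#' @export
init_latents <- function(N, K) {
  if (N < K) stop("cannot initialise ", K, " orthogonal latent rows from N = ",
                  N, " images")
  G <- matrix(stats::rnorm(N * K), N, K)
  Q <- qr.Q(qr(G))
  sqrt(N) * t(Q)
}

## ---- model construction -------------------------------------------------

#' Initialise the model, latents and Wishart state
#'
#' The mean is initialised from the unaligned data (observed-voxel mean,
#' through the logit / log link for the Bernoulli / categorical models); both
#' bases start at zero; the latents are random with orthogonal rows; the
#' expected precision starts at `(N + nu0) (N I + Lambda0^{-1})^{-1}`, which
#' is the identity under the default prior `nu0 = K`, `Lambda0 = I / nu0`.
#'
#' @param dataset A [as_dataset()] result.
#' @param config A [fit_config()].
#' @return List with `model` (`sam_model`), `latents` and `wishart`.
#' @export
init_model <- function(dataset, config) {
  stopifnot(inherits(dataset, "sam_dataset"), inherits(config, "fit_config"))
  grid <- dataset$grid
  N <- dataset$N
  K <- config$K
  C <- n_channels(dataset$images[[1]]$data, grid)
  eps <- 1e-3
  acc <- zero_field(grid, C)
  cnt <- zero_field(grid, C)
  for (im in dataset$images) {
    dat <- im$data
    ok <- !is.na(dat)
    dat[!ok] <- 0
    acc <- acc + dat
    cnt <- cnt + ok
  }
  mbar <- acc / pmax(cnt, 1)
  mu <- switch(config$noise,
    gaussian = mbar,
    bernoulli = stats::qlogis(pmin(pmax(mbar, eps), 1 - eps)),
    categorical = log(pmin(pmax(mbar, eps), 1 - eps)))
  if (C == 1L) mu <- array(mu, dim = grid$dims)

  mu_scale <- if (config$scale_mu_by_N) N else 1
  ops <- list(
    Lv = build_velocity_operator(grid, pmax(config$omega_v, c(1e-6, 0, 0, 0, 0))),
    La = build_scalar_operator(grid, config$omega_a),
    Lmu = build_scalar_operator(grid, mu_scale * config$omega_mu))

  sigma2 <- 1
  if (config$noise == "gaussian") {
    ss <- 0; nn <- 0
    for (im in dataset$images) {
      r <- im$data - mu
      r <- r[!is.na(r)]
      ss <- ss + sum(r^2); nn <- nn + length(r)
    }
    sigma2 <- update_sigma2(ss, nn, floor = 1e-6 * max(ss / max(nn, 1), 1e-6))
  }

  nu0 <- if (is.null(config$nu0)) K else config$nu0
  Lambda0_inv <- diag(nu0, K)
  A_hat <- (N + nu0) * solve(N * diag(K) + Lambda0_inv)
  A_hat <- (A_hat + t(A_hat)) / 2

  model <- structure(list(
    grid = grid, noise = config$noise, mode = config$mode,
    K = K, Ka = config$K_a, Kv = config$K_v, C = C, N = N,
    mu = mu,
    Wa = replicate(config$K_a, zero_field(grid, C), simplify = FALSE),
    Wv = replicate(config$K_v, zero_field(grid, grid$d), simplify = FALSE),
    sigma2 = sigma2, A_hat = A_hat,
    ops = ops, config = config), class = "sam_model")

  Z <- init_latents(N, K)
  latents <- list(Z = Z, S = matrix(0, K, K), Cz = Z %*% t(Z))
  wishart <- list(Lambda0_inv = Lambda0_inv, nu0 = nu0,
                  Lambda = A_hat / (N + nu0), nu = nu0 + N)
  list(model = model, latents = latents, wishart = wishart)
}

#' @export
print.sam_model <- function(x, ...) {
  cat(sprintf(
    "<sam_model> %s noise, %s latents (K=%d: %d appearance, %d shape), %s grid\n",
    x$noise, x$mode, x$K, x$Ka, x$Kv, paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

#' Reconstruct appearance and velocity from a latent code
#'
#' @param model A `sam_model`.
#' @param z Latent K-vector.
#' @return List with the template-space appearance `a = mu + W^a z_a` and the
#'   initial velocity `v = W^v z_v`.
#' @export
reconstruct <- function(model, z) {
  stopifnot(length(z) == model$K)
  a <- model$mu
  ia <- appearance_index(model)
  for (k in seq_len(model$Ka)) a <- a + z[ia[k]] * model$Wa[[k]]
  v <- zero_field(model$grid, model$grid$d)
  iv <- shape_index(model)
  for (k in seq_len(model$Kv)) v <- v + z[iv[k]] * model$Wv[[k]]
  list(a = a, v = v)
}

## Deformation for one latent code (identity when there are no shape modes).
shoot_z <- function(model, z) {
  if (model$Kv == 0L) return(identity_deformation(model$grid))
  v <- zero_field(model$grid, model$grid$d)
  iv <- shape_index(model)
  for (k in seq_len(model$Kv)) v <- v + z[iv[k]] * model$Wv[[k]]
  if (all(v == 0)) return(identity_deformation(model$grid))
  geodesic_shoot(v, model$ops$Lv, model$config$n_shoot)
}

compute_deformations <- function(model, Z) {
  lapply(seq_len(ncol(Z)), function(n) shoot_z(model, Z[, n]))
}

## ---- Gram matrices and the joint objective ------------------------------

## Gram matrix of basis columns under an operator: G[k, l] = <w_k, L w_l>.
gram_matrix <- function(W, op) {
  K <- length(W)
  if (K == 0L) return(matrix(0, 0, 0))
  LW <- lapply(W, function(w) apply_operator(op, w))
  G <- matrix(0, K, K)
  for (k in seq_len(K))
    for (l in seq_len(k)) {
      G[k, l] <- G[l, k] <- sum(W[[k]] * LW[[l]])
    }
  G
}

## Full K x K reconstruction-smoothness matrix (W^a)' La W^a + (W^v)' Lv W^v,
## padded into latent index space (block diagonal in split mode).
gram_full <- function(model, Ga = NULL, Gv = NULL) {
  if (is.null(Ga)) Ga <- gram_matrix(model$Wa, model$ops$La)
  if (is.null(Gv)) Gv <- gram_matrix(model$Wv, model$ops$Lv)
  G <- matrix(0, model$K, model$K)
  ia <- appearance_index(model); iv <- shape_index(model)
  if (model$Ka > 0L) G[ia, ia] <- G[ia, ia] + Ga
  if (model$Kv > 0L) G[iv, iv] <- G[iv, iv] + Gv
  G
}

## Latent prior precision lambda1 A + lambda2 (W' L W).
latent_precision <- function(model, Gamma = NULL) {
  if (is.null(Gamma)) Gamma <- gram_full(model)
  lam <- model$config$lambda
  P <- lam[1] * model$A_hat + lam[2] * Gamma
  (P + t(P)) / 2
}

## Sum of per-image energies for given latents and cached deformations.
sum_energies <- function(model, dataset, Z, defs) {
  tot <- 0
  for (n in seq_len(dataset$N)) {
    a <- reconstruct(model, Z[, n])$a
    tot <- tot + energy_derivs(dataset$images[[n]], a, defs[[n]],
                               sigma2 = model$sigma2,
                               want_derivs = FALSE)$energy
  }
  tot
}

#' Joint log-probability of the model (the fitting objective)
#'
#' Evaluates, up to additive constants, the joint log-probability combining
#' the likelihood energies, the mean penalty, the N-scaled basis penalties,
#' the Wishart/latent terms (with the expected precision plugged in) and the
#' reconstruction-smoothness cross term.  All line searches in fitting accept
#' steps only when this does not decrease.
#'
#' @param model,dataset,latents,wishart Current state.
#' @param defs Optional list of cached per-image deformations.
#' @param sumJ Optional precomputed sum of energies.
#' @return A single number (larger is better).
#' @export
joint_log_prob <- function(model, dataset, latents, wishart, defs = NULL,
                           sumJ = NULL) {
  if (is.null(sumJ)) {
    if (is.null(defs)) defs <- compute_deformations(model, latents$Z)
    sumJ <- sum_energies(model, dataset, latents$Z, defs)
  }
  cfg <- model$config
  lam <- cfg$lambda
  N <- dataset$N
  Nfac <- if (cfg$scale_prior_by_N) N else 1
  Ga <- gram_matrix(model$Wa, model$ops$La)
  Gv <- gram_matrix(model$Wv, model$ops$Lv)
  Gamma <- gram_full(model, Ga, Gv)
  Cz <- latents$Cz
  A <- model$A_hat
  ldA <- determinant(A, logarithm = TRUE)$modulus
  K <- model$K
  -sumJ - 0.5 * quad_form(model$ops$Lmu, model$mu) -
    (lam[1] * Nfac / 2) * (sum(diag(Ga)) + sum(diag(Gv))) +
    (lam[1] / 2) * ((N + wishart$nu0 - K - 1) * as.numeric(ldA) -
                      sum((Cz + wishart$Lambda0_inv) * A)) -
    (lam[2] / 2) * sum(Cz * Gamma)
}

## ---- backtracking line search ------------------------------------------

## Generic halving search: obj_fun(candidate(step)) must not exceed obj0.
## Returns list(value, obj, accepted, halvings).
backtrack <- function(obj0, candidate, obj_fun, max_halve = 10L) {
  step <- 1
  for (h in seq_len(max_halve)) {
    cand <- candidate(step)
    obj <- obj_fun(cand)
    if (is.finite(obj) && obj < obj0)
      return(list(value = cand, obj = obj, accepted = TRUE, halvings = h - 1L))
    step <- step / 2
  }
  list(value = NULL, obj = obj0, accepted = FALSE, halvings = max_halve)
}

## ---- Step 1a: mean update ------------------------------------------------

#' Single Gauss-Newton update of the mean template
#'
#' Sums per-image template-space gradients and Hessians, solves one
#' regularised Gauss-Newton step with the mean operator, and backtracks
#' (halving, up to 10 times) on the exact objective; on failure the old mean
#' is kept with a warning.
#'
#' @param model,dataset,latents Current state.
#' @param defs Cached per-image deformations.
#' @return List with the updated `model`, `sumJ` at acceptance and `accepted`.
#' @export
update_mean <- function(model, dataset, latents, defs) {
  grid <- model$grid
  C <- model$C
  g <- zero_field(grid, C)
  H <- if (model$noise == "categorical") array(0, c(grid$dims, C, C))
       else zero_field(grid, C)
  for (n in seq_len(dataset$N)) {
    a <- reconstruct(model, latents$Z[, n])$a
    dv <- energy_derivs(dataset$images[[n]], a, defs[[n]], model$sigma2)
    g <- g + dv$grad
    H <- H + dv$hess
  }
  if (model$noise != "categorical" && C == 1L) {
    g <- array(g, grid$dims); H <- array(H, grid$dims)
  }
  rhs <- g + apply_operator(model$ops$Lmu, model$mu)
  delta <- solve_regularized(H, model$ops$Lmu, rhs)$x
  obj_of <- function(mu_new) {
    m2 <- model; m2$mu <- mu_new
    sum_energies(m2, dataset, latents$Z, defs) +
      0.5 * quad_form(model$ops$Lmu, mu_new)
  }
  obj0 <- sum_energies(model, dataset, latents$Z, defs) +
    0.5 * quad_form(model$ops$Lmu, model$mu)
  ls <- backtrack(obj0, function(s) model$mu - s * delta, obj_of)
  if (ls$accepted) {
    model$mu <- ls$value
  } else {
    warning("update_mean: line search exhausted; keeping previous mean")
  }
  list(model = model, accepted = ls$accepted)
}

## ---- Step 1b: appearance basis ------------------------------------------

## Penalty term paired with the appearance-basis objective.
appearance_penalty <- function(model, latents, Ga) {
  cfg <- model$config
  Nfac <- if (cfg$scale_prior_by_N) model$N else 1
  ia <- appearance_index(model)
  Rw <- cfg$lambda[1] * Nfac * diag(model$Ka) +
    cfg$lambda[2] * latents$Cz[ia, ia, drop = FALSE]
  0.5 * sum(Rw * Ga)
}

#' Gauss-Newton update of the appearance basis
#'
#' One backtracked Gauss-Newton step per column (Gauss-Seidel over columns),
#' with gradient `sum_n z_kn g_n`, Hessian `sum_n z_kn^2 h_n` and regulariser
#' `(lambda1 N + lambda2 [ZZ']_kk) L^a`.  Assumes the rows of Z have been
#' orthogonalised.
#'
#' @inheritParams update_mean
#' @return List with the updated `model`.
#' @export
update_appearance_basis <- function(model, dataset, latents, defs) {
  if (model$Ka == 0L) return(list(model = model, accepted = TRUE))
  grid <- model$grid
  C <- model$C
  cfg <- model$config
  Nfac <- if (cfg$scale_prior_by_N) model$N else 1
  ia <- appearance_index(model)
  for (k in seq_len(model$Ka)) {
    zk <- latents$Z[ia[k], ]
    if (all(zk == 0)) next
    g <- zero_field(grid, C)
    H <- if (model$noise == "categorical") array(0, c(grid$dims, C, C))
         else zero_field(grid, C)
    for (n in seq_len(dataset$N)) {
      a <- reconstruct(model, latents$Z[, n])$a
      dv <- energy_derivs(dataset$images[[n]], a, defs[[n]], model$sigma2)
      g <- g + zk[n] * dv$grad
      H <- H + zk[n]^2 * dv$hess
    }
    if (model$noise != "categorical" && C == 1L) {
      g <- array(g, grid$dims); H <- array(H, grid$dims)
    }
    reg_k <- cfg$lambda[1] * Nfac + cfg$lambda[2] * latents$Cz[ia[k], ia[k]]
    rhs <- g + apply_operator(model$ops$La, model$Wa[[k]], scale = reg_k)
    delta <- solve_regularized(H, model$ops$La, rhs, scale = reg_k)$x
    obj_of <- function(wk) {
      m2 <- model; m2$Wa[[k]] <- wk
      sum_energies(m2, dataset, latents$Z, defs) +
        appearance_penalty(m2, latents, gram_matrix(m2$Wa, m2$ops$La))
    }
    obj0 <- sum_energies(model, dataset, latents$Z, defs) +
      appearance_penalty(model, latents, gram_matrix(model$Wa, model$ops$La))
    ls <- backtrack(obj0, function(s) model$Wa[[k]] - s * delta, obj_of)
    if (ls$accepted) model$Wa[[k]] <- ls$value
  }
  list(model = model, accepted = TRUE)
}

## ---- Step 1c: shape basis ------------------------------------------------

shape_penalty <- function(model, latents, Gv) {
  cfg <- model$config
  Nfac <- if (cfg$scale_prior_by_N) model$N else 1
  iv <- shape_index(model)
  Rw <- cfg$lambda[1] * Nfac * diag(model$Kv) +
    cfg$lambda[2] * latents$Cz[iv, iv, drop = FALSE]
  0.5 * sum(Rw * Gv)
}

## Per-image shape gradient field (template space, c(dims, d)):
## G_j = - sum_c push(residual)_c * d a_c / d x_j, and the per-voxel d x d
## Gauss-Newton Hessian from the same chain rule.
shape_image_derivs <- function(model, grad_t, hess_t, grad_a) {
  grid <- model$grid
  d <- grid$d
  C <- model$C
  M <- nvox(grid)
  Gm <- matrix(as.numeric(grad_t), M, C)
  Am <- array(grad_a, dim = c(M, C, d))
  g <- matrix(0, M, d)
  for (j in seq_len(d))
    for (c in seq_len(C))
      g[, j] <- g[, j] - Gm[, c] * Am[, c, j]
  ## Hessian: sum_{c,c'} h_{cc'} (da_c/dx_j)(da_c'/dx_j')
  H <- array(0, dim = c(M, d, d))
  if (model$noise == "categorical") {
    Hm <- matrix(as.numeric(hess_t), M, C * C)
    for (j in seq_len(d))
      for (jp in seq_len(j))
        for (ci in seq_len(C))
          for (cj in seq_len(C)) {
            H[, j, jp] <- H[, j, jp] +
              Hm[, (cj - 1L) * C + ci] * Am[, ci, j] * Am[, cj, jp]
          }
  } else {
    hv <- as.numeric(hess_t)
    for (j in seq_len(d))
      for (jp in seq_len(j))
        H[, j, jp] <- H[, j, jp] + hv * Am[, 1, j] * Am[, 1, jp]
  }
  for (j in seq_len(d))
    for (jp in seq_len(j))
      if (jp < j) H[, jp, j] <- H[, j, jp]
  list(g = g, H = H)
}

#' Gauss-Newton update of the shape (velocity) basis
#'
#' One backtracked Gauss-Newton step per column.  Per-image gradients are the
#' pointwise product of the pushed intensity residual with the template-space
#' spatial gradient of the reconstructed appearance (the chain rule through
#' the resampling), weighted by the latent loadings; the Hessian uses the
#' same majorisation.  Deformations are re-shot for every candidate step, and
#' the accepted deformations are returned for reuse.
#'
#' @inheritParams update_mean
#' @return List with the updated `model` and refreshed `defs`.
#' @export
update_shape_basis <- function(model, dataset, latents, defs) {
  if (model$Kv == 0L) return(list(model = model, defs = defs, accepted = TRUE))
  grid <- model$grid
  d <- grid$d
  M <- nvox(grid)
  cfg <- model$config
  Nfac <- if (cfg$scale_prior_by_N) model$N else 1
  iv <- shape_index(model)
  for (k in seq_len(model$Kv)) {
    zk <- latents$Z[iv[k], ]
    if (all(zk == 0)) next
    g <- matrix(0, M, d)
    H <- array(0, dim = c(M, d, d))
    for (n in seq_len(dataset$N)) {
      a <- reconstruct(model, latents$Z[, n])$a
      dv <- energy_derivs(dataset$images[[n]], a, defs[[n]], model$sigma2)
      ga <- spatial_gradient(a, grid)
      sd <- shape_image_derivs(model, dv$grad, dv$hess, ga)
      g <- g + zk[n] * sd$g
      H <- H + zk[n]^2 * sd$H
    }
    g <- array(g, dim = c(grid$dims, d))
    H <- array(H, dim = c(grid$dims, d, d))
    reg_k <- cfg$lambda[1] * Nfac + cfg$lambda[2] * latents$Cz[iv[k], iv[k]]
    rhs <- g + apply_operator(model$ops$Lv, model$Wv[[k]], scale = reg_k)
    delta <- solve_regularized(H, model$ops$Lv, rhs, scale = reg_k)$x
    cand_env <- new.env()
    obj_of <- function(wk) {
      m2 <- model; m2$Wv[[k]] <- wk
      dnew <- compute_deformations(m2, latents$Z)
      assign("defs", dnew, envir = cand_env)
      sum_energies(m2, dataset, latents$Z, dnew) +
        shape_penalty(m2, latents, gram_matrix(m2$Wv, m2$ops$Lv))
    }
    obj0 <- sum_energies(model, dataset, latents$Z, defs) +
      shape_penalty(model, latents, gram_matrix(model$Wv, model$ops$Lv))
    ls <- backtrack(obj0, function(s) model$Wv[[k]] - s * delta, obj_of,
                    max_halve = 6L)
    if (ls$accepted) {
      model$Wv[[k]] <- ls$value
      defs <- get("defs", envir = cand_env)
    }
  }
  list(model = model, defs = defs, accepted = TRUE)
}

## ---- Step 2: latent update ----------------------------------------------

## Design matrix for one image: (M*C) x K, column k giving the first-order
## change of the template-space appearance per unit z_k (appearance columns
## directly; shape columns via transport of the appearance gradient).
latent_design <- function(model, grad_a) {
  grid <- model$grid
  M <- nvox(grid)
  C <- model$C
  d <- grid$d
  D <- matrix(0, M * C, model$K)
  ia <- appearance_index(model)
  for (k in seq_len(model$Ka))
    D[, ia[k]] <- D[, ia[k]] + as.numeric(model$Wa[[k]])
  iv <- shape_index(model)
  if (model$Kv > 0L) {
    Am <- array(grad_a, dim = c(M, C, d))
    for (k in seq_len(model$Kv)) {
      wv <- matrix(as.numeric(model$Wv[[k]]), M, d)
      col <- matrix(0, M, C)
      for (c in seq_len(C))
        for (j in seq_len(d))
          col[, c] <- col[, c] - wv[, j] * Am[, c, j]
      D[, iv[k]] <- D[, iv[k]] + as.numeric(col)
    }
  }
  D
}

## Energy-only evaluation of the per-image latent objective (used by line
## searches; derivatives are computed only for accepted iterates).
latent_obj <- function(model, f, z, P, def = NULL) {
  if (is.null(def)) def <- shoot_z(model, z)
  a <- reconstruct(model, z)$a
  energy <- energy_derivs(f, a, def, sigma2 = model$sigma2,
                          want_derivs = FALSE)$energy
  list(obj = energy + 0.5 * sum(z * (P %*% z)), energy = energy, def = def)
}

## Gauss-Newton machinery for one image at a given z; returns grad, Hessian
## (both including the prior), the energy and the deformation used.
latent_gn_parts <- function(model, f, z, P, def = NULL) {
  if (is.null(def)) def <- shoot_z(model, z)
  rec <- reconstruct(model, z)
  dv <- energy_derivs(f, rec$a, def, model$sigma2)
  ga <- spatial_gradient(rec$a, model$grid)
  D <- latent_design(model, ga)
  gvec <- as.numeric(dv$grad)
  grad <- drop(crossprod(D, gvec)) + drop(P %*% z)
  HD <- if (model$noise == "categorical") {
    hd <- matrix(0, nrow(D), ncol(D))
    for (k in seq_len(ncol(D)))
      hd[, k] <- as.numeric(apply_hessian_field(
        dv$hess, array(D[, k], dim = c(model$grid$dims, model$C)), model$grid))
    hd
  } else {
    as.numeric(dv$hess) * D
  }
  Hz <- crossprod(D, HD) + P
  Hz <- (Hz + t(Hz)) / 2
  list(grad = grad, hess = Hz, energy = dv$energy, def = def,
       obj = dv$energy + 0.5 * sum(z * (P %*% z)))
}

solve_spd <- function(H, g) {
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    H <- H + diag(1e-8 * sum(diag(H)) / nrow(H) + 1e-12, nrow(H))
    ch <- chol(H)
  }
  backsolve(ch, forwardsolve(t(ch), g))
}

#' Update the latent variables of every image
#'
#' Per image, a few backtracked Gauss-Newton iterations on the latent code
#' (likelihood derivatives projected onto the appearance and, via the
#' transported appearance gradient, the shape basis, plus the prior term),
#' followed by the Laplace covariance from the final Hessian.
#'
#' @inheritParams update_mean
#' @param n_gn Gauss-Newton iterations per image.
#' @return List with new `latents` (modes `Z`, summed Laplace covariance `S`,
#'   `Cz = Z Z'`), refreshed `defs` and the summed energies `sumJ`.
#' @export
update_latents <- function(model, dataset, latents, defs = NULL,
                           n_gn = model$config$n_latent_iter) {
  K <- model$K
  N <- dataset$N
  P <- latent_precision(model)
  Z <- latents$Z
  S <- matrix(0, K, K)
  newdefs <- vector("list", N)
  sumJ <- 0
  for (n in seq_len(N)) {
    z <- Z[, n]
    parts <- latent_gn_parts(model, dataset$images[[n]], z, P,
                             def = if (is.null(defs)) NULL else defs[[n]])
    for (it in seq_len(n_gn)) {
      delta <- solve_spd(parts$hess, parts$grad)
      cand_env <- new.env()
      obj_of <- function(zc) {
        p <- latent_obj(model, dataset$images[[n]], zc, P)
        assign("cand", p, envir = cand_env)
        p$obj
      }
      ls <- backtrack(parts$obj, function(s) z - s * delta, obj_of,
                      max_halve = 6L)
      if (!ls$accepted) break
      z <- ls$value
      parts <- latent_gn_parts(model, dataset$images[[n]], z, P,
                               def = get("cand", envir = cand_env)$def)
    }
    Z[, n] <- z
    S <- S + chol2inv(chol(parts$hess))
    newdefs[[n]] <- parts$def
    sumJ <- sumJ + parts$energy
  }
  list(latents = list(Z = Z, S = (S + t(S)) / 2, Cz = Z %*% t(Z)),
       defs = newdefs, sumJ = sumJ)
}

## ---- Wishart precision ---------------------------------------------------

#' Variational update of the expected latent precision
#'
#' The approximate posterior on the precision is Wishart with scale
#' `Lambda = (Cz + S + Lambda0^{-1})^{-1}` and `nu = nu0 + N`; other stages
#' use its expectation `A_hat = nu * Lambda`.
#'
#' @param latents Latent posterior (uses `Cz` and `S`).
#' @param wishart Wishart state (prior inverse scale and dof).
#' @param N Number of images.
#' @return List with updated `wishart` and `A_hat`.
#' @export
update_precision <- function(latents, wishart, N) {
  EZZ <- latents$Cz + latents$S
  Lambda <- solve(EZZ + wishart$Lambda0_inv)
  Lambda <- (Lambda + t(Lambda)) / 2
  nu <- wishart$nu0 + N
  wishart$Lambda <- Lambda
  wishart$nu <- nu
  A_hat <- nu * Lambda
  list(wishart = wishart, A_hat = (A_hat + t(A_hat)) / 2)
}

## ---- Orthogonalisation ---------------------------------------------------

eig_floor <- function(Msym, floor_rel = 1e-12) {
  e <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  mx <- max(e$values, 0)
  vals <- pmax(e$values, if (mx > 0) floor_rel * mx else floor_rel)
  list(V = e$vectors, D = vals)
}

## Initial diagonalising transform for one latent block (eigendecompositions
## plus an SVD): T Cz T' and (T^-1)' C T^-1 both become diagonal.
ortho_transform_block <- function(Cz, C) {
  ez <- eig_floor(Cz)
  ew <- eig_floor(C)
  Mid <- diag(sqrt(ew$D), length(ew$D)) %*% t(ew$V) %*% ez$V %*%
    diag(sqrt(ez$D), length(ez$D))
  sv <- svd(Mid)
  diag(sv$d, length(sv$d)) %*% t(sv$v) %*%
    diag(1 / sqrt(ez$D), length(ez$D)) %*% t(ez$V)
}

## Gauss-Newton minimisation of the scaling objective in q (Q = diag(exp q)):
##   sum_k exp(-2 q_k) B_kk + sum_kl exp(q_k + q_l) (T Cz T')_kl A_lk
q_objective <- function(q, Bdiag, G) {
  e <- exp(q)
  sum(exp(-2 * q) * Bdiag) + sum(outer(e, e) * G)
}

q_step <- function(q, Bdiag, G) {
  e <- exp(q)
  Eg <- (outer(e, e) * G)
  grad <- -2 * exp(-2 * q) * Bdiag + 2 * rowSums(Eg)
  H <- 2 * Eg + diag(2 * rowSums(Eg) + 4 * exp(-2 * q) * Bdiag, length(q))
  solve_spd(H, grad)
}

#' Orthogonalise the latent factorisation
#'
#' Reparameterises latents and bases so that the rows of Z are orthogonal and
#' the basis smoothness matrix is diagonal (eigendecompositions and an SVD,
#' block-wise in split mode so shape and appearance latents are not mixed),
#' then iterates a fixed point between a diagonal rescaling `Q = diag(exp q)`
#' (Gauss-Newton on `q`) and the expected-precision refresh until
#' `||dq|| < 1e-8` (at most 100 iterations).  Reconstructions `W z` are
#' exactly preserved.
#'
#' @inheritParams update_mean
#' @param wishart Wishart state.
#' @return List with transformed `model`, `latents`, updated `wishart`, and
#'   the applied `transform` (matrix `R = Q T`).
#' @export
orthogonalise <- function(model, latents, wishart, N = ncol(latents$Z)) {
  K <- model$K
  Cz <- latents$Cz
  Ga <- gram_matrix(model$Wa, model$ops$La)
  Gv <- gram_matrix(model$Wv, model$ops$Lv)
  Cmat <- gram_full(model, Ga, Gv)
  Tm <- matrix(0, K, K)
  blocks <- if (model$mode == "shared") list(seq_len(K)) else
    Filter(length, list(appearance_index(model), shape_index(model)))
  for (b in blocks) {
    ## a block whose basis is still (numerically) zero has nothing to
    ## diagonalise; leave it untouched rather than collapse its latents
    if (sum(diag(Cmat[b, b, drop = FALSE])) <= 1e-10)
      Tm[b, b] <- diag(length(b))
    else
      Tm[b, b] <- ortho_transform_block(Cz[b, b, drop = FALSE],
                                        Cmat[b, b, drop = FALSE])
  }
  Tinv <- solve(Tm)
  Bdiag <- diag(t(Tinv) %*% Cmat %*% Tinv)
  Mz <- Tm %*% Cz %*% t(Tm)
  CzS <- Cz + latents$S
  q <- rep(0, K)
  A_hat <- model$A_hat
  n_q_iter <- if (min(Bdiag) > 0) 100L else 0L
  for (it in seq_len(n_q_iter)) {
    QT <- diag(exp(q), K) %*% Tm
    A_hat <- (N + wishart$nu0) *
      solve(QT %*% CzS %*% t(QT) + wishart$Lambda0_inv)
    A_hat <- (A_hat + t(A_hat)) / 2
    G <- Mz * t(A_hat)
    dq <- q_step(q, Bdiag, G)
    ## backtrack on the scaling objective
    obj0 <- q_objective(q, Bdiag, G)
    s <- 1
    for (h in 1:10) {
      if (q_objective(q - s * dq, Bdiag, G) <= obj0) break
      s <- s / 2
    }
    q <- q - s * dq
    if (sqrt(sum((s * dq)^2)) < 1e-8) break
  }
  R <- diag(exp(q), K) %*% Tm
  Rinv <- solve(R)
  ## apply: latents by R, bases by R^{-1} (columns)
  Z <- R %*% latents$Z
  S <- R %*% latents$S %*% t(R)
  latents <- list(Z = Z, S = (S + t(S)) / 2, Cz = Z %*% t(Z))
  ia <- appearance_index(model); iv <- shape_index(model)
  if (model$Ka > 0L) {
    Wa <- model$Wa
    for (j in seq_len(model$Ka)) {
      acc <- zero_field(model$grid, model$C)
      for (k in seq_len(model$Ka))
        acc <- acc + model$Wa[[k]] * Rinv[ia[k], ia[j]]
      Wa[[j]] <- acc
    }
    model$Wa <- Wa
  }
  if (model$Kv > 0L) {
    Wv <- model$Wv
    for (j in seq_len(model$Kv)) {
      acc <- zero_field(model$grid, model$grid$d)
      for (k in seq_len(model$Kv))
        acc <- acc + model$Wv[[k]] * Rinv[iv[k], iv[j]]
      Wv[[j]] <- acc
    }
    model$Wv <- Wv
  }
  QT <- R
  A_hat <- (N + wishart$nu0) *
    solve(QT %*% CzS %*% t(QT) + wishart$Lambda0_inv)
  model$A_hat <- (A_hat + t(A_hat)) / 2
  wishart$Lambda <- model$A_hat / (wishart$nu0 + N)
  wishart$nu <- wishart$nu0 + N
  list(model = model, latents = latents, wishart = wishart,
       transform = R)
}

## ---- the full fit --------------------------------------------------------

#' Fit the shape and appearance model
#'
#' Runs the alternating fitting loop: Gauss-Newton updates of the mean,
#' appearance basis and shape basis (each a single backtracked step), the
#' noise-variance update (Gaussian model), orthogonalisation, the latent
#' update and the variational precision update, recording the joint
#' log-probability after every stage.  Deterministic given `config$seed`.
#'
#' @param dataset A [as_dataset()] result (or list of arrays).
#' @param config A [fit_config()].
#' @param verbose Print per-stage objectives.
#' @return List of class `sam_fit` with `model`, `latents`, `wishart` and a
#'   `history` data frame (`iter`, `stage`, `objective`, `searched`; the
#'   objective is non-decreasing across every line-searched stage).
#' @export
fit <- function(dataset, config, verbose = FALSE) {
  if (!inherits(dataset, "sam_dataset"))
    dataset <- as_dataset(dataset, noise = config$noise)
  if (dataset$noise != config$noise)
    stop("dataset noise model (", dataset$noise, ") does not match config (",
         config$noise, ")")
  set.seed(config$seed)
  st <- init_model(dataset, config)
  model <- st$model; latents <- st$latents; wishart <- st$wishart
  defs <- compute_deformations(model, latents$Z)

  history <- data.frame(iter = integer(), stage = character(),
                        objective = numeric(), searched = logical())
  log_stage <- function(iter, stage, searched, sumJ = NULL) {
    obj <- joint_log_prob(model, dataset, latents, wishart, defs = defs,
                          sumJ = sumJ)
    history <<- rbind(history, data.frame(iter = iter, stage = stage,
                                          objective = obj,
                                          searched = searched))
    if (verbose)
      message(sprintf("iter %2d %-14s objective %.6f", iter, stage, obj))
    obj
  }
  log_stage(0L, "init", FALSE)

  for (iter in seq_len(config$n_iter)) {
    um <- update_mean(model, dataset, latents, defs)
    model <- um$model
    log_stage(iter, "mean", TRUE)

    if (model$Ka > 0L) {
      ua <- update_appearance_basis(model, dataset, latents, defs)
      model <- ua$model
      log_stage(iter, "appearance", TRUE)
    }

    if (model$Kv > 0L) {
      us <- update_shape_basis(model, dataset, latents, defs)
      model <- us$model; defs <- us$defs
      log_stage(iter, "shape", TRUE)
    }

    if (model$noise == "gaussian") {
      ss <- 0; nn <- 0
      for (n in seq_len(dataset$N)) {
        a <- reconstruct(model, latents$Z[, n])$a
        dv <- energy_derivs(dataset$images[[n]], a, defs[[n]], model$sigma2,
                            want_derivs = FALSE)
        ss <- ss + dv$resid_ss; nn <- nn + dv$n_obs
      }
      model$sigma2 <- update_sigma2(ss, nn)
      log_stage(iter, "sigma2", TRUE)
    }

    ot <- orthogonalise(model, latents, wishart, N = dataset$N)
    model <- ot$model; latents <- ot$latents; wishart <- ot$wishart
    log_stage(iter, "orthogonalise", FALSE)

    ul <- update_latents(model, dataset, latents, defs)
    latents <- ul$latents; defs <- ul$defs
    log_stage(iter, "latents", TRUE, sumJ = ul$sumJ)

    up <- update_precision(latents, wishart, dataset$N)
    wishart <- up$wishart
    model$A_hat <- up$A_hat
    log_stage(iter, "precision", FALSE)
  }
  structure(list(model = model, latents = latents, wishart = wishart,
                 history = history, dataset_n = dataset$N),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  fitted to %d images; final objective %.4f\n",
              x$dataset_n, utils::tail(x$history$objective, 1)))
  invisible(x)
}
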