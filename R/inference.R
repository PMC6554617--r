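## Using a fitted model: encoding new images with Laplace evidence,
## generative classification by model comparison, sampling, imputation of
## missing voxels, overlap metrics, and configuration cross-validation.

#' Encode an image against a frozen model
#'
#' Finds the mode of the latent posterior by backtracked Gauss-Newton (the
#' same machinery as in fitting, run to convergence), and returns the mode,
#' the Gauss-Newton Hessian at the mode (the Laplace precision) and the
#' Laplace approximation to the log model evidence
#' `ln p(f | M) ~ ln p(f, z-hat | M) - ln|S| / 2` (the 2*pi factors of the
#' penalised-prior normaliser and of the Laplace integral cancel).
#'
#' @param f An [observed_image()] (or bare array) on the model's grid.
#' @param model A fitted `sam_model` (or a `sam_fit`).
#' @param max_iter Gauss-Newton iteration cap per start.
#' @param tol Stop when the objective improves by less than this.
#' @param z_init Optional starting latent vector (defaults to zero).
#' @param extra_starts Number of additional deterministic starting points
#'   (one prior standard deviation along the principal axes of the latent
#'   distribution, alternating signs).  The Gauss-Newton search is local, so
#'   a handful of starts guards against registration local optima for images
#'   far from the template; the best mode wins.
#' @return List of class `sam_encoding` with `z`, `precision`,
#'   `log_evidence` and the per-image `energy` at the mode.
#' @export
encode <- function(f, model, max_iter = 20L, tol = 1e-6, z_init = NULL,
                   extra_starts = min(2L * model$K, 6L)) {
  if (inherits(model, "sam_fit")) model <- model$model
  if (!inherits(f, "observed_image"))
    f <- observed_image(f, model$noise, model$grid)
  Gamma <- gram_full(model)
  P <- latent_precision(model, Gamma)
  starts <- list(if (is.null(z_init)) rep(0, model$K) else as.numeric(z_init))
  if (is.null(z_init) && extra_starts > 0L) {
    eg <- eigen(solve(model$A_hat), symmetric = TRUE)
    dirs <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), model$K)
    for (j in seq_len(extra_starts)) {
      ax <- (j + 1L) %/% 2L
      if (ax > model$K) break
      starts[[length(starts) + 1L]] <- (-1)^j * 1.5 * dirs[, ax]
    }
  }
  best <- NULL
  for (z0 in starts) {
    run <- encode_gn(f, model, P, z0, max_iter, tol)
    if (is.null(best) || run$parts$obj < best$parts$obj) best <- run
  }
  z <- best$z
  parts <- best$parts
  Sprec <- parts$hess   # GN Hessian at the mode = Laplace precision
  ldP <- determinant(P, logarithm = TRUE)$modulus
  ldS <- log_det_floor(Sprec)
  log_evidence <- -parts$energy - 0.5 * sum(z * (P %*% z)) +
    0.5 * as.numeric(ldP) - 0.5 * ldS
  structure(list(z = z, precision = Sprec, log_evidence = log_evidence,
                 energy = parts$energy, deformation = parts$def),
            class = "sam_encoding")
}

## One Gauss-Newton descent on the latent objective from a given start.
encode_gn <- function(f, model, P, z, max_iter, tol) {
  parts <- latent_gn_parts(model, f, z, P)
  if (!is.finite(parts$energy)) stop("encode: non-finite energy at start")
  for (it in seq_len(max_iter)) {
    delta <- solve_spd(parts$hess, parts$grad)
    cand_env <- new.env()
    obj_of <- function(zc) {
      p <- latent_obj(model, f, zc, P)
      assign("cand", p, envir = cand_env)
      p$obj
    }
    prev <- parts$obj
    ls <- backtrack(prev, function(s) z - s * delta, obj_of, max_halve = 8L)
    if (!ls$accepted) break
    z <- ls$value
    parts <- latent_gn_parts(model, f, z, P,
                             def = get("cand", envir = cand_env)$def)
    if (prev - parts$obj < tol) break
  }
  list(z = z, parts = parts)
}

log_det_floor <- function(Msym, floor = 1e-10) {
  ev <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(log(pmax(ev, floor)))
}

#' @export
print.sam_encoding <- function(x, ...) {
  cat(sprintf("<sam_encoding> K=%d, log evidence %.3f\n",
              length(x$z), x$log_evidence))
  invisible(x)
}

#' Generative classification by model comparison
#'
#' Encodes `f` under each class-specific model and forms the posterior over
#' classes from the Laplace log evidences plus log priors.
#'
#' @param f Image (array or [observed_image()]).
#' @param models Named list of fitted models sharing grid and noise model.
#' @param priors Per-class prior probabilities; `NULL` uses the training-set
#'   frequencies stored in the models (uniform if absent).
#' @param ... Passed to [encode()].
#' @return List with `probs` (sums to one), `log_evidence` per class and the
#'   `argmax` label.
#' @export
classify <- function(f, models, priors = NULL, ...) {
  stopifnot(is.list(models), length(models) >= 1L)
  models <- lapply(models, function(m) if (inherits(m, "sam_fit")) m$model else m)
  g1 <- models[[1]]$grid$dims
  for (m in models)
    if (!identical(m$grid$dims, g1) || m$noise != models[[1]]$noise)
      stop("all models must share grid and noise model")
  if (is.null(priors)) {
    ns <- vapply(models, function(m) if (is.null(m$N)) 0 else m$N, numeric(1))
    ## training-set frequencies; uniform when they are unknown (e.g. a model
    ## that was never fitted to data)
    priors <- if (all(is.finite(ns)) && all(ns > 0)) ns / sum(ns)
              else rep(1 / length(models), length(models))
  }
  stopifnot(length(priors) == length(models), all(priors > 0))
  priors <- priors / sum(priors)
  le <- vapply(models, function(m) encode(f, m, ...)$log_evidence, numeric(1))
  lp <- le + log(priors)
  lp <- lp - max(lp)
  probs <- exp(lp) / sum(exp(lp))
  names(probs) <- names(models)
  list(probs = probs, log_evidence = le,
       argmax = if (is.null(names(models))) which.max(probs)
                else names(models)[which.max(probs)])
}

#' Draw latent vectors from the fitted latent distribution
#'
#' @param model A `sam_model` or `sam_fit`.
#' @param n Number of draws.
#' @return K x n matrix of draws from `N(0, A-hat^{-1})`.
#' @export
sample_latents <- function(model, n = 1L) {
  if (inherits(model, "sam_fit")) model <- model$model
  K <- model$K
  Sig <- solve(model$A_hat)
  t(chol((Sig + t(Sig)) / 2)) %*% matrix(stats::rnorm(K * n), K, n)
}

#' Sample an image from the model
#'
#' Draws `z ~ N(0, A-hat^{-1})`, reconstructs the appearance, shoots the
#' deformation and warps.  By default returns the noiseless expected image
#' (identity / sigmoid / softmax mean function); with `add_noise = TRUE` the
#' observation noise is also sampled.
#'
#' @param model A `sam_model` or `sam_fit`.
#' @param z Optional latent vector (overrides the random draw).
#' @param add_noise Sample the observation model too.
#' @return List with `image`, `z` and the `deformation` used.
#' @export
sample_model <- function(model, z = NULL, add_noise = FALSE) {
  if (inherits(model, "sam_fit")) model <- model$model
  if (is.null(z)) z <- drop(sample_latents(model, 1L))
  rec <- reconstruct(model, z)
  def <- shoot_z(model, z)
  ap <- pull(rec$a, def)
  img <- mean_function(ap, model$noise, model$grid)
  if (add_noise) {
    grid <- model$grid
    M <- nvox(grid)
    img <- switch(model$noise,
      gaussian = img + array(stats::rnorm(M, sd = sqrt(model$sigma2)),
                             dim = grid$dims),
      bernoulli = array(as.numeric(stats::runif(M) < img), dim = grid$dims),
      categorical = {
        C <- model$C
        pm <- matrix(as.numeric(img), M, C)
        pick <- max.col(log(pmax(pm, 1e-12)) - log(-log(matrix(
          stats::runif(M * C), M, C))))
        out <- matrix(0, M, C)
        out[cbind(seq_len(M), pick)] <- 1
        array(out, dim = c(grid$dims, C))
      })
  }
  list(image = img, z = z, deformation = def)
}

#' Impute missing voxels of an image
#'
#' Encodes the image using its observed voxels only and returns the full
#' model prediction (expected image in subject space).  When the true values
#' of held-out voxels are supplied, their predictive log-likelihood under the
#' model is also reported.
#'
#' @param f Image with `NaN` at missing voxels.
#' @param model A `sam_model` or `sam_fit`.
#' @param truth Optional complete image; the log-likelihood is evaluated at
#'   the voxels missing from `f`.
#' @param ... Passed to [encode()].
#' @return List with `image` (prediction), `encoding`, and when `truth` is
#'   given `heldout_loglik` (total) and `heldout_mean_loglik` (per voxel).
#' @export
impute <- function(f, model, truth = NULL, ...) {
  if (inherits(model, "sam_fit")) model <- model$model
  if (!inherits(f, "observed_image"))
    f <- observed_image(f, model$noise, model$grid)
  enc <- encode(f, model, ...)
  rec <- reconstruct(model, enc$z)
  ap <- pull(rec$a, enc$deformation)
  pred <- mean_function(ap, model$noise, model$grid)
  out <- list(image = pred, encoding = enc)
  if (!is.null(truth)) {
    sel <- !f$mask
    n_held <- sum(sel)
    if (n_held > 0) {
      ll <- predictive_loglik(ap, truth, model$noise, model$grid,
                              sel = as.numeric(sel) == 1,
                              sigma2 = model$sigma2)
      out$heldout_loglik <- ll
      out$heldout_mean_loglik <- ll / n_held
    }
  }
  out
}

#' Jaccard and binomial log-likelihood overlap of a mean mask with a binary mask
#'
#' The Jaccard index compares the thresholded (> 1/2) mean mask with the
#' binary mask; the log-likelihood measure is the mean per-voxel binomial
#' log2-likelihood of the binary mask under the mean mask, with the mean
#' clamped away from 0 and 1.
#'
#' @param mean_mask Array with values in `[0, 1]`.
#' @param binary_mask Array of the same shape with values in `{0, 1}`.
#' @param clamp Clamping bound for the mean mask.
#' @return List with `jaccard` and `loglik` (log2 scale, <= 0).
#' @export
overlap_metrics <- function(mean_mask, binary_mask, clamp = 1e-6) {
  stopifnot(identical(dim(mean_mask), dim(binary_mask)))
  if (any(mean_mask < 0 | mean_mask > 1, na.rm = TRUE))
    stop("mean_mask must lie in [0, 1]")
  b <- as.numeric(binary_mask)
  if (!all(b %in% c(0, 1))) stop("binary_mask must be 0/1")
  mthr <- as.numeric(mean_mask) > 0.5
  inter <- sum(mthr & b == 1)
  uni <- sum(mthr | b == 1)
  jac <- if (uni == 0) 1 else inter / uni
  mu <- pmin(pmax(as.numeric(mean_mask), clamp), 1 - clamp)
  ll <- mean(b * log2(mu) + (1 - b) * log2(1 - mu))
  list(jaccard = jac, loglik = ll)
}

#' Place a random wrapped rectangle of missing voxels in each image
#'
#' Each image gets one axis-aligned rectangle (wrapping around at the edges)
#' whose side lengths are `frac^(1/d)` of each axis, so it covers a fraction
#' `frac` of the area; voxels inside are set to `NaN`.
#'
#' @param images List of arrays (channels allowed).
#' @param grid The [grid_spec()].
#' @param frac Area fraction to remove.
#' @return List with `images` (masked) and `masks` (logical arrays, `TRUE`
#'   where removed).
#' @export
mask_rectangles <- function(images, grid, frac = 0.25) {
  d <- grid$d
  side <- frac^(1 / d)
  out <- vector("list", length(images))
  masks <- vector("list", length(images))
  for (n in seq_along(images)) {
    sel <- array(TRUE, dim = grid$dims)
    for (j in seq_len(d)) {
      nj <- grid$dims[j]
      len <- max(1L, round(side * nj))
      start <- sample.int(nj, 1L) - 1L
      covered <- (start + seq_len(len) - 1L) %% nj + 1L
      inside <- rep(FALSE, nj)
      inside[covered] <- TRUE
      sel <- sel & per_axis_array(inside, grid, j) > 0
    }
    img <- images[[n]]
    nc <- n_channels(img, grid)
    for (c in seq_len(nc)) {
      ch <- get_channel(img, grid, c)
      ch[sel] <- NaN
      img <- if (nc == 1L && length(dim(img)) == d) ch
             else set_channel(img, grid, c, ch)
    }
    out[[n]] <- img
    masks[[n]] <- sel
  }
  list(images = out, masks = masks)
}

#' Cross-validate model configurations by held-out imputation
#'
#' Masks a random wrapped rectangle in every image, fits each configuration
#' on the masked data, and scores the held-out voxels of every image by their
#' predictive log-likelihood under the fitted model's own reconstruction of
#' that image.  This is the mechanism for comparing shape-only,
#' appearance-only, shared and split configurations.
#'
#' @param dataset A [as_dataset()] result or list of complete arrays.
#' @param configs Named list of [fit_config()]s.
#' @param frac Masked area fraction.
#' @param seed Seed for mask placement (fits use each config's own seed).
#' @return List with `per_image` (matrix of mean held-out log-likelihoods,
#'   images x configs) and `mean` (per-config means).
#' @export
cross_validate_configs <- function(dataset, configs, frac = 0.25, seed = 1L) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  noise <- configs[[1]]$noise
  if (!inherits(dataset, "sam_dataset"))
    dataset <- as_dataset(dataset, noise = noise)
  set.seed(seed)
  full <- lapply(dataset$images, function(im) im$data)
  mk <- mask_rectangles(full, dataset$grid, frac = frac)
  masked <- as_dataset(mk$images, noise = noise, grid = dataset$grid)
  res <- matrix(NA_real_, dataset$N, length(configs),
                dimnames = list(NULL, names(configs)))
  for (ci in seq_along(configs)) {
    fitres <- fit(masked, configs[[ci]])
    for (n in seq_len(dataset$N)) {
      z <- fitres$latents$Z[, n]
      rec <- reconstruct(fitres$model, z)
      def <- shoot_z(fitres$model, z)
      ap <- pull(rec$a, def)
      sel <- as.numeric(mk$masks[[n]]) == 1
      res[n, ci] <- predictive_loglik(ap, full[[n]], noise, dataset$grid,
                                      sel = sel,
                                      sigma2 = fitres$model$sigma2) / sum(sel)
    }
  }
  list(per_image = res, mean = colMeans(res))
}
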