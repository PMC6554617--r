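## Ground-truth synthetic data: a known model (smooth template, bases drawn
## from their Sobolev priors as Green's-smoothed white noise) and datasets
## rendered from it through the full generative process, optionally with
## wrapped rectangular missing regions.  This is the test bed the package is
## validated on.

## Smooth multi-blob template on the grid, per noise model.  Blob centres,
## widths and amplitudes are jittered from the caller's RNG so that two
## ground-truth models drawn with different seeds have genuinely distinct
## templates (e.g. for classification test beds).
blob_template <- function(grid, noise, C = 3L) {
  d <- grid$d
  dims <- grid$dims
  coords <- lapply(seq_len(d), function(j)
    per_axis_array((seq_len(dims[j]) - 1) / dims[j], grid, j))
  bump <- function(centre, width, amp) {
    r2 <- 0
    for (j in seq_len(d)) {
      dx <- coords[[j]] - centre[j]
      dx <- dx - round(dx)              # periodic distance
      r2 <- r2 + (dx / width)^2
    }
    amp * exp(-0.5 * r2)
  }
  jc <- function(centre) centre + stats::runif(d, -0.08, 0.08)
  jw <- function(width) width * exp(stats::runif(1, -0.25, 0.25))
  ja <- function(amp) amp * exp(stats::runif(1, -0.3, 0.3))
  base <- bump(jc(rep(0.5, d)), jw(0.22), ja(1)) -
    bump(jc(rep(0.42, d)), jw(0.1), ja(0.5)) +
    bump(jc(rep(0.62, d)), jw(0.09), ja(0.6))
  switch(noise,
    gaussian = base,
    bernoulli = 8 * (base - 0.35),     # logits: crisp-ish blob
    categorical = {
      mu <- array(0, dim = c(dims, C))
      mu <- set_channel(mu, grid, 1L,
                        6 * (bump(jc(rep(0.5, d)), jw(0.16), ja(1)) - 0.45))
      mu <- set_channel(mu, grid, 2L,
                        6 * (bump(jc(rep(0.38, d)), jw(0.1), ja(1)) - 0.45))
      mu  # remaining channels stay 0 (background reference)
    })
}

## One basis column drawn from the operator's prior: Green's-smoothed white
## noise, mean-centred, rescaled so its largest amplitude equals `target`.
smooth_noise_field <- function(op, ncomp, target) {
  grid <- op$grid
  w <- array(stats::rnorm(nvox(grid) * ncomp),
             dim = if (ncomp == 1L) grid$dims else c(grid$dims, ncomp))
  sm <- apply_inverse_shifted(op, w)
  sm <- sm - mean(sm)
  mx <- max(abs(sm))
  if (mx > 0) sm <- sm * (target / mx)
  sm
}

#' Construct a known ground-truth model
#'
#' Samples appearance and velocity bases by applying the inverse of the
#' regularisation operators to white noise (Green's smoothing), scales the
#' velocity columns to a chosen peak displacement, builds a smooth multi-blob
#' template, and sets the latent precision to the identity.
#'
#' @param grid A [grid_spec()].
#' @param K Latent dimension (`mode = "shared"`), or use `K_a`/`K_v`.
#' @param K_a,K_v Split-mode dimensions.
#' @param mode `"shared"` or `"split"`.
#' @param noise Noise model.
#' @param max_displacement Peak amplitude of each velocity column, in voxels.
#' @param appearance_amp Peak amplitude of each appearance column.
#' @param omega_v,omega_a Smoothness weights used for the sampling operators.
#' @param n_shoot Euler steps used when rendering.
#' @param C Number of classes (categorical only).
#' @return A `sam_model` with known parameters.
#' @export
make_ground_truth_model <- function(grid, K = NULL, K_a = NULL, K_v = NULL,
                                    mode = c("shared", "split"),
                                    noise = c("gaussian", "bernoulli",
                                              "categorical"),
                                    max_displacement = 2.5,
                                    appearance_amp = 0.25,
                                    omega_v = c(1e-3, 0, 8, 0.25, 0.5),
                                    omega_a = c(0.01, 1, 4),
                                    n_shoot = 8L, C = 3L) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  if (mode == "shared") {
    if (is.null(K)) stop("shared mode needs K")
    K_a <- K_v <- K
  } else {
    K <- K_a + K_v
  }
  cfg <- fit_config(K = if (mode == "shared") K else NULL,
                    K_a = K_a, K_v = K_v, mode = mode, noise = noise,
                    omega_v = omega_v, omega_a = omega_a, n_shoot = n_shoot)
  Lv <- build_velocity_operator(grid, pmax(omega_v, c(1e-6, 0, 0, 0, 0)))
  La <- build_scalar_operator(grid, omega_a)
  Cc <- if (noise == "categorical") C else 1L
  amp <- if (noise == "gaussian") appearance_amp else 4 * appearance_amp
  structure(list(
    grid = grid, noise = noise, mode = mode, K = K, Ka = K_a, Kv = K_v,
    C = Cc, N = 0L,
    mu = blob_template(grid, noise, C = Cc),
    Wa = replicate(K_a, smooth_noise_field(La, Cc, amp), simplify = FALSE),
    Wv = replicate(K_v, smooth_noise_field(Lv, grid$d, max_displacement),
                   simplify = FALSE),
    sigma2 = 1, A_hat = diag(K),
    ops = list(Lv = Lv, La = La,
               Lmu = build_scalar_operator(grid, cfg$omega_mu)),
    config = cfg), class = "sam_model")
}

#' Render a dataset from a known model
#'
#' Draws latents `z ~ N(0, A-hat^{-1})`, reconstructs, shoots, warps, applies
#' the noise model's sampling, and optionally removes a wrapped rectangle of
#' voxels per image (set to `NaN`).
#'
#' @param model A `sam_model` (typically from [make_ground_truth_model()]).
#' @param N Number of images.
#' @param noise_level Gaussian noise standard deviation; for the Bernoulli
#'   and categorical models any positive value requests hard random draws and
#'   `0` returns the expected (soft) images.
#' @param missing_frac Fraction of each image's area removed (0 = none).
#' @return List with `images`, `z_true` (K x N), `masks` (or `NULL`) and the
#'   generating `model`.
#' @export
render_dataset <- function(model, N, noise_level = 0.05, missing_frac = 0) {
  grid <- model$grid
  K <- model$K
  Sig <- solve(model$A_hat)
  Ch <- chol((Sig + t(Sig)) / 2)
  Z <- t(Ch) %*% matrix(stats::rnorm(K * N), K, N)
  images <- vector("list", N)
  M <- nvox(grid)
  for (n in seq_len(N)) {
    rec <- reconstruct(model, Z[, n])
    def <- shoot_z(model, Z[, n])
    ap <- pull(rec$a, def)
    img <- mean_function(ap, model$noise, grid)
    if (noise_level > 0) {
      img <- switch(model$noise,
        gaussian = img + array(stats::rnorm(M, sd = noise_level),
                               dim = grid$dims),
        bernoulli = array(as.numeric(stats::runif(M) < img), dim = grid$dims),
        categorical = {
          C <- model$C
          pm <- matrix(as.numeric(img), M, C)
          pick <- max.col(log(pmax(pm, 1e-12)) -
                            log(-log(matrix(stats::runif(M * C), M, C))))
          out <- matrix(0, M, C)
          out[cbind(seq_len(M), pick)] <- 1
          array(out, dim = c(grid$dims, C))
        })
    }
    images[[n]] <- img
  }
  masks <- NULL
  if (missing_frac > 0) {
    mk <- mask_rectangles(images, grid, frac = missing_frac)
    images <- mk$images
    masks <- mk$masks
  }
  list(images = images, z_true = Z, masks = masks, model = model)
}
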