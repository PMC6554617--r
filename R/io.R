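## Image and model I/O.  3D images travel as NIfTI (spacing preserved, NaN
## for missing voxels in float volumes), 2D images as PNG (uint8/16 scaled to
## [0, 1]; no NaN support) or as a raw-array container (an RDS file holding
## the array and its voxel size; bit-exact round trip including NaN).  Model
## checkpoints are a single container of named arrays plus the config echo.

#' Read an image from disk
#'
#' Format is chosen by extension: `.nii`/`.nii.gz` (NIfTI, any
#' dimensionality), `.png` (2D, values scaled to `[0, 1]`), `.rds`
#' (raw-array container written by [write_image()]).
#'
#' @param path File path.
#' @param model Noise-model tag attached to the result.
#' @return An [observed_image()]; `NaN` voxels are marked missing.
#' @export
read_image <- function(path, model = "gaussian") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    v <- RNifti::readNifti(path)
    arr <- array(as.numeric(v), dim = dim(v))
    vs <- RNifti::pixdim(v)
    gd <- dim(arr)
    nd <- length(gd)
    if (model == "categorical") {
      grid <- grid_spec(gd[-nd], voxel_size = vs[seq_len(nd - 1L)])
    } else {
      grid <- grid_spec(gd, voxel_size = vs[seq_len(nd)])
    }
    observed_image(arr, model, grid)
  } else if (grepl("\\.png$", path)) {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]   # first channel of RGB(A)
    observed_image(array(as.numeric(p), dim = dim(p)), model)
  } else if (grepl("\\.rds$", path)) {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data))
      stop("not a raw-array image container: ", path)
    grid <- grid_spec(obj$grid_dims, voxel_size = obj$voxel_size)
    observed_image(obj$data, if (!is.null(obj$model)) obj$model else model,
                   grid)
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write an image to disk
#'
#' @param image An [observed_image()] or bare array.
#' @param path Destination; the extension selects NIfTI, PNG or the
#'   raw-array container.
#' @param grid Grid (needed for bare arrays with non-unit spacing).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, grid = NULL) {
  if (inherits(image, "observed_image")) {
    grid <- image$grid
    model <- image$model
    data <- image$data
  } else {
    data <- image
    model <- "gaussian"
    if (is.null(grid)) grid <- grid_spec(dim(image))
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    v <- RNifti::asNifti(data)
    nd <- length(dim(data))
    pd <- rep(1, nd)
    pd[seq_len(grid$d)] <- grid$voxel_size
    RNifti::pixdim(v) <- pd
    RNifti::writeNifti(v, path)
  } else if (grepl("\\.png$", path)) {
    if (length(dim(data)) != 2L) stop("PNG supports 2D single-channel only")
    if (any(is.na(data))) stop("PNG cannot represent NaN; use .rds or .nii")
    png::writePNG(pmin(pmax(data, 0), 1), path)
  } else if (grepl("\\.rds$", path)) {
    saveRDS(list(data = data, grid_dims = grid$dims,
                 voxel_size = grid$voxel_size, model = model), path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

#' Save a fitted model checkpoint
#'
#' A single container holding the template, bases, noise parameters,
#' expected precision, grid metadata and an echo of the fitting
#' configuration — named arrays only, no code.
#'
#' @param model A `sam_model` or `sam_fit`.
#' @param path Destination (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  fitobj <- NULL
  if (inherits(model, "sam_fit")) { fitobj <- model; model <- model$model }
  ck <- list(format = "shapeappear-checkpoint-1",
             grid_dims = model$grid$dims, voxel_size = model$grid$voxel_size,
             noise = model$noise, mode = model$mode,
             K = model$K, Ka = model$Ka, Kv = model$Kv, C = model$C,
             N = model$N,
             mu = model$mu, Wa = model$Wa, Wv = model$Wv,
             sigma2 = model$sigma2, A_hat = model$A_hat,
             config = unclass(model$config))
  if (!is.null(fitobj)) {
    ck$Z <- fitobj$latents$Z
    ck$history <- fitobj$history
  }
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint path.
#' @return A `sam_model` (with latents attached as attribute `"Z"` when the
#'   checkpoint holds them).
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "shapeappear-checkpoint-1"))
    stop("not a shapeappear checkpoint: ", path)
  grid <- grid_spec(ck$grid_dims, voxel_size = ck$voxel_size)
  cfg <- ck$config
  class(cfg) <- "fit_config"
  model <- structure(list(
    grid = grid, noise = ck$noise, mode = ck$mode,
    K = ck$K, Ka = ck$Ka, Kv = ck$Kv, C = ck$C, N = ck$N,
    mu = ck$mu, Wa = ck$Wa, Wv = ck$Wv,
    sigma2 = ck$sigma2, A_hat = ck$A_hat,
    ops = list(
      Lv = build_velocity_operator(grid, pmax(cfg$omega_v,
                                              c(1e-6, 0, 0, 0, 0))),
      La = build_scalar_operator(grid, cfg$omega_a),
      Lmu = build_scalar_operator(
        grid, (if (isTRUE(cfg$scale_mu_by_N)) max(ck$N, 1) else 1) *
          cfg$omega_mu)),
    config = cfg), class = "sam_model")
  if (!is.null(ck$Z)) attr(model, "Z") <- ck$Z
  model
}

#' Read a fitting configuration from a YAML file
#'
#' Recognised keys mirror the [fit_config()] arguments (`K`, `K_a`, `K_v`,
#' `mode`, `lambda`, `n_iter`, `n_shoot`, `omega_v`, `omega_a`, `omega_mu`,
#' `noise`, `n_latent_iter`, `nu0`, `seed`, ...).
#'
#' @param path YAML file.
#' @return A [fit_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(fit_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(fit_config, y)
}
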