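## Shared machinery for finite-difference verification of the Gauss-Newton
## gradients, used by both the per-module gradient tests and the acceptance
## suite.  Appearance-type gradients (mu, W^a columns, the appearance part of
## z) are exact derivatives of the objective at fixed deformations.
## Shape-type gradients use the transported appearance gradient (the chain
## rule through the resampling at first order), so they are checked against
## the objective they are the exact gradient of: the one where a velocity
## perturbation u acts on the template as a - (grad a . u) before warping.

gn_fixture <- function(noise, with_na, seed = 50) {
  set.seed(seed)
  g <- grid_spec(c(6, 6))
  gt <- make_ground_truth_model(g, K = 2, noise = noise,
                                max_displacement = 1.2)
  ds <- render_dataset(gt, N = 4, noise_level = 0.05,
                       missing_frac = if (with_na) 0.25 else 0)
  model <- gt
  model$sigma2 <- 0.05^2
  model$N <- 4
  Z <- init_latents(4, 2)
  lat <- list(Z = Z, S = matrix(0, 2, 2), Cz = Z %*% t(Z))
  dset <- as_dataset(ds$images, noise, g)
  defs <- lapply(seq_len(4), function(n)
    shapeappear:::shoot_z(model, Z[, n]))
  list(g = g, model = model, lat = lat, ds = dset, defs = defs)
}

sum_J <- function(model, ds, Z, defs) {
  tot <- 0
  for (n in seq_len(ds$N)) {
    a <- reconstruct(model, Z[, n])$a
    tot <- tot + energy_derivs(ds$images[[n]], a, defs[[n]],
                               sigma2 = model$sigma2,
                               want_derivs = FALSE)$energy
  }
  tot
}

fd_rel_err <- function(pred, fd) abs(pred - fd) / max(abs(fd), 1e-6)

## Max relative FD error of the mean-update gradient over a few voxels.
grad_err_mu <- function(fx, npick = 6) {
  m <- fx$model
  gsum <- 0
  for (n in 1:4) {
    a <- reconstruct(m, fx$lat$Z[, n])$a
    gsum <- gsum + energy_derivs(fx$ds$images[[n]], a, fx$defs[[n]],
                                 m$sigma2)$grad
  }
  gtot <- gsum + apply_operator(m$ops$Lmu, m$mu)
  objf <- function(mu) {
    m2 <- m; m2$mu <- mu
    sum_J(m2, fx$ds, fx$lat$Z, fx$defs) + 0.5 * quad_form(m$ops$Lmu, mu)
  }
  eps <- 1e-4
  set.seed(1)
  errs <- vapply(sample(length(m$mu), npick), function(j) {
    mp <- m$mu; mm <- m$mu
    mp[j] <- mp[j] + eps; mm[j] <- mm[j] - eps
    fd_rel_err(gtot[j], (objf(mp) - objf(mm)) / (2 * eps))
  }, numeric(1))
  max(errs)
}

grad_err_wa <- function(fx, npick = 6) {
  m <- fx$model
  k <- 1L
  zk <- fx$lat$Z[k, ]
  gsum <- 0
  for (n in 1:4) {
    a <- reconstruct(m, fx$lat$Z[, n])$a
    gsum <- gsum + zk[n] * energy_derivs(fx$ds$images[[n]], a,
                                         fx$defs[[n]], m$sigma2)$grad
  }
  cfg <- m$config
  reg_k <- cfg$lambda[1] * 4 + cfg$lambda[2] * fx$lat$Cz[k, k]
  gtot <- gsum + apply_operator(m$ops$La, m$Wa[[k]], scale = reg_k)
  objf <- function(wk) {
    m2 <- m; m2$Wa[[k]] <- wk
    Ga <- shapeappear:::gram_matrix(m2$Wa, m2$ops$La)
    sum_J(m2, fx$ds, fx$lat$Z, fx$defs) +
      shapeappear:::appearance_penalty(m2, fx$lat, Ga)
  }
  eps <- 1e-4
  set.seed(2)
  errs <- vapply(sample(length(m$Wa[[k]]), npick), function(j) {
    wp <- m$Wa[[k]]; wm <- m$Wa[[k]]
    wp[j] <- wp[j] + eps; wm[j] <- wm[j] - eps
    fd_rel_err(gtot[j], (objf(wp) - objf(wm)) / (2 * eps))
  }, numeric(1))
  max(errs)
}

grad_err_wv <- function(fx) {
  m <- fx$model
  g <- fx$g
  M <- nvox(g)
  k <- 1L
  zk <- fx$lat$Z[k, ]
  Gk <- matrix(0, M, 2)
  for (n in 1:4) {
    a <- reconstruct(m, fx$lat$Z[, n])$a
    dv <- energy_derivs(fx$ds$images[[n]], a, fx$defs[[n]], m$sigma2)
    ga <- shapeappear:::spatial_gradient(a, g)
    sd <- shapeappear:::shape_image_derivs(m, dv$grad, dv$hess, ga)
    Gk <- Gk + zk[n] * sd$g
  }
  cfg <- m$config
  reg_k <- cfg$lambda[1] * 4 + cfg$lambda[2] * fx$lat$Cz[k, k]
  gtot <- array(Gk, c(g$dims, 2)) +
    apply_operator(m$ops$Lv, m$Wv[[k]], scale = reg_k)
  set.seed(3)
  E <- array(rnorm(M * 2), c(g$dims, 2))
  objf <- function(delta) {
    tot <- 0
    for (n in 1:4) {
      a <- reconstruct(m, fx$lat$Z[, n])$a
      ga <- shapeappear:::spatial_gradient(a, g)
      corr <- array(0, dim = dim(a))
      for (c in seq_len(m$C)) {
        acc <- 0
        for (j in 1:2)
          acc <- acc + E[, , j] *
            array(ga[(((j - 1) * m$C + (c - 1)) * M) + seq_len(M)], g$dims)
        corr <- if (m$C == 1L) acc else
          shapeappear:::set_channel(corr, g, c, acc)
      }
      apert <- a - delta * zk[n] * corr
      tot <- tot + energy_derivs(fx$ds$images[[n]], apert, fx$defs[[n]],
                                 sigma2 = m$sigma2,
                                 want_derivs = FALSE)$energy
    }
    tot + 0.5 * reg_k * quad_form(m$ops$Lv, m$Wv[[k]] + delta * E)
  }
  eps <- 1e-4
  fd_rel_err(sum(gtot * E), (objf(eps) - objf(-eps)) / (2 * eps))
}

grad_err_z <- function(fx) {
  m <- fx$model
  g <- fx$g
  M <- nvox(g)
  P <- shapeappear:::latent_precision(m)
  n <- 2L
  z <- fx$lat$Z[, n]
  parts <- shapeappear:::latent_gn_parts(m, fx$ds$images[[n]], z, P,
                                         def = fx$defs[[n]])
  a0 <- reconstruct(m, z)$a
  ga <- shapeappear:::spatial_gradient(a0, g)
  objf <- function(zc) {
    dz <- zc - z
    a <- a0
    ia <- shapeappear:::appearance_index(m)
    for (k in 1:m$Ka) a <- a + dz[ia[k]] * m$Wa[[k]]
    iv <- shapeappear:::shape_index(m)
    for (k in 1:m$Kv) {
      wv <- m$Wv[[k]]
      for (c in seq_len(m$C)) {
        acc <- 0
        for (j in 1:2)
          acc <- acc + wv[, , j] *
            array(ga[(((j - 1) * m$C + (c - 1)) * M) + seq_len(M)], g$dims)
        if (m$C == 1L) a <- a - dz[iv[k]] * acc
        else a <- shapeappear:::set_channel(
          a, g, c, shapeappear:::get_channel(a, g, c) - dz[iv[k]] * acc)
      }
    }
    energy_derivs(fx$ds$images[[n]], a, fx$defs[[n]], sigma2 = m$sigma2,
                  want_derivs = FALSE)$energy + 0.5 * sum(zc * (P %*% zc))
  }
  eps <- 1e-5
  errs <- vapply(1:2, function(k) {
    zp <- z; zm <- z
    zp[k] <- zp[k] + eps; zm[k] <- zm[k] - eps
    fd_rel_err(parts$grad[k], (objf(zp) - objf(zm)) / (2 * eps))
  }, numeric(1))
  max(errs)
}
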