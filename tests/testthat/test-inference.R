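test_that("encoding the template rendering returns a near-zero latent code", {
  set.seed(60)
  g <- grid_spec(c(16, 16))
  gt <- make_ground_truth_model(g, K = 2, noise = "gaussian")
  gt$sigma2 <- 0.01
  enc <- encode(observed_image(gt$mu, "gaussian", g), gt)
  expect_lt(max(abs(enc$z)), 1e-6)
  expect_true(is.finite(enc$log_evidence))
})

test_that("evidence drops when structure is replaced by matched noise", {
  set.seed(61)
  g <- grid_spec(c(16, 16))
  gt <- make_ground_truth_model(g, K = 2, noise = "gaussian")
  gt$sigma2 <- 0.05^2
  draws <- render_dataset(gt, N = 10, noise_level = 0.05)
  wins <- 0
  for (n in 1:10) {
    img <- draws$images[[n]]
    noise_img <- array(sample(as.numeric(img)), dim(img))  # same marginals
    ev_real <- encode(observed_image(img, "gaussian", g), gt)$log_evidence
    ev_noise <- encode(observed_image(noise_img, "gaussian", g),
                       gt)$log_evidence
    wins <- wins + (ev_real > ev_noise)
  }
  expect_equal(wins, 10)
})

test_that("encoding is stable across latent starting points", {
  set.seed(62)
  g <- grid_spec(c(16, 16))
  gt <- make_ground_truth_model(g, K = 2, noise = "gaussian")
  gt$sigma2 <- 0.05^2
  img <- render_dataset(gt, N = 1, noise_level = 0.02)$images[[1]]
  f <- observed_image(img, "gaussian", g)
  zs <- sapply(1:3, function(i) {
    set.seed(100 + i)
    encode(f, gt, z_init = rnorm(2, sd = 0.3), max_iter = 40)$z
  })
  expect_lt(max(abs(zs[, 1] - zs[, 2])), 1e-3)
  expect_lt(max(abs(zs[, 1] - zs[, 3])), 1e-3)
})

test_that("class posteriors are proper and symmetric for identical models", {
  set.seed(63)
  g <- grid_spec(c(16, 16))
  gt <- make_ground_truth_model(g, K = 2, noise = "gaussian")
  gt$sigma2 <- 0.05^2
  img <- render_dataset(gt, N = 1, noise_level = 0.05)$images[[1]]
  one <- classify(img, list(a = gt))
  expect_equal(unname(one$probs), 1)
  two <- classify(img, list(a = gt, b = gt), priors = c(0.5, 0.5))
  expect_equal(unname(two$probs), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sum(two$probs), 1)
  ## invariance under a constant shift of all log evidences: posterior is a
  ## softmax, so shifting both classes' priors equally changes nothing
  two_b <- classify(img, list(a = gt, b = gt), priors = c(0.2, 0.2))
  expect_equal(two$probs, two_b$probs, tolerance = 1e-12)
})

test_that("sampling: z = 0 gives the template, -z mirrors, covariance matches", {
  set.seed(64)
  g <- grid_spec(c(16, 16))
  gt <- make_ground_truth_model(g, K = 2, noise = "gaussian")
  s0 <- sample_model(gt, z = c(0, 0))
  expect_equal(s0$image, gt$mu, tolerance = 1e-12)
  z <- c(0.8, -0.5)
  sp <- sample_model(gt, z = z)
  sn <- sample_model(gt, z = -z)
  rp <- reconstruct(gt, z); rn <- reconstruct(gt, -z)
  expect_equal(rp$a - gt$mu, -(rn$a - gt$mu), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sp$image, sn$image)))
  ## sampler audit: empirical covariance of many draws matches A-hat^{-1}
  A <- matrix(c(2, 0.6, 0.6, 1), 2, 2)
  gt$A_hat <- A
  Zs <- sample_latents(gt, 10000L)
  emp <- Zs %*% t(Zs) / 10000
  tgt <- solve(A)
  expect_lt(norm(emp - tgt, "F") / norm(tgt, "F"), 0.05)
})

test_that("imputation fills missing rectangles better than the mean baseline", {
  set.seed(65)
  fx <- tiny_synthetic(dims = c(16, 16), K = 2, N = 1, noise_level = 0.02)
  gt <- fx$gt
  gt$sigma2 <- 0.02^2
  truth <- fx$ds$images[[1]]
  masked <- mask_rectangles(list(truth), fx$grid, frac = 0.25)
  f <- observed_image(masked$images[[1]], "gaussian", fx$grid)
  imp <- impute(f, gt, truth = truth)
  expect_false(anyNA(imp$image))
  ## intensity-mean baseline scored with the same noise model
  sel <- as.numeric(masked$masks[[1]]) == 1
  base_pred <- array(mean(truth[!masked$masks[[1]]]), dim(truth))
  base_ll <- sum(-0.5 * log(2 * pi * gt$sigma2) -
                   (truth[sel] - base_pred[sel])^2 / (2 * gt$sigma2)) / sum(sel)
  expect_gt(imp$heldout_mean_loglik, base_ll)
  ## no missing voxels: imputation equals encode-then-reconstruct
  f_full <- observed_image(truth, "gaussian", fx$grid)
  imp2 <- impute(f_full, gt)
  enc <- encode(f_full, gt)
  rec <- reconstruct(gt, enc$z)
  expect_equal(imp2$image, pull(rec$a, enc$deformation), tolerance = 1e-10)
  ## fully missing image: reconstruction at the prior mean z = 0
  f_none <- observed_image(array(NaN, fx$grid$dims), "gaussian", fx$grid)
  imp3 <- impute(f_none, gt)
  expect_lt(max(abs(imp3$encoding$z)), 1e-10)
  expect_equal(imp3$image, gt$mu, tolerance = 1e-10)
})

test_that("overlap metrics reproduce hand-computed values", {
  mu <- array(c(0.9, 0.9, 0.1, 0.1), c(2, 2))
  b <- array(c(1, 0, 1, 0), c(2, 2))
  om <- overlap_metrics(mu, b)
  expect_equal(om$jaccard, 1 / 3)
  expect_equal(om$loglik,
               (log2(0.9) + log2(0.1) + log2(0.1) + log2(0.9)) / 4)
  ## perfect and disjoint cases
  bb <- array(c(1, 1, 0, 0), c(2, 2))
  expect_equal(overlap_metrics(array(c(1, 1, 0, 0), c(2, 2)), bb,
                               clamp = 1e-9)$jaccard, 1)
  expect_equal(overlap_metrics(array(c(1, 1, 0, 0), c(2, 2)), bb,
                               clamp = 1e-9)$loglik, 0, tolerance = 1e-7)
  expect_equal(overlap_metrics(array(c(0, 0, 1, 1), c(2, 2)), bb)$jaccard, 0)
})

test_that("mask_rectangles removes exactly the requested wrapped fraction", {
  set.seed(66)
  g <- grid_spec(c(32, 32))
  imgs <- lapply(1:5, function(i) array(rnorm(1024), c(32, 32)))
  mk <- mask_rectangles(imgs, g, frac = 0.25)
  for (n in 1:5) {
    expect_equal(mean(is.na(mk$images[[n]])), 0.25)
    expect_equal(mean(mk$masks[[n]]), 0.25)
  }
})

test_that("configuration cross-validation is reproducible and well-formed", {
  set.seed(67)
  fx <- tiny_synthetic(dims = c(16, 16), K = 2, N = 8, noise_level = 0.05)
  cfgs <- list(shared = fit_config(K = 2, noise = "gaussian", n_iter = 2,
                                   seed = 3))
  cv1 <- cross_validate_configs(fx$ds$images, cfgs, frac = 0.25, seed = 9)
  cv2 <- cross_validate_configs(fx$ds$images, cfgs, frac = 0.25, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(dim(cv1$per_image), c(8L, 1L))
  expect_true(all(is.finite(cv1$per_image)))
})
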