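test_that("patch extraction enumerates stride-1 origins with mean removal", {
  d <- c(7, 6, 5)
  set.seed(1)
  f <- array(runif(prod(d)), d)
  u <- array(runif(prod(d)), d)
  pairs <- extract_patch_pairs(f, u)
  expect_equal(ncol(pairs$inputs), prod(d - 3))
  expect_equal(dim(pairs$inputs), c(64L, prod(d - 3)))
  expect_equal(dim(pairs$labels), c(8L, prod(d - 3)))
  expect_equal(colSums(pairs$inputs), rep(0, prod(d - 3)))
  # labels carry the central section's deviation from the 4^3 patch mean of u
  expect_equal(extract_patch_pairs(f, array(5, d))$labels,
               matrix(0, 8, prod(d - 3)))

  const <- array(3, d)
  expect_equal(max(abs(extract_patch_pairs(const, u)$inputs)), 0)

  expect_error(extract_patch_pairs(f, u[, , 1:4]), "shape")
  expect_error(extract_patch_pairs(f[, 1:3, ], u[, 1:3, ]), ">= 4")
})

test_that("a single 4x4x4 patch yields the hand-indexed central label", {
  a <- array(0:63, c(4, 4, 4))   # raster order, x fastest
  u <- a * 2
  pairs <- extract_patch_pairs(a, u)
  expect_equal(ncol(pairs$inputs), 1L)
  # central 2x2x2 voxels of u: x,y,z in {2,3} (1-based), minus the mean of
  # the full 4x4x4 patch of u
  core_vals <- c(u[2, 2, 2], u[3, 2, 2], u[2, 3, 2], u[3, 3, 2],
             u[2, 2, 3], u[3, 2, 3], u[2, 3, 3], u[3, 3, 3])
  expect_equal(pairs$labels[, 1], core_vals - mean(as.vector(u)))
  expect_equal(pairs$inputs[, 1], 0:63 - mean(0:63))
})

test_that("variance ranking keeps the top labels plus a seeded random rest", {
  # 4 pairs with label variances 0 < 1 < 2 < 3 (up to a common factor)
  L <- rbind(c(0, 1, 2, 3), c(0, -1, -2, -3), matrix(0, 6, 4))
  fake <- structure(list(inputs = matrix(rnorm(64 * 4), 64),
                         labels = L, positions = 1:4),
                    class = "patch_pairs")
  cfg <- train_config(K = 2, high_variance_count = 2, iterations = 1)
  sel <- select_training_patches(fake, cfg)
  expect_setequal(sel$positions, c(3, 4))

  cfg1 <- train_config(K = 3, high_variance_count = 1, iterations = 1,
                       seed = 9)
  s1 <- select_training_patches(fake, cfg1)
  s2 <- select_training_patches(fake, cfg1)
  expect_identical(s1$positions, s2$positions)
  expect_true(4 %in% s1$positions)

  cfg_all <- train_config(K = 4, high_variance_count = 2, iterations = 1)
  expect_setequal(select_training_patches(fake, cfg_all)$positions, 1:4)
  expect_error(select_training_patches(
    fake, train_config(K = 5, high_variance_count = 2, iterations = 1)),
    "shrink K")
})

test_that("row min-max scaling is an exact bijection with a degenerate-row rule", {
  set.seed(2)
  fake <- structure(list(inputs = matrix(rnorm(64 * 50), 64),
                         labels = matrix(rnorm(8 * 50), 8),
                         positions = 1:50), class = "patch_pairs")
  sc <- fit_row_scaling(fake)
  expect_equal(apply(sc$inputs, 1, min), rep(-1, 64))
  expect_equal(apply(sc$inputs, 1, max), rep(1, 64))
  back <- unscale_rows(sc$inputs, sc$scaling$input_row_min,
                       sc$scaling$input_row_max)
  expect_lt(max(abs(back - fake$inputs)), 1e-12)

  m <- rbind(rep(5, 10), 1:10)
  rmin <- apply(m, 1, min); rmax <- apply(m, 1, max)
  s <- scale_rows(m, rmin, rmax)
  expect_equal(s[1, ], rep(0, 10))
  expect_equal(unscale_rows(s, rmin, rmax)[1, ], rep(5, 10))
})

test_that("the forward pass matches a naive loop oracle", {
  expect_equal(
    ann_forward(structure(list(W1 = matrix(0, 4, 6), b1 = numeric(4),
                               W2 = matrix(0, 2, 4), b2 = numeric(2),
                               dims = c(n_inp = 6, n_hid = 4, n_out = 2)),
                          class = "ann_model"), rnorm(6)),
    c(0, 0))
  m0 <- structure(list(W1 = matrix(0, 4, 6), b1 = numeric(4),
                       W2 = matrix(1, 2, 4), b2 = c(3, -2),
                       dims = c(n_inp = 6, n_hid = 4, n_out = 2)),
                  class = "ann_model")
  expect_equal(ann_forward(m0, rnorm(6)), c(3, -2))

  set.seed(7)
  mdl <- structure(list(W1 = matrix(rnorm(128 * 64, sd = 0.2), 128),
                        b1 = rnorm(128, sd = 0.1),
                        W2 = matrix(rnorm(8 * 128, sd = 0.2), 8),
                        b2 = rnorm(8, sd = 0.1),
                        dims = c(n_inp = 64, n_hid = 128, n_out = 8)),
                   class = "ann_model")
  for (rep in 1:10) {
    x <- rnorm(64)
    expect_lt(max(abs(ann_forward(mdl, x) -
                      oracle_forward(mdl$W1, mdl$b1, mdl$W2, mdl$b2, x))),
              1e-10)
  }
  expect_error(ann_forward(mdl, rnorm(10)), "input size")
})

test_that("SGD reaches the identity-task floor, converges, and is deterministic", {
  # noise-free smooth image: the label is a deterministic function of the
  # input patch, so the network can fit it nearly exactly
  d <- c(16, 16, 14)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  img <- array(exp(-((g$x - 8)^2 + (g$y - 8)^2 + (g$z - 7)^2) / 40) +
                 0.3 * sin(g$x / 2) * cos(g$y / 3), d) + 1
  cfg <- train_config(K = 1500, high_variance_count = 750,
                      iterations = 12000, seed = 5)
  model <- train_patch_denoiser(img, img, cfg)

  pairs <- extract_patch_pairs(img / max(img), img / max(img))
  pairs <- select_training_patches(pairs, cfg)
  sc <- fit_row_scaling(pairs)
  pred <- ann_forward(model, sc$inputs)
  mse <- mean((pred - sc$labels)^2)
  expect_lt(mse, 0.01 * mean(sc$labels^2))

  # smoothed loss decreased over training
  l <- model$loss_trace
  w <- 1000
  expect_lt(mean(l[(length(l) - w + 1):length(l)]), mean(l[1:w]))

  m2 <- train_patch_denoiser(img, img, cfg)
  expect_identical(model$W1, m2$W1)
  expect_identical(model$b2, m2$b2)

  # near-identity recovery on the training image, one pass
  out <- denoise_frame(model, img, passes = 1)
  expect_lt(sqrt(mean((out - img)^2)) / sqrt(mean(img^2)), 0.02)
  expect_identical(denoise_frame(model, img, passes = 0), img)
  expect_error(denoise_frame(model, img, passes = -1), "nonnegative")
})

test_that("frame denoising equals the brute-force patch-loop oracle", {
  set.seed(11)
  d <- c(8, 8, 8)
  z <- array(runif(prod(d), 1, 10), d)
  # small but genuine model with nontrivial scaling
  img <- array(runif(14 * 13 * 12, 0, 5), c(14, 13, 12))
  cfg <- train_config(K = 500, high_variance_count = 250, iterations = 300,
                      seed = 3)
  model <- train_patch_denoiser(img, img, cfg)
  got <- denoise_frame(model, z, passes = 1)
  want <- oracle_denoise_pass(model, z)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)

  zero <- array(0, d)
  expect_identical(denoise_frame(model, zero, passes = 2), zero)
})

test_that("series denoising composes frame denoising and keeps the schedule", {
  sch <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
  set.seed(4)
  arr <- array(runif(6 * 6 * 6 * 3, 0, 2), c(6, 6, 6, 3))
  dyn <- dynamic_image(arr, sch, 2)
  img <- array(runif(10^3, 0, 2), c(10, 10, 10))
  model <- train_patch_denoiser(
    img, img, train_config(K = 200, high_variance_count = 100,
                           iterations = 200, seed = 8))
  expect_identical(denoise_series(model, dyn, 0)$frames, dyn$frames)
  out <- denoise_series(model, dyn, 2)
  expect_identical(out$schedule, sch)
  for (i in 1:3)
    expect_equal(get_frame(out, i),
                 denoise_frame(model, get_frame(dyn, i), 2))
  # predict() dispatches on the input kind
  expect_equal(predict(model, dyn, passes = 2)$frames, out$frames)
  expect_equal(predict(model, get_frame(dyn, 1), passes = 2),
               get_frame(out, 1))
})

test_that("model serialization round-trips losslessly through JSON", {
  img <- array(runif(10^3, 0, 3), c(10, 10, 10))
  model <- train_patch_denoiser(
    img, img, train_config(K = 150, high_variance_count = 75,
                           iterations = 150, seed = 12))
  path <- tempfile(fileext = ".json")
  write_ann_model(model, path)
  back <- read_ann_model(path)
  expect_equal(back$W1, model$W1, tolerance = 0)
  expect_equal(back$b1, model$b1, tolerance = 0)
  expect_equal(back$W2, model$W2, tolerance = 0)
  expect_equal(back$b2, model$b2, tolerance = 0)
  expect_equal(back$scaling$input_row_min, model$scaling$input_row_min,
               tolerance = 0)
  expect_equal(back$scaling$global_max, model$scaling$global_max,
               tolerance = 0)
  z <- array(runif(6^3, 0, 3), c(6, 6, 6))
  expect_equal(denoise_frame(back, z, 1), denoise_frame(model, z, 1))
})
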