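sch <- default_schedule()
aif <- feng_aif()

test_that("NEC-style frame weights follow dt^2 / counts and normalize", {
  s2 <- frame_schedule(c(0, 1), c(1, 3))
  w <- compute_frame_weights(c(100, 400), s2)
  expect_equal(sum(w), 1)
  expect_equal(w[2] / w[1], (2^2 / 400) / (1^2 / 100))  # equal weights

  s4 <- frame_schedule(0:3, 1:4)
  expect_equal(as.numeric(compute_frame_weights(rep(7, 4), s4)),
               rep(0.25, 4))
  # count scale invariance
  expect_equal(as.numeric(compute_frame_weights(c(10, 20, 40, 30), s4)),
               as.numeric(compute_frame_weights(2 * c(10, 20, 40, 30), s4)))
  expect_warning(w0 <- compute_frame_weights(c(10, 0, 40, 30), s4), "zero")
  expect_equal(as.numeric(w0[2]), 0)
  expect_equal(as.numeric(compute_frame_weights(NULL, s4, "uniform")),
               rep(0.25, 4))
})

test_that("the basis set reproduces unit-K1 tissue curves and is monotone late", {
  basis <- build_basis(aif, sch)
  expect_equal(length(basis$k2_grid), 100L)
  expect_true(all(basis$B >= 0))
  expect_error(build_basis(aif, sch, n_bases = 1), "at least 2")

  # same integral as tissue_tac at a matched k2
  k2 <- basis$k2_grid[40]
  expect_lt(max(abs(basis$B[, 40] - tissue_tac(1, k2, aif, sch))) /
              max(basis$B[, 40]), 1e-3)

  # last frame (55-60 min, Cp near zero): basis decreasing in k2
  expect_true(all(diff(basis$B[21, ]) < 0))
})

test_that("basis-function fits invert the generative model", {
  basis05 <- build_basis(aif, sch,
                         k2_grid = sort(c(0.05, exp(seq(log(0.01), log(1),
                                                        length.out = 99)))))
  w <- compute_frame_weights(NULL, sch, "uniform")
  tac <- tissue_tac(0.15, 0.05, aif, sch)
  f <- fit_tac_1t(tac, basis05, w)
  expect_equal(f$k2, 0.05)
  expect_lt(abs(f$K1 - 0.15), 1e-6)
  expect_lt(abs(f$VT - 3), 1e-4)

  z <- fit_tac_1t(rep(0, 21), basis05, w)
  expect_equal(z$K1, 0)
  expect_equal(z$k2, basis05$k2_grid[1])
  expect_equal(z$VT, 0)
})

test_that("off-grid truth selects a bracketing grid point found by exhaustive search", {
  basis <- build_basis(aif, sch)
  w <- compute_frame_weights(NULL, sch, "uniform")
  grid <- basis$k2_grid
  k2_true <- sqrt(grid[50] * grid[51])   # midway in log space
  tac <- tissue_tac(0.2, k2_true, aif, sch)
  f <- fit_tac_1t(tac, basis, w)
  expect_true(f$k2 %in% grid[50:51])

  # exhaustive-search oracle over the grid
  rss <- sapply(seq_along(grid), function(j) {
    b <- basis$B[, j]
    k1 <- max(sum(w * b * tac) / sum(w * b^2), 0)
    sum(w * (tac - k1 * b)^2)
  })
  expect_equal(f$k2, grid[which.min(rss)])
  expect_equal(f$wrss, min(rss), tolerance = 1e-10)
})

test_that("voxel-wise mapping recovers the noise-free phantom parameters", {
  reg <- brain_region_map(c(16, 16, 12))
  truth <- brain_kinetic_truth()
  ph <- render_phantom(reg, truth, aif, sch, psf_fwhm = 0)
  basis <- build_basis(aif, sch)
  w <- compute_frame_weights(NULL, sch, "uniform")
  maps <- fit_parametric(ph, basis, w, mask = reg$labels > 0)

  for (l in as.character(1:6)) {
    idx <- which(reg$labels == as.integer(l))
    expect_lt(max(abs(maps$K1[idx] - truth$K1[[l]])) / truth$K1[[l]], 0.02)
    expect_lt(max(abs(maps$VT[idx] - truth$VT[[l]])) / truth$VT[[l]], 0.02)
  }
  # VT = K1/k2 identity over the full map
  m <- reg$labels > 0
  expect_equal(maps$VT[m], (maps$K1 / maps$k2)[m])
  # out-of-mask voxels are zero
  expect_equal(unique(maps$K1[!m]), 0)

  # single-voxel mask equals a direct TAC fit
  vox <- which(reg$labels == 3)[1]
  mask1 <- array(FALSE, dim(reg$labels)); mask1[vox] <- TRUE
  m1 <- fit_parametric(ph, basis, w, mask1)
  tac <- sapply(1:21, function(i) get_frame(ph, i)[vox])
  f1 <- fit_tac_1t(tac, basis, w)
  expect_equal(m1$K1[vox], f1$K1)
  expect_equal(m1$VT[vox], f1$VT)

  # spatially constant series gives spatially constant maps
  arr <- array(rep(tissue_tac(0.2, 0.07, aif, sch), each = 4^3),
               c(4, 4, 4, 21))
  cm <- fit_parametric(dynamic_image(arr, sch, 2), basis, w)
  expect_equal(length(unique(as.vector(cm$K1))), 1L)
  expect_error(fit_parametric(ph, basis, w,
                              array(FALSE, dim(reg$labels))), "empty mask")
})
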