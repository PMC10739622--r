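test_that("the standard protocol has 21 contiguous frames totalling 60 min", {
  sch <- default_schedule()
  expect_length(sch, 21L)
  expect_equal(sch$frame_end[21], 60)
  expect_equal(durations(sch),
               c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 10)))
  expect_equal(sch$frame_start[1], 0)
  expect_equal(sch$frame_start[-1], sch$frame_end[-21])
  expect_error(frame_schedule(c(0, 1), c(1.5, 2)), "contiguous")
  expect_error(frame_schedule(c(0, 1), c(1, 1)), "positive")
  expect_error(frame_schedule(c(1, 2), c(2, 3)), "start at 0")
})

test_that("the synthetic plasma curve rises from zero and peaks on cue", {
  expect_equal(max(feng_aif(amplitudes = c(0, 0, 0))$cp), 0)
  aif <- feng_aif()
  expect_equal(aif$cp[1], 0)
  expect_true(all(aif$cp >= 0))
  peak_at <- aif$time[which.max(aif$cp)]
  expect_lt(abs(peak_at - 0.5), 2)
  for (pt in c(0.3, 1, 2)) {
    a <- feng_aif(peak_time = pt)
    expect_lt(abs(a$time[which.max(a$cp)] - pt), 2)
  }
  expect_error(feng_aif(decay_rates = c(1, 1, 0.01)), "distinct")
})

test_that("tissue TACs match the analytic 1T solution", {
  sch <- default_schedule()
  aif <- feng_aif()
  expect_equal(tissue_tac(0, 0.05, aif, sch), rep(0, 21))

  # mono-exponential input: closed-form convolution, frame-averaged exactly
  lam <- 0.3; k2 <- 0.08; K1 <- 0.2
  t <- seq(0, 60, by = 1 / 60)
  expaif <- input_function(t, exp(-lam * t))
  got <- tissue_tac(K1, k2, expaif, sch)
  ct <- function(tt) K1 * (exp(-k2 * tt) - exp(-lam * tt)) / (lam - k2)
  want <- vapply(seq_len(21), function(i) {
    stats::integrate(ct, sch$frame_start[i], sch$frame_end[i],
                     rel.tol = 1e-10)$value / durations(sch)[i]
  }, numeric(1))
  expect_lt(max(abs(got - want) / max(want)), 1e-3)

  # constant input: late frames approach the steady state VT * c
  const <- input_function(t, rep(5, length(t)))
  tac <- tissue_tac(0.15, 0.25, const, sch)
  expect_lt(abs(tac[21] - 0.15 / 0.25 * 5) / (0.15 / 0.25 * 5), 1e-3)

  short <- input_function(seq(0, 30, by = 1 / 60), rep(1, 1801))
  expect_error(tissue_tac(0.1, 0.1, short, sch), "support")
})

test_that("rendered phantoms carry exact regional TACs and conserve mass under blur", {
  sch <- default_schedule()
  aif <- feng_aif()
  reg <- brain_region_map(c(20, 20, 16))
  truth <- brain_kinetic_truth()
  ph <- render_phantom(reg, truth, aif, sch, psf_fwhm = 0)
  tacs <- attr(ph, "tacs")
  for (l in c(1L, 3L, 6L)) {
    idx <- which(reg$labels == l)
    fr <- get_frame(ph, 12)
    expect_equal(unname(fr[idx]),
                 rep(unname(tacs[12, as.character(l)]), length(idx)))
  }
  rt <- regional_tac(ph, reg)
  expect_equal(unname(rt[, "1"]), unname(tacs[, "1"]))

  # blur conserves the global frame sum for an interior phantom
  ph3 <- render_phantom(reg, truth, aif, sch, psf_fwhm = 3)
  s0 <- sum(get_frame(ph, 12)); s3 <- sum(get_frame(ph3, 12))
  expect_lt(abs(s3 - s0) / s0, 0.005)

  bad <- kinetic_truth(K1 = c(`1` = 0.1), k2 = c(`1` = 0.05))
  expect_error(render_phantom(reg, bad, aif, sch), "label")
})

test_that("multinomial thinning partitions the full-count draw exactly", {
  sch <- default_schedule()
  aif <- feng_aif()
  reg <- brain_region_map(c(14, 14, 10))
  ph <- render_phantom(reg, brain_kinetic_truth(), aif, sch, psf_fwhm = 0)
  sens <- calibrate_sensitivity(ph, 50)
  rs <- poisson_realizations(ph, count_model(sens, seed = 11),
                             keep_counts = TRUE)
  cn <- attr(rs, "counts")
  expect_identical(Reduce(`+`, cn$reduced), cn$full)
  expect_length(rs$reduced, 10L)
  # zero-activity voxels stay zero in every realization
  bg <- which(reg$labels == 0)
  for (j in 1:10) expect_equal(get_frame(rs$reduced[[j]], 12)[bg],
                               rep(0, length(bg)))
  expect_error(
    poisson_realizations(ph, count_model(sens, dose_fraction = 0.2,
                                         n_realizations = 10)),
    "dose_fraction")
})

test_that("each thinned subset obeys the Poisson law at lambda/10", {
  n <- 10000
  lam <- 100
  img <- dynamic_image(array(lam, c(n, 1, 1, 1)),
                       frame_schedule(0, 1), 1)
  rs <- poisson_realizations(img, count_model(sensitivity = 1, seed = 3),
                             keep_counts = TRUE)
  cn <- attr(rs, "counts")
  for (j in c(1, 5, 10)) {
    x <- as.vector(cn$reduced[[j]])
    se <- sqrt(10 / n)
    expect_lt(abs(mean(x) - 10), 3 * se)
    expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  }
  # chi-square goodness of fit of one subset against Poisson(10)
  x <- as.vector(cn$reduced[[2]])
  br <- c(-Inf, 4:16, Inf)
  obs <- table(cut(x, br))
  p <- diff(ppois(c(-Inf, 4:16, Inf), 10))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("reduced-count realizations are noisier than full-count draws", {
  sch <- default_schedule()
  aif <- feng_aif()
  reg <- brain_region_map(c(14, 14, 10))
  ph <- render_phantom(reg, brain_kinetic_truth(), aif, sch, psf_fwhm = 0)
  sens <- calibrate_sensitivity(ph, 50)
  rs <- poisson_realizations(ph, count_model(sens, seed = 4))
  full_rs <- poisson_realizations(
    ph, count_model(sens, dose_fraction = 1, n_realizations = 10,
                    seed = 5, mode = "independent"))
  labs <- sort(unique(reg$labels[reg$labels > 0]))
  for (l in labs) {
    roi <- which(reg$labels == l)
    e_red <- ennsd(lapply(rs$reduced, get_frame, i = 12), roi)
    e_full <- ennsd(lapply(full_rs$reduced, get_frame, i = 12), roi)
    expect_gt(e_red, e_full)
  }
})
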