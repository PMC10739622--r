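#' Training configuration for the patch ANN
#'
#' @param K number of training patch pairs (default 100000).
#' @param high_variance_count how many of the K pairs are taken from the top
#'   of the label-patch variance ranking (default 50000); the rest are drawn
#'   uniformly without replacement from the remainder.
#' @param lr0 initial SGD learning rate (default 0.01).
#' @param decay_gamma,decay_power inverse-decay schedule
#'   lr_t = lr0 (1 + gamma t)^(-power); defaults 1e-4 and 0.75.
#' @param iterations number of mini-batch SGD parameter updates
#'   (default 150000).
#' @param batch_size samples per update (default 64).
#' @param init_scale weight-initialization scale; weights start symmetric
#'   uniform in +/- init_scale / sqrt(fan_in), offsets at 0.
#' @param n_hidden hidden-layer width (default 128).
#' @param seed integer seed controlling patch selection, initialization and
#'   batch shuffling.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(K = 100000, high_variance_count = 50000,
                         lr0 = 0.01, decay_gamma = 1e-4, decay_power = 0.75,
                         iterations = 150000, batch_size = 64,
                         init_scale = 1, n_hidden = 128, seed = 1) {
  if (high_variance_count > K)
    stop_badarg("high_variance_count must not exceed K")
  if (iterations <= 0) stop_badarg("iterations must be positive")
  structure(list(K = as.integer(K),
                 high_variance_count = as.integer(high_variance_count),
                 lr0 = lr0, decay_gamma = decay_gamma,
                 decay_power = decay_power,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 init_scale = init_scale, n_hidden = as.integer(n_hidden),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Linear indices of all 4x4x4 patch origins of a 3D array (stride 1) and the
# 64 within-patch offsets; `inner` gives the 8 central 2x2x2 offsets.
# Stacking order is x fastest, then y, then z (column-major).
.patch_geometry <- function(d, patch = 4L, core = 1:2) {
  ox <- seq_len(d[1] - patch + 1L)
  oy <- seq_len(d[2] - patch + 1L)
  oz <- seq_len(d[3] - patch + 1L)
  origins <- as.vector(outer(outer(ox, (oy - 1L) * d[1], `+`),
                             (oz - 1L) * d[1] * d[2], `+`))
  off <- function(rx, ry, rz)
    as.vector(outer(outer(rx, ry * d[1], `+`), rz * d[1] * d[2], `+`))
  list(origins = origins,
       input_off = off(0:(patch - 1L), 0:(patch - 1L), 0:(patch - 1L)),
       label_off = off(core, core, core))
}

# Gather a patch matrix (one column per origin) from a 3D array.
.gather_patches <- function(a, origins, offsets) {
  m <- matrix(0, length(offsets), length(origins))
  for (r in seq_along(offsets)) m[r, ] <- a[origins + offsets[r]]
  m
}

#' Extract co-located training patch pairs from an image pair
#'
#' Slides a 4x4x4 window with stride 1 over all valid origins of the
#' (pre-normalized) reduced-count image \code{f}; each input vector is the
#' flattened patch minus its own mean (stacked x fastest, then y, then z).
#' The label is the flattened central 2x2x2 (offsets 1-2 per axis) of the
#' co-located 4x4x4 patch in the full-count image \code{u}, minus that
#' patch's mean.  Subtracting the patch mean (rather than the central
#' section's own mean) keeps training consistent with reconstruction, where
#' the testing patch's mean is added back to the network output: the
#' identity mapping is then exactly representable and regional means are
#' preserved.
#'
#' @param f 3D reduced-count image, already divided by its global maximum.
#' @param u 3D full-count image divided by the same constant.
#' @return An object of class \code{patch_pairs}: \code{inputs} (64 x K),
#'   \code{labels} (8 x K), \code{positions} (linear origin indices).
#' @export
extract_patch_pairs <- function(f, u) {
  d <- dim(f)
  if (!identical(d, dim(u))) stop_badarg("f and u must have the same shape")
  if (length(d) != 3L || any(d < 4L))
    stop_badarg("images must be 3D with every dimension >= 4")
  g <- .patch_geometry(d)
  x <- .gather_patches(f, g$origins, g$input_off)
  u_patch_mean <- colMeans(.gather_patches(u, g$origins, g$input_off))
  y <- .gather_patches(u, g$origins, g$label_off)
  x <- sweep(x, 2L, colMeans(x))
  y <- sweep(y, 2L, u_patch_mean)
  structure(list(inputs = x, labels = y, positions = g$origins),
            class = "patch_pairs")
}

#' Variance-ranked training patch selection
#'
#' Ranks pairs by label-patch variance, keeps the top
#' \code{high_variance_count}, and draws the remaining
#' \code{K - high_variance_count} uniformly without replacement (seeded,
#' stream 2 of the seed-splitting scheme) from the rest.  High-variance
#' patches carry the strong gradients and noise; the random remainder keeps
#' uniform patches represented.
#'
#' @param pairs a \code{\link{extract_patch_pairs}} result.
#' @param cfg a \code{\link{train_config}}.
#' @return A \code{patch_pairs} object with K columns.
#' @export
select_training_patches <- function(pairs, cfg) {
  n <- ncol(pairs$inputs)
  if (n < cfg$K)
    stop_badarg("only ", n, " patch pairs available; shrink K (currently ",
                cfg$K, ")")
  v <- colMeans(pairs$labels^2) - colMeans(pairs$labels)^2
  ord <- order(v, decreasing = TRUE)
  top <- ord[seq_len(cfg$high_variance_count)]
  rest <- ord[-seq_len(cfg$high_variance_count)]
  n_rand <- cfg$K - cfg$high_variance_count
  if (n_rand > 0) {
    set.seed(split_seed(cfg$seed, 2L))
    top <- c(top, rest[sample.int(length(rest), n_rand)])
  }
  structure(list(inputs = pairs$inputs[, top, drop = FALSE],
                 labels = pairs$labels[, top, drop = FALSE],
                 positions = pairs$positions[top]),
            class = "patch_pairs")
}

#' Per-row min-max scaling of the training matrices
#'
#' Scales every row of the 64 x K input matrix and the 8 x K label matrix to
#' [-1, 1] by x_scaled = 2 (x - min) / (max - min) - 1, with min/max taken
#' over that row, and records all extrema.  Degenerate rows (max = min) are
#' mapped to 0 forward and to the stored constant backward.
#'
#' @param pairs selected \code{patch_pairs}.
#' @return List with \code{scaling} (a \code{scaling_record}),
#'   \code{inputs}, \code{labels} (scaled matrices).
#' @export
fit_row_scaling <- function(pairs) {
  if (ncol(pairs$inputs) < 1L) stop_badarg("empty patch set")
  rec <- list(input_row_min = apply(pairs$inputs, 1L, min),
              input_row_max = apply(pairs$inputs, 1L, max),
              label_row_min = apply(pairs$labels, 1L, min),
              label_row_max = apply(pairs$labels, 1L, max),
              global_max = NA_real_)
  class(rec) <- "scaling_record"
  list(scaling = rec,
       inputs = scale_rows(pairs$inputs, rec$input_row_min,
                           rec$input_row_max),
       labels = scale_rows(pairs$labels, rec$label_row_min,
                           rec$label_row_max))
}

#' Row-wise min-max scaling and its inverse
#'
#' @param m matrix (rows are scaled independently); row-extent vectors
#'   recycle down columns.
#' @param rmin,rmax per-row extrema recorded at training time.
#' @return The scaled (or unscaled) matrix.
#' @export
scale_rows <- function(m, rmin, rmax) {
  den <- rmax - rmin
  degen <- den == 0
  den[degen] <- 1
  out <- 2 * (m - rmin) / den - 1
  if (any(degen)) out[degen, ] <- 0
  out
}

#' @rdname scale_rows
#' @export
unscale_rows <- function(m, rmin, rmax) {
  den <- rmax - rmin
  degen <- den == 0
  out <- (m + 1) / 2 * den + rmin
  if (any(degen)) out[degen, ] <- rmin[degen]
  out
}

#' Train the single-hidden-layer patch ANN
#'
#' Minimizes the mean squared recovery loss (1/K) sum_k ||beta^k -
#' x_scaled^k||^2 by mini-batch stochastic gradient descent with the
#' inverse-decay learning rate lr_t = lr0 (1 + gamma t)^(-power).  The
#' network is input (64) -> ReLU hidden (128) -> linear output (8).  One
#' "iteration" is one mini-batch parameter update; the sample order is
#' reshuffled every epoch (seed stream 3) and weights start symmetric uniform
#' scaled by fan-in (seed stream 4).
#'
#' @param inputs scaled input matrix (n_inp x K, rows in [-1, 1]).
#' @param labels scaled label matrix (n_out x K).
#' @param cfg a \code{\link{train_config}}.
#' @param scaling optional \code{scaling_record} to embed in the model.
#' @return An object of class \code{ann_model} with weights \code{W1},
#'   \code{b1}, \code{W2}, \code{b2}, the scaling record, dims, config and
#'   the per-iteration training-loss trace.
#' @export
train_ann <- function(inputs, labels, cfg = train_config(), scaling = NULL) {
  n_inp <- nrow(inputs); n_out <- nrow(labels); K <- ncol(inputs)
  if (ncol(labels) != K) stop_badarg("inputs/labels column counts differ")
  nh <- cfg$n_hidden
  set.seed(split_seed(cfg$seed, 4L))
  W1 <- matrix(runif(nh * n_inp, -1, 1) * cfg$init_scale / sqrt(n_inp),
               nh, n_inp)
  W2 <- matrix(runif(n_out * nh, -1, 1) * cfg$init_scale / sqrt(nh),
               n_out, nh)
  b1 <- numeric(nh); b2 <- numeric(n_out)
  set.seed(split_seed(cfg$seed, 3L))
  perm <- sample.int(K)
  pos <- 1L
  B <- min(cfg$batch_size, K)
  loss_trace <- numeric(cfg$iterations)
  for (t in seq_len(cfg$iterations)) {
    if (pos + B - 1L > K) { perm <- sample.int(K); pos <- 1L }
    idx <- perm[pos:(pos + B - 1L)]
    pos <- pos + B
    Xb <- inputs[, idx, drop = FALSE]
    Yb <- labels[, idx, drop = FALSE]
    A <- W1 %*% Xb + b1
    H <- A * (A > 0)
    P <- W2 %*% H + b2
    D <- P - Yb
    loss_trace[t] <- sum(D * D) / B
    if (!is.finite(loss_trace[t]))
      stop("SGD diverged: non-finite loss at iteration ", t,
           " (reduce lr0 or init_scale)")
    dP <- 2 * D / B
    gW2 <- tcrossprod(dP, H)
    gb2 <- rowSums(dP)
    dA <- crossprod(W2, dP) * (A > 0)
    gW1 <- tcrossprod(dA, Xb)
    gb1 <- rowSums(dA)
    lr <- cfg$lr0 * (1 + cfg$decay_gamma * t)^(-cfg$decay_power)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 scaling = scaling,
                 dims = c(n_inp = n_inp, n_hid = nh, n_out = n_out),
                 config = cfg, loss_trace = loss_trace),
            class = "ann_model")
}

#' Forward pass of the patch ANN
#'
#' beta = W2 ReLU(W1 x + b1) + b2 applied column-wise.
#'
#' @param model an \code{\link{ann_model}}.
#' @param x scaled input vector (length n_inp) or matrix (n_inp x n).
#' @return Output matrix (n_out x n) or vector.
#' @export
ann_forward <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) != model$dims[["n_inp"]])
    stop_badarg("input length ", nrow(x), " does not match model input size ",
                model$dims[["n_inp"]])
  A <- model$W1 %*% x + model$b1
  out <- model$W2 %*% (A * (A > 0)) + model$b2
  if (ncol(out) == 1L) drop(out) else out
}

#' Train a patch denoiser from one reduced/full-count frame pair
#'
#' The full training pipeline: normalizes the reduced-count frame by its
#' global maximum (and, by default, the full-count frame by the same shared
#' constant, which preserves the scale of the identity mapping between dose
#' levels), extracts all patch pairs, performs variance-ranked selection,
#' fits the row scaling and runs SGD.
#'
#' @param low 3D reduced-count training frame.
#' @param full co-located 3D full-count frame.
#' @param cfg a \code{\link{train_config}}.
#' @param label_norm \code{"shared"} divides the label image by the input
#'   image's maximum; \code{"own"} uses the label image's own maximum.
#' @return A trained \code{\link{ann_model}} (its scaling record carries the
#'   normalization constant).
#' @export
train_patch_denoiser <- function(low, full, cfg = train_config(),
                                 label_norm = c("shared", "own")) {
  label_norm <- match.arg(label_norm)
  gm <- max(low)
  if (gm <= 0) stop_badarg("training frame has no positive voxels")
  um <- if (label_norm == "shared") gm else max(full)
  pairs <- extract_patch_pairs(low / gm, full / um)
  pairs <- select_training_patches(pairs, cfg)
  sc <- fit_row_scaling(pairs)
  sc$scaling$global_max <- gm
  train_ann(sc$inputs, sc$labels, cfg, scaling = sc$scaling)
}

#' Denoise a single 3D frame with the cascade patch ANN
#'
#' One pass: the frame is normalized by its own global maximum and
#' replicate-padded by one voxel; for every 4x4x4 patch origin the input
#' vector is formed (mean removal, then row scaling with the *training*
#' input extrema — values may fall outside [-1, 1]; no clipping), pushed
#' through the network, inverse-scaled with the *training* label extrema,
#' the testing patch's mean added back, and the 2x2x2 output accumulated at
#' its location.  Each voxel is divided by its coverage count (8 in the
#' interior), the pad is discarded and the frame is un-normalized.  The
#' result feeds the next pass.
#'
#' @param model a trained \code{\link{ann_model}} with a scaling record.
#' @param z 3D frame.
#' @param passes number of cascade applications (>= 0; 0 returns the input).
#' @return Denoised 3D array of the same shape.
#' @export
denoise_frame <- function(model, z, passes = 3) {
  if (passes < 0) stop_badarg("passes must be nonnegative")
  if (is.null(model$scaling))
    stop_badarg("model carries no scaling record; train with",
                " train_patch_denoiser()")
  sc <- model$scaling
  for (p in seq_len(passes)) {
    gm <- max(z)
    if (gm <= 0) return(z)  # all-zero (or nonpositive) frame: no-op
    zp <- pad_replicate3(z / gm, 1L)
    d <- dim(zp)
    g <- .patch_geometry(d)
    x <- .gather_patches(zp, g$origins, g$input_off)
    mu <- colMeans(x)
    x <- sweep(x, 2L, mu)
    xs <- scale_rows(x, sc$input_row_min, sc$input_row_max)
    ys <- ann_forward(model, xs)
    y <- unscale_rows(as.matrix(ys), sc$label_row_min, sc$label_row_max)
    y <- sweep(y, 2L, mu, `+`)
    acc <- array(0, d)
    cnt <- array(0, d)
    for (r in seq_along(g$label_off)) {
      idx <- g$origins + g$label_off[r]
      acc[idx] <- acc[idx] + y[r, ]
      cnt[idx] <- cnt[idx] + 1
    }
    covered <- cnt > 0
    acc[covered] <- acc[covered] / cnt[covered]
    z <- acc[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] * gm
  }
  z
}

#' Denoise every frame of a dynamic series
#'
#' Applies \code{\link{denoise_frame}} independently to each frame; the
#' schedule is preserved.
#'
#' @param model a trained \code{\link{ann_model}}.
#' @param dyn a \code{\link{dynamic_image}}.
#' @param passes cascade applications per frame (default 3).
#' @return A \code{\link{dynamic_image}}.
#' @export
denoise_series <- function(model, dyn, passes = 3) {
  map_frames(dyn, function(fr, i) denoise_frame(model, fr, passes))
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Patch ANN denoiser: %d -> %d (ReLU) -> %d\n",
              x$dims[["n_inp"]], x$dims[["n_hid"]], x$dims[["n_out"]]))
  if (length(x$loss_trace))
    cat(sprintf("  trained %d SGD iterations; final batch loss %.4g\n",
                length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  if (!is.null(x$scaling) && is.finite(x$scaling$global_max))
    cat(sprintf("  training-image normalization constant: %.4g Bq/mL\n",
                x$scaling$global_max))
  invisible(x)
}

#' @export
#' @importFrom graphics plot lines
plot.ann_model <- function(x, window = 1000, ...) {
  l <- x$loss_trace
  plot(l, type = "l", col = "grey70", log = "y",
       xlab = "SGD iteration", ylab = "batch loss", ...)
  if (length(l) > window)
    lines(stats::filter(l, rep(1 / window, window)), col = "red3", lwd = 2)
  invisible(x)
}

#' Predict method: denoise a frame or dynamic series
#'
#' @param object a trained \code{\link{ann_model}}.
#' @param newdata a 3D array or a \code{\link{dynamic_image}}.
#' @param passes cascade applications (default 3).
#' @param ... unused.
#' @return Denoised object of the same kind as \code{newdata}.
#' @export
predict.ann_model <- function(object, newdata, passes = 3, ...) {
  if (inherits(newdata, "dynamic_image"))
    denoise_series(object, newdata, passes)
  else denoise_frame(object, newdata, passes)
}

#' Serialize / restore a trained model as JSON
#'
#' The file holds dims, weights, offsets, the scaling record and an echo of
#' the training configuration at full double precision, so the round-trip is
#' lossless.
#'
#' @param model an \code{\link{ann_model}}.
#' @param path file path.
#' @return \code{read_ann_model} returns the restored \code{ann_model};
#'   \code{write_ann_model} returns \code{path} invisibly.
#' @export
write_ann_model <- function(model, path) {
  # weights and scaling go through %.17g strings: JSON double emitters round
  # at ~15 significant digits, while 17 round-trip IEEE doubles exactly
  num <- function(x) sprintf("%.17g", as.vector(x))
  payload <- list(
    dims = as.list(model$dims),
    W1 = num(model$W1), b1 = num(model$b1),
    W2 = num(model$W2), b2 = num(model$b2),
    scaling = if (!is.null(model$scaling)) lapply(
      unclass(model$scaling), num),
    config = unclass(model$config),
    loss_trace = model$loss_trace)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- unlist(p$dims)
  sc <- p$scaling
  if (!is.null(sc)) {
    sc <- lapply(sc, as.numeric)
    class(sc) <- "scaling_record"
  }
  cfg <- p$config
  if (!is.null(cfg)) class(cfg) <- "train_config"
  structure(list(
    W1 = matrix(as.numeric(p$W1), dims[["n_hid"]], dims[["n_inp"]]),
    b1 = as.numeric(p$b1),
    W2 = matrix(as.numeric(p$W2), dims[["n_out"]], dims[["n_hid"]]),
    b2 = as.numeric(p$b2),
    scaling = sc, dims = dims, config = cfg,
    loss_trace = as.numeric(p$loss_trace)),
    class = "ann_model")
}
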