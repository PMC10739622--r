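# Independent brute-force oracles: literal loop implementations of each
# operation, kept deliberately naive and separate from the package internals.

clamp <- function(i, lo, hi) pmin(pmax(i, lo), hi)

# Mean over the size^3 window with replicate (edge-clamp) padding: border
# voxels are counted as many times as the padding replicates them.
oracle_box_filter <- function(vol, size) {
  r <- (size - 1) / 2
  d <- dim(vol)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    s <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
      s <- s + vol[clamp(x + dx, 1, d[1]), clamp(y + dy, 1, d[2]),
                   clamp(z + dz, 1, d[3])]
    out[x, y, z] <- s / size^3
  }
  out
}

# Literal three-step HYPR: composite, filtered ratio, multiply.
oracle_hypr <- function(dyn, size) {
  dt <- durations(dyn$schedule)
  nf <- dim(dyn)[4]
  comp <- array(0, dim(dyn)[1:3])
  for (i in 1:nf) comp <- comp + dt[i] * get_frame(dyn, i)
  comp <- comp / sum(dt)
  fc <- oracle_box_filter(comp, size)
  eps <- 1e-9 * max(abs(comp))
  out <- dyn$frames
  for (i in 1:nf) {
    w <- oracle_box_filter(get_frame(dyn, i), size) / fc
    w[abs(fc) < eps] <- 1
    out[, , , i] <- comp * w
  }
  dynamic_image(out, dyn$schedule, dyn$voxel_size)
}

# Naive two-layer forward pass with explicit loops.
oracle_forward <- function(W1, b1, W2, b2, x) {
  h <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1))) {
    a <- b1[i]
    for (j in seq_along(x)) a <- a + W1[i, j] * x[j]
    h[i] <- max(a, 0)
  }
  out <- numeric(nrow(W2))
  for (i in seq_len(nrow(W2))) {
    a <- b2[i]
    for (j in seq_along(h)) a <- a + W2[i, j] * h[j]
    out[i] <- a
  }
  out
}

# Per-voxel loop implementation of one cascade pass of the patch denoiser:
# normalize by the global max, replicate-pad by 1, run every 4x4x4 patch
# through the network, reassemble the central 2x2x2 outputs by coverage
# averaging, crop and un-normalize.
oracle_denoise_pass <- function(model, z) {
  sc <- model$scaling
  gm <- max(z)
  d0 <- dim(z)
  zp <- array(0, d0 + 2)
  for (x in 1:(d0[1] + 2)) for (y in 1:(d0[2] + 2)) for (w in 1:(d0[3] + 2))
    zp[x, y, w] <- z[clamp(x - 1, 1, d0[1]), clamp(y - 1, 1, d0[2]),
                     clamp(w - 1, 1, d0[3])] / gm
  d <- dim(zp)
  acc <- array(0, d); cnt <- array(0, d)
  for (ox in 1:(d[1] - 3)) for (oy in 1:(d[2] - 3)) for (oz in 1:(d[3] - 3)) {
    patch <- zp[ox:(ox + 3), oy:(oy + 3), oz:(oz + 3)]
    v <- as.vector(patch)           # x fastest, then y, then z
    mu <- mean(v)
    v <- v - mu
    den <- sc$input_row_max - sc$input_row_min
    vs <- ifelse(den == 0, 0, 2 * (v - sc$input_row_min) / den - 1)
    o <- oracle_forward(model$W1, model$b1, model$W2, model$b2, vs)
    ldn <- sc$label_row_max - sc$label_row_min
    o <- ifelse(ldn == 0, sc$label_row_min,
                (o + 1) / 2 * ldn + sc$label_row_min) + mu
    k <- 0
    for (dz in 1:2) for (dy in 1:2) for (dx in 1:2) {
      k <- k + 1
      xx <- ox + dx; yy <- oy + dy; zz <- oz + dz
      acc[xx, yy, zz] <- acc[xx, yy, zz] + o[k]
      cnt[xx, yy, zz] <- cnt[xx, yy, zz] + 1
    }
  }
  out <- acc / pmax(cnt, 1)
  out[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] * gm
}

# Quadruple-loop 4D non-local means (centered, clamped temporal window),
# with the same per-frame bandwidth convention as the package: h is supplied
# per frame by the caller.
oracle_nlm <- function(arr, search_sp, search_tm, nb_sp, nb_tm, h) {
  d <- dim(arr)
  rs <- (search_sp - 1) / 2; rt <- (search_tm - 1) / 2
  qs <- (nb_sp - 1) / 2; qt <- (nb_tm - 1) / 2
  out <- array(0, d)
  nb <- function(x, y, z, t) {
    v <- numeric(0)
    for (dt in -qt:qt) for (dz in -qs:qs) for (dy in -qs:qs)
      for (dx in -qs:qs)
        v <- c(v, arr[clamp(x + dx, 1, d[1]), clamp(y + dy, 1, d[2]),
                      clamp(z + dz, 1, d[3]), clamp(t + dt, 1, d[4])])
    v
  }
  for (t in 1:d[4]) for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    ws <- 0; vs <- 0
    n0 <- nb(x, y, z, t)
    for (ct in clamp(t - rt, 1, d[4]):clamp(t + rt, 1, d[4]))
      for (cz in max(1, z - rs):min(d[3], z + rs))
        for (cy in max(1, y - rs):min(d[2], y + rs))
          for (cx in max(1, x - rs):min(d[1], x + rs)) {
            d2 <- mean((n0 - nb(cx, cy, cz, ct))^2)
            w <- if (h[t] > 0) exp(-d2 / h[t]^2) else as.numeric(d2 <= 0)
            ws <- ws + w
            vs <- vs + w * arr[cx, cy, cz, ct]
          }
    out[x, y, z, t] <- vs / ws
  }
  out
}

# Direct-formula EnNSD on an explicit value table (voxels x realizations).
oracle_ennsd <- function(vals) {
  J <- ncol(vals)
  cv <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    mu <- mean(vals[i, ])
    s <- sqrt(sum((vals[i, ] - mu)^2) / (J - 1))
    cv[i] <- s / mu
  }
  mean(cv) * 100
}
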