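#' Arterial input function container
#'
#' Plasma tracer concentration Cp(t) on a fine uniform time grid.  The grid
#' must start at 0 and is used both to drive the phantom simulation and to
#' build the kinetic basis functions.
#'
#' @param time numeric vector of times in minutes, uniform grid starting at 0.
#' @param cp nonnegative plasma activity in Bq/mL, same length as \code{time}.
#' @return An object of class \code{input_function}.
#' @export
input_function <- function(time, cp) {
  if (length(time) != length(cp) || length(time) < 2L)
    stop_badarg("time and cp must be equal length >= 2")
  if (abs(time[1]) > 1e-12) stop_badarg("time grid must start at 0")
  step <- diff(time)
  if (any(abs(step - step[1]) > 1e-9)) stop_badarg("time grid must be uniform")
  if (any(cp < 0)) stop_badarg("cp must be nonnegative")
  structure(list(time = as.double(time), cp = as.double(cp),
                 step = step[1]), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "Input function: %d samples, 0-%.1f min (step %.4g min), peak %.4g Bq/mL\n",
    length(x$time), max(x$time), x$step, max(x$cp)))
  invisible(x)
}

#' Tri-exponential arterial input function with a linear rise
#'
#' Generates a plasma curve of the Feng form
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' clipped at zero, on a uniform grid covering [0, \code{t_max}] min.  The
#' first decay rate defaults to \code{1/peak_time} so the bolus peak lands
#' near \code{peak_time}.  This is a synthetic stand-in for a measured,
#' metabolite-corrected arterial curve.
#'
#' @param peak_time approximate time of the bolus peak in minutes.
#' @param amplitudes length-3 vector (A1, A2, A3); A1 in Bq/mL/min, A2 and A3
#'   in Bq/mL.
#' @param decay_rates length-3 vector of distinct positive rates (1/min).
#' @param grid_step grid step in minutes (default 1 s).
#' @param t_max end of the grid in minutes.
#' @return An \code{\link{input_function}}.
#' @examples
#' aif <- feng_aif()
#' aif$time[which.max(aif$cp)]
#' @export
feng_aif <- function(peak_time = 0.5,
                     amplitudes = c(6000, 350, 250),
                     decay_rates = c(1 / peak_time, 0.35, 0.012),
                     grid_step = 1 / 60, t_max = 60) {
  if (length(amplitudes) != 3L || length(decay_rates) != 3L)
    stop_badarg("amplitudes and decay_rates must have length 3")
  if (any(decay_rates <= 0)) stop_badarg("decay_rates must be positive")
  if (min(dist(decay_rates)) < 1e-8)
    stop_badarg("decay_rates must be distinct (closed form degenerates)")
  if (grid_step <= 0) stop_badarg("grid_step must be positive")
  t <- seq(0, t_max, by = grid_step)
  a <- amplitudes; l <- decay_rates
  cp <- (a[1] * t - a[2] - a[3]) * exp(-l[1] * t) +
    a[2] * exp(-l[2] * t) + a[3] * exp(-l[3] * t)
  input_function(t, pmax(cp, 0))
}

#' Tissue time-activity curve under the one-tissue compartment model
#'
#' Computes the frame-averaged tissue concentration
#' \deqn{C_T(t) = K_1 \, (C_p \otimes e^{-k_2 t})}
#' where the convolution is evaluated on the input function's fine grid by
#' trapezoidal quadrature (recursively, so the cost is linear in grid length)
#' and each frame value is the exact time-average of the gridded curve over
#' the frame.
#'
#' @param K1 plasma-to-tissue uptake rate, mL cm^-3 min^-1.
#' @param k2 washout rate, min^-1 (> 0).
#' @param aif an \code{\link{input_function}} covering the schedule.
#' @param schedule a \code{\link{frame_schedule}}.
#' @return Numeric vector of per-frame activity (Bq/mL).
#' @export
tissue_tac <- function(K1, k2, aif, schedule) {
  if (k2 <= 0) stop_badarg("k2 must be positive")
  K1 * frame_average(convolve_exp(aif, k2), aif, schedule)
}

# Cp (x) exp(-k2 t) on the fine grid, trapezoidal, vectorized over k2.
# Returns a length(time) x length(k2) matrix.
convolve_exp <- function(aif, k2) {
  dt <- aif$step
  cp <- aif$cp
  n <- length(cp)
  nk <- length(k2)
  e <- exp(-k2 * dt)
  out <- matrix(0, n, nk)
  prev <- numeric(nk)
  for (i in 2:n) {
    prev <- prev * e + dt / 2 * (cp[i - 1] * e + cp[i])
    out[i, ] <- prev
  }
  out
}

# Exact trapezoidal time-average of gridded curves over each frame.
# `curve` is a vector or a grid x k matrix on the aif grid.
frame_average <- function(curve, aif, schedule) {
  curve <- as.matrix(curve)
  t_end <- schedule$frame_end[length(schedule)]
  if (max(aif$time) < t_end - 1e-9)
    stop_badarg("schedule extends beyond the input function support")
  dt <- aif$step
  i_start <- round(schedule$frame_start / dt) + 1L
  i_end <- round(schedule$frame_end / dt) + 1L
  if (any(abs(schedule$frame_start / dt - (i_start - 1L)) > 1e-6) ||
      any(abs(schedule$frame_end / dt - (i_end - 1L)) > 1e-6))
    stop_badarg("aif grid step must divide every frame boundary")
  out <- matrix(0, length(schedule), ncol(curve))
  for (f in seq_len(length(schedule))) {
    idx <- i_start[f]:i_end[f]
    w <- rep(1, length(idx)); w[1] <- 0.5; w[length(idx)] <- 0.5
    out[f, ] <- crossprod(w, curve[idx, , drop = FALSE]) / (length(idx) - 1L)
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Read / write an input function as a two-column CSV
#'
#' Columns are \code{time_min} and \code{cp_Bq_per_mL}.
#'
#' @param aif an \code{\link{input_function}}.
#' @param path file path.
#' @return \code{read_aif} returns an \code{\link{input_function}};
#'   \code{write_aif} returns \code{path} invisibly.
#' @export
write_aif <- function(aif, path) {
  write.csv(data.frame(time_min = aif$time, cp_Bq_per_mL = aif$cp),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_min", "cp_Bq_per_mL") %in% names(d)))
    stop_badarg("AIF file ", path,
                " must have columns time_min, cp_Bq_per_mL")
  input_function(d$time_min, d$cp_Bq_per_mL)
}
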