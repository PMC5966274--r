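# Evaluation grid and circular convolution machinery.
#
# All response distributions are evaluated on a regular grid of direction
# bins covering (-180, 180]. The default spacing of 0.5 degrees (720 points)
# places every design angle, and 0 and 180, exactly on a grid point, so
# rotations by design angles are integer index shifts and circular
# convolutions can use the FFT.

#' Angle evaluation grid
#'
#' @param step Grid spacing in degrees; must divide 360. Default 0.5.
#' @return List with `points` (grid centers in (-180, 180], ascending),
#'   `step`, `n`, and `disp` (the displacement grid used for convolution
#'   kernels).
#' @export
angle_grid <- function(step = 0.5) {
  n <- 360 / step
  if (abs(n - round(n)) > 1e-9) stop("step must divide 360")
  n <- as.integer(round(n))
  pts <- seq(-180 + step, 180, by = step)
  list(points = pts, step = step, n = n,
       disp = wrap_angle((seq_len(n) - 1) * step))
}

# circular convolution of a density vector with a kernel given by its FFT;
# kernel is indexed on the displacement grid. Returns a density vector.
circ_conv_fft <- function(a, kernel_fft, step) {
  Re(stats::fft(stats::fft(a) * kernel_fft, inverse = TRUE)) / length(a) * step
}

# as above for a complex-valued vector (used for resultant-vector means)
circ_conv_fft_c <- function(a, kernel_fft, step) {
  stats::fft(stats::fft(a) * kernel_fft, inverse = TRUE) / length(a) * step
}

# re-index a kernel defined on the displacement grid (index 1 <-> 0 deg)
# as a density on the point grid (index j <-> j*step - 180), centered at
# `center` (which must lie on the grid): integer circular index shift
rotate_kernel <- function(kernel, center, grid) {
  sh <- as.integer(round((center + 180) / grid$step))
  kernel[((seq_len(grid$n) - sh) %% grid$n) + 1L]
}

# linear interpolation of a grid function at arbitrary angles, circularly
grid_interp <- function(values, theta, grid) {
  pos <- (wrap_angle(theta) - grid$points[1]) / grid$step
  i0 <- floor(pos)
  fr <- pos - i0
  i1 <- (as.integer(i0) %% grid$n) + 1L
  i2 <- ((as.integer(i0) + 1L) %% grid$n) + 1L
  values[i1] * (1 - fr) + values[i2] * fr
}

# interpolation indices/weights, precomputed once per data set for speed
grid_interp_index <- function(theta, grid) {
  pos <- (wrap_angle(theta) - grid$points[1]) / grid$step
  i0 <- floor(pos)
  fr <- pos - i0
  list(i1 = (as.integer(i0) %% grid$n) + 1L,
       i2 = ((as.integer(i0) + 1L) %% grid$n) + 1L,
       w = fr)
}
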