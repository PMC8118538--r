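# shared fixtures, built in code

default_window <- function() heating_window(10, 90)

# a small noiseless truth + series pair used across files
tiny_truth <- function(params = eq1_params(0.05, 8, 20),
                       grid = c(2L, 24L, 24L), times = 0:119) {
  simulate_temperature_field(phantom_spec(grid = grid), params,
                             default_window(), times)
}

# exactly-zero background: block hotspot in an otherwise zero image
block_series <- function(ndyn = 40, traj = seq(0, 3, length.out = 40)) {
  dT <- array(0, c(ndyn, 1, 16, 16))
  for (t in seq_len(ndyn)) dT[t, 1, 7:9, 7:9] <- traj[t]
  temperature_series(dT, seq_len(ndyn) - 1, c(0.8, 0.8))
}

block_mask <- function() {
  m <- array(TRUE, c(1, 16, 16))
  m[1, 5:11, 5:11] <- FALSE
  m
}

# independent sort-based quantile oracle (linear interpolation convention)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
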