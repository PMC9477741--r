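# Fixture builders shared across test files. All fixtures are constructed in
# code; no data files.

# straight constant-velocity track along +x
straight_track <- function(n = 5, v = 1, dt = 1, id = "straight") {
  track(id, data.frame(t = (0:(n - 1)) * dt, x = (0:(n - 1)) * v * dt, y = 0),
        frame_interval = dt)
}

stationary_track <- function(n = 5, id = "still") {
  track(id, data.frame(t = 0:(n - 1), x = 0, y = 0), frame_interval = 1)
}

# random 2D walk track with per-axis step s.d. sigma
rw_track <- function(n = 20, sigma = 1, dt = 1, id = "rw") {
  track(id, data.frame(t = (0:(n - 1)) * dt,
                       x = cumsum(c(0, rnorm(n - 1, 0, sigma))),
                       y = cumsum(c(0, rnorm(n - 1, 0, sigma)))),
        frame_interval = dt)
}

# apply a rigid motion (rotation by angle + translation) to all positions
rigid_transform <- function(ts, angle = 0, shift = c(0, 0)) {
  ts$tracks <- lapply(ts$tracks, function(tr) {
    x <- tr$points$x; y <- tr$points$y
    tr$points$x <- cos(angle) * x - sin(angle) * y + shift[1]
    tr$points$y <- sin(angle) * x + cos(angle) * y + shift[2]
    tr
  })
  ts
}

# exhaustive MSD oracle: scalar loop over all overlapping index pairs
brute_force_msd <- function(tr, max_lag_fraction = 0.5) {
  p <- tr$points
  N <- nrow(p)
  has_z <- "z" %in% names(p)
  nmax <- floor(max_lag_fraction * (N - 1))
  out <- data.frame(lag = numeric(0), msd = numeric(0), n_intervals = integer(0))
  for (n in seq_len(nmax)) {
    d2 <- numeric(0)
    for (i in seq_len(N - n)) {
      dx <- p$x[i + n] - p$x[i]
      dy <- p$y[i + n] - p$y[i]
      v <- dx * dx + dy * dy
      if (has_z) {
        dz <- p$z[i + n] - p$z[i]
        v <- v + dz * dz
      }
      d2 <- c(d2, v)
    }
    out <- rbind(out, data.frame(lag = n * tr$frame_interval, msd = mean(d2),
                                 n_intervals = length(d2)))
  }
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(a, b)
  us <- apply(idx, 2L, function(k) u_of(pooled[k], pooled[-k]))
  mu <- na * (length(b)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

fast_cfg <- function(n = 50, seed = 1, ...) sim_config(n_tracks = n, seed = seed, ...)
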