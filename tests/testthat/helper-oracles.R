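# Shared fixtures and independent oracles for the test suite.

# A small, fast colony configuration (structure identical to the default
# study conditions, scaled down).
small_config <- function(...) {
  sim_config(n_birds = c(autumn = 2, spring = 3),
             n_east = c(autumn = 1, spring = 1),
             deployment_days = c(1L, 2L),
             n_sets = c(autumn = 20, spring = 15), ...)
}

# Naive sum-of-Gaussians KDE oracle (plain double loop).
naive_kde <- function(points, H, xs, ys) {
  Hinv <- solve(H)
  dH <- det(H)
  n <- nrow(points)
  z <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs)) {
    for (j in seq_along(ys)) {
      s <- 0
      for (k in seq_len(n)) {
        v <- c(xs[i] - points[k, 1], ys[j] - points[k, 2])
        s <- s + exp(-0.5 * drop(t(v) %*% Hinv %*% v))
      }
      z[i, j] <- s / (n * 2 * pi * sqrt(dH))
    }
  }
  z
}

# Naive cross-PCF oracle for a rectangular window: independent loop
# implementation of both edge corrections at the same discretisation
# parameters as the estimator under test.
naive_pcf_rect <- function(Pi, Pj, xlim, ylim, r, bw, n_angles) {
  a <- diff(xlim); b <- diff(ylim)
  area <- a * b
  lam_i <- nrow(Pi) / area
  lam_j <- nrow(Pj) / area
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  epan <- function(u) ifelse(abs(u) <= bw, 0.75 * (1 - (u / bw)^2) / bw, 0)
  g_iso <- g_tr <- numeric(length(r))
  for (k in seq_along(r)) {
    s_iso <- s_tr <- 0
    for (i in seq_len(nrow(Pi))) {
      for (j in seq_len(nrow(Pj))) {
        dx <- Pj[j, 1] - Pi[i, 1]; dy <- Pj[j, 2] - Pi[i, 2]
        d <- sqrt(dx^2 + dy^2)
        if (d < 1e-9) next
        kv <- epan(r[k] - d)
        if (kv == 0) next
        px <- Pi[i, 1] + d * cos(th); py <- Pi[i, 2] + d * sin(th)
        frac <- mean(px >= xlim[1] & px <= xlim[2] & py >= ylim[1] & py <= ylim[2])
        s_iso <- s_iso + kv / max(frac, 1 / n_angles)
        ov <- max(a - abs(dx), 0) * max(b - abs(dy), 0)
        s_tr <- s_tr + kv * area / max(ov, 1e-12)
      }
    }
    denom <- 2 * pi * r[k] * lam_i * lam_j * area
    g_iso[k] <- s_iso / denom
    g_tr[k] <- s_tr / denom
  }
  list(g_iso = g_iso, g_trans = g_tr)
}

# Build a depth trace with dives planted at known sample positions.
plant_dives <- function(total_s, dives, noise_sd = 0) {
  depth <- if (noise_sd > 0) pmax(rnorm(total_s, 0, noise_sd), -0.5) else rep(0, total_s)
  for (i in seq_len(nrow(dives))) {
    idx <- dives$start[i]:(dives$start[i] + dives$len[i] - 1L)
    prof <- forageoverlap:::dive_profile(dives$len[i], dives$depth[i])
    depth[idx] <- prof
  }
  depth
}
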