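# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths (and where possible the library
# calls) they are used to check.

# Welch statistics from the defining formulas.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Hedges' g from the defining formulas.
oracle_hedges <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  d * (1 - 3 / (4 * (n1 + n2) - 9))
}

# Step-up BH / BY from first principles (no p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- cm * p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Linear-interpolation quantile (type 7) written out directly.
oracle_quantile7 <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Tukey fences on the oracle quantiles.
oracle_iqr_fences <- function(x, k = 1.5) {
  q <- oracle_quantile7(x, c(0.25, 0.75))
  c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
}

# Exact one-sided Kendall p by exhaustive permutation (n <= 8).
oracle_kendall_p <- function(x, y) {
  n <- length(y)
  stopifnot(n <= 8)
  tau_stat <- function(a, b) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
    s
  }
  obs <- tau_stat(x, y)
  perms <- gtools_permutations(n)
  stats_all <- apply(perms, 1, function(idx) tau_stat(x, y[idx]))
  mean(stats_all >= obs)
}

# All permutations of 1..n (small n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1
  for (i in 1:n) {
    rest <- setdiff(1:n, i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1
    }
  }
  out
}

# (1, 2, 1)/4 convolution with renormalized endpoints.
oracle_smooth121 <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- c(1, 2, 1)
    idx <- (i - 1):(i + 1)
    ok <- idx >= 1 & idx <= n
    out[i] <- sum(w[ok] * x[idx[ok]]) / sum(w[ok])
  }
  out
}

# Pixel count of clump_size tangent discs by direct double loop.
oracle_disc_area <- function(width, height, x, y, r, clump_size = 1) {
  count <- 0L
  for (px in 0:(width - 1)) for (py in 0:(height - 1)) {
    for (k in seq_len(clump_size) - 1) {
      if ((px - (x + 2 * r * k))^2 + (py - y)^2 <= r^2) {
        count <- count + 1L
        break
      }
    }
  }
  count
}

# Shared fixture: a well-separated synthetic scene plus its spec.
make_test_scene <- function(n_cells = 12, intensity = 700, background = 100,
                            noise_sd = 5, seed = 42, width = 512,
                            height = 512, radius = 10, clump_sizes = 1L) {
  pos <- place_cells(n_cells, width, height, radius = radius,
                     clump_sizes = clump_sizes, seed = seed)
  pos$intensity <- intensity
  spec <- scene_spec(width, height, pos, background = background,
                     noise_sd = noise_sd, seed = seed)
  render_scene(spec)
}

# Shared fixture: replicate-resolved noisy series from a known rhythm.
make_test_series <- function(id = "s", amplitude = 2, period = 24, phase = 0,
                             equilibrium = 10, noise_sd = 0.2, seed = 1,
                             start = 16, interval = 4, span = 24,
                             replicates = 3) {
  tr <- ground_truth_rhythm(amplitude, 0, period, phase, equilibrium,
                            noise_sd = noise_sd)
  des <- experiment_design(start, interval, span, replicates, seed = seed)
  simulate_rhythm_series(tr, des, id = id, seed = seed)
}
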