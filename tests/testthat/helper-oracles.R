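# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized code paths.

# Scalar even-odd crossing test for a single point, written as the
# textbook loop (no shared code with even_odd_inside()).
oracle_point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, height, width) {
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) for (c in seq_len(width))
    m[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, vertices)
  m
}

# Per-pixel double-loop TIC oracle.
oracle_tic_means <- function(frames, mask) {
  T_ <- dim(frames)[3]
  out <- numeric(T_)
  for (k in seq_len(T_)) {
    s <- 0; n <- 0
    for (r in seq_len(dim(frames)[1])) for (c in seq_len(dim(frames)[2])) {
      if (mask[r, c]) { s <- s + frames[r, c, k]; n <- n + 1 }
    }
    out[k] <- s / n
  }
  out
}

# Brute-force formula evaluations for the test statistics.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

oracle_anova_f <- function(groups) {
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  k <- length(groups); N <- length(all_x)
  (ssb / (k - 1)) / (ssw / (N - k))
}

oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Random simple polygon: jittered equally-spaced angles around a center
# keep every angular gap below pi, so consecutive chords cannot cross.
random_star_polygon <- function(nv, cx, cy, rmin, rmax) {
  s <- 2 * pi / nv
  ang <- (seq_len(nv) - 1) * s + runif(nv, 0, 0.9 * s)
  rad <- runif(nv, rmin, rmax)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# Small random cine loop with valid timestamps.
random_cine <- function(h, w, t) {
  cine_loop(array(runif(h * w * t, 0, 255), dim = c(h, w, t)),
            timestamps = seq(0, by = 0.25, length.out = t))
}
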