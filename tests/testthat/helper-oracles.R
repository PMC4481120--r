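# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: rotations are solved with Horn's
# quaternion eigen-decomposition (not SVD), GPA by a separately written
# alternating minimization with random restarts, ANOVA and Pearson
# statistics from raw sums.

# Horn's closed-form absolute orientation: proper rotation R (row-vector
# convention, A %*% R ~ B) maximizing the alignment of centered A with B.
oracle_rotation <- function(A, B) {
  S <- t(A) %*% B
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4L, 4L, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R_col <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3L, 3L, byrow = TRUE)
  t(R_col)
}

# Alternating minimization GPA with random restarts; returns the smallest
# total Procrustes distance (sum of squared residuals to the unit mean).
oracle_gpa_ss <- function(configs, restarts = 4L, iters = 500L, tol = 1e-14) {
  unitize <- function(X) {
    X <- sweep(X, 2L, colMeans(X))
    X / sqrt(sum(X^2))
  }
  U <- lapply(configs, unitize)
  best <- Inf
  for (r in seq_len(restarts)) {
    mean_shape <- if (r == 1L) U[[1L]] else
      unitize(U[[sample.int(length(U), 1L)]] %*% oracle_rand_rotation())
    for (it in seq_len(iters)) {
      rot <- lapply(U, function(x) x %*% oracle_rotation(x, mean_shape))
      avg <- Reduce(`+`, rot) / length(rot)
      avg <- sweep(avg, 2L, colMeans(avg))
      new_mean <- avg / sqrt(sum(avg^2))
      if (sqrt(mean((new_mean - mean_shape)^2)) < tol) {
        mean_shape <- new_mean
        break
      }
      mean_shape <- new_mean
    }
    rot <- lapply(U, function(x) x %*% oracle_rotation(x, mean_shape))
    ss <- sum(vapply(rot, function(x) sum((x - mean_shape)^2), numeric(1)))
    best <- min(best, ss)
  }
  best
}

# Random proper rotation via Rodrigues' formula (axis-angle), independent of
# the package's QR-based sampler.
oracle_rand_rotation <- function() {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1L, 0, 2 * pi)
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

# One-way ANOVA components from raw sums of squares.
oracle_anova <- function(group, value) {
  group <- as.character(group)
  gm <- tapply(value, group, mean)
  n_i <- tapply(value, group, length)
  grand <- mean(value)
  a <- length(gm)
  N <- length(value)
  ss_among <- sum(n_i * (gm[names(n_i)] - grand)^2)
  ss_within <- sum((value - gm[group])^2)
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (N - a)
  k0 <- if (length(unique(n_i)) == 1L) unname(n_i[1]) else
    (N - sum(n_i^2) / N) / (a - 1)
  s2A <- (ms_among - ms_within) / k0
  s2A_c <- max(s2A, 0)
  r <- if (s2A_c + ms_within == 0) 0 else s2A_c / (s2A_c + ms_within)
  list(ms_among = ms_among, ms_within = ms_within, s2 = ms_within,
       s2_A = s2A_c, s2_A_raw = s2A, k0 = k0, r = r)
}

# Pearson r, t and two-sided p from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, df = df, t = t, p = p)
}

# Apply a similarity transform (row-vector convention).
apply_similarity <- function(X, R, s = 1, tr = c(0, 0, 0)) {
  s * X %*% R + matrix(tr, nrow(X), 3L, byrow = TRUE)
}

# Well-spread random configuration in a 10 mm box.
rand_config <- function(K) matrix(stats::runif(K * 3L, 0, 10), K, 3L)
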