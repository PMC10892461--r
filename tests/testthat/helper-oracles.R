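# Independent oracles and small fixture builders. Everything here is kept
# algorithmically disjoint from the package code paths it checks.

# brute-force Savitzky-Golay oracle: fit a quadratic by least squares in
# each centered window and read off 2 * (quadratic coefficient)
sg_d2_oracle <- function(grid, y, window, polyorder = 2) {
  half <- (window - 1) %/% 2
  n <- length(grid)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    x <- grid[idx] - grid[i]
    fit <- lm.fit(outer(x, 0:polyorder, "^"), y[idx])
    out[i] <- 2 * fit$coefficients[3]
  }
  out[(half + 1):(n - half)]
}

# dense summation oracle for the synchronous map
sync_oracle <- function(A, B) {
  m <- nrow(A)
  out <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A)))
    for (j in seq_len(ncol(B)))
      out[i, j] <- sum(A[, i] * B[, j]) / (m - 1)
  out
}

# explicit Hilbert-Noda-matrix oracle for the asynchronous map
async_oracle <- function(A, B) {
  m <- nrow(A)
  N <- matrix(0, m, m)
  for (j in seq_len(m))
    for (k in seq_len(m))
      if (j != k) N[j, k] <- 1 / (pi * (k - j))
  out <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A)))
    for (j in seq_len(ncol(B)))
      out[i, j] <- sum(A[, i] * (N %*% B[, j])) / (m - 1)
  out
}

# Krylov-subspace PLS1 oracle: the a-component PLS1 regression vector is
# the least-squares minimizer over the Krylov space K_a(X'X, X'y) of the
# centered data (conjugate-gradient equivalence) — an algorithmically
# disjoint route to the same coefficients as NIPALS
krylov_pls1_coef <- function(X, y, a) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), a)
  v <- s
  for (k in seq_len(a)) {
    K[, k] <- v
    v <- crossprod(Xc, Xc %*% v)
  }
  Q <- qr.Q(qr(K))
  g <- qr.solve(Xc %*% Q, yc)
  as.numeric(Q %*% g)
}

# brute-force run scanner for |r| >= tau band segmentation
threshold_runs_oracle <- function(r, tau) {
  sel <- !is.na(r) & abs(r) >= tau
  runs <- list()
  i <- 1
  while (i <= length(sel)) {
    if (sel[i]) {
      j <- i
      while (j < length(sel) && sel[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind.data.frame,
          lapply(runs, function(x) data.frame(start = x[1], end = x[2])))
}

# small hand-built spectra set on an arbitrary grid
toy_set <- function(m, kind = "absorbance", n_levels = nrow(m),
                    n_reps = 1L, grid = NULL, state = "dry",
                    casein = NULL, nitrate = NULL) {
  n <- nrow(m)
  if (is.null(grid)) grid <- seq(4000, by = 6, length.out = ncol(m))
  lev <- rep(seq_len(n_levels), each = n_reps)[seq_len(n)]
  rep_id <- as.integer(ave(lev, lev, FUN = seq_along))
  if (is.null(casein)) casein <- seq_len(n_levels) / 10
  if (is.null(nitrate)) nitrate <- rev(seq_len(n_levels)) / 20
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    level_id = lev, replicate_id = rep_id, state = state,
    casein_conc = casein[lev], nitrate_conc = nitrate[lev],
    water_content = NA_real_)
  spectra_set(grid, m, samples, kind)
}

# quick second-derivative set from a tiny noise-free synthetic design
tiny_d2_set <- function(n_levels = 5, n_reps = 2, seed = 42,
                        state = "dry", noise_sd = 0, ...) {
  d <- design_spec(n_levels = n_levels, n_replicates = n_reps,
                   state = state, noise_sd = noise_sd, scatter_sd = 0,
                   baseline_sd = 0, cellulose_sd = 0, water_jitter_sd = 0,
                   seed = seed, ...)
  gen <- generate_nir_set(d)
  list(d2 = restrict_region(second_derivative(to_absorbance(gen$set), 11, 2),
                            4000, 7500),
       truth = gen$truth, design = d)
}
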