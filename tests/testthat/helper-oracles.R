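# Independent reference implementations used to verify package results.

# Affine-gap global alignment score by explicit Gotoh dynamic programming.
# Gap of length k costs open + (k - 1) * extend. O(nm), small inputs only.
gotoh_score <- function(a, b, match = 1, mismatch = -1, open = -3,
                        extend = -0.5) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes x)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes y)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- open + (i - 1L) * extend
  for (j in seq_len(m)) Iy[1L, j + 1L] <- open + (j - 1L) * extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + open, Ix[i, j + 1L] + extend,
                                Iy[i, j + 1L] + open)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + open, Iy[i + 1L, j] + extend,
                                Ix[i + 1L, j] + open)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

# Naive quadratic perfect-tract finder: for every start, extend while the
# unit sequence repeats, keep only maximal runs.
naive_tracts <- function(units) {
  n <- length(units)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && units[j + 1L] == units[i]) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(
      variant_sequence = units[i], start_index = i - 1L,
      run_length = j - i + 1L, stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# Brute-force two-sample KS statistic: evaluate both ECDFs on the pooled
# support and take the largest absolute difference.
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), 0)
  Fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(Fx - Fy))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_unit_array <- function(n_units, alphabet_size = 4L) {
  pool <- vapply(seq_len(alphabet_size), function(i) random_dna(30L), "")
  sample(pool, n_units, replace = TRUE)
}

small_sim_config <- function(seed = 1L, ...) {
  cp <- default_class_params()
  cp$S$length_median_bp <- 1500; cp$S$length_sd_bp <- 300
  cp$L$length_median_bp <- 3600; cp$L$length_sd_bp <- 600
  sim_config(seed = seed, class_params = cp, min_length_bp = 600, ...)
}
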