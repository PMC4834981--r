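# Independent brute-force oracles. These re-derive each quantity from its
# definition by direct enumeration, sharing no code with the package
# internals they check.

# O(N^2) double-loop pair counting for sample entropy.
brute_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m                      # templates whose extensions exist
  A <- 0; B <- 0
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, value = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# Per-segment recomputation of coarse-graining, one segment at a time.
brute_coarse <- function(x, tau, moment) {
  nseg <- length(x) %/% tau
  vapply(seq_len(nseg), function(k) {
    seg <- x[((k - 1L) * tau + 1L):(k * tau)]
    switch(moment,
      mean = mean(seg),
      variance = if (tau == 1L) NA_real_ else sum((seg - mean(seg))^2) / (tau - 1))
  }, numeric(1L))
}

# Direct per-index application of the moving-window artifact criterion
# (truncated edge windows, >= (l-1)/2 neighbours required).
brute_filter_excluded <- function(x, l, a) {
  n <- length(x); h <- (l - 1L) %/% 2L
  out <- integer(0)
  for (i in seq_len(n)) {
    w <- setdiff(max(1L, i - h):min(n, i + h), i)
    if (length(w) < h) next
    m <- mean(x[w])
    if (x[i] < (1 - a) * m || x[i] > (1 + a) * m) out <- c(out, i)
  }
  out
}

# Write a series to a temp file, one value per line.
write_tmp_series <- function(values, digits = 15L) {
  path <- tempfile(fileext = ".txt")
  writeLines(sprintf(paste0("%.", digits, "g"), values), path)
  path
}
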