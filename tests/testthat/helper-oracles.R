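# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# brute-force DTW: enumerate every monotone warping path on the grid
dtw_brute_force <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible(NULL)) # prune, exact for nonneg costs
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
  }
  walk(1L, 1L, 0)
  best
}

# reference frequency response of a rational digital filter
freq_gain <- function(b, a, f, fs) {
  z <- exp(2i * pi * f / fs)
  Mod(sum(b * z^(-(seq_along(b) - 1))) / sum(a * z^(-(seq_along(a) - 1))))
}
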