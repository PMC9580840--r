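# Independent brute-force oracles and small fixture builders.

# Direct left-to-right scan for interior extrema: for every maximal run of
# equal values not touching either end, classify by the flanking values and
# report the run's central index (ties toward the smaller index).
oracle_extrema <- function(v) {
  n <- length(v)
  pos <- integer(0); kind <- character(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (i > 1L && j < n) {
      if (v[i - 1L] < v[i] && v[j + 1L] < v[i]) {
        pos <- c(pos, (i + j) %/% 2L); kind <- c(kind, "peak")
      } else if (v[i - 1L] > v[i] && v[j + 1L] > v[i]) {
        pos <- c(pos, (i + j) %/% 2L); kind <- c(kind, "valley")
      }
    }
    i <- j + 1L
  }
  list(position = pos, kind = kind)
}

# Exhaustive subset scan: size of the largest subset of values lying within
# epsilon of the subset's own mean.
oracle_level_members <- function(values, epsilon) {
  n <- length(values)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) <= best) next
    m <- mean(values[sel])
    if (all(abs(values[sel] - m) <= epsilon)) best <- length(sel)
  }
  best
}

# Closed-form simple least squares of y on x (textbook sums formulae),
# independent of lm().
oracle_slope_intercept <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# Random protein string over the 20 standard residues.
random_protein <- function(n) {
  paste(sample(hydrolevels:::AA_CODES, n, replace = TRUE), collapse = "")
}

# Build a profile-like numeric vector whose peaks are exactly `heights` at
# well-separated positions, on a baseline of 0.
planted_profile <- function(heights, gap = 4L) {
  out <- numeric(0)
  for (h in heights) out <- c(out, rep(0, gap), h)
  c(out, rep(0, gap))
}

write_toy_fasta <- function(path, entries) {
  lines <- unlist(lapply(names(entries), function(h)
    c(paste0(">", h), entries[[h]])))
  writeLines(lines, path)
  path
}
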