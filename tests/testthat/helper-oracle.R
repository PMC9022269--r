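# Independent pure-R oracles used to cross-check the package's own
# implementations. These deliberately use naive full-matrix dynamic
# programming / closed-form arithmetic, not the package's code paths.

# brute-force affine-gap local alignment score (gap of length L costs
# open + L * extend; N is always a mismatch)
sw_score_oracle <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# closed-form simple linear regression via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(
    slope = slope, intercept = mean(y) - slope * mean(x),
    r = r, p = 2 * stats::pt(-abs(tstat), n - 2)
  )
}

# pooled-SD all-pairs t-tests + Benjamini-Hochberg step-up, by hand
pairwise_oracle <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  ns <- lengths(gs)
  N <- sum(ns)
  sp2 <- sum((ns - 1) * vapply(gs, stats::var, numeric(1))) / (N - k)
  combos <- utils::combn(names(gs), 2)
  p_raw <- apply(combos, 2, function(pair) {
    a <- gs[[pair[1]]]
    b <- gs[[pair[2]]]
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    2 * stats::pt(-abs(tstat), N - k)
  })
  m <- length(p_raw)
  ord <- order(p_raw)
  adj <- p_raw[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  p_adj <- numeric(m)
  p_adj[ord] <- adj
  data.frame(
    a = combos[1, ], b = combos[2, ], p_raw = p_raw, p_adj = p_adj,
    stringsAsFactors = FALSE
  )
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# a related sequence pair: a random sequence and a substitution/indel
# perturbed copy, for aligner property tests
perturbed_pair <- function(max_len = 60) {
  n <- sample(10:max_len, 1)
  a <- random_seq(n)
  b <- mutate_sequence(a, substitution_rate = 0.1, indel_rate = 0.05)
  list(a = a, b = b)
}

# build y with an exact Pearson correlation r against x
exact_cor_y <- function(x, r, scale_to = c(1.5, 3.7)) {
  z <- seq_along(x)^2 # anything not collinear with x
  ex <- stats::resid(stats::lm(z ~ x))
  xs <- (x - mean(x)) / stats::sd(x)
  es <- ex / stats::sd(ex)
  y <- r * xs + sqrt(1 - r^2) * es
  # affine rescale into a plausible monomer-count range (cor-invariant)
  scale_to[1] + (y - min(y)) / (max(y) - min(y)) * diff(scale_to)
}
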