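# Independent reference implementations used as oracles.  They are kept
# deliberately naive (explicit loops, stats::lm for every fit) so they share
# no code path with the vectorized package internals.

naive_integrate <- function(px) {
  M <- nrow(px)
  N <- ncol(px)
  cmeans <- colMeans(px)
  rmeans <- rowMeans(px)
  y <- matrix(0, M, N)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      y[m, n] <- sum(px[seq_len(m), n] - cmeans[n]) + sum(px[m, seq_len(n)] - rmeans[m])
    }
  }
  y
}

# Per-segment plane fit with lm(), mean squared residual averaged over all
# segments, square root: the fluctuation function computed the slow way.
naive_fluctuation <- function(px, s) {
  y <- naive_integrate(px)
  Ms <- nrow(px) %/% s
  Ns <- ncol(px) %/% s
  E <- numeric(0)
  for (k in seq_len(Ms)) {
    for (l in seq_len(Ns)) {
      seg <- y[(k - 1) * s + seq_len(s), (l - 1) * s + seq_len(s)]
      d <- data.frame(z = as.vector(seg),
                      o = rep(seq_len(s), times = s),
                      p = rep(seq_len(s), each = s))
      E <- c(E, mean(resid(lm(z ~ o + p, data = d))^2))
    }
  }
  sqrt(mean(E))
}

# 1D counterpart: disjoint windows, lm() line per window.
naive_fluctuation_1d <- function(x, n) {
  y <- cumsum(x - mean(x))
  K <- length(y) %/% n
  ss <- 0
  for (k in seq_len(K)) {
    w <- y[(k - 1) * n + seq_len(n)]
    ss <- ss + sum(resid(lm(w ~ seq_len(n)))^2)
  }
  sqrt(ss / (n * K))
}

# Textbook one-way ANOVA F from the sum-of-squares decomposition.
naive_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  G <- length(unique(groups))
  (ss_between / (G - 1)) / (ss_within / (length(values) - G))
}

rand_image <- function(M, N, seed) {
  set.seed(seed)
  matrix(sample(0:255, M * N, replace = TRUE), M, N)
}

# alpha1 shortcut used by synthetic-image tests
alpha1_of <- function(img) {
  gray <- to_grayscale(img)
  fit_scaling_exponent(fluctuation_curve(gray, 4:11), 4, 11)$estimate
}
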