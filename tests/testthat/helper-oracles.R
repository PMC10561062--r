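# Independent straight-line oracles, kept deliberately naive and separate
# from the package implementations they check.

# Biweight midcorrelation from its defining formula: median/raw-MAD
# standardization, Tukey biweights, normalized cross product.
bicor_oracle <- function(x, y) {
  mx <- median(x); my <- median(y)
  madx <- median(abs(x - mx)); mady <- median(abs(y - my))
  ux <- (x - mx) / (9 * madx); uy <- (y - my) / (9 * mady)
  ax <- ifelse(abs(ux) < 1, (1 - ux^2)^2, 0)
  ay <- ifelse(abs(uy) < 1, (1 - uy^2)^2, 0)
  xt <- (x - mx) * ax; yt <- (y - my) * ay
  sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2)))
}

# Midranks by explicit position averaging (no call to rank()).
midranks_oracle <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Tie-corrected Kruskal-Wallis H by hand.
kw_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  R <- midranks_oracle(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(seq_len(N), groups, function(idx) {
      length(idx) * (mean(R[idx]) - (N + 1) / 2)^2
    }))
  tie_sizes <- table(values)
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  H / C
}

# Welch two-sample t statistic and p-value in closed form.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
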