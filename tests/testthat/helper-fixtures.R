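# Shared fixtures: tiny spectra, echo trains and phantoms built in code.

single_peak_spectrum <- function(ppm = 0) fat_spectrum(ppm, 1)

# The six-echo bipolar train used throughout (TE1 1.43 ms, dTE 1.1 ms, 3 T).
acq6 <- function() default_acq()

# A small default-geometry phantom for segmentation tests.
small_phantom_spec <- function(seed = 11, snr = Inf, ...) {
  phantom_spec(grid_shape = c(32, 32, 24), snr = snr, seed = seed, ...)
}

# Independent statistics oracles -------------------------------------------

# All permutations of 1..n (plain recursion; n <= 7 in tests).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Kruskal-Wallis H via stats::kruskal.test (reference implementation).
kw_H_reference <- function(values, groups) {
  unname(suppressWarnings(kruskal.test(values, factor(groups))$statistic))
}

# Exhaustive permutation p-value for Kruskal-Wallis: permute the values over
# the fixed group layout and count statistics at least as large.
kw_perm_oracle <- function(values, groups) {
  n <- length(values)
  P <- all_perms(n)
  ranks <- rank(values)
  g <- as.integer(factor(groups))
  n_i <- tabulate(g)
  tie <- table(values)
  C <- 1 - sum(tie^3 - tie) / (n^3 - n)
  H_of <- function(r) {
    R <- rowsum(r, g)
    H0 <- 12 / (n * (n + 1)) * sum(R^2 / n_i) - 3 * (n + 1)
    if (C <= 0) 0 else H0 / C
  }
  H_obs <- H_of(ranks)
  Hs <- apply(P, 1, function(ix) H_of(ranks[ix]))
  mean(Hs >= H_obs - 1e-12)
}

# Exhaustive two-sided rank-sum p-value by permuting group membership.
ranksum_perm_oracle <- function(v1, v2) {
  n1 <- length(v1); n <- n1 + length(v2)
  r <- rank(c(v1, v2))
  P <- all_perms(n)
  E <- n1 * mean(r)
  W_obs <- sum(r[seq_len(n1)])
  Ws <- apply(P, 1, function(ix) sum(r[ix][seq_len(n1)]))
  mean(abs(Ws - E) >= abs(W_obs - E) - 1e-12)
}
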