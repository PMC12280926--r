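# Shared fixtures built in code.

# A noiseless plan generating the reference-coefficient linear structure.
noiseless_plan <- function(seed = 1, n = 13)
  synth_plan(seed = seed, n_species = n, noise_sd = 0, ratio_noise_sd = 0)

# Independent normal-equations OLS oracle (pseudo-inverse, no lm).
ols_oracle <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(t(xm) %*% xm, t(xm) %*% y))
}

# Independent one-way ANOVA oracle from raw sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- sum(vapply(split(values, groups), function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(split(values, groups), function(g)
    sum((g - mean(g))^2), numeric(1)))
  k <- length(unique(groups)); n <- length(values)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  list(F = msb / msw, df1 = k - 1, df2 = n - k)
}

# All permutations of seq_len(n) (tiny n only).
all_perms <- function(n) {
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  perm(seq_len(n))
}

# Moran's I under a row-normalized weight matrix (independent of the
# package's internal implementation).
moran_oracle <- function(x, a) {
  w <- a / rowSums(a)
  x <- x - mean(x)
  sum(x * (w %*% x)) / sum(x^2)
}

# Hand-derived Abouheif proximity for the 4-taxon tree ((A,B),(C,D)):
# sister pairs share one bifurcating ancestor (1/2); cross pairs pass
# through three bifurcations (1/8).
abouheif_a4 <- function() {
  a <- matrix(1 / 8, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                           c("A", "B", "C", "D")))
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1 / 2
  diag(a) <- 0
  a
}
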