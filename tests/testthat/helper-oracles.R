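# Independent brute-force oracles used to check the implementation paths.

# Harrell's C by exhaustive pairwise enumeration (double loop).
cindex_oracle <- function(times, events, risks) {
  conc <- 0
  comp <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (events[i] == 1 && times[i] < times[j]) {
        comp <- comp + 1
        if (risks[i] > risks[j]) conc <- conc + 1
        else if (risks[i] == risks[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# Optimal contiguous k-partition of 1-D values by exhaustive search over cut
# points (optimal 1-D k-means clusters are contiguous in sorted order).
contiguous_partition_oracle <- function(values, k = 3L) {
  v <- sort(values)
  n <- length(v)
  stopifnot(n >= k)
  wcss <- function(x) sum((x - mean(x))^2)
  best <- list(ss = Inf, groups = NULL)
  cuts <- utils::combn(n - 1L, k - 1L)
  for (c_i in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, c_i], n)
    groups <- lapply(seq_len(k), function(g) v[(bounds[g] + 1L):bounds[g + 1L]])
    ss <- sum(vapply(groups, wcss, numeric(1L)))
    if (ss < best$ss) best <- list(ss = ss, groups = groups)
  }
  best
}

# Simple proportional-hazards simulator (exponential baseline, uniform
# administrative censoring).
simulate_ph_data <- function(n, beta, base_rate = 0.05, cens = c(10, 60),
                             p = length(beta)) {
  x <- matrix(rnorm(n * p), ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  lp <- as.numeric(x %*% beta)
  t_true <- rexp(n, base_rate * exp(lp))
  cmax <- runif(n, cens[1L], cens[2L])
  list(x = x, time = pmin(t_true, cmax),
       event = as.integer(t_true <= cmax))
}

# Well-separated Gaussian classes in a handful of features.
simulate_separable_classes <- function(n, sep = 4) {
  cls <- sample.int(3L, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  mu <- rbind(c(0, 0, 0), c(sep, 0, sep / 2), c(0, sep, sep))
  x <- mu[cls, ] + matrix(rnorm(n * 3), ncol = 3)
  colnames(x) <- c("f1", "f2", "f3")
  list(x = x, y = factor(paste0("C", cls), levels = c("C1", "C2", "C3")))
}
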