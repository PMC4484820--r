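# Independent oracles, written against the definitions only; they never
# call package internals.

# log-factorial binomial tails by direct pmf summation
oracle_binom_pmf <- function(i, n, p) {
  exp(lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
        i * log(p) + (n - i) * log1p(-p))
}
oracle_binom_lower <- function(k, n, p) sum(oracle_binom_pmf(0:k, n, p))
oracle_binom_upper <- function(k, n, p) sum(oracle_binom_pmf(k:n, n, p))

# two-sided Fisher exact p by hypergeometric enumeration
# (probability-ordering rule)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  a_min <- max(0, c1 - r2); a_max <- min(c1, r1)
  a <- a_min:a_max
  logp <- lgamma(r1 + 1) - lgamma(a + 1) - lgamma(r1 - a + 1) +
    lgamma(r2 + 1) - lgamma(c1 - a + 1) - lgamma(r2 - c1 + a + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  p <- exp(logp)
  p_obs <- p[a == tab[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square (1 df, no correction) closed form
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  num / prod(rowSums(tab)) / prod(colSums(tab)) * 1 # keep double
}

oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# Exhaustive maximizer over every (feature, observed value, orientation)
# candidate, mirroring the documented selection policy: max kappa among
# candidates with oracle-Fisher p < alpha, both branches >= min_node,
# ties by smaller p, earlier feature, smaller threshold.
oracle_best_cutpoint <- function(data, features, alpha = 0.01,
                                 min_node = 2, outcome = "remitted") {
  rows <- list()
  for (fi in seq_along(features)) {
    f <- features[fi]
    x <- data[[f]]
    y <- as.logical(data[[outcome]])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    for (v in sort(unique(x))) {
      ge <- x >= v
      if (sum(ge) < min_node || sum(!ge) < min_node) next
      # branch x outcome, rows = (ge, lt), cols = (nonremit, remit)
      tab <- rbind(c(sum(ge & !y), sum(ge & y)),
                   c(sum(!ge & !y), sum(!ge & y)))
      k_ge <- oracle_kappa(tab)
      k_lt <- oracle_kappa(tab[2:1, ])
      kap <- max(k_ge, k_lt)
      if (kap <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, feature_idx = fi, threshold = v,
        direction = if (k_ge >= k_lt) "ge" else "lt",
        kappa = kap, p_value = oracle_fisher(tab)
      )
    }
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  cand <- cand[cand$p_value < alpha, ]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$kappa, cand$p_value, cand$feature_idx,
                     cand$threshold), ]
  cand[1, ]
}

random_toy_instance <- function() {
  n <- sample(8:30, 1)
  k <- sample(1:5, 1)
  d <- tibble::tibble(remitted = as.logical(rbinom(n, 1, 0.5)))
  for (j in seq_len(k)) {
    # small integer grid so ties between candidates are common
    d[[paste0("f", j)]] <- sample(1:6, n, replace = TRUE) +
      ifelse(d$remitted, sample(0:1, n, replace = TRUE), 0)
  }
  d
}
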