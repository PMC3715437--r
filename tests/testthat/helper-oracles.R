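# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force maximal-run scan over a logical countable vector: walks the
# vector position by position instead of using rle().
brute_runs <- function(countable, k) {
  runs <- list()
  i <- 1L
  n <- length(countable)
  while (i <= n) {
    if (countable[i]) {
      j <- i
      while (j < n && countable[j + 1L]) j <- j + 1L
      if (j - i + 1L >= k) {
        runs[[length(runs) + 1L]] <- c(start = i, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(runs)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  out <- as.data.frame(do.call(rbind, runs))
  out$length <- out$end - out$start + 1L
  out
}

# Exhaustive permutation enumeration of the Mann-Whitney U null
# distribution (tie-free inputs only).
ranksum_enum <- function(a, b, alternative) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_all <- apply(utils::combn(length(pooled), n1), 2,
                 function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two_sided = min(1, 2 * min(mean(u_all <= u_obs),
                                    mean(u_all >= u_obs))))
}

# Direct hypergeometric summation (log-space binomial coefficients) for
# the one-sided enrichment p-value, conditioning on the 2x2 margins of
# (k_g of n_g) vs (k_b of n_b).
hyper_enum <- function(k_g, n_g, k_b, n_b, alternative = "greater") {
  r1 <- k_g + k_b
  support <- max(0L, r1 - n_b):min(r1, n_g)
  logp <- lchoose(n_g, support) + lchoose(n_b, r1 - support) -
    lchoose(n_g + n_b, r1)
  p <- exp(logp)
  if (alternative == "greater") sum(p[support >= k_g])
  else sum(p[support <= k_g])
}

# A protein record of the given length with an all-'A' sequence.
toy_protein <- function(len, accession = "TOY", ...) {
  protein_record(accession, paste(rep("A", len), collapse = ""), ...)
}

# A disorder track with exactly `n_dis` scoring residues placed first.
toy_track <- function(len, n_dis, kind = "disorder") {
  score_track(c(rep(0.9, n_dis), rep(0.1, len - n_dis)), kind)
}

# A random binary mask with optional excluded stretches.
random_mask <- function(len, p_true = 0.5, p_excl = 0) {
  flags <- runif(len) < p_true
  excl <- runif(len) < p_excl
  structure(list(flags = flags, excluded = excl,
                 effective_length = sum(!excl)),
            class = "binary_mask")
}

extdata <- function(name) {
  system.file("extdata", name, package = "vtdisorder", mustWork = TRUE)
}
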