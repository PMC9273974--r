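# Independent oracles used across tests; kept deliberately naive.

# Benjamini-Hochberg step-up, written directly from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Check a compact-letter display against the defining property:
# two groups share a letter if and only if their pairwise P > alpha.
letters_consistent <- function(letters, pmat, alpha = 0.05) {
  g <- names(letters)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    shared <- length(intersect(strsplit(letters[i], "")[[1]],
                               strsplit(letters[j], "")[[1]])) > 0
    signif <- pmat[g[i], g[j]] <= alpha
    if (shared == signif) return(FALSE)
  }
  TRUE
}

# Brute-force minimal letter count: smallest number of letter sets such
# that every non-significant pair shares a set and no significant pair
# does. Enumerates all assignments for tiny problems.
brute_min_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  for (n_sets in 1:k) {
    # each group gets a non-empty subset of n_sets letters
    subsets <- lapply(1:(2^n_sets - 1), function(m) which(bitwAnd(m, 2^(0:(n_sets - 1))) > 0))
    idx <- rep(1, k)
    repeat {
      assign <- subsets[idx]
      ok <- TRUE
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i >= j || !ok) next
        shared <- length(intersect(assign[[i]], assign[[j]])) > 0
        if (shared == (pmat[i, j] <= alpha)) ok <- FALSE
      }
      if (ok) return(n_sets)
      pos <- 1
      while (pos <= k) {
        idx[pos] <- idx[pos] + 1
        if (idx[pos] <= length(subsets)) break
        idx[pos] <- 1; pos <- pos + 1
      }
      if (pos > k) break
    }
  }
  NA_integer_
}

# Tiny balanced dataset for inference tests: t treatments x f fermenters
# x d days, lognormal noise around per-treatment means.
make_balanced_data <- function(means, fermenters_per_trt = 4, days = 7:13,
                               cv_f = 0.03, cv_d = 0.05, seed = 1) {
  set.seed(seed)
  trts <- names(means)
  rows <- list()
  fid <- 0
  for (trt in trts) for (f in seq_len(fermenters_per_trt)) {
    fid <- fid + 1
    fmult <- exp(rnorm(1, 0, cv_f))
    run <- ifelse(f <= fermenters_per_trt / 2, "R1", "R2")
    block <- paste0(run, "B", 1 + fid %% 2)
    rows[[fid]] <- data.frame(
      treatment = trt, fermenter = sprintf("F%02d", fid), run = run,
      block = block, day = days,
      y = means[[trt]] * fmult * exp(rnorm(length(days), 0, cv_d)))
  }
  do.call(rbind, rows)
}
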