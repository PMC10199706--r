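# Independent reference implementations used as oracles. These are written
# from the defining formulas, deliberately avoiding the package's own code
# paths (loops and order statistics instead of vectorized ranks, explicit
# tail sums instead of distribution functions).

# Literal weighted-trimmed-mean-of-M-values factors. Reference sample:
# 75th-percentile CPM closest to the mean of those percentiles. Trims by
# order statistics on M and A; inverse-variance weights; geometric mean 1.
oracle_tmm <- function(mat, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(mat)
  p75 <- vapply(seq_len(ncol(mat)), function(s) {
    unname(quantile(mat[, s], 0.75)) / lib[s]
  }, numeric(1))
  ref <- which.min(abs(p75 - mean(p75)))
  f <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    obs <- mat[, s]
    rfc <- mat[, ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]
    rfc <- rfc[keep]
    m_val <- log2((obs / lib[s]) / (rfc / lib[ref]))
    a_val <- 0.5 * log2((obs / lib[s]) * (rfc / lib[ref]))
    v_val <- (lib[s] - obs) / (lib[s] * obs) +
      (lib[ref] - rfc) / (lib[ref] * rfc)
    ok <- is.finite(m_val) & is.finite(a_val) & a_val > -1e10
    m_val <- m_val[ok]; a_val <- a_val[ok]; v_val <- v_val[ok]
    if (length(m_val) == 0L || max(abs(m_val)) < 1e-6) {
      f[s] <- 1
      next
    }
    n <- length(m_val)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    # average rank computed from first principles (ties share their rank)
    avg_rank <- function(x) {
      vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2,
             numeric(1))
    }
    pos_m <- avg_rank(m_val)
    pos_a <- avg_rank(a_val)
    sel <- pos_m >= lo_m & pos_m <= hi_m & pos_a >= lo_a & pos_a <= hi_a
    num <- 0; den <- 0
    for (g in which(sel)) {
      num <- num + m_val[g] / v_val[g]
      den <- den + 1 / v_val[g]
    }
    f[s] <- if (den > 0 && is.finite(num / den)) 2^(num / den) else 1
  }
  f / exp(mean(log(f)))
}

# Exact upper-tail hypergeometric probability by direct tail summation:
# P(overlap >= k) with term size K, universe N, study size n.
oracle_hyper_tail <- function(k, K, N, n) {
  upper <- min(K, n)
  if (k > upper) return(0)
  total <- 0
  for (i in k:upper) {
    total <- total +
      exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }
  min(1, total)
}

# Naive full scan of a promoter with a PWM: every offset, both strands,
# character by character; N scores 0. Returns the best score.
oracle_pwm_scan <- function(sequence, pwm) {
  score_window <- function(chars, lo) {
    s <- 0
    for (p in seq_along(chars)) {
      row <- match(chars[p], c("A", "C", "G", "T"))
      s <- s + if (is.na(row)) 0 else lo[row, p]
    }
    s
  }
  rc <- function(chars) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    out <- rev(chars)
    ifelse(out %in% names(comp), comp[out], "N")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(pwm$log_odds)
  best <- -Inf
  for (off in seq_len(length(chars) - w + 1)) {
    win <- chars[off:(off + w - 1)]
    best <- max(best,
                score_window(win, pwm$log_odds),
                score_window(rc(win), pwm$log_odds))
  }
  best
}

# Literal Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[ord[i]] / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Textbook one-way fixed-effects F statistic.
oracle_f <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    x <- values[groups == lev]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Brute-force membership partition of named sets.
oracle_partition <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  out <- character(length(universe))
  names(out) <- as.character(universe)
  for (g in universe) {
    inside <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    out[as.character(g)] <- paste(inside, collapse = "+")
  }
  out
}
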