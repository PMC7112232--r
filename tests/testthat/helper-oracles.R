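# Independent brute-force oracles and small fixture constructors shared by
# the test files. These deliberately avoid the package's vectorised /
# compiled code paths: plain loops and direct formula evaluation only.

# bitset from positions of set bits
bitset <- function(on, n_bits = 16) {
  b <- rep(FALSE, n_bits)
  b[on] <- TRUE
  b
}

# literal confusion-count MCC, scalar
oracle_mcc_counts <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# class-proportion MCC, scalar
oracle_mcc_props <- function(tp, fp, tn, fn) {
  tpr <- tp / (tp + fn); fpr <- fp / (fp + tn)
  den <- (tpr + fpr) * (2 - tpr - fpr)
  if (den <= 0) return(0)
  (tpr - fpr) / sqrt(den)
}

# does molecule row x pass the filter given as (descriptor, lo, hi) rows?
oracle_pass <- function(x, ranges) {
  all(vapply(seq_len(nrow(ranges)), function(k) {
    v <- x[[ranges$descriptor[k]]]
    !is.na(v) && v >= ranges$lo[k] && v <= ranges$hi[k]
  }, logical(1)))
}

# exhaustive scan over all grid sub-ranges of one descriptor; returns the
# maximal single-range score under the given objective
oracle_best_range <- function(values, labels, n_divisions,
                              objective = oracle_mcc_props) {
  g <- seq(min(values), max(values), length.out = n_divisions)
  nA <- sum(labels); nI <- sum(!labels)
  best <- -2
  for (lo in seq_len(n_divisions - 1)) {
    for (hi in seq.int(lo + 1, n_divisions)) {
      inr <- values >= g[lo] & values <= g[hi]
      tp <- sum(inr & labels); fp <- sum(inr & !labels)
      m <- objective(tp, fp, nI - fp, nA - tp)
      if (m > best) best <- m
    }
  }
  best
}

# brute-force top filter score: every subset of pool rows of the given
# sizes, evaluated molecule by molecule
oracle_top_filter_mcc <- function(data, labels, pool, sizes,
                                  objective = oracle_mcc_props) {
  nA <- sum(labels); nI <- sum(!labels)
  best <- -2
  for (k in sizes[sizes <= nrow(pool)]) {
    combos <- utils::combn(nrow(pool), k)
    for (j in seq_len(ncol(combos))) {
      ranges <- pool[combos[, j], , drop = FALSE]
      pass <- vapply(seq_len(nrow(data)), function(i)
        oracle_pass(data[i, , drop = FALSE], ranges), logical(1))
      tp <- sum(pass & labels); fp <- sum(pass & !labels)
      m <- objective(tp, fp, nI - fp, nA - tp)
      if (m > best) best <- m
    }
  }
  best
}

# small labelled descriptor table with an easily separable planted signal
tiny_planted <- function(n_act = 12, n_inact = 80, n_desc = 6, seed = 42,
                         width = 0.3) {
  set.seed(seed)
  sig <- paste0("d", seq_len(min(4, n_desc)))
  X <- as.data.frame(matrix(runif(n_desc * (n_act + n_inact)),
                            ncol = n_desc))
  colnames(X) <- paste0("d", seq_len(n_desc))
  for (s in sig) X[seq_len(n_act), s] <- runif(n_act, 0.4, 0.4 + width)
  list(data = X, labels = rep(c(TRUE, FALSE), c(n_act, n_inact)),
       signal = sig)
}

skip_message_noise <- function(expr) suppressMessages(expr)
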