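# Iterative stochastic elimination (ISE): a classifier built as an ensemble of
# descriptor-range "filters" optimised by the Matthews correlation coefficient
# (MCC) and used to score molecules to a molecular bioactivity index (MBI).

#' Configuration for ISE model building
#'
#' Collects every tunable of the ISE procedure in one validated list.
#'
#' @param n_divisions Number of grid points used to discretise each
#'   descriptor's observed range. With \code{n} points there are
#'   \code{n * (n - 1) / 2} candidate sub-ranges (4950 for the default 100).
#' @param filter_sizes Integer vector of allowed filter sizes (number of
#'   descriptor ranges per filter); sizes are drawn uniformly when sampling.
#' @param sample_size Number of random filters scored per elimination
#'   iteration.
#' @param decile_fraction Fraction of the MCC-sorted sample treated as the
#'   "worst" and "best" tails when assessing range bias.
#' @param alpha,beta Elimination bias thresholds: a range is dropped when its
#'   worst-tail appearances exceed \code{alpha} times expectation while its
#'   best-tail appearances fall below \code{beta} times expectation.
#' @param min_expected Minimum expected tail appearances per range for an
#'   elimination round to be statistically meaningful; rounds below this are
#'   skipped with a warning.
#' @param exhaustive_threshold Once the number of remaining filter
#'   combinations falls below this, every combination is evaluated
#'   exhaustively.
#' @param mcc_fraction Keep-rule fraction: a filter is retained when its
#'   MCC is at least \code{mcc_fraction} times the top MCC \emph{or} it
#'   ranks within the top \code{max_filters} by MCC (either criterion
#'   suffices).
#' @param max_filters Rank cutoff of the keep rule's second criterion.
#' @param n_folds Number of cross-validation folds for
#'   \code{\link{build_model}}.
#' @param mcc_components How the MCC that ranks ranges and filters is
#'   computed from the confusion counts: \code{"proportions"} (default)
#'   normalises the counts by class size first (TPR/FPR/TNR/FNR), the
#'   robust choice when the two classes are very different in size --
#'   otherwise the optimum degenerates to low-recall micro-ranges on
#'   imbalanced sets; \code{"counts"} uses the raw counts (the literal
#'   \code{\link{mcc}} formula).
#' @param mbi_mode Either \code{"proportion"} (efficiency = TP/(TP+FP),
#'   inefficiency = TN/(TN+FN); MBI bounded in [-1, 1]) or \code{"raw"}
#'   (literal TP/FP and TN/FN with add-one smoothing of zero denominators;
#'   unbounded). See the package vignette for why proportion is the default.
#' @param max_iterations Abort bound on elimination iterations.
#' @param protect_descriptors If \code{TRUE}, a descriptor whose every pooled
#'   range would be eliminated retains its best range instead. Off by
#'   default: with the standard one-best-range-per-descriptor pool the
#'   procedure reduces the pool precisely by retiring descriptors.
#' @param similar_jaccard Interval-overlap Jaccard threshold above which two
#'   filters on the same descriptor set are considered duplicates when folds
#'   are merged.
#' @return A list of class \code{"ise_config"}.
#' @export
ise_config <- function(n_divisions = 100, filter_sizes = c(4L, 5L),
                       sample_size = 50000, decile_fraction = 0.10,
                       alpha = 2, beta = 0.5, min_expected = 5,
                       exhaustive_threshold = 1e6,
                       mcc_fraction = 0.8, max_filters = 1000,
                       mcc_components = c("proportions", "counts"),
                       n_folds = 5, mbi_mode = c("proportion", "raw"),
                       max_iterations = 50, protect_descriptors = FALSE,
                       similar_jaccard = 0.8) {
  mbi_mode <- match.arg(mbi_mode)
  mcc_components <- match.arg(mcc_components)
  stopifnot(n_divisions >= 2, all(filter_sizes >= 1), sample_size >= 1,
            decile_fraction > 0, decile_fraction < 0.5,
            alpha > 0, beta > 0, exhaustive_threshold > 0,
            mcc_fraction > 0, mcc_fraction <= 1, max_filters >= 1,
            n_folds >= 2, max_iterations >= 1,
            similar_jaccard >= 0, similar_jaccard <= 1)
  structure(list(n_divisions = as.integer(n_divisions),
                 filter_sizes = sort(unique(as.integer(filter_sizes))),
                 sample_size = as.integer(sample_size),
                 decile_fraction = decile_fraction, alpha = alpha,
                 beta = beta, min_expected = min_expected,
                 exhaustive_threshold = exhaustive_threshold,
                 mcc_fraction = mcc_fraction,
                 max_filters = as.integer(max_filters),
                 mcc_components = mcc_components,
                 n_folds = as.integer(n_folds), mbi_mode = mbi_mode,
                 max_iterations = as.integer(max_iterations),
                 protect_descriptors = protect_descriptors,
                 similar_jaccard = similar_jaccard),
            class = "ise_config")
}

#' Enumerate contiguous sub-ranges on a discretisation grid
#'
#' A descriptor's observed range is discretised with \code{n_divisions} grid
#' points; every pair of distinct grid points bounds one candidate closed
#' sub-range, giving \code{n (n - 1) / 2} ranges (4950 for 100 divisions).
#'
#' @param n_divisions Number of grid points (at least 2).
#' @return Data frame with integer columns \code{lo_idx}, \code{hi_idx}
#'   (1-based grid indices, \code{lo_idx < hi_idx}).
#' @examples
#' nrow(enumerate_subranges(100)) # 4950
#' @export
enumerate_subranges <- function(n_divisions) {
  n <- as.integer(n_divisions)
  if (is.na(n) || n < 2) stop("n_divisions must be an integer >= 2")
  lo <- rep(seq_len(n - 1), times = seq.int(n - 1, 1))
  hi <- unlist(lapply(seq_len(n - 1), function(l) seq.int(l + 1, n)))
  data.frame(lo_idx = lo, hi_idx = hi)
}

#' Size of the filter combination space
#'
#' Number of distinct filters (unordered descriptor subsets) that can be
#' formed from a pool, summed over the allowed filter sizes. For 180
#' descriptors and 5-range filters this is about 1.5e9.
#'
#' @param n_descriptors Pool size.
#' @param sizes Allowed filter sizes.
#' @return A double (counts overflow integers quickly).
#' @export
filter_space_size <- function(n_descriptors, sizes = c(4, 5)) {
  sum(choose(n_descriptors, sizes))
}

#' Matthews correlation coefficient from confusion counts
#'
#' \code{(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}, with the
#' conventional value 0 whenever a denominator factor vanishes. Vectorised.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Numeric in [-1, 1].
#' @export
mcc <- function(tp, fp, tn, fn) {
  if (any((tp + fp + tn + fn) == 0)) stop("all confusion counts are zero")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  num <- tp * tn - fp * fn
  out <- numeric(length(den))
  pos <- den > 0
  out[pos] <- num[pos] / sqrt(den[pos])
  out
}

#' Matthews correlation on class-normalised confusion proportions
#'
#' The confusion counts are first normalised by class size (TP and FN by
#' the number of actives, FP and TN by the number of inactives) and the
#' correlation is computed on those proportions; algebraically
#' \code{(TPR - FPR) / sqrt((TPR + FPR) (2 - TPR - FPR))}, with 0 when the
#' denominator vanishes. This variant weighs both classes equally and is
#' the default objective for ranking ranges and filters on strongly
#' imbalanced learning sets (see \code{\link{ise_config}}).
#'
#' @inheritParams mcc
#' @return Numeric in [-1, 1].
#' @export
mcc_proportions <- function(tp, fp, tn, fn) {
  nA <- tp + fn; nI <- fp + tn
  if (any(nA == 0) || any(nI == 0)) stop("both classes must be present")
  tpr <- tp / nA; fpr <- fp / nI
  den <- (tpr + fpr) * (2 - tpr - fpr)
  out <- numeric(length(den))
  pos <- den > 0
  out[pos] <- (tpr - fpr)[pos] / sqrt(den[pos])
  out
}

filter_mcc <- function(tp, fp, tn, fn, components) {
  if (components == "proportions") mcc_proportions(tp, fp, tn, fn)
  else mcc(tp, fp, tn, fn)
}

#' Evaluate one filter on a labelled descriptor table
#'
#' A molecule passes the filter iff every referenced descriptor value lies
#' inside the corresponding closed range. Actives that pass are TP, inactives
#' that pass FP, inactives that fail TN, actives that fail FN.
#'
#' @param filter List with elements \code{descriptors} (character),
#'   \code{lo}, \code{hi} (numeric, parallel to \code{descriptors}).
#' @param data Data frame or matrix of descriptor values (columns named).
#' @param labels Logical vector, \code{TRUE} for actives.
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn}, \code{mcc}.
#' @export
evaluate_filter <- function(filter, data, labels) {
  miss <- setdiff(filter$descriptors, colnames(data))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  labels <- as.logical(labels)
  pass <- rep(TRUE, nrow(data))
  for (k in seq_along(filter$descriptors)) {
    v <- data[, filter$descriptors[k]]
    pass <- pass & !is.na(v) & v >= filter$lo[k] & v <= filter$hi[k]
  }
  tp <- sum(pass & labels); fp <- sum(pass & !labels)
  fn <- sum(!pass & labels); tn <- sum(!pass & !labels)
  list(tp = tp, fp = fp, tn = tn, fn = fn, mcc = mcc(tp, fp, tn, fn))
}

#' Best single discriminating range of one descriptor
#'
#' Scans every contiguous sub-range of the descriptor's min-max grid (see
#' \code{\link{enumerate_subranges}}) and returns the one whose single-range
#' filter maximises MCC. Ties are broken towards the narrowest range, then
#' the lowest lower bound.
#'
#' @param values Numeric descriptor values.
#' @param labels Logical actives indicator (both classes must be present).
#' @param n_divisions Grid resolution.
#' @param mcc_components Ranking objective; see \code{\link{ise_config}}.
#' @return List with \code{ok}; when \code{ok} is \code{TRUE} also
#'   \code{lo}, \code{hi}, \code{lo_idx}, \code{hi_idx}, \code{mcc},
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn} and the \code{grid}.
#' @export
best_range_per_descriptor <- function(values, labels, n_divisions = 100,
                                      mcc_components = c("proportions",
                                                         "counts")) {
  mcc_components <- match.arg(mcc_components)
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (anyNA(values)) stop("NA descriptor values are not allowed here")
  rng <- range(values)
  if (rng[1] == rng[2])
    return(list(ok = FALSE, reason = "constant descriptor", mcc = 0))
  g <- seq(rng[1], rng[2], length.out = n_divisions)
  sub <- enumerate_subranges(n_divisions)

  count_prefix <- function(v) {
    sv <- sort(v)
    le <- findInterval(g, sv)                       # #{v <= g[k]}
    lt <- findInterval(g, sv, left.open = TRUE)     # #{v <  g[k]}
    list(le = le, lt = lt)
  }
  a <- count_prefix(values[labels])
  i <- count_prefix(values[!labels])
  nA <- sum(labels); nI <- sum(!labels)
  tp <- a$le[sub$hi_idx] - a$lt[sub$lo_idx]
  fp <- i$le[sub$hi_idx] - i$lt[sub$lo_idx]
  m <- filter_mcc(tp, fp, nI - fp, nA - tp, mcc_components)
  width <- sub$hi_idx - sub$lo_idx
  best <- order(-m, width, sub$lo_idx)[1]
  list(ok = TRUE, lo = g[sub$lo_idx[best]], hi = g[sub$hi_idx[best]],
       lo_idx = sub$lo_idx[best], hi_idx = sub$hi_idx[best],
       mcc = m[best], tp = tp[best], fp = fp[best],
       tn = nI - fp[best], fn = nA - tp[best], grid = g)
}

#' Build the range pool: one best range per usable descriptor
#'
#' @param data Descriptor table (numeric columns).
#' @param labels Logical actives indicator.
#' @param cfg An \code{\link{ise_config}}.
#' @return List with \code{pool} (data frame: descriptor, lo, hi, lo_idx,
#'   hi_idx, mcc) and \code{excluded} (character, constant descriptors).
#' @export
build_range_pool <- function(data, labels, cfg = ise_config()) {
  data <- as.data.frame(data)
  nm <- colnames(data)
  rows <- list(); excluded <- character()
  for (d in nm) {
    br <- best_range_per_descriptor(data[[d]], labels, cfg$n_divisions,
                                    cfg$mcc_components)
    if (!br$ok) { excluded <- c(excluded, d); next }
    rows[[d]] <- data.frame(descriptor = d, lo = br$lo, hi = br$hi,
                            lo_idx = br$lo_idx, hi_idx = br$hi_idx,
                            mcc = br$mcc, stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(pool = pool, excluded = excluded)
}

# Membership matrix: molecules x pool rows, closed-interval test.
pool_pass_matrix <- function(data, pool) {
  data <- as.data.frame(data)
  out <- matrix(FALSE, nrow(data), nrow(pool))
  for (j in seq_len(nrow(pool))) {
    v <- data[[pool$descriptor[j]]]
    out[, j] <- !is.na(v) & v >= pool$lo[j] & v <= pool$hi[j]
  }
  out
}

#' Sample random filters from a range pool
#'
#' Each filter's size is drawn uniformly from \code{sizes} and its ranges are
#' a uniform random subset of distinct pool entries. Uses R's RNG, so results
#' are reproducible under \code{set.seed}.
#'
#' @param pool_size Number of ranges in the pool.
#' @param sizes Allowed filter sizes.
#' @param count Number of filters to draw.
#' @return Integer matrix \code{count x max(sizes)} of 1-based pool indices,
#'   NA-padded for smaller sizes.
#' @export
sample_filters <- function(pool_size, sizes, count) {
  if (pool_size < max(sizes)) stop("pool too small for requested filter sizes")
  sizes <- as.integer(sizes)
  ks <- if (length(sizes) == 1L) rep(sizes, count) else
    sizes[sample.int(length(sizes), count, replace = TRUE)]
  out <- matrix(NA_integer_, count, max(sizes))
  for (r in seq_len(count)) out[r, seq_len(ks[r])] <- sample.int(pool_size, ks[r])
  out
}

# Evaluate many filters (rows of an index matrix) against pre-computed
# membership matrices; returns confusion counts and MCC per filter.
eval_filter_combos <- function(pass_active, pass_inactive, combos,
                               mcc_components = "proportions") {
  counts <- cpp_count_filter_passes(pass_active, pass_inactive, combos)
  tp <- counts[, 1]; fp <- counts[, 2]
  nA <- nrow(pass_active); nI <- nrow(pass_inactive)
  data.frame(tp = tp, fp = fp, tn = nI - fp, fn = nA - tp,
             mcc = filter_mcc(tp, fp, nI - fp, nA - tp, mcc_components))
}

#' Eliminate biased ranges from the pool after a sampling round
#'
#' Filters are sorted by MCC; a range is eliminated when it is
#' over-represented in the worst tail (more than \code{alpha} times its
#' expected appearances) and under-represented in the best tail (less than
#' \code{beta} times expected), where the expectation is the range's total
#' sample appearances times the tail fraction.
#'
#' @param combos Integer matrix of sampled filters (pool indices, NA-padded).
#' @param mccs Numeric vector of the filters' MCC values.
#' @param pool Range pool data frame.
#' @param cfg An \code{\link{ise_config}}.
#' @return List with \code{pool} (reduced), \code{eliminated} (character
#'   descriptor names), \code{skipped} (logical: round had too little
#'   evidence), and \code{log} (per-range appearance statistics).
#' @export
eliminate_ranges <- function(combos, mccs, pool, cfg = ise_config()) {
  p <- nrow(pool)
  n <- length(mccs)
  m <- max(1L, floor(cfg$decile_fraction * n))
  ord <- order(mccs)
  worst_rows <- ord[seq_len(m)]
  best_rows <- ord[seq.int(n - m + 1L, n)]
  total <- tabulate(combos[!is.na(combos)], nbins = p)
  wcnt <- tabulate(combos[worst_rows, ][!is.na(combos[worst_rows, ])], nbins = p)
  bcnt <- tabulate(combos[best_rows, ][!is.na(combos[best_rows, ])], nbins = p)
  expected <- total * cfg$decile_fraction
  log <- data.frame(descriptor = pool$descriptor, total = total,
                    worst = wcnt, best = bcnt, expected = expected)
  if (any(expected < cfg$min_expected)) {
    warning("elimination round skipped: expected tail appearances below ",
            cfg$min_expected, " for some ranges")
    return(list(pool = pool, eliminated = character(), skipped = TRUE,
                log = log))
  }
  drop <- wcnt > cfg$alpha * expected & bcnt < cfg$beta * expected
  if (cfg$protect_descriptors) {
    # keep a descriptor's best range alive when all its ranges would go
    for (d in unique(pool$descriptor[drop])) {
      rows_d <- which(pool$descriptor == d)
      if (all(drop[rows_d])) {
        keep <- rows_d[which.max(pool$mcc[rows_d])]
        drop[keep] <- FALSE
        message("descriptor '", d, "' retains its best range")
      }
    }
  }
  # never shrink below the largest filter size: among candidates, drop the
  # most worst-biased first and stop at the working minimum
  if (p - sum(drop) < max(cfg$filter_sizes)) {
    allowed <- p - max(cfg$filter_sizes)
    bias <- ifelse(expected > 0, wcnt / expected, 0)
    cand <- which(drop)
    cand <- cand[order(-bias[cand])]
    drop <- seq_len(p) %in% utils::head(cand, allowed)
  }
  list(pool = pool[!drop, , drop = FALSE],
       eliminated = pool$descriptor[drop], skipped = FALSE, log = log)
}

ise_keep_rule <- function(stats, cfg) {
  # A filter is kept when either criterion grants it: MCC within
  # mcc_fraction of the top, OR rank within the top max_filters by MCC.
  top <- max(stats$mcc)
  thr <- if (top > 0) cfg$mcc_fraction * top else top
  by_mcc <- stats$mcc >= thr
  ord <- order(-stats$mcc)
  by_rank <- seq_len(nrow(stats)) %in%
    ord[seq_len(min(cfg$max_filters, nrow(stats)))]
  by_mcc | by_rank
}

#' Run ISE on one training fold
#'
#' Builds the best-range pool, alternates stochastic sampling with biased
#' range elimination until the combination space is below
#' \code{exhaustive_threshold}, then enumerates and scores every remaining
#' filter and applies the keep rule (MCC within \code{mcc_fraction} of the
#' top, or ranked within the top \code{max_filters}).
#'
#' @param data Descriptor table for the training molecules.
#' @param labels Logical actives indicator.
#' @param cfg An \code{\link{ise_config}}.
#' @return An object of class \code{"ise_ensemble"}: a data frame with one
#'   row per kept filter (columns \code{size}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{mcc}) and a list column \code{ranges}
#'   (each element a data frame \code{descriptor, lo, hi}); attributes
#'   record the pool and elimination history.
#' @export
run_ise_fold <- function(data, labels, cfg = ise_config()) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("training set has no actives")
  if (all(labels)) stop("training set has no inactives")
  data <- as.data.frame(data)
  bp <- build_range_pool(data, labels, cfg)
  pool <- bp$pool
  if (is.null(pool) || nrow(pool) < max(cfg$filter_sizes))
    stop("usable descriptor pool smaller than the largest filter size")

  passA <- pool_pass_matrix(data[labels, , drop = FALSE], pool)
  passI <- pool_pass_matrix(data[!labels, , drop = FALSE], pool)
  history <- list()
  iter <- 0L
  while (filter_space_size(nrow(pool), cfg$filter_sizes) >=
         cfg$exhaustive_threshold) {
    iter <- iter + 1L
    if (iter > cfg$max_iterations)
      stop("ISE did not converge below the exhaustive threshold within ",
           cfg$max_iterations, " iterations (pool size ", nrow(pool), ")")
    combos <- sample_filters(nrow(pool), cfg$filter_sizes, cfg$sample_size)
    ev <- eval_filter_combos(passA, passI, combos, cfg$mcc_components)
    el <- eliminate_ranges(combos, ev$mcc, pool, cfg)
    history[[iter]] <- list(pool_size = nrow(pool),
                            eliminated = el$eliminated,
                            skipped = el$skipped)
    if (el$skipped || length(el$eliminated) == 0L) {
      if (el$skipped)
        stop("elimination stalled: sample too small for the pool; ",
             "increase sample_size")
      next
    }
    kept_cols <- which(!(paste(pool$descriptor, pool$lo, pool$hi) %in%
                           setdiff(paste(pool$descriptor, pool$lo, pool$hi),
                                   paste(el$pool$descriptor, el$pool$lo,
                                         el$pool$hi))))
    pool <- el$pool
    passA <- passA[, kept_cols, drop = FALSE]
    passI <- passI[, kept_cols, drop = FALSE]
  }

  # exhaustive finish
  sizes <- cfg$filter_sizes[cfg$filter_sizes <= nrow(pool)]
  all_stats <- list(); all_combos <- list()
  for (k in sizes) {
    combos_k <- cpp_combinations(nrow(pool), k)
    pad <- matrix(NA_integer_, nrow(combos_k), max(sizes) - k)
    combos_k_p <- cbind(combos_k, pad)
    ev <- eval_filter_combos(passA, passI, combos_k_p, cfg$mcc_components)
    ev$size <- k
    all_stats[[as.character(k)]] <- ev
    all_combos[[as.character(k)]] <- combos_k_p
  }
  stats <- do.call(rbind, all_stats)
  combos <- do.call(rbind, all_combos)
  keep <- ise_keep_rule(stats, cfg)
  stats <- stats[keep, , drop = FALSE]
  combos <- combos[keep, , drop = FALSE]
  ord <- order(-stats$mcc, apply(combos, 1, paste, collapse = ","))
  stats <- stats[ord, , drop = FALSE]
  combos <- combos[ord, , drop = FALSE]

  ranges <- lapply(seq_len(nrow(combos)), function(r) {
    idx <- combos[r, ]
    idx <- idx[!is.na(idx)]
    data.frame(descriptor = pool$descriptor[idx], lo = pool$lo[idx],
               hi = pool$hi[idx], stringsAsFactors = FALSE)
  })
  ens <- data.frame(size = stats$size, tp = stats$tp, fp = stats$fp,
                    tn = stats$tn, fn = stats$fn, mcc = stats$mcc)
  ens$ranges <- ranges
  rownames(ens) <- NULL
  structure(ens, class = c("ise_ensemble", "data.frame"),
            pool = pool, history = history)
}

# interval-overlap Jaccard of [a1,a2] and [b1,b2]; two identical points -> 1
interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  uni <- pmax(a2, b2) - pmin(a1, b1)
  ifelse(uni == 0, as.numeric(a1 == b1), inter / uni)
}

filters_similar <- function(r1, r2, jaccard_min) {
  if (nrow(r1) != nrow(r2)) return(FALSE)
  if (!setequal(r1$descriptor, r2$descriptor)) return(FALSE)
  m <- match(r1$descriptor, r2$descriptor)
  all(interval_jaccard(r1$lo, r1$hi, r2$lo[m], r2$hi[m]) >= jaccard_min)
}

#' Build a cross-validated ISE model
#'
#' Splits the learning set into \code{n_folds} stratified folds, runs
#' \code{\link{run_ise_fold}} on each training 4/5, scores the held-out 1/5
#' (so every molecule receives exactly one held-out MBI), merges the fold
#' ensembles with duplicate-similar filters removed (same descriptor set,
#' all range pairs with interval Jaccard at least \code{similar_jaccard};
#' the higher-MCC filter survives), re-orders by MCC and re-applies the keep
#' rule.
#'
#' @param data Descriptor table for the full learning set.
#' @param labels Logical actives indicator.
#' @param cfg An \code{\link{ise_config}}.
#' @param seed Integer seed controlling the split and all sampling.
#' @param ids Optional molecule identifiers (default row numbers).
#' @return Object of class \code{"ise_model"}: list with \code{filters}
#'   (merged \code{ise_ensemble}), \code{descriptors}, \code{config},
#'   \code{seed}, \code{folds} (fold id per molecule) and \code{holdout}
#'   (data frame \code{id, fold, label, mbi}).
#' @export
build_model <- function(data, labels, cfg = ise_config(), seed = 1,
                        ids = NULL) {
  labels <- as.logical(labels)
  data <- as.data.frame(data)
  if (anyNA(data))
    stop("NA descriptor values are fatal in model building")
  if (sum(labels) < cfg$n_folds)
    stop("need at least n_folds actives")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(data)))

  set.seed(as.integer(seed))
  assign_folds <- function(idx) {
    # shuffled round-robin keeps every fold within one molecule of parity
    f <- rep_len(seq_len(cfg$n_folds), length(idx))
    setNames(f, sample(idx))
  }
  folds <- integer(nrow(data))
  for (attempt in seq_len(10L)) {
    fa <- assign_folds(which(labels)); fi <- assign_folds(which(!labels))
    folds[as.integer(names(fa))] <- fa
    folds[as.integer(names(fi))] <- fi
    ok <- all(vapply(seq_len(cfg$n_folds), function(k)
      any(labels[folds == k]) && any(!labels[folds == k]), logical(1)))
    if (ok) break
    if (attempt == 10L) stop("could not produce folds with both classes")
    message("re-drawing fold split (attempt ", attempt, ")")
  }

  ensembles <- vector("list", cfg$n_folds)
  holdout <- vector("list", cfg$n_folds)
  for (k in seq_len(cfg$n_folds)) {
    tr <- folds != k
    ens <- run_ise_fold(data[tr, , drop = FALSE], labels[tr], cfg)
    ensembles[[k]] <- ens
    fold_model <- structure(list(filters = ens,
                                 descriptors = colnames(data),
                                 config = cfg, seed = seed),
                            class = "ise_model")
    sc <- mbi_score(fold_model, data[!tr, , drop = FALSE],
                    ids = ids[!tr])
    holdout[[k]] <- data.frame(id = sc$id, fold = k, label = labels[!tr],
                               mbi = sc$mbi, stringsAsFactors = FALSE)
  }

  merged <- do.call(rbind, ensembles)
  ord <- order(-merged$mcc,
               vapply(merged$ranges, function(r)
                 paste(r$descriptor, r$lo, r$hi, collapse = ";"),
                 character(1)))
  merged <- merged[ord, , drop = FALSE]
  # duplicate-similar removal: only filters on the same descriptor set can
  # be similar, so dedup greedily within descriptor-set groups (higher-MCC
  # filter first, hence it survives)
  set_key <- vapply(merged$ranges, function(r)
    paste(sort(r$descriptor), collapse = "|"), character(1))
  keep <- rep(TRUE, nrow(merged))
  for (grp in split(seq_len(nrow(merged)), set_key)) {
    if (length(grp) < 2) next
    for (a in seq_along(grp)) {
      i <- grp[a]
      if (!keep[i]) next
      for (b in seq_along(grp)[-seq_len(a)]) {
        j <- grp[b]
        if (keep[j] && filters_similar(merged$ranges[[i]],
                                       merged$ranges[[j]],
                                       cfg$similar_jaccard))
          keep[j] <- FALSE
      }
    }
  }
  merged <- merged[keep, , drop = FALSE]
  merged <- merged[ise_keep_rule(merged, cfg), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("ise_ensemble", "data.frame")

  structure(list(filters = merged, descriptors = colnames(data),
                 config = cfg, seed = as.integer(seed), folds = folds,
                 holdout = do.call(rbind, holdout)),
            class = "ise_model")
}

filter_factors <- function(filters, mode) {
  tp <- filters$tp; fp <- filters$fp; tn <- filters$tn; fn <- filters$fn
  if (mode == "proportion") {
    eff <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    ineff <- ifelse(tn + fn > 0, tn / (tn + fn), 0)
  } else {
    eff <- tp / ifelse(fp == 0, fp + 1, fp)
    ineff <- tn / ifelse(fn == 0, fn + 1, fn)
  }
  list(efficiency = eff, inefficiency = ineff)
}

#' Score molecules to a molecular bioactivity index (MBI)
#'
#' Every filter of the model adds its efficiency factor when the molecule
#' passes it and subtracts its inefficiency factor when it does not; the MBI
#' is the average over all filters. In the default proportion mode the
#' factors are TP/(TP+FP) and TN/(TN+FN), bounding MBI in [-1, 1].
#'
#' @param model An \code{"ise_model"} (or any list with \code{filters} and
#'   \code{config}).
#' @param data Descriptor table for the molecules to score.
#' @param ids Optional identifiers.
#' @return Data frame \code{id, mbi, n_pass}; molecules with missing
#'   descriptor values get \code{NA} MBI with a warning.
#' @export
mbi_score <- function(model, data, ids = NULL) {
  data <- as.data.frame(data)
  filters <- model$filters
  need <- unique(unlist(lapply(filters$ranges, `[[`, "descriptor")))
  miss <- setdiff(need, colnames(data))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(data)))
  nf <- nrow(filters)
  fac <- filter_factors(filters, model$config$mbi_mode)

  bad <- !complete.cases(data[, need, drop = FALSE])
  if (any(bad))
    warning(sum(bad), " molecule(s) with missing descriptor values ",
            "excluded from scoring (MBI = NA)")
  pass <- matrix(FALSE, nrow(data), nf)
  for (f in seq_len(nf)) {
    r <- filters$ranges[[f]]
    p <- rep(TRUE, nrow(data))
    for (k in seq_len(nrow(r))) {
      v <- data[[r$descriptor[k]]]
      p <- p & !is.na(v) & v >= r$lo[k] & v <= r$hi[k]
    }
    pass[, f] <- p
  }
  mbi <- (pass %*% fac$efficiency - (!pass) %*% fac$inefficiency) / nf
  mbi <- as.numeric(mbi)
  mbi[bad] <- NA_real_
  data.frame(id = ids, mbi = mbi, n_pass = rowSums(pass),
             stringsAsFactors = FALSE)
}

#' TP/FP counts above MBI cutoffs plus ROC AUC
#'
#' For each cutoff, counts actives (TP) and inactives (FP) scoring strictly
#' above it; the AUC is the Mann-Whitney rank statistic with tie averaging.
#'
#' @param scores Numeric scores.
#' @param labels Logical actives indicator.
#' @param cutoffs Numeric cutoffs.
#' @return Data frame \code{cutoff, tp, fp} with attribute \code{"auc"}
#'   (NA with a message when only one class is present).
#' @export
score_table <- function(scores, labels, cutoffs = c(0, 0.2, 0.5, 0.85)) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  tab <- data.frame(cutoff = cutoffs,
                    tp = vapply(cutoffs, function(ct)
                      sum(scores > ct & labels), numeric(1)),
                    fp = vapply(cutoffs, function(ct)
                      sum(scores > ct & !labels), numeric(1)))
  attr(tab, "auc") <- rank_auc(scores, labels)
  tab
}

#' ROC AUC by the rank (Mann-Whitney) statistic with tie averaging
#'
#' @param scores Numeric scores (higher = more active-like).
#' @param labels Logical actives indicator.
#' @return AUC in [0, 1], or NA when only one class is present.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  nA <- sum(labels); nI <- sum(!labels)
  if (nA == 0 || nI == 0) {
    message("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - nA * (nA + 1) / 2) / (nA * nI)
}

#' @export
print.ise_model <- function(x, ...) {
  cat("ISE model:", nrow(x$filters), "filters over",
      length(x$descriptors), "descriptors\n")
  cat("  top MCC:", format(max(x$filters$mcc), digits = 4),
      " | folds:", x$config$n_folds,
      " | MBI mode:", x$config$mbi_mode, "\n")
  if (!is.null(x$holdout)) {
    auc <- rank_auc(x$holdout$mbi, x$holdout$label)
    cat("  held-out AUC:", format(auc, digits = 4), "\n")
  }
  invisible(x)
}
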