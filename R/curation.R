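# Learning-set curation: removal of redundant descriptors (pairwise r^2) and
# of near-duplicate molecules (pairwise Tanimoto), both by the
# largest-sum-of-similarity elimination rule.

#' Prune highly correlated descriptors
#'
#' Repeatedly finds the worst-offending descriptor pair (largest squared
#' Pearson correlation above \code{r2_max}) and eliminates, of the two, the
#' descriptor with the larger sum of r-squared against all other remaining
#' descriptors; ties are broken by removing the lexicographically later
#' name. Constant columns (undefined correlation) are removed first.
#'
#' @param data Data frame or matrix of numeric descriptor columns (an
#'   \code{id} column and a \code{label} column are ignored if present);
#'   at least 2 descriptors and 3 rows.
#' @param r2_max Squared-correlation threshold (pairs above it conflict).
#' @return List with \code{kept} (character names, no remaining pair has
#'   r^2 above the threshold) and \code{removed} (data frame
#'   \code{name, reason, value}).
#' @export
prune_correlated_descriptors <- function(data, r2_max = 0.81) {
  data <- as.data.frame(data)
  data <- data[, setdiff(colnames(data), c("id", "label")), drop = FALSE]
  if (ncol(data) < 2 || nrow(data) < 3)
    stop("need at least 2 descriptors and 3 molecules")
  removed <- data.frame(name = character(), reason = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  const <- vapply(data, function(v) sd(v) == 0 || anyNA(v), logical(1))
  if (any(const)) {
    removed <- rbind(removed,
                     data.frame(name = names(data)[const],
                                reason = "constant", value = NA_real_))
    data <- data[, !const, drop = FALSE]
  }
  repeat {
    if (ncol(data) < 2) break
    r2 <- cor(data)^2
    diag(r2) <- 0
    worst <- max(r2)
    if (worst <= r2_max) break
    pair <- which(r2 == worst, arr.ind = TRUE)[1, ]
    cand <- colnames(data)[pair]
    sums <- colSums(r2)[cand]
    victim <- if (sums[1] > sums[2]) cand[1]
      else if (sums[2] > sums[1]) cand[2]
      else sort(cand)[2]                       # tie: later name goes
    removed <- rbind(removed, data.frame(name = victim,
                                         reason = "correlated",
                                         value = worst))
    data <- data[, setdiff(colnames(data), victim), drop = FALSE]
  }
  list(kept = colnames(data), removed = removed)
}

#' Prune near-duplicate molecules by Tanimoto similarity
#'
#' Repeatedly finds the most similar pair with TC at or above \code{tc_max}
#' and eliminates, of the two, the molecule with the larger sum of TCs
#' against all other remaining molecules; ties remove the lexicographically
#' later id. The surviving set has all pairwise TC below the threshold.
#'
#' @param fps Logical fingerprint matrix (rows = molecules, rownames = ids),
#'   e.g. from \code{\link{compute_fingerprints}}.
#' @param tc_max Pairs with TC at or above this value conflict.
#' @return List with \code{kept} (ids), \code{removed}
#'   (data frame \code{id, partner, tc}).
#' @export
diversity_prune <- function(fps, tc_max = 0.7) {
  ids <- rownames(fps)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fps)))
  removed <- data.frame(id = character(), partner = character(),
                        tc = numeric(), stringsAsFactors = FALSE)
  if (nrow(fps) < 2) return(list(kept = ids, removed = removed))
  tc <- tanimoto_matrix(fps)
  dimnames(tc) <- list(ids, ids)
  diag(tc) <- 0
  alive <- ids
  repeat {
    sub <- tc[alive, alive, drop = FALSE]
    worst <- max(sub)
    if (worst < tc_max || length(alive) < 2) break
    pair <- which(sub == worst, arr.ind = TRUE)
    pair <- sort(alive[pair[1, ]])
    sums <- rowSums(sub)[pair]
    victim <- if (sums[1] > sums[2]) pair[1]
      else if (sums[2] > sums[1]) pair[2]
      else pair[2]                             # tie: later id goes
    partner <- setdiff(pair, victim)
    removed <- rbind(removed, data.frame(id = victim, partner = partner,
                                         tc = worst))
    alive <- setdiff(alive, victim)
  }
  list(kept = alive, removed = removed)
}
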