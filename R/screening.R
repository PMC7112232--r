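# Candidate-generation funnel: Tanimoto similarity screen against a fragment
# set, Lipinski applicability domain, solubility consensus gate and
# MBI-based candidate tiering.

#' Similarity screen of a library against a fragment set
#'
#' A library molecule is a hit when its best Tanimoto coefficient against
#' any fragment reaches \code{tc_min}; each hit is annotated with the
#' best-matching fragment (ties resolved to the lowest fragment id).
#'
#' @param library_fps Logical fingerprint matrix of the library (rownames =
#'   ids), from \code{\link{compute_fingerprints}}.
#' @param fragment_fps Fingerprint matrix of the fragment set.
#' @param tc_min Hit threshold (the screen keeps TC >= tc_min).
#' @return Data frame \code{id, tc_best, frag_best, hit} for every library
#'   molecule (so the funnel log retains non-hits too).
#' @export
similarity_screen <- function(library_fps, fragment_fps, tc_min = 0.6) {
  if (nrow(fragment_fps) == 0) stop("empty fragment set")
  ids <- rownames(library_fps)
  if (nrow(library_fps) == 0)
    return(data.frame(id = character(), tc_best = numeric(),
                      frag_best = character(), hit = logical()))
  tc <- tanimoto_matrix(library_fps, fragment_fps)
  ord <- order(colnames(tc))          # ties -> lowest fragment id
  tc_sorted <- tc[, ord, drop = FALSE]
  best <- max.col(tc_sorted, ties.method = "first")
  data.frame(id = ids,
             tc_best = tc_sorted[cbind(seq_len(nrow(tc)), best)],
             frag_best = colnames(tc_sorted)[best],
             hit = tc_sorted[cbind(seq_len(nrow(tc)), best)] >= tc_min,
             stringsAsFactors = FALSE)
}

#' Fit a Lipinski applicability domain from active molecules
#'
#' For each domain descriptor the allowed range is the actives' sample mean
#' plus/minus twice the sample standard deviation (denominator n - 1).
#' Zero-variance descriptors give a degenerate range (an equality
#' constraint), which is flagged.
#'
#' @param actives Descriptor table of the defining molecules (at least 3).
#' @param descriptors Which descriptors define the domain (default the
#'   Lipinski four).
#' @param n_sd Half-width in standard deviations.
#' @return Object of class \code{"applicability_domain"}: data frame
#'   \code{descriptor, lo, hi, mean, sd, degenerate} with attribute
#'   \code{n_defining}.
#' @export
fit_applicability_domain <- function(actives,
                                     descriptors = LIPINSKI_DESCRIPTORS,
                                     n_sd = 2) {
  actives <- as.data.frame(actives)
  miss <- setdiff(descriptors, colnames(actives))
  if (length(miss)) stop("missing descriptor(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(actives) < 3) stop("need at least 3 defining molecules")
  rows <- lapply(descriptors, function(d) {
    v <- actives[[d]]
    m <- mean(v); s <- sd(v)
    data.frame(descriptor = d, lo = m - n_sd * s, hi = m + n_sd * s,
               mean = m, sd = s, degenerate = s == 0,
               stringsAsFactors = FALSE)
  })
  dom <- do.call(rbind, rows)
  if (any(dom$degenerate))
    warning("zero-variance descriptor(s) give a degenerate domain range: ",
            paste(dom$descriptor[dom$degenerate], collapse = ", "))
  structure(dom, class = c("applicability_domain", "data.frame"),
            n_defining = nrow(actives))
}

#' Apply an applicability domain to a library
#'
#' A molecule is kept iff every domain descriptor lies inside its closed
#' range (boundary values pass).
#'
#' @param library Descriptor table with an \code{id} column.
#' @param domain An \code{\link{fit_applicability_domain}} result.
#' @return Data frame \code{id, kept, violations} (comma-separated names of
#'   violated descriptors, empty when kept).
#' @export
apply_applicability_domain <- function(library, domain) {
  library <- as.data.frame(library)
  viol <- matrix(FALSE, nrow(library), nrow(domain))
  for (k in seq_len(nrow(domain))) {
    v <- library[[domain$descriptor[k]]]
    if (is.null(v)) stop("library lacks descriptor ", domain$descriptor[k])
    viol[, k] <- is.na(v) | v < domain$lo[k] | v > domain$hi[k]
  }
  data.frame(id = library$id, kept = rowSums(viol) == 0,
             violations = apply(viol, 1, function(z)
               paste(domain$descriptor[z], collapse = ",")),
             stringsAsFactors = FALSE)
}

#' Solubility consensus gate
#'
#' Each molecule needs at least two independent cLogS estimates
#' (log10 mol/L). A molecule passes when the estimates' mean exceeds
#' \code{mean_min} and their sample standard deviation is below
#' \code{std_max}; molecules with fewer than two estimates are marked
#' \code{"insufficient evidence"} and do not pass.
#'
#' @param predictions Named list (or matrix with molecules as rows) of
#'   per-molecule numeric cLogS vectors.
#' @param mean_min Consensus-mean threshold (log10 mol/L).
#' @param std_max Consensus spread threshold.
#' @return Data frame \code{id, n, mean, sd, pass, note}.
#' @export
solubility_gate <- function(predictions, mean_min = -3.5, std_max = 1.5) {
  if (is.matrix(predictions))
    predictions <- split(predictions, row(predictions)) |>
      setNames(rownames(predictions))
  ids <- names(predictions)
  if (is.null(ids)) ids <- paste0("mol_", seq_along(predictions))
  if (!length(predictions))
    return(data.frame(id = character(), n = integer(), mean = numeric(),
                      sd = numeric(), pass = logical(), note = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(predictions), function(i) {
    v <- predictions[[i]]
    v <- v[is.finite(v)]
    if (length(v) < 2)
      return(data.frame(id = ids[i], n = length(v), mean = NA_real_,
                        sd = NA_real_, pass = FALSE,
                        note = "insufficient evidence",
                        stringsAsFactors = FALSE))
    data.frame(id = ids[i], n = length(v), mean = mean(v), sd = sd(v),
               pass = mean(v) > mean_min && sd(v) < std_max, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Built-in cLogS estimators
#'
#' Two simple intrinsic-solubility heuristics over computed descriptors,
#' usable as pluggable estimators for \code{\link{solubility_gate}}:
#' \code{logs_estimator_esol} is a linear model in logP, molecular weight,
#' rotatable bonds and aromatic proportion (Delaney-style coefficients);
#' \code{logs_estimator_logp} is the cruder general-solubility relation
#' \code{0.5 - logP}. Both return log10 mol/L.
#'
#' @param descriptors Descriptor table containing \code{logP}, \code{MW},
#'   \code{n_rotatable_bonds} and \code{frac_aromatic} as needed.
#' @return Numeric vector of cLogS values.
#' @export
logs_estimator_esol <- function(descriptors) {
  0.16 - 0.63 * descriptors$logP - 0.0062 * descriptors$MW +
    0.066 * descriptors$n_rotatable_bonds - 0.74 * descriptors$frac_aromatic
}

#' @rdname logs_estimator_esol
#' @export
logs_estimator_logp <- function(descriptors) {
  0.5 - descriptors$logP
}

#' Assign screening candidates to tiers by MBI
#'
#' Tiers follow the screening protocol: \code{top_ise} for MBI above
#' \code{top_min}; \code{mid_ise} for MBI in (\code{mid_min},
#' \code{top_min}]; \code{low_mbi_similar} for molecules scoring below
#' \code{low_max} that are nonetheless similarity hits (structural-similarity
#' controls); \code{random_control} only for explicitly requested ids;
#' everything else is \code{"none"}.
#'
#' @param scored Data frame with \code{id} and \code{mbi}.
#' @param similarity_hit Logical vector aligned with \code{scored} (default
#'   all \code{FALSE}).
#' @param top_min,mid_min,low_max Tier thresholds.
#' @param random_ids Ids to label as random controls.
#' @return \code{scored} with a \code{tier} factor column.
#' @export
tier_candidates <- function(scored, similarity_hit = NULL,
                            top_min = 0.85, mid_min = 0.2,
                            low_max = -0.97, random_ids = character()) {
  if (is.null(similarity_hit)) similarity_hit <- rep(FALSE, nrow(scored))
  stopifnot(length(similarity_hit) == nrow(scored))
  tier <- rep("none", nrow(scored))
  tier[scored$mbi > top_min] <- "top_ise"
  tier[scored$mbi > mid_min & scored$mbi <= top_min] <- "mid_ise"
  tier[scored$mbi < low_max & similarity_hit] <- "low_mbi_similar"
  tier[scored$id %in% random_ids] <- "random_control"
  scored$tier <- factor(tier, levels = c("top_ise", "mid_ise",
                                         "low_mbi_similar",
                                         "random_control", "none"))
  scored
}
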