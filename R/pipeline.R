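# End-to-end candidate-generation pipeline: inhibitors -> P5-P2 fragments ->
# similarity screen -> applicability domain -> ISE model + MBI scoring ->
# solubility consensus -> candidate tiers, with a per-stage funnel report.

#' Run the full screening pipeline
#'
#' Stages, in order: (1) cleave the inhibitors into a deduplicated P5-P2
#' fragment set; (2) Tanimoto similarity screen of the library against the
#' fragments; (3) Lipinski applicability domain fitted on the original
#' (full) inhibitors and applied to the hits; (4) descriptor curation (correlation pruning) and a
#' cross-validated ISE model of fragments vs in-domain library molecules
#' (assumed inactive), used to give every surviving hit an MBI; (5) solubility
#' consensus gate; (6) candidate tiering. Fully reproducible under
#' \code{seed}.
#'
#' @param library Data frame \code{id, smiles} of candidate molecules.
#' @param inhibitors Data frame \code{id, smiles} of known inhibitors.
#' @param seed Integer seed for all stochastic stages.
#' @param tc_min Similarity-screen threshold.
#' @param rule A \code{\link{cleavage_rule}}.
#' @param ise_cfg An \code{\link{ise_config}}.
#' @param estimators Named list of cLogS estimator functions (each taking a
#'   descriptor table).
#' @param mean_min,std_max Solubility gate thresholds.
#' @param out_dir Optional directory; when given, per-stage CSV/JSON outputs
#'   and a provenance sidecar are written there.
#' @return List of class \code{"ssi_pipeline"}: \code{fragments},
#'   \code{screen}, \code{domain}, \code{model}, \code{candidates} (per
#'   molecule: tc, domain verdict, mbi, solubility, tier) and \code{funnel}
#'   (stage, n_in, n_out).
#' @export
run_pipeline <- function(library, inhibitors, seed = 1, tc_min = 0.6,
                         rule = cleavage_rule(), ise_cfg = ise_config(),
                         estimators = list(esol = logs_estimator_esol,
                                           logp = logs_estimator_logp),
                         mean_min = -3.5, std_max = 1.5, out_dir = NULL) {
  set.seed(as.integer(seed))
  funnel <- list()
  note_stage <- function(stage, n_in, n_out)
    funnel[[length(funnel) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                                n_out = n_out)

  fragments <- build_fragment_set(inhibitors, rule)
  note_stage("fragment_derivation", nrow(inhibitors),
             nrow(fragments$fragments))
  if (!nrow(fragments$fragments)) stop("pipeline aborted at stage ",
                                       "'fragment_derivation': no fragments")

  lib_desc <- compute_descriptors(library)
  inh_desc <- compute_descriptors(inhibitors)
  frag_desc <- compute_descriptors(fragments$fragments)
  lib_fp <- compute_fingerprints(library)
  frag_fp <- compute_fingerprints(fragments$fragments)

  screen <- similarity_screen(lib_fp, frag_fp, tc_min)
  hits <- screen$id[screen$hit]
  note_stage("similarity_screen", nrow(library), length(hits))

  # domain from the original (full) inhibitors' Lipinski descriptors
  domain <- fit_applicability_domain(inh_desc)
  ad <- apply_applicability_domain(lib_desc, domain)
  in_domain <- ad$id[ad$kept]
  hits_in_domain <- intersect(hits, in_domain)
  note_stage("applicability_domain", length(hits), length(hits_in_domain))

  # learning set: fragments (actives) vs in-domain library molecules (the
  # standard assumption that a randomly drawn library molecule is inactive)
  inactive_ids <- in_domain
  desc_cols <- setdiff(colnames(lib_desc), c("id", "smiles"))
  model <- NULL
  scored <- data.frame(id = character(), mbi = numeric(),
                       n_pass = numeric(), stringsAsFactors = FALSE)
  if (length(hits_in_domain) &&
      nrow(frag_desc) >= ise_cfg$n_folds &&
      length(inactive_ids) >= ise_cfg$n_folds) {
    learn <- rbind(frag_desc[, c("id", desc_cols)],
                   lib_desc[lib_desc$id %in% inactive_ids,
                            c("id", desc_cols)])
    labels <- c(rep(TRUE, nrow(frag_desc)), rep(FALSE, length(inactive_ids)))
    pruned <- prune_correlated_descriptors(learn[, desc_cols, drop = FALSE])
    model <- build_model(learn[, pruned$kept, drop = FALSE], labels,
                         cfg = ise_cfg, seed = seed, ids = learn$id)
    scored <- mbi_score(model, lib_desc[lib_desc$id %in% hits_in_domain,
                                        pruned$kept, drop = FALSE],
                        ids = hits_in_domain)
  } else if (length(hits_in_domain)) {
    message("learning set too small for ", ise_cfg$n_folds,
            "-fold modelling: candidates left unscored")
  }
  note_stage("ise_scoring", length(hits_in_domain), nrow(scored))

  cand_desc <- lib_desc[match(scored$id, lib_desc$id), , drop = FALSE]
  preds <- lapply(seq_len(nrow(cand_desc)), function(i)
    vapply(estimators, function(f)
      f(cand_desc[i, , drop = FALSE]), numeric(1)))
  names(preds) <- scored$id
  sol <- solubility_gate(preds, mean_min, std_max)
  soluble <- sol$id[sol$pass]
  note_stage("solubility_gate", nrow(scored), length(soluble))

  tiers <- tier_candidates(scored[scored$id %in% soluble, , drop = FALSE],
                           similarity_hit = rep(TRUE, length(soluble)))
  note_stage("tiering", length(soluble),
             sum(tiers$tier != "none"))

  candidates <- merge(screen, ad, by = "id")
  candidates <- merge(candidates, scored[, c("id", "mbi")], by = "id",
                      all.x = TRUE)
  candidates <- merge(candidates, sol[, c("id", "mean", "sd", "pass")],
                      by = "id", all.x = TRUE)
  names(candidates)[names(candidates) == "mean"] <- "clogs_mean"
  names(candidates)[names(candidates) == "sd"] <- "clogs_sd"
  names(candidates)[names(candidates) == "pass"] <- "soluble"
  candidates <- merge(candidates, tiers[, c("id", "tier")], by = "id",
                      all.x = TRUE)
  candidates$tier <- as.character(candidates$tier)
  candidates$tier[is.na(candidates$tier)] <- "excluded"
  candidates <- candidates[order(candidates$id), , drop = FALSE]
  rownames(candidates) <- NULL

  funnel <- do.call(rbind, funnel)
  out <- structure(list(fragments = fragments, screen = screen,
                        domain = domain, model = model,
                        candidates = candidates, funnel = funnel,
                        seed = as.integer(seed)),
                   class = "ssi_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir,
                                                tc_min = tc_min)
  out
}

#' @export
print.ssi_pipeline <- function(x, ...) {
  cat("SSI screening pipeline (seed", x$seed, ")\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir, tc_min) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(
    tool = "ssikit",
    version = as.character(utils::packageVersion("ssikit")),
    seed = res$seed,
    config = list(tc_min = tc_min,
                  ise = if (!is.null(res$model))
                    unclass(res$model$config)))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(res$candidates, file.path(out_dir, "candidates.csv"),
            row.names = FALSE)
  write.csv(res$funnel, file.path(out_dir, "funnel.csv"), row.names = FALSE)
  if (!is.null(res$model))
    write_ise_model(res$model, file.path(out_dir, "model.json"))
  write_fragment_set(res$fragments, file.path(out_dir, "fragments.smi"))
  invisible(out_dir)
}
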