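# Deterministic generators for every input class of the pipeline, with
# planted ground truth for recovery benchmarks: descriptor tables with
# signal ranges, toy SMILES libraries of cleavable acyl-heterocycle
# scaffolds, and Michaelis-Menten rate data under the classical inhibition
# mechanisms.

#' Specification of a planted-signal descriptor dataset
#'
#' Emulates an imbalanced learning set (roughly 1:200 actives:inactives, the
#' scale of a fragment-vs-random screening set): actives concentrate inside
#' a planted sub-range on each signal descriptor, inactives and all noise
#' descriptors are uniform on [0, 1].
#'
#' @param n_actives,n_inactives Class sizes.
#' @param n_signal,n_noise Numbers of signal and noise descriptors.
#' @param range_width Width of each planted signal range (0 < width < 1).
#' @param leak_prob Probability that an active "leaks": a leaked active is
#'   drawn uniform on [0, 1] on every signal descriptor instead of inside
#'   the planted ranges (an unlearnable active, as real screening sets
#'   contain).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return List of class \code{"planted_spec"}.
#' @export
planted_descriptor_spec <- function(n_actives = 30, n_inactives = 6000,
                                    n_signal = 4, n_noise = 26,
                                    range_width = 0.2, leak_prob = 0.05,
                                    seed = 1) {
  stopifnot(range_width > 0, range_width < 1,
            leak_prob >= 0, leak_prob < 0.5,
            n_actives >= 1, n_inactives >= 1, n_signal >= 1)
  structure(list(n_actives = as.integer(n_actives),
                 n_inactives = as.integer(n_inactives),
                 n_signal = as.integer(n_signal),
                 n_noise = as.integer(n_noise),
                 range_width = range_width, leak_prob = leak_prob,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a labelled descriptor dataset with planted signal ranges
#'
#' @param spec A \code{\link{planted_descriptor_spec}}.
#' @return List with \code{data} (data frame: \code{id}, descriptor
#'   columns \code{sig1..}, \code{noise1..}, \code{label} in {1, 0}) and
#'   \code{truth} (signal descriptor names and their planted \code{lo},
#'   \code{hi}).
#' @export
gen_descriptor_dataset <- function(spec = planted_descriptor_spec()) {
  set.seed(spec$seed)
  sig_names <- paste0("sig", seq_len(spec$n_signal))
  noise_names <- if (spec$n_noise > 0)
    paste0("noise", seq_len(spec$n_noise)) else character()
  lo <- runif(spec$n_signal, 0, 1 - spec$range_width)
  hi <- lo + spec$range_width
  n <- spec$n_actives + spec$n_inactives
  label <- c(rep(1L, spec$n_actives), rep(0L, spec$n_inactives))

  # a leaked active behaves like background on every signal descriptor
  leak <- runif(spec$n_actives) < spec$leak_prob
  cols <- list()
  for (k in seq_len(spec$n_signal)) {
    act <- runif(spec$n_actives, lo[k], hi[k])
    act[leak] <- runif(sum(leak))
    cols[[sig_names[k]]] <- c(act, runif(spec$n_inactives))
  }
  for (k in seq_along(noise_names))
    cols[[noise_names[k]]] <- runif(n)
  data <- data.frame(id = sprintf("syn_%05d", seq_len(n)), cols,
                     label = label, stringsAsFactors = FALSE)
  list(data = data,
       truth = list(signal = sig_names,
                    ranges = data.frame(descriptor = sig_names,
                                        lo = lo, hi = hi)))
}

# scaffold parts for the SMILES fixtures
ssi_rings <- c(pyrrolidine = "N1CCCC1", piperidine = "N1CCCCC1")
ssi_acyl_parts <- c(
  "c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(Br)cc1",
  "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1ccc(N)cc1", "c1ccc(O)cc1",
  "c1ccncc1", "c1ccco1", "c1cccs1", "c1ccc2ccccc2c1",
  "CC", "CCC", "CCCC", "C1CCCCC1", "CC(C)C", "COC", "CCOC", "Cc1ccccc1",
  "CCc1ccccc1", "OCC", "c1ccc(CC)cc1", "c1ccc(CO)cc1", "C1CCCC1")
ssi_decoys <- c(
  "CCCCCCCC", "CCOCC", "CCNCC", "c1ccccc1CCO", "CC(C)CO",
  "c1ccc(S(=O)(=O)N)cc1", "CCCCN", "OCCOCCO", "c1ccc(C#N)cc1",
  "CC(=O)OC", "c1ccccc1OC", "CCS", "ClCCCl", "c1ccc(cc1)C(F)(F)F",
  "CCCC(=O)O", "c1ccc2c(c1)cccc2O", "CC(C)(C)O", "NCCN",
  "c1ccc(cc1)c1ccccc1", "CC=CC", "C1CCOC1", "CCCOC(=O)C", "Cn1cccc1",
  "c1ccc(N(C)C)cc1", "OC1CCCCC1")

#' Generate toy SMILES fixtures
#'
#' \code{inhibitor_like} molecules are acylated pyrrolidine/piperidine
#' scaffolds (enumerated acyl decorations of the proline-like ring), all
#' cleavable by the default \code{\link{cleavage_rule}}; \code{random_like}
#' molecules are scaffold-diverse decoys without the motif.
#'
#' @param kind \code{"inhibitor_like"} or \code{"random_like"}.
#' @param n How many molecules (bounded by the enumerable variants).
#' @param seed Seed controlling which variants are drawn.
#' @return Data frame \code{id, smiles}.
#' @export
gen_smiles_fixture <- function(kind = c("inhibitor_like", "random_like"),
                               n = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  pool <- if (kind == "inhibitor_like") {
    as.vector(outer(ssi_acyl_parts, ssi_rings,
                    function(a, r) paste0("O=C(", a, ")", r)))
  } else ssi_decoys
  if (n > length(pool))
    stop("at most ", length(pool), " ", kind, " variants are enumerable")
  set.seed(as.integer(seed))
  pick <- sort(sample.int(length(pool), n))
  data.frame(id = sprintf("%s_%03d", sub("_like", "", kind), seq_len(n)),
             smiles = pool[pick], stringsAsFactors = FALSE)
}

#' Generate a toy screening library
#'
#' Emulates the composition of a commercial screening library as the
#' similarity funnel sees it: a fraction of "analogue" molecules (methyl and
#' ethyl esters of the same acyl groups that decorate the inhibitor
#' scaffolds, hence Tanimoto-similar to the P5-P2 fragment acids) diluted
#' with scaffold-diverse decoys.
#'
#' @param n_analog,n_decoy How many analogue and decoy molecules.
#' @param seed Integer seed.
#' @return Data frame \code{id, smiles} with ids \code{lib_<i>}.
#' @export
gen_library_fixture <- function(n_analog = 20, n_decoy = 20, seed = 1) {
  analog_pool <- as.vector(outer(c("COC(=O)", "CCOC(=O)"), ssi_acyl_parts,
                                 paste0))
  if (n_analog > length(analog_pool))
    stop("at most ", length(analog_pool), " analogue variants are enumerable")
  if (n_decoy > length(ssi_decoys))
    stop("at most ", length(ssi_decoys), " decoy variants are enumerable")
  set.seed(as.integer(seed))
  smi <- c(analog_pool[sort(sample.int(length(analog_pool), n_analog))],
           ssi_decoys[sort(sample.int(length(ssi_decoys), n_decoy))])
  data.frame(id = sprintf("lib_%03d", seq_along(smi)), smiles = smi,
             stringsAsFactors = FALSE)
}

#' Specification of a simulated inhibition-kinetics experiment
#'
#' @param km,vmax Control Michaelis-Menten parameters (uM, uM/min).
#' @param mechanism Inhibition mechanism generating the rates.
#' @param ki Inhibition constant (uM).
#' @param substrate_grid,inhibitor_grid Concentrations measured (uM).
#' @param noise_sd Relative (multiplicative) Gaussian noise, the standard
#'   constant-CV assumption for initial-rate assays.
#' @param seed Integer seed.
#' @return List of class \code{"kinetics_spec"}.
#' @export
kinetics_sim_spec <- function(km = 5, vmax = 2,
                              mechanism = c("none", "competitive",
                                            "noncompetitive",
                                            "uncompetitive"),
                              ki = 10,
                              substrate_grid = c(0.5, 1, 2, 5, 10, 20, 50),
                              inhibitor_grid = c(0, 5, 10, 20),
                              noise_sd = 0, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(km > 0, vmax > 0, ki > 0, noise_sd >= 0,
            length(substrate_grid) > 0, length(inhibitor_grid) > 0)
  structure(list(km = km, vmax = vmax, mechanism = mechanism, ki = ki,
                 substrate_grid = substrate_grid,
                 inhibitor_grid = inhibitor_grid, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "kinetics_spec")
}

#' Closed-form inhibited Michaelis-Menten rate
#'
#' @param S,I Substrate and inhibitor concentrations (uM).
#' @param km,vmax,ki Kinetic parameters.
#' @param mechanism One of none / competitive / noncompetitive /
#'   uncompetitive.
#' @return Rate in uM/min.
#' @export
mm_rate <- function(S, I, km, vmax, ki,
                    mechanism = c("none", "competitive", "noncompetitive",
                                  "uncompetitive")) {
  mechanism <- match.arg(mechanism)
  a <- 1 + I / ki
  switch(mechanism,
         none = vmax * S / (km + S),
         competitive = vmax * S / (km * a + S),
         noncompetitive = vmax * S / (a * (km + S)),
         uncompetitive = vmax * S / (km + S * a))
}

#' Generate Michaelis-Menten rate measurements
#'
#' Rates follow the mechanism's closed-form law with multiplicative
#' Gaussian noise of relative standard deviation \code{noise_sd}, clipped
#' at zero.
#'
#' @param spec A \code{\link{kinetics_sim_spec}}.
#' @return Data frame \code{substrate, inhibitor, substrate_conc_uM,
#'   inhibitor_conc_uM, rate_uM_min}.
#' @export
gen_kinetics_data <- function(spec = kinetics_sim_spec()) {
  set.seed(spec$seed)
  grid <- expand.grid(substrate_conc_uM = spec$substrate_grid,
                      inhibitor_conc_uM = spec$inhibitor_grid)
  v <- mm_rate(grid$substrate_conc_uM, grid$inhibitor_conc_uM,
               spec$km, spec$vmax, spec$ki, spec$mechanism)
  if (spec$noise_sd > 0)
    v <- pmax(0, v * (1 + rnorm(length(v), 0, spec$noise_sd)))
  data.frame(substrate = "S", inhibitor = ifelse(
    grid$inhibitor_conc_uM == 0, "control", "inhibitor"),
    substrate_conc_uM = grid$substrate_conc_uM,
    inhibitor_conc_uM = grid$inhibitor_conc_uM,
    rate_uM_min = v, stringsAsFactors = FALSE)
}
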