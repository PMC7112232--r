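# Derivation of P5-P2 fragment sets: the proline-like ring occupying the
# P1 position of an inhibitor is removed by cleaving the acyl bond into the
# ring nitrogen; the carbonyl-side (N-terminal-direction) portion is kept
# and capped. Sites are located on the molecular graph: a saturated 5- or
# 6-membered ring of one nitrogen and otherwise carbons, whose nitrogen
# carries an exocyclic carbonyl carbon (the equivalent substructure patterns
# are O=C-N1CCCC1 / O=C-N1CCCCC1 with ring substituents allowed).

#' Cleavage rule for proline-like P1 rings
#'
#' @param ring_sizes Sizes of the nitrogen heterocycle to recognise
#'   (default pyrrolidine and piperidine, 5 and 6).
#' @param capping How the carbonyl carbon's open valence is satisfied:
#'   \code{"hydroxyl"} (default; yields a carboxylic acid, preserving the
#'   hydrogen-bonding character of the original amide) or \code{"hydrogen"}
#'   (aldehyde terminus). No capping choice can produce a radical; exactly
#'   one sigma bond is cut and the valence is completed.
#' @return List of class \code{"cleavage_rule"}.
#' @export
cleavage_rule <- function(ring_sizes = c(5L, 6L),
                          capping = c("hydroxyl", "hydrogen")) {
  capping <- match.arg(capping)
  stopifnot(all(ring_sizes >= 3))
  structure(list(ring_sizes = as.integer(ring_sizes), capping = capping),
            class = "cleavage_rule")
}

atom_elements <- function(sdf) {
  sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
}

# Cleavage sites of one SDF molecule: data frame (n_idx, c_idx) where n_idx
# is the ring nitrogen and c_idx the exocyclic carbonyl carbon.
find_cleavage_sites <- function(sdf, rule) {
  elements <- atom_elements(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0) return(data.frame())
  edges <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  bond_order <- function(i, j) {
    hit <- (edges$a == i & edges$b == j) | (edges$a == j & edges$b == i)
    if (any(hit)) edges$order[which(hit)[1]] else 0L
  }
  ring_list <- tryCatch(
    ChemmineR::rings(sdf, upper = max(rule$ring_sizes), type = "all",
                     arom = FALSE),
    error = function(e) list())
  sites <- list()
  for (ring in ring_list) {
    idx <- as.integer(sub("^.*_", "", ring))
    if (!(length(idx) %in% rule$ring_sizes)) next
    el <- elements[idx]
    if (sum(el == "N") != 1 || !all(el %in% c("C", "N"))) next
    # saturated ring: every ring bond is a single bond
    pairs <- cbind(idx, c(idx[-1], idx[1]))
    if (!all(apply(pairs, 1, function(p) bond_order(p[1], p[2]) == 1))) next
    n_idx <- idx[el == "N"]
    nb <- unique(c(edges$b[edges$a == n_idx], edges$a[edges$b == n_idx]))
    for (c_idx in setdiff(nb, idx)) {
      if (elements[c_idx] != "C" || bond_order(n_idx, c_idx) != 1) next
      cnb <- unique(c(edges$b[edges$a == c_idx], edges$a[edges$b == c_idx]))
      has_carbonyl_o <- any(vapply(cnb, function(o)
        elements[o] == "O" && bond_order(c_idx, o) == 2, logical(1)))
      if (has_carbonyl_o)
        sites[[length(sites) + 1]] <- data.frame(n_idx = n_idx,
                                                 c_idx = c_idx)
    }
  }
  if (!length(sites)) return(data.frame())
  unique(do.call(rbind, sites))
}

# Minimal V2000 molfile for a 2D-less connection table.
build_molfile <- function(title, elements, bonds) {
  hdr <- c(title, "  ssikit", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(elements), nrow(bonds)))
  atoms <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, elements)
  bl <- if (nrow(bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                                 bonds$a, bonds$b, bonds$order) else character()
  c(hdr, atoms, bl, "M  END", "$$$$")
}

# Cut bond (n_idx, c_idx), keep the component holding c_idx, cap, and return
# the fragment SMILES (NA when the cut does not separate ring from carbonyl,
# e.g. in a macrocycle).
cleave_at_site <- function(sdf, n_idx, c_idx, rule) {
  elements <- atom_elements(sdf)
  bb <- ChemmineR::bondblock(sdf)
  edges <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  cut <- (edges$a == n_idx & edges$b == c_idx) |
    (edges$a == c_idx & edges$b == n_idx)
  g <- igraph::graph_from_edgelist(as.matrix(edges[!cut, c("a", "b")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(elements) -
                                     igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  if (comp[c_idx] == comp[n_idx]) return(NA_character_)
  keep <- which(comp == comp[c_idx])
  remap <- match(seq_along(elements), keep)
  sub <- edges[!cut & edges$a %in% keep & edges$b %in% keep, ]
  frag_el <- elements[keep]
  frag_bonds <- data.frame(a = remap[sub$a], b = remap[sub$b],
                           order = sub$order)
  if (rule$capping == "hydroxyl") {
    frag_el <- c(frag_el, "O")
    frag_bonds <- rbind(frag_bonds,
                        data.frame(a = remap[c_idx], b = length(frag_el),
                                   order = 1L))
  }
  mf <- build_molfile("fragment", frag_el, frag_bonds)
  out <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(mf))
  as.character(ChemmineR::sdf2smiles(out))
}

#' Cleave the P1-parallel proline-like ring from one molecule
#'
#' Locates every acylated proline-like ring (see \code{\link{cleavage_rule}}),
#' cuts the acyl bond into the ring nitrogen and keeps the carbonyl-side
#' portion, discarding everything on the ring side of the cut (including
#' ring substituents). If the kept portion itself still contains a
#' recognisable site (two-site molecules), it is cleaved again, so no
#' returned fragment matches the ring pattern.
#'
#' @param mol One-row data frame with \code{id}, \code{smiles}, or a single
#'   SMILES string.
#' @param rule A \code{\link{cleavage_rule}}.
#' @return Data frame \code{id, smiles, parent, site} with one row per
#'   distinct cleavage site; zero rows (with a notice) when the molecule has
#'   no cleavage site.
#' @export
cleave_p1_fragment <- function(mol, rule = cleavage_rule()) {
  if (is.character(mol)) mol <- data.frame(id = "mol_1", smiles = mol,
                                           stringsAsFactors = FALSE)
  stopifnot(nrow(mol) == 1)
  empty <- data.frame(id = character(), smiles = character(),
                      parent = character(), site = integer(),
                      stringsAsFactors = FALSE)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(mol$smiles,
                                                         mol$id)))
  if (!ChemmineR::validSDF(sdf)) {
    message("no cleavage site in ", mol$id)
    return(empty)
  }
  sdf1 <- sdf[[1]]
  sites <- find_cleavage_sites(sdf1, rule)
  if (!nrow(sites)) {
    message("no cleavage site in ", mol$id)
    return(empty)
  }
  out <- list()
  for (s in seq_len(nrow(sites))) {
    smi <- cleave_at_site(sdf1, sites$n_idx[s], sites$c_idx[s], rule)
    if (is.na(smi)) next
    # exhaust residual sites in the kept portion (multi-site parents)
    for (guard in 1:10) {
      inner <- cleave_p1_fragment_once(smi, rule)
      if (is.na(inner)) break
      smi <- inner
    }
    out[[s]] <- data.frame(id = paste0(mol$id, "_f", s), smiles = smi,
                           parent = mol$id, site = s,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    message("no cleavage site in ", mol$id)
    return(empty)
  }
  res <- do.call(rbind, out)
  res$smiles <- canonical_smiles(res$smiles)
  res
}

# One further cleavage of an already-cut fragment, or NA when clean.
cleave_p1_fragment_once <- function(smiles, rule) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "x")))
  if (!ChemmineR::validSDF(sdf)) return(NA_character_)
  sites <- find_cleavage_sites(sdf[[1]], rule)
  if (!nrow(sites)) return(NA_character_)
  cleave_at_site(sdf[[1]], sites$n_idx[1], sites$c_idx[1], rule)
}

#' Build a deduplicated fragment set from a list of inhibitors
#'
#' Applies \code{\link{cleave_p1_fragment}} to every inhibitor and merges
#' the results, deduplicating by canonical SMILES; the provenance map links
#' every unique fragment to all parents that produced it.
#'
#' @param inhibitors Data frame with \code{id}, \code{smiles}.
#' @param rule A \code{\link{cleavage_rule}}.
#' @return Object of class \code{"fragment_set"}: list with
#'   \code{fragments} (data frame \code{id, smiles}) and \code{provenance}
#'   (named list fragment id -> character vector of parent ids).
#' @export
build_fragment_set <- function(inhibitors, rule = cleavage_rule()) {
  stopifnot(nrow(inhibitors) >= 1)
  pieces <- lapply(seq_len(nrow(inhibitors)), function(i)
    cleave_p1_fragment(inhibitors[i, , drop = FALSE], rule))
  all <- do.call(rbind, pieces)
  if (is.null(all) || !nrow(all)) {
    warning("no inhibitor had a cleavage site: empty fragment set")
    return(structure(list(fragments = data.frame(id = character(),
                                                 smiles = character()),
                          provenance = list()),
                     class = "fragment_set"))
  }
  usmi <- unique(all$smiles)
  ids <- paste0("frag_", seq_along(usmi))
  prov <- lapply(usmi, function(s) sort(unique(all$parent[all$smiles == s])))
  names(prov) <- ids
  structure(list(fragments = data.frame(id = ids, smiles = usmi,
                                        stringsAsFactors = FALSE),
                 provenance = prov),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "unique fragment(s) from",
      length(unique(unlist(x$provenance))), "parent(s)\n")
  invisible(x)
}

#' Cross-set Tanimoto matrix between two fragment sets
#'
#' @param setA,setB \code{"fragment_set"} objects (rows of the matrix are
#'   \code{setA}).
#' @param fp_cfg A \code{\link{fingerprint_config}}.
#' @return List with \code{matrix} (TC values), \code{row_max} (data frame
#'   \code{id, max_tc, best_match}) and \code{identical_pairs}
#'   (data frame of cross-set pairs at TC = 1).
#' @export
cross_set_similarity <- function(setA, setB,
                                 fp_cfg = fingerprint_config()) {
  if (!nrow(setA$fragments) || !nrow(setB$fragments))
    stop("empty fragment set")
  fa <- compute_fingerprints(setA$fragments, fp_cfg)
  fb <- compute_fingerprints(setB$fragments, fp_cfg)
  tc <- tanimoto_matrix(fa, fb)
  best <- max.col(tc, ties.method = "first")
  row_max <- data.frame(id = rownames(tc),
                        max_tc = tc[cbind(seq_len(nrow(tc)), best)],
                        best_match = colnames(tc)[best],
                        stringsAsFactors = FALSE)
  ident <- which(tc >= 1, arr.ind = TRUE)
  identical_pairs <- data.frame(a = rownames(tc)[ident[, 1]],
                                b = colnames(tc)[ident[, 2]],
                                stringsAsFactors = FALSE)
  list(matrix = tc, row_max = row_max, identical_pairs = identical_pairs)
}

#' Serialize a fragment set as SMI plus a JSON provenance sidecar
#'
#' @param fs A \code{"fragment_set"}.
#' @param path SMI output path; provenance goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_fragment_set <- function(fs, path) {
  write_smiles_library(fs$fragments, path)
  jsonlite::write_json(fs$provenance, paste0(path, ".json"))
  invisible(path)
}
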