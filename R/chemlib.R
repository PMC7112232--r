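# Chemical I/O and descriptor layer. SMILES parsing, canonicalisation,
# physico-chemical descriptors and FP2 path fingerprints are delegated to
# OpenBabel through ChemmineOB/ChemmineR; a small set of connectivity
# descriptors is derived from the canonical SMILES / molecular graph.

LIPINSKI_DESCRIPTORS <- c("MW", "logP", "HBD", "HBA")

#' Descriptor specification
#'
#' An ordered set of descriptor names. The four Lipinski descriptors --
#' molecular weight (Da), computed logP, H-bond donor count and H-bond
#' acceptor count -- are always required. The counting convention is:
#' donors = number of N and O atoms bearing at least one hydrogen,
#' acceptors = number of N and O atoms (conventions differ between
#' toolkits; this one is stated so models are only comparable under the
#' same spec).
#'
#' @param names Character vector of descriptor names.
#' @return Character vector of class \code{"descriptor_spec"}.
#' @export
descriptor_spec <- function(names = default_descriptor_names()) {
  if (anyDuplicated(names)) stop("descriptor names must be unique")
  miss <- setdiff(LIPINSKI_DESCRIPTORS, names)
  if (length(miss))
    stop("descriptor spec must include the Lipinski four; missing: ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names, default_descriptor_names())
  if (length(unknown))
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "))
  structure(names, class = "descriptor_spec")
}

#' Names of all descriptors this package can compute
#' @return Character vector.
#' @export
default_descriptor_names <- function() {
  c("MW", "logP", "HBD", "HBA", "TPSA", "MR", "nF",
    "heavy_atoms", "n_bonds", "n_rings", "n_aromatic_atoms",
    "n_rotatable_bonds", "n_C", "n_N", "n_O", "n_S", "n_halogen",
    "frac_aromatic", "frac_hetero", "mean_degree")
}

# ---- SMILES parsing -------------------------------------------------------

ob_props <- function(smiles, ids = NULL) {
  # One row per molecule (cansmi + OpenBabel property block); errors if any
  # SMILES fails to parse, so validate first for mixed-quality input.
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  txt <- paste(paste(smiles, ids), collapse = "\n")
  res <- ChemmineOB::forEachMol("SMILES", txt, function(m)
    ChemmineOB::prop_OB(m))
  do.call(rbind, res)
}

#' Is each SMILES parsable?
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    ok <- TRUE
    tryCatch(suppressWarnings(ob_props(s)),
             error = function(e) ok <<- FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical SMILES
#'
#' OpenBabel canonical form; canonicalisation is idempotent
#' (canonicalising a canonical SMILES returns it unchanged).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  ob_props(smiles)$cansmi
}

#' Read a SMILES library from an SMI or CSV file
#'
#' SMI files have one molecule per line: whitespace-separated SMILES plus an
#' optional identifier. CSV files need columns \code{smiles} and optionally
#' \code{id}. Identifiers are auto-generated as \code{mol_<line>} (1-based)
#' when absent. Unparsable records are reported with their line numbers and
#' skipped, or are fatal under \code{strict = TRUE}.
#'
#' @param path File path.
#' @param format \code{"smi"} or \code{"csv"} (default guessed from the
#'   extension).
#' @param strict Fail on any unparsable record or duplicated id.
#' @return Data frame with columns \code{id}, \code{smiles}; skipped line
#'   numbers in attribute \code{"skipped"}.
#' @export
read_smiles_library <- function(path, format = c("auto", "smi", "csv"),
                                strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    parts <- strsplit(trimws(lines[keep]), "\\s+")
    smi <- vapply(parts, `[[`, character(1), 1)
    id <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else
        paste0("mol_", lineno[i]), character(1))
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(tab)) stop("csv needs a 'smiles' column")
    smi <- tab$smiles
    id <- if ("id" %in% names(tab)) as.character(tab$id) else
      paste0("mol_", seq_along(smi))
    lineno <- seq_along(smi) + 1L
  }
  ok <- smiles_is_valid(smi)
  if (any(!ok)) {
    msg <- paste0("unparsable SMILES at line(s) ",
                  paste(lineno[!ok], collapse = ", "))
    if (strict) stop(msg)
    message(msg, " - skipped")
  }
  id <- id[ok]; smi <- smi[ok]
  if (!length(smi)) stop("zero parsable records in ", path)
  if (anyDuplicated(id)) {
    if (strict) stop("duplicate ids: ",
                     paste(unique(id[duplicated(id)]), collapse = ", "))
    warning("duplicate ids present (kept as-is)")
  }
  out <- data.frame(id = id, smiles = smi, stringsAsFactors = FALSE)
  attr(out, "skipped") <- lineno[!ok]
  out
}

#' Write an SMI file
#' @param lib Data frame with \code{id}, \code{smiles}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_smiles_library <- function(lib, path) {
  writeLines(paste(lib$smiles, lib$id), path)
  invisible(path)
}

# ---- SMILES token statistics ---------------------------------------------

# Counts of heavy atoms / elements / aromatic atoms / rings from a canonical
# SMILES string; used for the connectivity descriptors.
smiles_atom_stats <- function(smiles) {
  s <- smiles
  # bracket atoms first
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  s_rest <- gsub("\\[[^]]*\\]", "", s)
  elt <- character(); arom <- logical()
  for (b in brackets) {
    sym <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", b)
    if (toupper(sym) == "H") next  # explicit hydrogen: not a heavy atom
    # two-letter symbols keep their case ("Se", "se"); one-letter aromatic
    # atoms are lower case
    arom <- c(arom, substr(sym, 1, 1) %in% letters)
    elt <- c(elt, toupper(substr(sym, 1, 1)))
  }
  toks <- regmatches(s_rest,
                     gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", s_rest))[[1]]
  for (t in toks) {
    arom <- c(arom, t %in% c("b", "c", "n", "o", "p", "s"))
    elt <- c(elt, toupper(substr(t, 1, 1)))
  }
  halogens <- sum(elt %in% c("F", "I")) +
    length(grep("Cl|Br", c(brackets, toks)))
  # ring-closure bond count: digits and %nn outside brackets, paired
  closures <- regmatches(s_rest, gregexpr("%[0-9]{2}|[0-9]", s_rest))[[1]]
  n_comp <- length(strsplit(s, ".", fixed = TRUE)[[1]])
  heavy <- length(elt)
  n_rings <- length(closures) / 2
  n_bonds <- heavy - n_comp + n_rings
  list(heavy = heavy, n_C = sum(elt == "C"), n_N = sum(elt == "N"),
       n_O = sum(elt == "O"), n_S = sum(elt == "S"), n_halogen = halogens,
       n_aromatic = sum(arom), n_rings = n_rings, n_bonds = n_bonds)
}

# Rotatable bonds: acyclic single bonds between two heavy atoms that each
# carry at least two heavy neighbours. Computed from the SDF connection
# table; molecules without bonds have none.
count_rotatable_bonds <- function(smiles, id = "m1") {
  st <- smiles_atom_stats(smiles)
  if (st$n_bonds < 1) return(0)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, id)))
  if (!ChemmineR::validSDF(sdf)) return(0)
  bb <- ChemmineR::bondblock(sdf[[1]])
  g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2]), directed = FALSE)
  deg <- igraph::degree(g)
  br <- igraph::bridges(g)  # acyclic (non-ring) bonds
  is_bridge <- rep(FALSE, nrow(bb))
  is_bridge[br] <- TRUE
  sum(bb[, 3] == 1 & is_bridge & deg[bb[, 1]] >= 2 & deg[bb[, 2]] >= 2)
}

#' Compute descriptors for a molecule library
#'
#' Physico-chemical descriptors (MW, logP, donor/acceptor counts, TPSA,
#' molar refractivity, fluorine count) come from OpenBabel; connectivity
#' descriptors (atom/bond/ring counts, aromatic fraction, rotatable bonds)
#' are derived from the canonical SMILES and the connection table. All
#' values are finite for valid molecules and deterministic for a fixed
#' toolkit version.
#'
#' @param lib Data frame with \code{id}, \code{smiles} (see
#'   \code{\link{read_smiles_library}}), or a character vector of SMILES.
#' @param spec A \code{\link{descriptor_spec}}.
#' @return \code{lib} with one numeric column per descriptor appended and
#'   \code{smiles} replaced by its canonical form.
#' @export
compute_descriptors <- function(lib, spec = descriptor_spec()) {
  if (is.character(lib))
    lib <- data.frame(id = paste0("mol_", seq_along(lib)), smiles = lib,
                      stringsAsFactors = FALSE)
  props <- ob_props(lib$smiles, lib$id)
  can <- props$cansmi
  stats <- lapply(can, smiles_atom_stats)
  pick <- function(f) vapply(stats, function(s) as.numeric(s[[f]]), numeric(1))
  heavy <- pick("heavy"); nb <- pick("n_bonds"); narom <- pick("n_aromatic")
  nC <- pick("n_C")
  # HBA follows the documented convention (count of N and O atoms); HBD is
  # OpenBabel's donor count (N/O atoms bearing at least one hydrogen)
  all_desc <- data.frame(
    MW = props$MW, logP = props$logP, HBD = props$HBD,
    HBA = pick("n_N") + pick("n_O"),
    TPSA = props$TPSA, MR = props$MR, nF = props$nF,
    heavy_atoms = heavy, n_bonds = nb, n_rings = pick("n_rings"),
    n_aromatic_atoms = narom,
    n_rotatable_bonds = mapply(count_rotatable_bonds, can, lib$id),
    n_C = nC, n_N = pick("n_N"), n_O = pick("n_O"), n_S = pick("n_S"),
    n_halogen = pick("n_halogen"),
    frac_aromatic = ifelse(heavy > 0, narom / heavy, 0),
    frac_hetero = ifelse(heavy > 0, (heavy - nC) / heavy, 0),
    mean_degree = ifelse(heavy > 0, 2 * nb / heavy, 0))
  bad <- !vapply(all_desc, is.finite, logical(nrow(all_desc)))
  if (any(bad)) stop("non-finite descriptor values computed")
  out <- data.frame(id = lib$id, smiles = can, stringsAsFactors = FALSE)
  cbind(out, all_desc[, as.character(spec), drop = FALSE])
}

# ---- fingerprints ---------------------------------------------------------

#' Fingerprint configuration
#'
#' The default is the OpenBabel FP2 path fingerprint (linear fragments up to
#' 7 atoms hashed to 1024 bits). \code{kind = "circular"} selects an ECFP
#' circular fingerprint where the OpenBabel build provides one. Fingerprints
#' longer than \code{n_bits} are folded by OR-ing bit \code{i} onto
#' \code{i mod n_bits}.
#'
#' @param kind \code{"path"} or \code{"circular"}.
#' @param n_bits Bitset length, at least 64.
#' @param param Path length (path kind) or radius*2 (circular kind);
#'   informational for the OpenBabel-backed kinds, which fix these.
#' @return List of class \code{"fingerprint_config"}.
#' @export
fingerprint_config <- function(kind = c("path", "circular"), n_bits = 1024,
                               param = if (match.arg(kind) == "path") 7 else 4) {
  kind <- match.arg(kind)
  stopifnot(n_bits >= 64)
  structure(list(kind = kind, n_bits = as.integer(n_bits), param = param),
            class = "fingerprint_config")
}

fold_fp <- function(m, n_bits) {
  if (ncol(m) == n_bits) return(m)
  if (ncol(m) < n_bits)
    stop("n_bits exceeds the native fingerprint length (", ncol(m), ")")
  out <- matrix(FALSE, nrow(m), n_bits)
  for (j in seq_len(ncol(m)))
    out[, ((j - 1) %% n_bits) + 1] <- out[, ((j - 1) %% n_bits) + 1] | m[, j]
  out
}

#' Compute fingerprints for a molecule library
#'
#' @param lib Data frame with \code{id}, \code{smiles}, or a character
#'   vector of SMILES.
#' @param cfg A \code{\link{fingerprint_config}}.
#' @return Logical matrix, one row per molecule (rownames = ids). Molecules
#'   without bonds (single heavy atoms) have no paths and get all-zero rows.
#' @export
compute_fingerprints <- function(lib, cfg = fingerprint_config()) {
  if (is.character(lib))
    lib <- data.frame(id = paste0("mol_", seq_along(lib)), smiles = lib,
                      stringsAsFactors = FALSE)
  fpname <- switch(cfg$kind, path = "FP2", circular = "ECFP4")
  out <- matrix(FALSE, nrow(lib), cfg$n_bits,
                dimnames = list(lib$id, NULL))
  if (!nrow(lib)) return(out)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(lib$smiles, lib$id)))
  valid <- ChemmineR::validSDF(sdf)
  if (any(valid)) {
    fp <- tryCatch(ChemmineR::fingerprintOB(sdf[valid], fpname),
                   error = function(e)
                     stop("fingerprint kind '", cfg$kind,
                          "' (", fpname, ") unavailable: ",
                          conditionMessage(e)))
    m <- fp@fpma > 0
    out[which(valid), ] <- fold_fp(m, cfg$n_bits)
  }
  out
}

#' Tanimoto coefficient of two bitsets
#'
#' \code{|intersection| / |union|}; symmetric, 1 for identical non-empty
#' bitsets, and defined as 0 (with a warning) when both bitsets are empty.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Numeric in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bitset length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both bitsets empty: Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Pairwise Tanimoto matrix between two fingerprint sets
#'
#' @param A,B Logical matrices (rows = molecules) with equal column counts;
#'   \code{B} defaults to \code{A}.
#' @return Numeric matrix \code{nrow(A) x nrow(B)} of Tanimoto coefficients
#'   (0 where both rows are empty).
#' @export
tanimoto_matrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stop("bitset length mismatch")
  Ai <- matrix(as.numeric(A), nrow(A)); Bi <- matrix(as.numeric(B), nrow(B))
  inter <- Ai %*% t(Bi)
  uni <- outer(rowSums(Ai), rowSums(Bi), "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  dimnames(tc) <- list(rownames(A), rownames(B))
  tc
}
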