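# Bridge to the OpenBabel toolkit (via ChemmineR/ChemmineOB and the obabel
# CLI). Everything downstream talks SMILES or SDFset; this file is the only
# place that knows how molecules are parsed, canonicalized and matched.

# ChemmineOB's exported smartsSearch_OB is unusable in some builds, so the
# SWIG-level OBSmartsPattern bindings are fetched lazily from its namespace.
.ob <- new.env(parent = emptyenv())

.ob_fun <- function(name) {
  if (is.null(.ob[[name]])) {
    .ob[[name]] <- utils::getFromNamespace(name, "ChemmineOB")
  }
  .ob[[name]]
}

.obabel_bin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) stop("the 'obabel' executable is required but not on PATH")
  bin
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Strings that cannot be parsed
#' (syntax errors, unmatched ring bonds, bad valence blocks) yield `NA` rather
#' than an error, so callers can count validity.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` where the input is not a
#'   valid SMILES.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "C1CC"))  # "CCO", NA
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[ \t]", smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles[idx], seq_along(idx)), fin)
  system2(.obabel_bin(), c(fin, "-ocan", "-e", "-O", fout),
          stdout = FALSE, stderr = FALSE)
  res <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  res <- res[nzchar(res)]
  if (length(res)) {
    parts <- regmatches(res, regexpr("\t", res), invert = TRUE)
    can <- vapply(parts, `[[`, "", 1L)
    id <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) > 1L) p[[2L]] else NA_character_, "")))
    keep <- !is.na(id) & nzchar(can)
    out[idx[id[keep]]] <- can[keep]
  }
  out
}

#' Test SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector: can each string be parsed into a molecule?
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

# Parse valid SMILES into a ChemmineR SDFset. Errors on invalid input; callers
# are expected to have filtered through canonicalize_smiles() first.
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  nm <- names(smiles)
  if (is.null(nm)) nm <- paste0("M", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nm))),
    error = function(e) stop("failed to parse SMILES: ", conditionMessage(e)))
  # single-atom molecules come back with a mangled atom block; rebuild it
  for (i in seq_along(smiles)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    if (is.matrix(ab) && ncol(ab) >= 3L) next
    tk <- tokenize_smiles(smiles[i])[[1]]
    atom_tk <- tk[grepl("^\\[|^[A-Za-z]", tk)][1L]
    el <- if (startsWith(atom_tk, "[")) {
      regmatches(atom_tk, regexpr("[A-Za-z][a-z]?", atom_tk))
    } else {
      atom_tk
    }
    el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
    chg_txt <- regmatches(atom_tk, regexpr("[+-]+[0-9]*", atom_tk))
    chg <- if (length(chg_txt) == 0L) 0L else {
      sgn <- if (startsWith(chg_txt, "-")) -1L else 1L
      num <- suppressWarnings(as.integer(gsub("[+-]", "", chg_txt)))
      if (is.na(num) || num == 0L) num <- nchar(gsub("[0-9]", "", chg_txt))
      sgn * num
    }
    code <- if (chg == 0L) 0L else if (chg > 0L) 4L - chg else 4L - chg
    ab2 <- matrix(0, 1L, 15L,
                  dimnames = list(paste0(el, "_1"),
                                  c("C1", "C2", "C3", paste0("C", 5:16))))
    ab2[1L, "C6"] <- code
    mol <- sdf[[i]]
    mol@atomblock <- ab2
    mol@bondblock <- matrix(integer(), 0L, 7L)
    hd <- mol@header
    hd[["Counts_Line"]] <- "  1  0  0  0  0  0  0  0  0  0999 V2000"
    mol@header <- hd
    mol@obmolRef <- sdf_to_obmol(mol)
    sdf@SDF[[i]] <- mol
  }
  sdf
}

# Compiled SMARTS pattern handle.
smarts_pattern <- function(smarts) {
  sp <- .ob_fun("OBSmartsPattern")()
  if (!.ob_fun("OBSmartsPattern_Init")(sp, smarts)) {
    stop("invalid SMARTS pattern: ", smarts)
  }
  sp
}

# Unique SMARTS matches for one OBMol; list of integer atom-index vectors
# (1-based OpenBabel atom indices), empty list when there is no match.
smarts_match_one <- function(sp, mol) {
  hit <- .ob_fun("OBSmartsPattern_Match__SWIG_1")(sp, mol)
  if (!isTRUE(hit)) return(list())
  .ob_fun("OBSmartsPattern_GetUMapList")(sp)
}

# Build an OBMol directly from our own molfile serialization (the stock
# SDF serializer cannot round-trip every molecule we construct).
sdf_to_obmol <- function(sdf) {
  conv <- .ob_fun("OBConversion")()
  .ob_fun("OBConversion_SetInFormat")(conv, "SDF")
  mol <- .ob_fun("OBMol")()
  if (!.ob_fun("OBConversion_ReadString")(conv, mol, sdf_as_string(sdf))) {
    stop("failed to rebuild molecule from SDF blocks")
  }
  mol
}

# OBMol handles for every molecule of an SDFset, preferring the cached
# reference when the molecule was parsed by the toolkit itself.
obmol_handles <- function(sdf) {
  lapply(ChemmineR::SDFset2SDF(sdf), function(m) {
    if (!is.null(m@obmolRef)) m@obmolRef else sdf_to_obmol(m)
  })
}

# Match a SMARTS against every molecule of an SDFset.
# Returns a list (one per molecule) of integer-vector matches.
smarts_match_sdf <- function(sdf, smarts) {
  sp <- smarts_pattern(smarts)
  mols <- obmol_handles(sdf)
  lapply(mols, function(m) smarts_match_one(sp, m))
}

# Does each molecule of the SDFset contain the SMARTS?
smarts_hit_sdf <- function(sdf, smarts) {
  vapply(smarts_match_sdf(sdf, smarts), function(x) length(x) > 0L, logical(1))
}

# Rebuild an SDF molecule with atoms reordered/subset. `order` is a vector of
# old atom indices defining the new order; bonds with an endpoint outside
# `order` are dropped. Charges travel with the atomblock rows.
sdf_reindex_atoms <- function(sdf, order) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  stopifnot(all(order >= 1L), all(order <= n), !anyDuplicated(order))
  ab2 <- ab[order, , drop = FALSE]
  rownames(ab2) <- paste(sub("_.*", "", rownames(ab)[order]),
                         seq_along(order), sep = "_")
  newpos <- integer(n)
  newpos[order] <- seq_along(order)
  keep <- bb[, 1L] %in% order & bb[, 2L] %in% order
  bb2 <- bb[keep, , drop = FALSE]
  if (nrow(bb2)) {
    bb2[, 1L] <- newpos[bb2[, 1L]]
    bb2[, 2L] <- newpos[bb2[, 2L]]
    rownames(bb2) <- seq_len(nrow(bb2))
  }
  out <- sdf
  out@atomblock <- ab2
  out@bondblock <- bb2
  hd <- out@header
  hd[["Counts_Line"]] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 nrow(ab2), nrow(bb2))
  out@header <- hd
  out
}

# Serialize a single SDF object to an sd-file (V2000) string. Written by
# hand because the stock serializer mishandles one-atom molecules.
sdf_as_string <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*", "", rownames(ab))
  chg <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                   ab[, 1L], ab[, 2L], 0, el, as.integer(chg))
  bonds <- if (nrow(bb)) {
    sprintf("%3d%3d%3d  0  0  0  0", as.integer(bb[, 1L]),
            as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  } else {
    character()
  }
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(ab), nrow(bb))
  paste(c("", "  inertforge", "", counts, atoms, bonds, "M  END", "$$$$", ""),
        collapse = "\n")
}

# Convert a single SDF object to a SMILES string. `canonical` selects the
# canonical writer; otherwise the output follows the stored atom order, which
# is what SMILES augmentation exploits.
sdf_to_smiles <- function(sdf, canonical = FALSE) {
  out <- suppressWarnings(ChemmineOB::convertFormat(
    "SDF", if (canonical) "CAN" else "SMI", sdf_as_string(sdf)))
  out <- sub("[\t\n ].*", "", out)
  if (!nzchar(out)) NA_character_ else out
}

# Element symbols of an SDF molecule, in atom order.
sdf_elements <- function(sdf) {
  sub("_.*", "", rownames(ChemmineR::atomblock(sdf)))
}

# Bond table of an SDF molecule: from, to, order columns.
sdf_bonds <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  if (!is.matrix(bb)) bb <- matrix(bb, nrow = NROW(bb))
  if (nrow(bb) == 0L || ncol(bb) < 3L) {
    return(matrix(integer(), ncol = 3L,
                  dimnames = list(NULL, c("from", "to", "order"))))
  }
  cbind(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
        order = as.integer(bb[, 3L]))
}
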