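# Molecular profiling: physicochemical descriptors, rule-of-five and PAINS
# screening, hashed circular fingerprints with Tanimoto similarity, Murcko
# scaffolds, BRICS-style fragmentation, and scaffold enrichment between two
# compound sets.

#' Physicochemical property records
#'
#' Computes molecular weight, an atomic-contribution logP estimate, TPSA and
#' Lipinski-style hydrogen-bond donor/acceptor counts (acceptors counted as N
#' plus O) for each molecule.
#'
#' @param smiles Character vector of valid SMILES.
#' @return A `data.frame` with columns `smiles`, `mw`, `logp`, `tpsa`, `hbd`,
#'   `hba`; the logP estimator name is attached as attribute `logp_estimator`.
#' @export
compute_properties <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    stop("invalid structure(s): ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  sdf <- parse_smiles(can)
  p <- suppressWarnings(ChemmineR::propOB(sdf))
  out <- data.frame(smiles = smiles,
                    mw = as.numeric(p$MW),
                    logp = as.numeric(p$logP),
                    tpsa = as.numeric(p$TPSA),
                    hbd = as.integer(p$HBD),
                    hba = as.integer(p$HBA2),
                    stringsAsFactors = FALSE)
  attr(out, "logp_estimator") <- "OpenBabel atomic-contribution logP"
  out
}

#' Rule-of-five compliance
#'
#' Zero-violation Lipinski rule by default: MW <= 500, logP <= 5, donors
#' <= 5, acceptors <= 10 (boundaries inclusive). `max_violations = 1` gives
#' the common one-violation relaxation.
#'
#' @param props Property `data.frame` from [compute_properties()] (or any
#'   frame with `mw`, `logp`, `hbd`, `hba`).
#' @param max_violations Number of rule violations tolerated.
#' @return Logical vector.
#' @export
ro5_compliant <- function(props, max_violations = 0L) {
  stopifnot(is.data.frame(props))
  v <- (props$mw > 500) + (props$logp > 5) + (props$hbd > 5) +
    (props$hba > 10)
  v <= max_violations
}

# ---- PAINS ------------------------------------------------------------------

.pains_cache <- new.env(parent = emptyenv())

#' Load a PAINS pattern catalog
#'
#' Reads a TSV catalog of SMARTS patterns for pan-assay interference
#' substructures. The bundled catalog is a representative subset of the
#' published PAINS families (quinones, catechols, rhodanines, hydrazones,
#' azo dyes, ...); a full catalog in the same three-column format
#' (name, family, smarts) can be supplied instead.
#'
#' @param path Catalog file; defaults to the bundled subset.
#' @return A `data.frame` with columns `name`, `family`, `smarts`.
#' @export
pains_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pains-subset.tsv", package = "inertforge",
                        mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]  # "#" also occurs inside SMARTS
  utils::read.table(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

#' Flag pan-assay interference compounds
#'
#' Substructure-matches every catalog pattern against every molecule.
#'
#' @param smiles Character vector of valid SMILES.
#' @param catalog PAINS catalog `data.frame` (see [pains_catalog()]).
#' @return Logical vector: does any PAINS pattern match?
#' @export
pains_flag <- function(smiles, catalog = pains_catalog()) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    stop("invalid structure(s): ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  sdf <- parse_smiles(can)
  mols <- obmol_handles(sdf)
  hit <- rep(FALSE, length(mols))
  for (k in seq_len(nrow(catalog))) {
    sp <- smarts_pattern(catalog$smarts[k])
    todo <- which(!hit)
    if (length(todo) == 0L) break
    for (i in todo) {
      if (length(smarts_match_one(sp, mols[[i]]))) hit[i] <- TRUE
    }
  }
  hit
}

# ---- fingerprints -----------------------------------------------------------

#' Hashed circular fingerprints
#'
#' Extended-connectivity fingerprints of the given radius (radius 2 is the
#' conventional reading of "ECFP4": diameter four bond steps), folded to
#' `n_bits` bits.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Circular neighborhood radius in bonds (diameter/2).
#' @param n_bits Folded fingerprint length.
#' @return Binary integer matrix, one row per molecule, with attributes
#'   `radius` and `n_bits`.
#' @export
.hex_bits <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      m <- t(vapply(0:15, function(v) {
        as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L))
      }, integer(4)))
      rownames(m) <- c(0:9, letters[1:6])
      tab <<- m
    }
    tab
  }
})

ecfp <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            radius >= 0L, n_bits >= 8L)
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    stop("invalid structure(s): ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  type <- paste0("ECFP", 2L * as.integer(radius))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".fps")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(can, seq_along(can)), fin)
  system2(.obabel_bin(), c(fin, "-ofps", paste0("-xf", type),
                           "-xN", n_bits, "-O", fout),
          stdout = FALSE, stderr = FALSE)
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- as.integer(vapply(parts, `[[`, "", 2L))
  hx <- tolower(vapply(parts, `[[`, "", 1L))
  if (length(ids) != length(can) || anyNA(ids)) {
    stop("fingerprint generation failed for ",
         length(can) - sum(!is.na(ids)), " molecule(s)")
  }
  tab <- .hex_bits()
  m <- matrix(0L, length(can), n_bits)
  for (i in seq_along(hx)) {
    chars <- strsplit(hx[i], "", fixed = TRUE)[[1]]
    m[ids[i], ] <- as.integer(t(tab[chars, , drop = FALSE]))[seq_len(n_bits)]
  }
  rownames(m) <- names(smiles)
  structure(m, radius = as.integer(radius), n_bits = as.integer(n_bits))
}

#' Tanimoto coefficient of two fingerprints
#'
#' Shared on-bits over union of on-bits. Two all-zero fingerprints have, by
#' convention, similarity 0.
#'
#' @param a,b Binary vectors of equal length (e.g. rows of an [ecfp()]
#'   matrix).
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a != 0)
  b <- as.integer(b != 0)
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

# All-pairs Tanimoto between two binary matrices (rows = molecules).
.tanimoto_cross <- function(qm, rm) {
  qm <- matrix(as.numeric(qm != 0), nrow = nrow(qm))
  rm <- matrix(as.numeric(rm != 0), nrow = nrow(rm))
  inter <- qm %*% t(rm)
  uni <- outer(rowSums(qm), rowSums(rm), "+") - inter
  tc <- inter / uni
  tc[uni == 0] <- 0
  tc
}

#' Nearest-neighbor Tanimoto similarity
#'
#' For each query molecule, the maximum Tanimoto coefficient against every
#' reference molecule.
#'
#' @param queries,reference Character vectors of valid SMILES, or binary
#'   fingerprint matrices from [ecfp()].
#' @param ... Passed to [ecfp()] when SMILES are given.
#' @return Numeric vector, one value per query.
#' @export
nearest_neighbor_tc <- function(queries, reference, ...) {
  if (is.character(reference) && length(reference) == 0L ||
      is.matrix(reference) && nrow(reference) == 0L) {
    stop("reference set is empty")
  }
  qm <- if (is.matrix(queries)) queries else ecfp(queries, ...)
  rm_ <- if (is.matrix(reference)) reference else ecfp(reference, ...)
  if (ncol(qm) != ncol(rm_)) stop("fingerprint length mismatch")
  apply(.tanimoto_cross(qm, rm_), 1L, max)
}

# ---- scaffolds and fragments ------------------------------------------------

# Atoms retained by iterative removal of terminal atoms: the molecule's ring
# systems plus the linkers between them. Exocyclic atoms attached through
# multiple bonds (e.g. carbonyl oxygens on a linker) are retained too.
.scaffold_atom_set <- function(n_atoms, bonds) {
  if (n_atoms == 0L || nrow(bonds) == 0L) return(integer())
  alive <- rep(TRUE, n_atoms)
  repeat {
    deg <- tabulate(c(bonds[alive[bonds[, 1L]] & alive[bonds[, 2L]], 1L],
                      bonds[alive[bonds[, 1L]] & alive[bonds[, 2L]], 2L]),
                    nbins = n_atoms)
    leaves <- which(alive & deg <= 1L)
    if (length(leaves) == 0L) break
    alive[leaves] <- FALSE
    if (!any(alive)) break
  }
  core <- which(alive)
  if (length(core) == 0L) return(integer())
  # re-attach multiply-bonded exocyclic atoms
  extra <- integer()
  for (r in seq_len(nrow(bonds))) {
    if (bonds[r, "order"] >= 2L) {
      a <- bonds[r, 1L]; b <- bonds[r, 2L]
      if (a %in% core && !(b %in% core)) extra <- c(extra, b)
      if (b %in% core && !(a %in% core)) extra <- c(extra, a)
    }
  }
  sort(unique(c(core, extra)))
}

#' Murcko scaffolds
#'
#' The ring systems of each molecule plus the linkers connecting them, side
#' chains removed (exocyclic multiply-bonded atoms are kept). Acyclic
#' molecules have no scaffold and map to the empty string.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    stop("invalid structure(s): ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  sdf <- parse_smiles(can)
  vapply(seq_along(can), function(i) {
    mol <- sdf[[i]]
    bonds <- sdf_bonds(mol)
    n <- nrow(ChemmineR::atomblock(mol))
    keep <- .scaffold_atom_set(n, bonds)
    if (length(keep) == 0L) return("")
    s <- sdf_to_smiles(sdf_reindex_atoms(mol, keep), canonical = TRUE)
    if (is.na(s)) "" else s
  }, character(1))
}

# BRICS link environments (Degen et al. retrosynthetic rules) and the bond
# compatibility table. An environment SMARTS matches with the attachment atom
# first; a cleavable bond joins two compatible environment atoms through an
# acyclic bond of the stated order.
.brics_environs <- c(
  "1" = "[C;D3]([#6,#7,#8])(=O)",
  "3" = "[O;D2]-;!@[#6]",
  "4" = "[C;!D1;!$(C=*)]-;!@[#6]",
  "5" = "[N;!D1;!$(N=*);!$(N-[!#6;!#16]);!$([N;R]@[C;R]=O)]",
  "6" = "[C;D3;!R](=O)-;!@[#6,#7,#8]",
  "7" = "[C;D2,D3]-[#6]",
  "8" = "[C;!R;!D1;!$(C!-*)]",
  "9" = "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
  "10" = "[N;R;$(N(@C(=O))@[C,N,O,S])]",
  "11" = "[S;D2](-;!@[#6])",
  "12" = "[S;D4]([#6])(=O)(=O)",
  "13" = "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
  "14" = "[c;$(c(:[c,n,o,s]):[n,o,s])]",
  "15" = "[C;$(C(-;@C)-;@C)]",
  "16" = "[c;$(c(:c):c)]")

.brics_pairs <- rbind(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16), c(16, 16))

# Is each bond part of a ring? (removal keeps endpoints connected)
.ring_bonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical())
  adj <- lapply(seq_len(n_atoms), function(i) integer())
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    adj[[a]] <- c(adj[[a]], r)
    adj[[b]] <- c(adj[[b]], r)
  }
  vapply(seq_len(nrow(bonds)), function(r) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    seen <- rep(FALSE, n_atoms)
    seen[a] <- TRUE
    queue <- a
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (rr in adj[[u]]) {
        if (rr == r) next
        v <- if (bonds[rr, 1L] == u) bonds[rr, 2L] else bonds[rr, 1L]
        if (!seen[v]) {
          if (v == b) return(TRUE)
          seen[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' BRICS-style fragmentation
#'
#' Cleaves every bond joining two compatible retrosynthetic link environments
#' (acyclic single bonds, following the published BRICS rule table) and
#' returns the canonical SMILES of the resulting fragments. Attachment points
#' are not marked with dummy atoms; fragments are compared as plain
#' structures.
#'
#' @param smiles Character vector of valid SMILES.
#' @return List of character vectors, one per molecule (the whole molecule
#'   when no bond is cleavable).
#' @export
brics_fragments <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    stop("invalid structure(s): ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  sdf <- parse_smiles(can)
  mols <- obmol_handles(sdf)
  pats <- lapply(.brics_environs, smarts_pattern)
  lapply(seq_along(can), function(i) {
    mol <- sdf[[i]]
    obm <- mols[[i]]
    bonds <- sdf_bonds(mol)
    n <- nrow(ChemmineR::atomblock(mol))
    if (nrow(bonds) == 0L) return(can[i])
    env_atoms <- lapply(pats, function(sp) {
      mm <- smarts_match_one(sp, obm)
      unique(vapply(mm, `[[`, 0L, 1L))
    })
    in_ring <- .ring_bonds(n, bonds)
    cut <- logical(nrow(bonds))
    for (r in seq_len(nrow(bonds))) {
      if (in_ring[r]) next
      a <- bonds[r, 1L]; b <- bonds[r, 2L]
      if (bonds[r, "order"] == 2L) {
        # the lone double-bond rule: alkene carbons in matching environments
        if (a %in% env_atoms[["7"]] && b %in% env_atoms[["7"]]) {
          cut[r] <- TRUE
        }
        next
      }
      if (bonds[r, "order"] != 1L) next
      for (p in seq_len(nrow(.brics_pairs))) {
        e1 <- as.character(.brics_pairs[p, 1L])
        e2 <- as.character(.brics_pairs[p, 2L])
        if ((a %in% env_atoms[[e1]] && b %in% env_atoms[[e2]]) ||
            (b %in% env_atoms[[e1]] && a %in% env_atoms[[e2]])) {
          cut[r] <- TRUE
          break
        }
      }
    }
    if (!any(cut)) return(can[i])
    keep_bonds <- bonds[!cut, , drop = FALSE]
    comp <- rep(0L, n)
    nc <- 0L
    for (s in seq_len(n)) {
      if (comp[s] != 0L) next
      nc <- nc + 1L
      comp[s] <- nc
      queue <- s
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        for (r in seq_len(nrow(keep_bonds))) {
          v <- if (keep_bonds[r, 1L] == u) keep_bonds[r, 2L]
          else if (keep_bonds[r, 2L] == u) keep_bonds[r, 1L]
          else next
          if (comp[v] == 0L) {
            comp[v] <- nc
            queue <- c(queue, v)
          }
        }
      }
    }
    frags <- vapply(seq_len(nc), function(k) {
      s <- sdf_to_smiles(sdf_reindex_atoms(mol, which(comp == k)),
                         canonical = TRUE)
      if (is.na(s)) "" else s
    }, character(1))
    frags[nzchar(frags)]
  })
}

#' Scaffold enrichment between two compound sets
#'
#' Extracts the Murcko scaffold of every molecule in both sets and tests each
#' scaffold's presence/absence split across sets with a chi-squared test on
#' the 2x2 table (1 df, no continuity correction), adjusting p-values across
#' scaffolds. Scaffolds with a degenerate margin (present in every molecule
#' of both sets, or absent everywhere) are reported with statistic 0 and
#' never flagged.
#'
#' @param set_a,set_b Character vectors of valid SMILES.
#' @param alpha Significance level applied to adjusted p-values.
#' @param adjust Multiple-testing adjustment method (see
#'   [stats::p.adjust()]); `"none"` gives raw-p mode.
#' @return A `data.frame` with one row per scaffold: counts in both sets,
#'   `chi2`, `p`, `q`, and `enriched_in` (`"A"`, `"B"` or `NA`).
#' @export
scaffold_enrichment <- function(set_a, set_b, alpha = 0.05, adjust = "BH") {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both compound sets must be non-empty")
  }
  sa <- murcko_scaffold(set_a)
  sb <- murcko_scaffold(set_b)
  keys <- sort(unique(c(sa, sb)))
  na <- length(sa)
  nb <- length(sb)
  rows <- lapply(keys, function(k) {
    a1 <- sum(sa == k); b1 <- sum(sb == k)
    tab <- matrix(c(a1, na - a1, b1, nb - b1), nrow = 2L)
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    if (degenerate) {
      chi2 <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic)
      p <- ct$p.value
      if (!is.finite(chi2)) { chi2 <- 0; p <- 1 }
    }
    data.frame(scaffold = k, count_a = a1, count_b = b1,
               chi2 = chi2, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = adjust)
  prop_a <- out$count_a / na
  prop_b <- out$count_b / nb
  out$enriched_in <- ifelse(out$q <= alpha & out$chi2 > 0,
                            ifelse(prop_a > prop_b, "A", "B"), NA)
  out
}

# ---- classification metrics -------------------------------------------------

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("confusion counts must be non-negative")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention of 0 when any denominator factor vanishes.
#'
#' @param c A `confusion_counts` object (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Balanced accuracy
#'
#' Mean of true positive rate and true negative rate.
#'
#' @inheritParams mcc
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(c) {
  if (c$tp + c$fn < 1 || c$tn + c$fp < 1) {
    stop("balanced accuracy needs at least one observation of each class")
  }
  tpr <- c$tp / (c$tp + c$fn)
  tnr <- c$tn / (c$tn + c$fp)
  (tpr + tnr) / 2
}

#' Confusion counts from label vectors
#'
#' @param truth,predicted Binary (0/1 or logical) vectors.
#' @return A `confusion_counts` object.
#' @export
confusion_from_labels <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  confusion_counts(tp = sum(truth & predicted),
                   tn = sum(!truth & !predicted),
                   fp = sum(!truth & predicted),
                   fn = sum(truth & !predicted))
}
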