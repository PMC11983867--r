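# Seeded synthetic-data generators. Every pipeline stage can be exercised
# without any external download: bioassay tables with controllable category
# redundancy, valid SMILES corpora from a small fragment grammar, a
# deterministic text embedder, and benchmark endpoints whose negative pools
# sit at a controlled similarity to the verified inactives.

# ---- deterministic text embedder -------------------------------------------

# Portable polynomial string hash (independent of R's internals).
.shingle_hash <- function(s, salt) {
  h <- (salt * 7 + 13) %% 1048573
  for (v in utf8ToInt(s)) {
    h <- (h * 131 + v) %% 1048573
  }
  h
}

#' Deterministic fixture text embedder
#'
#' Hashes word unigrams and bigrams ("shingles") of a name into a signed
#' bag-of-shingles vector, then L2-normalizes. Names sharing words land on
#' shared coordinates, so related names have higher cosine similarity than
#' unrelated ones -- enough structure for clustering tests without any
#' language model.
#'
#' @param name A single non-empty string.
#' @param dim Embedding dimension.
#' @param seed Integer seed mixed into the hash.
#' @return Numeric vector of length `dim`.
#' @export
fixture_embedder <- function(name, dim = 32L, seed = 0L) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop("name must be a non-empty string")
  }
  if (dim < 1L) stop("dim must be positive")
  words <- tolower(strsplit(trimws(name), "[^a-zA-Z0-9]+")[[1]])
  words <- words[nzchar(words)]
  shingles <- c(words,
                if (length(words) > 1L) {
                  paste(words[-length(words)], words[-1L], sep = "_")
                })
  v <- numeric(dim)
  for (s in shingles) {
    idx <- (.shingle_hash(s, seed) %% dim) + 1L
    sgn <- if ((.shingle_hash(s, seed + 1L) %% 2L) == 0L) 1 else -1
    v[idx] <- v[idx] + sgn
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Embedding backend built on the fixture embedder
#'
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return A function mapping a character vector of names to an embedding
#'   matrix, suitable for [embed_assay_names()].
#' @export
make_fixture_embedder <- function(dim = 32L, seed = 0L) {
  force(dim); force(seed)
  function(names) {
    t(vapply(names, fixture_embedder, numeric(dim), dim = dim, seed = seed,
             USE.NAMES = FALSE))
  }
}

# ---- synthetic bioassay tables ---------------------------------------------

#' Configuration for synthetic bioassay tables
#'
#' Assays belong to families that tie together the three category axes
#' (cluster, type, target). Compounds are either redundant (all assays from
#' one family, probability `rho`) or diverse (assays across families), and
#' their testing depth follows a two-mode mixture (a low-count mode and a
#' heavy tail), emulating the strongly multimodal per-compound assay-count
#' distributions of public bioassay repositories.
#'
#' @param n_compounds,n_assays Population sizes.
#' @param n_clusters,n_types,n_targets Category vocabulary sizes per axis.
#' @param count_low,count_high Poisson means of the two testing-depth modes.
#' @param p_high Probability of the heavy (deeply tested) mode.
#' @param rho Probability that a compound's assays all fall in one family.
#' @param active_rate Probability that a compound has at least one active
#'   outcome planted.
#' @param p_literature Fraction of rows emitted as literature records with
#'   an AC50 instead of a direct label.
#' @param p_duplicate Fraction of rows duplicated (repeated depositions).
#' @param seed Integer seed.
#' @return A `synth_assay_config` list.
#' @export
synth_assay_config <- function(n_compounds = 90L, n_assays = 240L,
                               n_clusters = 8L, n_types = 4L,
                               n_targets = 8L, count_low = 3,
                               count_high = 150, p_high = 0.5, rho = 0.3,
                               active_rate = 0.25, p_literature = 0.05,
                               p_duplicate = 0.05, seed = 1L) {
  stopifnot(n_compounds >= 1L, n_assays >= 1L, n_clusters >= 1L,
            n_types >= 1L, n_targets >= 1L, count_low > 0, count_high > 0,
            p_high >= 0, p_high <= 1, rho >= 0, rho <= 1,
            active_rate >= 0, active_rate <= 1,
            p_literature >= 0, p_literature <= 1,
            p_duplicate >= 0, p_duplicate <= 1)
  if (n_clusters > n_assays) {
    stop("infeasible config: more clusters than assays")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_assays = as.integer(n_assays),
                 n_clusters = as.integer(n_clusters),
                 n_types = as.integer(n_types),
                 n_targets = as.integer(n_targets),
                 count_low = count_low, count_high = count_high,
                 p_high = p_high, rho = rho, active_rate = active_rate,
                 p_literature = p_literature, p_duplicate = p_duplicate,
                 seed = as.integer(seed)),
            class = "synth_assay_config")
}

.assay_name_words <- c("kinase", "viability", "binding", "inhibition",
                       "reporter", "uptake", "expression", "cytotoxicity",
                       "aggregation", "fluorescence", "luciferase",
                       "membrane", "receptor", "protease", "channel",
                       "oxidase")

#' Generate synthetic bioassay tables
#'
#' Produces a results table and a metadata table conforming to the reader
#' schemas, plus the planted ground truth: which compounds are deeply and
#' diversely tested with exclusively inactive outcomes (curation candidates),
#' which are redundant, and which have active outcomes.
#'
#' @param cfg A [synth_assay_config()].
#' @return List with `results`, `metadata`, `truth` data frames and the
#'   `config`.
#' @export
synth_bioassay_tables <- function(cfg = synth_assay_config()) {
  stopifnot(inherits(cfg, "synth_assay_config"))
  set.seed(cfg$seed)
  # assay families tie the three axes together
  family <- sample.int(cfg$n_clusters, cfg$n_assays, replace = TRUE)
  type_of_family <- ((seq_len(cfg$n_clusters) - 1L) %% cfg$n_types) + 1L
  target_of_family <- ((seq_len(cfg$n_clusters) - 1L) %% cfg$n_targets) + 1L
  family_phrase <- vapply(seq_len(cfg$n_clusters), function(k) {
    paste(sample(.assay_name_words, 3L), collapse = " ")
  }, "")
  assay_id <- sprintf("A%04d", seq_len(cfg$n_assays))
  metadata <- data.frame(
    assay_id = assay_id,
    name = sprintf("%s assay variant %d", family_phrase[family],
                   seq_len(cfg$n_assays)),
    assay_type = sprintf("type%02d", type_of_family[family]),
    target_id = ifelse(stats::runif(cfg$n_assays) < 0.1, NA_character_,
                       sprintf("T%03d", target_of_family[family])),
    stringsAsFactors = FALSE)

  compound_id <- sprintf("C%04d", seq_len(cfg$n_compounds))
  redundant <- stats::runif(cfg$n_compounds) < cfg$rho
  high <- stats::runif(cfg$n_compounds) < cfg$p_high
  planted_active <- stats::runif(cfg$n_compounds) < cfg$active_rate
  rows <- vector("list", cfg$n_compounds)
  for (i in seq_len(cfg$n_compounds)) {
    mean_n <- if (high[i]) cfg$count_high else cfg$count_low
    n_i <- max(1L, stats::rpois(1L, mean_n))
    cand <- if (redundant[i]) {
      fam <- sample.int(cfg$n_clusters, 1L)
      which(family == fam)
    } else {
      seq_len(cfg$n_assays)
    }
    n_i <- min(n_i, length(cand))
    picked <- if (length(cand) == 1L) cand else sample(cand, n_i)
    outcome <- rep("inactive", n_i)
    if (planted_active[i]) {
      outcome[sample.int(n_i, max(1L, round(0.05 * n_i)))] <- "active"
    }
    ac50 <- rep(NA_real_, n_i)
    source <- rep("hts", n_i)
    lit <- stats::runif(n_i) < cfg$p_literature
    if (any(lit)) {
      source[lit] <- "literature"
      # literature rows carry an AC50 consistent with the planted label
      outcome_lit <- outcome[lit]
      ac50[lit] <- ifelse(outcome_lit == "active",
                          stats::runif(sum(lit), 1, 900),
                          stats::runif(sum(lit), 1500, 50000))
      outcome[lit] <- "unspecified"
    }
    rows[[i]] <- data.frame(assay_id = assay_id[picked],
                            compound_id = compound_id[i],
                            outcome = outcome, ac50_uM = ac50,
                            source = source, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (cfg$p_duplicate > 0) {
    dup <- which(stats::runif(nrow(results)) < cfg$p_duplicate)
    if (length(dup)) results <- rbind(results, results[dup, ])
  }
  results <- results[sample.int(nrow(results)), ]
  rownames(results) <- NULL
  truth <- data.frame(
    compound_id = compound_id,
    redundant = redundant,
    deeply_tested = high,
    any_active = planted_active,
    class = ifelse(planted_active, "active",
                   ifelse(redundant, "redundant",
                          ifelse(high, "diverse-inactive", "diverse-low"))),
    stringsAsFactors = FALSE)
  list(results = results, metadata = metadata, truth = truth, config = cfg)
}

# ---- SMILES grammar corpus --------------------------------------------------

# Core templates ({A}/{B} are substitution slots) and substituents. Ring
# closure digits 8/9 are reserved for substituents so nesting cannot clash.
.smi_cores <- c("c1ccc({A})cc1",
                "c1ccc({A})c({B})c1",
                "c1cc({A})cc({B})c1",
                "c1ccc2cc({A})ccc2c1",
                "c1ccc2ncc({A})cc2c1",
                "c1cc({A})ncc1{B}",
                "C1CCN({A})CC1",
                "C1CCC({A})CC1",
                "c1csc({A})c1",
                "c1cnc({A})[nH]1",
                "C1COC({A})C1",
                "O=C({A})N({B})C")

.smi_subs <- c("C", "CC", "CCC", "CCO", "CO", "OC", "OCC", "N", "NC",
               "CN(C)C", "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)OC",
               "C(=O)N", "NC(C)=O", "S(=O)(=O)N", "S(=O)(=O)C", "C(F)(F)F",
               "OCCN", "Oc8ccccc8", "Cc8ccccc8", "Nc8ccccc8",
               "CC(=O)Nc8ccccc8", "N8CCOCC8", "N8CCN(C)CC8", "C8CC8",
               "OCC(=O)O")

.assemble_molecule <- function(core, subs) {
  s <- core
  s <- sub("{A}", subs[1L], s, fixed = TRUE)
  if (grepl("{B}", s, fixed = TRUE)) {
    s <- sub("{B}", subs[2L], s, fixed = TRUE)
  }
  s
}

#' Synthetic SMILES corpus from a fragment grammar
#'
#' Assembles molecules from a fixed set of ring cores and substituents
#' (organic elements only), canonicalizes, and returns `n` valid canonical
#' SMILES. All outputs pass the organic filter of [filter_generated()] by
#' construction.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return Character vector of `n` canonical SMILES.
#' @export
synth_smiles_corpus <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    need <- n - length(out)
    raw <- vapply(seq_len(need), function(i) {
      core <- sample(.smi_cores, 1L)
      .assemble_molecule(core, sample(.smi_subs, 2L))
    }, "")
    can <- canonicalize_smiles(raw)
    out <- c(out, can[!is.na(can)])
    guard <- guard + 1L
  }
  if (length(out) < n) stop("grammar failed to produce enough valid SMILES")
  out[seq_len(n)]
}

# ---- synthetic benchmark endpoints -----------------------------------------

#' Configuration for a synthetic benchmark endpoint
#'
#' Actives decorate one scaffold family and verified inactives another.
#' Additional negative pools are built at a controlled structural distance:
#' `tc_offset = 0` yields perturbations of the verified inactives (high
#' nearest-neighbor Tc), while larger offsets mix in unrelated grammar
#' molecules, lowering the pool's mean nearest-neighbor Tc monotonically.
#'
#' @param n_actives,n_inactives Verified set sizes (at least 10 each).
#' @param pool_size Size of the generated negative pool.
#' @param tc_offset Structural distance control in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `synth_endpoint_config` list.
#' @export
synth_endpoint_config <- function(n_actives = 30L, n_inactives = 60L,
                                  pool_size = 60L, tc_offset = 0,
                                  seed = 1L) {
  stopifnot(n_actives >= 10L, n_inactives >= 10L, pool_size >= 10L)
  if (tc_offset < 0 || tc_offset > 1) {
    stop("infeasible similarity target: tc_offset must lie in [0, 1]")
  }
  structure(list(n_actives = as.integer(n_actives),
                 n_inactives = as.integer(n_inactives),
                 pool_size = as.integer(pool_size),
                 tc_offset = tc_offset, seed = as.integer(seed)),
            class = "synth_endpoint_config")
}

# Endpoint chemistry: actives and verified inactives share the same ring
# cores and differ in their substituent distributions (with deliberate
# overlap), so classifying them is learnable but not trivial, and the choice
# of training negatives matters.
.ep_cores <- c("c1ccc({A})cc1{B}", "c1ccc2cc({A})c({B})cc2c1",
               "c1cc({A})ncc1{B}", "C1CCN({A})CC1{B}")
.sub_polar <- c("C(=O)O", "C(=O)N", "S(=O)(=O)N", "NC(C)=O", "OCC(=O)O",
                "N", "OCCN", "C#N", "CO", "OC", "Nc8ccccc8", "C(=O)OC")
.sub_lipo <- c("C", "CC", "CCC", "F", "Cl", "Br", "C(F)(F)F", "Cc8ccccc8",
               "C8CC8", "OCC", "CN(C)C", "S(=O)(=O)C")

.decorate <- function(cores, n, sub_pool) {
  vapply(seq_len(n), function(i) {
    .assemble_molecule(sample(cores, 1L), sample(sub_pool, 2L))
  }, "")
}

# Decoration with a mixed substituent distribution: each slot draws from the
# off-class pool with probability `p_other`.
.decorate_mix <- function(cores, n, main_subs, other_subs, p_other = 0.25) {
  vapply(seq_len(n), function(i) {
    subs <- vapply(1:2, function(j) {
      if (stats::runif(1) < p_other) sample(other_subs, 1L)
      else sample(main_subs, 1L)
    }, "")
    .assemble_molecule(sample(cores, 1L), subs)
  }, "")
}

#' Generate a synthetic benchmark endpoint
#'
#' @param cfg A [synth_endpoint_config()].
#' @return List with `endpoint` (an [endpoint()]), `negative_pool`
#'   (character vector at the configured similarity offset) and `config`.
#' @export
synth_endpoint <- function(cfg = synth_endpoint_config()) {
  stopifnot(inherits(cfg, "synth_endpoint_config"))
  set.seed(cfg$seed)
  uniq_valid <- function(recipe, n, exclude = character()) {
    can <- character()
    for (pass in 1:40) {
      more <- canonicalize_smiles(recipe(max(2L * n, 40L)))
      can <- unique(c(can, setdiff(more[!is.na(more)], exclude)))
      if (length(can) >= n) return(can[seq_len(n)])
    }
    stop("infeasible similarity target: family grammar exhausted after ",
         "reaching ", length(can), " of ", n, " structures")
  }
  active_recipe <- function(n) {
    .decorate_mix(.ep_cores, n, .sub_polar, .sub_lipo)
  }
  inactive_recipe <- function(n) {
    .decorate_mix(.ep_cores, n, .sub_lipo, .sub_polar)
  }
  actives <- uniq_valid(active_recipe, cfg$n_actives)
  inactives <- uniq_valid(inactive_recipe, cfg$n_inactives,
                          exclude = actives)
  n_near <- round((1 - cfg$tc_offset) * cfg$pool_size)
  near <- if (n_near > 0L) {
    # perturbations of the verified-inactive family: same cores, same
    # substituent distribution
    uniq_valid(inactive_recipe, n_near, exclude = c(actives, inactives))
  } else {
    character()
  }
  n_far <- cfg$pool_size - length(near)
  far <- if (n_far > 0L) {
    can <- setdiff(synth_smiles_corpus(4L * n_far, seed = cfg$seed + 13L),
                   c(actives, inactives, near))
    if (length(can) < n_far) stop("infeasible similarity target: ",
                                  "could not assemble a far pool")
    sample(can, n_far)
  } else {
    character()
  }
  list(endpoint = endpoint(sprintf("synthEP%03d", cfg$seed),
                           actives, inactives),
       negative_pool = c(near, far),
       config = cfg)
}
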