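# Assay-name categorization: names -> embeddings (pluggable backend) ->
# density clusters -> per-assay category assignment. The embedder is injected
# so a pretrained biomedical language model can be used in production while
# tests run on a deterministic hashing embedder (see fixture_embedder()).

#' Embed assay names with a pluggable backend
#'
#' Applies a text-embedding backend to a vector of assay names and validates
#' the contract: one fixed-dimension, all-finite vector per name, identical
#' names giving identical vectors. The backend may either return a matrix for
#' a character vector, or a single numeric vector per name.
#'
#' @param names Character vector of non-empty assay names.
#' @param embedder A function: either `f(names)` returning a numeric matrix
#'   with `length(names)` rows, or `f(name)` returning a numeric vector.
#' @return Numeric matrix, one row per name (in input order).
#' @export
embed_assay_names <- function(names, embedder) {
  stopifnot(is.character(names), is.function(embedder))
  if (length(names) == 0L) stop("no names to embed")
  if (any(is.na(names) | !nzchar(trimws(names)))) {
    stop("assay names must be non-empty strings")
  }
  out <- tryCatch(embedder(names), error = function(e) NULL)
  if (is.numeric(out) && is.matrix(out) && nrow(out) == length(names)) {
    mat <- out
  } else {
    rows <- lapply(names, embedder)
    dims <- lengths(rows)
    if (length(unique(dims)) != 1L) {
      stop("embedder contract violation: inconsistent dimensions (",
           paste(unique(dims), collapse = ", "), ")")
    }
    mat <- do.call(rbind, rows)
  }
  if (!all(is.finite(mat))) {
    stop("embedder contract violation: non-finite entries")
  }
  rownames(mat) <- NULL
  mat
}

# ---- density clustering ----------------------------------------------------
# Hierarchical density clustering on the mutual-reachability graph:
# single-linkage tree, condensed by minimum cluster size, clusters selected
# by excess of mass. Splits at or below `selection_epsilon` are not resolved,
# which merges micro-structure the way a cluster-selection epsilon does.

.hdbscan_condense <- function(merge, height, n, min_cluster_size,
                              selection_epsilon) {
  n_merge <- nrow(merge)
  # members of every internal node
  members <- vector("list", n_merge)
  node_members <- function(id) if (id < 0) -id else members[[id]]
  for (i in seq_len(n_merge)) {
    members[[i]] <- c(node_members(merge[i, 1L]), node_members(merge[i, 2L]))
  }
  lam <- function(h) 1 / max(h, .Machine$double.eps)

  clusters <- list()  # birth, stability, parent, children
  attach_cluster <- integer(n)   # condensed-tree cluster each point attaches to
  leave_lambda <- numeric(n)
  new_cluster <- function(birth, parent) {
    clusters[[length(clusters) + 1L]] <<- list(birth = birth,
                                               stability = 0,
                                               parent = parent,
                                               children = integer())
    id <- length(clusters)
    if (!is.na(parent)) {
      clusters[[parent]]$children <<- c(clusters[[parent]]$children, id)
    }
    id
  }
  drop_points <- function(pts, cid, h) {
    attach_cluster[pts] <<- cid
    leave_lambda[pts] <<- lam(h)
    clusters[[cid]]$stability <<- clusters[[cid]]$stability +
      length(pts) * (lam(h) - clusters[[cid]]$birth)
  }

  root <- new_cluster(birth = 0, parent = NA)
  stack <- list(list(node = n_merge, cid = root))
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- e$node
    cid <- e$cid
    h <- height[node]
    kids <- merge[node, ]
    if (h <= selection_epsilon) {
      # unresolved micro-split: whole subtree stays with the cluster
      drop_points(c(node_members(kids[1L]), node_members(kids[2L])), cid, h)
      next
    }
    sz <- c(if (kids[1L] < 0) 1L else length(members[[kids[1L]]]),
            if (kids[2L] < 0) 1L else length(members[[kids[2L]]]))
    big <- sz >= min_cluster_size
    if (all(big)) {
      # true split: cluster dies, two children born
      for (k in 1:2) {
        child <- new_cluster(birth = lam(h), parent = cid)
        clusters[[cid]]$stability <- clusters[[cid]]$stability +
          sz[k] * (lam(h) - clusters[[cid]]$birth)
        if (kids[k] < 0) {
          drop_points(-kids[k], child, h)
        } else {
          stack[[length(stack) + 1L]] <- list(node = kids[k], cid = child)
        }
      }
    } else if (any(big)) {
      # spur: small side falls out as noise-at-this-level, big side continues
      small <- which(!big)
      for (k in small) {
        drop_points(node_members(kids[k]), cid, h)
      }
      k <- which(big)
      if (kids[k] < 0) {
        drop_points(-kids[k], cid, h)
      } else {
        stack[[length(stack) + 1L]] <- list(node = kids[k], cid = cid)
      }
    } else {
      # cluster dissolves into fragments all below minimum size
      drop_points(c(node_members(kids[1L]), node_members(kids[2L])), cid, h)
    }
  }
  list(clusters = clusters, attach = attach_cluster, root = root)
}

.hdbscan_select <- function(clusters, root) {
  n_cl <- length(clusters)
  selected <- logical(n_cl)
  sel_stab <- numeric(n_cl)
  # children always have larger index than parents: process bottom-up
  for (id in rev(seq_len(n_cl))) {
    ch <- clusters[[id]]$children
    if (length(ch) == 0L) {
      selected[id] <- TRUE
      sel_stab[id] <- clusters[[id]]$stability
    } else if (id == root) {
      # the root (all points) is only a cluster when it never truly splits
      selected[id] <- FALSE
      sel_stab[id] <- sum(sel_stab[ch])
    } else if (clusters[[id]]$stability >= sum(sel_stab[ch])) {
      selected[id] <- TRUE
      sel_stab[id] <- clusters[[id]]$stability
      # unselect the whole subtree below
      queue <- ch
      while (length(queue)) {
        q <- queue[[1L]]; queue <- queue[-1L]
        selected[q] <- FALSE
        queue <- c(queue, clusters[[q]]$children)
      }
    } else {
      selected[id] <- FALSE
      sel_stab[id] <- sum(sel_stab[ch])
    }
  }
  if (!any(selected) ) selected[root] <- TRUE
  selected
}

#' Density clustering of assay-name embeddings
#'
#' Clusters embedding vectors with a hierarchical density method built on
#' mutual-reachability distances (single-linkage tree condensed by
#' `min_cluster_size`, clusters selected by excess of mass; splits at scales
#' `<= selection_epsilon` are not resolved). Points in no dense cluster are
#' noise; by default each such assay is relabeled as its own singleton
#' category so that one giant "noise" class cannot masquerade as a shared
#' category in the diversity score.
#'
#' @param emb Numeric matrix of embeddings, one row per assay.
#' @param min_cluster_size Smallest population a dense cluster may have.
#' @param selection_epsilon Distance scale below which splits are ignored.
#' @param noise `"singleton"` (default) gives every noise assay a fresh
#'   label; `"single-bucket"` labels all noise assays 0.
#' @return Integer vector of cluster labels (singleton noise labels continue
#'   after the dense-cluster labels), with attribute `noise`: logical vector
#'   marking density-unassigned assays.
#' @export
cluster_embeddings <- function(emb, min_cluster_size = 20,
                               selection_epsilon = 0.03,
                               noise = c("singleton", "single-bucket")) {
  noise <- match.arg(noise)
  stopifnot(is.matrix(emb), nrow(emb) >= 1L)
  if (!all(is.finite(emb))) stop("embeddings contain non-finite entries")
  if (min_cluster_size < 2) stop("min_cluster_size must be at least 2")
  n <- nrow(emb)
  labels <- integer(n)
  if (n >= min_cluster_size && n >= 2L) {
    d <- as.matrix(stats::dist(emb))
    k <- min(min_cluster_size - 1L, n - 1L)
    # core distance: distance to the k-th nearest *other* point
    core <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k],
                   numeric(1))
    mr <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
    diag(mr) <- 0
    hc <- stats::hclust(stats::as.dist(mr), method = "single")
    cond <- .hdbscan_condense(hc$merge, hc$height, n, min_cluster_size,
                              selection_epsilon)
    selected <- .hdbscan_select(cond$clusters, cond$root)
    # map each point's attachment cluster to nearest selected ancestor
    anc_label <- integer(length(cond$clusters))
    sel_ids <- which(selected)
    lab_of_sel <- stats::setNames(seq_along(sel_ids), sel_ids)
    for (p in seq_len(n)) {
      cid <- cond$attach[p]
      while (!is.na(cid) && !selected[cid]) {
        cid <- cond$clusters[[cid]]$parent
      }
      labels[p] <- if (is.na(cid)) 0L else unname(lab_of_sel[as.character(cid)])
    }
    # drop selected clusters that ended up underpopulated
    tab <- table(labels[labels > 0L])
    weak <- as.integer(names(tab)[tab < min_cluster_size])
    labels[labels %in% weak] <- 0L
    if (length(unique(labels[labels > 0L]))) {
      labels[labels > 0L] <- as.integer(factor(labels[labels > 0L]))
    }
  }
  is_noise <- labels == 0L
  if (noise == "singleton" && any(is_noise)) {
    labels[is_noise] <- max(labels) + seq_len(sum(is_noise))
  }
  structure(labels, noise = is_noise)
}

#' Combine cluster labels with assay annotations
#'
#' Joins density-cluster labels with the assay-type and target annotations of
#' an assay metadata table into the per-assay category assignment consumed by
#' [build_compound_profiles()].
#'
#' @param metas Metadata `data.frame` with columns `assay_id`, `name`,
#'   `assay_type`, and optionally `target_id` (`NA` allowed).
#' @param labels Cluster labels aligned with the rows of `metas` (e.g. from
#'   [cluster_embeddings()] applied to embeddings of `metas$name`), or a
#'   vector named by `assay_id`.
#' @return A `data.frame` with columns `assay_id`, `cluster_id`, `type_id`,
#'   `target_id`.
#' @export
assign_categories <- function(metas, labels) {
  stopifnot(is.data.frame(metas))
  need <- c("assay_id", "name", "assay_type")
  missing_col <- setdiff(need, names(metas))
  if (length(missing_col)) {
    stop("metadata lacks column(s): ", paste(missing_col, collapse = ", "))
  }
  if (anyDuplicated(metas$assay_id)) {
    stop("duplicated assay_id in metadata: ",
         paste(unique(metas$assay_id[duplicated(metas$assay_id)]),
               collapse = ", "))
  }
  if (any(is.na(metas$name) | !nzchar(trimws(metas$name)))) {
    stop("assay names must be non-empty")
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(metas$assay_id, names(labels))
    if (length(miss)) {
      stop("assay id(s) without a cluster label: ",
           paste(miss, collapse = ", "))
    }
    labels <- labels[as.character(metas$assay_id)]
  } else if (length(labels) != nrow(metas)) {
    stop("labels must cover every assay in the metadata")
  }
  data.frame(assay_id = metas$assay_id,
             cluster_id = paste0("k", as.integer(labels)),
             type_id = as.character(metas$assay_type),
             target_id = if ("target_id" %in% names(metas)) {
               as.character(metas$target_id)
             } else {
               NA_character_
             },
             stringsAsFactors = FALSE)
}

#' Two-dimensional projection of embeddings
#'
#' UMAP projection of the embedding matrix for visual inspection. Plumbing
#' only: coordinates are seeded and reproducible but carry no quantitative
#' guarantee. Very small inputs (under four rows, where a neighborhood graph
#' is degenerate) fall back to a principal-component projection.
#'
#' @param emb Numeric matrix with at least 2 rows.
#' @param seed Integer seed.
#' @return Numeric matrix with `nrow(emb)` rows and 2 columns.
#' @export
project_2d <- function(emb, seed = 1L) {
  stopifnot(is.matrix(emb))
  if (nrow(emb) < 2L) stop("need at least 2 rows to project")
  if (nrow(emb) < 4L) {
    pc <- stats::prcomp(emb, center = TRUE, scale. = FALSE)
    xy <- pc$x
    if (ncol(xy) < 2L) xy <- cbind(xy, 0)
    return(unname(xy[, 1:2, drop = FALSE]))
  }
  set.seed(seed)
  nn <- max(2L, min(15L, nrow(emb) - 1L))
  out <- uwot::umap(emb, n_components = 2L, n_neighbors = nn,
                    n_threads = 1L, n_sgd_threads = 1L)
  unname(out)
}
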