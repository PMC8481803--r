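# Search for maximally deregulated simple paths in a directed gene network,
# scored by the unweighted running-sum statistic on a ranked gene list.

# Running-sum maximum for a set of 1-based member ranks within a list of
# length n. Because misses only decrease the sum, the maximum over all list
# positions is attained immediately after one of the hits.
score_from_ranks <- function(pos, n) {
  m <- length(pos)
  pos <- sort(pos)
  j <- seq_len(m)
  max(j / m - (pos - j) / (n - m))
}

#' Running-sum path score
#'
#' Scores a set of path nodes against a ranked gene list with the
#' unweighted running-sum statistic in the enrichment direction: the
#' maximum of the running sum that gains `1/m` at each member rank and
#' loses `1/(N - m)` elsewhere. The score depends only on the members'
#' rank set and is at most 1.
#'
#' @param ranked A data frame with columns `gene`, `score`.
#' @param path_nodes Character vector of node genes; all must occur in the
#'   ranked list, and fewer than all list genes.
#' @return The path score (numeric scalar).
#' @export
path_score <- function(ranked, path_nodes) {
  ranked <- as_ranked_list(ranked)
  path_nodes <- unique(normalize_genes(path_nodes, "path node"))
  pos <- match(path_nodes, ranked$gene)
  if (anyNA(pos)) {
    stop("Path node not in ranked list: ", path_nodes[which(is.na(pos))[1]],
      call. = FALSE
    )
  }
  n <- nrow(ranked)
  if (length(pos) >= n) {
    stop("Path must cover fewer genes than the ranked list.", call. = FALSE)
  }
  score_from_ranks(pos, n)
}

# TRUE if node sequence a is lexicographically smaller than b.
seq_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

#' Most deregulated simple path per length
#'
#' For every path length from 2 to `k_max`, finds a node-simple directed
#' path maximizing [path_score()] against the ranked list, by exact
#' depth-bounded enumeration of simple paths. Network nodes absent from the
#' ranked list are pruned first (count recorded). Score ties are broken by
#' the lexicographically smallest node sequence. Each returned path gets a
#' permutation p-value from `n_perm` draws of a random distinct rank set of
#' the same size (add-one estimator), Benjamini-Hochberg-adjusted across
#' the returned lengths.
#'
#' @param net A `tk_network` edge tibble (see [gene_network()]).
#' @param ranked A data frame with columns `gene`, `score`.
#' @param k_max Maximum path length in nodes (>= 2).
#' @param n_perm Permutations per length for the null.
#' @param seed Integer seed.
#' @return A tibble of class `tk_paths` with columns `length`, `path`
#'   (comma-joined nodes), `nodes` (list column), `score`, `p_raw`,
#'   `p_adj`; attributes `pruned_nodes` (count removed) and `omitted`
#'   (lengths with no existing path, with reasons).
#' @export
best_paths <- function(net, ranked, k_max, n_perm = 1000, seed = 42) {
  stopifnot(k_max >= 2)
  ranked <- as_ranked_list(ranked)
  nodes_all <- network_nodes(net)
  keep <- nodes_all %in% ranked$gene
  pruned <- sum(!keep)
  nodes <- nodes_all[keep]
  edges <- net[net$from %in% nodes & net$to %in% nodes, ]
  if (nrow(edges) == 0) {
    stop("Network empty after pruning nodes absent from the ranked list.",
      call. = FALSE
    )
  }
  n <- nrow(ranked)
  node_rank <- match(nodes, ranked$gene)
  # adjacency over integer node indices, neighbors in lexicographic order
  adj <- lapply(seq_along(nodes), function(i) {
    which(nodes %in% edges$to[edges$from == nodes[i]])
  })

  best <- vector("list", k_max) # best[[l]] = list(score, idx_seq)
  visited <- logical(length(nodes))
  path <- integer(k_max)

  dfs <- function(v, depth) {
    visited[v] <<- TRUE
    path[depth] <<- v
    if (depth >= 2) {
      sc <- score_from_ranks(node_rank[path[seq_len(depth)]], n)
      cur <- best[[depth]]
      if (is.null(cur) || sc > cur$score ||
        (sc == cur$score &&
          seq_less(nodes[path[seq_len(depth)]], nodes[cur$idx]))) {
        best[[depth]] <<- list(score = sc, idx = path[seq_len(depth)])
      }
    }
    if (depth < k_max) {
      for (w in adj[[v]]) {
        if (!visited[w]) dfs(w, depth + 1L)
      }
    }
    visited[v] <<- FALSE
  }
  for (v in seq_along(nodes)) dfs(v, 1L)

  found <- which(!vapply(best, is.null, logical(1)))
  found <- found[found >= 2]
  if (length(found) == 0) {
    stop("No path of length >= 2 exists in the pruned network.",
      call. = FALSE
    )
  }
  p_raw <- withr::with_seed(seed, {
    vapply(found, function(l) {
      obs <- best[[l]]$score
      null <- vapply(seq_len(n_perm), function(b) {
        score_from_ranks(sample.int(n, l), n)
      }, numeric(1))
      (1 + sum(null >= obs)) / (n_perm + 1)
    }, numeric(1))
  })
  out <- tibble::tibble(
    length = as.integer(found),
    path = vapply(
      found, function(l) paste(nodes[best[[l]]$idx], collapse = ","),
      character(1)
    ),
    nodes = lapply(found, function(l) nodes[best[[l]]$idx]),
    score = vapply(found, function(l) best[[l]]$score, numeric(1)),
    p_raw = p_raw,
    p_adj = adjust_pvalues(p_raw, "benjamini_hochberg")
  )
  missing_l <- setdiff(2:k_max, found)
  attr(out, "pruned_nodes") <- pruned
  attr(out, "omitted") <- tibble::tibble(
    length = as.integer(missing_l),
    reason = rep("no_path_of_this_length", length(missing_l))
  )
  class(out) <- c("tk_paths", class(out))
  out
}
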