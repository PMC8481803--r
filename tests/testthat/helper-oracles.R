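# Independent oracles used to pin expected values. These deliberately use
# brute-force enumeration or direct definitional evaluation, never the
# package's own code paths.

# Hypergeometric tail by exhaustive enumeration over all C(N, n) test sets
# drawn from a reference of size N containing K category members: returns
# P(overlap >= k) and P(overlap <= k) as exact fractions of set counts.
ora_enum_oracle <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  overlaps <- colSums(sets <= K) # members are items 1..K
  c(
    enrich = mean(overlaps >= k),
    deplete = mean(overlaps <= k)
  )
}

# Running-sum enrichment score by direct evaluation at every rank.
es_brute <- function(scores, is_hit, weight_p) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight_p
  nr <- sum(w[is_hit])
  running <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + if (is_hit[i]) {
      if (nr > 0) w[i] / nr else 1 / nh
    } else {
      -1 / (n - nh)
    }
    running[i] <- s
  }
  running[which(abs(running) >= max(abs(running)) - 1e-12)[1]]
}

# Maximum of the running sum (enrichment direction) at every rank.
path_score_brute <- function(n, member_ranks) {
  m <- length(member_ranks)
  s <- 0
  best <- -Inf
  for (i in seq_len(n)) {
    s <- s + if (i %in% member_ranks) 1 / m else -1 / (n - m)
    best <- max(best, s)
  }
  best
}

# All simple directed paths with exactly l nodes, from an edge data frame.
enumerate_simple_paths <- function(edges, l) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(nodes, function(v) sort(edges$to[edges$from == v]))
  names(adj) <- nodes
  out <- list()
  extend <- function(path) {
    if (length(path) == l) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[path[length(path)]]]) {
      if (!w %in% path) extend(c(path, w))
    }
  }
  for (v in nodes) extend(v)
  out
}

# Benjamini-Hochberg by the step-up definition: sort ascending, p * m / i,
# cumulative minimum from the largest rank, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Tiny deterministic expression fixture: two groups of three samples.
tiny_bulk <- function() {
  x <- rbind(
    UP = c(8, 9, 10, 2, 3, 4),
    DOWN = c(1, 2, 3, 7, 8, 9),
    FLAT = c(5, 5, 5, 5, 5, 5),
    NOISY = c(4, 6, 5, 5, 6, 4)
  )
  colnames(x) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  list(
    m = expr_mat(x, mode = "normalized"),
    groups = tibble::tibble(
      id = colnames(x), group = rep(c("A", "B"), each = 3)
    )
  )
}
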