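# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (loops, enumeration, direct
# formulas) rather than calling package internals.

# exhaustive one/two-sided rank-sum p by enumerating every assignment of the
# pooled values to the two groups
oracle_ranksum <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  pg <- mean(ws >= w_obs - 1e-9)
  pl <- mean(ws <= w_obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Spearman rho from scratch: average ranks, then the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# product-limit estimate by direct tabulation; returns step function values
# at each distinct event time
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]
  events <- events[ord]
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(0)
  for (t in ev_times) {
    n_at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_at_risk)
    out <- c(out, s)
  }
  data.frame(time = ev_times, survival = out)
}

# two-group log-rank chi-square by direct O - E / V tabulation over event
# times, hypergeometric variance, ties aggregated
oracle_logrank <- function(times, events, groups) {
  g1 <- sort(unique(groups))[1]
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# sqrt Jensen-Shannon divergence by direct KL arithmetic (base 2)
oracle_sqrt_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}

# decode a Pruefer sequence into a labeled tree's edge list
prufer_decode <- function(seq, n) {
  degree <- rep(1, n)
  for (s in seq) degree[s] <- degree[s] + 1
  edges <- matrix(0, nrow = 0, ncol = 2)
  for (s in seq) {
    leaf <- min(which(degree == 1))
    edges <- rbind(edges, c(leaf, s))
    degree[leaf] <- degree[leaf] - 1
    degree[s] <- degree[s] - 1
  }
  u <- which(degree == 1)
  rbind(edges, u)
}

# minimum spanning tree weight by enumerating all n^(n-2) labeled trees
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], n)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# betweenness of every node in a tree by enumerating the unique path between
# all unordered pairs (breadth-first search), normalized by (n-1)(n-2)/2
oracle_tree_betweenness <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) {
    c(edges$probe_b[edges$probe_a == v], edges$probe_a[edges$probe_b == v])
  })
  names(adj) <- nodes
  path_between <- function(a, b) {
    prev <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
    visited <- stats::setNames(logical(length(nodes)), nodes)
    queue <- a
    visited[a] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v == b) break
      for (w in adj[[v]]) if (!visited[w]) {
        visited[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
    path <- b
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    path
  }
  counts <- stats::setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (j in seq_len(ncol(pairs))) {
    p <- path_between(pairs[1, j], pairs[2, j])
    interior <- setdiff(p, c(pairs[1, j], pairs[2, j]))
    counts[interior] <- counts[interior] + 1
  }
  n <- length(nodes)
  counts / ((n - 1) * (n - 2) / 2)
}

# Ward merge heights by a direct Lance-Williams recursion on squared
# distances (ward.D2 convention: heights on the original distance scale)
oracle_ward_heights <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    ni <- sizes[i]; nj <- sizes[j]
    new_d2 <- sapply(seq_len(k), function(h) {
      if (h == i || h == j) return(NA_real_)
      nh <- sizes[h]
      ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] - nh * d2[i, j]) /
        (ni + nj + nh)
    })
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- d2[keep, keep, drop = FALSE]
    d2 <- rbind(cbind(d2, new_d2[keep]), c(new_d2[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  heights
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small deterministic expr_mat fixture
make_expr <- function(m, roles, platform = "test") {
  expression_matrix(m, rownames(m), colnames(m), sample_role = roles,
                    platform = platform)
}
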