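## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's code paths: ranks and correlations are spelled out,
## permutations are enumerated, and shortest paths are found by exhaustive
## search.

## all permutations of 1..n (n small), independent of the package's helper
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in oracle_perms(n - 1)) {
      out[[length(out) + 1]] <- c(k, setdiff(seq_len(n), k)[p])
    }
  }
  out
}

## Pearson correlation written out longhand
oracle_pearson <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

## Spearman via explicit mid-ranks + longhand Pearson
oracle_spearman <- function(x, y) {
  mid_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  oracle_pearson(mid_rank(x), mid_rank(y))
}

## BH step-up written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in m:1) {
    val <- min(1, p[ord[k]] * m / k)
    q_sorted[k] <- if (k == m) val else min(val, q_sorted[k + 1])
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

## ANOSIM R from the definition (mid-ranked dissimilarities)
oracle_anosim_R <- function(d, groups) {
  n <- nrow(d)
  vals <- c(); between <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j]); between <- c(between, groups[i] != groups[j])
  }
  rk <- vapply(vals, function(v) sum(vals < v) + (1 + sum(vals == v)) / 2,
               numeric(1))
  m <- n * (n - 1) / 2
  (mean(rk[between]) - mean(rk[!between])) / (m / 2)
}

## exhaustive ANOSIM permutation distribution: R for every relabeling
oracle_anosim_exact <- function(d, groups) {
  n <- nrow(d)
  rs <- vapply(oracle_perms(n), function(idx) oracle_anosim_R(d, groups[idx]),
               numeric(1))
  r_obs <- oracle_anosim_R(d, groups)
  list(R = r_obs, p = mean(rs >= r_obs - 1e-12))
}

## exhaustive Mantel: r and exact tail p over all joint permutations of d2
oracle_mantel_exact <- function(d1, d2) {
  n <- nrow(d1)
  up <- upper.tri(d1)
  v1 <- d1[up]
  r_obs <- oracle_pearson(v1, d2[up])
  rs <- vapply(oracle_perms(n), function(idx) {
    oracle_pearson(v1, d2[idx, idx][up])
  }, numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

## exhaustive betweenness: enumerate every simple path between each pair,
## keep the shortest ones, split credit equally
oracle_betweenness <- function(adj_mat) {
  n <- nrow(adj_mat)
  bc <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nb in which(adj_mat[last, ] > 0)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(from)
    paths
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(i, j)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- p[-c(1, length(p))]
      for (v in inner) bc[v] <- bc[v] + 1 / length(shortest)
    }
  }
  bc
}

## modularity Q recomputed from a partition and an edge list
oracle_modularity <- function(membership, edges) {
  m <- nrow(edges)
  if (m == 0) return(0)
  cls <- unique(membership)
  q <- 0
  for (cc in cls) {
    within <- sum(membership[edges$from] == cc & membership[edges$to] == cc)
    ends <- sum(membership[edges$from] == cc) + sum(membership[edges$to] == cc)
    q <- q + within / m - (ends / (2 * m))^2
  }
  q
}

## adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## construct a cooccurrence_network directly from an edge list (test-only)
make_test_network <- function(ids, from, to, rho = NULL) {
  if (is.null(rho)) rho <- rep(0.9, length(from))
  edges <- data.frame(from = from, to = to, rho = rho,
                      stringsAsFactors = FALSE)
  deg <- vapply(ids, function(v) sum(from == v) + sum(to == v), numeric(1))
  nodes <- data.frame(otu_id = ids, taxonomy = NA_character_,
                      source = NA_character_, degree = as.integer(deg),
                      isolated = deg == 0, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = 0.5,
                 p_threshold = 0.001),
            class = "cooccurrence_network")
}

## dense adjacency matrix of a network (test-only)
net_adjacency <- function(net) {
  ids <- net$nodes$otu_id
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    a[net$edges$from[k], net$edges$to[k]] <- 1L
    a[net$edges$to[k], net$edges$from[k]] <- 1L
  }
  a
}

## small labeled dissimilarity matrix from a point set
euclid_d <- function(pts, ids = NULL) {
  d <- as.matrix(dist(pts))
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  d
}

## default small dataset shared by several tests (kept small for speed)
small_design <- function(seed = 1, ...) {
  simulation_design(n_otus = 120, n_diff_otus = 8, n_modules = 1,
                    module_size_range = c(6, 6),
                    library_size_range = c(4000, 6000), seed = seed, ...)
}
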