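## Co-occurrence network inference: Spearman correlation matrix with BH-FDR
## over the upper triangle, random-matrix-theory (RMT) automatic threshold
## selection from nearest-neighbour eigenvalue spacings, graph construction,
## exact betweenness (Brandes), greedy modularity (Clauset-Newman-Moore)
## modules, keystone ranking, module source attribution, and
## module-environment Mantel tests.

#' Spearman rank correlation matrix with BH-adjusted p-values
#'
#' Computes mid-rank Spearman correlations between OTU rows, two-sided
#' p-values from the t approximation
#' `t = r * sqrt((n-2) / (1-r^2))`, and BH adjustment over the
#' `k(k-1)/2` upper-triangle tests. Zero-variance rows are flagged and get
#' `rho = 0`, `p = 1` against all partners.
#'
#' @param abundances numeric matrix, OTUs as rows, samples as columns
#'   (>= 4 samples).
#' @return object of class `"correlation_matrix"`: list with `rho`, `p`, `q`
#'   matrices, `otu_ids`, `n_samples` and `constant_otus`.
#' @export
spearman_matrix <- function(abundances) {
  if (ncol(abundances) < 4) {
    stop("spearman_matrix: >= 4 samples required", call. = FALSE)
  }
  k <- nrow(abundances)
  n <- ncol(abundances)
  ids <- rownames(abundances)
  if (is.null(ids)) ids <- paste0("V", seq_len(k))
  const <- apply(abundances, 1, function(r) length(unique(r)) == 1L)
  if (any(const)) {
    log_warn("spearman_matrix: ", sum(const), " zero-variance OTU row(s)")
  }
  rk <- t(apply(abundances, 1, rank_mid))
  rho <- suppressWarnings(cor(t(rk)))
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1
  r_clamped <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clamped * sqrt((n - 2) / (1 - r_clamped^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  up <- upper.tri(p)
  q <- p
  q[up] <- adjust_bh(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  dimnames(rho) <- dimnames(p) <- dimnames(q) <- list(ids, ids)
  structure(list(rho = rho, p = p, q = q, otu_ids = ids,
                 n_samples = n, constant_otus = ids[const]),
            class = "correlation_matrix")
}

## Nearest-neighbour spacing distribution of one thresholded matrix.
## Returns the chi-square statistic and p-value of the test against the
## Poisson law P(s) = exp(-s), plus the retained eigenvalue count.
nnsd_poisson_test <- function(rho, t, dedup_tol = 1e-8) {
  m <- rho
  m[abs(m) < t] <- 0
  diag(m) <- 1
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  ## drop (near-)degenerate eigenvalues before unfolding, standard in RMT
  ## threshold scanning where isolated nodes pile up identical eigenvalues
  keep <- c(TRUE, diff(ev) > dedup_tol)
  ev <- ev[keep]
  ne <- length(ev)
  nil <- list(chi_sq = NA_real_, p = NA_real_, poisson_per_df = NA_real_,
              wigner_per_df = NA_real_, n_retained = ne)
  if (ne < 20) return(nil)
  ## unfold: monotone cubic smoothing of the empirical spectral CDF
  fr <- (seq_len(ne)) / ne
  n_knots <- max(4L, ceiling(ne / 10))
  idx <- unique(round(seq(1, ne, length.out = n_knots)))
  sf <- tryCatch(splinefun(ev[idx], fr[idx], method = "hyman"),
                 error = function(e) NULL)
  if (is.null(sf)) return(nil)
  unfolded <- ne * pmin(pmax(sf(ev), 0), 1)
  s <- diff(unfolded)
  s <- s[is.finite(s) & s >= 0]
  if (length(s) < 10 || mean(s) == 0) return(nil)
  s <- s / mean(s)
  breaks <- c(seq(0, 3, by = 0.1), Inf)
  obs <- tabulate(findInterval(s, breaks, left.open = TRUE) + 0L,
                  nbins = length(breaks) - 1)
  ## findInterval with left.open puts s = 0 in bin 0; fold into first bin
  obs[1] <- obs[1] + sum(s == 0)
  expd <- length(s) * diff(1 - exp(-breaks))
  ## pool adjacent sparse bins (Cochran rule: expected count >= 5) so the
  ## chi-square approximation stays valid for small spectra
  ob <- c(); ex <- c(); acc_o <- 0; acc_e <- 0
  for (b in seq_along(obs)) {
    acc_o <- acc_o + obs[b]; acc_e <- acc_e + expd[b]
    if (acc_e >= 5) {
      ob <- c(ob, acc_o); ex <- c(ex, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(ex)) {
    ob[length(ob)] <- ob[length(ob)] + acc_o
    ex[length(ex)] <- ex[length(ex)] + acc_e
  }
  if (length(ex) < 3) return(nil)
  chi_sq <- sum((ob - ex)^2 / ex)
  dfree <- length(ex) - 1
  ## same histogram against the Wigner-Dyson (GOE) surmise
  ## P(s) = (pi/2) s exp(-pi s^2 / 4), CDF 1 - exp(-pi s^2 / 4)
  expd_w <- length(s) * diff(-exp(-pi * breaks^2 / 4))
  obw <- c(); exw <- c(); acc_o <- 0; acc_e <- 0
  for (b in seq_along(obs)) {
    acc_o <- acc_o + obs[b]; acc_e <- acc_e + expd_w[b]
    if (acc_e >= 5) {
      obw <- c(obw, acc_o); exw <- c(exw, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(exw)) {
    obw[length(obw)] <- obw[length(obw)] + acc_o
    exw[length(exw)] <- exw[length(exw)] + acc_e
  }
  chi_w <- if (length(exw) >= 3) sum((obw - exw)^2 / exw) / (length(exw) - 1)
           else NA_real_
  list(chi_sq = chi_sq,
       p = pchisq(chi_sq, df = dfree, lower.tail = FALSE),
       poisson_per_df = chi_sq / dfree,
       wigner_per_df = chi_w,
       n_retained = ne)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans a grid of candidate cutoffs. For each `t`, correlations below `t`
#' in magnitude are zeroed (diagonal kept at 1), the eigenvalue spectrum is
#' unfolded with a monotone cubic spline over `~n/10` knots, and the
#' nearest-neighbour spacing distribution is histogrammed over bins of
#' width 0.1 on `[0, 3]` (adjacent bins pooled to expected counts of at
#' least 5) and compared with both the Poisson law `P(s) = exp(-s)`
#' (uncorrelated, modular spectra) and the Wigner-Dyson surmise
#' `P(s) = (pi/2) s exp(-pi s^2/4)` (GOE, dense random spectra). A grid
#' point is Poisson-consistent when the Poisson chi-square test passes at
#' `p_pass` or the histogram is strictly closer (chi-square per degree of
#' freedom) to the Poisson law than to the Wigner-Dyson law; the chosen
#' threshold is the smallest Poisson-consistent point whose successor is
#' also consistent (stability). If none qualifies, the normalized
#' chi-square minimizer is chosen with a warning.
#'
#' @param corr `"correlation_matrix"` object (or plain symmetric correlation
#'   matrix) over at least 20 OTUs.
#' @param grid increasing vector of candidate thresholds in (0, 1).
#' @param p_pass Poisson-consistency level for the scan (default 0.05).
#' @return object of class `"rmt_scan"`: data frame `scan` (`threshold`,
#'   `chi_sq`, `chi_sq_p`, `poisson_per_df`, `wigner_per_df`,
#'   `n_retained`) and `chosen_threshold`.
#' @export
rmt_threshold <- function(corr, grid = seq(0.30, 0.95, by = 0.01),
                          p_pass = 0.05) {
  rho <- if (inherits(corr, "correlation_matrix")) corr$rho else corr
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    stop("rmt_threshold: need a square correlation matrix", call. = FALSE)
  }
  if (nrow(rho) < 20) {
    stop("rmt_threshold: fewer than 20 OTUs; the eigenvalue spectrum is too ",
         "small for spacing statistics - supply a manual threshold",
         call. = FALSE)
  }
  if (!length(grid) || any(grid <= 0) || any(grid >= 1)) {
    stop("rmt_threshold: grid must lie in (0, 1)", call. = FALSE)
  }
  grid <- sort(grid)
  rec <- lapply(grid, function(t) nnsd_poisson_test(rho, t))
  scan <- data.frame(threshold = grid,
                     chi_sq = vapply(rec, `[[`, numeric(1), "chi_sq"),
                     chi_sq_p = vapply(rec, `[[`, numeric(1), "p"),
                     poisson_per_df = vapply(rec, `[[`, numeric(1),
                                             "poisson_per_df"),
                     wigner_per_df = vapply(rec, `[[`, numeric(1),
                                            "wigner_per_df"),
                     n_retained = vapply(rec, `[[`, numeric(1), "n_retained"))
  ## Poisson-consistent: the spacing histogram either passes the absolute
  ## goodness-of-fit test or sits strictly closer to the Poisson law than to
  ## the Wigner-Dyson surmise (the robust transition signal on small spectra)
  consistent <- !is.na(scan$poisson_per_df) &
    ((!is.na(scan$chi_sq_p) & scan$chi_sq_p >= p_pass) |
     (!is.na(scan$wigner_per_df) &
        scan$poisson_per_df < scan$wigner_per_df))
  chosen <- NA_real_
  for (i in seq_along(grid)) {
    if (consistent[i] && i < length(grid) && consistent[i + 1]) {
      chosen <- grid[i]
      break
    }
  }
  if (is.na(chosen)) {
    if (all(is.na(scan$chi_sq))) {
      warning("rmt_threshold: spacing statistics degenerate on the whole ",
              "grid; falling back to the largest grid point", call. = FALSE)
      chosen <- grid[length(grid)]
    } else {
      warning("rmt_threshold: no stable Poisson-consistent threshold; ",
              "using the normalized chi-square minimizer", call. = FALSE)
      chosen <- grid[which.min(scan$poisson_per_df)]
    }
  }
  structure(list(scan = scan, chosen_threshold = chosen), class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan over", nrow(x$scan), "candidates;",
      "chosen threshold:", fmt_real(x$chosen_threshold), "\n")
  invisible(x)
}

#' Build a thresholded co-occurrence network
#'
#' An edge joins OTUs `i != j` when `|rho_ij| >= t` and the BH-adjusted
#' correlation p-value `q_ij < p_threshold`. Self connections are removed;
#' isolated nodes are retained and flagged. Edge signs are kept as
#' attributes.
#'
#' @param corr `"correlation_matrix"` object.
#' @param t correlation magnitude cutoff in (0, 1).
#' @param p_threshold FDR cutoff on the adjusted correlation p-values.
#' @param node_meta optional data frame with `otu_id` plus `taxonomy` and/or
#'   `source` columns carried onto the nodes.
#' @return object of class `"cooccurrence_network"`: `nodes` data frame
#'   (`otu_id`, `taxonomy`, `source`, `degree`, `isolated`), `edges` data
#'   frame (`from`, `to`, `rho`), and the cutoffs used.
#' @export
build_network <- function(corr, t, p_threshold = 0.001, node_meta = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  check_fraction(t, "t")
  check_fraction(p_threshold, "p_threshold")
  ids <- corr$otu_ids
  adj <- abs(corr$rho) >= t & corr$q < p_threshold
  diag(adj) <- FALSE
  up <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[up[, 1]], to = ids[up[, 2]],
                      rho = corr$rho[up], stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- rowSums(adj)
  nodes <- data.frame(otu_id = ids,
                      taxonomy = NA_character_,
                      source = NA_character_,
                      degree = as.integer(deg),
                      isolated = deg == 0,
                      stringsAsFactors = FALSE)
  if (!is.null(node_meta)) {
    m <- match(nodes$otu_id, node_meta$otu_id)
    if ("taxonomy" %in% names(node_meta)) nodes$taxonomy <- node_meta$taxonomy[m]
    if ("source" %in% names(node_meta)) nodes$source <- node_meta$source[m]
  }
  structure(list(nodes = nodes, edges = edges,
                 threshold = t, p_threshold = p_threshold),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "nodes (",
      sum(!x$nodes$isolated), "connected ),", nrow(x$edges), "edges\n")
  cat("  |rho| >=", fmt_real(x$threshold), " q <", fmt_pval(x$p_threshold), "\n")
  invisible(x)
}

## adjacency list (by node index) from a network
adjacency_list <- function(net) {
  idx <- setNames(seq_len(nrow(net$nodes)), net$nodes$otu_id)
  adj <- vector("list", length(idx))
  if (nrow(net$edges)) {
    fi <- idx[net$edges$from]
    ti <- idx[net$edges$to]
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  adj
}

## Exact betweenness centrality, Brandes' algorithm, undirected unweighted,
## unnormalized with each unordered pair counted once.
brandes_betweenness <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist_v <- rep(-1L, n); dist_v[s] <- 0L
    preds <- vector("list", n)
    order_v <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_v <- c(order_v, v)
      for (w in adj[[v]]) {
        if (dist_v[w] < 0) {
          dist_v[w] <- dist_v[v] + 1L
          queue <- c(queue, w)
        }
        if (dist_v[w] == dist_v[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_v)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

#' Node centralities
#'
#' Degree (incident edge count) and exact betweenness centrality by Brandes'
#' all-pairs shortest-path accumulation on the unweighted, undirected,
#' sign-ignored graph. Betweenness is unnormalized, counting each unordered
#' pair once with equal splitting over equally short paths.
#'
#' @param net `"cooccurrence_network"` object.
#' @return the network with `degree` and `betweenness` columns filled on
#'   `nodes`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  net$nodes$betweenness <- brandes_betweenness(adjacency_list(net))
  net
}

## community partition quality on the unweighted graph
modularity_q <- function(membership, edges, ids) {
  m <- nrow(edges)
  if (m == 0) return(0)
  comm <- membership[ids]
  e_from <- membership[edges$from]
  e_to <- membership[edges$to]
  q <- 0
  for (c in unique(comm)) {
    e_cc <- sum(e_from == c & e_to == c) / m
    a_c <- (sum(e_from == c) + sum(e_to == c)) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

#' Greedy modularity module detection (Clauset-Newman-Moore)
#'
#' Agglomerative modularity maximization on the sign-ignored unweighted
#' graph: starting from singleton communities, repeatedly merges the pair
#' with the largest modularity gain until no positive gain remains, with
#' deterministic tie-breaking (lowest lexicographic community-label pair).
#' Modules below `min_module_size` stay in the raw partition but are
#' excluded from the module report.
#'
#' @param net `"cooccurrence_network"` object with at least one edge
#'   (an edgeless network yields singleton communities, `Q = 0`, with a
#'   warning).
#' @param min_module_size smallest module size admitted to the report.
#' @return object of class `"module_report"`: `membership` (named integer
#'   vector over all nodes), `modularity` (Q of the final partition),
#'   `modules` data frame (`module`, `size`, `members`), `min_module_size`.
#' @export
detect_modules <- function(net, min_module_size = 4) {
  stopifnot(inherits(net, "cooccurrence_network"))
  min_module_size <- check_count(min_module_size, "min_module_size")
  ids <- net$nodes$otu_id
  n <- length(ids)
  m <- nrow(net$edges)
  if (m == 0) {
    warning("detect_modules: edgeless network; singleton communities, Q = 0",
            call. = FALSE)
    membership <- setNames(seq_len(n), ids)
    return(structure(list(membership = membership, modularity = 0,
                          modules = data.frame(module = integer(0),
                                               size = integer(0),
                                               members = character(0)),
                          min_module_size = min_module_size),
                     class = "module_report"))
  }
  idx <- setNames(seq_len(n), ids)
  ## e[i, j]: fraction of edges between communities i and j (e[i, i] within)
  e <- matrix(0, n, n)
  for (k in seq_len(m)) {
    i <- idx[net$edges$from[k]]; j <- idx[net$edges$to[k]]
    e[i, j] <- e[i, j] + 1 / (2 * m)
    e[j, i] <- e[j, i] + 1 / (2 * m)
  }
  a <- rowSums(e)
  active <- rep(TRUE, n)
  comm <- as.list(seq_len(n))          # members (node indices) per community
  label <- ids                          # deterministic tie-break label
  repeat {
    best <- -Inf; bi <- 0L; bj <- 0L
    act <- which(active)
    if (length(act) < 2) break
    for (i in act) {
      js <- act[act > i]
      if (!length(js)) next
      dq <- 2 * (e[i, js] - a[i] * a[js])
      ## only communities sharing an edge can improve Q
      dq[e[i, js] == 0] <- -Inf
      jbest <- which(dq > best - 1e-15)
      for (j2 in jbest) {
        j <- js[j2]
        cand <- dq[j2]
        if (cand > best + 1e-15) {
          best <- cand; bi <- i; bj <- j
        } else if (abs(cand - best) <= 1e-15 && bi > 0) {
          ## lexicographic tie-break on (label_i, label_j)
          old <- c(sort(c(label[bi], label[bj])))
          new <- c(sort(c(label[i], label[j])))
          if (new[1] < old[1] || (new[1] == old[1] && new[2] < old[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    if (best <= 1e-15) break
    ## merge bj into bi
    ## row then column addition leaves e[bi,bi] increased by exactly
    ## e[bj,bj] + 2*e[bi,bj], the CNM diagonal update
    e[bi, ] <- e[bi, ] + e[bj, ]
    e[, bi] <- e[, bi] + e[, bj]
    a[bi] <- a[bi] + a[bj]
    comm[[bi]] <- c(comm[[bi]], comm[[bj]])
    label[bi] <- min(label[bi], label[bj])
    active[bj] <- FALSE
    e[bj, ] <- 0; e[, bj] <- 0; a[bj] <- 0
  }
  membership <- integer(n)
  act <- which(active)
  ## stable module numbering: by decreasing size, then lexicographic label
  ord <- act[order(-vapply(comm[act], length, integer(1)), label[act])]
  for (r in seq_along(ord)) membership[comm[[ord[r]]]] <- r
  names(membership) <- ids
  q_final <- modularity_q(membership, net$edges, ids)
  sizes <- table(membership)
  keep <- as.integer(names(sizes))[sizes >= min_module_size]
  ## modules of isolated singletons are not meaningful communities
  keep <- keep[vapply(keep, function(mm)
    sum(net$nodes$degree[membership == mm]) > 0, logical(1))]
  modules <- data.frame(
    module = keep,
    size = as.integer(sizes[as.character(keep)]),
    members = vapply(keep, function(mm)
      paste(sort(ids[membership == mm]), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(list(membership = membership, modularity = q_final,
                 modules = modules, min_module_size = min_module_size),
            class = "module_report")
}

#' @export
print.module_report <- function(x, ...) {
  cat("Modularity Q =", fmt_real(x$modularity), ";",
      nrow(x$modules), "module(s) of size >=", x$min_module_size, "\n")
  if (nrow(x$modules)) {
    for (i in seq_len(nrow(x$modules))) {
      cat("  M", x$modules$module[i], ": ", x$modules$size[i], " nodes\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Keystone ranking by betweenness centrality
#'
#' Ranks nodes by betweenness (descending), breaking ties by degree
#' (descending) and then OTU id.
#'
#' @param net `"cooccurrence_network"` with centralities computed (computed
#'   on the fly otherwise).
#' @param top_k number of nodes to return.
#' @return data frame of the top-ranked nodes with `rank`, `otu_id`,
#'   `betweenness`, `degree`, `taxonomy`, `source`.
#' @export
identify_keystones <- function(net, top_k = 5) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (is.null(net$nodes$betweenness)) net <- centralities(net)
  nd <- net$nodes
  ord <- order(-nd$betweenness, -nd$degree, nd$otu_id)
  out <- nd[ord, c("otu_id", "betweenness", "degree", "taxonomy", "source")]
  out <- utils::head(out, top_k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Module source composition
#'
#' Counts, per module, how many member OTUs were selected by each
#' differential-abundance contrast. A module is labeled `"<T>-derived"` when
#' every member traces to contrast `T`, and `"mixed"` otherwise.
#'
#' @param report `"module_report"` object.
#' @param selection data frame with `otu_id` and `source` (comma-joined
#'   contrast labels) from [select_network_otus()].
#' @return data frame per module: `module`, `size`, `n_CF`, `n_CFM`,
#'   `n_shared`, `label`.
#' @export
module_sources <- function(report, selection) {
  stopifnot(inherits(report, "module_report"))
  mods <- report$modules
  if (!nrow(mods)) {
    return(data.frame(module = integer(0), size = integer(0),
                      n_CF = integer(0), n_CFM = integer(0),
                      n_shared = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  src <- setNames(selection$source, selection$otu_id)
  out <- lapply(seq_len(nrow(mods)), function(i) {
    members <- strsplit(mods$members[i], ",", fixed = TRUE)[[1]]
    missing_m <- members[!members %in% names(src)]
    if (length(missing_m)) {
      stop("module_sources: member(s) without a source label: ",
           paste(missing_m, collapse = ", "), call. = FALSE)
    }
    sets <- strsplit(src[members], ",", fixed = TRUE)
    has_cf <- vapply(sets, function(s) "CF" %in% s, logical(1))
    has_cfm <- vapply(sets, function(s) "CFM" %in% s, logical(1))
    label <- if (all(has_cfm)) "CFM-derived"
             else if (all(has_cf)) "CF-derived"
             else "mixed"
    data.frame(module = mods$module[i], size = mods$size[i],
               n_CF = sum(has_cf), n_CFM = sum(has_cfm),
               n_shared = sum(has_cf & has_cfm), label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Module-environment Mantel tests
#'
#' For one module: Bray-Curtis dissimilarity among samples restricted to the
#' module's OTU counts, against the Euclidean distance of each standardized
#' environmental variable, through the [mantel_test()] primitive. P-values
#' are BH-adjusted across the variables tested for the module.
#'
#' @param module_otus character vector of member OTU ids (>= the module size
#'   floor).
#' @param table OTU count matrix for the stratum's samples.
#' @param metadata sample metadata data frame.
#' @param variables environmental variable names to test.
#' @param n_perm Mantel permutations per variable.
#' @param seed integer seed.
#' @param min_module_size smallest admissible module.
#' @return data frame per variable: `variable`, `mantel_r`, `p`, `q`.
#' @export
module_env_mantel <- function(module_otus, table, metadata, variables,
                              n_perm = 999, seed = 1L, min_module_size = 4) {
  if (length(module_otus) < min_module_size) {
    stop("module_env_mantel: module smaller than ", min_module_size,
         " members", call. = FALSE)
  }
  sub <- table[module_otus, , drop = FALSE]
  d1 <- bray_curtis(sub)
  env <- standardize_env(metadata, variables)
  env <- env[match(colnames(table), rownames(env)), , drop = FALSE]
  res <- lapply(seq_along(variables), function(j) {
    d2 <- as.matrix(dist(env[, j]))
    dimnames(d2) <- dimnames(d1)
    mt <- mantel_test(d1, d2, n_perm = n_perm, seed = seed + j)
    data.frame(variable = variables[j], mantel_r = mt$r, p = mt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- if (all(is.na(out$p))) NA_real_ else adjust_bh(ifelse(is.na(out$p), 1, out$p))
  out
}
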