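test_that("Spearman matrix matches hand-ranked Pearson and handles ties", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40))
  colnames(x) <- paste0("s", 1:4)
  cm <- spearman_matrix(x)
  expect_equal(cm$rho["a", "b"], 1)

  y <- rbind(a = c(1, 2, 3, 4), b = c(3, 1, 2, 5))
  colnames(y) <- paste0("s", 1:4)
  ## hand evaluation on the first three points of the classic example
  z <- rbind(a = c(1, 2, 3, 9), b = c(3, 1, 2, 9))
  colnames(z) <- paste0("s", 1:4)
  expect_equal(spearman_matrix(z)$rho["a", "b"],
               oracle_spearman(z["a", ], z["b", ]), tolerance = 1e-12)

  ## symmetric, unit diagonal, q dominates p
  set.seed(30)
  m <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(paste0("o", 1:12), paste0("s", 1:10)))
  cm2 <- spearman_matrix(m)
  expect_equal(cm2$rho, t(cm2$rho))
  expect_equal(unname(diag(cm2$rho)), rep(1, 12))
  up <- upper.tri(cm2$p)
  expect_true(all(cm2$q[up] >= cm2$p[up] - 1e-15))

  ## zero-variance row flagged: rho 0, p 1 against all partners
  m[3, ] <- 5
  cm3 <- spearman_matrix(m)
  expect_equal(cm3$constant_otus, "o3")
  expect_equal(unname(cm3$rho["o3", "o1"]), 0)
  expect_equal(unname(cm3$p["o3", "o1"]), 1)

  expect_error(spearman_matrix(m[, 1:3]), ">= 4 samples")
})

test_that("Spearman p-values are calibrated on independent pairs", {
  set.seed(31)
  n <- 30
  hits <- 0
  n_pairs <- 400
  for (k in seq_len(n_pairs)) {
    x <- rbind(a = rnorm(n), b = rnorm(n))
    colnames(x) <- paste0("s", 1:n)
    cm <- spearman_matrix(x)
    hits <- hits + (cm$p["a", "b"] < 0.05)
  }
  ci <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / n_pairs)
  expect_gt(hits / n_pairs, ci[1])
  expect_lt(hits / n_pairs, ci[2])
})

test_that("RMT scan finds Poisson spacings on null and planted structure", {
  ## dense null: low thresholds look GOE, a Poisson-consistent threshold
  ## exists inside the grid
  set.seed(32)
  x <- matrix(rnorm(150 * 30), 150, 30,
              dimnames = list(sprintf("v%03d", 1:150), NULL))
  scan <- rmt_threshold(spearman_matrix(x))
  expect_true(scan$chosen_threshold %in% scan$scan$threshold)
  expect_gte(min(scan$scan$chi_sq_p, na.rm = TRUE), 0)

  ## planted blocks: threshold below the within-block level, blocks kept
  ## as connected components
  bl <- simulate_correlated_blocks(n_blocks = 4, block_size = 10,
                                   n_noise = 10, n_samples = 250, seed = 1)
  cm <- spearman_matrix(bl$abundances)
  scan2 <- rmt_threshold(cm)
  expect_lt(scan2$chosen_threshold, 0.9)
  net <- build_network(cm, scan2$chosen_threshold, 0.001)
  adj <- net_adjacency(net)
  for (b in as.character(1:4)) {
    mem <- names(bl$labels)[!is.na(bl$labels) & bl$labels == b]
    sub <- adj[mem, mem]
    ## block internally connected (single BFS component)
    seen <- mem[1]
    repeat {
      nxt <- unique(c(seen, unlist(lapply(seen, function(v)
        mem[sub[v, ] > 0]))))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    expect_setequal(seen, mem)
    ## no edges leaving the block
    expect_equal(sum(adj[mem, setdiff(rownames(adj), mem)]), 0)
  }

  ## degenerate identity matrix: no numerical failure, fallback warning
  ids <- sprintf("u%02d", 1:25)
  idcm <- structure(list(rho = diag(25), p = matrix(1, 25, 25),
                         q = matrix(1, 25, 25), otu_ids = ids,
                         n_samples = 10, constant_otus = character(0)),
                    class = "correlation_matrix")
  dimnames(idcm$rho) <- list(ids, ids)
  expect_warning(scan3 <- rmt_threshold(idcm), "degenerate|no stable")
  expect_true(is.finite(scan3$chosen_threshold))

  expect_error(rmt_threshold(spearman_matrix(x[1:10, ])), "fewer than 20")
  expect_error(rmt_threshold(spearman_matrix(x), grid = c(0, 1.2)), "grid")
})

test_that("network construction enforces both edge cutoffs and no loops", {
  ids <- c("A", "B", "C")
  rho <- matrix(c(1, 0.8, 0.2, 0.8, 1, -0.85, 0.2, -0.85, 1), 3,
                dimnames = list(ids, ids))
  q <- matrix(c(0, 5e-4, 0.5, 5e-4, 0, 0.01, 0.5, 0.01, 0), 3,
              dimnames = list(ids, ids))
  cm <- structure(list(rho = rho, p = q, q = q, otu_ids = ids,
                       n_samples = 20, constant_otus = character(0)),
                  class = "correlation_matrix")
  net <- build_network(cm, 0.79, 0.001)
  ## A-B passes both cutoffs; B-C fails the q cutoff; A-C fails |rho|
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
  expect_equal(net$edges$rho, 0.8)
  expect_true(all(net$edges$from != net$edges$to))
  expect_true(net$nodes$isolated[net$nodes$otu_id == "C"])

  ## negative correlations form edges too, sign preserved
  q2 <- q; q2["B", "C"] <- q2["C", "B"] <- 1e-5
  cm2 <- cm; cm2$q <- q2
  net2 <- build_network(cm2, 0.79, 0.001)
  expect_equal(net2$edges$rho[net2$edges$from == "B"], -0.85)
})

test_that("every reported edge satisfies both cutoffs on real pipeline input", {
  ds <- generate_dataset(small_design(seed = 2))
  cm <- spearman_matrix(ds$otu_table[1:40, ])
  net <- build_network(cm, 0.5, 0.01)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$from[k]; j <- net$edges$to[k]
    expect_gte(abs(cm$rho[i, j]), 0.5)
    expect_lt(cm$q[i, j], 0.01)
  }
  ## degree equals incident edge count
  for (v in net$nodes$otu_id) {
    expect_equal(net$nodes$degree[net$nodes$otu_id == v],
                 sum(net$edges$from == v) + sum(net$edges$to == v))
  }
})

test_that("betweenness matches simple configurations and brute force", {
  ## path A-B-C
  p <- centralities(make_test_network(c("A", "B", "C"),
                                      c("A", "B"), c("B", "C")))
  expect_equal(p$nodes$betweenness, c(0, 1, 0))

  ## star with 4 leaves: center carries C(4,2) = 6
  st <- centralities(make_test_network(
    c("c", "l1", "l2", "l3", "l4"),
    rep("c", 4), paste0("l", 1:4)))
  expect_equal(st$nodes$betweenness[st$nodes$otu_id == "c"], 6)
  expect_equal(sum(st$nodes$betweenness), 6)

  ## exhaustive oracle on random graphs up to 8 nodes
  set.seed(33)
  for (k in 1:60) {
    n <- sample(4:8, 1)
    ids <- paste0("n", seq_len(n))
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
    a <- a + t(a)
    up <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
    if (!nrow(up)) next
    net <- make_test_network(ids, ids[up[, 1]], ids[up[, 2]])
    net <- centralities(net)
    expect_equal(net$nodes$betweenness, oracle_betweenness(a),
                 tolerance = 1e-10)
  }
})

test_that("betweenness agrees with igraph on a larger graph", {
  skip_if_not_installed("igraph")
  set.seed(34)
  g <- igraph::sample_gnp(40, 0.12)
  el <- igraph::as_edgelist(g)
  ids <- paste0("n", 1:40)
  net <- centralities(make_test_network(ids, ids[el[, 1]], ids[el[, 2]]))
  expect_equal(net$nodes$betweenness,
               unname(igraph::betweenness(g, directed = FALSE)),
               tolerance = 1e-10)
})

test_that("greedy modularity finds planted partitions and exact Q", {
  ## two disconnected triangles: Q = 0.5, triangles recovered
  tri <- make_test_network(
    paste0("t", 1:6),
    c("t1", "t2", "t1", "t4", "t5", "t4"),
    c("t2", "t3", "t3", "t5", "t6", "t6"))
  mods <- detect_modules(tri, min_module_size = 3)
  expect_equal(mods$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mods$membership)), 2L)
  expect_equal(length(unique(mods$membership[paste0("t", 1:3)])), 1L)

  ## complete graph: a single community, Q = 0
  pairs <- t(combn(paste0("k", 1:5), 2))
  k5 <- make_test_network(paste0("k", 1:5), pairs[, 1], pairs[, 2])
  mods5 <- detect_modules(k5, 4)
  expect_equal(length(unique(mods5$membership)), 1L)
  expect_equal(mods5$modularity, 0, tolerance = 1e-12)

  ## edgeless: warning, singleton communities, Q = 0
  e0 <- make_test_network(paste0("x", 1:4), character(0), character(0))
  expect_warning(mods0 <- detect_modules(e0, 4), "edgeless")
  expect_equal(mods0$modularity, 0)
  expect_equal(nrow(mods0$modules), 0L)

  ## reported Q equals independent recomputation on random graphs
  set.seed(35)
  for (k in 1:10) {
    n <- 15
    ids <- paste0("r", seq_len(n))
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, 0.25)
    a <- a + t(a)
    up <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
    if (!nrow(up)) next
    net <- make_test_network(ids, ids[up[, 1]], ids[up[, 2]])
    mods <- detect_modules(net, 4)
    expect_equal(mods$modularity,
                 oracle_modularity(mods$membership, net$edges),
                 tolerance = 1e-12)
  }
})

test_that("planted correlation blocks are recovered as modules", {
  ok <- 0
  for (sd_ in 1:5) {
    bl <- simulate_correlated_blocks(n_blocks = 2, block_size = 10,
                                     n_noise = 5, n_samples = 120,
                                     seed = sd_)
    cm <- spearman_matrix(bl$abundances)
    net <- build_network(cm, 0.5, 0.001)
    mods <- detect_modules(net, 4)
    truth <- bl$labels[!is.na(bl$labels)]
    pred <- mods$membership[names(truth)]
    ok <- ok + (oracle_ari(truth, pred) >= 0.8)
  }
  expect_gte(ok, 4)
})

test_that("keystone ranking follows betweenness with deterministic ties", {
  st <- centralities(make_test_network(
    c("hub", "l1", "l2", "l3"), rep("hub", 3), paste0("l", 1:3)))
  ks <- identify_keystones(st, 2)
  expect_equal(ks$otu_id[1], "hub")
  expect_equal(ks$rank, 1:2)

  ## equal betweenness: higher degree wins, then lexicographic id
  net <- make_test_network(
    c("a", "b", "z1", "z2", "z3"),
    c("a", "a", "a", "b", "b"),
    c("z1", "z2", "b", "z2", "z3"))
  net <- centralities(net)
  ks2 <- identify_keystones(net, 5)
  bt <- setNames(net$nodes$betweenness, net$nodes$otu_id)
  expect_true(all(diff(ks2$betweenness) <= 1e-12))
  ties <- ks2[ks2$betweenness == max(bt), ]
  if (nrow(ties) > 1) {
    expect_true(all(diff(ties$degree) <= 0))
  }
})

test_that("module source attribution counts contrasts and labels modules", {
  report <- structure(list(
    membership = setNames(c(1, 1, 1, 1, 1, 2, 2, 2, 2),
                          paste0("O", 1:9)),
    modularity = 0.4,
    modules = data.frame(
      module = 1:2, size = c(5L, 4L),
      members = c(paste(paste0("O", 1:5), collapse = ","),
                  paste(paste0("O", 6:9), collapse = ",")),
      stringsAsFactors = FALSE),
    min_module_size = 4L), class = "module_report")
  sel <- data.frame(otu_id = paste0("O", 1:9),
                    source = c(rep("CFM", 5), "CF", "CFM", "CF,CFM", "CF"),
                    stringsAsFactors = FALSE)
  ms <- module_sources(report, sel)
  expect_equal(ms$label[1], "CFM-derived")
  expect_equal(ms$n_CFM[1], 5L)
  expect_equal(ms$n_CF[1], 0L)
  expect_equal(ms$label[2], "mixed")
  expect_equal(ms$n_shared[2], 1L)

  sel_missing <- sel[-3, ]
  expect_error(module_sources(report, sel_missing), "O3")

  empty <- report
  empty$modules <- empty$modules[0, ]
  expect_equal(nrow(module_sources(empty, sel)), 0L)
})

test_that("module-environment Mantel detects planted drivers", {
  ds <- generate_dataset(simulation_design(
    n_otus = 150, n_diff_otus = 0, n_modules = 1,
    module_size_range = c(8, 8), library_size_range = c(4000, 6000),
    seed = 3))
  truth <- ds$truth
  members <- truth$otus$otu_id[!is.na(truth$otus$module)]
  env_true <- truth$modules$env_var[1]
  res <- module_env_mantel(members, ds$otu_table, ds$metadata,
                           c("pH", "MO", "SOC", "TN", "NH4", "NO3",
                             "OP", "AK"),
                           n_perm = 199, seed = 1)
  expect_equal(res$variable[which.max(res$mantel_r)], env_true)
  expect_lt(res$p[res$variable == env_true], 0.05)

  ## degenerate module counts: r = 0 with warning (one per variable)
  const <- matrix(5L, 4, 8, dimnames = list(paste0("M", 1:4),
                                            ds$metadata$sample_id[1:8]))
  expect_warning(
    module_env_mantel(paste0("M", 1:4), const, ds$metadata[1:8, ],
                      "pH", n_perm = 99, seed = 1),
    "degenerate")
  res2 <- suppressWarnings(
    module_env_mantel(paste0("M", 1:4), const, ds$metadata[1:8, ],
                      c("pH", "SOC"), n_perm = 99, seed = 1))
  expect_equal(res2$mantel_r, c(0, 0))

  expect_error(module_env_mantel(members[1:2], ds$otu_table, ds$metadata,
                                 "pH", 99, 1), "smaller")
})
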