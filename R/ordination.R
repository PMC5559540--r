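## Community ordination and distance-based statistics: Hellinger transform,
## Bray-Curtis dissimilarity, principal coordinates analysis, ANOSIM, db-RDA
## with per-variable vector fitting, environment standardization, and the
## Mantel test primitive reused by the network stage.

#' Hellinger transform
#'
#' Per sample j, `y_ij = sqrt(n_ij / N_j)`: the square root of relative
#' abundances. Each transformed sample vector has unit sum of squares, which
#' downweights dominant taxa before distance computation.
#'
#' @param table count or abundance matrix (OTUs x samples) with positive
#'   sample totals.
#' @return numeric matrix of the same shape.
#' @export
hellinger_transform <- function(table) {
  if (any(table < 0)) stop("negative abundances", call. = FALSE)
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("hellinger_transform: zero-total sample(s): ",
         paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sqrt(sweep(table, 2, totals, "/"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over the abundance
#' columns. A pair of samples that are both entirely zero gets `d = 0` with a
#' warning.
#'
#' @param abundances non-negative matrix with samples as columns.
#' @return symmetric dissimilarity matrix (samples x samples), zero diagonal,
#'   entries in `[0, 1]`.
#' @export
bray_curtis <- function(abundances) {
  if (any(abundances < 0)) stop("negative abundances", call. = FALSE)
  totals <- colSums(abundances)
  num <- as.matrix(dist(t(abundances), method = "manhattan"))
  den <- outer(totals, totals, "+")
  d <- num / den
  if (any(!is.finite(d))) {
    warning("bray_curtis: sample pair(s) with zero total abundance set to d = 0",
            call. = FALSE)
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(abundances), colnames(abundances))
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported as a mass but neither
#' corrected nor embedded.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return an object of class `"pcoa_ord"`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (over positive eigenvalues) and
#'   `negative_eigenvalue_mass`.
#' @export
pcoa <- function(d) {
  validate_dissimilarity(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  ## Gower centering: (I - 11'/n) A (I - 11'/n)
  g <- a - matrix(rowMeans(a), n, n) - matrix(colMeans(a), n, n, byrow = TRUE) +
    mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-12 + 1e-12
  pos <- e$values > tol
  if (any(pos)) {
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos))
    dimnames(coords) <- list(rownames(d),
                             paste0("Axis", seq_len(ncol(coords))))
  } else {
    coords <- matrix(numeric(0), n, 0, dimnames = list(rownames(d), NULL))
  }
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = if (any(pos)) e$values[pos] / sum(e$values[pos])
                           else numeric(0),
    negative_eigenvalue_mass = sum(abs(e$values[e$values < -tol]))
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat("  samples:", nrow(x$coordinates),
      " positive axes:", ncol(x$coordinates), "\n")
  if (length(x$proportion_explained)) {
    cat("  first axes explain:",
        paste0(fmt_real(100 * utils::head(x$proportion_explained, 3)), "%",
               collapse = ", "), "\n")
  }
  cat("  negative eigenvalue mass:", fmt_real(x$negative_eigenvalue_mass), "\n")
  invisible(x)
}

## shared rank helper: mid-ranks for ties
rank_mid <- function(x) rank(x, ties.method = "average")

## all n! permutations of 1..n as a matrix (rows); small n only
all_permutations <- function(n) {
  if (n > 8) stop("all_permutations: n too large", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (mid-ranks for ties) and compares mean
#' between-group rank to mean within-group rank:
#' `R = (mean_between - mean_within) / (M/2)` with `M = n(n-1)/2`. The
#' p-value is one-sided (large `R`) under random permutation of group labels,
#' with the add-one convention `p = (1 + hits) / (1 + n_perm)`. When `n! <=
#' n_perm` (small sample sets) every relabeling is enumerated instead and
#' the exact tail probability is returned.
#'
#' @param d dissimilarity matrix (samples x samples).
#' @param groups vector of group labels, one per sample; at least two groups
#'   with at least two samples each.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return object of class `"anosim_result"` with `R`, `p_value`,
#'   `n_permutations` and the permuted statistics.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1L) {
  validate_dissimilarity(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2) stop(">= 2 groups required", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("anosim: every group needs >= 2 samples", call. = FALSE)
  }
  n <- nrow(d)
  up <- upper.tri(d)
  rk <- rank_mid(d[up])
  m <- n * (n - 1) / 2
  pair_i <- row(d)[up]
  pair_j <- col(d)[up]
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / (m / 2)
  }
  r_obs <- stat(groups)
  if (n <= 8 && factorial(n) <= n_perm) {
    ## exhaustive: enumerate every relabeling, p is the exact tail
    pm <- all_permutations(n)
    r_perm <- apply(pm, 1, function(idx) stat(groups[idx]))
    return(structure(list(
      R = r_obs,
      p_value = mean(r_perm >= r_obs - 1e-12),
      n_permutations = nrow(pm),
      permuted_R = r_perm,
      exact = TRUE
    ), class = "anosim_result"))
  }
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) stat(groups[sample.int(n)]),
                   numeric(1))
  structure(list(
    R = r_obs,
    p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    n_permutations = as.integer(n_perm),
    permuted_R = r_perm,
    exact = FALSE
  ), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", fmt_real(x$R), " p =", fmt_pval(x$p_value),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Standardize environmental variables
#'
#' Centers each requested variable to mean 0 and scales to sample standard
#' deviation 1 (denominator n-1).
#'
#' @param metadata data frame of per-sample metadata.
#' @param variables character vector of numeric column names.
#' @return numeric matrix (samples x variables) with row names taken from
#'   `metadata`'s `sample_id` column (or row names).
#' @export
standardize_env <- function(metadata, variables) {
  missing_v <- setdiff(variables, names(metadata))
  if (length(missing_v)) {
    stop("standardize_env: variable(s) absent: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(metadata[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("environmental variables must be numeric", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("standardize_env: zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  rn <- if ("sample_id" %in% names(metadata)) metadata$sample_id
        else rownames(metadata)
  rownames(out) <- rn
  out
}

#' Distance-based redundancy analysis
#'
#' PCoA of the dissimilarity matrix (positive axes), then a least-squares
#' projection of the coordinate matrix onto the span of the environmental
#' variables. `pseudo_F = (constrained/q) / (residual/(n-q-1))`, tested by
#' permuting rows of the environment matrix. Per-variable goodness-of-fit
#' follows the vector-fitting convention: `R^2` of each variable regressed on
#' the first two ordination axes, with its own permutation p-value.
#'
#' @param d dissimilarity matrix (samples x samples).
#' @param env standardized environment matrix from [standardize_env()].
#' @param n_perm permutations for both the model test and the vector fits.
#' @param seed integer seed.
#' @return object of class `"db_rda_result"`: constrained/unconstrained
#'   eigenvalues, inertias, `pseudo_F`, `model_p`, and an `envfit` data frame
#'   (`variable`, `r2`, `p`).
#' @export
db_rda <- function(d, env, n_perm = 999, seed = 1L) {
  validate_dissimilarity(d)
  env <- as.matrix(env)
  n <- nrow(d)
  if (nrow(env) != n) stop("env rows must match d samples", call. = FALSE)
  q <- ncol(env)
  if (q >= n) stop("db_rda: more variables than samples", call. = FALSE)
  qr_env <- qr(scale(env, scale = FALSE))
  if (qr_env$rank < q) {
    drop_idx <- qr_env$pivot[(qr_env$rank + 1):q]
    stop("db_rda: rank-deficient environment; collinear variable(s): ",
         paste(colnames(env)[drop_idx], collapse = ", "), call. = FALSE)
  }
  ord <- pcoa(d)
  y <- ord$coordinates             # centered by construction
  total <- sum(ord$eigenvalues[ord$eigenvalues > 0])

  constrained_inertia <- function(x) {
    fit <- qr.fitted(qr(cbind(1, x)), y)
    sum(fit^2)
  }
  cons <- constrained_inertia(env)
  resid_in <- total - cons
  pseudo_f <- (cons / q) / (resid_in / (n - q - 1))

  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(k) {
    xp <- env[sample.int(n), , drop = FALSE]
    cp <- constrained_inertia(xp)
    (cp / q) / ((total - cp) / (n - q - 1))
  }, numeric(1))
  model_p <- (1 + sum(f_perm >= pseudo_f)) / (1 + n_perm)

  ## eigenvalues of the constrained and unconstrained components
  fit <- qr.fitted(qr(cbind(1, env)), y)
  res <- y - fit
  cons_eig <- svd(fit, nu = 0, nv = 0)$d^2
  uncons_eig <- svd(res, nu = 0, nv = 0)$d^2

  ## vector fitting on the plotted plane (first two axes)
  envfit <- fit_env_vectors(y, env, n_perm = n_perm, seed = seed + 1L)

  structure(list(
    constrained_eigenvalues = cons_eig[cons_eig > 1e-12],
    unconstrained_eigenvalues = uncons_eig[uncons_eig > 1e-12],
    total_inertia = total,
    constrained_inertia = cons,
    unconstrained_inertia = resid_in,
    pseudo_F = pseudo_f,
    model_p = model_p,
    n_permutations = as.integer(n_perm),
    envfit = envfit,
    ordination = ord
  ), class = "db_rda_result")
}

#' @export
print.db_rda_result <- function(x, ...) {
  cat("db-RDA:", fmt_real(100 * x$constrained_inertia / x$total_inertia),
      "% of inertia constrained; pseudo-F =", fmt_real(x$pseudo_F),
      " p =", fmt_pval(x$model_p), "\n")
  ef <- x$envfit[order(-x$envfit$r2), ]
  for (i in seq_len(nrow(ef))) {
    cat(sprintf("  %-12s R2 = %s  p = %s\n", ef$variable[i],
                fmt_real(ef$r2[i]), fmt_pval(ef$p[i])))
  }
  invisible(x)
}

## per-variable R^2 of each environmental vector on the first two
## ordination axes, with permutation p-values (vector-fitting convention)
fit_env_vectors <- function(coords, env, n_perm = 999, seed = 1L) {
  n <- nrow(coords)
  axes <- coords[, seq_len(min(2L, ncol(coords))), drop = FALSE]
  qr_axes <- qr(cbind(1, axes))
  fit_r2 <- function(v) {
    vc <- v - mean(v)
    1 - sum(qr.resid(qr_axes, v)^2) / sum(vc^2)
  }
  out <- data.frame(variable = colnames(env), r2 = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  set.seed(seed)
  for (j in seq_len(ncol(env))) {
    v <- env[, j]
    r2_obs <- fit_r2(v)
    r2_perm <- vapply(seq_len(n_perm), function(k) fit_r2(v[sample.int(n)]),
                      numeric(1))
    out$r2[j] <- r2_obs
    out$p[j] <- (1 + sum(r2_perm >= r2_obs)) / (1 + n_perm)
  }
  out
}

#' Environmental vector fitting on ordination axes
#'
#' Fits each environmental variable to the first two PCoA axes of the
#' dissimilarity matrix and reports the goodness-of-fit `R^2` with a
#' permutation p-value. This is the per-variable half of [db_rda()]; it
#' remains usable when the sample count is too small to support the full
#' constrained model (more variables than residual degrees of freedom).
#'
#' @inheritParams db_rda
#' @return data frame with `variable`, `r2`, `p`.
#' @export
env_fit <- function(d, env, n_perm = 999, seed = 1L) {
  validate_dissimilarity(d)
  env <- as.matrix(env)
  if (nrow(env) != nrow(d)) stop("env rows must match d samples", call. = FALSE)
  ord <- pcoa(d)
  if (ncol(ord$coordinates) < 1) {
    stop("env_fit: degenerate ordination (no positive eigenvalues)",
         call. = FALSE)
  }
  fit_env_vectors(ord$coordinates, env, n_perm = n_perm, seed = seed)
}

#' Mantel test between two dissimilarity matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' permutation p-value obtained by jointly permuting rows and columns of the
#' second matrix. When `n! <= n_perm` all permutations are enumerated and
#' the exact tail probability is returned.
#'
#' @param d1,d2 dissimilarity matrices over the same samples in the same
#'   order (checked via dimnames when present).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p_value` and `n_permutations`. A degenerate matrix
#'   (zero variance among dissimilarities) yields `r = 0` with a warning.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  validate_dissimilarity(d1, "d1")
  validate_dissimilarity(d2, "d2")
  if (nrow(d1) != nrow(d2)) stop("mantel: sample sets differ", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("mantel: sample sets/order differ", call. = FALSE)
  }
  n <- nrow(d1)
  up <- upper.tri(d1)
  v1 <- d1[up]
  v2 <- d2[up]
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("mantel: degenerate (constant) dissimilarities; r reported as 0",
            call. = FALSE)
    return(list(r = 0, p_value = NA_real_, n_permutations = as.integer(n_perm)))
  }
  r_obs <- cor(v1, v2)
  if (n <= 7 && factorial(n) <= n_perm) {
    ## exhaustive: all n! joint row/column permutations, exact tail p
    pm <- all_permutations(n)
    r_perm <- apply(pm, 1, function(idx) cor(v1, d2[idx, idx][up]))
    return(list(r = r_obs,
                p_value = mean(r_perm >= r_obs - 1e-12),
                n_permutations = nrow(pm),
                exact = TRUE))
  }
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    cor(v1, d2[idx, idx][up])
  }, numeric(1))
  list(r = r_obs,
       p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
       n_permutations = as.integer(n_perm),
       exact = FALSE)
}
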