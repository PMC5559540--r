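## Negative-binomial Wald differential abundance between fertilization
## treatments: median-of-ratios size factors, moment dispersion estimates
## shrunk toward a 1/mean trend, per-OTU NB GLM fits (log link, IRLS with
## fixed dispersion), BH adjustment and enriched/depleted OTU classification.

#' Median-of-ratios size factors
#'
#' Per-OTU reference = geometric mean across samples, computed over OTUs
#' positive in every sample; each sample's size factor is the median of its
#' count-to-reference ratios. When no OTU is positive everywhere, a
#' pseudo-reference over OTUs positive in at least half the samples is used
#' (geometric mean of the positive counts), with a logged note.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @return named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(table) {
  validate_otu_table(table)
  n_samp <- ncol(table)
  if (n_samp == 1L) return(setNames(1, colnames(table)))
  all_pos <- rowSums(table > 0) == n_samp
  if (any(all_pos)) {
    sub <- table[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
  } else {
    half_pos <- rowSums(table > 0) >= n_samp / 2
    if (!any(half_pos)) {
      stop("size_factors: no OTU positive in >= 50% of samples", call. = FALSE)
    }
    log_warn("size_factors: no OTU positive in all samples; ",
             "pseudo-reference over ", sum(half_pos), " OTUs")
    sub <- table[half_pos, , drop = FALSE]
    ref <- exp(apply(sub, 1, function(r) mean(log(r[r > 0]))))
  }
  s <- apply(sub, 2, function(col) median((col / ref)[ref > 0]))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size_factors: non-positive size factor computed", call. = FALSE)
  }
  setNames(s, colnames(table))
}

#' Per-OTU dispersion estimates with trend shrinkage
#'
#' NB dispersion `alpha` in `var = mu + alpha * mu^2`. Per OTU, a
#' method-of-moments estimate from within-group variances of normalized
#' counts, `alpha_hat = max(0, (var_w - mu) / mu^2)`, is shrunk toward a
#' mean-dispersion trend `alpha_tr(mu) = a1/mu + a0` (robust fit over OTUs)
#' by averaging with weights proportional to within-group degrees of freedom
#' versus a fixed prior weight.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @param s size factors from [size_factors()].
#' @param design factor of group labels (one per sample); at least one group
#'   must have replication.
#' @param prior_df prior degrees of freedom controlling shrinkage strength.
#' @param alpha_min lower floor on the returned dispersions.
#' @return named numeric vector of final dispersions, one per OTU.
#' @export
estimate_dispersions <- function(table, s, design, prior_df = 6,
                                 alpha_min = 1e-8) {
  validate_otu_table(table)
  design <- as.factor(design)
  tab <- table(design)
  df_w <- sum(tab - 1L)
  if (df_w < 1) stop("estimate_dispersions: no replication in any group",
                     call. = FALSE)
  norm <- sweep(table, 2, s, "/")
  mu_bar <- rowMeans(norm)
  ## pooled within-group variance of normalized counts
  var_w <- rowSums(vapply(levels(design), function(g) {
    cols <- design == g
    if (sum(cols) < 2) return(numeric(nrow(norm)))
    m <- rowMeans(norm[, cols, drop = FALSE])
    rowSums((norm[, cols, drop = FALSE] - m)^2)
  }, numeric(nrow(norm)))) / df_w
  alpha_hat <- pmax(0, (var_w - mu_bar) / mu_bar^2)
  alpha_hat[!is.finite(alpha_hat)] <- 0

  ## robust trend alpha ~ a1/mu + a0 over informative OTUs
  use <- is.finite(mu_bar) & mu_bar > 0
  a0 <- 0; a1 <- 0
  if (sum(use) >= 10 && any(alpha_hat[use] > 0)) {
    dat <- data.frame(a = alpha_hat[use], im = 1 / mu_bar[use])
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(a ~ im, data = dat, maxit = 50)),
      error = function(e) lm(a ~ im, data = dat))
    cf <- coef(fit)
    a0 <- max(0, cf[[1]]); a1 <- max(0, cf[[2]])
  }
  alpha_tr <- ifelse(mu_bar > 0, a1 / mu_bar + a0, a0)
  alpha_final <- (df_w * alpha_hat + prior_df * alpha_tr) / (df_w + prior_df)
  setNames(pmax(alpha_min, alpha_final), rownames(table))
}

## NB GLM fit for one OTU: mu_j = s_j * exp(b0 + b1 * x_j), fixed dispersion.
## Returns log2 scale coefficient, its SE from the expected information, and
## a convergence flag.
nb_irls_fit <- function(y, s, x, alpha, max_iter = 50, tol = 1e-10) {
  offset <- log(s)
  xm <- cbind(1, x)
  grp1 <- x == 1
  m0 <- sum(y[!grp1]) / sum(s[!grp1])
  m1 <- sum(y[grp1]) / sum(s[grp1])
  b <- c(log(max(m0, 1e-8)), log(max(m1, 1e-8)) - log(max(m0, 1e-8)))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + xm %*% b
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- as.numeric(mu / (1 + alpha * mu))
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(xm * w)
    b_new <- tryCatch(solve(xtw %*% xm, xtw %*% z),
                      error = function(e) NULL)
    if (is.null(b_new) || any(!is.finite(b_new))) break
    b_new <- pmin(pmax(b_new, -50), 50)
    delta <- max(abs(b_new - b))
    b <- as.numeric(b_new)
    if (delta < tol) { ok <- TRUE; break }
  }
  se <- NA_real_
  if (ok) {
    mu <- pmin(pmax(exp(offset + xm %*% b), 1e-10), 1e12)
    w <- as.numeric(mu / (1 + alpha * mu))
    info <- t(xm * w) %*% xm
    cov_b <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov_b) || cov_b[2, 2] <= 0) ok <- FALSE
    else se <- sqrt(cov_b[2, 2])
  }
  list(beta_log2 = b[2] / log(2), se_log2 = se / log(2), converged = ok)
}

#' Negative-binomial Wald test for a treatment contrast
#'
#' Fits, per OTU, `mu_ij = s_j * q_i * 2^(beta_i * x_j)` (NB GLM, log link,
#' IRLS with the supplied fixed dispersion) over the samples of the two
#' contrast levels, and reports the log2 fold change `beta_i`, its standard
#' error, and the two-sided Wald p-value. OTUs that are all-zero in both
#' groups, or whose fit does not converge, are flagged and given
#' `beta = 0, p = 1` (all-zero) or `p = 1` (non-converged); the table is
#' never aborted.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @param s size factors for the same samples.
#' @param alpha per-OTU dispersions.
#' @param design vector of treatment labels per sample.
#' @param contrast length-2 character vector `c(treatment, control)`.
#' @return data frame (one row per OTU): `otu_id`, `base_mean`,
#'   `log2_fold_change`, `lfc_se`, `stat`, `wald_p`, `flag`.
#' @export
nb_wald_test <- function(table, s, alpha, design, contrast) {
  validate_otu_table(table)
  design <- as.character(design)
  if (length(contrast) != 2L || !all(contrast %in% design)) {
    stop("contrast levels must both be present in the design", call. = FALSE)
  }
  keep <- design %in% contrast
  tab <- table[, keep, drop = FALSE]
  if (is.null(names(s))) names(s) <- colnames(table)
  if (is.null(names(alpha))) names(alpha) <- rownames(table)
  sv <- s[colnames(tab)]
  x <- as.integer(design[keep] == contrast[1L])
  if (sum(keep) < 2) stop("contrast needs >= 2 samples", call. = FALSE)

  norm <- sweep(tab, 2, sv, "/")
  res <- data.frame(otu_id = rownames(tab),
                    base_mean = rowMeans(norm),
                    log2_fold_change = 0,
                    lfc_se = NA_real_,
                    stat = NA_real_,
                    wald_p = 1,
                    flag = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    y <- tab[i, ]
    if (all(y == 0)) { res$flag[i] <- "all_zero"; next }
    fit <- nb_irls_fit(y, sv, x, alpha[rownames(tab)[i]])
    if (!fit$converged || !is.finite(fit$se_log2) ||
        abs(fit$beta_log2 * log(2)) >= 49.9) {
      res$flag[i] <- "no_convergence"
      next
    }
    z <- fit$beta_log2 / fit$se_log2
    res$log2_fold_change[i] <- fit$beta_log2
    res$lfc_se[i] <- fit$se_log2
    res$stat[i] <- z
    res$wald_p[i] <- 2 * pnorm(-abs(z))
  }
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper around
#' `p.adjust(..., method = "BH")` returning q-values in the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("adjust_bh: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify enriched and depleted OTUs
#'
#' `enriched` when `log2_fold_change > lfc_threshold` and the BH-adjusted
#' p-value is below `fdr`; `depleted` when `log2_fold_change <
#' -lfc_threshold` with the same FDR condition; `unclassified` otherwise.
#'
#' @param result data frame from [nb_wald_test()]; a `bh_adjusted_p` column
#'   is added from `wald_p` if absent.
#' @param lfc_threshold absolute log2 fold-change cutoff.
#' @param fdr FDR cutoff on the adjusted p-value.
#' @return the result data frame with `bh_adjusted_p` and `class` columns.
#' @export
classify_eotus <- function(result, lfc_threshold = 1.0, fdr = 0.1) {
  check_fraction(fdr, "fdr")
  if (!"bh_adjusted_p" %in% names(result)) {
    result$bh_adjusted_p <- adjust_bh(result$wald_p)
  }
  cls <- rep("unclassified", nrow(result))
  sig <- result$bh_adjusted_p < fdr
  cls[sig & result$log2_fold_change > lfc_threshold] <- "enriched"
  cls[sig & result$log2_fold_change < -lfc_threshold] <- "depleted"
  result$class <- cls
  result
}

#' Select differentially abundant OTUs for network inference
#'
#' Takes the classified per-contrast results of one depth stratum and returns
#' the union of enriched and depleted OTUs, each labeled with the contrast(s)
#' that selected it.
#'
#' @param results named list of classified result data frames, e.g.
#'   `list(CF = ..., CFM = ...)`.
#' @return data frame with `otu_id` and `source` (comma-joined contrast
#'   names); empty (with a warning) when no OTU qualifies.
#' @export
select_network_otus <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  picks <- lapply(results, function(r) r$otu_id[r$class != "unclassified"])
  all_ids <- sort(unique(unlist(picks)))
  if (!length(all_ids)) {
    warning("select_network_otus: no differentially abundant OTUs; ",
            "network stage will be empty", call. = FALSE)
    return(data.frame(otu_id = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  src <- vapply(all_ids, function(id) {
    paste(names(picks)[vapply(picks, function(p) id %in% p, logical(1))],
          collapse = ",")
  }, character(1))
  data.frame(otu_id = all_ids, source = unname(src), stringsAsFactors = FALSE)
}

#' Differential abundance for one depth stratum
#'
#' Convenience wrapper running the full per-stratum chain: size factors,
#' dispersion estimation on the stratum's samples, NB Wald tests for each
#' treatment-vs-control contrast, per-contrast BH adjustment and
#' classification, and the network OTU selection.
#'
#' @param table rarefied OTU count matrix.
#' @param metadata sample metadata data frame (`sample_id`, `treatment`, ...).
#' @param samples character vector of sample ids forming the stratum.
#' @param treatments treatment levels to contrast against the control.
#' @param control control level label.
#' @param lfc_threshold,fdr classification cutoffs.
#' @return list with `results` (named list of classified data frames per
#'   treatment), `selection` (network OTU data frame), `size_factors` and
#'   `dispersions`.
#' @export
diff_abundance_stratum <- function(table, metadata, samples,
                                   treatments = c("CF", "CFM"),
                                   control = "CK",
                                   lfc_threshold = 1.0, fdr = 0.1) {
  tab <- table[, samples, drop = FALSE]
  meta <- metadata[match(samples, metadata$sample_id), ]
  design <- as.character(meta$treatment)
  s <- size_factors(tab)
  alpha <- estimate_dispersions(tab, s, design)
  results <- lapply(treatments, function(trt) {
    r <- nb_wald_test(tab, s, alpha, design, c(trt, control))
    r$bh_adjusted_p <- adjust_bh(r$wald_p)
    classify_eotus(r, lfc_threshold = lfc_threshold, fdr = fdr)
  })
  names(results) <- treatments
  list(results = results,
       selection = select_network_otus(results),
       size_factors = s,
       dispersions = alpha)
}
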