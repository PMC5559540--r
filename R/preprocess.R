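## Preprocessing of OTU count tables: singleton removal, rarefaction to a
## fixed depth, Good's coverage, analytic rarefaction curves, and taxon-level
## relative-abundance aggregation.

#' Remove table-wide singleton OTUs
#'
#' Drops OTUs whose total count summed over all samples equals exactly 1,
#' the standard filter applied to pooled OTU tables before rarefaction.
#' OTUs with total 0 are retained (they carry no reads but are not
#' singletons).
#'
#' @param table OTU count matrix (OTUs x samples) with dimnames.
#' @return the filtered count matrix; the sample set is unchanged.
#' @examples
#' x <- matrix(c(1, 0, 2, 3, 4, 5), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' remove_singletons(x)
#' @export
remove_singletons <- function(table) {
  validate_otu_table(table)
  keep <- rowSums(table) != 1
  table[keep, , drop = FALSE]
}

#' Rarefy samples to a fixed depth
#'
#' Draws exactly `depth` reads per sample uniformly without replacement
#' (one multivariate hypergeometric draw per sample). Samples whose total is
#' below `depth` are dropped with a logged warning; column sums of the result
#' all equal `depth`.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @param depth positive integer rarefaction depth (reads per sample).
#' @param seed integer seed controlling the draw.
#' @return rarefied count matrix with the same OTU rows and the retained
#'   samples.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  validate_otu_table(table)
  depth <- check_count(depth, "depth")
  totals <- colSums(table)
  keep <- totals >= depth
  if (!all(keep)) {
    log_warn("rarefy: dropping ", sum(!keep), " sample(s) below depth ",
             depth, ": ", paste(colnames(table)[!keep], collapse = ", "))
    warning("rarefy: ", sum(!keep), " sample(s) below depth ", depth,
            " dropped", call. = FALSE)
  }
  table <- table[, keep, drop = FALSE]
  out <- table
  set.seed(seed)
  for (j in seq_len(ncol(table))) {
    n <- sum(table[, j])
    if (n == depth) next
    ## index reads 1..n; map sampled read indices back to OTUs
    cs <- cumsum(table[, j])
    idx <- sample.int(n, depth)
    out[, j] <- tabulate(findInterval(idx - 1L, c(0L, cs), left.open = FALSE),
                         nbins = nrow(table))
  }
  storage.mode(out) <- "integer"
  out
}

#' Good's coverage per sample
#'
#' Coverage is `C = 1 - F1/N` where `F1` is the number of OTUs observed
#' exactly once in the sample and `N` is the sample's read total: the
#' estimated fraction of reads belonging to OTUs already seen.
#'
#' @param table OTU count matrix (OTUs x samples); all sample totals must be
#'   positive.
#' @return data frame with one row per sample: `sample_id`, `total_reads`,
#'   `singletons`, `coverage`.
#' @examples
#' x <- matrix(c(8, 1, 1, 5, 5, 0), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' goods_coverage(x)
#' @export
goods_coverage <- function(table) {
  validate_otu_table(table)
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("goods_coverage: zero-total sample(s): ",
         paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  f1 <- colSums(table == 1)
  data.frame(sample_id = colnames(table),
             total_reads = as.integer(totals),
             singletons = as.integer(f1),
             coverage = 1 - f1 / totals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analytic rarefaction curve
#'
#' Expected richness at subsample size `m`:
#' `E[S_m] = sum_i (1 - choose(N - N_i, m) / choose(N, m))`, the exact
#' hypergeometric expectation, evaluated through `lchoose` for numerical
#' safety at large read totals.
#'
#' @param sample_counts non-negative integer vector of per-OTU counts for one
#'   sample.
#' @param depths increasing vector of subsample sizes, all `<=` the sample
#'   total.
#' @return numeric vector of expected richness values, one per depth.
#' @export
rarefaction_curve <- function(sample_counts, depths) {
  if (any(sample_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_tot <- sum(sample_counts)
  if (any(depths > n_tot)) {
    stop("rarefaction_curve: depth exceeds sample total (", n_tot, ")",
         call. = FALSE)
  }
  if (any(depths < 1) || any(depths != floor(depths))) {
    stop("depths must be positive integers", call. = FALSE)
  }
  counts <- sample_counts[sample_counts > 0]
  vapply(depths, function(m) {
    ## log C(N - Ni, m) - log C(N, m); -Inf when N - Ni < m (OTU always seen)
    lp <- lchoose(n_tot - counts, m) - lchoose(n_tot, m)
    sum(1 - exp(lp))
  }, numeric(1))
}

#' Aggregate relative abundance at a taxonomic rank
#'
#' Collapses OTU counts to taxa at the requested rank and converts to
#' per-sample proportions. OTUs missing from the taxonomy (or unassigned at
#' the rank) are pooled into `"Unclassified"`. When `top_k` is given, taxa
#' beyond the `top_k` most abundant (by mean proportion across samples) are
#' pooled into `"Others"`.
#'
#' @param table OTU count matrix (OTUs x samples).
#' @param taxonomy taxonomy data frame from [read_taxonomy_table()] (columns
#'   `otu_id` plus rank columns).
#' @param rank taxonomic rank name, e.g. `"phylum"`.
#' @param top_k optional integer; pool taxa beyond the top `top_k`.
#' @return proportion matrix (taxa x samples); every column sums to 1.
#' @export
relative_abundance_by_taxon <- function(table, taxonomy, rank = "phylum",
                                        top_k = NULL) {
  validate_otu_table(table)
  if (!rank %in% names(taxonomy)) {
    stop("rank '", rank, "' not present in taxonomy (have: ",
         paste(setdiff(names(taxonomy), "otu_id"), collapse = ", "), ")",
         call. = FALSE)
  }
  tax <- setNames(as.character(taxonomy[[rank]]), taxonomy$otu_id)
  lab <- tax[rownames(table)]
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  agg <- rowsum(table, group = lab)
  totals <- colSums(agg)
  if (any(totals == 0)) {
    stop("relative_abundance_by_taxon: zero-total sample(s)", call. = FALSE)
  }
  prop <- sweep(agg, 2, totals, "/")
  if (!is.null(top_k) && nrow(prop) > top_k) {
    ord <- order(rowMeans(prop), decreasing = TRUE)
    top <- rownames(prop)[ord][seq_len(top_k)]
    rest <- !rownames(prop) %in% top
    pooled <- rbind(prop[!rest, , drop = FALSE],
                    Others = colSums(prop[rest, , drop = FALSE]))
    prop <- pooled
  }
  prop[order(rowMeans(prop), decreasing = TRUE), , drop = FALSE]
}
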