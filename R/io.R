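## Readers and writers for the pipeline's tabular and graph formats: classic
## OTU-table TSV (optionally transposed), sample metadata TSV, taxonomy TSV,
## labeled square dissimilarity TSV, GraphML and edge-list network exports.

#' Read a classic OTU-table TSV
#'
#' Expects a header row of sample identifiers, a first column of OTU
#' identifiers, and non-negative integer cells. A leading `#` comment line
#' (the classic dialect's provenance line) is skipped; a header starting
#' with `#OTU` is recognized as a header.
#'
#' @param path input TSV path.
#' @param transpose set when the file stores samples as rows and OTUs as
#'   columns.
#' @return integer count matrix, OTUs as rows, samples as columns.
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("OTU table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ## drop a leading pure comment line (no tab => not the '#OTU ID' header)
  if (length(lines) && startsWith(lines[1], "#") && !grepl("\t", lines[1])) {
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("OTU table is empty: ", path, call. = FALSE)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- read.delim(con, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  samples <- names(df)[-1]
  if (anyDuplicated(ids)) {
    stop("duplicate OTU identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop("invalid count '", df[[j + 1]][bad[1]], "' at OTU '",
           ids[bad[1]], "', sample '", samples[j], "'", call. = FALSE)
    }
    mat[, j] <- v
  }
  storage.mode(mat) <- "integer"
  if (transpose) {
    mat <- t(mat)
  }
  validate_otu_table(mat)
  mat
}

#' Write an OTU table as classic TSV
#'
#' @param table integer count matrix (OTUs x samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  df <- data.frame(`#OTU ID` = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' One row per sample; the first column is the sample identifier. The
#' `treatment` and `depth` columns are kept as character design factors;
#' every other column except `replicate` is parsed as a numeric
#' environmental variable. Extra columns are carried through.
#'
#' @param path input TSV path.
#' @param required_vars variable names that must be present (error listing
#'   missing names otherwise).
#' @return data frame with `sample_id` first.
#' @export
read_sample_metadata <- function(path, required_vars = NULL) {
  if (!file.exists(path)) stop("metadata not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample identifier(s) in metadata", call. = FALSE)
  }
  if (!is.null(required_vars)) {
    missing_v <- setdiff(required_vars, names(df))
    if (length(missing_v)) {
      stop("metadata missing required variable(s): ",
           paste(missing_v, collapse = ", "), call. = FALSE)
    }
  }
  keep_chr <- c("sample_id", "treatment", "depth")
  for (v in setdiff(names(df), c(keep_chr, "replicate"))) {
    parsed <- suppressWarnings(as.numeric(df[[v]]))
    if (is.numeric(df[[v]]) || !anyNA(parsed)) {
      df[[v]] <- parsed
    } else if (v %in% required_vars) {
      stop("metadata variable '", v, "' is not numeric", call. = FALSE)
    }
  }
  df
}

#' Read a taxonomy TSV
#'
#' Two columns: OTU id and a semicolon-delimited lineage
#' (domain;phylum;class;order;family;genus). Missing trailing ranks are
#' filled as `NA`.
#'
#' @param path input TSV path.
#' @return data frame with `otu_id`, `lineage` and one column per rank.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("taxonomy not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("otu_id", "lineage")
  split_taxonomy(df)
}

#' @keywords internal
split_taxonomy <- function(df) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
  for (r in seq_along(ranks)) {
    df[[ranks[r]]] <- vapply(parts, function(p)
      if (length(p) >= r && nzchar(trimws(p[r]))) trimws(p[r]) else NA_character_,
      character(1))
  }
  df
}

#' Write a labeled square dissimilarity matrix TSV
#'
#' @param d symmetric matrix with sample dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  validate_dissimilarity(d)
  df <- data.frame(sample_id = rownames(d),
                   apply(d, 2, fmt_real),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square dissimilarity matrix TSV
#'
#' @param path input path (as written by [write_dissimilarity()]).
#' @return symmetric numeric matrix.
#' @export
read_dissimilarity <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_dissimilarity(m)
  m
}

#' Export a co-occurrence network
#'
#' `edge_list`: three-column TSV (`from`, `to`, `rho`) storing the signed
#' correlation; re-reading reconstructs the same topology. `graphml`: full
#' attribute export (taxonomy, source, degree, betweenness, module) loadable
#' by external visualization tools such as Cytoscape.
#'
#' @param net `"cooccurrence_network"` object.
#' @param path output path.
#' @param format `"edge_list"` or `"graphml"`.
#' @param membership optional named module membership vector attached as a
#'   node attribute in GraphML.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "graphml"),
                          membership = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  format <- match.arg(format)
  if (format == "edge_list") {
    df <- data.frame(from = net$edges$from, to = net$edges$to,
                     rho = fmt_real(net$edges$rho),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  nd <- net$nodes
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to"), drop = FALSE],
    directed = FALSE, vertices = nd$otu_id)
  if (nrow(net$edges)) {
    igraph::E(g)$rho <- net$edges$rho
    igraph::E(g)$sign <- ifelse(net$edges$rho >= 0, "positive", "negative")
  }
  igraph::V(g)$taxonomy <- ifelse(is.na(nd$taxonomy), "", nd$taxonomy)
  igraph::V(g)$source <- ifelse(is.na(nd$source), "", nd$source)
  igraph::V(g)$degree <- nd$degree
  if (!is.null(nd$betweenness)) igraph::V(g)$betweenness <- nd$betweenness
  if (!is.null(membership)) {
    igraph::V(g)$module <- as.integer(membership[nd$otu_id])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list network TSV
#'
#' @param path edge-list path as written by [write_network()].
#' @return data frame with `from`, `to`, `rho`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "rho")
  df$rho <- as.numeric(df$rho)
  df
}
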