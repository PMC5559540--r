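## Internal helpers shared across the pipeline: input validation, numeric
## formatting for deterministic writers, and leveled logging to stderr.

## ---- validation -----------------------------------------------------------

#' Validate an OTU count table
#'
#' Checks that `x` is a non-negative integer matrix (OTUs as rows, samples as
#' columns) with unique, non-missing row and column names.
#'
#' @param x matrix to validate.
#' @param what label used in error messages.
#' @return the validated matrix, invisibly usable downstream.
#' @keywords internal
validate_otu_table <- function(x, what = "OTU table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (OTUs x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry OTU row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop(what, ": duplicate OTU identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop(what, ": duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(what, ": negative count at OTU '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  if (any(x != floor(x))) {
    bad <- which(x != floor(x), arr.ind = TRUE)[1L, ]
    stop(what, ": non-integer count at OTU '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
validate_dissimilarity <- function(d, what = "dissimilarity matrix",
                                   tol = 1e-8) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop(what, " must be a square numeric matrix", call. = FALSE)
  }
  if (max(abs(d - t(d))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > tol)) {
    stop(what, " must have a zero diagonal", call. = FALSE)
  }
  invisible(d)
}

#' @keywords internal
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop("'", name, "' must be a single number in (0, 1)", call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

## ---- deterministic numeric formatting ------------------------------------

## Reals at 6 significant digits, p-values in scientific notation: stable,
## diff-able outputs.

#' @keywords internal
fmt_real <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

#' @keywords internal
fmt_pval <- function(x) {
  out <- formatC(x, format = "e", digits = 4)
  out[is.na(x)] <- "NA"
  out
}

#' Write a data frame as a deterministic TSV
#'
#' Numeric columns are rendered at 6 significant digits; columns whose name
#' looks like a p-value (`p`, `p_value`, `q`, `padj`, ...) use scientific
#' notation. Row order is written as given.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  pv <- grepl("^(p|q|padj|p_value|q_value|wald_p|bh_adjusted_p|model_p|chi_sq_p)$",
              names(df))
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- if (pv[j]) fmt_pval(out[[j]]) else fmt_real(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- logging --------------------------------------------------------------

.log_env <- new.env(parent = emptyenv())
.log_env$verbose <- TRUE

#' @keywords internal
set_verbose <- function(on) {
  old <- .log_env$verbose
  .log_env$verbose <- isTRUE(on)
  invisible(old)
}

#' @keywords internal
log_msg <- function(level, ...) {
  if (!.log_env$verbose && identical(level, "INFO")) return(invisible(NULL))
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}

#' @keywords internal
log_info <- function(...) log_msg("INFO", ...)

#' @keywords internal
log_warn <- function(...) log_msg("WARN", ...)
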