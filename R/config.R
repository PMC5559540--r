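## Pipeline configuration: the fixed analysis constants (rarefaction depth,
## permutation count, FDR levels, correlation thresholds, module size floor)
## with YAML override and CLI-flag override on top (flag wins).

#' Pipeline configuration
#'
#' Collects the pipeline's tunable constants. Defaults follow the analysis
#' protocol the pipeline implements: rarefaction to 9500 reads per sample,
#' 999 permutations for every permutation test, a 10% FDR with
#' |log2 fold change| > 1 for the enriched/depleted OTU rule, an FDR cutoff
#' of 0.001 on network correlations, an RMT scan grid of 0.30-0.95 in steps
#' of 0.01, and a minimum reported module size of 4 nodes.
#'
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param n_permutations permutations for ANOSIM/db-RDA/Mantel.
#' @param diffabund_fdr FDR for enriched/depleted classification.
#' @param network_lfc_threshold |log2 fold change| cutoff selecting network
#'   OTUs.
#' @param network_p_threshold FDR cutoff on network correlation q-values.
#' @param rmt_grid_start,rmt_grid_stop,rmt_grid_step RMT threshold scan grid.
#' @param min_module_size smallest module admitted to reports.
#' @param rng_seed default seed for all stochastic steps.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(rarefaction_depth = 9500,
                            n_permutations = 999,
                            diffabund_fdr = 0.10,
                            network_lfc_threshold = 1.0,
                            network_p_threshold = 0.001,
                            rmt_grid_start = 0.30,
                            rmt_grid_stop = 0.95,
                            rmt_grid_step = 0.01,
                            min_module_size = 4,
                            rng_seed = 1) {
  cfg <- list(rarefaction_depth = check_count(rarefaction_depth,
                                              "rarefaction_depth"),
              n_permutations = check_count(n_permutations, "n_permutations"),
              diffabund_fdr = diffabund_fdr,
              network_lfc_threshold = network_lfc_threshold,
              network_p_threshold = network_p_threshold,
              rmt_grid_start = rmt_grid_start,
              rmt_grid_stop = rmt_grid_stop,
              rmt_grid_step = rmt_grid_step,
              min_module_size = check_count(min_module_size,
                                            "min_module_size"),
              rng_seed = check_count(rng_seed, "rng_seed", min = 0L))
  check_fraction(cfg$diffabund_fdr, "diffabund_fdr")
  check_fraction(cfg$network_p_threshold, "network_p_threshold")
  if (cfg$network_lfc_threshold < 0) {
    stop("network_lfc_threshold must be >= 0", call. = FALSE)
  }
  check_fraction(cfg$rmt_grid_start, "rmt_grid_start")
  check_fraction(cfg$rmt_grid_stop, "rmt_grid_stop")
  if (cfg$rmt_grid_start >= cfg$rmt_grid_stop) {
    stop("rmt_grid_start must be < rmt_grid_stop", call. = FALSE)
  }
  if (cfg$rmt_grid_step <= 0) stop("rmt_grid_step must be > 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
rmt_grid <- function(cfg) {
  seq(cfg$rmt_grid_start, cfg$rmt_grid_stop, by = cfg$rmt_grid_step)
}

#' Load a pipeline configuration from YAML with overrides
#'
#' Precedence (lowest to highest): package defaults, YAML file entries,
#' explicit overrides (typically CLI flags).
#'
#' @param path optional YAML file with a subset of the
#'   [pipeline_config()] fields.
#' @param overrides named list of final overrides.
#' @return `"pipeline_config"` object.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(y), known)
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    args <- y
  }
  args <- modifyList(args, overrides[lengths(overrides) > 0])
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' @keywords internal
config_echo <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) paste0(k, "\t", format(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split samples into topsoil and subsoil strata
#'
#' The tilled 0-20 cm layer is the topsoil stratum; deeper layers
#' (20-90 cm) are pooled as subsoil.
#'
#' @param metadata metadata data frame with `sample_id` and `depth`.
#' @return named list of sample-id character vectors `topsoil`, `subsoil`.
#' @export
depth_strata <- function(metadata) {
  top <- metadata$depth %in% c("0-20", "0_20")
  list(topsoil = metadata$sample_id[top],
       subsoil = metadata$sample_id[!top])
}
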