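## Synthetic community generator. Emulates the post-OTU-picking state of a
## 3-treatment x 4-depth x 3-replicate soil profile experiment: negative
## binomial counts with planted treatment fold changes, a monotone depth
## trend on a subset of OTUs, correlated OTU modules driven by shared latent
## factors, and environmental covariates tied to those factors. Every run is
## fully reproducible from the design seed and returns a machine-readable
## ground-truth record.

.depth_levels <- c("0-20", "20-40", "40-60", "60-90")
.env_vars <- c("pH", "MO", "SOC", "TN", "NH4", "NO3", "OP", "AK")

## mock lineages assigned round-robin; exercises taxonomy joins only
.mock_lineages <- c(
  "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae;Hydrogenophaga",
  "Bacteria;Acidobacteria;Acidobacteria_Gp4;Gp4_order;Gp4_family;Gp4",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Caulobacterales;Caulobacteraceae;Phenylobacterium",
  "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolineaceae;Leptolinea",
  "Bacteria;Verrucomicrobia;Subdivision3;Subdivision3_order;Subdivision3_family;Subdivision3_genera_incertae_sedis",
  "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
  "Bacteria;Bacteroidetes;Cytophagia;Cytophagales;Cytophagaceae;Ohtaekwangia",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Sinobacteraceae;Steroidobacter",
  "Bacteria;Gemmatimonadetes;Gemmatimonadetes;Gemmatimonadales;Gemmatimonadaceae;Gemmatimonas",
  "Archaea;Thaumarchaeota;Nitrososphaerales_class;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera",
  "Bacteria;Actinobacteria;Actinobacteria_class;Micromonosporales;Micromonosporaceae;Micromonospora",
  "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolineaceae;Bellilinea")

#' Simulation design
#'
#' Collects and validates every knob of the synthetic community generator.
#' Defaults reproduce the study layout the pipeline targets: 3 treatments
#' (CK/CF/CFM) x 4 depth layers x 3 replicates = 36 samples, 500 OTUs, 20
#' planted differential OTUs at |log2 fold change| = 2, and two planted
#' 10-OTU co-abundance modules whose latent factors drive one environmental
#' covariate each (SOC and OP).
#'
#' @param n_otus number of OTUs.
#' @param n_treatments,n_depths,n_replicates design dimensions; treatments
#'   are labeled CK, CF, CFM (then T4, ...), depths use the 0-20/20-40/
#'   40-60/60-90 cm layer labels.
#' @param mean_log_abundance_range log2 relative-mass interval for
#'   background OTUs.
#' @param planted_log_abundance_range log2 relative-mass interval for
#'   planted (differential and module) OTUs; kept high so planted effects
#'   act on well-observed counts.
#' @param dispersion_range NB dispersion interval (`var = mu + alpha*mu^2`),
#'   sampled log-uniformly.
#' @param n_diff_otus number of planted module-independent differential
#'   OTUs; module members additionally carry planted fold changes of their
#'   own so they enter the network selection.
#' @param planted_lfc_magnitude |log2 fold change| planted on differential
#'   OTUs; 0 plants none (null configuration).
#' @param n_modules number of planted co-abundance modules.
#' @param module_size_range min/max module size.
#' @param module_latent_correlation target correlation, on the log-mean
#'   scale, between members of one module (in (0,1)).
#' @param module_latent_sd log2 standard deviation of the total module
#'   latent signal per OTU.
#' @param module_dispersion residual NB dispersion of module members; kept
#'   small because the shared latent factor already carries their dominant
#'   biological variability.
#' @param library_size_range pre-rarefaction library size interval.
#' @param env_noise_sd noise SD added to module-linked environmental
#'   variables (latent factor has SD 1).
#' @param depth_effect_fraction fraction of background OTUs carrying a
#'   monotone depth trend on the log2 mean.
#' @param depth_effect_range |slope| interval (log2 per layer) of the depth
#'   trend.
#' @param seed non-negative integer seed.
#' @return validated list of class `"simulation_design"`.
#' @export
simulation_design <- function(n_otus = 500,
                              n_treatments = 3,
                              n_depths = 4,
                              n_replicates = 3,
                              mean_log_abundance_range = c(0, 6.5),
                              planted_log_abundance_range = c(5.5, 6.5),
                              dispersion_range = c(0.05, 0.5),
                              n_diff_otus = 20,
                              planted_lfc_magnitude = 2,
                              n_modules = 2,
                              module_size_range = c(10, 10),
                              module_latent_correlation = 0.9,
                              module_latent_sd = 0.8,
                              module_dispersion = 0.05,
                              library_size_range = c(15000, 30000),
                              env_noise_sd = 0.5,
                              depth_effect_fraction = 0.2,
                              depth_effect_range = c(0.3, 0.8),
                              seed = 1L) {
  d <- list(n_otus = check_count(n_otus, "n_otus"),
            n_treatments = check_count(n_treatments, "n_treatments"),
            n_depths = check_count(n_depths, "n_depths"),
            n_replicates = check_count(n_replicates, "n_replicates"),
            mean_log_abundance_range = mean_log_abundance_range,
            planted_log_abundance_range = planted_log_abundance_range,
            dispersion_range = dispersion_range,
            n_diff_otus = check_count(n_diff_otus, "n_diff_otus", min = 0L),
            planted_lfc_magnitude = planted_lfc_magnitude,
            n_modules = check_count(n_modules, "n_modules", min = 0L),
            module_size_range = round(module_size_range),
            module_latent_correlation = module_latent_correlation,
            module_latent_sd = module_latent_sd,
            module_dispersion = module_dispersion,
            library_size_range = round(library_size_range),
            env_noise_sd = env_noise_sd,
            depth_effect_fraction = depth_effect_fraction,
            depth_effect_range = depth_effect_range,
            seed = check_count(seed, "seed", min = 0L))
  if (d$planted_lfc_magnitude < 0) stop("planted_lfc_magnitude must be >= 0",
                                        call. = FALSE)
  if (d$n_modules > 0) {
    check_fraction(d$module_latent_correlation, "module_latent_correlation")
    if (d$n_modules * max(d$module_size_range) + d$n_diff_otus > d$n_otus) {
      stop("infeasible design: planted OTUs exceed n_otus", call. = FALSE)
    }
    if (d$n_modules > length(.env_vars)) {
      stop("at most ", length(.env_vars), " modules (one env variable each)",
           call. = FALSE)
    }
  } else if (d$n_diff_otus > d$n_otus) {
    stop("infeasible design: n_diff_otus > n_otus", call. = FALSE)
  }
  if (d$env_noise_sd <= 0) stop("env_noise_sd must be > 0", call. = FALSE)
  structure(d, class = "simulation_design")
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws counts `NB(mu_ij, alpha_i)` with
#' `log2 mu_ij = baseline_i + lfc_i * x_treat(j) + depth_i * layer(j) +
#' lambda * f_m(j) + eps_ij` (the latent term only for module members),
#' normalizes relative masses within each sample and scales by its library
#' size. Module `m`'s environmental covariate is `f_m + N(0, env_noise_sd)`;
#' the remaining soil variables carry depth trends plus noise.
#'
#' @param design a [simulation_design()] object.
#' @return list with `otu_table` (integer matrix, OTUs x samples),
#'   `metadata` (data frame: `sample_id`, `treatment`, `depth`, `replicate`,
#'   soil variables), `taxonomy` (data frame), and `truth` (class
#'   `"ground_truth"`).
#' @export
generate_dataset <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(d$seed)

  trt_levels <- c("CK", "CF", "CFM", paste0("T", seq_len(max(0, d$n_treatments - 3)) + 3))
  trt_levels <- trt_levels[seq_len(d$n_treatments)]
  depth_levels <- if (d$n_depths <= length(.depth_levels))
    .depth_levels[seq_len(d$n_depths)] else paste0("L", seq_len(d$n_depths))
  grid <- expand.grid(replicate = seq_len(d$n_replicates),
                      depth = depth_levels, treatment = trt_levels,
                      stringsAsFactors = FALSE)
  n_samp <- nrow(grid)
  sample_id <- paste(grid$treatment, gsub("-", "_", grid$depth),
                     paste0("R", grid$replicate), sep = ".")
  otu_ids <- sprintf("OTU_%04d", seq_len(d$n_otus))

  ## --- planted roles ------------------------------------------------------
  n_diff <- if (d$planted_lfc_magnitude > 0) d$n_diff_otus else 0L
  module_sizes <- if (d$n_modules > 0) {
    pmin(pmax(round(runif(d$n_modules, d$module_size_range[1],
                          d$module_size_range[2])), 1L), d$n_otus)
  } else integer(0)
  pool <- sample.int(d$n_otus)
  diff_idx <- if (n_diff > 0) pool[seq_len(n_diff)] else integer(0)
  pool <- setdiff(pool, diff_idx)
  module_idx <- vector("list", d$n_modules)
  for (m in seq_len(d$n_modules)) {
    module_idx[[m]] <- pool[seq_len(module_sizes[m])]
    pool <- setdiff(pool, module_idx[[m]])
  }
  planted <- c(diff_idx, unlist(module_idx))
  background <- setdiff(seq_len(d$n_otus), planted)

  ## --- per-OTU parameters -------------------------------------------------
  baseline <- numeric(d$n_otus)
  baseline[background] <- runif(length(background),
                                d$mean_log_abundance_range[1],
                                d$mean_log_abundance_range[2])
  if (length(planted)) {
    baseline[planted] <- runif(length(planted),
                               d$planted_log_abundance_range[1],
                               d$planted_log_abundance_range[2])
  }
  alpha <- exp(runif(d$n_otus, log(d$dispersion_range[1]),
                     log(d$dispersion_range[2])))
  if (length(module_idx)) alpha[unlist(module_idx)] <- d$module_dispersion

  ## treatment fold changes: per differential OTU a contrast pattern
  ## (CFM-only : CF-only : both = 2 : 1 : 1) with random sign
  lfc <- matrix(0, d$n_otus, d$n_treatments,
                dimnames = list(otu_ids, trt_levels))
  if (n_diff > 0 && d$n_treatments >= 2) {
    pattern <- sample(c("CFM", "CF", "both"), n_diff, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25))
    sign_v <- sample(c(-1, 1), n_diff, replace = TRUE)
    for (k in seq_len(n_diff)) {
      i <- diff_idx[k]
      val <- sign_v[k] * d$planted_lfc_magnitude
      if (pattern[k] %in% c("CF", "both") && "CF" %in% trt_levels)
        lfc[i, "CF"] <- val
      if (pattern[k] %in% c("CFM", "both") && "CFM" %in% trt_levels)
        lfc[i, "CFM"] <- val
    }
  }
  ## module members are themselves treatment-responsive (enriched under the
  ## manure-amended treatment), so they pass the differential-abundance
  ## selection rule and enter the co-occurrence network, as the analysis
  ## design assumes; module 1, 3, ... under CFM, module 2, 4, ... under both
  ## CF and CFM
  if (d$n_modules > 0 && d$planted_lfc_magnitude > 0 &&
      all(c("CF", "CFM") %in% trt_levels)) {
    for (m in seq_len(d$n_modules)) {
      mem <- module_idx[[m]]
      lfc[mem, "CFM"] <- d$planted_lfc_magnitude
      if (m %% 2 == 0) lfc[mem, "CF"] <- d$planted_lfc_magnitude
    }
  }

  ## monotone depth trend on a random background subset
  depth_slope <- numeric(d$n_otus)
  n_depth_otus <- round(d$depth_effect_fraction * length(background))
  if (n_depth_otus > 0 && d$n_depths > 1) {
    depth_otus <- sample(background, n_depth_otus)
    depth_slope[depth_otus] <- sample(c(-1, 1), n_depth_otus, TRUE) *
      runif(n_depth_otus, d$depth_effect_range[1], d$depth_effect_range[2])
  }

  ## --- latent module factors and per-sample log2 means --------------------
  layer <- match(grid$depth, depth_levels) - 1L
  trt_col <- match(grid$treatment, trt_levels)
  log2mu <- matrix(baseline, d$n_otus, n_samp) +
    lfc[, trt_col, drop = FALSE] +
    outer(depth_slope, layer)
  f <- matrix(rnorm(d$n_modules * n_samp), d$n_modules, n_samp)
  if (d$n_modules > 0) {
    lambda <- sqrt(d$module_latent_correlation) * d$module_latent_sd
    eps_sd <- sqrt(1 - d$module_latent_correlation) * d$module_latent_sd
    for (m in seq_len(d$n_modules)) {
      mem <- module_idx[[m]]
      log2mu[mem, ] <- log2mu[mem, ] +
        matrix(lambda * f[m, ], length(mem), n_samp, byrow = TRUE) +
        matrix(rnorm(length(mem) * n_samp, sd = eps_sd), length(mem), n_samp)
    }
  }

  ## --- counts -------------------------------------------------------------
  lib <- round(runif(n_samp, d$library_size_range[1], d$library_size_range[2]))
  mass <- 2^log2mu
  mu <- sweep(mass, 2, colSums(mass), "/")
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
                   d$n_otus, n_samp, dimnames = list(otu_ids, sample_id))
  storage.mode(counts) <- "integer"

  ## --- metadata: soil variables -------------------------------------------
  module_env <- if (d$n_modules > 0) .env_vars[c(3, 7, 4, 8, 1, 2, 5, 6)][seq_len(d$n_modules)]
                else character(0)
  meta <- data.frame(sample_id = sample_id,
                     treatment = grid$treatment,
                     depth = grid$depth,
                     replicate = grid$replicate,
                     stringsAsFactors = FALSE)
  env_centers <- c(pH = 7.5, MO = 25, SOC = 12, TN = 1.2, NH4 = 6,
                   NO3 = 2.5, OP = 8, AK = 90)
  env_depth_slope <- c(pH = 0.15, MO = -2.5, SOC = -2.0, TN = -0.15,
                       NH4 = 0.4, NO3 = -0.6, OP = -1.0, AK = -8)
  for (v in .env_vars) {
    m <- match(v, module_env)
    if (!is.na(m)) {
      meta[[v]] <- env_centers[[v]] +
        f[m, ] + rnorm(n_samp, sd = d$env_noise_sd)
    } else {
      meta[[v]] <- env_centers[[v]] + env_depth_slope[[v]] * layer +
        rnorm(n_samp, sd = abs(env_centers[[v]]) * 0.05 + 0.05)
    }
  }

  taxonomy <- data.frame(otu_id = otu_ids,
                         lineage = rep_len(.mock_lineages, d$n_otus),
                         stringsAsFactors = FALSE)

  truth_otus <- data.frame(
    otu_id = otu_ids,
    lfc_CF = if ("CF" %in% trt_levels) lfc[, "CF"] else 0,
    lfc_CFM = if ("CFM" %in% trt_levels) lfc[, "CFM"] else 0,
    is_differential = rowSums(abs(lfc)) > 0,
    module = NA_integer_,
    stringsAsFactors = FALSE)
  for (m in seq_len(d$n_modules)) truth_otus$module[module_idx[[m]]] <- m
  truth_modules <- data.frame(
    module = seq_len(d$n_modules),
    size = if (d$n_modules) vapply(module_idx, length, integer(1)) else integer(0),
    env_var = module_env,
    stringsAsFactors = FALSE)
  truth <- structure(list(otus = truth_otus,
                          modules = truth_modules,
                          library_sizes = setNames(lib, sample_id),
                          latent_factors = f,
                          design = d),
                     class = "ground_truth")

  list(otu_table = counts, metadata = meta, taxonomy = taxonomy, truth = truth)
}

#' Simulate block-structured correlated abundance profiles
#'
#' Generates Gaussian abundance profiles with planted correlation blocks:
#' members of block `b` share a latent factor so that their pairwise
#' correlation is `within`; distinct blocks share a weaker global factor
#' giving between-block correlation `between` (0 for independent blocks).
#' Optionally adds one bridge variable loading equally on the first two
#' block factors, which links the two blocks in the thresholded graph and
#' should emerge as the maximum-betweenness keystone. Used to validate the
#' RMT threshold scan and keystone ranking against known structure.
#'
#' @param n_blocks number of planted blocks.
#' @param block_size variables per block.
#' @param n_noise additional independent noise variables.
#' @param n_samples number of samples (columns).
#' @param within within-block correlation level in (0, 1).
#' @param between between-block correlation level in `[0, within)`.
#' @param bridge add a bridge variable tying blocks 1 and 2.
#' @param bridge_strength variance fraction of the bridge variable carried
#'   by the two block factors.
#' @param seed integer seed.
#' @return list with `abundances` (variables x samples matrix) and `labels`
#'   (block id per variable, `NA` for noise, `"bridge"` for the bridge).
#' @export
simulate_correlated_blocks <- function(n_blocks = 4, block_size = 10,
                                       n_noise = 10, n_samples = 250,
                                       within = 0.9, between = 0,
                                       bridge = FALSE, bridge_strength = 0.85,
                                       seed = 1L) {
  stopifnot(within > 0, within < 1, between >= 0, between < within)
  if (bridge && n_blocks < 2) stop("bridge needs >= 2 blocks", call. = FALSE)
  set.seed(seed)
  f <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  g <- rnorm(n_samples)
  n_vars <- n_blocks * block_size + n_noise + as.integer(bridge)
  x <- matrix(0, n_vars, n_samples)
  labels <- rep(NA_character_, n_vars)
  row <- 1L
  for (b in seq_len(n_blocks)) {
    for (k in seq_len(block_size)) {
      x[row, ] <- sqrt(between) * g + sqrt(within - between) * f[b, ] +
        sqrt(1 - within) * rnorm(n_samples)
      labels[row] <- as.character(b)
      row <- row + 1L
    }
  }
  if (n_noise > 0) {
    x[row:(row + n_noise - 1L), ] <- matrix(rnorm(n_noise * n_samples),
                                            n_noise, n_samples)
    row <- row + n_noise
  }
  if (bridge) {
    x[row, ] <- sqrt(bridge_strength / 2) * (f[1, ] + f[2, ]) +
      sqrt(1 - bridge_strength) * rnorm(n_samples)
    labels[row] <- "bridge"
  }
  rownames(x) <- sprintf("VAR_%03d", seq_len(n_vars))
  colnames(x) <- sprintf("S%03d", seq_len(n_samples))
  names(labels) <- rownames(x)
  list(abundances = x, labels = labels)
}

#' Summarize the planted ground truth
#'
#' Per-contrast counts of planted enriched and depleted OTUs plus module
#' sizes, directly comparable with the pipeline's differential-abundance and
#' module reports.
#'
#' @param truth `"ground_truth"` object from [generate_dataset()].
#' @return data frame with `item`, `contrast`/`module` info and `count`.
#' @export
summarize_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  ot <- truth$otus
  rows <- list(
    data.frame(item = "enriched", contrast = "CF",
               count = sum(ot$lfc_CF > 0)),
    data.frame(item = "depleted", contrast = "CF",
               count = sum(ot$lfc_CF < 0)),
    data.frame(item = "enriched", contrast = "CFM",
               count = sum(ot$lfc_CFM > 0)),
    data.frame(item = "depleted", contrast = "CFM",
               count = sum(ot$lfc_CFM < 0)))
  out <- do.call(rbind, rows)
  if (nrow(truth$modules)) {
    out <- rbind(out, data.frame(
      item = paste0("module_", truth$modules$module, "_size"),
      contrast = truth$modules$env_var,
      count = truth$modules$size))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", nrow(x$otus), "OTUs;",
      sum(x$otus$is_differential), "planted differential;",
      nrow(x$modules), "module(s)\n")
  invisible(x)
}
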