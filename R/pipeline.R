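## orchestration layer: each step reads/writes CSV (plus VCF/genepop at
## ingestion), records a JSON manifest, and is callable from the thin CLI
## script shipped in inst/cli/riverscape.R

write_manifest <- function(out_dir, step, inputs, parameters, seed = NULL) {
  manifest <- list(step = step,
                   package_version = as.character(utils::packageVersion("riverscape")),
                   inputs = inputs, parameters = parameters,
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Generate and write a synthetic study to disk
#'
#' Emits the full file set of a riverscape study: network/sites/barriers
#' CSVs, genotypes as VCF and genepop, the environmental table with its
#' category map, and the generator ground truth as JSON.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed (default 42, the reference study).
#' @param ... further arguments to [synthetic_study].
#' @return the `synthetic_study`, invisibly; files under `out_dir`.
#' @export
pipeline_synth <- function(out_dir, seed = 42L, ...) {
  ensure_dir(out_dir)
  st <- synthetic_study(seed = seed, ...)
  utils::write.csv(st$edges, file.path(out_dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(st$sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
  if (!is.null(st$barriers))
    utils::write.csv(st$barriers, file.path(out_dir, "barriers.csv"),
                     row.names = FALSE)
  write_vcf(st$genotypes, file.path(out_dir, "genotypes.vcf"))
  write_genepop(st$genotypes, file.path(out_dir, "genotypes.gen"))
  utils::write.csv(st$env, file.path(out_dir, "env.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = names(st$categories),
                              category = unname(st$categories)),
                   file.path(out_dir, "env_categories.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fst_model = st$truth$fst_model,
         section_f = as.list(st$truth$section_f),
         site_divergence = as.list(st$truth$site_divergence),
         projection_rms = st$truth$projection_rms, seed = st$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "synth", list(), list(...), seed)
  invisible(st)
}

load_study_dir <- function(dir) {
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  bfile <- file.path(dir, "barriers.csv")
  barriers <- if (file.exists(bfile)) utils::read.csv(bfile) else NULL
  net <- build_network(edges, sites, barriers)
  gt <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  env <- utils::read.csv(file.path(dir, "env.csv"), check.names = FALSE)
  cats <- utils::read.csv(file.path(dir, "env_categories.csv"))
  list(network = net, sites = sites, genotypes = gt, env = env,
       categories = stats::setNames(cats$category, cats$variable))
}

#' Filter genotypes and write the filtered panel
#'
#' @param dir study directory (from [pipeline_synth] or equivalent files).
#' @param out_dir output directory (default: `dir`).
#' @param ... thresholds for [filter_snps].
#' @param hwe apply the Hardy-Weinberg screen after the main filter.
#' @export
pipeline_filter <- function(dir, out_dir = dir, hwe = TRUE, ...) {
  ensure_dir(out_dir)
  gt <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  fl <- filter_snps(gt, ...)
  gt2 <- fl$genotypes
  removed_hwe <- character(0)
  if (hwe) {
    hw <- hwe_screen(gt2)
    gt2 <- hw$genotypes
    removed_hwe <- hw$removed
    fl$report$n_removed_hwe <- length(removed_hwe)
    fl$report$n_retained <- ncol(gt2$G)
  }
  write_vcf(gt2, file.path(out_dir, "genotypes_filtered.vcf"))
  rep <- fl$report
  utils::write.csv(
    data.frame(n_input = rep$n_input_loci,
               removed_missingness = rep$n_removed_missingness,
               removed_maf = rep$n_removed_maf,
               removed_duplicate = rep$n_removed_duplicate,
               removed_hwe = rep$n_removed_hwe,
               retained = rep$n_retained),
    file.path(out_dir, "filter_report.csv"), row.names = FALSE)
  write_manifest(out_dir, "filter", list(genotypes = "genotypes.vcf"),
                 list(...))
  invisible(list(genotypes = gt2, report = fl$report))
}

#' Pairwise FST and diversity statistics step
#'
#' @param dir study directory holding `genotypes_filtered.vcf` (falls back
#'   to the unfiltered file).
#' @param out_dir output directory.
#' @param n_perm permutations for pairwise FST significance (0 = none).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @export
pipeline_stats <- function(dir, out_dir = dir, n_perm = 0, seed = NULL) {
  ensure_dir(out_dir)
  f <- file.path(dir, "genotypes_filtered.vcf")
  if (!file.exists(f)) f <- file.path(dir, "genotypes.vcf")
  gt <- read_vcf_genotypes(f)
  pw <- pairwise_fst_wc(gt, n_perm = n_perm, seed = seed)
  write_matrix_csv(pw$fst, file.path(out_dir, "fst_matrix.csv"))
  if (!is.null(pw$p_values))
    write_matrix_csv(pw$p_values, file.path(out_dir, "fst_pvalues.csv"))
  write_diversity_table(gt, file.path(out_dir, "diversity.csv"))
  write_manifest(out_dir, "stats", list(genotypes = basename(f)),
                 list(n_perm = n_perm), seed)
  invisible(pw)
}

#' StreamTree step: section distances from the FST matrix
#'
#' @param dir study directory with network CSVs and `fst_matrix.csv`.
#' @param out_dir output directory.
#' @export
pipeline_streamtree <- function(dir, out_dir = dir) {
  ensure_dir(out_dir)
  sd <- load_study_dir(dir)
  fst <- read_matrix_csv(file.path(dir, "fst_matrix.csv"))
  fit <- streamtree(sd$network, fst)
  cls <- section_fst_breaks(fit)
  utils::write.csv(
    data.frame(section_id = fit$sections$section_id,
               distance = fit$sections$distance,
               identifiable = fit$sections$identifiable,
               class = as.character(cls)),
    file.path(out_dir, "streamtree_sections.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(site_i = fit$pairs$site_i, site_j = fit$pairs$site_j,
               observed = fit$observed, fitted = fit$fitted),
    file.path(out_dir, "streamtree_fitted.csv"), row.names = FALSE)
  write_manifest(out_dir, "streamtree", list(fst = "fst_matrix.csv"),
                 list(r_squared = fit$r_squared))
  invisible(fit)
}

#' MMRR step: spatial + environmental attribution of FST
#'
#' Builds river-distance, barrier, catchment and environmental predictors,
#' screens them univariately and fits the multivariate model.
#'
#' @param dir study directory.
#' @param out_dir output directory.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param gate univariate inclusion p-value threshold.
#' @export
pipeline_mmrr <- function(dir, out_dir = dir, n_perm = 10000, seed = 1L,
                          gate = 0.05) {
  ensure_dir(out_dir)
  sd <- load_study_dir(dir)
  fst <- read_matrix_csv(file.path(dir, "fst_matrix.csv"))
  preds <- list(river_km = river_distance_matrix(sd$network),
                barriers = barrier_count_matrix(sd$network),
                catchment = catchment_model_matrix(sd$network))
  envp <- env_predictor_set(sd$env, sd$categories)
  preds <- c(preds, envp$matrices)
  ## align predictor labels to the FST matrix order
  labs <- rownames(fst)
  preds <- lapply(preds, function(m) m[labs, labs])
  res <- mmrr_analysis(fst, preds, n_perm = n_perm, seed = seed, gate = gate)
  utils::write.csv(res$table, file.path(out_dir, "mmrr_table.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "mmrr", list(fst = "fst_matrix.csv"),
                 list(n_perm = n_perm, gate = gate,
                      retained_env = envp$retained_vars), seed)
  invisible(res)
}

#' LD-Ne step: per-site effective population sizes
#'
#' @param dir study directory.
#' @param out_dir output directory.
#' @param pcrit allele-frequency screen (default 0.075).
#' @export
pipeline_ne <- function(dir, out_dir = dir, pcrit = 0.075) {
  ensure_dir(out_dir)
  f <- file.path(dir, "genotypes_filtered.vcf")
  if (!file.exists(f)) f <- file.path(dir, "genotypes.vcf")
  gt <- read_vcf_genotypes(f)
  tab <- ld_ne(gt, pcrit = pcrit)
  out <- tab
  for (cl in c("Ne", "ci_lo", "ci_hi"))
    out[[cl]] <- ifelse(is.infinite(out[[cl]]), "inf",
                        formatC(out[[cl]], format = "fg", digits = 6))
  utils::write.csv(out, file.path(out_dir, "ne_estimates.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "ne", list(genotypes = basename(f)),
                 list(pcrit = pcrit))
  invisible(tab)
}

#' Fragmentation-simulation step
#'
#' @param out_dir output directory.
#' @param ne_total,n_demes scenario.
#' @param n_replicates ensemble size.
#' @param seed master seed.
#' @param ... further arguments to [sim_config].
#' @export
pipeline_simulate <- function(out_dir, ne_total = 500, n_demes = 2,
                              n_replicates = 100, seed = 1L, ...) {
  ensure_dir(out_dir)
  cfg <- sim_config(ne_total = ne_total, n_demes = n_demes,
                    n_replicates = n_replicates, seed = seed, ...)
  ens <- run_fragmentation(run_burnin(cfg), cfg)
  utils::write.csv(
    data.frame(ne_total = ne_total, n_demes = n_demes,
               replicate = seq_along(ens$crossing),
               crossing_generation = ens$crossing),
    file.path(out_dir, "crossing_generations.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(ne_total = ne_total, n_demes = n_demes,
               mean_crossing = ens$mean_crossing,
               n_crossed = sum(!is.na(ens$crossing))),
    file.path(out_dir, "crossing_summary.csv"), row.names = FALSE)
  write_manifest(out_dir, "simulate", list(),
                 list(ne_total = ne_total, n_demes = n_demes,
                      n_replicates = n_replicates), seed)
  invisible(ens)
}

#' Run the whole analysis chain on one study directory
#'
#' filter -> stats -> streamtree -> mmrr -> ne, all outputs and manifests
#' under `dir`.
#'
#' @param dir study directory (e.g. written by [pipeline_synth]).
#' @param n_perm MMRR permutations.
#' @param seed RNG seed.
#' @export
pipeline_all <- function(dir, n_perm = 10000, seed = 1L) {
  pipeline_filter(dir)
  pipeline_stats(dir)
  st <- pipeline_streamtree(dir)
  mm <- pipeline_mmrr(dir, n_perm = n_perm, seed = seed)
  ne <- pipeline_ne(dir)
  invisible(list(streamtree = st, mmrr = mm, ne = ne))
}
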