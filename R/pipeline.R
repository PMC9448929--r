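#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]. Any element
#' can be overridden via `...` (or supplied from a YAML file with
#' [read_pipeline_config()]). The defaults are a desk-scale profile:
#' 10 subjects per archetype per sex, 20 s simulations on a 21-point K grid.
#'
#' @param outdir output directory.
#' @param ... overrides of the default elements.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(outdir = "connectotype_run", ...) {
  cfg <- list(
    outdir = outdir,
    seed = 1L,
    generator = list(n_per_group = 10L, sexes = c("male", "female"),
                     contrast = 0.45, shape = 0.25, sigma = 0.25,
                     sigma_coarse = 0.075,
                     texture_sd = 0.45, texture_cor = 0.5,
                     edge_mean_target = 1e-4),
    cluster = list(gamma_min = 0.5, gamma_max = 1.5, gamma_step = 0.01,
                   min_frac = 0.05, n_restarts = 100L, folds = 5L),
    km = list(K_min = 0, K_max = 2, K_step = 0.1, T = 20, dt = 1e-4,
              burn_in = 5, n_reps = 1L),
    lesion = list(levels = c(0.05, 0.10, 0.25, 0.50, 0.75),
                  measure = "strength", renormalize = FALSE),
    alpha = 0.05)
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file mirroring [pipeline_config()]'s structure.
#' @return Configuration list (defaults filled in for missing elements).
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(pipeline_config(), user)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> cluster -> metrics -> simulate -> lesion -> report
#' with one master seed, writing every stage's artifacts under
#' `config$outdir` and a `run_manifest.json` listing seeds and outputs.
#' Clustering, dynamics and reporting are run per sex; the lesion stage uses
#' a population-wide hub ranking.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pipeline_log("generate: %d subjects/archetype/sex, seed %d",
               config$generator$n_per_group, config$seed)
  spec <- do.call(population_spec, c(config$generator, list(seed = config$seed)))
  pop <- generate_population(spec)
  write_population(pop, file.path(outdir, "population"))

  gamma_grid <- seq(config$cluster$gamma_min, config$cluster$gamma_max,
                    by = config$cluster$gamma_step)
  sexes <- unique(pop$labels$sex)
  cluster_res <- list()
  partition_rows <- list()
  for (sx in sexes) {
    idx <- which(pop$labels$sex == sx)
    res <- cluster_population(pop$subjects[idx], gamma_grid = gamma_grid,
                              min_frac = config$cluster$min_frac,
                              n_restarts = config$cluster$n_restarts,
                              seed = derive_seed(config$seed, match(sx, sexes),
                                                 salt = 41L))
    cv <- crossval_accuracy(res$similarity, res$partition,
                            k = config$cluster$folds,
                            gamma_grid = gamma_grid,
                            n_restarts = config$cluster$n_restarts,
                            seed = derive_seed(config$seed, match(sx, sexes),
                                               salt = 43L))
    pipeline_log("cluster[%s]: gamma* = %g, Q = %.3f, CV accuracy = %.2f",
                 sx, res$gamma, res$partition$Q, cv$accuracy)
    cluster_res[[sx]] <- c(res, list(crossval = cv))
    partition_rows[[sx]] <- data.frame(
      subject_id = res$partition$subject_ids, sex = sx,
      module = res$partition$assignment,
      gamma = res$gamma, Q = res$partition$Q)
    utils::write.table(round(res$similarity$S, 6),
                       file.path(outdir, paste0("similarity_", sx, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  partition <- do.call(rbind, c(unname(partition_rows),
                                list(make.row.names = FALSE)))
  utils::write.csv(partition, file.path(outdir, "partition.csv"),
                   row.names = FALSE)

  pipeline_log("metrics: %d subjects", length(pop$subjects))
  metrics <- population_metrics(pop$subjects)
  utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)

  K_grid <- seq(config$km$K_min, config$km$K_max, by = config$km$K_step)
  pipeline_log("simulate: K grid %g..%g (%d points), T = %g s",
               min(K_grid), max(K_grid), length(K_grid), config$km$T)
  sweep_summary <- population_sweeps(
    pop$subjects, seed = derive_seed(config$seed, 1L, salt = 47L),
    K_grid = K_grid, T = config$km$T, dt = config$km$dt,
    burn_in = config$km$burn_in, n_reps = config$km$n_reps)
  sweep_long <- do.call(rbind, lapply(attr(sweep_summary, "sweeps"),
    function(sw) data.frame(subject_id = sw$subject_id, K = sw$K_grid,
                            synchrony = sw$synchrony,
                            metastability = sw$metastability)))
  utils::write.csv(sweep_long, file.path(outdir, "sweeps.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep_summary, file.path(outdir, "sweep_summary.csv"),
                   row.names = FALSE)

  pipeline_log("lesion: levels %s", paste(config$lesion$levels, collapse = ", "))
  plan <- rank_nodes(pop$subjects, measure = config$lesion$measure,
                     levels = config$lesion$levels)
  lesions <- lesion_experiment(
    pop$subjects, plan,
    km_settings = list(K_grid = K_grid, T = config$km$T, dt = config$km$dt,
                       burn_in = config$km$burn_in,
                       n_reps = config$km$n_reps),
    renormalize = config$lesion$renormalize,
    seed = derive_seed(config$seed, 1L, salt = 53L))
  lesions_out <- lesions
  attr(lesions_out, "sweeps") <- NULL
  utils::write.csv(lesions_out, file.path(outdir, "lesions.csv"),
                   row.names = FALSE)

  pipeline_log("report: ANOVA + Tukey-Kramer at alpha = %g", config$alpha)
  reports <- list()
  for (sx in sexes) {
    part <- cluster_res[[sx]]$partition
    sexvec <- rep(sx, length(part$subject_ids))
    reports[[sx]] <- list(
      structure = module_report(part, metrics, sex = sexvec,
                                alpha = config$alpha),
      dynamics = module_report(part, sweep_summary, sex = sexvec,
                               alpha = config$alpha))
  }
  report_json <- lapply(reports, function(rs) lapply(rs, function(r)
    lapply(r, function(gc) list(F = gc$F, p = gc$p,
                                pairing_classes = gc$pairing_classes))))
  jsonlite::write_json(report_json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_out <- config
  if (inherits(cfg_out$generator$fine, "parcellation"))
    cfg_out$generator$fine <- cfg_out$generator$fine$name
  manifest <- list(
    package_version = as.character(utils::packageVersion("connectotype")),
    seed = config$seed,
    config = cfg_out,
    artifacts = list.files(outdir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done: artifacts in %s", outdir)
  invisible(list(population = pop, clusters = cluster_res,
                 metrics = metrics, sweeps = sweep_summary,
                 lesion_plan = plan, lesions = lesions, reports = reports))
}
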