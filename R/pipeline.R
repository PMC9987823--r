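# Pipeline runner: ties the stages together with a validated config, a
# manifest, and fixed-format artifacts under an output directory. Every
# stage derives its own seed deterministically from the master seed.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a named list; user configs
#' (R lists or YAML via [read_run_config()]) are merged over it, so every
#' default is explicit in the manifest.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return Named list.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("voxsparse_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    phantom = list(preset = "default"),
    fit = list(method = "sft", k = 8L, max_iter = 400L, n_starts = 3L),
    parcellate = list(k = 8L, sweep_ks = c(1L, 2L, 4L, 6L, 8L, 10L, 12L, 16L)),
    metrics = list(n_bins = 256L, n_levels = 16L),
    compress = list(schedule = c(600L, 360L, 240L), rule = "max"),
    probe = list(n_genes = 10L, folds = 5L)
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()].
#'
#' @param path YAML file path.
#' @return Named config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(user)
}

#' @rdname read_run_config
#' @param config Partial config list to merge over the defaults.
#' @export
merge_config <- function(config = list()) {
  modifyList(default_run_config(), config, keep.null = TRUE)
}

validate_config <- function(config) {
  config <- merge_config(config)
  check_count(config$seed, "seed", min = 0L)
  if (!is.character(config$outdir) || length(config$outdir) != 1L) {
    abort("invalid config field: `outdir` must be a single path",
          class = "voxsparse_config_error")
  }
  check_count(config$fit$k, "fit$k")
  check_count(config$parcellate$k, "parcellate$k")
  if (!length(config$parcellate$sweep_ks)) {
    abort("invalid config field: `parcellate$sweep_ks` must be nonempty",
          class = "voxsparse_config_error")
  }
  if (!length(config$compress$schedule)) {
    abort("invalid config field: `compress$schedule` must be nonempty",
          class = "voxsparse_config_error")
  }
  config
}

require_artifact <- function(outdir, name, stage, produced_by) {
  path <- file.path(outdir, name)
  if (!file.exists(path)) {
    abort(paste0("stage '", stage, "' needs missing artifact '", name,
                 "'; run stage '", produced_by, "' first"),
          class = "voxsparse_dependency_error")
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes one stage or the whole chain on the configured phantom, writing
#' fixed-format artifacts and a manifest (config, per-stage seeds, wall
#' times, package version) under the output directory. Stages read their
#' inputs from the artifacts of earlier stages, so any stage can be rerun
#' in isolation; a missing upstream artifact raises a dependency error.
#'
#' Stages and artifacts:
#' * `simulate` — `annotation.nii.gz`, `expression.tsv`, `markers.json`
#' * `fit` — `fit/weights.tsv`, `fit/features.tsv`, `fit/meta.json`
#' * `parcellate` — `parcellation.tsv`, `sweep.csv`
#' * `metrics` — `feature_metrics.csv`, `metric_aggregates.json`
#' * `compress` — `compression_trace.csv`, `gene_lists/`
#' * `probe` — `probe.json`
#' * `all` — the chain in that order.
#'
#' @param config Config list (merged over [default_run_config()]), or a
#'   YAML path.
#' @param command One of `"simulate"`, `"fit"`, `"parcellate"`,
#'   `"metrics"`, `"compress"`, `"probe"`, `"all"`.
#' @return The config, invisibly. Artifacts are written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = list(), command = "all") {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- validate_config(config)
  commands <- c("simulate", "fit", "parcellate", "metrics", "compress",
                "probe", "all")
  if (!command %in% commands) {
    abort(paste0("unknown command '", command, "'"))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all") commands[commands != "all"] else command
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(package = "voxsparse",
         version = as.character(utils::packageVersion("voxsparse")),
         config = config, stages = list())
  }
  for (stage in stages) {
    t0 <- Sys.time()
    seed <- switch(stage,
      simulate = derive_seed(config$seed, "phantom"),
      fit = derive_seed(config$seed, "fit"),
      parcellate = derive_seed(config$seed, "parcellate"),
      metrics = derive_seed(config$seed, "metrics"),
      compress = derive_seed(config$seed, "compress"),
      probe = derive_seed(config$seed, "probe"))
    run_stage(stage, config, outdir, seed)
    manifest$stages[[stage]] <- list(
      seed = seed,
      wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }
  manifest$config <- config
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(config)
}

run_stage <- function(stage, config, outdir, seed) {
  switch(
    stage,
    simulate = {
      spec <- if (identical(config$phantom$preset, "default")) {
        default_phantom_spec(seed = seed)
      } else if (identical(config$phantom$preset, "small")) {
        small_phantom_spec(seed = seed)
      } else {
        do.call(phantom_spec, c(config$phantom, list(seed = seed)))
      }
      ph <- make_phantom(spec)
      write_phantom(ph, outdir)
    },
    fit = {
      E <- read_expression_tsv(
        require_artifact(outdir, "expression.tsv", "fit", "simulate"))
      C <- if (identical(config$fit$method, "sft")) {
        sparse_filter(E, config$fit$k, max_iter = config$fit$max_iter,
                      seed = seed, n_starts = config$fit$n_starts %||% 1L)
      } else {
        decompose(E, config$fit$method, config$fit$k,
                  hyperparams = config$fit$hyperparams %||% list(),
                  seed = seed)
      }
      write_component_set(C, file.path(outdir, "fit"))
    },
    parcellate = {
      C <- read_component_set(
        dirname(require_artifact(outdir, "fit/features.tsv",
                                 "parcellate", "fit")))
      ann <- read_annotation_nifti(
        require_artifact(outdir, "annotation.nii.gz", "parcellate", "simulate"))
      p <- kmeans_cluster(C, config$parcellate$k, seed = seed)
      write_parcellation(p, file.path(outdir, "parcellation.tsv"))
      sw <- sweep_k(C, ann, config$parcellate$sweep_ks, seed = seed)
      readr::write_csv(sw, file.path(outdir, "sweep.csv"))
    },
    metrics = {
      C <- read_component_set(
        dirname(require_artifact(outdir, "fit/features.tsv",
                                 "metrics", "fit")))
      ann <- read_annotation_nifti(
        require_artifact(outdir, "annotation.nii.gz", "metrics", "simulate"))
      rep <- feature_report(C, ann, n_bins = config$metrics$n_bins,
                            n_levels = config$metrics$n_levels)
      write_feature_report(rep, file.path(outdir, "feature_metrics.csv"),
                           file.path(outdir, "metric_aggregates.json"))
    },
    compress = {
      E <- read_expression_tsv(
        require_artifact(outdir, "expression.tsv", "compress", "simulate"))
      ann <- read_annotation_nifti(
        require_artifact(outdir, "annotation.nii.gz", "compress", "simulate"))
      tr <- compress_iteratively(
        E, ann, k_features = config$fit$k,
        schedule = config$compress$schedule, seed = seed,
        max_iter = config$fit$max_iter,
        n_starts = config$fit$n_starts %||% 1L,
        rule = config$compress$rule)
      write_compression_trace(tr, file.path(outdir, "compression_trace.csv"),
                              file.path(outdir, "gene_lists"))
    },
    probe = {
      E <- read_expression_tsv(
        require_artifact(outdir, "expression.tsv", "probe", "simulate"))
      ann <- read_annotation_nifti(
        require_artifact(outdir, "annotation.nii.gz", "probe", "simulate"))
      C <- read_component_set(
        dirname(require_artifact(outdir, "fit/features.tsv", "probe", "fit")))
      metrics_path <- require_artifact(outdir, "feature_metrics.csv",
                                       "probe", "metrics")
      pf <- readr::read_csv(metrics_path, show_col_types = FALSE)
      pf <- pf[!is.na(pf$dice), ]
      best <- pf$feature[which.max(pf$dice)]
      region <- pf$matched_region[which.max(pf$dice)]
      genes <- top_genes(C$weights[, best], n = config$probe$n_genes,
                         gene_ids = C$gene_ids)
      panel <- train_probe(E, ann, region, genes,
                           folds = config$probe$folds, seed = seed)
      write_probe_panel(panel, file.path(outdir, "probe.json"))
    }
  )
  invisible(NULL)
}
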