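#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) with the model, the
#' environmental condition, at least one formulation block
#' (\code{MCSe}/\code{MCSf}/\code{MCSw}/\code{EAw}/\code{EAm}), filter
#' settings and optional analysis inputs. See
#' \code{system.file("extdata", "toyb_pipeline.yaml", package =
#' "coupledesign")} for a complete example.
#'
#' @param config YAML file path or a list.
#' @return validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("MCSe", "MCSf", "MCSw", "EAw", "EAm")
  forms <- names(config$formulations)
  if (is.null(forms) || !length(forms))
    stop("config must define at least one formulation block")
  bad <- setdiff(forms, known)
  if (length(bad)) stop("unknown formulation(s): ", paste(bad, collapse = ", "))
  if (is.null(config$model)) stop("config must name a model")
  if (is.null(config$product)) stop("config must name the product reaction")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.pipeline_model <- function(config) {
  if (file.exists(config$model))
    model <- load_model(config$model, objective = config$biomass)
  else if (config$model %in% c("TOY-A", "TOY-B", "TOY-C"))
    model <- toy_network(config$model)
  else stop("model '", config$model, "' is neither a file nor a packaged toy network")
  if (!is.null(config$biomass)) model$objective_id <- config$biomass
  if (!is.null(config$atpm)) model$maintenance_id <- config$atpm
  model
}

.pipeline_env <- function(config) {
  if (is.null(config$environment)) return(NULL)
  do.call(environment_spec, lapply(config$environment, as.numeric))
}

#' Run the end-to-end design pipeline
#'
#' For every formulation block: generate strategies (cut-set enumeration or
#' evolutionary search), filter them by the three screening criteria, and
#' build phenotype reports. All outputs are TSV files in
#' \code{out_dir/<formulation>/} plus a JSON run manifest; results are also
#' returned as a list. Reruns with the same seed are identical.
#'
#' @param config YAML path or config list (see
#'   \code{\link{pipeline_config}}).
#' @param out_dir output directory (default: \code{config$output_dir} or
#'   a temporary directory).
#' @return list with per-formulation results and the manifest, invisibly
#'   when writing files.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  if (is.null(out_dir)) out_dir <- tempfile("coupledesign_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- .pipeline_model(config)
  env <- .pipeline_env(config)
  base <- set_environment(model, env)
  fcfg <- config$filter
  criteria <- filter_criteria(
    product_id = config$product, env = env,
    min_growth_fraction_of_wt = fcfg$min_growth_fraction_of_wt %||% 0.01,
    coupling_growth_fraction = fcfg$coupling_growth_fraction %||% 0.90)
  pmat <- if (!is.null(config$analysis$pathways))
    pathway_matrix(config$analysis$pathways, reaction_ids = model$reaction_ids)
  carbon <- if (!is.null(config$analysis$carbon))
    unlist(config$analysis$carbon)

  results <- list()
  manifest <- list(package = "coupledesign",
                   version = as.character(utils::packageVersion("coupledesign")),
                   seed = config$seed, solver = "internal bounded-variable simplex",
                   model = config$model, stages = list())
  for (form in names(config$formulations)) {
    t0 <- Sys.time()
    block <- config$formulations[[form]]
    stage_dir <- file.path(out_dir, form)
    dir.create(stage_dir, showWarnings = FALSE)
    res <- tryCatch({
      if (form %in% c("MCSe", "MCSf", "MCSw"))
        .run_mcs_stage(base, env, config, form, block)
      else
        .run_ea_stage(base, env, config, form, block)
    }, error = function(e) {
      manifest$stages[[form]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", form, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    write_cutsets(res$cutsets, file.path(stage_dir, "strategies.tsv"),
                  json_path = file.path(stage_dir, "strategies.json"),
                  meta = list(formulation = form, seed = config$seed))
    strategies <- lapply(res$cutsets, `[[`, "reactions")
    filt <- filter_strategies(model, strategies, criteria)
    write.table(cutsets_to_df(lapply(filt$kept, cut_set, formulation = form)),
                file.path(stage_dir, "kept.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(filt$rejected, file.path(stage_dir, "rejected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report <- if (length(filt$kept))
      build_report(model, filt$kept, criteria,
                   substrate_id = config$substrate, pmat = pmat,
                   carbon = carbon)
    else NULL
    if (!is.null(report)) {
      write.table(report$reports, file.path(stage_dir, "report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(report$summary, file.path(stage_dir, "summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages[[form]] <- list(
      status = res$status %||% "ok",
      n_strategies = length(strategies), n_kept = length(filt$kept),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    results[[form]] <- list(cutsets = res$cutsets, kept = filt$kept,
                            rejected = filt$rejected, report = report,
                            status = res$status)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_mcs_stage <- function(base, env, config, form, block) {
  params <- formulation_params(
    form,
    product = config$product, substrate = config$substrate,
    biomass = base$objective_id, atpm = config$atpm,
    s_max = block$s_max, y_min = block$y_min, m_atp = block$m_atp,
    eps = block$eps %||% .tol$eps, F = block$F)
  target <- build_target_space(base, params)
  desired <- build_desired_space(base, env,
                                 min_biomass = block$min_biomass %||% .tol$eps)
  res <- enumerate_mcs(base, target, desired = desired,
                       max_size = block$max_size %||% 3,
                       max_solutions = block$max_solutions %||% Inf,
                       time_limit = block$time_limit %||% Inf)
  list(cutsets = res$cutsets, status = res$status)
}

.run_ea_stage <- function(base, env, config, form, block) {
  cfg <- ea_config(
    form, product_id = config$product,
    max_knockouts = block$max_knockouts %||% 20,
    max_evaluations = block$max_evaluations %||% 1e5,
    pop_size = block$pop_size %||% 100,
    archive_size = block$archive_size %||% 100,
    mutation_rate = block$mutation_rate %||% 0.8,
    crossover_rate = block$crossover_rate %||% 0.5)
  runs <- block$runs %||% 10
  batch <- run_ea_batch(base, NULL, cfg, runs = runs, seed = config$seed)
  seen <- character(0); cutsets <- list()
  for (r in batch) for (cand in r$archive) {
    key <- paste(cand$knockouts, collapse = ";")
    if (key %in% seen || !length(cand$knockouts)) next
    seen <- c(seen, key)
    cutsets[[length(cutsets) + 1L]] <-
      cut_set(cand$knockouts, formulation = form, order = length(cutsets) + 1L)
  }
  list(cutsets = cutsets, status = "ok")
}
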