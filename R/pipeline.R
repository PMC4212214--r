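#' Configure an end-to-end pipeline run
#'
#' Exactly one of `sim` (a [SimulationConfig-class]) or the three input
#' paths must be provided. All stage thresholds default to the screening
#' rule of the analysis: M-value cutoff 1, significance cutoff 0.01, 1000
#' permutations, absolute expression cutoff 500, 2-fold representation
#' criterion.
#'
#' @param out_dir output directory (created if absent).
#' @param sim optional [SimulationConfig-class]; mutually exclusive with
#'   the input paths.
#' @param expression,design,annotation optional input file paths (see
#'   [readExpression()], [readAnnotation()]).
#' @param n_permutations permutations of the rank-product test.
#' @param m_cut,p_cut,threshold_on see [deThresholds()].
#' @param cutoff absolute expression cutoff for identity tracking.
#' @param min_category_size,fold_criterion see [categoryProfile()].
#' @param focal_comparison comparison whose category profile is written
#'   (default the consecutive contrast with the largest expected shift,
#'   `"sb_72_vs_sb_24"`, when present; otherwise the last baseline
#'   comparison).
#' @param floor intensity floor shared by ratio and M computations.
#' @param seed master seed; every stochastic stage derives its own
#'   substream from it.
#' @return a validated pipeline config (list).
#' @export
pipelineConfig <- function(out_dir, sim = NULL, expression = NULL,
                           design = NULL, annotation = NULL,
                           n_permutations = 1000, m_cut = 1, p_cut = 0.01,
                           threshold_on = "p", cutoff = 500,
                           min_category_size = 10, fold_criterion = 2,
                           focal_comparison = NULL, floor = 1, seed = 1) {
  has_paths <- !is.null(expression) || !is.null(design) ||
    !is.null(annotation)
  if (is.null(sim) && !has_paths)
    stop("provide either a simulation config or input paths")
  if (!is.null(sim) && has_paths)
    stop("provide either a simulation config or input paths, not both")
  if (has_paths && (is.null(expression) || is.null(design) ||
                    is.null(annotation)))
    stop("input mode needs all of expression, design and annotation paths")
  cfg <- list(out_dir = out_dir, sim = sim, expression = expression,
              design = design, annotation = annotation,
              n_permutations = as.integer(n_permutations),
              thresholds = deThresholds(m_cut, p_cut, threshold_on),
              cutoff = cutoff,
              min_category_size = as.integer(min_category_size),
              fold_criterion = fold_criterion,
              focal_comparison = focal_comparison, floor = floor,
              seed = as.integer(seed))
  class(cfg) <- "arshift_pipeline_config"
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' The file mirrors the arguments of [pipelineConfig()]; a nested
#' `simulation:` section holds the generator parameters when the run is
#' simulated.
#'
#' @param config a pipeline config.
#' @param path file path.
#' @export
writePipelineConfig <- function(config, path) {
  lst <- unclass(config)
  lst$thresholds <- config$thresholds
  if (!is.null(config$sim)) {
    s <- config$sim
    lst$sim <- list(
      n_genes = s@n_genes, timepoints_hpe = s@timepoints_hpe,
      replicates = s@replicates, baseline_log_mean = s@baseline_log_mean,
      baseline_log_sd = s@baseline_log_sd, noise_cv = s@noise_cv,
      n_de_per_comparison = s@n_de_per_comparison, de_fold = s@de_fold,
      de_frac_up = s@de_frac_up, frac_wound_shared = s@frac_wound_shared,
      n_stem_identity = s@n_stem_identity,
      n_root_identity = s@n_root_identity,
      identity_high = s@identity_high, identity_low = s@identity_low,
      stem_decay_hpe = s@stem_decay_hpe, root_rise_hpe = s@root_rise_hpe,
      seed = s@seed)
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @param out_dir overrides the config's output directory when not `NULL`.
#' @param seed overrides the config's seed when not `NULL`.
#' @export
readPipelineConfig <- function(path, out_dir = NULL, seed = NULL) {
  lst <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(lst$sim)) sim <- do.call(simulationConfig, lst$sim)
  pipelineConfig(
    out_dir = if (is.null(out_dir)) lst$out_dir else out_dir,
    sim = sim, expression = lst$expression, design = lst$design,
    annotation = lst$annotation,
    n_permutations = lst$n_permutations %||% 1000,
    m_cut = lst$thresholds$m_cut %||% 1,
    p_cut = lst$thresholds$p_cut %||% 0.01,
    threshold_on = lst$thresholds$threshold_on %||% "p",
    cutoff = lst$cutoff %||% 500,
    min_category_size = lst$min_category_size %||% 10,
    fold_criterion = lst$fold_criterion %||% 2,
    focal_comparison = lst$focal_comparison,
    floor = lst$floor %||% 1,
    seed = if (is.null(seed)) lst$seed %||% 1 else seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: data (generate or read), rank-product DE
#' for every standard comparison, wound-response set, organ-identity sets,
#' identity-shift table with the largest-shift interval, category profile
#' of the focal comparison, and the hormone time-course. All outputs are
#' tab-separated text under `config$out_dir`, plus a JSON manifest with the
#' config snapshot, per-file checksums, per-stage wall-clock and (for
#' simulated runs) DE sensitivity/FDR against the planted truth.
#'
#' @param config from [pipelineConfig()] or [readPipelineConfig()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "arshift_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  note <- function(...) if (!quiet) message("[arshift] ", ...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## stage: data -------------------------------------------------------------
  truth <- NULL
  dat <- stage("data", {
    if (!is.null(config$sim)) {
      sim <- generateDataset(config$sim)
      truth <- sim$truth  # promise evaluates in this frame; visible below
      writeExpression(sim$dataset, out("expression.tsv"), out("design.tsv"))
      writeAnnotation(sim$annotation, out("annotation.tsv"))
      tm <- data.frame(gene_id = rownames(truth@condition_means),
                       truth@condition_means, check.names = FALSE)
      writeTsv(tm, out("true_condition_means.tsv"))
      sim
    } else {
      list(dataset = readExpression(config$expression, config$design),
           annotation = readAnnotation(config$annotation))
    }
  })
  x <- dat$dataset
  note("data: ", nrow(x), " genes x ", ncol(x), " samples")

  ## stage: differential expression -----------------------------------------
  cmps <- standardComparisons(x)
  de_list <- stage("differential_expression", {
    res <- list()
    for (i in seq_len(nrow(cmps))) {
      cm <- runComparison(x, cmps$a[i], cmps$b[i],
                          n_permutations = config$n_permutations,
                          seed = deriveSeed(config$seed, "de"),
                          thresholds = config$thresholds,
                          floor = config$floor)
      writeRPResult(cm$rp, out("rp_", cmps$comparison[i], ".tsv"))
      writeDETable(cm$de, out("de_", cmps$comparison[i], ".tsv"))
      res[[cmps$comparison[i]]] <- cm$de
      note("DE ", cmps$comparison[i], ": ",
           length(regulatedGenes(cm$de, "up")), " up, ",
           length(regulatedGenes(cm$de, "down")), " down")
    }
    res
  })

  ## stage: wound + organ identity sets -------------------------------------
  wound <- stage("wound_set", {
    ws <- woundRegulatedGenes(de_list[["leaf_wounded_vs_leaf_fresh"]])
    writeGeneSet(ws, out("geneset_wound_regulated.txt"))
    ws
  })
  note("wound set: ", length(wound), " genes")
  organ_seed <- deriveSeed(config$seed, "organ")
  stem_set <- stage("stem_identity_set", {
    s <- organSpecificGenes(x, "stem_base", thresholds = config$thresholds,
                            cutoff = config$cutoff,
                            n_permutations = config$n_permutations,
                            seed = organ_seed, floor = config$floor)
    writeGeneSet(s, out("geneset_stem_base_identity.txt"))
    s
  })
  root_set <- stage("root_identity_set", {
    s <- organSpecificGenes(x, "root", thresholds = config$thresholds,
                            cutoff = config$cutoff,
                            n_permutations = config$n_permutations,
                            seed = organ_seed, floor = config$floor)
    writeGeneSet(s, out("geneset_root_identity.txt"))
    s
  })
  note("identity sets: ", length(stem_set), " stem base, ",
       length(root_set), " root")

  ## stage: identity shift ----------------------------------------------------
  baseline_keys <- cmps$comparison[cmps$type == "vs_baseline"]
  shift_tbl <- stage("identity_shift", {
    tbl <- identityShiftTable(x, stem_set, root_set, wound,
                              de_list[baseline_keys],
                              cutoff = config$cutoff)
    writeTsv(tbl, out("identity_shift_table.tsv"))
    tbl
  })
  shift <- if (nrow(shift_tbl) >= 2) largestShiftInterval(shift_tbl)
           else NULL
  if (!is.null(shift))
    note("largest identity shift between ", shift$from, " and ", shift$to,
         " hpe")

  ## stage: category representation -----------------------------------------
  focal <- config$focal_comparison
  if (is.null(focal))
    focal <- if ("sb_72_vs_sb_24" %in% names(de_list)) "sb_72_vs_sb_24"
             else baseline_keys[length(baseline_keys)]
  rep_tbl <- stage("category_representation", {
    prof <- categoryProfile(de_list[[focal]], dat$annotation,
                            min_category_size = config$min_category_size,
                            fold_criterion = config$fold_criterion)
    writeTsv(prof, out("category_profile_", focal, ".tsv"))
    prof
  })
  hormone_keys <- c(baseline_keys,
                    intersect("root_vs_sb_0", names(de_list)))
  hormone_tbl <- stage("hormone_timecourse", {
    ht <- hormoneTimecourse(de_list[hormone_keys], dat$annotation,
                            min_category_size = config$min_category_size,
                            fold_criterion = config$fold_criterion)
    writeTsv(ht, out("hormone_timecourse.tsv"))
    ht
  })

  ## manifest -----------------------------------------------------------------
  summary <- NULL
  if (!is.null(truth)) {
    sens <- fdr <- numeric(0)
    for (key in baseline_keys) {
      parts <- strsplit(key, "_vs_")[[1]]
      tr <- trueRegulated(truth, parts[1], parts[2])
      true_reg <- c(tr$up, tr$down)
      called <- regulatedGenes(de_list[[key]], "both")
      sens[key] <- if (length(true_reg))
        length(intersect(called, true_reg)) / length(true_reg) else NA
      fdr[key] <- if (length(called))
        length(setdiff(called, true_reg)) / length(called) else 0
    }
    summary <- list(de_sensitivity = as.list(sens), de_fdr = as.list(fdr))
  }
  files <- list.files(config$out_dir, full.names = TRUE)
  ## manifest (wall-clock) and the config snapshot (out_dir) are run
  ## metadata, not analysis outputs; checksums cover the outputs only
  files <- files[!basename(files) %in% c("manifest.json", "config.yaml")]
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  manifest <- list(
    package = "ARShift",
    version = as.character(packageVersion("ARShift")),
    seed = config$seed,
    config = list(n_permutations = config$n_permutations,
                  thresholds = config$thresholds, cutoff = config$cutoff,
                  min_category_size = config$min_category_size,
                  fold_criterion = config$fold_criterion,
                  floor = config$floor, focal_comparison = focal,
                  simulated = !is.null(config$sim)),
    largest_shift = shift,
    summary = summary,
    timings_sec = timings,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writePipelineConfig(config, file.path(config$out_dir, "config.yaml"))
  invisible(manifest)
}
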