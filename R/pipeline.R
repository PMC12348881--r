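# Pipeline orchestration: validated run configuration, staged execution in
# dependency order, artifact writing and a machine-readable run report.

#' Build and validate a pipeline run configuration
#'
#' Stages execute in dependency order: `simdata` -> `scaffold` / `nucseg`
#' -> `phenotype`; `crosstalk` is independent. When `simdata` is disabled,
#' `stack_path` must point to an existing stack; when `phenotype` is
#' requested without `nucseg`, a `labels_path` (or `use_truth_labels` with
#' `simdata`) must supply the instance masks. Validation errors are raised
#' before any stage runs.
#'
#' @param out_dir Output directory for all artifacts and the run report.
#' @param stages Character vector of stages to run.
#' @param seed Integer seed forwarded to the synthetic generator.
#' @param sim List of overrides for [sim_params()].
#' @param filter List of overrides for [filter_params()].
#' @param seg List of overrides for [seg_params()].
#' @param percentiles Named marker percentiles for classification.
#' @param coloc_mode Co-localization counting mode.
#' @param caspase_rule Caspase positivity rule (`"otsu"`/`"percentile"`).
#' @param crosstalk List: `min_pct`, `alpha`, `min_confidence`, `n_genes`,
#'   `n_planted` (toy bundle), or `ppi_path`/`b_de_path`/`bmsc_de_path`.
#' @param stack_path,labels_path Optional external inputs (TIFF).
#' @param use_truth_labels Use the generator's ground-truth labels for
#'   phenotyping instead of a segmentation (default `FALSE`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simdata", "scaffold", "nucseg",
                                  "phenotype", "crosstalk"),
                       seed = 1L,
                       sim = list(),
                       filter = list(),
                       seg = list(),
                       percentiles = c(CD19 = 40, CD3 = 95),
                       coloc_mode = "double_pos_or_adjacent",
                       caspase_rule = "otsu",
                       crosstalk = list(),
                       stack_path = NULL,
                       labels_path = NULL,
                       use_truth_labels = FALSE) {
  known <- c("simdata", "scaffold", "nucseg", "phenotype", "crosstalk")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg <- list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
              sim = sim, filter = filter, seg = seg,
              percentiles = percentiles, coloc_mode = coloc_mode,
              caspase_rule = caspase_rule, crosstalk = crosstalk,
              stack_path = stack_path, labels_path = labels_path,
              use_truth_labels = isTRUE(use_truth_labels))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  needs_stack <- any(c("scaffold", "nucseg", "phenotype") %in% st)
  if (needs_stack && !("simdata" %in% st)) {
    if (is.null(config$stack_path))
      stop("stack_path is required when imaging stages run without simdata",
           call. = FALSE)
    if (!file.exists(config$stack_path))
      stop(sprintf("stack_path does not exist: %s", config$stack_path),
           call. = FALSE)
  }
  if ("phenotype" %in% st && !("nucseg" %in% st)) {
    have_labels <- !is.null(config$labels_path) ||
      (config$use_truth_labels && "simdata" %in% st)
    if (!have_labels)
      stop(paste("phenotype requires labels: enable nucseg, set labels_path,",
                 "or set use_truth_labels with simdata"), call. = FALSE)
    if (!is.null(config$labels_path) && !file.exists(config$labels_path))
      stop(sprintf("labels_path does not exist: %s", config$labels_path),
           call. = FALSE)
  }
  if ("crosstalk" %in% st && !("simdata" %in% st)) {
    ct <- config$crosstalk
    for (p in c("ppi_path", "b_de_path", "bmsc_de_path")) {
      if (is.null(ct[[p]]))
        stop(sprintf("crosstalk without simdata requires %s", p),
             call. = FALSE)
      if (!file.exists(ct[[p]]))
        stop(sprintf("%s does not exist: %s", p, ct[[p]]), call. = FALSE)
    }
  }
  # parameter blocks must satisfy their own invariants
  do.call(sim_params, c(config$sim, list(seed = config$seed)))
  do.call(filter_params, config$filter)
  do.call(seg_params, config$seg)
  invisible(config)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`); its fields
#'   are passed to [run_config()].
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.null(raw$percentiles)) raw$percentiles <- unlist(raw$percentiles)
  do.call(run_config, raw)
}

#' Run the configured pipeline
#'
#' Executes the requested stages in dependency order, writes every
#' intermediate artifact under `out_dir`, and returns (and writes as
#' `report.json`) a run report with the package version, seed, parameters,
#' per-stage counts and MD5 checksums of all written artifacts. A stage
#' failure aborts the run with the failing stage named and leaves a
#' `FAILED_<stage>` marker next to the partial outputs. The report carries
#' no timestamps, so identical configurations yield byte-identical output
#' trees.
#'
#' @param config A [run_config()] object.
#' @return The run report (list), invisibly also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package = "nichequant",
    version = as.character(utils::packageVersion("nichequant")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      sim = config$sim, filter = config$filter, seg = config$seg,
      percentiles = as.list(config$percentiles),
      coloc_mode = config$coloc_mode, caspase_rule = config$caspase_rule,
      crosstalk = config$crosstalk
    ),
    counts = list(),
    artifacts = list()
  )
  artifacts <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      marker <- file.path(out, paste0("FAILED_", name))
      writeLines(conditionMessage(e), marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  run_stage("simdata", function() {
    p <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
    sim <- generate_coculture_stack(p)
    state$stack <- sim$stack
    state$truth <- sim$truth
    state$truth_labels <- sim$labels
    write_stack(sim$stack, file.path(out, "stack.tif"))
    write_labels(sim$labels, file.path(out, "labels_truth.tif"))
    write_ground_truth(sim$truth, file.path(out, "truth.json"))
    artifacts <<- c(artifacts, file.path(out, c(
      "stack.tif", "stack.tif.json", "labels_truth.tif", "truth.json")))
    report$counts$simdata <<- list(
      n_cells = nrow(sim$truth$cells),
      n_b = sum(sim$truth$cells$type == "B"),
      n_t = sum(sim$truth$cells$type == "T"))
  })

  get_stack <- function() {
    if (is.null(state$stack)) state$stack <- read_stack(config$stack_path)
    state$stack
  }

  run_stage("scaffold", function() {
    fp <- do.call(filter_params, config$filter)
    mask <- segment_scaffold(get_stack(), fp, channels = "CD90")
    state$scaffold_mask <- mask
    write_labels(mask, file.path(out, "scaffold_mask.tif"))
    artifacts <<- c(artifacts, file.path(out, "scaffold_mask.tif"))
    report$counts$scaffold <<- list(foreground_voxels = sum(mask))
  })

  run_stage("nucseg", function() {
    sp <- do.call(seg_params, config$seg)
    labs <- segment_nuclei(get_stack()$nuc, sp)
    state$labels <- labs
    write_labels(labs, file.path(out, "labels_seg.tif"))
    artifacts <<- c(artifacts, file.path(out, "labels_seg.tif"))
    report$counts$nucseg <<- list(n_labels = max(labs))
  })

  run_stage("phenotype", function() {
    labs <- if (!is.null(state$labels)) state$labels
            else if (!is.null(config$labels_path)) read_labels(config$labels_path)
            else state$truth_labels
    stk <- get_stack()
    markers <- unique(c(names(config$percentiles), "CASP3"))
    markers <- intersect(markers, names(stk))
    tab <- extract_mask_intensities(labs, stk, markers)
    tab <- normalize_intensities(tab)
    thr <- pool_and_threshold(tab, config$percentiles)
    tab <- classify_cells(tab, thr)
    cc <- count_colocalized(labs, tab, mode = config$coloc_mode,
                            markers = names(config$percentiles))
    tab <- cc$table
    if ("CASP3" %in% markers) {
      fl <- flag_caspase(list(tab), rule = config$caspase_rule)
      tab <- fl[[1]]
    }
    state$cell_table <- tab
    state$counts <- cc$counts
    utils::write.csv(tab, file.path(out, "cell_table.csv"), row.names = FALSE)
    utils::write.csv(cc$counts, file.path(out, "stack_counts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(thresholds = as.list(thr$thresholds),
                              percentiles = as.list(thr$percentiles),
                              n_pooled = thr$n_pooled, pool = thr$pool),
                         file.path(out, "thresholds.json"), auto_unbox = TRUE,
                         digits = NA)
    artifacts <<- c(artifacts, file.path(out, c(
      "cell_table.csv", "stack_counts.csv", "thresholds.json")))
    report$counts$phenotype <<- as.list(cc$counts[, c(
      "n_cd19", "n_cd3", "n_coloc", "n_total_masks")])
  })

  run_stage("crosstalk", function() {
    if ("simdata" %in% config$stages) {
      ct <- config$crosstalk
      bundle <- generate_omics_bundle(
        n_genes = if (is.null(ct$n_genes)) 100L else ct$n_genes,
        n_planted = if (is.null(ct$n_planted)) 5L else ct$n_planted,
        seed = config$seed)
      write_omics_bundle(bundle, file.path(out, "omics"))
      ppi <- bundle$ppi
      b_de <- bundle$b_de
      cl_de <- bundle$cluster_de
      artifacts <<- c(artifacts, file.path(out, "omics", c(
        "b_de.tsv", "cluster_de.tsv", "ppi.tsv", "planted.tsv")))
    } else {
      ct <- config$crosstalk
      ppi <- read_ppi_table(ct$ppi_path,
                            dialect = if (is.null(ct$dialect)) "generic_tsv"
                                      else ct$dialect,
                            min_confidence = if (is.null(ct$min_confidence)) 0
                                             else ct$min_confidence)
      b_de <- read_b_de_table(ct$b_de_path)
      cl_de <- read_cluster_de_table(ct$bmsc_de_path)
    }
    ct <- config$crosstalk
    bmsc_map <- filter_bmsc_genes(
      cl_de,
      min_pct = if (is.null(ct$min_pct)) 0.10 else ct$min_pct,
      alpha = if (is.null(ct$alpha)) 0.05 else ct$alpha)
    res <- cross_reference(ppi, b_de, bmsc_map,
                           alpha = if (is.null(ct$alpha)) 0.05 else ct$alpha)
    state$interactions <- res
    utils::write.csv(res, file.path(out, "interactions.csv"),
                     row.names = FALSE)
    artifacts <<- c(artifacts, file.path(out, "interactions.csv"))
    report$counts$crosstalk <<- list(
      n_edges_in = nrow(ppi), n_records = nrow(res),
      n_by_class = as.list(table(res$class)))
  })

  sums <- tools::md5sum(artifacts)
  report$artifacts <- as.list(stats::setNames(unname(sums), basename(artifacts)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
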