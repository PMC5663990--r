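#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs. Inputs are either a
#' [phantom_spec()] (synthetic run) or NIfTI paths for the count image and
#' the liver / lung / tumor / vessel masks (all on one grid; no resampling
#' is performed). Scalar settings cover the margin policy, tissue density,
#' count-capture distance, territory grouping generation, threshold preset
#' and optional BSA body data.
#'
#' @param phantom optional [phantom_spec()]; when given, image paths are
#'   ignored and the phantom supplies all inputs.
#' @param counts,liver,lung,tumor,vessels NIfTI file paths (patient-data runs).
#' @param root_hint_mm optional vessel-root position for graph rooting.
#' @param margin a [margin_policy()].
#' @param density_kg_per_L tissue density.
#' @param capture_mm background count-capture distance for [partition_counts()].
#' @param generation territory grouping generation (see [group_branches()]).
#' @param limits a [thresholds()] object.
#' @param body optional [patient_body()].
#' @param seed integer seed (phantom runs).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, counts = NULL, liver = NULL, lung = NULL,
                       tumor = NULL, vessels = NULL, root_hint_mm = NULL,
                       margin = margin_policy(), density_kg_per_L = 1.05,
                       capture_mm = 0, generation = 2L,
                       limits = thresholds("T1"), body = NULL,
                       seed = 1L, out_dir = tempfile("sirt_run_")) {
  if (is.null(phantom)) {
    paths <- c(counts = counts, liver = liver, lung = lung, tumor = tumor,
               vessels = vessels)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  structure(list(phantom = phantom, counts = counts, liver = liver,
                 lung = lung, tumor = tumor, vessels = vessels,
                 root_hint_mm = root_hint_mm, margin = margin,
                 density_kg_per_L = density_kg_per_L, capture_mm = capture_mm,
                 generation = as.integer(generation), limits = limits,
                 body = body, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full planning chain
#'
#' phantom (or file inputs) -> vessel skeletonization -> centerline graph ->
#' territory labeling -> tumor margin and partition counting -> PM / TM /
#' BSA activity planning -> dose map. Writes the territory label map,
#' partition table (CSV + JSON), model comparison (JSON), territorial dose
#' map (NIfTI) and a run log; every output directory carries the config
#' hash. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return list with `territories`, `table`, `plans` (PM and TM
#'   [plan_activity()] results), `comparison`, `dose_map`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  logf("sirtpartition %s, config %s",
       as.character(utils::packageVersion("sirtpartition")), config_hash(config))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$rng_seed <- config$seed
    ph <- stage("phantom", build_phantom(spec))
    counts <- ph$count_image; liver <- ph$liver_mask; lung <- ph$lung_mask
    tumor <- ph$tumor_mask; vessels <- ph$vessel_mask
    root_hint <- spec$vessel_root_mm
    logf("phantom built: grid %s", paste(spec$grid_shape, collapse = "x"))
  } else {
    counts <- stage("read", read_volume(config$counts))
    liver <- stage("read", read_volume(config$liver))
    lung <- stage("read", read_volume(config$lung))
    tumor <- stage("read", read_volume(config$tumor))
    vessels <- stage("read", read_volume(config$vessels))
    root_hint <- config$root_hint_mm
    for (v in list(liver, lung, tumor, vessels))
      check_same_grid(counts, v, "count image", "mask")
  }

  skel <- stage("skeletonize", skeletonize_vessels(vessels))
  graph <- stage("graph", build_centerline_graph(skel, root_hint = root_hint))
  gmax <- max(branch_generations(graph), na.rm = TRUE)
  grouping <- stage("grouping",
                    group_branches(graph, generation = min(config$generation, gmax)))
  nl_region <- as_volume(vol_data(liver) & !vol_data(tumor), vol_spacing(liver))
  terr <- stage("territories", assign_territories(nl_region, graph, grouping))
  logf("territories: %d branches -> %d territories",
       length(graph$branches), length(terr$names))

  tab <- stage("uptake", partition_counts(counts, terr, tumor, lung,
                                          margin = config$margin,
                                          density_kg_per_L = config$density_kg_per_L,
                                          capture_mm = config$capture_mm))
  logf("uptake: lung shunt %.4f, T/N %.3f", lung_shunt_fraction(tab),
       tryCatch(tn_ratio(tab), error = function(e) NA))

  plans <- list(PM = stage("planning", plan_activity(tab, "PM", config$limits)),
                TM = stage("planning", plan_activity(tab, "TM", config$limits)))
  comparison <- stage("planning", compare_models(tab, config$limits, config$body))
  dose_map <- stage("dose_map", render_dose_map(plans$TM$doses))
  logf("plan: PM %.3f GBq (%s), TM %.3f GBq (%s)",
       plans$PM$A0_GBq, plans$PM$limiting, plans$TM$A0_GBq, plans$TM$limiting)

  stage("write", {
    write_volume(terr$labels, file.path(config$out_dir, "territories.nii.gz"))
    write_volume(dose_map, file.path(config$out_dir, "dose_map_tm.nii.gz"))
    write_partition_table(plans$TM$doses, file.path(config$out_dir, "partitions"))
    jsonlite::write_json(
      list(config_hash = config_hash(config),
           comparison = comparison,
           thresholds = unclass(config$limits)),
      file.path(config$out_dir, "plan.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })
  logf("done")
  invisible(list(territories = terr, table = tab, plans = plans,
                 comparison = comparison, dose_map = dose_map,
                 out_dir = config$out_dir))
}

#' Write a partition table as CSV and JSON
#'
#' @param table a [partition_counts()] table.
#' @param stem output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @export
write_partition_table <- function(table, stem) {
  df <- as.data.frame(table)
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(partitions = df,
         total_counts = attr(table, "total_counts"),
         background_counts = attr(table, "background_counts")),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(stem)
}
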