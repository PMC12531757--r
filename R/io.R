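# File I/O: TIFF stacks, tabular/JSON/YAML round-trips, and the end-to-end
# synthetic reproduction pipeline.

#' Read a (multi-frame) TIFF stack
#'
#' @param path Path to a TIFF file.
#' @return Numeric array `rows x cols x frames` (frames = 1 for single
#'   images), intensities on the stored integer scale.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                          length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3L) f <- f[, , 1]  # first channel
    arr[, , k] <- f * 65535
  }
  arr
}

#' Write a numeric stack as multi-frame 16-bit TIFF
#'
#' Intensities must lie in `[0, 65535]`; values are rounded to the 16-bit
#' grid, so integer-valued stacks round-trip exactly through
#' [read_image_stack()].
#'
#' @param stack Matrix or `rows x cols x frames` array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (min(stack) < 0 || max(stack) > 65535)
    abort("intensities must be within [0, 65535] for 16-bit storage.")
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(k) round(stack[, , k]) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write records to CSV
#'
#' @param records Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a ground-truth record as JSON
#'
#' Round-trips a [ground_truth()] record losslessly (full numeric
#' precision).
#'
#' @param truth A `ground_truth` object.
#' @param path JSON path.
#' @return `path` invisibly; `read_ground_truth()` returns the record.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$generator, x$params, x$derived, x$seed)
}

#' Write / read a run configuration as YAML
#'
#' @param config Named list of run parameters.
#' @param path YAML path.
#' @return `path` invisibly; `read_run_config()` returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  yaml::read_yaml(path)
}

#' Run the full synthetic reproduction pipeline
#'
#' Generates synthetic datasets for every analysis module (calcium
#' transients, vessel morphometry, permeability, extravasation), runs the
#' corresponding analyses, and reports ground-truth versus recovered
#' values. Every source of randomness derives from `config$seed`.
#'
#' @param config Named list; recognized sections (all optional, with
#'   defaults): `seed`, `calcium` (`n_traces`, `mean_frequency`, ...
#'   passed to [beat_train_params()]), `vessels` (passed to
#'   [vessel_network_params()]), `permeability` (passed to
#'   [permeability_sim_params()]), `extravasation`
#'   (`outside_fraction`), `output_dir` (when set, CSV/JSON outputs are
#'   written there).
#' @return A `pipeline_report` list: `results` tibble
#'   (`module, metric, truth, recovered, delta`), `config`, `config_hash`,
#'   `versions`, `seed`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  results <- list()

  cal_cfg <- config$calcium %||% list()
  n_traces <- cal_cfg$n_traces %||% 3L
  cal_cfg$n_traces <- NULL
  freqs <- numeric(0); true_freqs <- numeric(0)
  for (i in seq_len(n_traces)) {
    p <- do.call(beat_train_params,
                 c(cal_cfg, list(seed = seed * 100 + i)))
    tr <- gen_calcium_trace(p)
    s <- analyze_calcium_trace(tr)
    freqs <- c(freqs, s$frequency)
    true_freqs <- c(true_freqs, p$mean_frequency)
  }
  results$calcium <- tibble::tibble(
    module = "calcium", metric = "mean_frequency",
    truth = mean(true_freqs), recovered = mean(freqs))

  ves_cfg <- config$vessels %||% list(image_shape = c(384, 384),
                                      target_coverage = 0.4)
  net <- gen_vessel_network(do.call(vessel_network_params,
                                    c(ves_cfg, list(seed = seed * 100 + 51))))
  px <- net$truth$params$pixel_size
  vm <- analyze_vessels(net$image, pixel_size = px)
  results$vessels <- tibble::tibble(
    module = "vessels",
    metric = c("coverage", "mean_diameter"),
    truth = c(net$truth$derived$coverage, net$truth$derived$mean_diameter),
    recovered = c(vm$area_fraction, vm$mean_diameter))

  per_cfg <- config$permeability %||% list()
  sim <- gen_permeability_stack(do.call(permeability_sim_params,
                                        c(per_cfg, list(seed = seed * 100 + 71))))
  pr <- analyze_permeability(sim$stack, sim$vessel_mask, sim$times,
                             diameter = sim$truth$params$vessel_diameter,
                             saturation_frac = Inf)
  results$permeability <- tibble::tibble(
    module = "permeability", metric = "permeability",
    truth = sim$truth$derived$permeability, recovered = pr$permeability)

  ext_cfg <- config$extravasation %||% list(outside_fraction = 0.618)
  pair <- gen_extravasation_pair(ext_cfg$outside_fraction, net$mask,
                                 n_positive = ext_cfg$n_positive %||% 1000,
                                 seed = seed * 100 + 91)
  ef <- extravascular_fraction(pair$liposome, pair$vessel_mask,
                               dilation_px = 0)
  results$extravasation <- tibble::tibble(
    module = "extravasation", metric = "extravascular_fraction",
    truth = pair$truth$derived$realized_fraction,
    recovered = ef$extravascular_fraction)

  res <- dplyr::bind_rows(results) |>
    dplyr::mutate(delta = .data$recovered - .data$truth)
  report <- structure(list(
    results = res, config = config, config_hash = rlang::hash(config),
    versions = list(package = as.character(utils::packageVersion("cardiochip")),
                    r = R.version.string),
    seed = seed
  ), class = "pipeline_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(res, file.path(config$output_dir, "recovery_report.csv"))
    jsonlite::write_json(list(config = config, hash = report$config_hash,
                              versions = report$versions, seed = seed),
                         file.path(config$output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$seed, ", config hash ", x$config_hash,
      "\n", sep = "")
  print(x$results)
  invisible(x)
}
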