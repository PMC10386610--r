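# Batch orchestration: simulate -> calibrate -> measure -> evaluate over
# sample directories, with file-based configuration and per-sample fault
# isolation. These functions back the command-line interface shipped in
# inst/cli/.

pp_log <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  message(msg)
  lf <- config$log_file
  if (!is.null(lf)) cat(msg, "\n", file = lf, append = TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; keys mirror the arguments of the `run_*` functions.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- read_config_file(path)
  if (!is.list(cfg)) stop("unreadable config: ", path, call. = FALSE)
  cfg
}

#' Generate a tree of synthetic scene bundles
#'
#' Writes `n_scenes` randomized scenes under `out_dir/scene_<k>/` plus a
#' `ground_truth.csv` property table. Per-scene failures are recorded and
#' do not abort the batch. Deterministic for a fixed config.
#'
#' @param config list (or path read by [read_pipeline_config()]) with
#'   keys: `out_dir`, `n_scenes`, `seed`, optional `noise_sigma`, `cast`
#'   (3x3, nested list), `fpc`.
#' @return List with `dirs`, `ground_truth`, `errors`, `status` (0 unless
#'   every scene failed).
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  n <- as.integer(config$n_scenes %||% 1L)
  seed <- as.integer(config$seed %||% 1L)
  noise <- config$noise_sigma %||% 0
  cast <- if (!is.null(config$cast)) matrix(unlist(config$cast), 3L, 3L,
                                            byrow = TRUE) else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("scene_%03d", seq_len(n))
  errors <- character(0)
  rows <- list()
  dirs <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      spec <- random_scene_spec(seed + i - 1L, fpc = config$fpc,
                                noise_sigma = noise, cast = cast)
      bundle <- generate_scene(spec)
      d <- file.path(out_dir, ids[i])
      write_scene_bundle(bundle, d)
      tr <- bundle$truth
      rows[[ids[i]]] <- data.frame(
        sample_id = ids[i], FL = tr$FL_mm, FW = tr$FW_mm,
        VL = tr$VL_mm, VW = tr$VW_mm, FPC = tr$FPC,
        stringsAsFactors = FALSE)
      dirs <- c(dirs, d)
      pp_log(config, "simulate %s: ok (mm_per_px %.4f)", ids[i],
             spec$mm_per_px)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errors <- c(errors, paste0(ids[i], ": ", res))
      pp_log(config, "simulate %s: FAILED (%s)", ids[i], res)
    }
  }
  gt <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(gt)) {
    gt[QUANT_PROPS] <- lapply(gt[QUANT_PROPS], round, digits = 6)
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  status <- if (n > 0 && length(errors) == n) 2L else 0L
  list(dirs = dirs, ground_truth = gt, errors = errors, status = status)
}

# measurement of a single sample directory
measure_sample_dir <- function(dir, config) {
  img_path <- file.path(dir, "image.png")
  if (!file.exists(img_path))
    img_path <- Filter(file.exists,
                       file.path(dir, c("image.jpg", "image.jpeg")))[1]
  if (is.na(img_path) || is.null(img_path))
    stop("no image found in ", dir, call. = FALSE)
  image <- read_image(img_path)

  scfg_path <- file.path(dir, "scene_config.json")
  scfg <- if (file.exists(scfg_path))
    jsonlite::read_json(scfg_path, simplifyVector = TRUE) else list()
  ruler_length_mm <- scfg$ruler_length_mm %||% config$ruler_length_mm
  if (is.null(ruler_length_mm))
    stop("ruler_length_mm missing (scene_config.json or config)",
         call. = FALSE)

  # optional color correction against the reference chip colors
  if (isTRUE(config$color_correction %||% TRUE)) {
    grid_path <- file.path(dir, "chip_grid.json")
    if (file.exists(grid_path)) {
      grid <- read_chip_grid(grid_path)
      ref <- scfg$reference_colors %||% config$reference_colors
      ref <- if (is.null(ref)) checker_reference_colors() else
        matrix(unlist(ref), 24L, 3L)
      src <- extract_chip_means(image, grid)
      cm <- fit_correction_matrix(src, ref,
                                  model = config$correction_model %||% "linear")
      image <- apply_correction(image, cm)
      pp_log(config,
             "%s: color correction (condition %.3g, residual %.3g, %d clipped)",
             basename(dir), cm$condition, cm$residual,
             attr(image, "n_clipped"))
    } else {
      pp_log(config, "%s: no chip grid, skipping color correction",
             basename(dir))
    }
  }

  rp_cfg <- config$ruler_params %||% list()
  rp <- do.call(ruler_params, rp_cfg)
  line <- detect_ruler(image, rp)
  scale <- compute_scale(line, ruler_length_mm)
  pp_log(config,
         "%s: ruler (%.1f,%.1f)-(%.1f,%.1f) len %.1f px -> %.5f mm/px",
         basename(dir), line$x1, line$y1, line$x2, line$y2, line$length,
         scale$mm_per_px)

  fruit_path <- file.path(dir, "fruit_mask.png")
  vine_path <- file.path(dir, "vine_mask.png")
  fruit_mask <- if (file.exists(fruit_path)) read_mask(fruit_path) else NULL
  vine_mask <- if (file.exists(vine_path)) read_mask(vine_path) else NULL
  if (is.null(fruit_mask) && is.null(vine_mask)) {
    coco_path <- file.path(dir, "coco.json")
    if (file.exists(coco_path)) {
      cm <- read_coco_masks(coco_path, H = dim(image)[1], W = dim(image)[2])
      fruit_mask <- cm$fruit
      vine_mask <- cm$vine
    }
  }
  if (is.null(fruit_mask) && is.null(vine_mask))
    stop("no component masks found in ", dir, call. = FALSE)

  measure_sample(image, fruit_mask, vine_mask, scale,
                 sample_id = basename(dir),
                 width_method = NULL,
                 step_model = config$step_model %||% "pixel_count")
}

#' Measure every sample directory under an input tree
#'
#' Each subdirectory of `input_dir` is one sample: an image, component
#' masks (PNG or COCO JSON), an optional chip grid for color correction
#' and an optional `scene_config.json` carrying the ruler's physical
#' length. Per sample, the pipeline optionally fits and applies the color
#' correction, detects the ruler, computes the pixel scale, measures the
#' components and appends a record row. Failures are recorded per sample
#' without aborting the batch.
#'
#' @param config list (or config file path) with keys: `input_dir`,
#'   optional `out_csv`, `out_json`, `color_correction` (default TRUE),
#'   `reference_colors`, `correction_model`, `ruler_params` (list),
#'   `ruler_length_mm` (fallback when samples carry none), `step_model`,
#'   `log_file`.
#' @return List with `records` (data frame, mm values rounded half-even
#'   to 2 decimals for display), `errors` (named character), `status`
#'   (0 = success or empty input, 2 = all samples failed).
#' @export
run_measure <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  input_dir <- config$input_dir %||% stop("config needs input_dir",
                                          call. = FALSE)
  if (!dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  dirs <- list.dirs(input_dir, recursive = FALSE)
  dirs <- dirs[order(basename(dirs))]
  if (length(dirs) == 0L) {
    warning("no sample directories under ", input_dir, call. = FALSE)
    empty <- data.frame(sample_id = character(0), FL_mm = numeric(0),
                        FW_mm = numeric(0), VL_mm = numeric(0),
                        VW_mm = numeric(0), FPC = character(0),
                        stringsAsFactors = FALSE)
    return(list(records = empty, errors = character(0), status = 0L))
  }
  rows <- list()
  errors <- character(0)
  for (d in dirs) {
    rec <- tryCatch(measure_sample_dir(d, config), error = function(e) e)
    if (inherits(rec, "error")) {
      errors[basename(d)] <- conditionMessage(rec)
      pp_log(config, "%s: FAILED (%s)", basename(d), conditionMessage(rec))
    } else {
      rows[[basename(d)]] <- rec
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), FL_mm = numeric(0),
               FW_mm = numeric(0), VL_mm = numeric(0), VW_mm = numeric(0),
               FPC = character(0), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  num <- c("FL_mm", "FW_mm", "VL_mm", "VW_mm")
  records[num] <- lapply(records[num], round, digits = 2)  # half-even display
  if (!is.null(config$out_csv))
    utils::write.csv(records, config$out_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(config$out_json))
    jsonlite::write_json(records, config$out_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  status <- if (length(rows) == 0L) 2L else 0L
  list(records = records, errors = errors, status = status)
}

#' Evaluate predicted against ground-truth property tables
#'
#' Reads both CSVs (columns `sample_id, FL, FW, VL, VW, FPC`; the
#' measurement output's `_mm` suffixes are accepted), delegates to
#' [evaluate_table()] and optionally writes per-sample and aggregate
#' reports.
#'
#' @param config list (or config file path) with keys `gt_csv`,
#'   `pred_csv`, optional `out_json`, `out_csv`.
#' @return The [evaluate_table()] report.
#' @export
run_evaluate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  gt <- read_property_table(config$gt_csv)
  pred <- read_property_table(config$pred_csv)
  report <- evaluate_table(gt, pred)
  if (!is.null(config$out_csv)) {
    per <- report$per_sample
    per$mae <- round(per$mae, 2)
    per$mape_pct <- round(per$mape_pct, 2)
    utils::write.csv(per, config$out_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(config$out_json))
    jsonlite::write_json(report, config$out_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  report
}

#' Fit a color-correction matrix from an image pair
#'
#' Extracts chip means from the input image using its chip grid, fits the
#' correction toward reference chip colors (from a reference image +
#' grid, or an explicit 24 x 3 table) and writes the matrix as JSON.
#'
#' @param config list (or config file path) with keys: `image`,
#'   `chip_grid`, and either (`reference_image`, `reference_chip_grid`)
#'   or `reference_colors` (24 x 3); optional `model`, `out_matrix`.
#' @return The fitted `correction_matrix`.
#' @export
run_calibrate <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  image <- read_image(config$image)
  grid <- read_chip_grid(config$chip_grid)
  src <- extract_chip_means(image, grid)
  ref <- if (!is.null(config$reference_image)) {
    rgrid <- read_chip_grid(config$reference_chip_grid %||% config$chip_grid)
    extract_chip_means(read_image(config$reference_image), rgrid)
  } else if (!is.null(config$reference_colors)) {
    matrix(unlist(config$reference_colors), 24L, 3L)
  } else {
    stop("config needs reference_image or reference_colors", call. = FALSE)
  }
  cm <- fit_correction_matrix(src, ref, model = config$model %||% "linear")
  if (!is.null(config$out_matrix)) write_correction_matrix(cm, config$out_matrix)
  cm
}
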