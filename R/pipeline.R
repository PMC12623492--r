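#' Assemble a pipeline run configuration
#'
#' A run configuration selects one or more denoising methods and their
#' parameters. Method entries are named lists with a `method` field:
#' `list(method = "gp", n_levels = 5)` or
#' `list(method = "wavelet", family = "haar", n_levels = 2,
#' threshold_mode = "soft", selector = "universal")`. A fixed threshold is
#' spelled `selector = "fixed:20"`.
#'
#' @param methods list of method entries (see above).
#' @param color_mode `"per-channel"` (denoise each RGB channel) or `"luma"`
#'   (denoise the luminance, keep chroma).
#' @param seed integer seed recorded with the run.
#' @return a `"run_config"` list.
#' @export
run_config <- function(methods, color_mode = c("per-channel", "luma"),
                       seed = 1L) {
  color_mode <- match.arg(color_mode)
  if (!is.list(methods) || length(methods) < 1L) {
    stop("`methods` must be a non-empty list of method entries",
         call. = FALSE)
  }
  for (m in methods) {
    if (is.null(m$method) || !m$method %in% c("gp", "wavelet")) {
      stop("each method entry needs method = \"gp\" or \"wavelet\"",
           call. = FALSE)
    }
  }
  structure(list(methods = methods, color_mode = color_mode,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The document mirrors [run_config()]: top-level keys `methods` (a list),
#' `color_mode`, `seed`.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop(sprintf("unsupported config format '.%s'", ext), call. = FALSE))
  run_config(methods = doc$methods,
             color_mode = if (is.null(doc$color_mode)) "per-channel"
                          else doc$color_mode,
             seed = if (is.null(doc$seed)) 1L else doc$seed)
}

method_label <- function(m) {
  if (m$method == "gp") {
    sprintf("gp%d", if (is.null(m$n_levels)) 5L else m$n_levels)
  } else {
    sprintf("wavelet-%s-%s",
            if (is.null(m$family)) "db4" else m$family,
            if (is.null(m$threshold_mode)) "soft" else m$threshold_mode)
  }
}

# run one configured method on one plane (or per channel on RGB)
run_method <- function(image, m) {
  denoise_plane <- function(plane) {
    if (m$method == "gp") {
      n_levels <- if (is.null(m$n_levels)) 5L else m$n_levels
      denoise_gp(plane, n_levels = n_levels)$image
    } else {
      sel <- if (is.null(m$selector)) "universal" else m$selector
      threshold <- if (startsWith(sel, "fixed:")) {
        as.numeric(sub("^fixed:", "", sel))
      } else sel
      denoise_wavelet(plane,
                      family = if (is.null(m$family)) "db4" else m$family,
                      n_levels = if (is.null(m$n_levels)) 2L else m$n_levels,
                      mode = if (is.null(m$threshold_mode)) "soft"
                             else m$threshold_mode,
                      threshold = threshold)
    }
  }
  apply_channels(image, denoise_plane)
}

# rec.601 luma and back
rgb_to_luma <- function(x) {
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Run the full benchmark pipeline over a manifest
#'
#' For each manifest pair: read the clean and noisy images, denoise with
#' every configured method, evaluate the metric battery, and append a report
#' row. With two or more methods, every method is also compared against the
#' first with [compare_methods()] on PSNR. Writes `metrics.csv` (and
#' `comparisons.csv` when applicable) under `out_dir`.
#'
#' @param config a [run_config()] or path to a YAML/JSON config.
#' @param manifest data frame from [make_benchmark_set()] (or a path to a
#'   manifest CSV) with `image_id`, `path_clean`, `path_noisy` columns.
#' @param out_dir output directory for CSV artifacts.
#' @return list with `metrics` (data frame), `comparisons` (list of
#'   `"paired_comparison"` or `NULL`), and the output paths.
#' @export
run_pipeline <- function(config, manifest, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.character(manifest)) {
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    clean <- read_image(manifest$path_clean[i])
    noisy <- read_image(manifest$path_noisy[i])
    if (config$color_mode == "luma" && length(dim(noisy)) == 3L) {
      clean <- rgb_to_luma(clean)
      noisy <- rgb_to_luma(noisy)
    }
    for (m in config$methods) {
      t0 <- proc.time()[["elapsed"]]
      den <- run_method(noisy, m)
      elapsed <- proc.time()[["elapsed"]] - t0
      ref_plane <- if (is.matrix(clean)) clean else rgb_to_luma(clean)
      den_plane <- if (is.matrix(den)) den else rgb_to_luma(den)
      rows[[length(rows) + 1L]] <- evaluate_pair(
        ref_plane, den_plane, image_id = manifest$image_id[i],
        method = method_label(m), elapsed_seconds = elapsed)
    }
  }
  metrics <- do.call(rbind, rows)
  metrics_path <- file.path(out_dir, "metrics.csv")
  write_metric_csv(metrics, metrics_path)
  comparisons <- NULL
  if (length(config$methods) >= 2L) {
    labels <- vapply(config$methods, method_label, character(1))
    base <- metrics[metrics$method == labels[1L], ]
    comparisons <- lapply(labels[-1L], function(lb) {
      compare_methods(base, metrics[metrics$method == lb, ])
    })
    write_comparison_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  }
  list(metrics = metrics, comparisons = comparisons,
       metrics_path = metrics_path,
       comparisons_path = if (is.null(comparisons)) NULL
                          else file.path(out_dir, "comparisons.csv"))
}
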