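#' Read and write unit-annotated CSV tables
#'
#' Numeric tables round trip at full precision (17 significant digits);
#' column names carry their units (`x_um`, `load_mN`, ...). A schema can be
#' enforced on read, turning missing columns into validation errors that
#' name the file.
#'
#' @param path CSV file path.
#' @param required character vector of required column names.
#' @return `read_table_csv()` returns a tibble; `write_table_csv()` the
#'   path, invisibly.
#' @export
read_table_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_claw("no such file: ", path)
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop_claw(path, ": missing column(s) ", paste(missing, collapse = ", "))
    }
  }
  df
}

#' @rdname read_table_csv
#' @param table data frame to write.
#' @export
write_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_claw_pipeline()]: a global seed, the
#' physical pixel size, an output directory, and per-stage parameter
#' blocks. Unknown keys are rejected before any stage runs. A YAML file
#' with the same structure can be loaded with `pipeline_config_from_yaml()`.
#'
#' @param seed integer seed driving every random stage.
#' @param pixel_size micrometres per pixel of the simulated image.
#' @param out_dir output directory for stage artifacts.
#' @param simulate,denoise,edges,fit named lists of stage parameters:
#'   `simulate` accepts `phantom` ([phantom_spec()]) and `noise`
#'   ([noise_spec()]); `denoise` accepts `params` ([nlm_params()]) and
#'   `scheme`; `edges` accepts `scales` and `lambda_frac`; `fit` accepts
#'   `families` and `min_points`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, pixel_size = 1,
                            out_dir = tempfile("clawmech_run_"),
                            simulate = list(), denoise = list(),
                            edges = list(), fit = list()) {
  check_number(seed, "seed")
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  allowed <- list(
    simulate = c("phantom", "noise"),
    denoise = c("params", "scheme"),
    edges = c("scales", "lambda_frac"),
    fit = c("families", "min_points")
  )
  for (stage in names(allowed)) {
    block <- get(stage)
    bad <- setdiff(names(block), allowed[[stage]])
    if (length(bad)) {
      stop_claw("unknown ", stage, " option(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(seed = as.integer(seed), pixel_size = pixel_size, out_dir = out_dir,
         simulate = simulate, denoise = denoise, edges = edges, fit = fit),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys mirror the
#'   `pipeline_config()` arguments.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "pixel_size", "out_dir", "simulate", "denoise",
             "edges", "fit")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_claw("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Run the claw analysis pipeline end to end
#'
#' Executes simulate -> denoise -> edges -> fit in order, mirroring the
#' analysis flow from raw micrograph to fitted boundary curves. Every
#' stage writes its artifacts under `out_dir` and is logged in the
#' returned manifest with parameter echo and an MD5 checksum, so a run is
#' fully traceable and, for a fixed seed, bit-reproducible. A stage
#' failure aborts with the failing stage named; artifacts of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return tibble manifest of class `claw_manifest`: one row per artifact
#'   with `stage`, `artifact`, `path`, `md5`, `params`.
#' @export
#' @examples
#' \donttest{
#' man <- run_claw_pipeline(pipeline_config(seed = 7))
#' man$stage
#' }
run_claw_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_artifact <- function(stage, artifact, path, params) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = artifact, path = path,
      md5 = unname(tools::md5sum(path)),
      params = paste(names(params), unlist(lapply(params, toString)),
                     sep = "=", collapse = "; ")
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_claw("pipeline stage '", stage, "' failed: ", conditionMessage(e),
                class = "clawmech_stage_error")
    })
  }

  # simulate ---------------------------------------------------------------
  sim <- config$simulate
  phantom <- sim$phantom %||% phantom_spec()
  noise <- sim$noise %||% noise_spec()
  noise$seed <- config$seed
  clean <- run_stage("simulate", generate_claw_phantom(phantom))
  noisy <- run_stage("simulate", add_noise(clean, noise))
  p_clean <- file.path(config$out_dir, "phantom_clean.png")
  p_noisy <- file.path(config$out_dir, "phantom_noisy.png")
  write_image(clean, p_clean)
  write_image(noisy, p_noisy)
  log_artifact("simulate", "phantom_clean", p_clean,
               list(width = phantom$width, height = phantom$height))
  log_artifact("simulate", "phantom_noisy", p_noisy,
               list(gaussian_sd = noise$gaussian_sd,
                    impulse_fraction = noise$impulse_fraction,
                    seed = config$seed))

  # denoise ----------------------------------------------------------------
  dn_params <- config$denoise$params %||% nlm_params()
  scheme <- config$denoise$scheme %||% "improved"
  denoised <- run_stage("denoise", nlm_denoise(noisy, dn_params, scheme))
  p_dn <- file.path(config$out_dir, "denoised.png")
  write_image(denoised, p_dn)
  metrics <- list(
    scheme = scheme,
    mse_noisy = mse(clean, noisy), psnr_noisy = psnr(mse(clean, noisy)),
    mse_denoised = mse(clean, denoised),
    psnr_denoised = psnr(mse(clean, denoised))
  )
  p_met <- file.path(config$out_dir, "denoise_metrics.json")
  jsonlite::write_json(metrics, p_met, auto_unbox = TRUE, digits = NA)
  log_artifact("denoise", "denoised", p_dn, list(scheme = scheme))
  log_artifact("denoise", "metrics", p_met, metrics[c("mse_denoised")])

  # edges ------------------------------------------------------------------
  scales <- config$edges$scales %||% 1L
  lambda_frac <- config$edges$lambda_frac %||% 0.2
  maps <- run_stage(
    "edges",
    multiscale_edge_detect(denoised, scales, lambda_frac = lambda_frac)
  )
  for (nm in names(maps)) {
    p_edge <- file.path(config$out_dir, paste0("edges_", nm, ".png"))
    write_image(maps[[nm]]$edges * 255, p_edge)
    log_artifact("edges", nm, p_edge,
                 list(scale = maps[[nm]]$scale_index,
                      lambda_frac = lambda_frac))
  }

  # fit --------------------------------------------------------------------
  families <- config$fit$families %||% fit_families
  min_points <- config$fit$min_points %||% 20L
  fits <- run_stage("fit", {
    chains <- extract_boundary(maps[[1]], config$pixel_size)
    segs <- split_monotone(chains[[1]], min_points)
    purrr::map(segs, function(seg) {
      best <- select_model(fit_all_families(seg, families))
      list(family = best$family,
           coefficients = as.list(best$coefficients),
           sse = best$sse, sst = best$sst, r_squared = best$r_squared,
           n = best$n)
    })
  })
  p_fit <- file.path(config$out_dir, "fits.json")
  jsonlite::write_json(fits, p_fit, auto_unbox = TRUE, digits = NA)
  log_artifact("fit", "fits", p_fit,
               list(families = paste(families, collapse = ","),
                    segments = length(fits)))

  out <- dplyr::bind_rows(manifest)
  structure(out, class = c("claw_manifest", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
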