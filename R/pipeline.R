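#' Pipeline configuration
#'
#' Composite configuration of a full end-to-end run: synthetic data
#' generation, multispace reconstruction, tiling, feature extraction,
#' selector training and image-level cross-validated evaluation. The
#' single `seed` propagates to every stochastic stage.
#'
#' @param image_size `(W, H)` of the generated images.
#' @param n_per_class images per class.
#' @param profiles class profiles ([default_class_profiles()] scaled to
#'   `image_size` by default).
#' @param patch_size tiling patch side (64).
#' @param space space-operator parameters ([space_params()]).
#' @param selector selector settings ([selector_config()]); its
#'   `feature_dim` must stay 2048.
#' @param k cross-validation folds.
#' @param seed master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(image_size = c(192L, 128L), n_per_class = 4L,
                            profiles = NULL, patch_size = 64L,
                            space = space_params(),
                            selector = selector_config(iterations = 30L),
                            k = 3L, seed = 1L) {
  if (is.null(profiles)) {
    # scale the full-size densities to the requested pixel area
    scale <- prod(image_size) / (1388 * 1040)
    profiles <- lapply(default_class_profiles(), function(p) {
      p$density <- max(3L, as.integer(round(p$density * scale)))
      p
    })
  }
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 profiles = profiles, patch_size = as.integer(patch_size),
                 space = space, selector = selector,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' nested `space` and `selector` maps are passed to [space_params()] and
#' [selector_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("image_size", "n_per_class", "profiles",
                        "patch_size", "k", "seed"))]
  if (!is.null(y$space)) args$space <- do.call(space_params, y$space)
  if (!is.null(y$selector)) args$selector <- do.call(selector_config, y$selector)
  do.call(pipeline_config, args)
}

# short polynomial content hash of the serialized config, for run logs
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

run_stage <- function(stage, input_id, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed on '", input_id, "': ",
         conditionMessage(e), call. = FALSE))
}

write_features_csv <- function(path, image_id, patch_idx, origins, rgb, rec) {
  df <- data.frame(image_id = image_id, patch_idx = patch_idx,
                   row_px = origins[, 1], col_px = origins[, 2])
  colnames(rgb) <- paste0("rgb", seq_len(ncol(rgb)))
  colnames(rec) <- paste0("rec", seq_len(ncol(rec)))
  write.csv(cbind(df, rgb, rec), path, row.names = FALSE)
}

read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  rgb_cols <- grep("^rgb[0-9]+$", names(df))
  rec_cols <- grep("^rec[0-9]+$", names(df))
  list(image_id = as.character(df$image_id), patch_idx = df$patch_idx,
       origins = cbind(row_px = df$row_px, col_px = df$col_px),
       rgb = as.matrix(df[, rgb_cols]), rec = as.matrix(df[, rec_cols]))
}

#' Run the full pipeline end to end
#'
#' Executes the four-stage flow — synthetic data generation, multispace
#' reconstruction, patch tiling + backbone feature extraction, selector
#' training with image-level cross-validated evaluation — writing every
#' intermediate artifact (images, reconstructed images, feature table,
#' report, run log with config hash and seed) under `out_dir`. With
#' `resume = TRUE` an existing feature table is reloaded instead of
#' recomputed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory for artifacts.
#' @param resume reuse `features.csv` under `out_dir` if present.
#' @param verbose print stage progress.
#' @return The [cross_validate()] `cv_report`; artifact paths in the
#'   `paths` attribute.
#' @export
run_pipeline <- function(cfg, out_dir, resume = FALSE, verbose = FALSE) {
  if (!inherits(cfg, "pipeline_config")) stop("expected a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list(images = file.path(out_dir, "images"),
                reconstructed = file.path(out_dir, "reconstructed"),
                features = file.path(out_dir, "features.csv"),
                report = file.path(out_dir, "report.json"),
                log = file.path(out_dir, "run_log.txt"))

  say("stage synth: %d images/class at %d x %d px",
      cfg$n_per_class, cfg$image_size[1], cfg$image_size[2])
  scfg <- synth_config(image_size = cfg$image_size,
                       n_per_class = cfg$n_per_class,
                       profiles = cfg$profiles, seed = cfg$seed)
  ds <- run_stage("synth", "dataset",
                  generate_dataset(scfg, out_dir = paths$images))

  if (resume && file.exists(paths$features)) {
    say("stage extract: resuming from %s", paths$features)
    feats <- read_features_csv(paths$features)
  } else {
    dir.create(paths$reconstructed, showWarnings = FALSE)
    backbone <- run_stage("extract", "backbone",
                          build_backbone(backbone_config(seed = cfg$seed)))
    image_id <- patch_idx <- character(0)
    origins <- matrix(integer(0), 0, 2)
    rgb_rows <- rec_rows <- list()
    for (id in ds$manifest$image_id) {
      img <- ds$images[[id]]
      rec_img <- run_stage("reconstruct", id, reconstruct(img, cfg$space))
      write_image(rec_img, file.path(paths$reconstructed,
                                     paste0(id, ".png")))
      g_rgb <- run_stage("tile", id, tile_image(img, cfg$patch_size))
      g_rec <- run_stage("tile", id, tile_image(rec_img, cfg$patch_size))
      say("stage extract: %s (%d patches)", id, length(g_rgb$patches))
      rgb_rows[[id]] <- run_stage("extract", id,
                                  extract_features(backbone, g_rgb))
      rec_rows[[id]] <- run_stage("extract", id,
                                  extract_features(backbone, g_rec))
      n <- length(g_rgb$patches)
      image_id <- c(image_id, rep(id, n))
      patch_idx <- c(patch_idx, seq_len(n) - 1L)
      origins <- rbind(origins, g_rgb$origins)
    }
    feats <- list(image_id = image_id,
                  patch_idx = as.integer(patch_idx), origins = origins,
                  rgb = do.call(rbind, rgb_rows),
                  rec = do.call(rbind, rec_rows))
    write_features_csv(paths$features, feats$image_id, feats$patch_idx,
                       feats$origins, feats$rgb, feats$rec)
  }

  img_class <- setNames(ds$manifest$class, ds$manifest$image_id)
  dataset <- list(rgb = feats$rgb, rec = feats$rec,
                  labels = unname(img_class[feats$image_id]),
                  image_id = feats$image_id)
  say("stage evaluate: %d-fold image-level cross-validation", cfg$k)
  report <- run_stage("evaluate", "cross_validation",
                      cross_validate(dataset, k = cfg$k,
                                     config = cfg$selector, seed = cfg$seed))

  out <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    patch_level = report_table(report, "patch"),
    image_level = report_table(report, "image"))
  jsonlite::write_json(out, paths$report, auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("config_hash: %s", config_hash(cfg)),
               sprintf("seed: %d", cfg$seed),
               sprintf("generated: %d images, %d patches",
                       length(ds$images), nrow(feats$rgb))),
             paths$log)
  attr(report, "paths") <- paths
  report
}
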