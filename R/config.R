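# Run configuration: one YAML file drives the whole pipeline
# (synth -> mask -> train -> predict -> heatmap -> evaluate), with every
# default equal to the standard recipe where one exists (k = 8, N = 256,
# batch 32, lr 0.001, decay 0.95 / 2 epochs, early stop 10, mining switch
# 2, bootstrap 1000) and the two canonical tiling configurations
# (20x / 512 px and 10x / 224 px).

#' Default run configuration
#'
#' @param magnification `"20x"` (512 px tiles) or `"10x"` (224 px tiles).
#' @return a `wsiRunConfig` nested list.
#' @export
defaultRunConfig <- function(magnification = "20x") {
  stopifnot(magnification %in% c("20x", "10x"))
  cfg <- list(
    seed = 1L,
    paths = list(manifest = NULL, output_dir = "wsimine_out"),
    tiles = list(magnification = magnification,
                 tile_size = if (magnification == "20x") 512L else 224L,
                 stride = NULL,  # NULL = tile_size (non-overlapping)
                 min_tissue_frac = 0.1),
    synth = list(n_pos = 5L, n_neg = 5L, image_size = 2048L, n_cores = 3L,
                 core_shape = "needle", lesion_fraction = 0.3,
                 texture_contrast = 60, background_level = 245L,
                 split_fractions = c(train = 0.6, validation = 0.2,
                                     test = 0.2)),
    mining = list(k = 8L, N = 256L, batch_size = 32L, num_labels = 2L,
                  switch_patience = 2L),
    train = list(lr0 = 0.001, decay_factor = 0.95, decay_every = 2L,
                 beta1 = 0.9, beta2 = 0.999, early_stop_patience = 10L,
                 max_epochs = 100L, backbone = "tiny_cnn",
                 finetune = "partial", val_tiles_per_slide = 64L),
    evaluate = list(threshold = 0.5, n_bootstrap = 1000L))
  structure(cfg, class = "wsiRunConfig")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [defaultRunConfig()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated `wsiRunConfig`.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(
    if (!is.null(user$tiles$magnification)) user$tiles$magnification else "20x")
  mergeInto <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", prefix, nm)
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- mergeInto(base[[nm]], upd[[nm]],
                                paste0(prefix, nm, "."))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  cfg2 <- mergeInto(unclass(cfg), user)
  validateRunConfig(structure(cfg2, class = "wsiRunConfig"))
}

#' @rdname readRunConfig
#' @param cfg a `wsiRunConfig`.
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(inherits(cfg, "wsiRunConfig"))
  t <- cfg$tiles
  if (!t$magnification %in% c("20x", "10x"))
    stop("tiles.magnification must be '20x' or '10x'")
  if (!is.numeric(t$tile_size) || t$tile_size < 8)
    stop("tiles.tile_size must be a tile side in pixels")
  if (!is.null(t$stride) && t$stride < 1) stop("tiles.stride must be >= 1")
  if (t$min_tissue_frac < 0 || t$min_tissue_frac > 1)
    stop("tiles.min_tissue_frac must be in [0, 1]")
  # constructing the S4 configs runs their validity checks
  miningConfigFrom(cfg); trainConfigFrom(cfg)
  if (cfg$evaluate$threshold < 0 || cfg$evaluate$threshold > 1)
    stop("evaluate.threshold must be in [0, 1]")
  sf <- cfg$synth$split_fractions
  if (abs(sum(sf) - 1) > 1e-8) stop("synth.split_fractions must sum to 1")
  cfg
}

miningConfigFrom <- function(cfg) {
  m <- cfg$mining
  miningConfig(m$k, m$N, m$batch_size, m$num_labels, m$switch_patience)
}

trainConfigFrom <- function(cfg) {
  tr <- cfg$train
  trainConfig(tr$lr0, tr$decay_factor, tr$decay_every, tr$beta1, tr$beta2,
              tr$early_stop_patience, tr$max_epochs, tr$backbone,
              tr$finetune, tr$val_tiles_per_slide, seed = cfg$seed)
}

strideFrom <- function(cfg) {
  if (is.null(cfg$tiles$stride)) cfg$tiles$tile_size else cfg$tiles$stride
}

writeRunManifest <- function(cfg, name, dir, artifacts) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(subcommand = name, config = unclass(cfg),
         config_hash = configHash(unclass(cfg)), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("wsimine")),
         r_version = R.version.string, artifacts = artifacts),
    file.path(dir, paste0(name, "_run.json")), auto_unbox = TRUE,
    digits = NA, null = "null")
}

#' Run one pipeline subcommand
#'
#' Executes one stage of the pipeline and writes its artifacts plus a
#' run-manifest JSON (config hash, seed, versions) under the configured
#' output directory. Stages compose as synth -> mask -> train -> predict ->
#' heatmap -> evaluate; with the same configuration the chain is
#' deterministic.
#'
#' @param name one of `"synth", "mask", "train", "predict", "heatmap",
#'   "evaluate"`.
#' @param cfg a `wsiRunConfig` from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return the stage's main artifact (manifest, fit, scored cohort, report,
#'   ...), invisibly.
#' @export
runSubcommand <- function(name = c("synth", "mask", "train", "predict",
                                   "heatmap", "evaluate"), cfg) {
  name <- match.arg(name)
  cfg <- validateRunConfig(cfg)
  outDir <- cfg$paths$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tileSize <- as.integer(cfg$tiles$tile_size)
  stride <- as.integer(strideFrom(cfg))
  mtf <- cfg$tiles$min_tissue_frac
  manifestPath <- if (!is.null(cfg$paths$manifest)) cfg$paths$manifest
                  else file.path(outDir, "slides", "manifest.csv")

  result <- switch(name,
    synth = {
      s <- cfg$synth
      params <- synthParams(s$image_size, s$n_cores, s$core_shape,
                            s$lesion_fraction, s$texture_contrast,
                            s$background_level, seed = cfg$seed)
      generateCohort(s$n_pos, s$n_neg, params,
                     splitFractions = s$split_fractions,
                     dir = file.path(outDir, "slides"),
                     magnification = cfg$tiles$magnification)
    },
    mask = {
      manifest <- readManifest(manifestPath)
      maskDir <- file.path(outDir, "masks")
      tilesDir <- file.path(outDir, "tiles")
      dir.create(maskDir, showWarnings = FALSE, recursive = TRUE)
      dir.create(tilesDir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(manifest))) {
        img <- readSlideImage(manifest$image_path[i])
        tm <- buildTissueMask(img)
        writeMaskImage(maskMatrix(tm),
                       file.path(maskDir, paste0(manifest$slide_id[i],
                                                 "_mask.png")))
        writeTilesTSV(tileGrid(tm, tileSize, stride, mtf,
                               slideId = manifest$slide_id[i]),
                      file.path(tilesDir, paste0(manifest$slide_id[i],
                                                 "_tiles.tsv")))
      }
      manifest
    },
    train = {
      manifest <- readManifest(manifestPath)
      fit(manifest, trainConfigFrom(cfg), miningConfigFrom(cfg),
          tileSize = tileSize, stride = stride, minTissueFrac = mtf,
          outDir = file.path(outDir, "model"))
    },
    predict = {
      manifest <- readManifest(manifestPath)
      testM <- manifest[manifest$split == "test", , drop = FALSE]
      model <- readRDS(file.path(outDir, "model", "checkpoint.rds"))
      scored <- scoreCohort(model, testM, tileSize, stride, mtf,
                            batchSize = cfg$mining$batch_size,
                            mapsDir = file.path(outDir, "predictions"))
      utils::write.csv(scored, file.path(outDir, "scores.csv"),
                       row.names = FALSE, quote = FALSE)
      scored
    },
    heatmap = {
      manifest <- readManifest(manifestPath)
      testM <- manifest[manifest$split == "test", , drop = FALSE]
      model <- readRDS(file.path(outDir, "model", "checkpoint.rds"))
      hmDir <- file.path(outDir, "heatmaps")
      dir.create(hmDir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(testM))) {
        img <- readSlideImage(testM$image_path[i])
        tm <- buildTissueMask(img)
        grid <- tileGrid(tm, tileSize, stride, mtf,
                         slideId = testM$slide_id[i])
        map <- predictTiles(model, img, grid, cfg$mining$batch_size, stride)
        renderHeatmap(map, img, alpha = 0.5,
                      path = file.path(hmDir, paste0(testM$slide_id[i],
                                                     "_heatmap.png")))
      }
      hmDir
    },
    evaluate = {
      scored <- utils::read.csv(file.path(outDir, "scores.csv"),
                                stringsAsFactors = FALSE)
      report <- metricReport(scored, threshold = cfg$evaluate$threshold,
                             nBootstrap = cfg$evaluate$n_bootstrap,
                             seed = cfg$seed)
      writeMetricReport(report, scored, file.path(outDir, "evaluation"))
      report
    })

  writeRunManifest(cfg, name, outDir, artifacts = list(output_dir = outDir))
  invisible(result)
}
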