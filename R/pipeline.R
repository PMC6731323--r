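#' Demo pseudo-slide specification
#'
#' A standard synthetic scene used by the end-to-end pipeline, examples
#' and validation: a large stroma field holding two tumour nests with
#' different Ki67 fractions, a benign epithelium region and (optionally)
#' a lymphocytic infiltrate field.  Region outlines are star-shaped
#' polygons with seed-jittered centres, radii and phases, so different
#' seeds give different geometry.
#'
#' @param width,height canvas size in pixels.
#' @param seed integer; controls both geometry jitter and rendering.
#' @param tumour_ki67 Ki67-positive fraction of the first (larger)
#'   tumour nest; the second nest uses 0.15.
#' @param with_infiltrate include the infiltrate field.
#' @return A [slide_spec()].
#' @export
demo_slide_spec <- function(width = 1024L, height = 1024L, seed = 1L,
                            tumour_ki67 = 0.25, with_infiltrate = TRUE) {
  s <- min(width, height)
  blob <- function(cx, cy, R, wobble, phase, nv = 14) {
    th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    r <- R * (1 + wobble * sin(3 * th + phase))
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  g <- with_seed(seed, list(j = runif(8, -0.03, 0.03), ph = runif(4, 0, 2 * pi)))
  regions <- c(
    list(slide_region(blob(width * 0.5, height * 0.5, s * 0.46, 0.04,
                           g$ph[1], 18), "stroma")),
    list(slide_region(blob(width * (0.33 + g$j[1]), height * (0.35 + g$j[2]),
                           s * 0.20, 0.12, g$ph[2]),
                      "tumour", ki67_fraction = tumour_ki67)),
    list(slide_region(blob(width * (0.72 + g$j[3]), height * (0.42 + g$j[4]),
                           s * 0.14, 0.12, g$ph[3]),
                      "tumour", ki67_fraction = 0.15)),
    list(slide_region(blob(width * (0.32 + g$j[5]), height * (0.75 + g$j[6]),
                           s * 0.13, 0.10, g$ph[4]), "benign")),
    if (with_infiltrate)
      list(slide_region(blob(width * (0.72 + g$j[7]), height * (0.78 + g$j[8]),
                             s * 0.11, 0.10, g$ph[1]), "infiltrate")))
  slide_spec(width, height, regions = regions, rng_seed = seed)
}

#' Pipeline run configuration
#'
#' Single configuration object for the whole workflow, with every
#' stage's defaults in one place.  Unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param ... named overrides; nested lists merge into the defaults,
#'   e.g. `run_config(train = list(epochs = 5))`.
#' @return A `run_config` object.
#' @export
run_config <- function(...) {
  defaults <- list(
    schema_version = 1L,
    stages = c("synth", "extract", "train", "infer", "hotspot", "validate"),
    seeds = list(synth = 1L, eval_synth = 2L, train = 11L,
                 infiltrate = 12L),
    synth = list(width = 1024L, height = 1024L, tumour_ki67 = 0.25,
                 downsample = 8L, hotspot_fraction = 0.5,
                 hotspot_radius = 150L),
    extract = list(patch_size = 64L, stride = 32L, purity = 0.9,
                   mi_threshold = 235, max_per_class = 1000L,
                   augmentations = character()),
    train = list(learning_rate = 0.001, momentum = 0.9, epochs = 15L,
                 batch_size = 25L, infiltrate_epochs = 8L),
    infer = list(stride = 32L, infiltrate_threshold = 0.5,
                 binarise_threshold = 0.55,
                 colour_breaks = c(0.55, 0.65, 0.75)),
    hotspot = list(od_threshold = 0.15, min_area_px = 20L,
                   morph_radius = 1L, ra = 200, diameter_px = 100,
                   ratio_threshold = 0.20),
    validate = list(downsample = 8L, tissue_only = TRUE),
    paths = list(out_dir = "ihcseg-run", model = NULL,
                 infiltrate_model = NULL))
  structure(merge_config(defaults, list(...), "config"), class = "run_config")
}

merge_config <- function(base, override, where) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(!nzchar(nm)))
    stopf("all overrides under '%s' must be named", where)
  bad <- setdiff(nm, names(base))
  if (length(bad))
    stopf("unknown configuration key(s) under '%s': %s", where,
          paste(bad, collapse = ", "))
  for (k in nm) {
    ov <- override[[k]]
    if (is.null(ov)) {                 # keep explicit NULLs (YAML '~')
      base[k] <- list(NULL)
      next
    }
    if (is.list(base[[k]]) && is.list(ov)) {
      base[[k]] <- merge_config(base[[k]], ov, paste(where, k, sep = "$"))
    } else {
      # YAML hands atomic vectors back as lists; restore the base type
      if (is.list(ov) && !is.list(base[[k]]))
        ov <- if (length(ov)) unlist(ov) else vector(mode(base[[k]]), 0)
      base[[k]] <- ov
    }
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full workflow
#'
#' Executes the configured stages in order: `synth` (generate training
#' and evaluation pseudo-slides with ground truth), `extract` (tissue
#' detection and labelled patch extraction), `train` (tumour classifier
#' and, when infiltrate is present, the infiltrate classifier sharing
#' the same architecture), `infer` (overlapping-tile probability map,
#' infiltrate exclusion, binarisation, pseudo-colour rendering),
#' `hotspot` (DAB extraction, centroids, subtractive clustering, circle
#' scoring) and `validate` (confusion metrics against ground truth).
#' Every artefact is written under `config$paths$out_dir` and recorded
#' in `manifest.json` together with the configuration hash and seeds.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(schema_version = config$schema_version,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seeds = config$seeds, stages = list())
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- res
    invisible(NULL)
  }

  stage("synth", function() {
    spec <- demo_slide_spec(config$synth$width, config$synth$height,
                            seed = config$seeds$synth,
                            tumour_ki67 = config$synth$tumour_ki67)
    gen <- generate_pseudo_slide(spec)
    espec <- demo_slide_spec(config$synth$width, config$synth$height,
                             seed = config$seeds$eval_synth,
                             tumour_ki67 = config$synth$tumour_ki67)
    egen <- generate_pseudo_slide(espec)
    state$train_gen <- gen; state$eval_gen <- egen
    files <- list(train_slide = file.path(out_dir, "train_slide.png"),
                  eval_slide = file.path(out_dir, "eval_slide.png"),
                  eval_annotation = file.path(out_dir, "eval_annotation.xml"),
                  eval_label_mask = file.path(out_dir, "eval_label_mask.png"))
    write_slide(gen$slide, files$train_slide)
    write_slide(egen$slide, files$eval_slide)
    write_imagescope_xml(egen$ground_truth$annotation_set,
                         files$eval_annotation)
    write_mask_png(egen$ground_truth$label_mask, files$eval_label_mask)
    files
  })

  stage("extract", function() {
    if (is.null(state$train_gen))
      stopf("no synthesised slide; run the 'synth' stage or supply patches")
    gen <- state$train_gen
    grid <- tile_grid(config$extract$patch_size, config$extract$patch_size,
                      config$extract$stride)
    rule <- tissue_rule(config$extract$mi_threshold)
    ps <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                   grid, config$extract$purity, rule)
    ps <- subsample_balanced(ps, config$extract$max_per_class,
                             config$seeds$train)
    if (length(config$extract$augmentations))
      ps <- augment_patches(ps, config$extract$augmentations)
    state$patches <- ps
    ips <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                    grid, config$extract$purity, rule,
                                    target = "infiltrate")
    state$infiltrate_patches <- if (length(unique(ips$labels)) == 2)
      balance_with_augmentation(ips, config$extract$max_per_class,
                                config$seeds$infiltrate)
    else ips
    manifest_path <- file.path(out_dir, "patch_manifest.csv")
    write.csv(data.frame(slide_id = ps$slide_id, x = ps$x, y = ps$y,
                         label = ps$labels), manifest_path, row.names = FALSE)
    list(patch_manifest = manifest_path,
         class_balance = as.list(class_balance(ps)))
  })

  stage("train", function() {
    if (is.null(state$patches)) stopf("no patches; run the 'extract' stage")
    model <- build_cnn(network_spec(), seed = config$seeds$train)
    cfg <- train_config(config$train$learning_rate, config$train$momentum,
                        config$train$epochs, config$train$batch_size,
                        seed = config$seeds$train)
    model <- train_cnn(model, state$patches, cfg)
    state$model <- model
    files <- list(model = file.path(out_dir, "tumour_model.rds"),
                  train_log = file.path(out_dir, "training_log.csv"))
    save_cnn(model, files$model)
    write.csv(model$train_log, files$train_log, row.names = FALSE)
    ip <- state$infiltrate_patches
    if (!is.null(ip) && length(unique(ip$labels)) == 2) {
      icfg <- train_config(config$train$learning_rate, config$train$momentum,
                           config$train$infiltrate_epochs,
                           config$train$batch_size,
                           seed = config$seeds$infiltrate)
      imodel <- train_cnn(build_cnn(network_spec(),
                                    seed = config$seeds$infiltrate), ip, icfg)
      state$infiltrate_model <- imodel
      files$infiltrate_model <- file.path(out_dir, "infiltrate_model.rds")
      save_cnn(imodel, files$infiltrate_model)
    }
    files
  })

  stage("infer", function() {
    model <- state$model
    if (is.null(model)) {
      if (is.null(config$paths$model))
        stopf("no trained model in this run and 'paths$model' is not set")
      model <- load_cnn(config$paths$model)
    }
    imodel <- state$infiltrate_model
    if (is.null(imodel) && !is.null(config$paths$infiltrate_model))
      imodel <- load_cnn(config$paths$infiltrate_model)
    if (is.null(state$eval_gen))
      stopf("no evaluation slide; run the 'synth' stage")
    slide <- state$eval_gen$slide
    rule <- tissue_rule(config$extract$mi_threshold)
    pmap <- infer_slide(slide, model, config$infer$stride, rule)
    if (!is.null(imodel)) {
      imap <- infer_slide(slide, imodel, config$infer$stride, rule)
      pmap <- exclude_infiltrate(pmap, imap, config$infer$infiltrate_threshold)
    }
    state$pmap <- pmap
    state$binary <- binarise_map(pmap, config$infer$binarise_threshold)
    files <- list(probability_map = file.path(out_dir, "probability_map.tiff"),
                  overlay = file.path(out_dir, "probability_overlay.png"),
                  binary_mask = file.path(out_dir, "tumour_mask.png"))
    write_probability_map(pmap, files$probability_map)
    png::writePNG(render_pseudocolour(pmap, colour_binning(
      config$infer$colour_breaks), slide), files$overlay)
    png::writePNG(state$binary * 1.0, files$binary_mask)
    files
  })

  stage("hotspot", function() {
    if (is.null(state$pmap)) stopf("no probability map; run the 'infer' stage")
    slide <- state$eval_gen$slide
    # tumour mask at full resolution from the binarised cell map
    full <- map_to_mask(state$pmap, state$binary, 1L)
    hp <- config$hotspot
    dab <- extract_dab(slide$img, full, hp$od_threshold, hp$min_area_px,
                       hp$morph_radius)
    cent <- dab_centroids(dab)
    centres <- subtractive_cluster(cent, ra = hp$ra)
    report <- score_circles(dab, centres, hp$diameter_px, hp$ratio_threshold)
    report <- band_proliferation(report,
                                 c(hp$ratio_threshold / 2, hp$ratio_threshold))
    path <- file.path(out_dir, "hotspots.json")
    write_hotspot_report(report, path)
    list(report = path, n_centres = nrow(report$circles),
         n_hotspots = sum(report$circles$is_hotspot))
  })

  stage("validate", function() {
    if (is.null(state$pmap)) stopf("no probability map; run the 'infer' stage")
    gt <- state$eval_gen$ground_truth
    d <- config$validate$downsample
    pred <- map_to_mask(state$pmap, state$binary, d)
    truth <- gt$label_mask == 2L
    tissue <- if (config$validate$tissue_only) gt$label_mask > 0L else NULL
    rep <- metric_report(confusion_counts(pred, truth, tissue))
    files <- list(metrics = file.path(out_dir, "metrics.csv"),
                  confusion_overlay = file.path(out_dir, "confusion.png"))
    write.csv(cbind(slide = rownames(rep$per_slide), rep$per_slide),
              files$metrics, row.names = FALSE)
    png::writePNG(render_confusion_overlay(pred, truth),
                  files$confusion_overlay)
    c(files, as.list(round(rep$summary["mean", ], 4)))
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# Balance a patch set whose minority class is scarce: classes below
# n_per_class are topped up with dihedral-transformed copies before the
# balanced subsample.  Used for the infiltrate classifier, whose
# positive class covers far less slide area than the negative one.
balance_with_augmentation <- function(patchset, n_per_class, seed = 1L) {
  stopifnot(inherits(patchset, "patch_set"))
  counts <- table(patchset$labels)
  for (lab in names(counts)[counts < n_per_class]) {
    idx <- which(patchset$labels == lab)
    sub <- patch_set(patchset$patches[, , , idx, drop = FALSE],
                     patchset$labels[idx], patchset$x[idx],
                     patchset$y[idx], patchset$slide_id[idx])
    aug <- augment_patches(sub, c("hflip", "vflip", "rot180"))
    extra_idx <- seq(length(idx) + 1L, dim(aug$patches)[4])
    extra <- patch_set(aug$patches[, , , extra_idx, drop = FALSE],
                       aug$labels[extra_idx], aug$x[extra_idx],
                       aug$y[extra_idx], aug$slide_id[extra_idx])
    patchset <- concat_patch_sets(patchset, extra)
  }
  subsample_balanced(patchset, n_per_class, seed)
}

# Balanced subsample of a patch set: at most n_per_class patches per
# class, chosen deterministically under the seed.
subsample_balanced <- function(patchset, n_per_class, seed = 1L) {
  stopifnot(inherits(patchset, "patch_set"))
  if (is.null(n_per_class) || !is.finite(n_per_class)) return(patchset)
  keep <- with_seed(seed, {
    unlist(lapply(unique(patchset$labels), function(l) {
      idx <- which(patchset$labels == l)
      if (length(idx) > n_per_class) sort(sample(idx, n_per_class)) else idx
    }))
  })
  patch_set(patchset$patches[, , , keep, drop = FALSE],
            patchset$labels[keep], patchset$x[keep], patchset$y[keep],
            patchset$slide_id[keep])
}
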