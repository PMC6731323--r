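# Shared fixtures, built lazily and cached for the whole test run.
# The expensive ones (2048 px slides, trained classifiers) are used by
# several test files; training runs once and is reused.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(builder), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# small slide for unit tests
fx_small_gen <- function() fixture("small_gen", {
  generate_pseudo_slide(demo_slide_spec(640, 640, seed = 5,
                                        tumour_ki67 = 0.3))
})

# training scene and balanced patches (500 per class)
fx_train_gen <- function() fixture("train_gen", {
  generate_pseudo_slide(demo_slide_spec(2048, 2048, seed = 101,
                                        tumour_ki67 = 0.25))
})

fx_train_patches <- function() fixture("train_patches", {
  gen <- fx_train_gen()
  ps <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                 tile_grid(stride_px = 32L))
  ihcseg:::subsample_balanced(ps, 500L, 7L)
})

# evaluation scene (different seed -> different geometry) and held-out
# patches the classifier never saw
fx_eval_gen <- function() fixture("eval_gen", {
  generate_pseudo_slide(demo_slide_spec(2048, 2048, seed = 202,
                                        tumour_ki67 = 0.25))
})

# held-out patches are balanced (250 per class) so that accuracy is
# interpretable against the 0.5 chance level; stride 32 yields enough
# pure tumour tiles to balance
fx_heldout_patches <- function() fixture("heldout_patches", {
  gen <- fx_eval_gen()
  ps <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                 tile_grid(stride_px = 32L))
  ihcseg:::subsample_balanced(ps, 250L, 8L)
})

# the tumour classifier, trained once at the pinned configuration
fx_tumour_model <- function() fixture("tumour_model", {
  model <- build_cnn(network_spec(), seed = 42L)
  train_cnn(model, fx_train_patches(), train_config(seed = 42L))
})

# infiltrate classifier: identical architecture, infiltrate labels;
# the scarce infiltrate class is topped up by dihedral augmentation
fx_infiltrate_model <- function() fixture("infiltrate_model", {
  gen <- fx_train_gen()
  ips <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                  tile_grid(stride_px = 32L),
                                  target = "infiltrate")
  ips <- ihcseg:::balance_with_augmentation(ips, 150L, 10L)
  train_cnn(build_cnn(network_spec(), seed = 44L), ips,
            train_config(epochs = 8L, seed = 44L))
})

heldout_accuracy <- function(model, patchset) {
  pr <- predict_patches(model, patchset)
  mean(colnames(pr$probabilities)[max.col(pr$probabilities)] ==
         patchset$labels)
}

# two-colour, linearly separable patch fixture: DAB-brown-ish vs
# haematoxylin-blue-ish uniform patches with mild noise
fx_separable_patches <- function(n_per_class = 60, seed = 1) {
  ihcseg:::with_seed(seed, {
    mk <- function(col, n) {
      vapply(seq_len(n), function(i) {
        base <- array(rep(col, each = 64 * 64), c(64, 64, 3))
        pmin(pmax(base + array(rnorm(64 * 64 * 3, 0, 0.03),
                               c(64, 64, 3)), 0), 1)
      }, array(0, c(64, 64, 3)))
    }
    brown <- mk(c(0.55, 0.33, 0.14), n_per_class)
    blue <- mk(c(0.26, 0.28, 0.58), n_per_class)
    patch_set(array(c(brown, blue), c(64, 64, 3, 2 * n_per_class)),
              rep(c("tumour", "non-tumour"), each = n_per_class))
  })
}

# tumour-region full-resolution mask of a ground truth
tumour_full_mask <- function(gt) {
  tum <- which(vapply(gt$spec$regions, function(r) r$class == "tumour", TRUE))
  matrix(gt$region_raster %in% tum,
         nrow(gt$region_raster), ncol(gt$region_raster))
}
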