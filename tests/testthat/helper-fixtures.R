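# Shared fixtures, built once per test session and cached. All fixtures are
# generated in code under fixed seeds; sizes are desk-scale so the whole
# suite stays within a developer's patience.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

fixture_phantom_params <- function(width = 512L) phantom_params(image_width = width)

# 6 phantom B-scans -> 96 patches with ground-truth masks.
fixture_train_data <- function() {
  cache_get("train_data", function() {
    data <- generate_dataset(fixture_phantom_params(), 6, seed = 11)
    patches <- list(); masks <- list()
    for (d in data) {
      patches <- c(patches, split_into_patches(d$image))
      masks <- c(masks, split_into_patches(d$mask))
    }
    list(patches = patches, masks = masks)
  })
}

# The shared segmentation network: 48 patches, mini-batch 8, 10 epochs.
fixture_unet <- function() {
  cache_get("unet", function() {
    td <- fixture_train_data()
    idx <- with_seed_test(1, sample(length(td$patches), 48))
    model <- build_unet(unet_config(), seed = 2)
    train_unet(model, td$patches[idx], td$masks[idx],
               train_config(batch_size = 8, epochs = 10, seed = 3))
  })
}

# Held-out phantoms never seen in fixture training.
fixture_heldout <- function() {
  cache_get("heldout", function()
    generate_dataset(fixture_phantom_params(), 2, seed = 99))
}

# A tiny architecture for fast structural/gradient tests.
tiny_unet_config <- function() {
  unet_config(input_height = 16, input_width = 8, n_classes = 3,
              n_stages = 2, base_features = 2)
}

# 1000 pooled e&d feature rows from phantom-normal patches.
fixture_normal_features <- function() {
  cache_get("normal_features", function() {
    data <- generate_dataset(fixture_phantom_params(width = 2048L), 16, seed = 21)
    patches <- list()
    for (d in data) patches <- c(patches, split_into_patches(d$image))
    model <- fixture_unet()
    mat <- octoneclass:::featurize_set(model, patches[seq_len(1000)],
                                       "e_and_d")$e_and_d$mat
    stopifnot(nrow(mat) == 1000)
    mat
  })
}

# One-class SVM trained on the fixture normal features at nu = 0.08.
fixture_ocsvm <- function() {
  cache_get("ocsvm", function()
    train_ocsvm(fixture_normal_features(), ocsvm_config(nu = 0.08, seed = 4)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
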