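# Shared fixtures, built in code and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# a small cancer slide with one large annotated tumor and an island
fixture_cancer_slide <- function() {
  fixture("cancer_slide", function() {
    set.seed(42)
    outer_ring <- star_polygon(1400, 1300, 560, n = 24L, wobble = 0.2)
    island <- cbind(X = 1400 + 180 * cos(seq(0, 2 * pi, length.out = 13)[-13]),
                    Y = 1300 + 180 * sin(seq(0, 2 * pi, length.out = 13)[-13]))
    spec <- synthetic_slide_spec(
      672L, 672L, seed = 42L, slide_id = "fix_cancer",
      cancer_polygons = list(outer_ring, island),
      polygon_groups = c("", "island"))
    generate_slide(spec)
  })
}

fixture_noncancer_slide <- function() {
  fixture("noncancer_slide", function() {
    generate_slide(synthetic_slide_spec(672L, 672L, seed = 17L,
                                        slide_id = "fix_noncancer"))
  })
}

# crafted mask geometry: tissue+cancer on four isolated 224x224 squares
fixture_four_square_masks <- function() {
  fixture("four_squares", function() {
    H <- 1120L; W <- 1120L
    tissue <- matrix(FALSE, H, W)
    origins <- list(c(113L, 113L), c(113L, 785L), c(785L, 113L), c(785L, 785L))
    for (o in origins) {
      tissue[o[1]:(o[1] + 223L), o[2]:(o[2] + 223L)] <- TRUE
    }
    list(masks = derive_masks(tissue, tissue, 2L), origins = origins,
         H = H, W = W)
  })
}

# tiny mit model pair for training-contract tests
tiny_cfg <- function(mode, input = 32L, dropout = 0) {
  model_config(mode, "mit", "test_tiny", input_size = input, dropout = dropout)
}

random_image <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(n * n * 3, 0, 255), c(n, n, 3))
}

# micro training set: colored half-plane targets at a given tile size
micro_samples <- function(n_samples, tile = 32L, seed = 1L, with_context = TRUE) {
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    img <- array(stats::runif(tile * tile * 3, 0, 255), c(tile, tile, 3))
    mask <- matrix(0, tile, tile)
    mask[, seq_len(tile %/% 2L)] <- 1
    img[, seq_len(tile %/% 2L), 1] <- pmin(255, img[, seq_len(tile %/% 2L), 1] + 60)
    list(detail = img,
         context = if (with_context) img else NULL,
         mask = mask)
  })
}

params_checksum <- function(model, groups = NULL) {
  nms <- names(model$params)
  if (!is.null(groups)) nms <- nms[model$groups[nms] %in% groups]
  sum(vapply(nms, function(nm) sum(model$params[[nm]]), 1))
}

param_snapshot <- function(model, groups) {
  nms <- names(model$params)[model$groups[names(model$params)] %in% groups]
  model$params[nms]
}
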