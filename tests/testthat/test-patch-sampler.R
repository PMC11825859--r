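# Patch extraction: composition assessment, pass criteria, overlap
# rule, boundary/seed sampling, quota reallocation, fallback floor,
# pair extraction arithmetic and slide-level splitting.

test_that("assess counts window fractions exactly", {
  tissue <- matrix(FALSE, 500, 500); tissue[1:500, 1:500] <- TRUE
  cancer <- matrix(FALSE, 500, 500); cancer[, 1:250] <- TRUE
  ms <- derive_masks(tissue, cancer)
  expect_equal(assess(c(250L, 250L), ms),
               c(tissue_frac = 1, cancer_frac = 0.5, noncancer_frac = 0.5))
  full <- assess(c(130L, 250L), ms)
  expect_equal(full[["cancer_frac"]], 1)
  ms0 <- derive_masks(matrix(FALSE, 500, 500), matrix(FALSE, 500, 500))
  expect_equal(unname(assess(c(250L, 250L), ms0)), c(0, 0, 0))
  expect_null(assess(c(50L, 250L), ms))   # window out of bounds
})

test_that("pass criteria encode the published thresholds", {
  f <- function(t, c, n = 1 - c) c(tissue_frac = t, cancer_frac = c,
                                   noncancer_frac = n)
  expect_true(meets_criteria("cancer", 1, f(0.9, 0.80)))
  expect_false(meets_criteria("cancer", 1, f(0.9, 0.60)))
  expect_true(meets_criteria("cancer", 2, f(0.9, 0.60)))
  expect_false(meets_criteria("cancer", 2, f(0.9, 0.40)))
  expect_true(meets_criteria("cancer_boundary", 1, f(0.8, 0.5)))
  expect_false(meets_criteria("cancer_boundary", 1, f(0.8, 0.8)))
  expect_true(meets_criteria("cancer_boundary", 2, f(0.55, 0.30)))
  expect_true(meets_criteria("cancer_boundary", 3, f(0.30, 0.12)))
  expect_false(meets_criteria("cancer_boundary", 3, f(0.30, 0.95)))
  expect_true(meets_criteria("noncancer_from_cancer_slide", 1, f(0.8, 0, 0.8)))
  expect_false(meets_criteria("noncancer_from_cancer_slide", 1, f(0.8, 0.01, 0.79)))
  expect_error(meets_criteria("nope", 1, f(1, 1)), "unknown")
})

test_that("overlap fraction is intersection over one patch area", {
  expect_equal(overlap_fraction(c(500, 500), c(500, 500)), 1)
  expect_equal(overlap_fraction(c(500, 500), c(612, 500)), 0.5)
  expect_equal(overlap_fraction(c(500, 500), c(724, 500)), 0)
  expect_equal(overlap_fraction(c(500, 500), c(612, 612)), 0.25)
})

test_that("boundary centers stay within the 112-px band of the edges", {
  sq <- annotation_set(list(cbind(X = c(800, 2000, 2000, 800),
                                  Y = c(800, 800, 2000, 2000))))
  # distance from a point to the square's edge path (level-2 coords)
  edge_dist <- function(cx, cy) {
    lo <- 200; hi <- 500
    if (cx >= lo && cx <= hi && cy >= lo && cy <= hi) {
      min(cx - lo, hi - cx, cy - lo, hi - cy)
    } else {
      dx <- max(lo - cx, 0, cx - hi); dy <- max(lo - cy, 0, cy - hi)
      max(dx, dy)  # Chebyshev distance outside
    }
  }
  set.seed(31)
  for (k in 1:1000) {
    cc <- boundary_center(sq, band = 112L)
    expect_lte(edge_dist(cc[1], cc[2]), 112 + 1)  # +1 for rounding
  }
  set.seed(5); a <- boundary_center(sq)
  set.seed(5); b <- boundary_center(sq)
  expect_identical(a, b)
  expect_error(boundary_center(NULL), "non-cancer slide")
})

test_that("small-tumor seeds are drawn from scaled annotation vertices", {
  sq <- annotation_set(list(cbind(X = c(0, 800, 800, 0), Y = c(0, 0, 800, 800))))
  set.seed(41)
  seeds <- small_tumor_seeds(sq, 10L)
  expect_equal(nrow(seeds), 10L)
  allowed <- unique(rbind(c(0, 0), c(200, 0), c(200, 200), c(0, 200)))
  for (i in 1:10) {
    expect_true(any(seeds[i, 1] == allowed[, 1] & seeds[i, 2] == allowed[, 2]))
  }
  set.seed(2); s1 <- small_tumor_seeds(sq)
  set.seed(2); s2 <- small_tumor_seeds(sq)
  expect_identical(s1, s2)
  expect_error(small_tumor_seeds(NULL), "no annotations")
})

test_that("deficits move to the closest category only", {
  q <- c(cancer = 25L, cancer_boundary = 50L, noncancer_island_boundary = 25L,
         noncancer_from_cancer_slide = 50L)
  got <- c(cancer = 25L, cancer_boundary = 40L, noncancer_island_boundary = 25L,
           noncancer_from_cancer_slide = 10L)
  adj <- deficit_reallocation(got, q)
  expect_equal(adj[["noncancer_island_boundary"]], 35L)
  expect_equal(adj[["cancer_boundary"]], 50L)
  expect_equal(adj[["noncancer_from_cancer_slide"]], 50L)  # never reallocated
  expect_equal(deficit_reallocation(q, q), q)
  got2 <- q; got2[["cancer"]] <- 20L
  expect_equal(deficit_reallocation(got2, q)[["cancer_boundary"]], 55L)
})

test_that("a slide admitting exactly four qualifying windows yields four records", {
  fx <- fixture_four_square_masks()
  set.seed(51)
  recs <- sample_category(fx$masks, NULL, "cancer", quota = 25L,
                          slide_id = "squares")
  expect_equal(nrow(recs), 4L)
  # one record per square; a >= 75%-cancer window can sit at most 56 px
  # off the square center on an axis
  owners <- integer(4)
  for (i in 1:4) {
    o <- fx$origins[[i]]
    hit <- abs(recs$cy - (o[1] + 111L)) <= 56L & abs(recs$cx - (o[2] + 111L)) <= 56L
    owners[i] <- sum(hit)
  }
  expect_equal(owners, rep(1L, 4))
  # recorded fractions re-derivable from the masks
  for (i in 1:4) {
    fr <- assess(c(recs$cx[i], recs$cy[i]), fx$masks)
    expect_equal(unname(fr), c(recs$tissue_frac[i], recs$cancer_frac[i],
                               recs$noncancer_frac[i]), tolerance = 1e-12)
    expect_true(meets_criteria("cancer", recs$pass_index[i], fr))
  }
})

test_that("cancer sampling on a slide without cancer is empty", {
  sl <- fixture_noncancer_slide()
  recs <- sample_category(sl$masks2, sl$annotations, "cancer", 25L,
                          slide_id = "fix_noncancer")
  expect_equal(nrow(recs), 0L)
})

test_that("fallback tops the slide up to the 80-patch floor without constraints", {
  sl <- fixture_cancer_slide()
  expect_equal(nrow(cancer_fallback(sl$masks2, sl$annotations, 80L)), 0L)
  set.seed(61)
  fb <- cancer_fallback(sl$masks2, sl$annotations, 15L,
                        slide_id = "fix_cancer")
  expect_equal(nrow(fb), 65L)
  expect_true(all(fb$fallback))
  # fallback records may overlap heavily
  ov <- outer(seq_len(nrow(fb)), seq_len(nrow(fb)), Vectorize(function(i, j) {
    if (i >= j) 0 else overlap_fraction(c(fb$cx[i], fb$cy[i]),
                                        c(fb$cx[j], fb$cy[j]))
  }))
  expect_gt(max(ov), 0.5)
})

test_that("extract_pair crops co-centered windows at both levels", {
  sl <- fixture_cancer_slide()
  fr <- assess(c(500L, 500L), sl$masks2)
  rec <- cgsnet:::new_record("fix_cancer", "cancer", 500L, 500L, 1L, fr)
  pr <- extract_pair(sl, rec)
  expect_equal(dim(pr$detail_image), c(224L, 224L, 3L))
  expect_equal(dim(pr$context_image), c(224L, 224L, 3L))
  # detail pixel (1,1) is slide pixel (cy-112+1, cx-112+1)
  expect_equal(pr$detail_image[1, 1, ], sl$pyramid$level2_image[389, 389, ])
  # context window centered at floor(center/2) at level 3
  expect_equal(pr$context_image[112, 112, ],
               sl$pyramid$level3_image[250, 250, ])
  expect_equal(pr$detail_mask, sl$masks2$cancer[389:612, 389:612])
  bad <- rec; bad$slide_id <- "other"
  expect_error(extract_pair(sl, bad), "belongs to slide")
  # a fully cancerous window has an all-ones detail mask
  big <- generate_slide(synthetic_slide_spec(
    672L, 672L, seed = 4L, slide_id = "bigsq",
    cancer_polygons = list(cbind(X = c(400, 2000, 2000, 400),
                                 Y = c(400, 400, 2000, 2000)))))
  rec2 <- cgsnet:::new_record("bigsq", "cancer", 300L, 300L, 1L,
                              assess(c(300L, 300L), big$masks2))
  pr2 <- extract_pair(big, rec2)
  expect_true(all(pr2$detail_mask))
})

test_that("slide splits are stratified, leak-free and deterministic", {
  strata <- setNames(rep(c("noncancer", "cancer", "cancer_unique"), each = 10),
                     sprintf("s%02d", 1:30))
  sp <- split_slides(strata, seed = 3L)
  tab <- table(sp$stratum, sp$split)
  expect_true(all(tab[, "train"] == 6 & tab[, "val"] == 2 & tab[, "test"] == 2))
  expect_equal(anyDuplicated(sp$slide_id), 0L)
  expect_identical(sp, split_slides(strata, seed = 3L))
  expect_error(split_slides(strata, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})
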