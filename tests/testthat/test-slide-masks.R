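# Annotation parsing, Otsu tissue masking with clean-up, rasterization
# scaling and the tissue/cancer/non-cancer mask algebra.

test_that("vertices listed out of Order are sorted on load", {
  xml <- paste0(
    '<ASAP_Annotations><Annotations><Annotation Name="A" Type="Polygon" ',
    'PartOfGroup="None"><Coordinates>',
    '<Coordinate Order="2" X="10" Y="20"/>',
    '<Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '</Coordinates></Annotation></Annotations></ASAP_Annotations>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ann <- load_annotations(path)
  expect_equal(unname(ann$polygons[[1]]),
               unname(cbind(c(0, 10, 10), c(0, 0, 20))))
})

test_that("a two-vertex annotation is rejected", {
  xml <- paste0(
    '<ASAP_Annotations><Annotations><Annotation Name="bad"><Coordinates>',
    '<Coordinate Order="0" X="0" Y="0"/><Coordinate Order="1" X="5" Y="5"/>',
    '</Coordinates></Annotation></Annotations></ASAP_Annotations>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_error(load_annotations(path), "fewer than 3")
})

test_that("constant-saturation images give an all-background mask with a warning", {
  white <- array(255, c(64, 64, 3))
  expect_warning(m <- compute_tissue_mask(white), "constant saturation")
  expect_false(any(m))
})

test_that("tissue mask recovers the generator's tissue fraction", {
  sl <- fixture_cancer_slide()
  m <- compute_tissue_mask(sl$pyramid$level2_image)
  gt <- mean(sl$masks2$tissue)
  expect_lt(abs(mean(m) - gt), 0.02)
})

test_that("closing bridges a 3-pixel gap at radius 4", {
  img <- array(0, c(64, 64, 3))
  # two saturated color bars separated by a 3-px white gap
  img[, , 1] <- 240; img[, , 2] <- 240; img[, , 3] <- 240
  bar <- function(cols) {
    img[20:44, cols, 1] <<- 180; img[20:44, cols, 2] <<- 80
    img[20:44, cols, 3] <<- 160
  }
  bar(10:30); bar(34:54)
  m <- compute_tissue_mask(img, tissue_mask_params(closing_radius = 4L,
                                                   min_hole_area = 0L,
                                                   min_object_area = 0L))
  expect_true(all(m[30, 31:33]))  # gap closed
  m0 <- compute_tissue_mask(img, tissue_mask_params(closing_radius = 0L,
                                                    min_hole_area = 0L,
                                                    min_object_area = 0L))
  expect_false(any(m0[30, 31:33]))
})

test_that("rasterization divides level-0 coordinates by the level factor", {
  sq <- annotation_set(list(cbind(X = c(0, 800, 800, 0), Y = c(0, 0, 800, 800))))
  m2 <- rasterize_cancer_mask(sq, 2L, c(672L, 672L))
  m3 <- rasterize_cancer_mask(sq, 3L, c(336L, 336L))
  expect_equal(sum(m2), 200L^2)
  expect_equal(sum(m3), 100L^2)
  expect_true(all(m2[1:200, 1:200]))
  empty <- rasterize_cancer_mask(NULL, 2L, c(100L, 100L))
  expect_false(any(empty))
})

test_that("rasterization area scales by ~4 between levels", {
  set.seed(21)
  for (k in 1:5) {
    ring <- star_polygon(1300, 1300, runif(1, 250, 700), n = 17L)
    ann <- annotation_set(list(ring))
    a2 <- sum(rasterize_cancer_mask(ann, 2L, c(672L, 672L)))
    a3 <- sum(rasterize_cancer_mask(ann, 3L, c(336L, 336L)))
    expect_gt(a2 / a3, 3.6)
    expect_lt(a2 / a3, 4.4)
  }
})

test_that("mask algebra: noncancer = tissue minus cancer, cancer not tissue-gated", {
  tissue <- matrix(FALSE, 50, 50); tissue[10:40, 10:40] <- TRUE
  tissue[20:25, 20:25] <- FALSE           # adipocyte-style hole
  cancer <- matrix(FALSE, 50, 50); cancer[15:30, 15:30] <- TRUE
  ms <- derive_masks(tissue, cancer)
  expect_false(any(ms$cancer & ms$noncancer))
  expect_identical(ms$noncancer, tissue & !cancer)
  # cancer retained inside the tissue hole
  expect_true(all(ms$cancer[20:25, 20:25]))
  # partition: tissue = noncancer | (cancer & tissue)
  expect_identical(ms$tissue, ms$noncancer | (ms$cancer & ms$tissue))
  ms0 <- derive_masks(tissue, matrix(FALSE, 50, 50))
  expect_identical(ms0$noncancer, tissue)
  expect_error(derive_masks(tissue, matrix(FALSE, 10, 10)), "mismatch")
})
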