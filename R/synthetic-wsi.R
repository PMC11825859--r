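# Deterministic synthetic pyramidal slides: H&E-like tissue blobs on a
# bright glass background, polygon cancer annotations in level-0
# coordinates, two pyramid levels related by exact 2x box downsampling,
# and exact ground-truth masks at both levels. The generator exists so
# that every downstream stage (masking, patch extraction, training,
# evaluation) is testable without downloading a real slide archive.
#
# "Ambiguous-texture" regions are discs rendered with one and the same
# local color distribution whether or not they are cancer, so a
# detail-only classifier is at chance there by construction; cancerous
# ambiguous discs carry a dark ring at a configurable radius that is
# outside a detail patch's field of view but inside the context patch's
# -- the desk-scale analogue of "the context carries the signal".

default_tissue_colors <- function() {
  list(tissue     = list(mean = c(193, 122, 166), sd = c(8, 8, 8)),
       background = list(mean = c(243, 243, 243), sd = c(2.5, 2.5, 2.5)),
       cancer     = list(mean = c(118, 62, 138), sd = c(8, 8, 8)),
       ambiguous  = list(mean = c(152, 112, 152), sd = c(8, 8, 8)),
       ring       = list(mean = c(70, 95, 115), sd = c(3, 3, 3)))
}

#' Specification of one synthetic slide
#'
#' @param level2_width,level2_height level-2 dimensions in pixels; at
#'   least 672 so the slide holds several non-overlapping 224-px patches
#'   per axis.
#' @param tissue_blob_count number of tissue blobs.
#' @param tissue_color_model mean/sd RGB triplets for the pixel classes;
#'   see `default_tissue_colors()`.
#' @param cancer_polygons list of rings in level-0 coordinates
#'   (level-2 x 4); rings with group `"island"` cut non-cancer holes.
#' @param polygon_groups optional group labels per ring.
#' @param small_tumor flag: the tumor bounding box fits inside one
#'   224 x 224 level-2 patch ("cancer unique" stratum).
#' @param ambiguous_texture_fraction fraction of tissue rendered with a
#'   label-uninformative local appearance (auto-placed discs).
#' @param ambiguous_discs optional explicit disc list; each element is
#'   `list(cx, cy, r, cancer, ring_radius)` in level-2 pixels.
#' @param seed integer RNG seed; identical specs give byte-identical
#'   slides.
#' @param slide_id identifier.
#' @export
synthetic_slide_spec <- function(level2_width = 672L, level2_height = 672L,
                                 tissue_blob_count = 5L,
                                 tissue_color_model = default_tissue_colors(),
                                 cancer_polygons = list(),
                                 polygon_groups = NULL,
                                 small_tumor = FALSE,
                                 ambiguous_texture_fraction = 0,
                                 ambiguous_discs = NULL,
                                 seed = 1L, slide_id = "synthetic") {
  if (level2_width < 672L || level2_height < 672L) {
    stop("slide must be at least 672 pixels per axis at level 2")
  }
  if (ambiguous_texture_fraction < 0 || ambiguous_texture_fraction > 1) {
    stop("ambiguous_texture_fraction must lie in [0, 1]")
  }
  W0 <- 4 * level2_width; H0 <- 4 * level2_height
  for (i in seq_along(cancer_polygons)) {
    p <- cancer_polygons[[i]]
    if (any(p[, 1] < 0) || any(p[, 1] > W0) ||
        any(p[, 2] < 0) || any(p[, 2] > H0)) {
      stop("cancer polygon ", i, " lies outside the slide bounds")
    }
  }
  if (is.null(polygon_groups)) polygon_groups <- rep("", length(cancer_polygons))
  structure(list(level2_width = as.integer(level2_width),
                 level2_height = as.integer(level2_height),
                 tissue_blob_count = as.integer(tissue_blob_count),
                 tissue_color_model = tissue_color_model,
                 cancer_polygons = cancer_polygons,
                 polygon_groups = polygon_groups,
                 small_tumor = isTRUE(small_tumor),
                 ambiguous_texture_fraction = ambiguous_texture_fraction,
                 ambiguous_discs = ambiguous_discs,
                 seed = as.integer(seed), slide_id = slide_id),
            class = "synthetic_slide_spec")
}

#' Star-shaped polygon around a center (level-0 coordinates)
#'
#' @param cx,cy center; `r0` base radius; all in level-0 pixels.
#' @param n vertex count; `wobble` relative radius perturbation.
#' @keywords internal
#' @export
star_polygon <- function(cx, cy, r0, n = 20L, wobble = 0.25) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- r0 * (1 + stats::runif(n, -wobble, wobble))
  cbind(X = cx + r * cos(th), Y = cy + r * sin(th))
}

disc_polygon <- function(cx, cy, r, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(X = cx + r * cos(th), Y = cy + r * sin(th))
}

# exact 2x2 box downsample with fixed integer rounding (floor(x + 0.5));
# odd dimensions are padded by edge replication before averaging
box_downsample2 <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  H2 <- ceiling(H / 2); W2 <- ceiling(W / 2)
  ri <- pmin(seq_len(2L * H2), H); ci <- pmin(seq_len(2L * W2), W)
  out <- array(0, c(H2, W2, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    x <- img[ri, ci, ch]
    s <- x[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
         x[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
         x[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
         x[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]
    out[, , ch] <- floor(s / 4 + 0.5)
  }
  out
}

disc_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

ring_mask <- function(H, W, cx, cy, r, width = 3) {
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  abs(d - r) <= width
}

fill_color <- function(img, mask, color) {
  n <- sum(mask)
  if (n == 0L) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- pmin(pmax(color$mean[ch] + stats::rnorm(n, 0, color$sd[ch]), 0), 255)
    img[, , ch] <- plane
  }
  img
}

#' Generate one synthetic pyramidal slide
#'
#' Renders the slide at level 2, derives level 3 by exact 2x2 box
#' downsampling, and returns the annotations plus exact ground-truth
#' masks at both levels. Identical specs (including the seed) give
#' byte-identical output.
#'
#' @param spec a [synthetic_slide_spec].
#' @return a `synthetic_slide`: list with `pyramid` (level2/level3
#'   images, microns-per-pixel, slide id), `annotations`
#'   ([annotation_set]), `masks2`, `masks3` (ground-truth
#'   [derive_masks] sets) and the spec.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  set.seed(spec$seed)
  H <- spec$level2_height; W <- spec$level2_width
  col <- spec$tissue_color_model

  # tissue geometry (level-2 pixels)
  tissue <- matrix(FALSE, H, W)
  for (b in seq_len(spec$tissue_blob_count)) {
    cx <- stats::runif(1, 0.25 * W, 0.75 * W)
    cy <- stats::runif(1, 0.25 * H, 0.75 * H)
    r0 <- stats::runif(1, 0.20, 0.32) * min(H, W)
    ring <- star_polygon(cx * 4, cy * 4, r0 * 4, n = 24L) / 4
    tissue <- tissue | rasterize_rings_px(list(ring), H, W)
  }

  # ambiguous discs: explicit, or auto-placed to cover the requested
  # fraction of the tissue area
  discs <- spec$ambiguous_discs
  polys <- spec$cancer_polygons
  groups <- spec$polygon_groups
  if (is.null(discs) && spec$ambiguous_texture_fraction > 0) {
    discs <- list()
    target <- spec$ambiguous_texture_fraction * sum(tissue)
    r <- max(10, round(0.018 * min(H, W)))
    area <- pi * r^2
    n_discs <- max(1L, round(target / area))
    tis_idx <- which(tissue)
    for (k in seq_len(n_discs)) {
      pos <- tis_idx[sample.int(length(tis_idx), 1L)]
      cy <- (pos - 1L) %% H + 0.5
      cx <- (pos - 1L) %/% H + 0.5
      cx <- min(max(cx, r + 1), W - r - 1)
      cy <- min(max(cy, r + 1), H - r - 1)
      discs[[k]] <- list(cx = cx, cy = cy, r = r,
                         cancer = stats::runif(1) < 0.5,
                         ring_radius = 2.1 * r)
    }
  }
  if (!is.null(discs)) {
    for (d in discs) {
      if (isTRUE(d$cancer)) {
        polys <- c(polys, list(disc_polygon(d$cx * 4, d$cy * 4, d$r * 4)))
        groups <- c(groups, "ambiguous")
      }
    }
  }

  ann <- if (length(polys)) annotation_set(polys, spec$slide_id, groups) else NULL

  cancer2 <- rasterize_cancer_mask(ann, 2L, c(H, W))
  amb_mask <- matrix(FALSE, H, W)
  if (!is.null(discs)) {
    for (d in discs) amb_mask <- amb_mask | disc_mask(H, W, d$cx, d$cy, d$r)
  }
  tissue_gt <- tissue | cancer2 | amb_mask

  # render level-2 image
  img <- array(0, c(H, W, 3L))
  img <- fill_color(img, !tissue_gt, col$background)
  img <- fill_color(img, tissue_gt, col$tissue)
  img <- fill_color(img, cancer2 & !amb_mask, col$cancer)
  img <- fill_color(img, amb_mask, col$ambiguous)
  if (!is.null(discs)) {
    for (d in discs) {
      if (isTRUE(d$cancer) && !is.null(d$ring_radius)) {
        img <- fill_color(img, ring_mask(H, W, d$cx, d$cy, d$ring_radius),
                          col$ring)
      }
    }
  }

  img3 <- box_downsample2(img)
  H3 <- dim(img3)[1]; W3 <- dim(img3)[2]
  cancer3 <- rasterize_cancer_mask(ann, 3L, c(H3, W3))
  tissue3 <- downsample_mask2(tissue_gt, H3, W3)

  pyramid <- structure(list(level2_image = img, level3_image = img3,
                            level2_mpp = 3.89, level3_mpp = 7.78,
                            slide_id = spec$slide_id),
                       class = "slide_pyramid")
  structure(list(pyramid = pyramid, annotations = ann,
                 masks2 = derive_masks(tissue_gt, cancer2, 2L),
                 masks3 = derive_masks(tissue3, cancer3, 3L),
                 ambiguous_discs = discs, spec = spec),
            class = "synthetic_slide")
}

# majority 2x2 downsample for logical masks (>= 2 of 4)
downsample_mask2 <- function(mask, H2, W2) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(seq_len(2L * H2), H); ci <- pmin(seq_len(2L * W2), W)
  x <- mask[ri, ci] * 1L
  s <- x[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
       x[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
       x[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
       x[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]
  s >= 2L
}

#' Generate a cohort of synthetic slides with stratum labels
#'
#' Strata follow the slide-level sampling design: `noncancer` slides
#' (no annotations), `cancer` slides (large tumors, one with a
#' non-cancer island), and `cancer_unique` slides whose single small
#' tumor fits inside one 224-px level-2 patch.
#'
#' @param n_noncancer,n_cancer,n_cancer_unique slide counts (>= 0, not
#'   all zero).
#' @param seed integer; drives every slide's spec deterministically.
#' @param level2_size slide side length at level 2.
#' @param ambiguous_texture_fraction forwarded to each slide spec.
#' @return list with `slides` (list of `synthetic_slide`) and `strata`
#'   (named character vector keyed by slide id).
#' @export
generate_cohort <- function(n_noncancer, n_cancer, n_cancer_unique, seed = 1L,
                            level2_size = 672L,
                            ambiguous_texture_fraction = 0) {
  stopifnot(n_noncancer >= 0, n_cancer >= 0, n_cancer_unique >= 0)
  if (n_noncancer + n_cancer + n_cancer_unique == 0L) stop("empty cohort")
  set.seed(seed)
  specs <- list(); strata <- character(0)
  k <- 0L
  mk_id <- function() sprintf("slide_%03d", k)
  S0 <- 4 * level2_size
  for (i in seq_len(n_noncancer)) {
    k <- k + 1L
    specs[[k]] <- synthetic_slide_spec(
      level2_size, level2_size, seed = seed * 1000L + k, slide_id = mk_id(),
      ambiguous_texture_fraction = ambiguous_texture_fraction)
    strata[mk_id()] <- "noncancer"
  }
  for (i in seq_len(n_cancer)) {
    k <- k + 1L
    set.seed(seed * 1000L + k)
    c1 <- stats::runif(2, 0.3, 0.7) * S0
    outer_ring <- star_polygon(c1[1], c1[2], 0.16 * S0, n = 24L)
    island <- disc_polygon(c1[1], c1[2], 0.05 * S0)
    c2 <- stats::runif(2, 0.25, 0.75) * S0
    second <- star_polygon(c2[1], c2[2], 0.10 * S0, n = 20L)
    specs[[k]] <- synthetic_slide_spec(
      level2_size, level2_size, seed = seed * 1000L + k, slide_id = mk_id(),
      cancer_polygons = list(outer_ring, island, second),
      polygon_groups = c("", "island", ""),
      ambiguous_texture_fraction = ambiguous_texture_fraction)
    strata[mk_id()] <- "cancer"
  }
  for (i in seq_len(n_cancer_unique)) {
    k <- k + 1L
    set.seed(seed * 1000L + k)
    cc <- stats::runif(2, 0.35, 0.65) * S0
    small <- star_polygon(cc[1], cc[2], 0.055 * level2_size * 4, n = 16L,
                          wobble = 0.15)
    specs[[k]] <- synthetic_slide_spec(
      level2_size, level2_size, seed = seed * 1000L + k, slide_id = mk_id(),
      cancer_polygons = list(small), small_tumor = TRUE,
      ambiguous_texture_fraction = ambiguous_texture_fraction)
    strata[mk_id()] <- "cancer_unique"
  }
  list(slides = lapply(specs, generate_slide), strata = strata)
}

#' Write polygons as ASAP-dialect annotation XML
#'
#' Round-trips exactly through [load_annotations].
#'
#' @param polygons list of rings (level-0 coordinates) or an
#'   [annotation_set].
#' @param path output file path.
#' @param groups optional PartOfGroup labels per ring.
#' @export
write_annotation_xml <- function(polygons, path, groups = NULL) {
  if (inherits(polygons, "annotation_set")) {
    groups <- polygons$groups
    polygons <- polygons$polygons
  }
  if (length(polygons) == 0L) stop("no polygons to write")
  if (is.null(groups)) groups <- rep("", length(polygons))
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1L),
                             Type = "Polygon",
                             PartOfGroup = groups[i], Color = "#F4FA58")
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (v in seq_len(nrow(p))) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(v - 1L),
                          X = format(p[v, 1], digits = 17),
                          Y = format(p[v, 2], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
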