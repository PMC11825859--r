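# Slide-level masks: annotation loading (ASAP-dialect XML), HSV/Otsu
# tissue masking with morphological clean-up, polygon rasterization at a
# chosen pyramid level, and the tissue/cancer/non-cancer mask triple
# used for patch quality control.

#' Annotation set: polygon rings in level-0 pixel coordinates
#'
#' @param polygons list of n x 2 matrices (columns X, Y), each a closed
#'   ring with at least 3 vertices; coordinates are full-resolution
#'   (level-0) pixels.
#' @param slide_id slide identifier.
#' @param groups optional character vector (one per ring), e.g.
#'   `"island"` for pockets of normal tissue inside a cancer region.
#' @export
annotation_set <- function(polygons, slide_id = "slide", groups = NULL) {
  if (is.null(groups)) groups <- rep("", length(polygons))
  stopifnot(length(groups) == length(polygons))
  for (i in seq_along(polygons)) {
    p <- polygons[[i]] <- as.matrix(polygons[[i]])
    if (nrow(p) < 3L) stop("annotation ", i, " has fewer than 3 vertices")
    if (!all(is.finite(p)) || any(p < 0)) {
      stop("annotation ", i, " has non-finite or negative coordinates")
    }
  }
  structure(list(polygons = polygons, slide_id = slide_id, groups = groups),
            class = "annotation_set")
}

#' Load polygon annotations from ASAP-dialect XML
#'
#' Expects `<Annotations><Annotation><Coordinates><Coordinate X Y Order>`
#' (the Camelyon16 annotation format). Vertices are ordered by the
#' `Order` attribute.
#'
#' @param xml_path path to the XML file.
#' @return an [annotation_set].
#' @export
load_annotations <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  polygons <- list(); groups <- character(0)
  for (a in anns) {
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    if (length(coords) == 0L) stop("Annotation element without Coordinates")
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))
    y <- as.numeric(xml2::xml_attr(coords, "Y"))
    if (anyNA(ord) || anyNA(x) || anyNA(y)) {
      stop("Coordinate element with missing X/Y/Order attribute")
    }
    o <- order(ord)
    ring <- cbind(X = x[o], Y = y[o])
    if (nrow(ring) < 3L) {
      stop("Annotation '", xml2::xml_attr(a, "Name"),
           "' has fewer than 3 vertices")
    }
    polygons[[length(polygons) + 1L]] <- ring
    g <- xml2::xml_attr(a, "PartOfGroup")
    groups <- c(groups, if (is.na(g)) "" else g)
  }
  slide_id <- xml2::xml_attr(xml2::xml_root(doc), "SlideId")
  annotation_set(polygons, if (is.na(slide_id)) "slide" else slide_id, groups)
}

#' Tissue-mask clean-up parameters
#'
#' The morphological operations follow the standard slide QC recipe:
#' binary closing (to keep adipocyte regions attached), then removal of
#' small holes and small isolated objects. Sizes are level-2 pixels;
#' halve them at level 3.
#'
#' @param closing_radius disc radius for binary closing, pixels.
#' @param min_hole_area,min_object_area areas in pixels^2 below which
#'   holes are filled / objects removed.
#' @export
tissue_mask_params <- function(closing_radius = 4L, min_hole_area = 16L,
                               min_object_area = 16L) {
  stopifnot(closing_radius >= 0, min_hole_area >= 0, min_object_area >= 0)
  list(closing_radius = as.integer(closing_radius),
       min_hole_area = as.integer(min_hole_area),
       min_object_area = as.integer(min_object_area))
}

rgb_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(s, dim(img)[1], dim(img)[2])
}

#' Compute the tissue mask of an RGB slide image
#'
#' Converts to HSV saturation, thresholds with Otsu (256-bin histogram
#' over the whole level), then applies binary closing and removes small
#' holes and objects per `params`.
#'
#' @param rgb_image H x W x 3 array, values 0..255.
#' @param params a [tissue_mask_params] list.
#' @return logical H x W matrix (TRUE = tissue).
#' @export
compute_tissue_mask <- function(rgb_image, params = tissue_mask_params()) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L) {
    stop("rgb_image must be an H x W x 3 array")
  }
  s <- rgb_saturation(rgb_image)
  if (max(s) - min(s) < 1e-12) {
    warning("constant saturation; Otsu threshold undefined, returning all-background mask")
    return(matrix(FALSE, nrow(s), ncol(s)))
  }
  thr <- EBImage::otsu(s, range = c(0, 1), levels = 256L)
  mask <- s > thr
  if (params$closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  mask <- fill_small_holes(mask, params$min_hole_area)
  drop_small_objects(mask, params$min_object_area)
}

# fill background components not touching the border and smaller than min_area
fill_small_holes <- function(mask, min_area) {
  if (min_area <= 0L) return(mask)
  lab <- EBImage::bwlabel((!mask) * 1)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  fill_ids <- setdiff(which(sizes < min_area), border)
  if (length(fill_ids)) mask[lab %in% fill_ids] <- TRUE
  mask
}

drop_small_objects <- function(mask, min_area) {
  if (min_area <= 0L) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop_ids <- which(sizes < min_area)
  if (length(drop_ids)) mask[lab %in% drop_ids] <- FALSE
  mask
}

# Even-odd (parity) rasterization of polygon rings in pixel coordinates.
# A pixel is inside iff its center -- pixel (r, c) of the matrix has
# center (x = c - 0.5, y = r - 0.5) -- is inside under the even-odd rule
# over all rings jointly (so "island" rings cut holes).
rasterize_rings_px <- function(rings, H, W) {
  toggles_r <- integer(0); toggles_c <- integer(0)
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    for (e in seq_len(n)) {
      y1 <- y[e]; y2e <- y2[e]
      if (y1 == y2e) next
      ylo <- min(y1, y2e); yhi <- max(y1, y2e)
      # pixel rows whose center y in [ylo, yhi)
      r0 <- floor(ylo + 0.5) + 1L
      r1 <- ceiling(yhi + 0.5) - 1L
      r0 <- max(r0, 1L); r1 <- min(r1, H)
      if (r0 > r1) next
      rows <- r0:r1
      yc <- rows - 0.5
      keep <- yc >= ylo & yc < yhi
      rows <- rows[keep]; yc <- yc[keep]
      if (!length(rows)) next
      xint <- x[e] + (yc - y1) * (x2[e] - x[e]) / (y2e - y1)
      # toggle starts at first pixel column whose center x > xint
      k <- floor(xint + 0.5)                # pixels 1..k have center < xint
      k <- pmin(pmax(k, 0), W)
      sel <- k < W
      toggles_r <- c(toggles_r, rows[sel])
      toggles_c <- c(toggles_c, k[sel] + 1L)
    }
  }
  mask <- matrix(FALSE, H, W)
  if (!length(toggles_r)) return(mask)
  diffm <- matrix(0L, H, W)
  idx <- (toggles_c - 1L) * H + toggles_r
  tab <- tabulate(idx, nbins = H * W)
  diffm[] <- tab
  cs <- t(apply(diffm, 1L, cumsum))
  cs %% 2L == 1L
}

#' Rasterize cancer annotations to a binary mask at a pyramid level
#'
#' Level-0 coordinates are divided by the level's linear factor (4 at
#' level 2, 8 at level 3) and filled with the pixel-center even-odd
#' rule, so rings marked as islands cut holes.
#'
#' @param annotations an [annotation_set] (may be empty).
#' @param level 2 or 3.
#' @param dims integer (H, W) of the mask at that level.
#' @return logical H x W matrix.
#' @export
rasterize_cancer_mask <- function(annotations, level, dims) {
  stopifnot(level %in% c(2L, 3L), length(dims) == 2L)
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  if (is.null(annotations) || length(annotations$polygons) == 0L) {
    return(matrix(FALSE, H, W))
  }
  fac <- if (level == 2L) 4 else 8
  rings <- lapply(annotations$polygons, function(p) p / fac)
  rasterize_rings_px(rings, H, W)
}

#' Derive the tissue / cancer / non-cancer mask triple
#'
#' The non-cancer mask is tissue outside the annotations; the cancer
#' mask is annotation-driven and is *not* gated by the tissue mask, so
#' adipocyte holes inside an annotation stay cancer.
#'
#' @param tissue,cancer logical matrices of equal dimension.
#' @param level pyramid level the masks live at (2 or 3).
#' @return a `slide_mask_set`: list with `tissue`, `cancer`, `noncancer`,
#'   `level`, `dims`.
#' @export
derive_masks <- function(tissue, cancer, level = 2L) {
  if (!all(dim(tissue) == dim(cancer))) stop("mask dimension mismatch")
  structure(list(tissue = tissue, cancer = cancer,
                 noncancer = tissue & !cancer,
                 level = as.integer(level), dims = dim(tissue)),
            class = "slide_mask_set")
}
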