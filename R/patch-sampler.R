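# Five-category, multi-pass patch extraction with quotas, the <50%
# overlap constraint, deficit reallocation between neighboring
# categories, small-tumor seeding and the 80-cancer-patch fallback
# floor. Centers are 0-based level-2 pixel coordinates; a patch window
# is the half-open square [cx-112, cx+112) x [cy-112, cy+112) (for the
# default 224-px patch).

PATCH_CATEGORIES <- c("noncancer_from_noncancer_slide",
                      "noncancer_from_cancer_slide",
                      "cancer", "cancer_boundary",
                      "noncancer_island_boundary")

#' Per-slide extraction quotas and limits
#'
#' Defaults follow the published recipe: 50 non-cancer + 25 cancer + 50
#' cancer-boundary + 25 island-boundary patches per cancer slide, 25
#' non-cancer patches per non-cancer slide, at most 25,000 proposed
#' centers per category, boundary sampling within 112 px of an
#' annotation edge, and at least 80 cancer-bearing patches per cancer
#' slide (topped up by unconstrained fallback sampling).
#'
#' @param patch_size patch side length in level-2 pixels.
#' @export
quota_config <- function(noncancer_per_cancer_slide = 50L,
                         cancer_per_cancer_slide = 25L,
                         cancer_boundary = 50L,
                         island_boundary = 25L,
                         noncancer_per_noncancer_slide = 25L,
                         attempt_cap = 25000L,
                         boundary_band = 112L,
                         min_cancer_patches = 80L,
                         seed_pairs = 10L,
                         patch_size = 224L) {
  cfg <- list(noncancer_per_cancer_slide = noncancer_per_cancer_slide,
              cancer_per_cancer_slide = cancer_per_cancer_slide,
              cancer_boundary = cancer_boundary,
              island_boundary = island_boundary,
              noncancer_per_noncancer_slide = noncancer_per_noncancer_slide,
              attempt_cap = attempt_cap, boundary_band = boundary_band,
              min_cancer_patches = min_cancer_patches,
              seed_pairs = seed_pairs, patch_size = patch_size)
  stopifnot(all(unlist(cfg) > 0))
  lapply(cfg, as.integer)
}

#' Multi-pass acceptance schedule
#'
#' Cancer patches: pass 1 requires >75% tissue and >=75% cancer; pass 2
#' (after 10,000 attempts) relaxes cancer to >=45%. Both non-cancer
#' categories use a single pass: >75% tissue, >=75% non-cancer tissue
#' and zero cancer. Boundary categories: pass 1 cancer 40-75% with >75%
#' tissue; pass 2 (after 10,000 attempts) cancer 20-75% with >=50%
#' tissue; pass 3 (the final 3,000 attempts) cancer 10-90% with >=25%
#' tissue.
#'
#' @param attempt_cap total proposal budget per category.
#' @param pass2_at,pass3_at attempt indices at which the cancer /
#'   boundary criteria relax.
#' @return named list of per-category pass tables.
#' @export
pass_schedule <- function(attempt_cap = 25000L, pass2_at = 10001L,
                          pass3_at = 22001L) {
  pass_row <- function(pass, lo, hi, tis_min, tis_strict, clo, chi, nc_min = 0) {
    data.frame(pass = pass, attempt_lo = lo, attempt_hi = hi,
               tissue_min = tis_min, tissue_strict = tis_strict,
               cancer_lo = clo, cancer_hi = chi, noncancer_min = nc_min)
  }
  noncancer <- pass_row(1L, 1L, attempt_cap, 0.75, TRUE, 0, 0, nc_min = 0.75)
  boundary <- rbind(
    pass_row(1L, 1L, pass2_at - 1L, 0.75, TRUE, 0.40, 0.75),
    pass_row(2L, pass2_at, pass3_at - 1L, 0.50, FALSE, 0.20, 0.75),
    pass_row(3L, pass3_at, attempt_cap, 0.25, FALSE, 0.10, 0.90))
  list(noncancer_from_noncancer_slide = noncancer,
       noncancer_from_cancer_slide = noncancer,
       cancer = rbind(
         pass_row(1L, 1L, pass2_at - 1L, 0.75, TRUE, 0.75, 1),
         pass_row(2L, pass2_at, attempt_cap, 0.75, TRUE, 0.45, 1)),
       cancer_boundary = boundary,
       noncancer_island_boundary = boundary)
}

pass_for_attempt <- function(schedule_cat, attempt) {
  i <- which(attempt >= schedule_cat$attempt_lo & attempt <= schedule_cat$attempt_hi)
  if (!length(i)) nrow(schedule_cat) else i[1]
}

#' Tissue/cancer composition of a patch window
#'
#' @param center integer (cx, cy), 0-based level-2 coordinates.
#' @param masks a `slide_mask_set` at level 2.
#' @param patch_size window side length.
#' @return named vector `tissue_frac`, `cancer_frac`, `noncancer_frac`,
#'   or `NULL` if the window leaves the slide bounds (rejection, not an
#'   error).
#' @export
assess <- function(center, masks, patch_size = 224L) {
  half <- patch_size %/% 2L
  cx <- center[1]; cy <- center[2]
  H <- masks$dims[1]; W <- masks$dims[2]
  if (cx - half < 0L || cy - half < 0L || cx + half > W || cy + half > H) {
    return(NULL)
  }
  rows <- (cy - half + 1L):(cy + half)
  cols <- (cx - half + 1L):(cx + half)
  area <- patch_size^2
  c(tissue_frac = sum(masks$tissue[rows, cols]) / area,
    cancer_frac = sum(masks$cancer[rows, cols]) / area,
    noncancer_frac = sum(masks$noncancer[rows, cols]) / area)
}

# summed-area tables for fast window fractions during sampling
make_sat <- function(mask) {
  cs <- apply(mask * 1L, 2L, cumsum)
  rbind(0, cbind(0, t(apply(cs, 1L, cumsum))))[, , drop = FALSE]
}

sat_env <- function(masks) {
  e <- new.env(parent = emptyenv())
  e$tissue <- make_sat(masks$tissue)
  e$cancer <- make_sat(masks$cancer)
  e$noncancer <- make_sat(masks$noncancer)
  e
}

sat_frac <- function(S, r0, r1, c0, c1) {
  (S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]) /
    ((r1 - r0 + 1) * (c1 - c0 + 1))
}

assess_sat <- function(sats, cx, cy, half, H, W) {
  if (cx - half < 0L || cy - half < 0L || cx + half > W || cy + half > H) {
    return(NULL)
  }
  r0 <- cy - half + 1L; r1 <- cy + half
  c0 <- cx - half + 1L; c1 <- cx + half
  c(tissue_frac = sat_frac(sats$tissue, r0, r1, c0, c1),
    cancer_frac = sat_frac(sats$cancer, r0, r1, c0, c1),
    noncancer_frac = sat_frac(sats$noncancer, r0, r1, c0, c1))
}

#' Pure pass-criteria predicate
#'
#' @param category one of the five patch categories.
#' @param pass_index pass number within the category's schedule.
#' @param fracs named vector from [assess].
#' @param schedule from [pass_schedule].
#' @export
meets_criteria <- function(category, pass_index, fracs,
                           schedule = pass_schedule()) {
  tab <- schedule[[category]]
  if (is.null(tab)) stop("unknown patch category: ", category)
  if (pass_index < 1L || pass_index > nrow(tab)) {
    stop("invalid pass ", pass_index, " for category ", category)
  }
  row <- tab[pass_index, ]
  tis_ok <- if (row$tissue_strict) fracs[["tissue_frac"]] > row$tissue_min
            else fracs[["tissue_frac"]] >= row$tissue_min
  if (category %in% c("noncancer_from_noncancer_slide",
                      "noncancer_from_cancer_slide")) {
    return(tis_ok && fracs[["noncancer_frac"]] >= row$noncancer_min &&
           fracs[["cancer_frac"]] == 0)
  }
  cf <- fracs[["cancer_frac"]]
  tis_ok && cf >= row$cancer_lo && cf <= row$cancer_hi
}

#' Overlap fraction of two patch windows
#'
#' Intersection area of the two axis-aligned squares divided by the
#' single-patch area; two patches on the same slide must stay below 0.5.
#'
#' @param c1,c2 integer (cx, cy) centers.
#' @param patch_size window side length.
#' @export
overlap_fraction <- function(c1, c2, patch_size = 224L) {
  dx <- abs(c1[1] - c2[1]); dy <- abs(c1[2] - c2[2])
  max(0, patch_size - dx) * max(0, patch_size - dy) / patch_size^2
}

scaled_rings <- function(annotations, groups = NULL) {
  keep <- if (is.null(groups)) seq_along(annotations$polygons)
          else which(annotations$groups %in% groups)
  lapply(annotations$polygons[keep], function(p) p / 4)
}

#' Random candidate center near an annotation edge
#'
#' Picks a point uniformly (by arc length) on the polygon edges scaled
#' to level 2 and jitters it within a Chebyshev band of `band` pixels.
#' Uses the ambient R RNG.
#'
#' @param annotations an [annotation_set]; must be non-empty.
#' @param band jitter half-width, level-2 pixels.
#' @param groups restrict to rings with these group labels (e.g.
#'   `"island"` for island-boundary sampling); `NULL` uses all rings.
#' @return integer (cx, cy) 0-based level-2 center.
#' @export
boundary_center <- function(annotations, band = 112L, groups = NULL) {
  if (is.null(annotations) || length(annotations$polygons) == 0L) {
    stop("boundary sampling on non-cancer slide")
  }
  rings <- scaled_rings(annotations, groups)
  if (!length(rings)) stop("no annotation rings in the requested group")
  segs <- do.call(rbind, lapply(rings, function(r) {
    nxt <- rbind(r[-1, , drop = FALSE], r[1, , drop = FALSE])
    cbind(r, nxt)
  }))
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  e <- sample.int(nrow(segs), 1L, prob = pmax(len, 1e-9))
  t <- stats::runif(1)
  px <- segs[e, 1] + t * (segs[e, 3] - segs[e, 1])
  py <- segs[e, 2] + t * (segs[e, 4] - segs[e, 2])
  c(as.integer(round(px + stats::runif(1, -band, band))),
    as.integer(round(py + stats::runif(1, -band, band))))
}

#' Small-tumor seed centers from annotation vertices
#'
#' @param annotations non-empty [annotation_set].
#' @param n number of centers (sampling with replacement if the
#'   annotation has fewer vertices).
#' @return n x 2 integer matrix of 0-based level-2 centers.
#' @export
small_tumor_seeds <- function(annotations, n = 10L) {
  if (is.null(annotations) || length(annotations$polygons) == 0L) {
    stop("no annotations to seed from")
  }
  verts <- do.call(rbind, scaled_rings(annotations))
  idx <- sample.int(nrow(verts), n, replace = TRUE)
  matrix(as.integer(round(verts[idx, ])), ncol = 2L)
}

new_record <- function(slide_id, category, cx, cy, pass_index, fracs,
                       fallback = FALSE, glass_exempt = FALSE) {
  data.frame(slide_id = slide_id, category = category,
             cx = as.integer(cx), cy = as.integer(cy),
             pass_index = as.integer(pass_index),
             tissue_frac = fracs[["tissue_frac"]],
             cancer_frac = fracs[["cancer_frac"]],
             noncancer_frac = fracs[["noncancer_frac"]],
             fallback = fallback, glass_exempt = glass_exempt,
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  new_record("x", "cancer", 0L, 0L, 1L,
             c(tissue_frac = 0, cancer_frac = 0, noncancer_frac = 0))[0, ]
}

overlap_ok <- function(cx, cy, accepted, patch_size) {
  if (nrow(accepted) == 0L) return(TRUE)
  dx <- abs(accepted$cx - cx); dy <- abs(accepted$cy - cy)
  ov <- pmax(0, patch_size - dx) * pmax(0, patch_size - dy) / patch_size^2
  all(ov < 0.5)
}

# Annotation vertices whose `band`-neighborhood contains non-tissue
# pixels: candidates near these vertices qualify for the glass-boundary
# exemption from the tissue requirement.
glass_vertices <- function(annotations, sats, band, H, W) {
  if (is.null(annotations) || length(annotations$polygons) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  verts <- do.call(rbind, scaled_rings(annotations))
  vx <- as.integer(round(verts[, 1])); vy <- as.integer(round(verts[, 2]))
  r0 <- pmax(1L, vy - band); r1 <- pmin(H, vy + band)
  c0 <- pmax(1L, vx - band); c1 <- pmin(W, vx + band)
  keep <- r0 <= r1 & c0 <= c1
  fr <- rep(1, nrow(verts))
  S <- sats$tissue
  fr[keep] <- (S[cbind(r1[keep] + 1L, c1[keep] + 1L)] -
               S[cbind(r0[keep], c1[keep] + 1L)] -
               S[cbind(r1[keep] + 1L, c0[keep])] +
               S[cbind(r0[keep], c0[keep])]) /
    ((r1[keep] - r0[keep] + 1) * (c1[keep] - c0[keep] + 1))
  verts[fr < 1, , drop = FALSE]
}

#' Sample one category of patches on a slide
#'
#' Proposes up to `attempt_cap` centers (uniform over the slide for
#' non-cancer categories, uniform over cancer-mask pixels for cancer
#' patches, annotation-edge jitter for boundary categories), applies
#' the attempt-indexed pass criteria and the <50% overlap constraint
#' against all previously accepted patches on the slide, and stops at
#' the quota.
#'
#' @param masks `slide_mask_set` at level 2.
#' @param annotations [annotation_set] or NULL.
#' @param category one of `PATCH_CATEGORIES`.
#' @param quota maximum number of records.
#' @param schedule from [pass_schedule].
#' @param accepted data frame of previously accepted records (any
#'   category) on this slide.
#' @param qc [quota_config].
#' @param slide_id id recorded on the output.
#' @return data frame of accepted `patch records` (possibly short).
#' @export
sample_category <- function(masks, annotations, category, quota,
                            schedule = pass_schedule(),
                            accepted = empty_records(),
                            qc = quota_config(), slide_id = "slide") {
  stopifnot(category %in% PATCH_CATEGORIES)
  H <- masks$dims[1]; W <- masks$dims[2]
  half <- qc$patch_size %/% 2L
  sats <- sat_env(masks)
  tab <- schedule[[category]]
  out <- empty_records()
  if (quota <= 0L) return(out)
  is_boundary_like <- category %in% c("cancer", "cancer_boundary",
                                      "noncancer_island_boundary")

  cancer_idx <- NULL; segs <- NULL
  if (category == "cancer") {
    cancer_idx <- which(masks$cancer)
    if (!length(cancer_idx)) return(out)
  }
  if (category %in% c("cancer_boundary", "noncancer_island_boundary")) {
    grp <- if (category == "noncancer_island_boundary") "island" else NULL
    if (is.null(annotations) || length(annotations$polygons) == 0L) return(out)
    if (!is.null(grp) && !any(annotations$groups %in% grp)) return(out)
    rings <- scaled_rings(annotations, grp)
    segs <- do.call(rbind, lapply(rings, function(r) {
      nxt <- rbind(r[-1, , drop = FALSE], r[1, , drop = FALSE])
      cbind(r, nxt)
    }))
    seg_len <- pmax(sqrt((segs[, 3] - segs[, 1])^2 +
                         (segs[, 4] - segs[, 2])^2), 1e-9)
  }
  gverts <- if (is_boundary_like) {
    glass_vertices(annotations, sats, qc$boundary_band, H, W)
  } else matrix(numeric(0), ncol = 2L)

  acc_cx <- c(accepted$cx); acc_cy <- c(accepted$cy)
  attempts_used <- 0L
  chunk <- 2000L
  while (attempts_used < qc$attempt_cap && nrow(out) < quota) {
    n <- min(chunk, qc$attempt_cap - attempts_used)
    att <- attempts_used + seq_len(n)
    centers <- switch(category,
      cancer = {
        pos <- cancer_idx[sample.int(length(cancer_idx), n, replace = TRUE)]
        cbind((pos - 1L) %/% H, (pos - 1L) %% H)   # 0-based (cx, cy)
      },
      cancer_boundary = ,
      noncancer_island_boundary = {
        e <- sample.int(nrow(segs), n, replace = TRUE, prob = seg_len)
        t <- stats::runif(n)
        px <- segs[e, 1] + t * (segs[e, 3] - segs[e, 1])
        py <- segs[e, 2] + t * (segs[e, 4] - segs[e, 2])
        cbind(as.integer(round(px + stats::runif(n, -qc$boundary_band,
                                                 qc$boundary_band))),
              as.integer(round(py + stats::runif(n, -qc$boundary_band,
                                                 qc$boundary_band))))
      },
      cbind(sample.int(W - 2L * half + 1L, n, replace = TRUE) + half - 1L,
            sample.int(H - 2L * half + 1L, n, replace = TRUE) + half - 1L))
    cx <- centers[, 1]; cy <- centers[, 2]
    inb <- cx - half >= 0L & cy - half >= 0L & cx + half <= W & cy + half <= H
    r0 <- cy - half + 1L; r1 <- cy + half
    c0 <- cx - half + 1L; c1 <- cx + half
    area <- qc$patch_size^2
    winsum <- function(S) {
      v <- rep(NA_real_, n)
      k <- which(inb)
      v[k] <- (S[cbind(r1[k] + 1L, c1[k] + 1L)] - S[cbind(r0[k], c1[k] + 1L)] -
               S[cbind(r1[k] + 1L, c0[k])] + S[cbind(r0[k], c0[k])]) / area
      v
    }
    tf <- winsum(sats$tissue); cf <- winsum(sats$cancer)
    nf <- winsum(sats$noncancer)
    pidx <- vapply(att, function(a) pass_for_attempt(tab, a), 1L)
    ok <- rep(FALSE, n); exempt <- rep(FALSE, n)
    for (p in unique(pidx)) {
      row <- tab[p, ]
      sel <- pidx == p & inb
      tis_ok <- if (row$tissue_strict) tf > row$tissue_min else tf >= row$tissue_min
      ok_p <- if (startsWith(category, "noncancer_from")) {
        tis_ok & nf >= row$noncancer_min & cf == 0
      } else {
        tis_ok & cf >= row$cancer_lo & cf <= row$cancer_hi
      }
      ok[sel] <- ok_p[sel]
      # glass-boundary exemption in the final pass: the tissue criterion
      # alone failed and the annotation runs along a non-tissue region
      if (is_boundary_like && p == nrow(tab) && nrow(gverts)) {
        fail <- sel & !ok & cf >= row$cancer_lo & cf <= row$cancer_hi
        for (i in which(fail)) {
          if (any(abs(gverts[, 1] - cx[i]) <= half &
                  abs(gverts[, 2] - cy[i]) <= half)) {
            ok[i] <- TRUE; exempt[i] <- TRUE
          }
        }
      }
    }
    for (i in which(ok)) {
      if (nrow(out) >= quota) break
      if (length(acc_cx)) {
        ov <- pmax(0, qc$patch_size - abs(acc_cx - cx[i])) *
              pmax(0, qc$patch_size - abs(acc_cy - cy[i])) / area
        if (any(ov >= 0.5)) next
      }
      fr <- c(tissue_frac = tf[i], cancer_frac = cf[i], noncancer_frac = nf[i])
      out <- rbind(out, new_record(slide_id, category, cx[i], cy[i], pidx[i],
                                   fr, glass_exempt = exempt[i]))
      acc_cx <- c(acc_cx, cx[i]); acc_cy <- c(acc_cy, cy[i])
    }
    attempts_used <- attempts_used + n
  }
  out
}

#' Reallocate unmet quotas to the closest category
#'
#' Cancer-boundary deficit goes to island-boundary and vice versa;
#' cancer deficit goes to cancer-boundary; non-cancer categories are
#' never reallocated.
#'
#' @param counts named integer vector of achieved counts.
#' @param quotas named integer vector of original quotas.
#' @return adjusted quotas (named like `quotas`).
#' @export
deficit_reallocation <- function(counts, quotas) {
  stopifnot(all(names(counts) %in% names(quotas)))
  get0i <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0L
  adj <- quotas
  d_cb <- max(0L, get0i(quotas, "cancer_boundary") - get0i(counts, "cancer_boundary"))
  d_ib <- max(0L, get0i(quotas, "noncancer_island_boundary") -
                 get0i(counts, "noncancer_island_boundary"))
  d_ca <- max(0L, get0i(quotas, "cancer") - get0i(counts, "cancer"))
  if ("noncancer_island_boundary" %in% names(adj)) {
    adj[["noncancer_island_boundary"]] <- adj[["noncancer_island_boundary"]] + d_cb
  }
  if ("cancer_boundary" %in% names(adj)) {
    adj[["cancer_boundary"]] <- adj[["cancer_boundary"]] + d_ib + d_ca
  }
  adj
}

#' Unconstrained fallback sampling up to the cancer floor
#'
#' When a cancer slide yields fewer than `floor_n` cancer-bearing
#' patches, annotation vertices are sampled (with replacement) as
#' centers until the floor is met. Fallback records ignore tissue,
#' cancer and overlap requirements; window centers are clamped into the
#' slide bounds.
#'
#' @param masks level-2 `slide_mask_set` (used only to record fractions).
#' @param annotations non-empty [annotation_set].
#' @param existing_count cancer-bearing patches already accepted.
#' @param floor_n required total (default 80).
#' @export
cancer_fallback <- function(masks, annotations, existing_count,
                            floor_n = 80L, qc = quota_config(),
                            slide_id = "slide") {
  if (existing_count >= floor_n) return(empty_records())
  if (is.null(annotations) || length(annotations$polygons) == 0L) {
    stop("fallback sampling requires annotations")
  }
  H <- masks$dims[1]; W <- masks$dims[2]
  half <- qc$patch_size %/% 2L
  n <- floor_n - existing_count
  verts <- do.call(rbind, scaled_rings(annotations))
  idx <- sample.int(nrow(verts), n, replace = TRUE)
  out <- empty_records()
  for (i in idx) {
    cx <- min(max(as.integer(round(verts[i, 1])), half), W - half)
    cy <- min(max(as.integer(round(verts[i, 2])), half), H - half)
    fr <- assess(c(cx, cy), masks, qc$patch_size)
    out <- rbind(out, new_record(slide_id, "cancer", cx, cy, 0L, fr,
                                 fallback = TRUE))
  }
  out
}

#' Run the full extraction recipe on one slide
#'
#' Cancer slides: non-cancer, cancer, cancer-boundary and
#' island-boundary categories at their quotas; small-tumor seed centers
#' added for `cancer_unique` slides; deficits reallocated to the
#' closest category and the receiving categories resampled; finally the
#' 80-cancer-patch floor is topped up with fallback records. Non-cancer
#' slides: 25 non-cancer patches.
#'
#' @param slide a `synthetic_slide` (or list with `masks2` +
#'   `annotations` + `spec`).
#' @param qc [quota_config]; `schedule` from [pass_schedule].
#' @param stratum `"noncancer"`, `"cancer"` or `"cancer_unique"`.
#' @return data frame of patch records.
#' @export
extract_slide_patches <- function(slide, stratum, qc = quota_config(),
                                  schedule = pass_schedule(attempt_cap = qc$attempt_cap)) {
  masks <- slide$masks2
  ann <- slide$annotations
  sid <- slide$pyramid$slide_id
  if (stratum == "noncancer") {
    return(sample_category(masks, ann, "noncancer_from_noncancer_slide",
                           qc$noncancer_per_noncancer_slide, schedule,
                           qc = qc, slide_id = sid))
  }
  quotas <- c(noncancer_from_cancer_slide = qc$noncancer_per_cancer_slide,
              cancer = qc$cancer_per_cancer_slide,
              cancer_boundary = qc$cancer_boundary,
              noncancer_island_boundary = qc$island_boundary)
  acc <- empty_records()
  for (cat in names(quotas)) {
    acc <- rbind(acc, sample_category(masks, ann, cat, quotas[[cat]],
                                      schedule, acc, qc, sid))
  }
  # seed centers for small tumors (cancer-unique stratum)
  if (stratum == "cancer_unique") {
    seeds <- small_tumor_seeds(ann, qc$seed_pairs)
    half <- qc$patch_size %/% 2L
    for (i in seq_len(nrow(seeds))) {
      cx <- min(max(seeds[i, 1], half), masks$dims[2] - half)
      cy <- min(max(seeds[i, 2], half), masks$dims[1] - half)
      fr <- assess(c(cx, cy), masks, qc$patch_size)
      tab <- schedule$cancer_boundary
      pass_hit <- which(vapply(seq_len(nrow(tab)), function(p) {
        meets_criteria("cancer_boundary", p, fr, schedule)
      }, TRUE))
      if (length(pass_hit) && overlap_ok(cx, cy, acc, qc$patch_size)) {
        acc <- rbind(acc, new_record(sid, "cancer_boundary", cx, cy,
                                     pass_hit[1], fr))
      } else {
        acc <- rbind(acc, new_record(sid, "cancer_boundary", cx, cy, 0L, fr,
                                     fallback = TRUE))
      }
    }
  }
  counts <- table(factor(acc$category[!acc$fallback], levels = names(quotas)))
  adj <- deficit_reallocation(as.integer(counts) |>
                                stats::setNames(names(quotas)), quotas)
  for (cat in c("cancer_boundary", "noncancer_island_boundary")) {
    extra <- adj[[cat]] - quotas[[cat]]
    have <- sum(acc$category == cat & !acc$fallback)
    if (extra > 0L && have < adj[[cat]]) {
      acc <- rbind(acc, sample_category(masks, ann, cat, adj[[cat]] - have,
                                        schedule, acc, qc, sid))
    }
  }
  n_cancer_bearing <- sum(acc$cancer_frac > 0)
  if (n_cancer_bearing < qc$min_cancer_patches) {
    acc <- rbind(acc, cancer_fallback(masks, ann, n_cancer_bearing,
                                      qc$min_cancer_patches, qc, sid))
  }
  acc
}

#' Paired detail/context patch extraction
#'
#' The detail patch is the level-2 window at the record's center; the
#' context patch is the level-3 window at the floor-halved center
#' (same physical center, twice the field of view); both cancer masks
#' are cropped identically. Context windows are clamped to the slide
#' with edge replication.
#'
#' @param slide a `synthetic_slide` (or any list with `pyramid`,
#'   `masks2`, `masks3`).
#' @param record one patch record row.
#' @param patch_size window side length.
#' @return a `patch_pair`: detail/context images (patch^2 x 3 arrays)
#'   and binary masks, plus the record.
#' @export
extract_pair <- function(slide, record, patch_size = 224L) {
  if (!identical(record$slide_id, slide$pyramid$slide_id)) {
    stop("record belongs to slide ", record$slide_id, ", not ",
         slide$pyramid$slide_id)
  }
  half <- patch_size %/% 2L
  cx <- record$cx; cy <- record$cy
  img2 <- slide$pyramid$level2_image
  rows <- (cy - half + 1L):(cy + half)
  cols <- (cx - half + 1L):(cx + half)
  detail <- img2[rows, cols, , drop = FALSE]
  dmask <- slide$masks2$cancer[rows, cols]
  cx3 <- cx %/% 2L; cy3 <- cy %/% 2L
  img3 <- slide$pyramid$level3_image
  H3 <- dim(img3)[1]; W3 <- dim(img3)[2]
  r3 <- pmin(pmax((cy3 - half + 1L):(cy3 + half), 1L), H3)
  c3 <- pmin(pmax((cx3 - half + 1L):(cx3 + half), 1L), W3)
  context <- img3[r3, c3, , drop = FALSE]
  cmask <- slide$masks3$cancer[r3, c3]
  structure(list(detail_image = detail, context_image = context,
                 detail_mask = dmask, context_mask = cmask,
                 record = record),
            class = "patch_pair")
}

#' Stratified slide-level train/validation/test split
#'
#' Slides (never patches) are assigned to splits, stratified over the
#' three slide types, so no slide leaks across splits. Largest-remainder
#' rounding within each stratum.
#'
#' @param cohort output of [generate_cohort] (or a named `strata`
#'   vector).
#' @param ratios train/val/test proportions summing to 1.
#' @param seed RNG seed for the within-stratum shuffle.
#' @return data frame with `slide_id`, `stratum`, `split`.
#' @export
split_slides <- function(cohort, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  strata <- if (is.list(cohort)) cohort$strata else cohort
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (!length(strata)) stop("empty cohort")
  set.seed(seed)
  out <- NULL
  for (st in unique(strata)) {
    ids <- sample(names(strata)[strata == st])
    n <- length(ids)
    base <- floor(ratios * n)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_order <- order(ratios * n - base, decreasing = TRUE)
      base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1L
    }
    split <- rep(c("train", "val", "test"), times = base)
    out <- rbind(out, data.frame(slide_id = ids, stratum = st, split = split))
  }
  out[order(out$slide_id), ]
}

#' Build the patch manifest for a whole cohort
#'
#' Computes tissue masks from the rendered images (the real pipeline,
#' not the generator's ground truth), rasterizes annotations, extracts
#' patches per slide and attaches the slide-level split.
#'
#' @param cohort from [generate_cohort].
#' @param qc [quota_config]; `ratios`, `seed` as in [split_slides].
#' @return list with `manifest` (data frame) and `splits`.
#' @export
build_patch_dataset <- function(cohort, qc = quota_config(),
                                ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  splits <- split_slides(cohort, ratios, seed)
  set.seed(seed + 1L)
  manifest <- NULL
  for (slide in cohort$slides) {
    sid <- slide$pyramid$slide_id
    stratum <- cohort$strata[[sid]]
    # pipeline masks: Otsu tissue mask from the rendered image, cancer
    # mask rasterized from the annotations
    tissue <- compute_tissue_mask(slide$pyramid$level2_image)
    cancer <- rasterize_cancer_mask(slide$annotations, 2L, dim(tissue))
    slide$masks2 <- derive_masks(tissue, cancer, 2L)
    recs <- extract_slide_patches(slide, stratum, qc)
    if (nrow(recs)) {
      recs$split <- splits$split[match(sid, splits$slide_id)]
      manifest <- rbind(manifest, recs)
    }
  }
  list(manifest = manifest, splits = splits)
}
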