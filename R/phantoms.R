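# Seeded ultrasound-phantom generator with exact ground truth.
#
# Scene model: a speckle-textured echogenic background, one darker
# (hypoechoic) elliptical ovary, and 0+ near-black (anechoic) elliptical
# follicles fully contained in the ovary and pairwise separated. Speckle is
# the squared magnitude of low-pass-filtered complex Gaussian noise
# (fully-developed-speckle approximation) applied multiplicatively to a
# smooth echogenicity field. Geometry is exact: masks are analytic ellipse
# rasterizations and every follicle's true diameter (mean of its two axis
# diameters) is recorded in mm.

# binary rasterization of an ellipse at pixel centers (0-based row/col)
ellipse_mask <- function(size, cr, cc, sa, sb, theta) {
  r0 <- max(0L, floor(cr - sa - 2)); r1 <- min(size - 1L, ceiling(cr + sa + 2))
  c0 <- max(0L, floor(cc - sa - 2)); c1 <- min(size - 1L, ceiling(cc + sa + 2))
  m <- matrix(0L, size, size)
  if (r1 < r0 || c1 < c0) return(m)
  rs <- r0:r1; cs <- c0:c1
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  m[rs + 1L, cs + 1L] <- as.integer((u / sa)^2 + (v / sb)^2 <= 1)
  m
}

# are all boundary points of ellipse A inside ellipse B shrunk by margin?
ellipse_inside <- function(crA, ccA, saA, sbA, thA,
                           crB, ccB, saB, sbB, thB, margin) {
  ang <- seq(0, 2 * pi, length.out = 64L)
  pr <- crA + saA * cos(ang) * cos(thA) - sbA * sin(ang) * sin(thA)
  pc <- ccA + saA * cos(ang) * sin(thA) + sbA * sin(ang) * cos(thA)
  dr <- pr - crB; dc <- pc - ccB
  u <- dr * cos(thB) + dc * sin(thB)
  v <- -dr * sin(thB) + dc * cos(thB)
  all((u / max(saB - margin, 1e-6))^2 + (v / max(sbB - margin, 1e-6))^2 <= 1)
}

gaussian_blur <- function(x, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}

# unit-mean multiplicative speckle field
speckle_field <- function(size, blur_sigma = 1.2) {
  z1 <- gaussian_blur(matrix(rnorm(size * size), size), blur_sigma)
  z2 <- gaussian_blur(matrix(rnorm(size * size), size), blur_sigma)
  s <- z1^2 + z2^2
  s / mean(s)
}

#' Generate one ultrasound phantom scene
#'
#' Produces a speckle-textured grayscale image with one hypoechoic ovary
#' ellipse and `n_follicles` anechoic follicle ellipses, together with exact
#' ground-truth masks and the true per-follicle diameters. Follicle diameters
#' are drawn from a right-skewed distribution over `diameter_range_mm`
#' (mostly small antral follicles, occasionally a dominant one); the ovary is
#' enlarged when needed so the largest drawn follicle fits, mimicking the
#' enlarged ovary that accompanies a dominant follicle. Follicles are placed
#' by rejection sampling with a minimal separation of `min_sep_px` pixels, so
#' components are pairwise disjoint at 8-connectivity. The whole scene is a
#' deterministic function of `seed`.
#'
#' @param n_follicles number of follicles (>= 0).
#' @param diameter_range_mm admissible true diameter range in mm.
#' @param size_px image side length in pixels.
#' @param spacing_mm physical pixel size in mm (default 0.1, i.e. a
#'   38.4 mm field of view at 384 px).
#' @param speckle list of texture parameters: `blur_sigma` (px),
#'   `background`, `ovary`, `follicle` (mean echogenicity levels; must be
#'   decreasing to preserve the echogenic > hypoechoic > anechoic ordering).
#' @param shadow add a vertical acoustic-shadow band (intensity drop).
#' @param contrast contrast factor in (0, 1]; values below 1 compress the
#'   intensity range around its mean to mimic poor-contrast acquisitions.
#' @param min_sep_px minimal separation between follicle components.
#' @param max_attempts rejection-sampling attempts per follicle before the
#'   packing is declared infeasible.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return an object of class `phantom_scene`: list with `image` (matrix in
#'   `[0, 1]`), `ovary_mask`, `follicle_mask`, `follicles` (data frame:
#'   center_row, center_col, semi_a_px, semi_b_px, theta, diameter_mm),
#'   `spacing_mm`, `size_px`, `seed`, `shadow`.
#' @examples
#' sc <- generate_phantom(n_follicles = 3, size_px = 96, spacing_mm = 0.4,
#'                        seed = 7)
#' range(sc$image)
#' sum(sc$follicle_mask)
#' @export
generate_phantom <- function(n_follicles,
                             diameter_range_mm = c(2, 28),
                             size_px = 384L,
                             spacing_mm = 0.1,
                             speckle = list(blur_sigma = 1.2,
                                            background = 0.55,
                                            ovary = 0.28,
                                            follicle = 0.04),
                             shadow = FALSE,
                             contrast = 1,
                             min_sep_px = 2L,
                             max_attempts = 300L,
                             seed = NULL) {
  stopifnot(n_follicles >= 0, length(diameter_range_mm) == 2L,
            diameter_range_mm[1] > 0,
            diameter_range_mm[1] <= diameter_range_mm[2],
            size_px >= 32L, spacing_mm > 0, contrast > 0, contrast <= 1)
  with_seed(seed, {
    fov <- size_px * spacing_mm
    px <- function(mm) mm / spacing_mm

    # Follicle diameters (diameter = semi-major + semi-minor axis). Mixture
    # reflecting clinical size distributions: mostly antral follicles in the
    # 2-10 mm range, occasionally (10%) a dominant follicle above 10 mm.
    # Draws avoid a guard band around the 2 and 10 mm recruitable cutoffs so
    # the true diameter and the pixel-level moment measurement always agree
    # on which side of the cutoff a follicle lies.
    guard <- 0.3
    lo <- diameter_range_mm[1]; hi <- diameter_range_mm[2]
    a_lo <- lo + guard; a_hi <- min(10 - guard, hi)
    draw_antral <- function(k) a_lo + (a_hi - a_lo) * rbeta(k, 1.2, 2.2)
    draw_one <- function() {
      if (hi > 10 + guard && runif(1) < 0.1) runif(1, 10 + guard, hi)
      else draw_antral(1L)
    }
    d <- numeric(0); q <- numeric(0)
    if (n_follicles > 0) {
      d <- vapply(seq_len(n_follicles), function(i) draw_one(), 0)
      q <- runif(n_follicles, 0.7, 1)
    }

    # ovary: sized to the scene, enlarged to hold the drawn follicles
    # (an ovary crowded with follicles is enlarged, as in stimulated
    # cycles); if even the largest admissible ovary cannot offer enough
    # area, the largest follicles are redrawn from the antral range
    margin <- 1.0        # mm clearance between follicle and ovary boundary
    cap <- fov / 2 - 1
    area_need <- function(d, q) {
      sa <- d / (1 + q)
      sum(pi * (sa + margin) * (q * sa + margin))
    }
    if (n_follicles > 0) {
      max_area <- 0.55 * pi * cap * cap
      tries <- 0L
      while ((area_need(d, q) > max_area ||
              max(d / (1 + q)) + 3 * margin > cap) && tries < 100L) {
        d[which.max(d)] <- draw_antral(1L)
        tries <- tries + 1L
      }
      if (area_need(d, q) > max_area)
        stop(sprintf(paste0("infeasible packing: %d follicles of the drawn ",
                            "sizes cannot fit a %.1f mm field of view"),
             n_follicles, fov))
    }
    sa_mm <- d / (1 + q); sb_mm <- q * sa_mm
    ord <- order(-d)     # place the largest follicles first

    oa <- runif(1, 13, 17); ob <- runif(1, 10, 14)
    if (n_follicles > 0) {
      oa <- max(oa, max(sa_mm) + 3 * margin)
      ob <- max(ob, max(sb_mm) + 3 * margin)
      grow <- sqrt(area_need(d, q) / (0.5 * pi * oa * ob))
      if (grow > 1) { oa <- oa * grow; ob <- ob * grow }
    }
    oa <- min(oa, cap); ob <- min(ob, cap)
    oth <- runif(1, -25, 25) * pi / 180
    ocr <- size_px / 2 + runif(1, -px(1.5), px(1.5))
    occ <- size_px / 2 + runif(1, -px(1.5), px(1.5))
    oa_px <- px(oa); ob_px <- px(ob)

    ovary_mask <- ellipse_mask(size_px, ocr, occ, oa_px, ob_px, oth)

    # rejection-sampled placement; if one pass dead-ends (earlier follicles
    # blocked the remaining space) the whole arrangement is redrawn
    place_all <- function() {
      follicle_mask <- matrix(0L, size_px, size_px)
      occupied <- matrix(FALSE, size_px, size_px)
      fol <- data.frame(center_row = double(0), center_col = double(0),
                        semi_a_px = double(0), semi_b_px = double(0),
                        theta = double(0), diameter_mm = double(0))
      for (i in ord) {
        sa <- px(sa_mm[i]); sb <- px(sb_mm[i])
        th <- runif(1, 0, pi)
        # sample centers from (approximately) the feasible offset ellipse so
        # large follicles, whose admissible region is small, still place
        amax <- max(oa_px - sa - px(margin), 0.5)
        bmax <- max(ob_px - sb - px(margin), 0.5)
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          rad <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
          dr <- rad * amax * cos(ang); dc <- rad * bmax * sin(ang)
          cr <- ocr + dr * cos(oth) - dc * sin(oth)
          cc <- occ + dr * sin(oth) + dc * cos(oth)
          if (!ellipse_inside(cr, cc, sa, sb, th, ocr, occ, oa_px, ob_px, oth,
                              margin = px(margin)))
            next
          grown <- ellipse_mask(size_px, cr, cc, sa + min_sep_px,
                                sb + min_sep_px, th)
          if (any(grown & occupied)) next
          this <- ellipse_mask(size_px, cr, cc, sa, sb, th)
          if (sum(this) == 0L) next
          follicle_mask <- follicle_mask | this
          occupied <- occupied | (this > 0)
          fol <- rbind(fol, data.frame(center_row = cr, center_col = cc,
                                       semi_a_px = sa, semi_b_px = sb,
                                       theta = th, diameter_mm = d[i]))
          placed <- TRUE
          break
        }
        if (!placed) return(NULL)
      }
      list(mask = matrix(as.integer(follicle_mask), size_px, size_px),
           fol = fol)
    }
    res <- NULL
    for (pass in 1:10) {
      res <- place_all()
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop(sprintf(paste0("infeasible packing: could not place %d follicles ",
                          "after repeated attempts"), n_follicles))
    follicle_mask <- res$mask
    fol <- res$fol

    base <- matrix(speckle$background, size_px, size_px)
    base[ovary_mask == 1] <- speckle$ovary
    base[follicle_mask == 1] <- speckle$follicle
    base <- gaussian_blur(base, 1.5)          # soft tissue boundaries
    img <- base * speckle_field(size_px, speckle$blur_sigma)
    if (shadow) {
      c0 <- runif(1, 0.15, 0.75) * size_px
      wdt <- runif(1, 0.06, 0.15) * size_px
      prof <- 1 - 0.55 * exp(-((seq_len(size_px) - c0)^2) / (2 * (wdt / 2)^2))
      img <- img * matrix(prof, size_px, size_px, byrow = TRUE)
    }
    if (contrast < 1) img <- mean(img) + contrast * (img - mean(img))
    img <- pmin(pmax(img, 0), 1)

    structure(list(image = img, ovary_mask = ovary_mask,
                   follicle_mask = follicle_mask, follicles = fol,
                   spacing_mm = spacing_mm, size_px = as.integer(size_px),
                   seed = seed, shadow = shadow), class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %dx%d px at %.3g mm/px, %d follicle(s)\n",
              x$size_px, x$size_px, x$spacing_mm, nrow(x$follicles)))
  invisible(x)
}

#' Build (image, mask) training pairs from phantom scenes
#'
#' @param scenes list of `phantom_scene`s.
#' @param target `"ovary"` or `"follicle"`: which ground-truth mask to pair
#'   with the image.
#' @return list of `(image, mask)` pairs for [train_network()].
#' @export
phantom_pairs <- function(scenes, target = c("follicle", "ovary")) {
  target <- match.arg(target)
  lapply(scenes, function(s)
    list(image = s$image,
         mask = if (target == "ovary") s$ovary_mask else s$follicle_mask))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_images` phantom scenes as 8-bit PNGs (image plus ovary and
#' follicle masks) into `dir`, split into train/val/test subsets, together
#' with a `manifest.csv` (one row per image: file names, split, per-image
#' seed and generator arguments), a `follicles.csv` (true follicle table)
#' and a `dataset.json` with the generator configuration. Regenerating with
#' the manifest's per-image seeds reproduces the scenes exactly.
#'
#' @param n_images total number of images (>= number of splits).
#' @param dir output directory (created if missing).
#' @param split_fractions named fractions summing to 1.
#' @param seed master seed; per-image seeds are drawn from it.
#' @param n_follicles_range inclusive range of per-image follicle counts.
#' @param shadow_prob probability of a shadow artifact per image.
#' @param ... further arguments passed to [generate_phantom()]
#'   (`size_px`, `spacing_mm`, `diameter_range_mm`, ...).
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(n_images, dir,
                             split_fractions = c(train = 0.6, val = 0.2,
                                                 test = 0.2),
                             seed = NULL, n_follicles_range = c(0L, 12L),
                             shadow_prob = 0.25, ...) {
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  if (n_images < length(split_fractions))
    stop("need at least one image per split")
  dots <- list(...)
  with_seed(seed, {
    counts <- diff(round(cumsum(c(0, split_fractions)) * n_images))
    splits <- rep(names(split_fractions), counts)
    seeds <- sample.int(.Machine$integer.max, n_images)
    nf <- sample(seq(n_follicles_range[1], n_follicles_range[2]),
                 n_images, replace = TRUE)
    shadows <- runif(n_images) < shadow_prob
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sub in c("images", "ovary_masks", "follicle_masks"))
      dir.create(file.path(dir, sub), showWarnings = FALSE)
    rows <- vector("list", n_images)
    ftabs <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      sc <- do.call(generate_phantom,
                    c(list(n_follicles = nf[i], shadow = shadows[i],
                           seed = seeds[i]), dots))
      id <- sprintf("%s_%04d", splits[i], i)
      fi <- file.path("images", paste0(id, ".png"))
      fo <- file.path("ovary_masks", paste0(id, ".png"))
      ff <- file.path("follicle_masks", paste0(id, ".png"))
      png::writePNG(sc$image, file.path(dir, fi))
      write_mask(sc$ovary_mask, file.path(dir, fo))
      write_mask(sc$follicle_mask, file.path(dir, ff))
      rows[[i]] <- data.frame(id = id, split = splits[i], seed = seeds[i],
                              n_follicles = nf[i], shadow = shadows[i],
                              size_px = sc$size_px,
                              spacing_mm = sc$spacing_mm,
                              image = fi, ovary_mask = fo, follicle_mask = ff)
      if (nrow(sc$follicles))
        ftabs[[i]] <- cbind(id = id, sc$follicles)
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    ftab <- do.call(rbind, ftabs)
    if (is.null(ftab)) ftab <- data.frame()
    write.csv(ftab, file.path(dir, "follicles.csv"), row.names = FALSE)
    jsonlite::write_json(c(list(n_images = n_images, seed = seed,
                                split_fractions = as.list(split_fractions),
                                n_follicles_range = n_follicles_range,
                                shadow_prob = shadow_prob), dots),
                         file.path(dir, "dataset.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(manifest)
  })
}

#' Load a phantom dataset written by [generate_dataset()]
#'
#' @param dir dataset directory.
#' @param split optional subset (`"train"`, `"val"`, `"test"`).
#' @param target which mask to pair with each image.
#' @return list of `(image, mask)` pairs; the manifest is attached as the
#'   `"manifest"` attribute.
#' @export
load_dataset <- function(dir, split = NULL,
                         target = c("follicle", "ovary")) {
  target <- match.arg(target)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$image[i]))
    mfile <- if (target == "ovary") manifest$ovary_mask[i]
             else manifest$follicle_mask[i]
    msk <- png::readPNG(file.path(dir, mfile))
    list(image = img, mask = matrix(as.integer(msk > 0.5), nrow(msk)))
  })
  attr(pairs, "manifest") <- manifest
  pairs
}
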