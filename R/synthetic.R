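# Synthetic dermoscopy-like image/mask generator.
#
# The lesion is a star-convex region in polar form
#   r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k))
# drawn inside a rotated ellipse frame, so at zero perturbation amplitude the
# mask equals an analytic ellipse rasterization exactly. The image is a
# skin-tone background with a smooth illumination gradient and noise, blended
# with a darker lesion texture through a Gaussian-blurred boundary; optional
# dark hair-like arcs occlude both lesion and skin (the mask is unchanged).
# Star-convexity guarantees a single connected component; area fraction is
# enforced by rejection sampling.

#' Parameters of the synthetic lesion generator
#'
#' @param seed RNG seed; the pair is fully reproducible from it
#' @param image_size image side length in pixels
#' @param area_fraction_range (lo, hi) bounds on the lesion area fraction
#' @param n_harmonics number of polar boundary harmonics
#' @param harmonic_amplitude total amplitude budget of the harmonics; must
#'   stay below 1 to keep the radius positive
#' @param blur_sigma Gaussian blur (pixels) applied to the lesion boundary in
#'   the image (not the mask)
#' @param contrast lesion/skin intensity gap in `[0, 1]`
#' @param hair_count number of hair-like occluder arcs
#' @return named parameter list
#' @export
lesion_params <- function(seed = 1, image_size = 256,
                          area_fraction_range = c(0.05, 0.40),
                          n_harmonics = 6, harmonic_amplitude = 0.25,
                          blur_sigma = 2, contrast = 0.25, hair_count = 3) {
  if (harmonic_amplitude >= 1)
    stop("harmonic_amplitude must be < 1 to keep the lesion radius positive")
  stopifnot(image_size >= 16, area_fraction_range[1] > 0,
            area_fraction_range[2] < 1,
            area_fraction_range[1] < area_fraction_range[2],
            contrast >= 0, contrast <= 1, hair_count >= 0)
  list(seed = as.integer(seed), image_size = as.integer(image_size),
       area_fraction_range = area_fraction_range,
       n_harmonics = as.integer(n_harmonics),
       harmonic_amplitude = harmonic_amplitude,
       blur_sigma = blur_sigma, contrast = contrast,
       hair_count = as.integer(hair_count))
}

# rasterize one star-convex lesion; returns binary (S, S) matrix
rasterize_lesion <- function(S, cx, cy, rx, ry, rot, amps, phases) {
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # columns
  ys <- matrix(rep(seq_len(S), times = S), S, S)  # rows
  dx <- xs - cx
  dy <- ys - cy
  xr <- (cos(rot) * dx + sin(rot) * dy) / rx
  yr <- (-sin(rot) * dx + cos(rot) * dy) / ry
  rho <- sqrt(xr^2 + yr^2)
  if (length(amps) && any(amps != 0)) {
    theta <- atan2(yr, xr)
    lim <- 1
    for (k in seq_along(amps))
      lim <- lim + amps[k] * sin(k * theta + phases[k])
    (rho <= lim) * 1
  } else {
    (rho <= 1) * 1
  }
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # separable, zero-padded
  H <- nrow(m); W <- ncol(m)
  padv <- rbind(matrix(0, r, W), m, matrix(0, r, W))
  v <- vapply(seq_len(H), function(i)
    as.vector(k %*% padv[i:(i + 2 * r), , drop = FALSE]), numeric(W))
  v <- t(v)
  padh <- cbind(matrix(0, H, r), v, matrix(0, H, r))
  h <- vapply(seq_len(W), function(j)
    as.vector(padh[, j:(j + 2 * r), drop = FALSE] %*% k), numeric(H))
  matrix(h, H, W)
}

label_components4 <- function(mask) {
  # number of 4-connected foreground components (BFS)
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  idx <- which(mask == 1)
  for (start in idx) {
    r0 <- (start - 1) %% H + 1; c0 <- (start - 1) %/% H + 1
    if (seen[r0, c0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + dd[1]; cc <- p[2] + dd[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] == 1 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  ncomp
}

draw_hairs <- function(img, S, n) {
  if (n == 0) return(img)
  ts <- seq(0, 1, length.out = 6L * S)
  for (i in seq_len(n)) {
    p0 <- stats::runif(2, 1, S)
    p2 <- stats::runif(2, 1, S)
    mid <- (p0 + p2) / 2 + stats::runif(2, -S / 3, S / 3)
    px <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * mid[1] + ts^2 * p2[1]
    py <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * mid[2] + ts^2 * p2[2]
    thick <- sample(0:1, 1)
    shade <- stats::runif(1, 0.05, 0.25)
    col <- c(shade, shade * 0.8, shade * 0.7)
    for (dd in if (thick) list(c(0, 0), c(1, 0), c(0, 1)) else list(c(0, 0))) {
      rr <- round(px) + dd[1]; cc <- round(py) + dd[2]
      ok <- rr >= 1 & rr <= S & cc >= 1 & cc <= S
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[cbind(rr[ok], cc[ok])] <- col[ch]
        img[, , ch] <- sl
      }
    }
  }
  img
}

#' Generate one synthetic dermoscopy image/mask pair
#'
#' Fully reproducible from `p$seed`; the same seed yields byte-identical
#' output. The mask area fraction is kept inside `p$area_fraction_range` by
#' rejection sampling, and the mask is always a single 4-connected component.
#'
#' @param p parameters from [lesion_params()]
#' @return list with `image` (S, S, 3 array in `[0, 1]`) and `mask`
#'   (S x S binary matrix)
#' @export
generate_pair <- function(p = lesion_params()) {
  set.seed(p$seed)
  S <- p$image_size
  for (attempt in 1:50) {
    target_af <- stats::runif(1, p$area_fraction_range[1], p$area_fraction_range[2])
    aspect <- stats::runif(1, 0.6, 1)
    # ellipse area pi*rx*ry = target_af * S^2
    rx <- sqrt(target_af * S^2 / (pi * aspect))
    ry <- rx * aspect
    rot <- stats::runif(1, 0, pi)
    cx <- S / 2 + stats::runif(1, -0.08 * S, 0.08 * S)
    cy <- S / 2 + stats::runif(1, -0.08 * S, 0.08 * S)
    if (p$n_harmonics > 0 && p$harmonic_amplitude > 0) {
      raw <- stats::runif(p$n_harmonics) / seq_len(p$n_harmonics)
      amps <- raw / sum(raw) * p$harmonic_amplitude
      phases <- stats::runif(p$n_harmonics, 0, 2 * pi)
    } else {
      amps <- numeric(0); phases <- numeric(0)
    }
    mask <- rasterize_lesion(S, cx, cy, rx, ry, rot, amps, phases)
    af <- mean(mask)
    if (af >= p$area_fraction_range[1] && af <= p$area_fraction_range[2] &&
        label_components4(mask) == 1L) break
    if (attempt == 50) stop("generate_pair: could not satisfy area constraints")
  }
  # skin background: base tone + illumination gradient + speckle
  base <- c(0.80, 0.60, 0.52)
  gdir <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(rep(seq_len(S), each = S), S, S) / S - 0.5
  gy <- matrix(rep(seq_len(S), times = S), S, S) / S - 0.5
  grad <- 0.08 * (cos(gdir) * gx + sin(gdir) * gy)
  # channel-mean tint > 1 keeps the mean lesion/skin gap above `contrast`
  # even after boundary blur dilutes the rim
  lesion_tint <- c(1.1, 1.25, 1.4)
  alpha <- if (p$blur_sigma > 0) gauss_blur(mask, p$blur_sigma) else mask
  alpha <- pmin(pmax(alpha, 0), 1)
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) {
    skin <- base[ch] + grad + matrix(stats::rnorm(S * S, 0, 0.015), S, S)
    lesion <- skin - p$contrast * lesion_tint[ch] +
      matrix(stats::rnorm(S * S, 0, 0.02), S, S)
    img[, , ch] <- (1 - alpha) * skin + alpha * lesion
  }
  img <- draw_hairs(img, S, p$hair_count)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a dataset of synthetic pairs on disk
#'
#' Writes `images/NNN.png` and `masks/NNN.png` (masks as single-channel
#' `{0, 255}` PNG) plus `manifest.json` recording seed, parameters and a
#' 7:3 train/test split.
#'
#' @param n number of pairs
#' @param seed base seed; pair i uses `seed + i`
#' @param out_dir output directory (must not already contain files unless
#'   `force`)
#' @param params template from [lesion_params()]; its seed field is ignored
#' @param force allow writing into a non-empty directory
#' @return the manifest, invisibly
#' @export
generate_dataset <- function(n, seed, out_dir, params = lesion_params(),
                             force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("generate_dataset: ", out_dir, " is not empty (use force = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("%03d", seq_len(n))
  for (i in seq_len(n)) {
    params$seed <- as.integer(seed + i)
    pr <- generate_pair(params)
    png::writePNG(pr$image, file.path(out_dir, "images", paste0(ids[i], ".png")))
    png::writePNG(pr$mask, file.path(out_dir, "masks", paste0(ids[i], ".png")))
  }
  set.seed(seed)
  n_train <- round(0.7 * n)
  train_ids <- sort(sample(seq_len(n), n_train))
  manifest <- list(seed = seed, n = n, params = params[names(params) != "seed"],
                   split = list(train = ids[train_ids],
                                test = ids[setdiff(seq_len(n), train_ids)]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load an images/ + masks/ dataset directory
#'
#' Masks are binarized at > 127/255; images resized to `size` bilinearly and
#' masks with nearest-neighbour if needed.
#'
#' @param dir dataset directory with `images/` and `masks/`
#' @param size target side length (NULL keeps native size)
#' @return list with `images`, `masks`, `ids`
#' @export
load_dataset <- function(dir, size = NULL) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  msks <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  bi <- basename(imgs); bm <- basename(msks)
  if (!identical(bi, bm))
    stop("load_dataset: image/mask mismatch: ",
         paste(union(setdiff(bi, bm), setdiff(bm, bi)), collapse = ", "))
  images <- list(); masks <- list()
  for (i in seq_along(imgs)) {
    im <- png::readPNG(imgs[i])
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    im <- im[, , 1:3, drop = FALSE]
    mk <- png::readPNG(msks[i])
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    mk <- (mk > 127 / 255) * 1
    if (!is.null(size) && !all(dim(mk) == size)) {
      im <- cpp_bilinear_fw(im, size, size)
      mk <- resize_nearest(mk, size, size)
    }
    images[[i]] <- im
    masks[[i]] <- mk
  }
  list(images = images, masks = masks, ids = sub("\\.png$", "", bi))
}

resize_nearest <- function(m, Ho, Wo) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(Ho) - 0.5) * H / Ho) + 1, 1), H)
  ci <- pmin(pmax(floor((seq_len(Wo) - 0.5) * W / Wo) + 1, 1), W)
  m[ri, ci, drop = FALSE]
}
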