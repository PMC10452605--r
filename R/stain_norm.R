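#' Stain normalization of H&E tiles
#'
#' Histology tiles from different laboratories vary in stain colour and
#' intensity. The normalizer maps every tile onto a reference appearance by
#' (i) masking background in CIELAB lightness, (ii) estimating the tile's
#' two stain colour vectors from the SVD of its optical-density (OD) pixel
#' cloud (Macenko-style extreme-angle selection), (iii) unmixing each pixel
#' into two stain concentrations, (iv) rescaling concentrations to the
#' reference's robust maxima and (v) reconstructing RGB through the
#' reference stain matrix via the Beer-Lambert law.
#'
#' @name stain_norm
NULL

#' Stain-normalization configuration
#'
#' @param l_threshold background threshold as a fraction of full lightness:
#'   a pixel is background iff `L > l_threshold * 100`. Default 0.9.
#' @param alpha percentile (fraction) for robust extreme-angle selection of
#'   the stain vectors inside the SVD plane. Default 0.01.
#' @param conc_quantile quantile of per-stain concentration used as the
#'   robust maximum when matching a source tile to the reference. Default 0.99.
#' @param i0 incident light intensity of the OD transform. Default 255.
#' @param eps offset avoiding `log(0)`; OD is
#'   `-log10((I + eps) / (i0 + eps))` so that `OD(i0) = 0` exactly.
#' @param min_foreground minimum number of tissue pixels required for stain
#'   estimation. Default 100.
#' @return a list of class `stain_norm_config`.
#' @export
stain_norm_config <- function(l_threshold = 0.9, alpha = 0.01,
                              conc_quantile = 0.99, i0 = 255, eps = 1,
                              min_foreground = 100) {
  stopifnot(l_threshold > 0, l_threshold < 1, alpha > 0, alpha < 0.5)
  structure(list(l_threshold = l_threshold, alpha = alpha,
                 conc_quantile = conc_quantile, i0 = i0, eps = eps,
                 min_foreground = min_foreground),
            class = "stain_norm_config")
}

#' Convert an RGB tile to CIELAB
#'
#' Standard sRGB (D65) to CIELAB conversion; the round trip back to RGB is
#' exact to within one intensity level per channel.
#'
#' @param tile `H x W x 3` array in `[0, 255]`.
#' @return `H x W x 3` array: L in `[0, 100]`, A/B roughly `[-128, 127]`.
#' @export
rgb_to_lab <- function(tile) {
  assert_tile(tile)
  d <- dim(tile)
  rgb <- matrix(tile, ncol = 3L) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  array(lab, d)
}

#' Convert a CIELAB tile back to RGB
#' @param lab `H x W x 3` CIELAB array as produced by [rgb_to_lab()].
#' @return `H x W x 3` integer-valued array in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  stopifnot(is.array(lab), length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  d <- dim(lab)
  rgb <- grDevices::convertColor(matrix(lab, ncol = 3L), from = "Lab", to = "sRGB")
  array(round(pmin(pmax(rgb, 0), 1) * 255), d)
}

#' Background mask from lightness
#'
#' A pixel counts as background when its CIELAB lightness exceeds
#' `l_threshold * 100` (glass/background is near-white in H&E). Errors when
#' no tissue pixel remains, since stain estimation is then impossible.
#'
#' @param lab CIELAB array from [rgb_to_lab()].
#' @param l_threshold fraction of full lightness, in (0, 1).
#' @return list with `mask` (`H x W` logical, `TRUE` = background) and
#'   `n_foreground` (tissue pixel count).
#' @export
background_mask <- function(lab, l_threshold = 0.9) {
  stopifnot(l_threshold > 0, l_threshold < 1)
  mask <- lab[, , 1] > l_threshold * 100
  n_fg <- sum(!mask)
  if (n_fg == 0L) abort("no tissue: every pixel is background at this threshold")
  list(mask = mask, n_foreground = n_fg)
}

#' Optical-density transform
#'
#' `OD = -log10((I + eps) / (i0 + eps))`: zero at full intensity, strictly
#' decreasing in intensity, non-negative. Stain contributions are additive
#' in OD (Beer-Lambert).
#'
#' @param tile RGB array in `[0, 255]`.
#' @param i0,eps see [stain_norm_config()].
#' @return `H x W x 3` array of non-negative optical densities.
#' @export
od_transform <- function(tile, i0 = 255, eps = 1) {
  assert_tile(tile)
  -log10((tile + eps) / (i0 + eps))
}

od_to_rgb <- function(od, i0 = 255, eps = 1) {
  ints <- (i0 + eps) * 10^(-od) - eps
  round(pmin(pmax(ints, 0), 255))
}

#' Estimate a tile's stain profile
#'
#' SVD of the mean-centred foreground OD cloud gives the two-dimensional
#' stain plane; pixels are projected into that plane and the stain vectors
#' are taken as the `alpha` / `1 - alpha` percentile angular extremes
#' (robust against outliers), unit-normalised, with a deterministic sign
#' convention (first nonzero component positive) so repeated estimation is
#' reproducible. Per-stain 99th-percentile concentrations and per-channel
#' 99th-percentile ODs are recorded as the scale statistics used later for
#' reference matching.
#'
#' @param tile RGB array in `[0, 255]`.
#' @param mask optional background mask as returned by [background_mask()];
#'   computed from `config` when missing.
#' @param config a [stain_norm_config()].
#' @return object of class `stain_profile`: `stain_matrix` (2 x 3, unit
#'   rows), `conc_scales` (length 2), `channel_scales` (length 3), `config`.
#' @export
estimate_stain_profile <- function(tile, mask = NULL,
                                   config = stain_norm_config()) {
  assert_tile(tile)
  if (is.null(mask)) {
    mask <- background_mask(rgb_to_lab(tile), config$l_threshold)
  }
  if (mask$n_foreground < config$min_foreground) {
    abort(sprintf("no tissue: %d foreground pixels < min_foreground = %d",
                  mask$n_foreground, config$min_foreground))
  }
  od <- od_transform(tile, config$i0, config$eps)
  odm <- matrix(od, ncol = 3L)
  X <- odm[!as.vector(mask$mask), , drop = FALSE]

  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 || sv$d[2] < 1e-6 * sv$d[1]) {
    abort("degenerate stain geometry: OD cloud has rank < 2")
  }
  V <- sv$v[, 1:2, drop = FALSE]
  proj <- X %*% V
  if (mean(proj[, 1]) < 0) {
    V[, 1] <- -V[, 1]; proj[, 1] <- -proj[, 1]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  a_lo <- quantile(phi, config$alpha, names = FALSE)
  a_hi <- quantile(phi, 1 - config$alpha, names = FALSE)
  v1 <- as.vector(V %*% c(cos(a_lo), sin(a_lo)))
  v2 <- as.vector(V %*% c(cos(a_hi), sin(a_hi)))
  v1 <- fix_sign(v1 / sqrt(sum(v1^2)))
  v2 <- fix_sign(v2 / sqrt(sum(v2^2)))
  # deterministic row order: stain with the larger blue-channel OD first
  # (hematoxylin-like), ties broken on the first component
  if (v2[3] > v1[3] || (v2[3] == v1[3] && v2[1] > v1[1])) {
    tmp <- v1; v1 <- v2; v2 <- tmp
  }
  sm <- rbind(v1, v2)
  dimnames(sm) <- list(c("stain1", "stain2"), c("R", "G", "B"))

  conc <- unmix_od(X, sm)
  profile <- structure(list(
    stain_matrix = sm,
    conc_scales = apply(conc, 2, quantile, config$conc_quantile, names = FALSE),
    channel_scales = apply(X, 2, quantile, config$conc_quantile, names = FALSE),
    config = config
  ), class = "stain_profile")
  profile
}

fix_sign <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) -v else v
}

# least-squares unmixing of N x 3 OD rows onto the two stain vectors,
# negatives clamped to zero
unmix_od <- function(odm, sm) {
  g <- sm %*% t(sm)
  conc <- odm %*% t(sm) %*% solve(g)
  conc[conc < 0] <- 0
  conc
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  print(round(x$stain_matrix, 4))
  cat("conc_scales:", paste(signif(x$conc_scales, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-pixel stain concentrations
#'
#' Least-squares projection of each OD pixel onto the two stain vectors of
#' the profile; negative solutions are clamped to zero.
#'
#' @param od `H x W x 3` OD array from [od_transform()].
#' @param profile a `stain_profile`.
#' @return `H x W x 2` array of non-negative concentrations.
#' @export
compute_concentrations <- function(od, profile) {
  stopifnot(inherits(profile, "stain_profile"),
            is.array(od), length(dim(od)) == 3L, dim(od)[3] == 3L)
  d <- dim(od)
  conc <- unmix_od(matrix(od, ncol = 3L), profile$stain_matrix)
  array(conc, c(d[1], d[2], 2L))
}

#' Normalize a tile to a reference stain appearance
#'
#' Estimates the source tile's own profile, unmixes all pixels, rescales
#' each stain's concentrations by the ratio of reference to source robust
#' maxima (`conc_quantile`), and reconstructs RGB through the *reference*
#' stain matrix. Output is clipped to `[0, 255]` and rounded.
#'
#' @param tile RGB array in `[0, 255]`.
#' @param ref_profile reference `stain_profile` (from
#'   [estimate_stain_profile()] on a reference tile, or [read_stain_profile()]).
#' @param config a [stain_norm_config()].
#' @return normalized `H x W x 3` RGB array.
#' @export
normalize_to_reference <- function(tile, ref_profile,
                                   config = stain_norm_config()) {
  stopifnot(inherits(ref_profile, "stain_profile"))
  src <- estimate_stain_profile(tile, config = config)
  od <- od_transform(tile, config$i0, config$eps)
  d <- dim(tile)
  conc <- unmix_od(matrix(od, ncol = 3L), src$stain_matrix)
  scale <- ref_profile$conc_scales / pmax(src$conc_scales, 1e-8)
  conc <- sweep(conc, 2, scale, `*`)
  od_n <- conc %*% ref_profile$stain_matrix
  array(od_to_rgb(od_n, config$i0, config$eps), d)
}

#' Serialize / load a stain profile as JSON
#'
#' @param profile a `stain_profile`; @param path JSON file path.
#' @return `write_stain_profile()` returns `path` invisibly;
#'   `read_stain_profile()` returns the `stain_profile`.
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  jsonlite::write_json(list(
    stain_matrix = unname(as.matrix(profile$stain_matrix)),
    conc_scales = profile$conc_scales,
    channel_scales = profile$channel_scales,
    config = unclass(profile$config)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sm <- matrix(as.numeric(obj$stain_matrix), nrow = 2L)
  dimnames(sm) <- list(c("stain1", "stain2"), c("R", "G", "B"))
  structure(list(
    stain_matrix = sm,
    conc_scales = as.numeric(obj$conc_scales),
    channel_scales = as.numeric(obj$channel_scales),
    config = do.call(stain_norm_config, obj$config)
  ), class = "stain_profile")
}

#' Angular error between two sets of stain vectors
#'
#' Utility for parameter-recovery checks: matches estimated to true stain
#' vectors (both row orders considered) and returns the mean angle, in
#' degrees, of the best assignment.
#'
#' @param est,truth 2 x 3 matrices with unit rows.
#' @return angle in degrees (mean over the two stains, best row matching).
#' @export
stain_angle_error <- function(est, truth) {
  ang <- function(a, b) {
    c <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    acos(pmin(pmax(c, -1), 1)) * 180 / pi
  }
  direct <- (ang(est[1, ], truth[1, ]) + ang(est[2, ], truth[2, ])) / 2
  swapped <- (ang(est[1, ], truth[2, ]) + ang(est[2, ], truth[1, ])) / 2
  min(direct, swapped)
}
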