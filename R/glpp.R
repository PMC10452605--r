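#' Global-local pyramid pattern (GLPP) texture descriptor
#'
#' A multi-scale binary-pattern descriptor. For every pixel, the P
#' neighbours on a circle of radius r are compared against the centre
#' (`>=` gives bit 1), read once clockwise and once counterclockwise as
#' P-bit words (most significant bit first), and the larger of the two
#' decimal codes is kept. Repeating this over a schedule of growing
#' (radius, P) pairs — local to global — and histogramming each code image
#' yields one concatenated, per-scale-normalised feature vector per image.
#'
#' Conventions (binding): image coordinates, row increasing downward;
#' neighbour 0 sits due east and the clockwise pass advances toward
#' increasing row first; the counterclockwise pass visits the same
#' neighbours in reverse order (starting one step counterclockwise of east,
#' ending at east), so its code is exactly the P-bit reversal of the
#' clockwise code.
#'
#' @name glpp
NULL

#' GLPP configuration
#'
#' @param schedule data frame (or list of `c(radius, P)` pairs) with
#'   columns `radius` and `P`; radii strictly increasing, every P even and
#'   at least 4. Default `(1,8), (2,16), (3,24)`.
#' @param interpolation `"bilinear"` (default) or `"nearest"` sampling of
#'   non-integer circle positions. Comparisons of raw pixels (nearest) are
#'   exactly invariant under strictly increasing intensity maps; bilinear
#'   is only approximately so.
#' @param histogram_mode `"auto"` (full binning for P <= 12, uniform-pattern
#'   binning with P+2 bins above), `"full"` (only allowed when every
#'   P <= 12) or `"uniform"`.
#' @return a list of class `glpp_config`.
#' @export
glpp_config <- function(schedule = list(c(1, 8), c(2, 16), c(3, 24)),
                        interpolation = c("bilinear", "nearest"),
                        histogram_mode = c("auto", "full", "uniform")) {
  interpolation <- match.arg(interpolation)
  histogram_mode <- match.arg(histogram_mode)
  if (is.data.frame(schedule)) {
    sched <- tibble::as_tibble(schedule[, c("radius", "P")])
  } else {
    sched <- tibble::tibble(
      radius = purrr::map_dbl(schedule, 1),
      P = as.integer(purrr::map_dbl(schedule, 2))
    )
  }
  stopifnot(nrow(sched) >= 1)
  if (any(diff(sched$radius) <= 0)) abort("schedule radii must be strictly increasing")
  if (any(sched$P < 4L) || any(sched$P %% 2L != 0L)) {
    abort("every P must be even and >= 4")
  }
  if (histogram_mode == "full" && any(sched$P > 12L)) {
    abort("full histograms are only allowed for P <= 12 (2^P bins)")
  }
  sched$mode <- dplyr::case_when(
    histogram_mode == "full" ~ "full",
    histogram_mode == "uniform" ~ "uniform",
    sched$P <= 12L ~ "full",
    TRUE ~ "uniform"
  )
  sched$bins <- ifelse(sched$mode == "full", 2L^sched$P, sched$P + 2L)
  structure(list(schedule = sched, interpolation = interpolation,
                 histogram_mode = histogram_mode),
            class = "glpp_config")
}

# circle offsets (clockwise from east, row-down coordinates); near-integer
# positions snapped so nearest/bilinear agree on exact grid points
circle_offsets <- function(radius, P) {
  k <- seq_len(P) - 1
  theta <- 2 * pi * k / P
  dr <- radius * sin(theta)
  dc <- radius * cos(theta)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(dr = snap(dr), dc = snap(dc))
}

sample_offset <- function(gray, rows, cols, dr, dc, interpolation) {
  if (interpolation == "nearest") {
    return(gray[rows + round(dr), cols + round(dc), drop = FALSE])
  }
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  if (fr == 0 && fc == 0) return(gray[rows + r0, cols + c0, drop = FALSE])
  g00 <- gray[rows + r0, cols + c0, drop = FALSE]
  g01 <- gray[rows + r0, cols + c0 + 1, drop = FALSE]
  g10 <- gray[rows + r0 + 1, cols + c0, drop = FALSE]
  g11 <- gray[rows + r0 + 1, cols + c0 + 1, drop = FALSE]
  (1 - fr) * ((1 - fc) * g00 + fc * g01) + fr * ((1 - fc) * g10 + fc * g11)
}

#' Binary code of a single pixel
#'
#' Reference implementation for one centre pixel; [glpp_code_image()] is
#' the vectorised whole-image version.
#'
#' @param gray numeric matrix of intensities.
#' @param center `c(row, col)`, at least `radius` away from every border.
#' @param radius circle radius, pixels; @param P neighbour count.
#' @param direction `"cw"` or `"ccw"` traversal.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return the P-bit word as a decimal integer in `[0, 2^P - 1]`.
#' @export
glpp_code_pixel <- function(gray, center, radius, P,
                            direction = c("cw", "ccw"),
                            interpolation = c("bilinear", "nearest")) {
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  m <- ceiling(radius)
  if (center[1] - m < 1 || center[1] + m > nrow(gray) ||
      center[2] - m < 1 || center[2] + m > ncol(gray)) {
    abort("center is closer than `radius` to the image border")
  }
  off <- circle_offsets(radius, P)
  order <- if (direction == "cw") seq_len(P) else rev(seq_len(P))
  centre_val <- gray[center[1], center[2]]
  code <- 0
  for (i in seq_len(P)) {
    k <- order[i]
    nb <- sample_offset(gray, center[1], center[2], off[k, 1], off[k, 2],
                        interpolation)
    bit <- as.numeric(nb >= centre_val)
    code <- code + bit * 2^(P - i)
  }
  code
}

#' Reverse the P-bit representation of codes
#' @param x non-negative integer code(s) below `2^P`; @param P word length.
#' @return codes with bit order reversed.
#' @export
bit_reverse <- function(x, P) {
  out <- numeric(length(x))
  for (k in seq_len(P) - 1) {
    bit <- (x %/% 2^k) %% 2
    out <- out + bit * 2^(P - 1 - k)
  }
  out
}

#' Fused GLPP code image
#'
#' Per valid pixel, the fused code `max(cw, ccw)` where the
#' counterclockwise code is the bit reversal of the clockwise one. Pixels
#' within `ceiling(radius)` of a border are invalid and carry `NA`.
#'
#' @param gray numeric intensity matrix, each side larger than
#'   `2 * radius + 1`.
#' @param radius circle radius; @param P neighbour count.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return object of class `glpp_code_image`: list with `codes`
#'   (numeric matrix, `NA` borders), `P`, `radius`, `interpolation`.
#' @export
glpp_code_image <- function(gray, radius, P,
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  m <- ceiling(radius)
  h <- nrow(gray); w <- ncol(gray)
  if (h <= 2 * radius + 1 || w <= 2 * radius + 1) {
    abort(sprintf("image %dx%d too small for radius %s", h, w, radius))
  }
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  centre <- gray[rows, cols, drop = FALSE]
  off <- circle_offsets(radius, P)
  cw <- matrix(0, length(rows), length(cols))
  ccw <- matrix(0, length(rows), length(cols))
  for (k in seq_len(P)) {
    nb <- sample_offset(gray, rows, cols, off[k, 1], off[k, 2], interpolation)
    bit <- (nb >= centre) * 1
    cw <- cw + bit * 2^(P - k)      # MSB first along the clockwise pass
    ccw <- ccw + bit * 2^(k - 1)    # reversal: same bits, LSB first
  }
  codes <- matrix(NA_real_, h, w)
  codes[rows, cols] <- pmax(cw, ccw)
  structure(list(codes = codes, P = P, radius = radius,
                 interpolation = interpolation),
            class = "glpp_code_image")
}

#' @export
print.glpp_code_image <- function(x, ...) {
  cat(sprintf("<glpp_code_image> %dx%d, radius %s, P = %d (%s)\n",
              nrow(x$codes), ncol(x$codes), format(x$radius), x$P,
              x$interpolation))
  invisible(x)
}

# per-pixel bit planes of stored codes: n x P matrix (MSB first)
code_bits <- function(codes, P) {
  bits <- matrix(0, length(codes), P)
  for (k in seq_len(P)) bits[, k] <- (codes %/% 2^(P - k)) %% 2
  bits
}

#' Histogram of a code image
#'
#' Full binning (`2^P` bins) counts every code; uniform-pattern binning
#' (`P + 2` bins) groups codes by their number of ones when the circular
#' bit string has at most two 0-1 transitions, with one shared bin for all
#' non-uniform codes. Normalised to sum 1 over valid pixels.
#'
#' @param code_img a [glpp_code_image()].
#' @param mode `"full"` or `"uniform"`.
#' @return numeric vector of bin probabilities.
#' @export
glpp_histogram <- function(code_img, mode = c("full", "uniform")) {
  mode <- match.arg(mode)
  P <- code_img$P
  codes <- code_img$codes[!is.na(code_img$codes)]
  if (mode == "full") {
    if (P > 12L) abort("full histograms are only allowed for P <= 12")
    counts <- tabulate(codes + 1, nbins = 2^P)
  } else {
    bits <- code_bits(codes, P)
    ones <- rowSums(bits)
    transitions <- rowSums(abs(bits - bits[, c(2:P, 1), drop = FALSE]))
    bin <- ifelse(transitions <= 2, ones + 1, P + 2) # 1..P+1 uniform, P+2 rest
    counts <- tabulate(bin, nbins = P + 2L)
  }
  counts / sum(counts)
}

#' Multi-scale GLPP feature vector
#'
#' Computes the fused code image for every (radius, P) of the schedule,
#' histograms it, normalises each per-scale block to sum 1 and
#' concatenates the blocks in schedule order.
#'
#' @param gray numeric intensity matrix (large enough for the biggest
#'   radius in the schedule).
#' @param config a [glpp_config()].
#' @return object of class `glpp_feature`: list with `vector` (named
#'   numeric) and `blocks` (tibble: radius, P, mode, bins).
#' @export
glpp_features <- function(gray, config = glpp_config()) {
  stopifnot(inherits(config, "glpp_config"))
  sched <- config$schedule
  blocks <- purrr::pmap(sched, function(radius, P, mode, bins) {
    ci <- glpp_code_image(gray, radius, P, config$interpolation)
    h <- glpp_histogram(ci, mode)
    names(h) <- sprintf("r%s_P%d_b%03d", format(radius), P, seq_along(h) - 1)
    h
  })
  structure(list(vector = unlist(blocks), blocks = sched),
            class = "glpp_feature")
}

#' @export
print.glpp_feature <- function(x, ...) {
  cat(sprintf("<glpp_feature> length %d over %d scales\n",
              length(x$vector), nrow(x$blocks)))
  print(x$blocks)
  invisible(x)
}

#' Grayscale channel feeding the texture descriptor
#'
#' The CIELAB lightness of the (typically stain-normalized) tile, rescaled
#' to `[0, 255]`.
#'
#' @param tile `H x W x 3` RGB array.
#' @return `H x W` numeric matrix.
#' @export
tile_lightness <- function(tile) {
  rgb_to_lab(tile)[, , 1] * 2.55
}

#' GLPP feature table for a tile set
#'
#' @param tiles a [tile_set]; @param config a [glpp_config()].
#' @param gray_fun function mapping a tile to the grayscale matrix
#'   (default [tile_lightness()]).
#' @return tibble: one row per tile (`id`, `label`, `split`, then one
#'   column per descriptor entry).
#' @export
glpp_feature_table <- function(tiles, config = glpp_config(),
                               gray_fun = tile_lightness) {
  feats <- purrr::map(tiles$tiles, function(tl) {
    glpp_features(gray_fun(tl), config)$vector
  })
  dplyr::bind_cols(tiles$manifest[, c("id", "label", "split")],
                   tibble::as_tibble(do.call(rbind, feats)))
}

#' Render a code image as a heatmap tile
#'
#' Codes are min-max scaled onto a fixed sequential colormap; invalid
#' border pixels are rendered neutral gray.
#'
#' @param code_img a [glpp_code_image()].
#' @param palette passed to [grDevices::hcl.colors()].
#' @return `H x W x 3` RGB array in `[0, 255]`.
#' @export
glpp_heatmap <- function(code_img, palette = "Inferno") {
  codes <- code_img$codes
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, palette)))
  rng <- range(codes, na.rm = TRUE)
  idx <- if (diff(rng) == 0) {
    matrix(1L, nrow(codes), ncol(codes))
  } else {
    matrix(1L + round(255 * (codes - rng[1]) / diff(rng)), nrow(codes))
  }
  out <- array(128, c(dim(codes), 3L))
  valid <- !is.na(codes)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[valid] <- pal[idx[valid], ch]
    out[, , ch] <- plane
  }
  out
}
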