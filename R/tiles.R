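#' Tile containers and image I/O
#'
#' A *tile* is a plain numeric array `H x W x 3` with intensities in
#' `[0, 255]` (row index increases downward, origin top-left; this
#' convention is binding across the whole package). A [tile_set] bundles a
#' list of tiles with a tibble manifest (one row per tile: `id`, `label`,
#' `split`) so that downstream feature tables can be joined on `id`.
#'
#' @name tiles
NULL

assert_tile <- function(x, arg = "tile") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 array (got %s)",
                  arg, paste(dim(x), collapse = "x")))
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    abort(sprintf("`%s` must contain finite intensities in [0, 255]", arg))
  }
  invisible(x)
}

#' Bundle tiles, labels and split assignments
#'
#' @param tiles list of `H x W x 3` numeric arrays in `[0, 255]`.
#' @param labels character or factor, one class label per tile.
#' @param split optional character vector (`"train"`, `"val"`, `"test"`),
#'   one entry per tile; if `NULL` the split column is `NA` until
#'   [assign_splits()] is called.
#' @param ids optional tile identifiers; defaults to `tile_0001`, ...
#' @return An object of class `tile_set`: a list with elements `tiles`
#'   (list of arrays) and `manifest` (tibble with `id`, `label`, `split`).
#' @export
tile_set <- function(tiles, labels, split = NULL, ids = NULL) {
  stopifnot(is.list(tiles), length(tiles) == length(labels))
  purrr::walk(tiles, assert_tile)
  n <- length(tiles)
  if (is.null(ids)) ids <- sprintf("tile_%04d", seq_len(n))
  if (is.null(split)) split <- rep(NA_character_, n)
  manifest <- tibble::tibble(
    id = as.character(ids),
    label = as.character(labels),
    split = as.character(split)
  )
  structure(list(tiles = tiles, manifest = manifest), class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  dims <- if (length(x$tiles)) paste(dim(x$tiles[[1]])[1:2], collapse = "x") else "-"
  cat(sprintf("<tile_set> %d tiles (%s), %d classes\n",
              length(x$tiles), dims, dplyr::n_distinct(x$manifest$label)))
  print(dplyr::count(x$manifest, .data$label, .data$split))
  invisible(x)
}

#' @export
length.tile_set <- function(x) length(x$tiles)

#' Stratified train/validation/test assignment
#'
#' Splits are drawn per class so every class keeps (up to rounding) the same
#' proportions. Fully determined by `seed`.
#'
#' @param tiles a [tile_set].
#' @param fractions numeric length-3 vector (train, val, test) summing to 1.
#' @param seed integer seed controlling the permutation.
#' @return The tile set with its manifest `split` column filled in.
#' @export
assign_splits <- function(tiles, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  man <- tiles$manifest
  split <- rep(NA_character_, nrow(man))
  with_seed_(seed, {
    for (cls in sort(unique(man$label))) {
      idx <- which(man$label == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_train <- round(fractions[1] * n)
      n_val <- min(round(fractions[2] * n), n - n_train)
      parts <- rep("test", n)
      parts[seq_len(n_train)] <- "train"
      if (n_val > 0) parts[n_train + seq_len(n_val)] <- "val"
      split[idx] <- parts
    }
  })
  tiles$manifest$split <- split
  tiles
}

#' Subset a tile set by split
#' @param tiles a [tile_set]; @param which one of `"train"`, `"val"`, `"test"`.
#' @return a [tile_set] restricted to the requested split.
#' @export
split_subset <- function(tiles, which) {
  keep <- which(tiles$manifest$split == which)
  tile_set(tiles$tiles[keep], tiles$manifest$label[keep],
           tiles$manifest$split[keep], tiles$manifest$id[keep])
}

#' Read one tile from disk
#'
#' PNG and TIFF are read natively; JPEG is read through EBImage when that
#' package is available.
#'
#' @param path image file path.
#' @return numeric `H x W x 3` array in `[0, 255]`.
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        abort("reading JPEG requires the EBImage package")
      }
      ar <- EBImage::imageData(EBImage::readImage(path))
      aperm(ar, c(2L, 1L, 3L)) # EBImage stores x,y,c
    },
    abort(sprintf("unsupported image extension '%s'", ext))
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write one tile to a PNG file
#' @param tile `H x W x 3` array in `[0, 255]`; @param path output path.
#' @export
write_tile <- function(tile, path) {
  assert_tile(tile)
  png::writePNG(tile / 255, path)
  invisible(path)
}

#' Load a one-directory-per-class image dataset
#'
#' Mirrors the common public layout (e.g. five classes ACAC, BTC, ACAL,
#' BTL, SCCL): each immediate subdirectory of `root` is a class, each
#' readable PNG/TIFF/JPEG inside becomes one tile. Files are taken in
#' lexicographic order so two loads of the same folder give identical
#' ordering; unreadable files are skipped with a warning that reports the
#' count.
#'
#' @param root dataset root directory.
#' @param class_map optional named character vector mapping folder names to
#'   label names; folders absent from the map keep their own name.
#' @return a [tile_set] (split column unassigned).
#' @export
load_dataset <- function(root, class_map = NULL) {
  if (!dir.exists(root)) abort(sprintf("dataset root '%s' does not exist", root))
  class_dirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(class_dirs)) abort(sprintf("no class folders under '%s'", root))
  tiles <- list(); labels <- character(); ids <- character()
  n_skipped <- 0L
  for (d in class_dirs) {
    folder <- basename(d)
    label <- if (!is.null(class_map) && folder %in% names(class_map)) {
      unname(class_map[[folder]])
    } else folder
    files <- sort(list.files(d, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      img <- tryCatch(read_tile(f), error = function(e) NULL)
      if (is.null(img)) {
        n_skipped <- n_skipped + 1L
        next
      }
      tiles[[length(tiles) + 1L]] <- img
      labels <- c(labels, label)
      ids <- c(ids, paste0(folder, "/", basename(f)))
    }
  }
  if (!length(tiles)) abort(sprintf("no readable images under '%s'", root))
  if (n_skipped > 0L) warn(sprintf("skipped %d unreadable file(s)", n_skipped))
  tile_set(tiles, labels, ids = ids)
}

#' Resize a tile or grayscale image
#'
#' Area averaging when the source size is an integer multiple of the target
#' (the usual case when feeding a coarser network input), bilinear
#' interpolation otherwise.
#'
#' @param img `H x W x 3` array or `H x W` matrix.
#' @param size target `c(H, W)`.
#' @return resized array/matrix of the same kind.
#' @export
resize_image <- function(img, size) {
  stopifnot(length(size) == 2L)
  if (is.matrix(img)) return(resize_plane(img, size))
  out <- array(0, c(size[1], size[2], dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- resize_plane(img[, , c], size)
  out
}

resize_plane <- function(m, size) {
  h <- nrow(m); w <- ncol(m)
  if (h == size[1] && w == size[2]) return(m)
  if (h %% size[1] == 0 && w %% size[2] == 0) {
    fy <- h %/% size[1]; fx <- w %/% size[2]
    # block mean via two matrix contractions
    ry <- matrix(0, size[1], h)
    ry[cbind(rep(seq_len(size[1]), each = fy), seq_len(h))] <- 1 / fy
    rx <- matrix(0, w, size[2])
    rx[cbind(seq_len(w), rep(seq_len(size[2]), each = fx))] <- 1 / fx
    return(ry %*% m %*% rx)
  }
  # bilinear fallback
  yi <- (seq_len(size[1]) - 0.5) * h / size[1] + 0.5
  xi <- (seq_len(size[2]) - 0.5) * w / size[2] + 0.5
  y0 <- pmin(pmax(floor(yi), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xi), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c2 <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, size[1]), 1 - wx) + b * outer(rep(1, size[1]), wx)
  bot <- c2 * outer(rep(1, size[1]), 1 - wx) + d * outer(rep(1, size[1]), wx)
  top * outer(1 - wy, rep(1, size[2])) + bot * outer(wy, rep(1, size[2]))
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG stream so
# library code never perturbs user-level randomness.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed for a named stage under a global seed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483647)
}
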