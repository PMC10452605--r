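#' Synthetic H&E-like tile generator
#'
#' Generates seeded, fully reproducible histology-like tiles so the whole
#' pipeline (stain normalization, texture descriptor, network, fused
#' classification) can be exercised without any external dataset. Each tile
#' is rendered with the Beer-Lambert law from two latent stain
#' concentration fields — elliptical "nuclei" carrying stain 1
#' (hematoxylin-like) over a smooth stromal background carrying stain 2
#' (eosin-like) — so the stain-normalization module's physical model is
#' exactly satisfiable and stain-vector estimation is a true
#' parameter-recovery problem. Classes differ along two axes: nuclear
#' density (benign low, malignant high) and intra-nucleus texture frequency
#' (adenocarcinoma-like vs squamous-like chromatin), so both the network and
#' the handcrafted-texture pathways carry class signal.
#'
#' @name synthetic
NULL

#' Parameters of one synthetic tissue class
#'
#' @param name class label.
#' @param density expected nuclei count per tile (Poisson mean).
#' @param radius_mean,radius_sd nucleus semi-major axis, pixels.
#' @param texture_freq intra-nucleus chromatin texture frequency,
#'   cycles/pixel (must stay below the Nyquist limit 0.5).
#' @param texture_amp relative amplitude of the sinusoidal texture.
#' @param nucleus_conc length-2 range of stain-1 concentration inside nuclei.
#' @param stroma_conc length-2 range of the smooth stain-2 background field.
#' @param stain_matrix 2 x 3 matrix of unit-norm stain vectors
#'   (rows: nuclear stain, stromal stain) over R, G, B optical density.
#' @param noise_sd additive Gaussian sensor noise, intensity levels.
#' @return a list of class `synthetic_class`.
#' @export
synthetic_class <- function(name, density, radius_mean = 6, radius_sd = 1,
                            texture_freq = 0.1, texture_amp = 0.35,
                            nucleus_conc = c(0.7, 1.1),
                            stroma_conc = c(0.05, 0.5),
                            stain_matrix = he_stain_matrix(),
                            noise_sd = 2) {
  stopifnot(density >= 0, radius_mean > 0, texture_freq < 0.5)
  sm <- validate_stain_matrix(stain_matrix)
  structure(list(name = name, density = density, radius_mean = radius_mean,
                 radius_sd = radius_sd, texture_freq = texture_freq,
                 texture_amp = texture_amp, nucleus_conc = nucleus_conc,
                 stroma_conc = stroma_conc, stain_matrix = sm,
                 noise_sd = noise_sd),
            class = "synthetic_class")
}

validate_stain_matrix <- function(sm) {
  sm <- as.matrix(sm)
  if (!all(dim(sm) == c(2L, 3L))) abort("invalid stain vectors: need a 2 x 3 matrix")
  norms <- sqrt(rowSums(sm^2))
  if (any(abs(norms - 1) > 1e-6)) abort("invalid stain vectors: rows must be unit-norm")
  if (abs(sum(sm[1, ] * sm[2, ])) > 1 - 1e-6) {
    abort("invalid stain vectors: rows must be linearly independent")
  }
  dimnames(sm) <- list(c("stain1", "stain2"), c("R", "G", "B"))
  sm
}

#' Canonical H&E stain vectors
#' @param rotate_deg optional in-plane rotation of the hematoxylin vector
#'   toward eosin, degrees, to emulate laboratory-to-laboratory variation.
#' @return 2 x 3 matrix with unit rows.
#' @export
he_stain_matrix <- function(rotate_deg = 0) {
  h <- c(0.65, 0.70, 0.29); e <- c(0.07, 0.99, 0.11)
  h <- h / sqrt(sum(h^2)); e <- e / sqrt(sum(e^2))
  if (rotate_deg != 0) {
    t <- rotate_deg * pi / 180
    # rotate h within span(h, e) toward e
    e_perp <- e - sum(e * h) * h
    e_perp <- e_perp / sqrt(sum(e_perp^2))
    h <- cos(t) * h + sin(t) * e_perp
  }
  validate_stain_matrix(rbind(h, e))
}

#' Default five-class parameter sets
#'
#' Mirrors the balanced five-class colon/lung layout: colon adenocarcinoma
#' (ACAC) and benign colon (BTC); lung adenocarcinoma (ACAL), benign lung
#' (BTL) and squamous carcinoma of lung (SCCL). Malignant classes are
#' nuclei-dense; squamous-like chromatin is the finest texture; colon
#' classes use a slightly rotated stain matrix to emulate a different
#' laboratory.
#'
#' @return named list of [synthetic_class()] objects.
#' @export
default_synthetic_classes <- function() {
  colon <- he_stain_matrix(6)
  lung <- he_stain_matrix(0)
  list(
    ACAC = synthetic_class("ACAC", density = 70, radius_mean = 6,
                           texture_freq = 0.12, stroma_conc = c(0.2, 0.6),
                           stain_matrix = colon),
    BTC = synthetic_class("BTC", density = 30, radius_mean = 4.5,
                          texture_freq = 0.06, stroma_conc = c(0.2, 0.6),
                          stain_matrix = colon),
    ACAL = synthetic_class("ACAL", density = 55, radius_mean = 7,
                           texture_freq = 0.18, stain_matrix = lung),
    BTL = synthetic_class("BTL", density = 14, radius_mean = 7.5,
                          texture_freq = 0.03, stain_matrix = lung),
    SCCL = synthetic_class("SCCL", density = 65, radius_mean = 8,
                           texture_freq = 0.30, stain_matrix = lung)
  )
}

#' Specification of a synthetic dataset
#'
#' @param n_per_class tiles generated per class.
#' @param classes named list of [synthetic_class()] objects.
#' @param tile_size tile side, pixels (square tiles).
#' @param split_fractions train/val/test fractions, summing to 1.
#' @param seed integer; the same spec with the same seed yields a
#'   byte-identical dataset.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 60,
                           classes = default_synthetic_classes(),
                           tile_size = 128,
                           split_fractions = c(0.7, 0.15, 0.15),
                           seed = 1L) {
  stopifnot(n_per_class >= 0, tile_size >= 16)
  purrr::walk(classes, function(cl) stopifnot(inherits(cl, "synthetic_class")))
  structure(list(n_per_class = n_per_class, classes = classes,
                 tile_size = tile_size, split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return a [tile_set] with stratified splits assigned; the manifest
#'   carries an extra `n_nuclei` column with the realised nucleus count of
#'   each tile (ground truth for density checks).
#' @export
generate_tiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tiles <- list(); labels <- character(); n_nuclei <- integer()
  with_seed_(spec$seed, {
    for (cls in spec$classes) {
      for (i in seq_len(spec$n_per_class)) {
        tl <- render_tile(cls, spec$tile_size)
        tiles[[length(tiles) + 1L]] <- tl$tile
        labels <- c(labels, cls$name)
        n_nuclei <- c(n_nuclei, tl$n_nuclei)
      }
    }
  })
  ts <- tile_set(tiles, labels)
  ts$manifest$n_nuclei <- n_nuclei
  assign_splits(ts, spec$split_fractions, seed = child_seed(spec$seed, "split"))
}

# Render one tile: Poisson-count elliptical nuclei with sinusoidal
# chromatin texture on a smooth stromal field, Beer-Lambert reconstruction,
# additive sensor noise.  Runs inside the caller's seeded RNG scope.
render_tile <- function(cls, size, i0 = 255, eps = 1) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index

  # smooth stromal stain-2 field: sum of low-frequency sinusoids
  f1 <- runif(1, 0.5, 1.5) / size; f2 <- runif(1, 0.5, 1.5) / size
  ph1 <- runif(2, 0, 2 * pi)
  field <- sin(2 * pi * f1 * xs + ph1[1]) * sin(2 * pi * f2 * ys + ph1[2])
  lo <- cls$stroma_conc[1]; hi <- cls$stroma_conc[2]
  c2 <- lo + (hi - lo) * (field + 1) / 2
  c1 <- matrix(0.01, size, size)

  n <- rpois(1, cls$density)
  for (k in seq_len(n)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    a <- max(2, rnorm(1, cls$radius_mean, cls$radius_sd))
    b <- a * runif(1, 0.6, 1)
    th <- runif(1, 0, pi)
    level <- runif(1, cls$nucleus_conc[1], cls$nucleus_conc[2])
    tdir <- runif(1, 0, pi); tph <- runif(1, 0, 2 * pi)
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- (u^2 + v^2) <= 1
    if (!any(inside)) next
    tex <- 1 + cls$texture_amp *
      sin(2 * pi * cls$texture_freq * (dx * cos(tdir) + dy * sin(tdir)) + tph)
    c1[inside] <- pmax(c1[inside], level * tex[inside])
    c2[inside] <- c2[inside] * 0.2
  }

  od <- cbind(as.vector(c1), as.vector(c2)) %*% cls$stain_matrix
  ints <- (i0 + eps) * 10^(-od) - eps
  ints <- ints + rnorm(length(ints), 0, cls$noise_sd)
  tile <- array(round(pmin(pmax(ints, 0), 255)), c(size, size, 3L))
  list(tile = tile, n_nuclei = n)
}

#' Ground-truth stain vectors of a synthetic spec
#'
#' Oracle for stain-recovery tests: the exact stain matrices used in
#' rendering, per class. Determined entirely by the spec (independent of
#' the seed).
#'
#' @param spec a [synthetic_spec()].
#' @return named list of 2 x 3 unit-row matrices.
#' @export
ground_truth_stains <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  purrr::map(spec$classes, "stain_matrix")
}

#' Write a synthetic dataset to disk
#'
#' Writes PNG tiles into one-directory-per-class layout (the same layout
#' [load_dataset()] reads) plus a `manifest.csv` with filename, class,
#' split and the generator's per-tile nucleus count.
#'
#' @param spec a [synthetic_spec()]; @param dir output directory.
#' @return the manifest tibble, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  ts <- generate_tiles(spec)
  man <- ts$manifest
  man$filename <- file.path(man$label, paste0(man$id, ".png"))
  for (cls in unique(man$label)) {
    dir.create(file.path(dir, cls), recursive = TRUE, showWarnings = FALSE)
  }
  purrr::walk2(ts$tiles, man$filename,
               function(tl, fn) write_tile(tl, file.path(dir, fn)))
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(man)
}
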