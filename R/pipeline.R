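#' End-to-end pipeline: normalize -> texture -> train -> fuse -> classify
#'
#' [run_pipeline()] executes the enabled stages in order on either a
#' directory dataset or the synthetic generator, writing every artifact
#' (config echo, feature CSVs, model checkpoint, evaluation reports, a
#' line-delimited JSON log) under one run directory. A single global seed
#' derives per-stage child seeds, so stages are independently reproducible
#' and two identical runs produce byte-identical feature CSVs and reports.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param stages character subset of
#'   `c("normalize", "glpp", "train", "evaluate")`, executed in this order.
#' @param data_dir directory dataset root ([load_dataset()] layout); when
#'   `NULL` the synthetic generator supplies the data.
#' @param synthetic a [synthetic_spec()] used when `data_dir` is `NULL`.
#' @param stain a [stain_norm_config()]; @param glpp a [glpp_config()].
#' @param train a [train_config()].
#' @param classifiers character vector among `"svm"`, `"knn"`, `"tree"`.
#' @param seed global seed; every stage derives a child seed from it.
#' @param write_tiles write normalized tiles as PNGs (off by default).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("normalize", "glpp", "train", "evaluate"),
                            data_dir = NULL,
                            synthetic = synthetic_spec(),
                            stain = stain_norm_config(),
                            glpp = glpp_config(),
                            train = train_config(),
                            classifiers = "svm",
                            seed = 1L,
                            write_tiles = FALSE) {
  stopifnot(all(stages %in% c("normalize", "glpp", "train", "evaluate")),
            all(classifiers %in% c("svm", "knn", "tree")))
  structure(list(stages = stages, data_dir = data_dir, synthetic = synthetic,
                 stain = stain, glpp = glpp, train = train,
                 classifiers = classifiers, seed = as.integer(seed),
                 write_tiles = write_tiles),
            class = "pipeline_config")
}

log_line <- function(con, stage, msg, ...) {
  rec <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              stage = stage, msg = msg, ...)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory; created (timestamped subdirectory of
#'   `tempdir()` when `NULL`). An existing completed run directory is not
#'   overwritten unless `overwrite = TRUE`.
#' @param overwrite allow re-running into an existing run directory.
#' @return (invisibly) a list with `dir`, the loaded `tiles`, `model`,
#'   `features`, and `reports` (named list of `eval_report`s); all also
#'   written under `dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(),
                         format(Sys.time(), "histofuse_run_%Y%m%d_%H%M%S"))
  }
  if (file.exists(file.path(out_dir, "config.yaml")) && !overwrite) {
    abort(sprintf("run directory '%s' already holds a run; use overwrite = TRUE",
                  out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  log_con <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  run_stage <- function(stage, expr) {
    log_line(log_con, stage, "start")
    out <- tryCatch(expr, error = function(e) {
      log_line(log_con, stage, paste("error:", conditionMessage(e)))
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    log_line(log_con, stage, "done")
    out
  }

  tiles <- run_stage("data", {
    if (is.null(config$data_dir)) {
      spec <- config$synthetic
      spec$seed <- child_seed(config$seed, "synth")
      generate_tiles(spec)
    } else {
      assign_splits(load_dataset(config$data_dir),
                    seed = child_seed(config$seed, "split"))
    }
  })
  readr::write_csv(tiles$manifest, file.path(out_dir, "manifest.csv"))

  ref_profile <- NULL
  if ("normalize" %in% config$stages) {
    tiles <- run_stage("normalize", {
      ref_idx <- which(tiles$manifest$split == "train")[1]
      ref_profile <- estimate_stain_profile(tiles$tiles[[ref_idx]],
                                             config = config$stain)
      write_stain_profile(ref_profile, file.path(out_dir, "reference_stain.json"))
      tiles$tiles <- purrr::map(tiles$tiles, normalize_to_reference,
                                ref_profile = ref_profile,
                                config = config$stain)
      if (config$write_tiles) {
        tdir <- file.path(out_dir, "normalized")
        for (cls in unique(tiles$manifest$label)) {
          dir.create(file.path(tdir, cls), recursive = TRUE, showWarnings = FALSE)
        }
        purrr::walk2(tiles$tiles,
                     file.path(tdir, tiles$manifest$label,
                               paste0(tiles$manifest$id, ".png")),
                     write_tile)
      }
      tiles
    })
  }

  glpp_tbl <- NULL
  if ("glpp" %in% config$stages) {
    glpp_tbl <- run_stage("glpp", glpp_feature_table(tiles, config$glpp))
    readr::write_csv(glpp_tbl, file.path(out_dir, "features_glpp.csv"))
  }

  model <- NULL
  if ("train" %in% config$stages) {
    model <- run_stage("train", {
      d <- if (is.null(glpp_tbl)) 0L else length(feature_cols(glpp_tbl))
      spec <- network_spec(
        input_size = c(dim(tiles$tiles[[1]])[1:2], 3),
        glpp_dim = d,
        n_classes = dplyr::n_distinct(tiles$manifest$label)
      )
      cfg <- config$train
      cfg$seed <- child_seed(config$seed, "train")
      m <- train_network(spec, tiles, glpp_tbl, cfg)
      readr::write_csv(m$history, file.path(out_dir, "history.csv"))
      save_model(m, file.path(out_dir, "model.rds"))
      m
    })
  }

  features <- NULL; reports <- list()
  if ("evaluate" %in% config$stages) {
    reports <- run_stage("evaluate", {
      if (is.null(model)) abort("evaluate stage requires the train stage")
      features <- extract_fused_features(model, tiles, glpp_tbl)
      readr::write_csv(features, file.path(out_dir, "features_fused.csv"))
      tr <- dplyr::filter(features, .data$split == "train")
      out <- list()
      for (kind in config$classifiers) {
        clf <- fit_classifier(tr, kind = kind,
                              seed = child_seed(config$seed, kind))
        for (sp in c("val", "test")) {
          sub <- dplyr::filter(features, .data$split == sp)
          if (!nrow(sub)) next
          rep <- evaluate_classifier(clf, sub)
          nm <- paste(kind, sp, sep = "_")
          out[[nm]] <- rep
          write_eval_report(rep, file.path(out_dir, paste0("report_", nm, ".json")))
          readr::write_csv(tidy(rep),
                           file.path(out_dir, paste0("report_", nm, ".csv")))
        }
      }
      summary_tbl <- purrr::imap_dfr(out, function(rep, nm) {
        dplyr::bind_cols(tibble::tibble(run = nm), glance(rep))
      })
      readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"))
      out
    })
  }

  invisible(list(dir = out_dir, tiles = tiles, model = model,
                 features = features, reports = reports,
                 ref_profile = ref_profile))
}

## ---- config serialization --------------------------------------------------

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is exact: `read_pipeline_config(write_pipeline_config(x))`
#' reconstructs a configuration equal to `x`.
#'
#' @param config a [pipeline_config()]; @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  obj <- list(
    stages = as.list(config$stages),
    data_dir = config$data_dir,
    synthetic = list(
      n_per_class = syn$n_per_class,
      tile_size = syn$tile_size,
      split_fractions = syn$split_fractions,
      seed = syn$seed,
      classes = purrr::map(syn$classes, function(cl) {
        u <- unclass(cl)
        u$stain_matrix <- as.vector(t(cl$stain_matrix))
        u
      })
    ),
    stain = unclass(config$stain),
    glpp = list(
      schedule = purrr::pmap(config$glpp$schedule[, c("radius", "P")], c),
      interpolation = config$glpp$interpolation,
      histogram_mode = config$glpp$histogram_mode
    ),
    train = unclass(config$train),
    classifiers = as.list(config$classifiers),
    seed = config$seed,
    write_tiles = config$write_tiles
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  classes <- purrr::map(obj$synthetic$classes, function(cl) {
    cl$stain_matrix <- matrix(as.numeric(cl$stain_matrix), 2L, 3L, byrow = TRUE)
    do.call(synthetic_class, cl)
  })
  pipeline_config(
    stages = unlist(obj$stages),
    data_dir = obj$data_dir,
    synthetic = synthetic_spec(
      n_per_class = obj$synthetic$n_per_class,
      classes = classes,
      tile_size = obj$synthetic$tile_size,
      split_fractions = unlist(obj$synthetic$split_fractions),
      seed = obj$synthetic$seed
    ),
    stain = do.call(stain_norm_config, obj$stain),
    glpp = glpp_config(
      schedule = purrr::map(obj$glpp$schedule, unlist),
      interpolation = obj$glpp$interpolation,
      histogram_mode = obj$glpp$histogram_mode
    ),
    train = do.call(train_config, obj$train),
    classifiers = unlist(obj$classifiers),
    seed = obj$seed,
    write_tiles = obj$write_tiles
  )
}

#' Training-history curves
#' @param object a `histofuse_model` with a history; @param ... unused.
#' @return a ggplot object with loss and accuracy panels over epochs.
#' @export
autoplot.histofuse_model <- function(object, ...) {
  stopifnot(!is.null(object$history))
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = c("split", "metric"),
                              names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
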