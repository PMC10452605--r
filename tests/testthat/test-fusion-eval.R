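gaussian_features <- function(n_per_class, centers, sd = 0.6, seed = 50,
                              split = TRUE) {
  withr::with_seed(seed, {
    rows <- purrr::imap(centers, function(mu, cls) {
      m <- matrix(rnorm(n_per_class * length(mu), sd = sd), n_per_class,
                  byrow = TRUE) + matrix(mu, n_per_class, length(mu), byrow = TRUE)
      colnames(m) <- sprintf("f%02d", seq_along(mu))
      dplyr::bind_cols(tibble::tibble(id = sprintf("%s_%02d", cls, seq_len(n_per_class)),
                                      label = cls), tibble::as_tibble(m))
    })
    tbl <- dplyr::bind_rows(rows)
    if (split) {
      tbl$split <- rep(c("train", "test"),
                       length.out = nrow(tbl))
    }
    tbl
  })
}

test_that("all three classifier kinds separate well-separated clusters", {
  feats <- gaussian_features(12, list(a = c(0, 0), b = c(8, 8)), sd = 0.3)
  for (kind in c("svm", "knn", "tree")) {
    clf <- fit_classifier(feats, kind = kind, seed = 2)
    rep <- evaluate_classifier(clf, feats)
    expect_equal(rep$accuracy, 1.0)
  }
})

test_that("1-nearest-neighbour memorises duplicate-free training data", {
  feats <- gaussian_features(10, list(a = c(0, 0), b = c(1.5, 0), c = c(0, 1.5)),
                             sd = 0.4, seed = 51)
  clf <- fit_classifier(feats, kind = "knn", k = 1)
  rep <- evaluate_classifier(clf, feats)
  expect_equal(rep$accuracy, 1.0)
})

test_that("single-class input is rejected", {
  feats <- gaussian_features(6, list(only = c(0, 0)))
  expect_error(fit_classifier(feats), "2 classes")
})

test_that("five-class Gaussian fused features beat chance on held-out data", {
  centers <- purrr::map(1:5, function(i) {
    mu <- numeric(10); mu[i] <- 2.5; mu[10] <- i / 2
    mu
  })
  names(centers) <- paste0("c", 1:5)
  feats <- gaussian_features(20, centers, sd = 1, seed = 52)
  clf <- fit_classifier(dplyr::filter(feats, split == "train"), kind = "svm",
                        seed = 3)
  rep <- evaluate_classifier(clf, dplyr::filter(feats, split == "test"))
  expect_gt(rep$macro$f1, 0.2)
})

test_that("metric suite matches hand computation from the definitions", {
  # binary confusion TP=50, FN=10, FP=5, TN=35 for class "pos"
  truth <- factor(c(rep("pos", 60), rep("neg", 40)), levels = c("neg", "pos"))
  predicted <- factor(c(rep("pos", 50), rep("neg", 10),
                        rep("pos", 5), rep("neg", 35)), levels = c("neg", "pos"))
  rep <- eval_report(truth, predicted)
  row <- dplyr::filter(rep$per_class, class == "pos")
  expect_equal(row$sensitivity, 50 / 60)
  expect_equal(row$specificity, 35 / 40)
  expect_equal(row$precision, 50 / 55)
  p <- 50 / 55; r <- 50 / 60
  expect_equal(row$f1, 2 * p * r / (p + r))
  expect_equal(rep$accuracy, 85 / 100)
  expect_equal(sum(rep$confusion), 100)

  # perfect predictions
  perf <- eval_report(truth, truth,
                      prob = cbind(neg = as.numeric(truth == "neg"),
                                   pos = as.numeric(truth == "pos")))
  expect_true(all(perf$per_class$sensitivity == 1))
  expect_true(all(perf$per_class$precision == 1))
  expect_true(all(perf$per_class$auc == 1))
  expect_equal(sum(perf$confusion) - sum(diag(perf$confusion)), 0)
})

test_that("metric identities hold on random confusions", {
  set.seed(53)
  for (rep_i in 1:10) {
    n <- 60
    lev <- c("a", "b", "c")
    truth <- factor(sample(lev, n, replace = TRUE), levels = lev)
    predicted <- factor(sample(lev, n, replace = TRUE), levels = lev)
    er <- eval_report(truth, predicted)
    expect_equal(er$accuracy, sum(diag(er$confusion)) / n)
    f1 <- er$per_class$f1[er$per_class$support > 0]
    expect_gte(er$macro$f1, min(f1))
    expect_lte(er$macro$f1, max(f1))
    expect_true(all(dplyr::select(er$per_class, sensitivity:f1) >= 0 &
                      dplyr::select(er$per_class, sensitivity:f1) <= 1,
                    na.rm = TRUE))
  }
})

test_that("trapezoidal AUC equals pairwise concordance (and pROC)", {
  # 4-point toy set
  scores <- c(0.9, 0.4, 0.35, 0.1)
  positive <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(scores, positive),
               oracle_auc_concordance(scores, positive))

  set.seed(54)
  for (rep_i in 1:20) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), 2) # ties likely
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(positive) || all(positive)) next
    got <- roc_auc(scores, positive)
    expect_equal(got, oracle_auc_concordance(scores, positive))
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(got,
                   as.numeric(pROC::auc(pROC::roc(positive, scores,
                                                  quiet = TRUE,
                                                  direction = "<"))))
    }
  }
})

test_that("evaluation reports survive a JSON round trip", {
  truth <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
  predicted <- factor(sample(c("a", "b", "c"), 30, replace = TRUE),
                      levels = levels(truth))
  set.seed(55)
  prob <- matrix(runif(90), 30, 3, dimnames = list(NULL, levels(truth)))
  prob <- prob / rowSums(prob)
  er <- eval_report(truth, predicted, prob)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(er, path)
  er2 <- read_eval_report(path)
  expect_equal(unclass(er2$confusion), unclass(er$confusion),
               ignore_attr = FALSE)
  expect_equal(er2$per_class, er$per_class)
  expect_equal(er2$macro, er$macro)
})

test_that("classes absent from the labels are excluded from macro averages", {
  truth <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "ghost"))
  predicted <- factor(c("a", "b", "b", "b"), levels = levels(truth))
  er <- eval_report(truth, predicted)
  ghost <- dplyr::filter(er$per_class, class == "ghost")
  expect_true(is.na(ghost$sensitivity))
  expect_equal(er$macro$f1,
               mean(dplyr::filter(er$per_class, class != "ghost")$f1))
})

texture_contrast_tiles <- function(seed = 606) {
  # classes identical in density, size and stain; they differ only in a
  # fine chromatin frequency that block-averaging to the network input
  # resolution erases
  mk <- function(f) {
    synthetic_class(paste0("t", f), density = 50, radius_mean = 9,
                    radius_sd = 0.5, texture_freq = f, texture_amp = 0.5)
  }
  classes <- list(t1 = mk(0.12), t2 = mk(0.28), t3 = mk(0.44))
  generate_tiles(synthetic_spec(n_per_class = 30, classes = classes,
                                tile_size = 96, split_fractions = c(0.5, 0.25, 0.25),
                                seed = seed))
}

test_that("ablation: texture-only features beat the coarse network, fusion keeps the best", {
  ts <- texture_contrast_tiles()
  spec <- network_spec(input_size = c(32, 32, 3),
                       blocks = default_blocks(3), glpp_dim = 1L, n_classes = 3L)
  res <- ablation_compare(
    ts,
    glpp_cfg = glpp_config(schedule = list(c(1, 8))),
    net_spec = spec,
    train_cfg = train_config(epochs = 2, batch_size = 8, seed = 7),
    classifier = "svm"
  )
  expect_equal(nrow(res$table), 6)
  tab <- dplyr::filter(res$table, split == "test")
  f1_of <- function(cfg) tab$f1[tab$configuration == cfg]
  expect_gt(f1_of("glpp_only"), f1_of("cnn_only"))
  expect_gte(f1_of("fused") + 1e-9, f1_of("glpp_only"))
  expect_gte(f1_of("fused") + 1e-9, f1_of("cnn_only"))

  # shared-split contract: identical ids and splits across configurations
  for (cfg in c("cnn_only", "glpp_only")) {
    expect_identical(res$features[[cfg]][, c("id", "split")],
                     res$features$fused[, c("id", "split")])
  }
})
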