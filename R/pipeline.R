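#' Backend training settings
#'
#' Desk-scale training settings for one reference backend instance. Several
#' instances with different names (and therefore different derived seeds)
#' form the ensemble.
#'
#' @param name Backend name.
#' @param steps,batch_size,learning_rate,feature_size See
#'   [softmax_classifier()].
#' @return A list of class `backend_config`.
#' @export
backend_config <- function(name, steps = 150, batch_size = 24,
                           learning_rate = 0.08, feature_size = 12) {
  structure(list(name = name, steps = steps, batch_size = batch_size,
                 learning_rate = learning_rate, feature_size = feature_size),
            class = "backend_config")
}

#' Registry of heavyweight convolutional backends
#'
#' The six published architectures commonly benchmarked on camera-trap
#' classification, with the training schedule they are conventionally run
#' under (ImageNet transfer learning, Adam, 500 epochs). These entries are
#' configuration defaults for users wiring the pipeline to a deep-learning
#' backend of their own; the package does not implement or ship the networks
#' themselves, and all packaged experiments run on the reference backend.
#'
#' @return Named list of configuration stubs.
#' @export
heavy_backend_defaults <- function() {
  nets <- c("DenseNet201", "Inception-ResNet-V2", "InceptionV3",
            "NASNetMobile", "MobileNetV2", "Xception")
  setNames(lapply(nets, function(n) {
    list(name = n, optimizer = "adam", epochs = 500,
         transfer_learning = "imagenet", implemented = FALSE)
  }), nets)
}

#' Experiment configuration
#'
#' Bundles everything one end-to-end run needs: the data source (a synthetic
#' world config, a manifest path, or an in-memory catalog), the split
#' protocol and its parameters, the rebalancing/supplementation settings,
#' the augmentation settings, the backend roster, and explicit seeds for
#' every source of randomness. All derived seeds are resolved at
#' construction and embedded in every report, so a report fully describes
#' how to reproduce itself.
#'
#' @param world A [synthetic_world_config()], or `NULL`.
#' @param manifest Path to a manifest CSV, or `NULL`.
#' @param catalog A prebuilt [catalog()], or `NULL`. Exactly one of `world`,
#'   `manifest`, `catalog` must be given.
#' @param protocol `"trained_location"` or `"untrained_location"`.
#' @param test_fraction Held-out fraction for the trained-location protocol
#'   (default 0.10).
#' @param k Fold count for the untrained-location protocol (default 5).
#' @param min_count Per-class supplementation floor (default 100); `0`
#'   disables supplementation.
#' @param backends List of [backend_config()]s; default three reference
#'   backends (`ref_a`, `ref_b`, `ref_c`).
#' @param max_redraws Rebalancing sampler cap.
#' @param augment_cfg An [augmentation_config()] for training-time
#'   augmentation and supplementation, or `NULL` to disable augmentation.
#' @param seed Master seed from which the split/sampler/model/augmentation
#'   seeds are derived (individually overridable through `seeds`).
#' @param seeds Optional named list overriding any of `split`, `sampler`,
#'   `model`, `augment`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(world = NULL, manifest = NULL, catalog = NULL,
                              protocol = c("trained_location", "untrained_location"),
                              test_fraction = 0.10, k = 5, min_count = 100,
                              backends = NULL, max_redraws = 10,
                              augment_cfg = augmentation_config(),
                              seed = 1, seeds = NULL) {
  protocol <- match.arg(protocol)
  n_src <- sum(!is.null(world), !is.null(manifest), !is.null(catalog))
  if (n_src != 1) {
    stop("give exactly one of `world`, `manifest`, `catalog`", call. = FALSE)
  }
  if (is.null(backends)) {
    backends <- lapply(c("ref_a", "ref_b", "ref_c"), backend_config)
  }
  resolved_seeds <- list(
    split = derive_seed(seed, "split"),
    sampler = derive_seed(seed, "sampler"),
    model = derive_seed(seed, "model"),
    augment = derive_seed(seed, "augment")
  )
  if (!is.null(seeds)) resolved_seeds[names(seeds)] <- seeds
  structure(
    list(world = world, manifest = manifest, catalog = catalog,
         protocol = protocol, test_fraction = test_fraction, k = k,
         min_count = min_count, backends = backends,
         max_redraws = max_redraws, augment_cfg = augment_cfg,
         seed = seed, seeds = resolved_seeds),
    class = "experiment_config"
  )
}

resolve_catalog <- function(config) {
  if (!is.null(config$catalog)) return(config$catalog)
  if (!is.null(config$world)) return(generate_world(config$world))
  load_manifest(config$manifest)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Train all configured backends on one training catalog and evaluate them
# (plus their voting ensemble) on one test catalog.
evaluate_split <- function(config, full_cat, train_ids, test_ids, stage_seed) {
  if (length(intersect(train_ids, test_ids)) > 0) {
    stop("internal leakage guard: train and test ids overlap", call. = FALSE)
  }
  train_cat <- subset_catalog(full_cat, train_ids)
  test_cat <- subset_catalog(full_cat, test_ids)
  if (any(test_cat$records$is_augmented)) {
    stop("internal leakage guard: augmented record in test set", call. = FALSE)
  }
  if (config$min_count > 0) {
    train_cat <- supplement_to_minimum(
      train_cat, min_count = config$min_count,
      augment_config = config$augment_cfg %||% augmentation_config(),
      seed = derive_seed(config$seeds$sampler, "supplement", stage_seed)
    )
  }
  ratios <- compute_class_ratios(class_counts(train_cat))
  label_order <- unique(c(full_cat$classes, train_cat$classes))
  truth <- test_cat$records$class_label

  probas <- list()
  per_model <- list()
  recall_tbl <- NULL
  train_counts_all <- setNames(rep(0L, length(label_order)), label_order)
  cc <- class_counts(train_cat)
  train_counts_all[names(cc)] <- cc

  for (bk in config$backends) {
    fit <- softmax_classifier(
      train_cat, ratios = ratios, augment_cfg = config$augment_cfg,
      steps = bk$steps, batch_size = bk$batch_size,
      learning_rate = bk$learning_rate, feature_size = bk$feature_size,
      max_redraws = config$max_redraws,
      seed = derive_seed(config$seeds$model, bk$name, stage_seed),
      name = bk$name
    )
    P <- predict(fit, test_cat, type = "prob")
    probas[[bk$name]] <- P
    pred <- predict_top1_from_proba(P, fit$class_labels)
    cm <- confusion(truth, pred, label_order)
    per_model[[bk$name]] <- metrics_report(cm)
    tbl <- per_class_recall_table(cm, train_counts_all, model_name = bk$name)
    recall_tbl <- if (is.null(recall_tbl)) tbl else {
      recall_tbl[[bk$name]] <- tbl[[bk$name]]
      attr(recall_tbl, "models") <- c(attr(recall_tbl, "models"), bk$name)
      recall_tbl
    }
  }

  if (length(probas) >= 2) {
    ens <- ensemble_vote(probas, class_labels = train_cat$classes)
    ens_pred <- ens$winner
  } else {
    # a one-model "ensemble" is just that model
    ens_pred <- predict_top1_from_proba(probas[[1]], train_cat$classes)
  }
  cm_ens <- confusion(truth, ens_pred, label_order)
  ens_report <- metrics_report(cm_ens)
  tbl <- per_class_recall_table(cm_ens, train_counts_all, model_name = "ensemble")
  recall_tbl$ensemble <- tbl$ensemble
  attr(recall_tbl, "models") <- c(attr(recall_tbl, "models"), "ensemble")

  list(per_model = per_model, ensemble = ens_report, recall_table = recall_tbl,
       n_train = length(train_ids), n_test = length(test_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the trained-location experiment
#'
#' End to end: resolve the catalog, draw the seeded random image-level
#' split, supplement rare classes on the training side, fit every configured
#' backend on the rebalanced (and optionally augmented) training stream,
#' evaluate each backend and their voting ensemble on the held-out images,
#' and assemble per-model metrics plus a per-class recall table.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`.
#' @export
run_trained_location <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  full_cat <- resolve_catalog(config)
  split <- trained_location_split(full_cat, config$test_fraction,
                                  seed = config$seeds$split)
  res <- evaluate_split(config, full_cat, split$train_ids, split$test_ids,
                        stage_seed = 0L)
  structure(
    c(list(protocol = "trained_location", seeds = config$seeds,
           test_fraction = config$test_fraction,
           min_count = config$min_count,
           backend_names = vapply(config$backends, `[[`, "", "name")),
      res),
    class = "experiment_report"
  )
}

#' Run the untrained-location (location-blocked k-fold) experiment
#'
#' Builds the contiguous location-blocked fold plan, then trains and
#' evaluates every backend independently within each fold - training data
#' never contain images from the fold's test locations, which the runtime
#' leakage guard re-checks. Accuracy and macro F1 are aggregated across
#' folds as mean and population SD.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report` with a `folds` element
#'   (one entry per fold) and an `aggregate` element (per-model and ensemble
#'   mean +/- SD).
#' @export
run_untrained_location <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  full_cat <- resolve_catalog(config)
  plan <- location_kfold_plan(full_cat$locations, config$k)
  folds <- vector("list", plan$k)
  for (i in seq_len(plan$k)) {
    split <- materialize_fold(full_cat, plan, i)
    if (!verify_no_location_leakage(split, full_cat)) {
      stop(sprintf("location leakage detected in fold %d", i), call. = FALSE)
    }
    folds[[i]] <- evaluate_split(config, full_cat, split$train_ids,
                                 split$test_ids, stage_seed = i)
    folds[[i]]$test_locations <- plan$folds[[i]]$test_locations
  }
  model_names <- c(vapply(config$backends, `[[`, "", "name"), "ensemble")
  aggregate <- lapply(setNames(model_names, model_names), function(mn) {
    acc <- vapply(folds, function(f) {
      r <- if (mn == "ensemble") f$ensemble else f$per_model[[mn]]
      r$top1_accuracy
    }, numeric(1))
    f1 <- vapply(folds, function(f) {
      r <- if (mn == "ensemble") f$ensemble else f$per_model[[mn]]
      r$macro_f1
    }, numeric(1))
    list(accuracy_mean = mean(acc), accuracy_sd = pop_sd(acc),
         macro_f1_mean = mean(f1), macro_f1_sd = pop_sd(f1),
         fold_accuracy = acc, fold_macro_f1 = f1)
  })
  structure(
    list(protocol = "untrained_location", seeds = config$seeds,
         k = plan$k, min_count = config$min_count,
         backend_names = vapply(config$backends, `[[`, "", "name"),
         folds = folds, aggregate = aggregate),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment report: %s>\n", x$protocol))
  if (x$protocol == "trained_location") {
    for (mn in names(x$per_model)) {
      r <- x$per_model[[mn]]
      cat(sprintf("  %-10s accuracy %.3f  macro F1 %.3f\n",
                  mn, r$top1_accuracy, r$macro_f1))
    }
    cat(sprintf("  %-10s accuracy %.3f  macro F1 %.3f\n",
                "ensemble", x$ensemble$top1_accuracy, x$ensemble$macro_f1))
  } else {
    for (mn in names(x$aggregate)) {
      a <- x$aggregate[[mn]]
      cat(sprintf("  %-10s accuracy %.3f +/- %.3f  macro F1 %.3f +/- %.3f\n",
                  mn, a$accuracy_mean, a$accuracy_sd,
                  a$macro_f1_mean, a$macro_f1_sd))
    }
  }
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes a plain-JSON rendition of the report (metrics, per-class tables,
#' seeds, settings); identical configurations and seeds produce
#' byte-identical files.
#'
#' @param report An `experiment_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_report_json <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  strip <- function(x) {
    if (inherits(x, "metrics_report")) {
      list(top1_accuracy = x$top1_accuracy, macro_f1 = x$macro_f1,
           n_images = x$n_images, per_class = x$per_class)
    } else if (is.data.frame(x)) {
      as.data.frame(x)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a configuration file (YAML or JSON)
#'
#' Reads a plain list of settings; JSON is detected by file extension,
#' anything else is parsed as YAML. Used by the command-line driver to build
#' [synthetic_world_config()] and [experiment_config()] objects from files.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
load_config_list <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
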