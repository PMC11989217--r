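#' End-to-end held-out-class experiment on synthetic leaves
#'
#' Runs the full pipeline under one seed: generate a synthetic withering
#' dataset, hold out whole classes as an external test set, train the
#' mini-profile classifier on the remaining classes, predict moisture for the
#' held-out images via confidence weighting, and evaluate with Rp / RMSEP /
#' RPD (SD taken over the training labels). With the defaults (13 classes,
#' classes 1/5/9 held out) the training set carries exactly the ten reference
#' moisture labels, and the held-out labels are moisture values the model
#' never saw — the interpolation setting the confidence-weighted method is
#' designed for.
#'
#' @param seed Integer master seed; generator, weight initialization and
#'   shuffling use `seed`, `seed + 1`, `seed + 2`.
#' @param n_classes Total synthetic classes (default 13).
#' @param held_classes Class indices held out (default `c(1, 5, 9)`).
#' @param images_per_class Images per class (default 40).
#' @param image_size Image side in pixels (default 64).
#' @param epochs,lr,batch_size Training settings (defaults 30 / 0.01 / 16).
#' @param verbose Print training progress.
#' @return A `tea_experiment` list: `model`, `assessments` (held-out
#'   predictions), `metrics` (overall) and `metrics_by_class`.
#' @export
run_withering_experiment <- function(seed = 1L, n_classes = 13L,
                                     held_classes = c(1L, 5L, 9L),
                                     images_per_class = 40L, image_size = 64L,
                                     epochs = 30L, lr = 0.01,
                                     batch_size = 16L, verbose = FALSE) {
  seed <- as.integer(seed)
  cfg <- synthetic_config(n_classes = n_classes,
                          images_per_class = images_per_class,
                          image_size = image_size, seed = seed)
  data <- generate_leaf_images(cfg)
  sp <- holdout_split(data, held_classes)
  n_train_classes <- n_classes - length(unique(held_classes))
  plan <- mini_profile_plan(n_train_classes)
  model <- build_classifier(plan, seed = seed + 1L)
  model <- train_classifier(model, sp$train, epochs = epochs, lr = lr,
                            batch_size = batch_size, seed = seed + 2L,
                            verbose = verbose)
  assessments <- assess_samples(sp$external, model)
  ref <- model$label_table$moisture
  overall <- moisture_metrics(assessments, .data$moisture,
                              .data$predicted_moisture,
                              reference_labels = ref)
  by_class <- moisture_metrics(assessments, .data$moisture,
                               .data$predicted_moisture,
                               reference_labels = ref,
                               group = .data$class_index)
  structure(list(model = model, assessments = assessments,
                 metrics = overall, metrics_by_class = by_class,
                 seed = seed),
            class = "tea_experiment")
}

#' @export
print.tea_experiment <- function(x, ...) {
  cat(sprintf("<tea_experiment: seed %d, %d held-out images>\n",
              x$seed, nrow(x$assessments)))
  print(x$metrics)
  invisible(x)
}
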