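# Named ablation presets and the ablation-grid runner: train each
# preset x seed on a phantom benchmark, evaluate DSC/ASD/HD95 on the
# test split under both MRI+CT and CT-only inference.

#' Ablation presets
#'
#' Named training configurations spanning the ablation grid: the
#' single-encoder baseline (`snet-*`, stacked 2-channel input), the
#' dual-encoder modality-attention model (`snetma-*`), each with Dice
#' loss alone (`-dsc`) or Dice + muscle/bone inclusion losses (`-mb`),
#' plus the input-regime variants: `mrict` (no modality dropout),
#' `modo` (dropout p = 0.5) and `ct-only` (MRI always dropped).
#'
#' @param name preset name.
#' @return list of [sunet()] arguments.
#' @export
ablation_preset <- function(name = c("snet-dsc", "snet-mb", "snetma-dsc",
                                     "snetma-mb", "mrict", "modo", "ct-only")) {
  name <- match.arg(name)
  base <- switch(
    name,
    "snet-dsc" = list(variant = "snet", weights = loss_weights(0, 0),
                      modo_probability = 0),
    "snet-mb" = list(variant = "snet", weights = loss_weights(),
                     modo_probability = 0),
    "snetma-dsc" = list(variant = "snetma", weights = loss_weights(0, 0),
                        modo_probability = 0),
    "snetma-mb" = list(variant = "snetma", weights = loss_weights(),
                       modo_probability = 0),
    "mrict" = list(variant = "snetma", weights = loss_weights(),
                   modo_probability = 0),
    "modo" = list(variant = "snetma", weights = loss_weights(),
                  modo_probability = 0.5),
    "ct-only" = list(variant = "snetma", weights = loss_weights(),
                     modo_probability = 1)
  )
  c(base, list(preset = name))
}

evaluate_on_test <- function(fit, test_pairs, threshold = 0.5) {
  do.call(rbind, lapply(seq_along(test_pairs), function(i) {
    p <- test_pairs[[i]]
    gt <- as_array3d(p$label)
    sp <- p$ct_input$spacing
    one <- function(mode, prob) {
      m <- prob$voxels >= threshold
      if (!any(m) || !any(gt > 0.5)) {
        data.frame(sample = i, input_mode = mode, dsc = dsc(m, gt > 0.5),
                   asd = NA_real_, hd95 = NA_real_)
      } else {
        data.frame(sample = i, input_mode = mode, dsc = dsc(m, gt > 0.5),
                   asd = asd(m, gt > 0.5, sp), hd95 = hd95(m, gt > 0.5, sp))
      }
    }
    rbind(one("mri_ct", sunet_forward(fit$model, p$ct_input, p$mri_input)),
          one("ct_only", sunet_forward(fit$model, p$ct_input, NULL)))
  }))
}

#' Run an ablation grid on a phantom benchmark
#'
#' Trains every preset for every seed on the benchmark's training
#' split and evaluates DSC, ASD and HD95 on the test split under both
#' MRI+CT and CT-only inference.  Failed runs are recorded with `NA`
#' metrics rather than aborting the grid.
#'
#' @param benchmark a [make_benchmark()] result (or a list with
#'   `train`/`test` lists of `phantom_sample`s).
#' @param presets character vector of [ablation_preset()] names.
#' @param seeds integer vector of training seeds.
#' @param label train against `"noisy"` (default) or `"clean"` labels.
#' @param threshold binarisation threshold for evaluation.
#' @param ... further arguments passed to [sunet()] (epochs,
#'   base_channels, ...).
#' @return list with `runs` (per-sample per-run data frame) and
#'   `table` (mean and sd per preset x input mode).
#' @export
run_ablation <- function(benchmark, presets = c("mrict", "modo"),
                         seeds = c(1L, 2L, 3L), label = "noisy",
                         threshold = 0.5, ...) {
  train_pairs <- prepare_samples(benchmark$train, label = label)
  test_pairs <- prepare_samples(benchmark$test, label = "clean")
  runs <- list()
  for (preset in presets) {
    pre <- ablation_preset(preset)
    pre$preset <- NULL
    for (sd_ in seeds) {
      res <- tryCatch({
        fit <- do.call(sunet, c(list(samples = train_pairs, seed = sd_), pre,
                                list(...)))
        ev <- evaluate_on_test(fit, test_pairs, threshold)
        ev$preset <- preset
        ev$seed <- sd_
        ev
      }, error = function(e) {
        warning(sprintf("run %s/seed %d failed: %s", preset, sd_,
                        conditionMessage(e)))
        data.frame(sample = NA_integer_,
                   input_mode = c("mri_ct", "ct_only"),
                   dsc = NA_real_, asd = NA_real_, hd95 = NA_real_,
                   preset = preset, seed = sd_)
      })
      runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, runs)
  agg <- stats::aggregate(runs[, c("dsc", "asd", "hd95")],
                          by = list(preset = runs$preset,
                                    input_mode = runs$input_mode),
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x, na.rm = TRUE)))
  table <- data.frame(preset = agg$preset, input_mode = agg$input_mode,
                      dsc_mean = agg$dsc[, "mean"], dsc_sd = agg$dsc[, "sd"],
                      asd_mean = agg$asd[, "mean"], asd_sd = agg$asd[, "sd"],
                      hd95_mean = agg$hd95[, "mean"], hd95_sd = agg$hd95[, "sd"])
  list(runs = runs, table = table)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single-file archive holding a schema key, the
#' model configuration, all weights and the training configuration.
#'
#' @param fit a [sunet()] fit or a `sunet_model`.
#' @param path checkpoint file path.
#' @return `sunet_load` returns a `sunet` object (with empty history if
#'   only a model was saved).
#' @export
sunet_save <- function(fit, path) {
  if (inherits(fit, "sunet_model")) {
    fit <- structure(list(model = fit, history = NULL, config = NULL),
                     class = "sunet")
  }
  stopifnot(inherits(fit, "sunet"))
  obj <- list(schema = "pudoseg-checkpoint-1",
              model_config = fit$model$config,
              weights = params_snapshot(fit$model$params),
              train_config = fit$config,
              history = fit$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname sunet_save
#' @export
sunet_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "pudoseg-checkpoint-1")) {
    stop("unrecognised checkpoint schema")
  }
  model <- structure(list(config = obj$model_config,
                          params = sunet_params(obj$model_config)),
                     class = "sunet_model")
  params_restore(model$params, obj$weights)
  structure(list(model = model, history = obj$history,
                 best_epoch = NA_integer_, config = obj$train_config),
            class = "sunet")
}
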