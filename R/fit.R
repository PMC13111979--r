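# The central model-fitting interface: train skip-gram models on a fan design
# across several seeds and expose activations, linking predictions, and
# simulated behavior through standard S3 methods.

#' Fit skip-gram models to a fan design
#'
#' Trains one skip-gram-with-negative-sampling model per seed on the design's
#' target-context pairs and returns them as a single fit. Per-pair dot
#' products are averaged across seeds (vectors themselves are never averaged:
#' the dot products are the quantity of interest). With pretrained target
#' vectors supplied, target rows are copied from the store and frozen by
#' default, reproducing the fine-tuning setup of the semantic experiment.
#'
#' @param design A `fan_design`.
#' @param seeds Integer vector of training seeds (default 1:3; results are
#'   averaged over them).
#' @param pretrained Optional word-vector matrix covering all target tokens.
#' @param freeze Freeze target vectors during training; defaults to `TRUE`
#'   exactly when `pretrained` is supplied.
#' @param epochs Training epochs; defaults to 24 for classic designs and 65
#'   for semantic ones.
#' @param config An [sgns_config()]; `epochs`/`freeze` arguments override its
#'   fields.
#' @return An object of class `fan_sgns`: list with `models` (one
#'   `sgns_model` per seed), `design`, `pairs`, `config`, `seeds`.
#' @examples
#' persons <- c("kapitein", "verkoper", "soldaat", "dokter",
#'              "schilder", "cowboy", "rechter", "bakker")
#' locations <- data.frame(
#'   word = c("toren", "zwembad", "grot", "dorp", "schuur", "ravijn",
#'            "kerk", "station", "haven", "museum", "molen", "strand"),
#'   determiner = c("de", "het", "de", "het", "de", "het",
#'                  "de", "het", "de", "het", "de", "het")
#' )
#' design <- build_classic_design(persons, locations,
#'                                varied_category = "person", rng_seed = 1)
#' fit <- fit_fan_sgns(design, seeds = 1, epochs = 2,
#'                     config = sgns_config(dimension = 10))
#' summary(fit)
#' @export
fit_fan_sgns <- function(design, seeds = c(1L, 2L, 3L), pretrained = NULL,
                         freeze = !is.null(pretrained), epochs = NULL,
                         config = sgns_config()) {
  stopifnot(inherits(design, "fan_design"), inherits(config, "sgns_config"),
            length(seeds) >= 1L)
  if (is.null(epochs)) {
    epochs <- if (design$design_mode == "semantic") 65L else 24L
  }
  config$epochs <- as.integer(epochs)
  config$freeze_targets <- isTRUE(freeze)
  if (config$freeze_targets && is.null(pretrained)) {
    stop("freeze = TRUE requires pretrained target vectors")
  }
  pairs <- to_training_pairs(design)
  models <- lapply(as.integer(seeds), function(s) {
    m <- sgns_init(pairs, config, seed = s, pretrained = pretrained)
    sgns_train(m, pairs)
  })
  structure(
    list(models = models, design = design, pairs = pairs, config = config,
         seeds = as.integer(seeds), call = match.call()),
    class = "fan_sgns"
  )
}

#' @export
print.fan_sgns <- function(x, ...) {
  cat(sprintf("Skip-gram fan-effect fit (%s design, %s fan varied)\n",
              x$design$design_mode, x$design$varied_category))
  cat(sprintf("  %d seed(s), %d epochs, d = %d, k = %d%s\n",
              length(x$models), x$config$epochs, x$config$dimension,
              x$config$k_negatives,
              if (x$config$freeze_targets) ", frozen targets" else ""))
  rec <- vapply(x$models, function(m) utils::tail(m$epoch_log$recall_error, 1),
                numeric(1))
  cat(sprintf("  final recall error per seed: %s\n",
              paste(format(rec, digits = 3), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fan_sgns <- function(object, ...) {
  act <- build_activation_table(object, object$design)
  means <- activation_means(act)
  rec <- vapply(object$models,
                function(m) utils::tail(m$epoch_log$recall_error, 1),
                numeric(1))
  loss <- vapply(object$models,
                 function(m) utils::tail(m$epoch_log$loss, 1), numeric(1))
  structure(
    list(design_mode = object$design$design_mode,
         varied_category = object$design$varied_category,
         seeds = object$seeds, epochs = object$config$epochs,
         k_negatives = object$config$k_negatives,
         condition_means = means, final_recall = rec, final_loss = loss),
    class = "summary.fan_sgns"
  )
}

#' @export
print.summary.fan_sgns <- function(x, ...) {
  cat(sprintf("Skip-gram fan-effect fit: %s design, %s fan varied\n",
              x$design_mode, x$varied_category))
  cat(sprintf("  seeds: %s | epochs: %d | k: %d\n",
              paste(x$seeds, collapse = ", "), x$epochs, x$k_negatives))
  cat(sprintf("  final recall error: %s | final mean loss: %s\n",
              paste(format(x$final_recall, digits = 3), collapse = ", "),
              paste(format(x$final_loss, digits = 3), collapse = ", ")))
  cat("  shifted dot product (pmi / spreading activation) by condition:\n")
  m <- x$condition_means
  for (i in seq_len(nrow(m))) {
    cat(sprintf("    fan %d: mean = %.3f, sd = %.3f  (%d pairs)\n",
                m$fan_condition[i], m$mean_shifted_dot[i],
                m$sd_shifted_dot[i], m$n_pairs[i]))
  }
  invisible(x)
}

#' Extract embedding matrices from a fit
#'
#' @param object A `fan_sgns` fit.
#' @param matrix Which matrix, `"target"` or `"context"`.
#' @param seed Which seed's model (defaults to the first).
#' @param ... Unused.
#' @return Numeric matrix with token rownames.
#' @export
coef.fan_sgns <- function(object, matrix = c("target", "context"),
                          seed = NULL, ...) {
  matrix <- match.arg(matrix)
  seed <- seed %||% object$seeds[1]
  i <- match(seed, object$seeds)
  if (is.na(i)) stop("no model trained with seed ", seed)
  object$models[[i]][[matrix]]
}

#' Predict activation, retrieval time, or retrieval probability
#'
#' @param object A `fan_sgns` fit.
#' @param newdata A `fan_design` (defaults to the fitted design; its
#'   vocabulary must be covered by the models).
#' @param type `"activation"` returns the per-pair activation table;
#'   `"time"`/`"prob"` additionally map the shifted dot product through the
#'   ACT-R linking functions.
#' @param linking A [linking_params()] for `type = "time"`/`"prob"`.
#' @param ... Unused.
#' @return An `activation_table`, with a `predicted` column for
#'   `type != "activation"`.
#' @export
predict.fan_sgns <- function(object, newdata = NULL,
                             type = c("activation", "time", "prob"),
                             linking = linking_params(), ...) {
  type <- match.arg(type)
  design <- newdata %||% object$design
  act <- build_activation_table(object, design)
  if (type == "time") {
    act$predicted <- retrieval_time(act$shifted_dot, linking)
  } else if (type == "prob") {
    act$predicted <- retrieval_prob(act$shifted_dot, linking)
  }
  act
}

#' Plot training curves of a fit
#'
#' Mean per-edge loss (left axis, one line per seed) and recall error by
#' epoch.
#'
#' @param x A `fan_sgns` fit.
#' @param which `"loss"` or `"recall"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly `x`.
#' @export
plot.fan_sgns <- function(x, which = c("loss", "recall"), ...) {
  which <- match.arg(which)
  col <- if (which == "loss") "loss" else "recall_error"
  logs <- lapply(x$models, function(m) m$epoch_log[[col]])
  n <- max(lengths(logs))
  mat <- sapply(logs, function(v) c(v, rep(NA, n - length(v))))
  graphics::matplot(seq_len(n), mat, type = "l", lty = 1,
                    xlab = "epoch",
                    ylab = if (which == "loss") "mean edge loss"
                    else "recall error", ...)
  invisible(x)
}

#' Simulate behavioral trial data from a fit
#'
#' Generates recognition trials whose RTs and accuracies follow the ACT-R
#' linking functions applied to the fitted activations (see
#' [generate_trials()]).
#'
#' @param object A `fan_sgns` fit.
#' @param nsim Number of data sets.
#' @param seed Integer seed for the first data set; data set i uses
#'   `seed + i - 1`.
#' @param params A [generator_params()].
#' @param ... Unused.
#' @return A trial data.frame for `nsim = 1`, otherwise a list of them.
#' @export
simulate.fan_sgns <- function(object, nsim = 1, seed = 1L,
                              params = generator_params(), ...) {
  act <- build_activation_table(object, object$design)
  sims <- lapply(seq_len(nsim), function(i) {
    generate_trials(object$design, act, params, rng_seed = seed + i - 1L)
  })
  if (nsim == 1) sims[[1]] else sims
}
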