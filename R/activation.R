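# Spreading activation from embeddings (shifted dot product = pmi estimate)
# and the ACT-R linking functions from activation to behavior.

#' Shifted dot product (pointwise mutual information estimate)
#'
#' The dot product of a trained target and context vector plus log(k), where k
#' is the number of negative samples, estimates the pointwise mutual
#' information of the pair, which equals spreading activation in the rational
#' analysis of memory.
#'
#' @param t_vec,c_vec Numeric vectors of equal length.
#' @param k Number of negative samples used in training (>= 1).
#' @return `sum(t_vec * c_vec) + log(k)`.
#' @export
shifted_dot <- function(t_vec, c_vec, k = 5L) {
  if (length(t_vec) != length(c_vec)) {
    stop("target and context vectors must have the same length")
  }
  stopifnot(is_count(k))
  sum(t_vec * c_vec) + log(k)
}

#' Spreading activation from probabilities
#'
#' The rational-analysis definition: the log ratio of the probability that
#' item i is needed given cue j to its base probability, i.e. the pointwise
#' mutual information of i and j. With `p_i_given_j = 1/fan` and
#' `p_i = 1/memory_size` this reduces to `log(memory_size) - log(fan)`.
#'
#' @param p_i_given_j,p_i Probabilities in (0, 1].
#' @return `log(p_i_given_j / p_i)`.
#' @export
pmi_activation <- function(p_i_given_j, p_i) {
  if (any(p_i_given_j <= 0) || any(p_i <= 0)) {
    stop("probabilities must be positive")
  }
  if (any(p_i_given_j > 1) || any(p_i > 1)) {
    stop("probabilities must not exceed 1")
  }
  log(p_i_given_j / p_i)
}

#' ACT-R linking parameters
#'
#' Parameters of the standard linking functions from activation to behavior:
#' retrieval latency `F * exp(-A)` and retrieval probability
#' `1 / (1 + exp(-(A - T)/s))`.
#'
#' @param latency_factor Latency scale F (> 0), in the time units of the
#'   output (defaults assume milliseconds).
#' @param threshold Retrieval threshold T, in activation units.
#' @param noise_s Logistic noise scale s (> 0), in activation units.
#' @return An object of class `linking_params`.
#' @export
linking_params <- function(latency_factor = 2000, threshold = 0.7,
                           noise_s = 0.45) {
  stopifnot(is_number(latency_factor), latency_factor > 0,
            is_number(threshold), is_number(noise_s), noise_s > 0)
  structure(list(latency_factor = latency_factor, threshold = threshold,
                 noise_s = noise_s),
            class = "linking_params")
}

#' Predicted retrieval time for an activation
#'
#' @param A Activation (vectorized).
#' @param params A [linking_params()].
#' @return `latency_factor * exp(-A)`; strictly decreasing in `A`.
#' @export
retrieval_time <- function(A, params = linking_params()) {
  stopifnot(inherits(params, "linking_params"))
  params$latency_factor * exp(-A)
}

#' Predicted retrieval probability for an activation
#'
#' @inheritParams retrieval_time
#' @return `plogis((A - threshold) / noise_s)`; in (0, 1), increasing in `A`.
#' @export
retrieval_prob <- function(A, params = linking_params()) {
  stopifnot(inherits(params, "linking_params"))
  stats::plogis((A - params$threshold) / params$noise_s)
}

#' Per-pair activation table from trained models
#'
#' One row per target sentence's content-word pair (articles are excluded:
#' the reported pair activations are over person-location pairs). Dot products
#' are averaged across the supplied models (one per training seed) and shifted
#' by log(k) to give the pmi / spreading-activation estimate.
#'
#' @param models A `fan_sgns` fit, a single `sgns_model`, or a list of
#'   `sgns_model`s sharing a vocabulary.
#' @param design The `fan_design` the models were trained on.
#' @return A data.frame of class `activation_table` with columns
#'   `sentence_id`, `target`, `context`, `fan_condition`, `kind`, `dot`,
#'   `shifted_dot`, `n_seeds`.
#' @export
build_activation_table <- function(models, design) {
  models <- as_model_list(models)
  stopifnot(inherits(design, "fan_design"))
  pairs <- to_training_pairs(design)
  k <- models[[1]]$config$k_negatives
  dots <- sapply(models, function(m) {
    ti <- store_lookup(m$target, pairs$target)
    ci <- store_lookup(m$context, pairs$context_word)
    rowSums(m$target[ti, , drop = FALSE] * m$context[ci, , drop = FALSE])
  })
  dots <- if (is.matrix(dots)) rowMeans(dots) else mean(dots)
  out <- data.frame(
    sentence_id = pairs$sentence_id,
    target = pairs$target,
    context = pairs$context_word,
    fan_condition = pairs$fan_condition,
    kind = "target",
    dot = as.numeric(dots),
    shifted_dot = as.numeric(dots) + log(k),
    n_seeds = length(models),
    stringsAsFactors = FALSE
  )
  class(out) <- c("activation_table", "data.frame")
  out
}

as_model_list <- function(models) {
  if (inherits(models, "fan_sgns")) {
    return(models$models)
  }
  if (inherits(models, "sgns_model")) {
    return(list(models))
  }
  if (is.list(models) && all(vapply(models, inherits, logical(1), "sgns_model"))) {
    return(models)
  }
  stop("models must be a fan_sgns fit, an sgns_model, or a list of sgns_models")
}

#' Condition means of an activation table
#'
#' Mean and standard deviation of the shifted dot product per fan condition.
#'
#' @param activations An `activation_table`.
#' @return A data.frame with columns `fan_condition`, `mean_shifted_dot`,
#'   `sd_shifted_dot`, `n_pairs`.
#' @export
activation_means <- function(activations) {
  stopifnot(is.data.frame(activations),
            all(c("fan_condition", "shifted_dot") %in% names(activations)))
  fans <- sort(unique(activations$fan_condition))
  out <- do.call(rbind, lapply(fans, function(f) {
    x <- activations$shifted_dot[activations$fan_condition == f]
    data.frame(fan_condition = f, mean_shifted_dot = mean(x),
               sd_shifted_dot = stats::sd(x), n_pairs = length(x))
  }))
  out
}
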