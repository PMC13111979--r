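# Binarized-cue ACT-R spreading activation: injects lexical knowledge from
# embeddings into the classical cue-based activation formula S - log(fan).

#' Binarize a word-vector store to +1/-1 cues
#'
#' Element-wise sign coding: strictly positive values become +1, all others
#' (including exact zeros) -1. ACT-R spreading activation works with discrete
#' match/mismatch cues, so every vector dimension becomes one binary cue.
#'
#' @param store Numeric matrix with token rownames.
#' @return Matrix of the same shape with entries in \{-1, +1\}.
#' @export
binarize_store <- function(store) {
  store <- as_store(store)
  out <- ifelse(store > 0, 1, -1)
  rownames(out) <- rownames(store)
  out
}

#' Build a binarized cue space from embeddings and a study set
#'
#' The study chunks are the design's target sentences. Every embedding
#' dimension of a probe word is one cue (a dimension/sign pair); the fan of a
#' cue is the number of study chunks whose same-category word carries the same
#' sign in that dimension.
#'
#' @param store Word-vector matrix covering the design's words.
#' @param design A `fan_design`; its targets form the chunk set.
#' @param S Log memory size. ACT-R treats this as a free parameter; the
#'   default is `log(number of study chunks)`, the reading under which every
#'   chunk is equally likely to be needed.
#' @param total_weight Total cue weight W, spread uniformly over the d cues
#'   (W_j = W/d). Rescales but never reorders activations; the default of 100
#'   gives one unit per cue for 100-dimensional vectors.
#' @return An object of class `cue_space`.
#' @export
cue_space <- function(store, design, S = NULL, total_weight = 100) {
  stopifnot(inherits(design, "fan_design"), is_number(total_weight),
            total_weight > 0)
  tg <- design$targets
  words <- unique(c(tg$person, tg$location))
  bin <- binarize_store(store[store_lookup(store, words), , drop = FALSE])
  S <- S %||% log(nrow(tg))
  stopifnot(is_number(S))
  structure(
    list(binarized = bin, chunks = tg, S = S, total_weight = total_weight,
         dimension = ncol(bin), varied_category = design$varied_category),
    class = "cue_space"
  )
}

#' ACT-R spreading activation of a probe word over binarized cues
#'
#' For each of the probe's d cues (dimension j with the probe's sign), the fan
#' `fan_j` is the number of study chunks whose same-category word matches that
#' sign in that dimension; the activation is `sum_j W_j * (S - log(fan_j))`
#' with uniform cue weights `W_j = W/d`. A cue matched by no chunk is treated
#' as fan 1 with a warning.
#'
#' @param probe A token among the design's person or location words.
#' @param space A [cue_space()].
#' @return Activation (scalar).
#' @export
actr_fan_activation <- function(probe, space) {
  stopifnot(inherits(space, "cue_space"))
  tg <- space$chunks
  category <- if (probe %in% tg$person) "person"
  else if (probe %in% tg$location) "location"
  else stop("probe '", probe, "' is not a word of the study set")
  pvec <- space$binarized[store_lookup(space$binarized, probe), ]
  words <- if (category == "person") tg$person else tg$location
  cmat <- space$binarized[store_lookup(space$binarized, words), , drop = FALSE]
  fan_j <- colSums(cmat == matrix(pvec, nrow(cmat), length(pvec), byrow = TRUE))
  if (any(fan_j == 0)) {
    warning(sum(fan_j == 0), " cue(s) matched by no chunk; treated as fan 1")
    fan_j[fan_j == 0] <- 1
  }
  w <- space$total_weight / space$dimension
  sum(w * (space$S - log(fan_j)))
}

#' ACT-R activations for all varied-category probes of a design
#'
#' Convenience wrapper computing [actr_fan_activation()] for every
#' varied-category target word, with its fan condition label.
#'
#' @param design A `fan_design`.
#' @param store Word-vector matrix covering the design's words.
#' @inheritParams cue_space
#' @return A data.frame with columns `probe`, `fan_condition`, `activation`.
#' @export
actr_activation_table <- function(design, store, S = NULL, total_weight = 100) {
  space <- cue_space(store, design, S = S, total_weight = total_weight)
  tg <- design$targets
  probes <- if (design$varied_category == "person") tg$person else tg$location
  fan <- fan_conditions(design)[as.character(tg$sentence_id)]
  keep <- !duplicated(probes)
  data.frame(
    probe = probes[keep],
    fan_condition = as.integer(fan[keep]),
    activation = vapply(probes[keep], actr_fan_activation, numeric(1),
                        space = space),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
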