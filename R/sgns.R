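# Skip-gram with negative sampling, trained on fan-design target-context
# pairs. Pure R: the vocabularies (tens of tokens) and corpora (dozens of
# edges) of fan experiments make compiled code unnecessary.

#' Skip-gram training configuration
#'
#' Hyperparameters for [sgns_init()]/[sgns_train()]. Defaults follow the
#' simulation setup: 100-dimensional vectors initialized uniform(-1, 1), five
#' negative samples drawn from the unigram distribution raised to 3/4, and the
#' Adam optimizer with learning rate 0.003.
#'
#' @param dimension Embedding dimensionality.
#' @param k_negatives Negative samples per observed edge (>= 1).
#' @param noise_exponent Exponent applied to context counts for the noise
#'   distribution (0 < exponent <= 1).
#' @param learning_rate Adam learning rate.
#' @param init_low,init_high Bounds of the uniform initialization.
#' @param epochs Full passes over the edge corpus (24 reproduces the classic
#'   simulation; 65 the semantic one).
#' @param freeze_targets When `TRUE`, target vectors are never updated (used
#'   with pretrained target embeddings).
#' @param recall_stop_threshold Optional: stop at the first epoch whose recall
#'   error is at or below this value (e.g. 0.01 for criterion-based stopping).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and epsilon.
#' @return An object of class `sgns_config`.
#' @export
sgns_config <- function(dimension = 100L, k_negatives = 5L,
                        noise_exponent = 0.75, learning_rate = 0.003,
                        init_low = -1, init_high = 1, epochs = 24L,
                        freeze_targets = FALSE, recall_stop_threshold = NULL,
                        adam_beta1 = 0.9, adam_beta2 = 0.999,
                        adam_eps = 1e-8) {
  stopifnot(is_count(dimension), is_count(k_negatives),
            is_number(noise_exponent), noise_exponent > 0, noise_exponent <= 1,
            is_number(learning_rate), learning_rate > 0,
            is_number(init_low), is_number(init_high), init_low < init_high,
            is_count(epochs), is.logical(freeze_targets))
  if (!is.null(recall_stop_threshold)) {
    stopifnot(is_number(recall_stop_threshold), recall_stop_threshold >= 0)
  }
  structure(
    list(dimension = as.integer(dimension),
         k_negatives = as.integer(k_negatives),
         noise_exponent = noise_exponent, learning_rate = learning_rate,
         init_low = init_low, init_high = init_high,
         epochs = as.integer(epochs), freeze_targets = freeze_targets,
         recall_stop_threshold = recall_stop_threshold,
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps),
    class = "sgns_config"
  )
}

#' Negative-sampling noise distribution
#'
#' Probabilities proportional to context counts raised to `exponent` (the
#' standard p^(3/4) smoothing at the default).
#'
#' @param context_counts Named vector of positive token counts.
#' @param exponent Smoothing exponent.
#' @return Named probability vector summing to 1.
#' @export
noise_distribution <- function(context_counts, exponent = 0.75) {
  if (length(context_counts) == 0L) stop("empty context counts")
  if (any(context_counts <= 0)) stop("context counts must be positive")
  w <- context_counts^exponent
  w / sum(w)
}

sgns_vocab <- function(pairs) {
  edges <- training_edges(pairs)
  list(
    targets = sort(unique(edges$target)),
    contexts = sort(unique(edges$context)),
    edges = edges
  )
}

#' Initialize a skip-gram model for a set of training pairs
#'
#' Context rows are always drawn uniform(init_low, init_high); target rows are
#' either drawn the same way or copied exactly from a pretrained store.
#' Bit-identical under a fixed seed.
#'
#' @param pairs Training pairs from [to_training_pairs()].
#' @param config An [sgns_config()].
#' @param seed Integer seed.
#' @param pretrained Optional word-vector matrix supplying every target token.
#' @return An object of class `sgns_model` with matrices `target` and
#'   `context` (token rownames), the config, seed, and an empty `epoch_log`.
#' @export
sgns_init <- function(pairs, config = sgns_config(), seed = 1L,
                      pretrained = NULL) {
  stopifnot(inherits(config, "sgns_config"))
  voc <- sgns_vocab(pairs)
  d <- config$dimension
  model <- with_seed(seed, {
    cm <- matrix(stats::runif(length(voc$contexts) * d, config$init_low,
                              config$init_high),
                 nrow = length(voc$contexts), dimnames = list(voc$contexts, NULL))
    tm <- matrix(stats::runif(length(voc$targets) * d, config$init_low,
                              config$init_high),
                 nrow = length(voc$targets), dimnames = list(voc$targets, NULL))
    list(tm = tm, cm = cm)
  })
  if (!is.null(pretrained)) {
    pretrained <- as_store(pretrained)
    missing <- setdiff(voc$targets, rownames(pretrained))
    if (length(missing)) {
      stop("pretrained store lacks target token(s): ",
           paste(missing, collapse = ", "))
    }
    if (ncol(pretrained) != d) {
      stop("pretrained vectors have dimension ", ncol(pretrained),
           " but config requires ", d)
    }
    model$tm <- pretrained[voc$targets, , drop = FALSE]
  }
  structure(
    list(target = model$tm, context = model$cm, config = config,
         seed = as.integer(seed), pretrained = !is.null(pretrained),
         epoch_log = data.frame(epoch = integer(0), loss = numeric(0),
                                recall_error = numeric(0)),
         trained = FALSE),
    class = "sgns_model"
  )
}

# Loss and gradients for one (target, context) edge. The model scores the
# target word given the cue (context) word; negative samples replace the
# target, so `neg_tm` holds noise rows from the target matrix.
# loss = -log s(t.c) - sum_n log s(-t_n.c).
sgns_edge_grad <- function(tv, cv, neg_tm) {
  xp <- sum(tv * cv)
  xn <- as.numeric(neg_tm %*% cv)
  spos <- stats::plogis(xp)
  sneg <- stats::plogis(xn)
  loss <- -(stats::plogis(xp, log.p = TRUE) +
              sum(stats::plogis(-xn, log.p = TRUE)))
  gpos <- spos - 1
  list(
    loss = loss,
    grad_t = gpos * cv,
    grad_c = gpos * tv + as.numeric(crossprod(neg_tm, sneg)),
    grad_neg = outer(sneg, cv)
  )
}

#' Train a skip-gram model on fan-design pairs
#'
#' Runs full passes over the (target, context-token) edge corpus, shuffled per
#' epoch. The model scores the target (varied-category) word against its cue
#' tokens; for each edge, `k_negatives` noise targets are drawn with
#' replacement from the target unigram distribution raised to
#' `noise_exponent`, and one Adam step is taken (sparse row updates, global
#' step counter). Context rows are always updated; target rows (positive and
#' negative) only when `freeze_targets` is `FALSE`. Per-epoch mean loss and
#' recall error are logged; when `recall_stop_threshold` is set training stops
#' at the first epoch at or below it.
#'
#' @param model An `sgns_model` from [sgns_init()] built on these pairs.
#' @param pairs The training pairs used at initialization.
#' @param seed Optional seed for shuffling/negative sampling; defaults to a
#'   stream derived from the model's seed.
#' @return The trained `sgns_model` with populated `epoch_log`.
#' @export
sgns_train <- function(model, pairs, seed = NULL) {
  stopifnot(inherits(model, "sgns_model"))
  cfg <- model$config
  voc <- sgns_vocab(pairs)
  if (!identical(voc$targets, rownames(model$target)) ||
      !identical(voc$contexts, rownames(model$context))) {
    stop("model vocabulary does not match these training pairs; ",
         "initialize the model on the same pairs")
  }
  seed <- seed %||% ((model$seed %% 2147480000L) + 7L)

  TM <- model$target
  CM <- model$context
  d <- cfg$dimension
  k <- cfg$k_negatives
  lr <- cfg$learning_rate
  b1 <- cfg$adam_beta1
  b2 <- cfg$adam_beta2
  eps <- cfg$adam_eps
  freeze <- cfg$freeze_targets

  edges <- voc$edges
  et <- match(edges$target, voc$targets)
  ec <- match(edges$context, voc$contexts)
  n_edges <- length(et)
  counts <- tabulate(et, nbins = length(voc$targets))
  noise_p <- noise_distribution(stats::setNames(counts, voc$targets),
                                cfg$noise_exponent)

  # Adam state, one row per vocabulary row; one global step counter.
  mT <- vT <- matrix(0, nrow(TM), d)
  mC <- vC <- matrix(0, nrow(CM), d)
  stepn <- 0L

  log_epoch <- integer(0)
  log_loss <- numeric(0)
  log_recall <- numeric(0)

  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      total_loss <- 0
      for (e in sample.int(n_edges)) {
        ti <- et[e]
        ci <- ec[e]
        neg <- sample.int(length(noise_p), k, replace = TRUE, prob = noise_p)
        g <- sgns_edge_grad(TM[ti, ], CM[ci, ], TM[neg, , drop = FALSE])
        total_loss <- total_loss + g$loss
        if (!is.finite(g$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; try a smaller learning_rate")
        }
        stepn <- stepn + 1L
        bc1 <- 1 - b1^stepn
        bc2 <- 1 - b2^stepn
        mC[ci, ] <- b1 * mC[ci, ] + (1 - b1) * g$grad_c
        vC[ci, ] <- b2 * vC[ci, ] + (1 - b2) * g$grad_c^2
        CM[ci, ] <- CM[ci, ] - lr * (mC[ci, ] / bc1) /
          (sqrt(vC[ci, ] / bc2) + eps)
        if (!freeze) {
          gall <- rowsum(rbind(g$grad_t, g$grad_neg), c(ti, neg))
          rows <- as.integer(rownames(gall))
          for (j in seq_along(rows)) {
            r <- rows[j]
            gr <- gall[j, ]
            mT[r, ] <- b1 * mT[r, ] + (1 - b1) * gr
            vT[r, ] <- b2 * vT[r, ] + (1 - b2) * gr^2
            TM[r, ] <- TM[r, ] - lr * (mT[r, ] / bc1) /
              (sqrt(vT[r, ] / bc2) + eps)
          }
        }
      }
      model$target <- TM
      model$context <- CM
      rec <- recall_error(model, pairs)
      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, total_loss / n_edges)
      log_recall <- c(log_recall, rec)
      if (!is.null(cfg$recall_stop_threshold) &&
          rec <= cfg$recall_stop_threshold) {
        break
      }
    }
  })
  model$target <- TM
  model$context <- CM
  model$epoch_log <- data.frame(epoch = log_epoch, loss = log_loss,
                                recall_error = log_recall)
  model$trained <- TRUE
  model
}

#' Recall error of a model on its training pairs
#'
#' For each target with `f` observed content-word contexts (its fan), all
#' content-word context tokens are ranked by dot product with the target; each
#' observed context outside the target's top `f` counts as one mistake. The
#' error is mistakes divided by the number of observed content-word edges.
#' Articles are excluded from the ranking, since an article co-occurs with
#' half the targets and would dominate it.
#'
#' @param model An `sgns_model`.
#' @param pairs Training pairs sharing the model's vocabulary.
#' @return Error rate in \[0, 1\].
#' @export
recall_error <- function(model, pairs) {
  stopifnot(inherits(model, "sgns_model"))
  edges <- training_edges(pairs)
  edges <- edges[edges$context_type == "word", ]
  ctok <- sort(unique(edges$context))
  store_lookup(model$target, edges$target)
  cidx <- store_lookup(model$context, ctok)
  scores <- model$target %*% t(model$context[cidx, , drop = FALSE])
  colnames(scores) <- ctok
  mistakes <- 0L
  for (t in unique(edges$target)) {
    obs <- edges$context[edges$target == t]
    f <- length(obs)
    sc <- scores[match(t, rownames(model$target)), ]
    top <- ctok[order(-sc, ctok)][seq_len(f)]
    mistakes <- mistakes + sum(!(obs %in% top))
  }
  mistakes / nrow(edges)
}
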