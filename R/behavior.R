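# Synthetic behavioral data with the statistical structure fan-effect
# analyses assume (shifted log-normal RTs, Bernoulli accuracy, participant and
# item random effects), plus the cleaning, exclusion, contrast-coding, and
# summary steps applied to recognition data.

trial_columns <- c("participant_id", "sentence_id", "kind", "fan_condition",
                   "varied_category", "round", "rt_ms", "correct")

#' Behavioral generator parameters
#'
#' @param linking A [linking_params()] mapping activation to retrieval time
#'   and probability.
#' @param shift_ms Constant onset shift added to every RT (non-negative,
#'   milliseconds).
#' @param sigma_log Residual standard deviation of log RT (> 0).
#' @param participant_sd,item_sd Random-effect standard deviations, applied on
#'   the log scale for RTs and the logit scale for accuracy.
#' @param n_participants Number of simulated participants.
#' @param n_rounds Testing rounds per participant (each round presents all 48
#'   sentences).
#' @param rng_seed Integer seed.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(linking = linking_params(), shift_ms = 1300,
                             sigma_log = 0.25, participant_sd = 0.12,
                             item_sd = 0.05, n_participants = 100L,
                             n_rounds = 3L, rng_seed = 1L) {
  stopifnot(inherits(linking, "linking_params"),
            is_number(shift_ms), shift_ms >= 0,
            is_number(sigma_log), sigma_log > 0,
            is_number(participant_sd), participant_sd >= 0,
            is_number(item_sd), item_sd >= 0,
            is_count(n_participants), is_count(n_rounds))
  structure(
    list(linking = linking, shift_ms = shift_ms, sigma_log = sigma_log,
         participant_sd = participant_sd, item_sd = item_sd,
         n_participants = as.integer(n_participants),
         n_rounds = as.integer(n_rounds), rng_seed = as.integer(rng_seed)),
    class = "generator_params"
  )
}

# Activation of every design sentence: targets take their pair activation;
# foils take the mean of their constituent words' trained pair activations
# (an artifact convention for synthesis; the underlying theory gives no
# generative account of foils).
sentence_activations <- function(design, activations) {
  stopifnot(inherits(design, "fan_design"))
  tg <- design$targets
  fl <- design$foils
  act <- stats::setNames(
    activations$shifted_dot[match(tg$sentence_id, activations$sentence_id)],
    tg$sentence_id
  )
  if (anyNA(act)) {
    stop("missing activation for target sentence(s): ",
         paste(tg$sentence_id[is.na(act)], collapse = ", "))
  }
  word_act <- function(word) {
    hit <- activations$target == word | activations$context == word
    if (!any(hit)) {
      return(NA_real_)
    }
    mean(activations$shifted_dot[hit])
  }
  if (!is.null(fl) && nrow(fl)) {
    if (design$varied_category == "person") {
      a1 <- vapply(fl$person, word_act, numeric(1))
      a2 <- vapply(fl$location, word_act, numeric(1))
    } else {
      a1 <- vapply(fl$location, word_act, numeric(1))
      a2 <- vapply(fl$person, word_act, numeric(1))
    }
    foil_act <- (a1 + a2) / 2
    if (anyNA(foil_act)) {
      stop("missing activation for foil sentence(s): ",
           paste(fl$sentence_id[is.na(foil_act)], collapse = ", "))
    }
    act <- c(act, stats::setNames(foil_act, fl$sentence_id))
  }
  act
}

#' Generate synthetic recognition trials from activations
#'
#' Each trial's RT is a shifted log-normal around the ACT-R latency
#' prediction: `rt = shift + exp(log(F exp(-A)) + u_p + w_i + e)` with
#' participant effect `u_p`, item effect `w_i`, and residual `e`. Correctness
#' is Bernoulli with probability `plogis((A - T)/s + u'_p + w'_i)`, with
#' independent participant/item effects on the logit scale. Foil activations
#' are the mean of their constituent words' trained pair activations.
#'
#' @param design A `fan_design` (24 targets + 24 foils).
#' @param activations An `activation_table` for the design.
#' @param params A [generator_params()].
#' @param rng_seed Optional override of `params$rng_seed`.
#' @return A data.frame of `n_participants * n_rounds * 48` trials with
#'   columns `participant_id`, `sentence_id`, `kind`, `fan_condition`,
#'   `varied_category`, `round`, `rt_ms`, `correct`.
#' @export
generate_trials <- function(design, activations, params = generator_params(),
                            rng_seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  act <- sentence_activations(design, activations)
  all_sent <- rbind(design$targets, design$foils)
  fan <- fan_conditions(design)
  seed <- rng_seed %||% params$rng_seed
  n_p <- params$n_participants
  n_s <- nrow(all_sent)
  n_r <- params$n_rounds
  lk <- params$linking

  with_seed(seed, {
    u_rt <- stats::rnorm(n_p, 0, params$participant_sd)
    u_acc <- stats::rnorm(n_p, 0, params$participant_sd)
    w_rt <- stats::rnorm(n_s, 0, params$item_sd)
    w_acc <- stats::rnorm(n_s, 0, params$item_sd)

    grid <- expand.grid(s = seq_len(n_s), round = seq_len(n_r),
                        p = seq_len(n_p))
    A <- act[as.character(all_sent$sentence_id[grid$s])]
    mu <- log(retrieval_time(A, lk)) + u_rt[grid$p] + w_rt[grid$s]
    rt <- params$shift_ms + exp(mu + stats::rnorm(nrow(grid), 0,
                                                  params$sigma_log))
    eta <- (A - lk$threshold) / lk$noise_s + u_acc[grid$p] + w_acc[grid$s]
    correct <- stats::runif(nrow(grid)) < stats::plogis(eta)

    data.frame(
      participant_id = sprintf("pp%03d", grid$p),
      sentence_id = all_sent$sentence_id[grid$s],
      kind = all_sent$kind[grid$s],
      fan_condition = as.integer(fan[as.character(all_sent$sentence_id[grid$s])]),
      varied_category = design$varied_category,
      round = grid$round,
      rt_ms = as.numeric(rt),
      correct = as.logical(correct),
      stringsAsFactors = FALSE
    )
  })
}

#' RT cleaning configuration
#'
#' @param rt_floor_ms,rt_ceiling_ms Absolute RT bounds (stage 1 removes RTs
#'   faster than the floor or slower than the ceiling; defaults 200 ms and
#'   90,000 ms).
#' @param sd_multiplier Stage 2 removes RTs more than this many standard
#'   deviations from the mean of the stage-1 survivors.
#' @param accuracy_threshold Participant-exclusion threshold (strict `<`);
#'   0.6 for the classic design, 0.65 for the semantic one.
#' @param per_participant When `TRUE`, the stage-2 mean/sd are computed within
#'   participant instead of globally (off by default).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(rt_floor_ms = 200, rt_ceiling_ms = 90000,
                            sd_multiplier = 3, accuracy_threshold = 0.6,
                            per_participant = FALSE) {
  stopifnot(is_number(rt_floor_ms), is_number(rt_ceiling_ms),
            rt_floor_ms < rt_ceiling_ms, is_number(sd_multiplier),
            sd_multiplier > 0, is_number(accuracy_threshold),
            is.logical(per_participant))
  structure(
    list(rt_floor_ms = rt_floor_ms, rt_ceiling_ms = rt_ceiling_ms,
         sd_multiplier = sd_multiplier,
         accuracy_threshold = accuracy_threshold,
         per_participant = per_participant),
    class = "cleaning_config"
  )
}

#' Two-stage RT cleaning
#'
#' Stage 1 removes extreme RTs outside the absolute bounds; stage 2 removes
#' RTs more than `sd_multiplier` standard deviations from the mean, where mean
#' and sd are computed once on the stage-1 survivors (globally by default).
#'
#' @param trials Trial data.frame with an `rt_ms` column.
#' @param config A [cleaning_config()].
#' @return A list with `trials` (the survivors) and `report`, a data.frame of
#'   per-stage removal counts and percentages.
#' @export
clean_rts <- function(trials, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  if (is.null(trials) || nrow(trials) == 0L) stop("no trials to clean")
  n0 <- nrow(trials)
  stage1_out <- trials$rt_ms < config$rt_floor_ms |
    trials$rt_ms > config$rt_ceiling_ms
  s1 <- trials[!stage1_out, , drop = FALSE]
  if (nrow(s1) == 0L) stop("all trials removed by the absolute RT bounds")

  if (config$per_participant) {
    keep <- unlist(lapply(split(seq_len(nrow(s1)), s1$participant_id),
                          function(idx) {
                            m <- mean(s1$rt_ms[idx])
                            s <- stats::sd(s1$rt_ms[idx])
                            if (is.na(s) || s == 0) return(idx)
                            idx[abs(s1$rt_ms[idx] - m) <= config$sd_multiplier * s]
                          }), use.names = FALSE)
    stage2_keep <- sort(keep)
  } else {
    m <- mean(s1$rt_ms)
    s <- stats::sd(s1$rt_ms)
    stage2_keep <- if (is.na(s) || s == 0) seq_len(nrow(s1))
    else which(abs(s1$rt_ms - m) <= config$sd_multiplier * s)
  }
  out <- s1[stage2_keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all trials removed by the sd trim")
  report <- data.frame(
    stage = c("absolute_bounds", "sd_trim"),
    n_removed = c(sum(stage1_out), nrow(s1) - length(stage2_keep)),
    pct_removed = c(100 * sum(stage1_out) / n0,
                    100 * (nrow(s1) - length(stage2_keep)) / n0)
  )
  list(trials = out, report = report)
}

#' Exclude participants below an accuracy threshold
#'
#' Participants whose mean accuracy over all their trials is strictly below
#' the threshold are dropped entirely. Exclusion is computed before any RT
#' cleaning.
#'
#' @param trials Trial data.frame with `participant_id` and `correct` columns.
#' @param threshold Accuracy threshold (strict `<`; a participant at exactly
#'   the threshold is retained).
#' @return A list with `trials` (retained rows) and `excluded` (participant
#'   ids dropped).
#' @export
exclude_participants <- function(trials, threshold = 0.6) {
  stopifnot(is_number(threshold))
  acc <- tapply(as.numeric(trials$correct), trials$participant_id, mean)
  excluded <- names(acc)[acc < threshold]
  list(trials = trials[!(trials$participant_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' Sum-contrast codes for fan and stimulus type
#'
#' `fan_target` is -1/+1 for target sentences at fan 2/4 and 0 for foils;
#' `fan_foil` mirrors this for foils; `stimulus_type` is +1 for targets and
#' -1 for foils. Codes depend only on `kind` and `fan_condition`.
#'
#' @param trials Trial data.frame with `kind` and `fan_condition` columns.
#' @return The input with columns `fan_target`, `fan_foil`, `stimulus_type`
#'   appended.
#' @export
code_contrasts <- function(trials) {
  stopifnot(all(c("kind", "fan_condition") %in% names(trials)))
  if (!all(trials$fan_condition %in% c(2L, 4L))) {
    stop("fan_condition must be 2 or 4")
  }
  fan_code <- ifelse(trials$fan_condition == 4L, 1L, -1L)
  trials$fan_target <- ifelse(trials$kind == "target", fan_code, 0L)
  trials$fan_foil <- ifelse(trials$kind == "foil", fan_code, 0L)
  trials$stimulus_type <- ifelse(trials$kind == "target", 1L, -1L)
  trials
}

#' Condition summary of mean RT and accuracy
#'
#' Rows for person / location / combined at fan 2 and fan 4, mirroring the
#' descriptive tables of fan experiments. The fan-2 row is identical across
#' the three condition labels by design: fan 2 means both concepts at fan 2,
#' so the same trials enter each label. Standard errors are over trials.
#'
#' @param trials Trial data.frame (typically cleaned first).
#' @param kind Which trials to summarize: `"target"` (default), `"foil"`, or
#'   `"both"`.
#' @return A data.frame with columns `condition`, `fan`, `n`, `mean_rt`,
#'   `se_rt`, `mean_accuracy`, `se_accuracy`.
#' @export
summarize_conditions <- function(trials, kind = c("target", "foil", "both")) {
  kind <- match.arg(kind)
  if (kind != "both") trials <- trials[trials$kind == kind, , drop = FALSE]
  cell <- function(condition, rows) {
    n <- length(rows)
    if (n == 0L) {
      return(data.frame(condition = condition$label, fan = condition$fan,
                        n = 0L, mean_rt = NA_real_, se_rt = NA_real_,
                        mean_accuracy = NA_real_, se_accuracy = NA_real_))
    }
    rt <- trials$rt_ms[rows]
    acc <- as.numeric(trials$correct[rows])
    data.frame(condition = condition$label, fan = condition$fan, n = n,
               mean_rt = mean(rt), se_rt = stats::sd(rt) / sqrt(n),
               mean_accuracy = mean(acc),
               se_accuracy = stats::sd(acc) / sqrt(n))
  }
  fan2 <- which(trials$fan_condition == 2L)
  rows_for <- function(label) {
    if (label == "combined") which(trials$fan_condition == 4L)
    else which(trials$fan_condition == 4L & trials$varied_category == label)
  }
  out <- do.call(rbind, unlist(lapply(c("person", "location", "combined"),
                                      function(lab) {
    list(cell(list(label = lab, fan = 2L), fan2),
         cell(list(label = lab, fan = 4L), rows_for(lab)))
  }), recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Split target trials by item dot product
#'
#' Groups target trials by whether their item's (shifted) dot product falls
#' below the given quantile of the item dot products, and summarizes mean RT
#' and SE per group. Items at exactly the split value go to the upper group.
#'
#' @param trials Trial data.frame (targets are selected internally).
#' @param activations An `activation_table` mapping sentences to dot products.
#' @param quantile Split quantile of the item dot products (default 0.5, the
#'   median split).
#' @return A data.frame with one row per group (`below`, `above`) and columns
#'   `group`, `n_items`, `n_trials`, `mean_rt`, `se_rt`; the split value and
#'   rule are attached as attributes `split_value` and `split_rule`.
#' @export
split_by_dot_product <- function(trials, activations, quantile = 0.5) {
  stopifnot(is_number(quantile), quantile > 0, quantile < 1)
  tt <- trials[trials$kind == "target", , drop = FALSE]
  dots <- activations$shifted_dot[match(tt$sentence_id,
                                        activations$sentence_id)]
  if (anyNA(dots)) stop("trials reference sentences missing from activations")
  item_dots <- activations$shifted_dot
  if (length(unique(item_dots)) == 1L) {
    warning("all item dot products are equal; returning a single group")
    out <- data.frame(group = "all", n_items = length(item_dots),
                      n_trials = nrow(tt), mean_rt = mean(tt$rt_ms),
                      se_rt = stats::sd(tt$rt_ms) / sqrt(nrow(tt)))
    attr(out, "split_value") <- unique(item_dots)
    attr(out, "split_rule") <- "degenerate: all dots equal"
    return(out)
  }
  q <- stats::quantile(item_dots, probs = quantile, names = FALSE)
  grp <- ifelse(dots < q, "below", "above")
  summarize_grp <- function(g) {
    rows <- grp == g
    data.frame(group = g,
               n_items = length(unique(tt$sentence_id[rows])),
               n_trials = sum(rows),
               mean_rt = mean(tt$rt_ms[rows]),
               se_rt = stats::sd(tt$rt_ms[rows]) / sqrt(sum(rows)))
  }
  out <- rbind(summarize_grp("below"), summarize_grp("above"))
  attr(out, "split_value") <- q
  attr(out, "split_rule") <- sprintf(
    "below: dot < %.6g; above: dot >= %.6g (quantile %.2f of item dots)",
    q, q, quantile)
  out
}

#' Recover the fan effect from trial data
#'
#' Estimates the by-participant mean log-RT difference between fan-4 and fan-2
#' target trials, with a seeded nonparametric bootstrap confidence interval.
#' Positive estimates mean slower responses at higher fan. Because items are
#' crossed with participants (every participant sees the same items, and item
#' effects therefore shift all participants alike), each bootstrap replicate
#' resamples both participants and items within fan condition; resampling
#' participants alone would ignore item-level uncertainty and badly undercover
#' when the design's item effects are non-negligible.
#'
#' @param trials Cleaned trial data.frame.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf_level Confidence level of the percentile interval.
#' @param rng_seed Integer seed for the bootstrap.
#' @return A list of class `fan_effect` with `estimate`, `ci` (length-2
#'   vector), `participant_diffs`, `n_participants`, `n_boot`, `conf_level`.
#' @export
recover_fan_effect <- function(trials, n_boot = 2000L, conf_level = 0.95,
                               rng_seed = 1L) {
  stopifnot(is_count(n_boot), is_number(conf_level), conf_level > 0,
            conf_level < 1)
  tt <- trials[trials$kind == "target", , drop = FALSE]
  pps <- sort(unique(tt$participant_id))
  n <- length(pps)
  if (n < 2L) stop("need at least 2 participants to estimate the fan effect")
  items <- unique(tt[, c("sentence_id", "fan_condition")])
  i2 <- items$sentence_id[items$fan_condition == 2L]
  i4 <- items$sentence_id[items$fan_condition == 4L]
  if (length(i2) == 0L || length(i4) == 0L) {
    stop("need target trials in both fan conditions")
  }
  # participant x item matrix of mean log RTs (rounds averaged)
  all_items <- c(i2, i4)
  M <- matrix(NA_real_, n, length(all_items),
              dimnames = list(pps, as.character(all_items)))
  agg <- tapply(log(tt$rt_ms),
                list(factor(tt$participant_id, levels = pps),
                     factor(tt$sentence_id, levels = all_items)),
                mean)
  M[] <- agg
  c2 <- seq_along(i2)
  c4 <- length(i2) + seq_along(i4)
  diffs <- rowMeans(M[, c4, drop = FALSE], na.rm = TRUE) -
    rowMeans(M[, c2, drop = FALSE], na.rm = TRUE)
  if (anyNA(diffs)) {
    warning("dropping ", sum(is.na(diffs)),
            " participant(s) without trials in both fan conditions")
    keep <- !is.na(diffs)
    M <- M[keep, , drop = FALSE]
    diffs <- diffs[keep]
    n <- length(diffs)
    if (n < 2L) stop("need at least 2 participants to estimate the fan effect")
  }
  boot <- with_seed(rng_seed, {
    vapply(seq_len(n_boot), function(b) {
      rp <- sample.int(n, n, replace = TRUE)
      r2 <- sample(c2, length(c2), replace = TRUE)
      r4 <- sample(c4, length(c4), replace = TRUE)
      mean(rowMeans(M[rp, r4, drop = FALSE], na.rm = TRUE) -
             rowMeans(M[rp, r2, drop = FALSE], na.rm = TRUE), na.rm = TRUE)
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  structure(
    list(estimate = mean(diffs),
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
         participant_diffs = diffs, n_participants = n,
         n_boot = as.integer(n_boot), conf_level = conf_level),
    class = "fan_effect"
  )
}

#' @export
print.fan_effect <- function(x, ...) {
  cat(sprintf(
    "Fan effect (fan 4 - fan 2, mean by-participant log-RT difference)\n"))
  cat(sprintf("  estimate: %.4f   %d%% bootstrap CI: [%.4f, %.4f]   (n = %d)\n",
              x$estimate, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$n_participants))
  invisible(x)
}

#' Read a trial table from CSV
#'
#' Accepts both synthetic tables written by this package and externally
#' deposited tables following the same column contract (`participant_id`,
#' `sentence_id`, `kind`, `fan_condition`, `varied_category`, `round`,
#' `rt_ms`, `correct`).
#'
#' @param path CSV file path.
#' @return A validated trial data.frame.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(df))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  cr <- df$correct
  df$correct <- if (is.logical(cr)) cr
  else if (is.numeric(cr)) cr != 0
  else toupper(trimws(cr)) %in% c("TRUE", "T", "1")
  df$fan_condition <- as.integer(df$fan_condition)
  if (any(df$rt_ms <= 0)) stop("rt_ms must be positive")
  if (!all(df$fan_condition %in% c(2L, 4L))) {
    stop("fan_condition must be 2 or 4")
  }
  df
}

#' Write a trial table to CSV
#'
#' @param trials Trial data.frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, intersect(c(trial_columns, names(trials)),
                                      names(trials))],
                   path, row.names = FALSE)
  invisible(path)
}
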