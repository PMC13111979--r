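# Fan-experiment stimulus designs: targets, re-paired foils, training pairs.
#
# A design is a set of 24 study sentences of the form "De <person> is in
# <de/het> <location>". One category (person or location) is held at fan 2
# while the other varies between fan 2 and fan 4: 8 sentences have both
# concepts at fan 2 and 16 have the varied category at fan 4.

# Fixed letter pattern shared by the classic and semantic designs:
# varied-category groups a-d are fan 2 (2 items each), e-h are fan 4
# (4 items each); fixed-category groups A-L all contribute 2 sentences.
fan_pattern <- function() {
  data.frame(
    varied_group = c("a", "b", "a", "c", "b", "d", "c", "d",
                     "e", "f", "e", "f", "e", "g", "e", "g",
                     "f", "h", "f", "h", "g", "h", "g", "h"),
    varied_item  = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 2L,
                     1L, 1L, 2L, 2L, 3L, 1L, 4L, 2L,
                     3L, 1L, 4L, 2L, 3L, 3L, 4L, 4L),
    fixed_group  = rep(LETTERS[1:12], each = 2L),
    fixed_item   = rep(1:2, times = 12L),
    stringsAsFactors = FALSE
  )
}

varied_fan_of_group <- function(group) ifelse(group %in% c("a", "b", "c", "d"), 2L, 4L)

new_fan_design <- function(targets, foils, varied_category, design_mode) {
  structure(
    list(
      targets = targets,
      foils = foils,
      varied_category = varied_category,
      design_mode = design_mode
    ),
    class = "fan_design"
  )
}

render_sentence <- function(person, determiner, location) {
  sprintf("De %s is in %s %s", person, determiner, location)
}

assemble_targets <- function(pattern, varied_category, varied_words, fixed_words,
                             determiners) {
  if (varied_category == "person") {
    person <- varied_words
    location <- fixed_words
    group_person <- pattern$varied_group
    group_location <- pattern$fixed_group
    person_fan <- varied_fan_of_group(pattern$varied_group)
    location_fan <- rep(2L, nrow(pattern))
  } else {
    person <- fixed_words
    location <- varied_words
    group_person <- pattern$fixed_group
    group_location <- pattern$varied_group
    person_fan <- rep(2L, nrow(pattern))
    location_fan <- varied_fan_of_group(pattern$varied_group)
  }
  det <- unname(determiners[location])
  data.frame(
    sentence_id = seq_len(nrow(pattern)),
    kind = "target",
    person = person,
    location = location,
    determiner = det,
    person_fan = person_fan,
    location_fan = location_fan,
    group_person = group_person,
    group_location = group_location,
    text = render_sentence(person, det, location),
    stringsAsFactors = FALSE
  )
}

det_imbalance <- function(dets) abs(sum(dets == "de") - sum(dets == "het"))

#' Build a classic fan design
#'
#' Constructs a 24-sentence study set following the classic fan pattern:
#' lexical items are randomly assigned to pattern letters, every sentence of a
#' group reuses one identical word, 8 sentences have both concepts at fan 2
#' and 16 have the varied category at fan 4. Re-paired foils are generated
#' alongside the targets.
#'
#' @param person_lexicon Character vector of person words (all take the
#'   determiner "de").
#' @param location_lexicon Either a data.frame with columns `word` and
#'   `determiner` ("de" or "het"), or a character vector of location words
#'   (determiner then defaults to "de", which usually cannot satisfy the
#'   determiner-balance constraint; supply real determiners).
#' @param varied_category Which category carries the fan manipulation,
#'   `"person"` or `"location"`.
#' @param rng_seed Integer seed; the design is a deterministic function of the
#'   seed and the lexicons.
#' @param det_balance_tol Maximum allowed difference between the counts of
#'   "de" and "het" among target-location determiners (default 2).
#' @param max_tries Rejection-sampling budget for the determiner balance.
#' @return An object of class `fan_design`: a list with data.frames `targets`
#'   and `foils` (columns `sentence_id`, `kind`, `person`, `location`,
#'   `determiner`, `person_fan`, `location_fan`, `group_person`,
#'   `group_location`, `text`) plus `varied_category` and `design_mode`.
#' @seealso [build_semantic_design()], [make_foils()], [to_training_pairs()]
#' @export
build_classic_design <- function(person_lexicon, location_lexicon,
                                 varied_category = c("person", "location"),
                                 rng_seed = 1L, det_balance_tol = 2L,
                                 max_tries = 1000L) {
  varied_category <- match.arg(varied_category)
  location_lexicon <- as_location_lexicon(location_lexicon)
  person_lexicon <- unique(as.character(person_lexicon))
  n_varied <- 8L
  n_fixed <- 12L
  need_person <- if (varied_category == "person") n_varied else n_fixed
  need_location <- if (varied_category == "person") n_fixed else n_varied
  if (length(person_lexicon) < need_person) {
    stop("lexicon too small: need at least ", need_person,
         " person words, got ", length(person_lexicon))
  }
  if (nrow(location_lexicon) < need_location) {
    stop("lexicon too small: need at least ", need_location,
         " location words, got ", nrow(location_lexicon))
  }
  determiners <- stats::setNames(location_lexicon$determiner, location_lexicon$word)
  pattern <- fan_pattern()

  design <- with_seed(rng_seed, {
    targets <- NULL
    for (try in seq_len(max_tries)) {
      persons <- sample(person_lexicon, need_person)
      locations <- sample(location_lexicon$word, need_location)
      if (varied_category == "person") {
        varied_words <- persons[match(pattern$varied_group, letters[1:8])]
        fixed_words <- locations[match(pattern$fixed_group, LETTERS[1:12])]
      } else {
        varied_words <- locations[match(pattern$varied_group, letters[1:8])]
        fixed_words <- persons[match(pattern$fixed_group, LETTERS[1:12])]
      }
      cand <- assemble_targets(pattern, varied_category, varied_words,
                               fixed_words, determiners)
      if (det_imbalance(cand$determiner) <= det_balance_tol) {
        targets <- cand
        break
      }
    }
    if (is.null(targets)) {
      stop("could not satisfy determiner balance |#de - #het| <= ",
           det_balance_tol, " within ", max_tries, " tries; ",
           "supply a location lexicon with a better de/het mix or raise ",
           "det_balance_tol")
    }
    d <- new_fan_design(targets, NULL, varied_category, "classic")
    d$foils <- make_foils(d, rng_seed = sample.int(.Machine$integer.max, 1L))
    d
  })
  validate_fan_design(design)
  design
}

#' Build a semantic fan design
#'
#' Constructs the semantic-similarity variant of the fan design: all 24 target
#' sentences use pairwise-distinct words, and the fan of a sentence is carried
#' by the semantic group of its varied-category word (groups of similar words
#' stand in for a repeated word). Group order and within-group item order are
#' shuffled before assignment to the pattern.
#'
#' @param groups_person,groups_location Named lists of character vectors, one
#'   vector of semantically similar words per group. Varied-category groups
#'   assigned to fan 4 must have at least 4 members; all other groups at least
#'   2.
#' @param location_determiners Named character vector mapping location words to
#'   "de"/"het"; unnamed words default to "de".
#' @inheritParams build_classic_design
#' @return A `fan_design` with `design_mode = "semantic"`.
#' @export
build_semantic_design <- function(groups_person, groups_location,
                                  varied_category = c("person", "location"),
                                  rng_seed = 1L, location_determiners = NULL,
                                  det_balance_tol = 2L, max_tries = 1000L) {
  varied_category <- match.arg(varied_category)
  groups_person <- normalize_groups(groups_person, "person")
  groups_location <- normalize_groups(groups_location, "location")
  varied_groups <- if (varied_category == "person") groups_person else groups_location
  fixed_groups <- if (varied_category == "person") groups_location else groups_person
  if (length(varied_groups) < 8L) {
    stop("need at least 8 ", varied_category, " groups, got ",
         length(varied_groups))
  }
  fixed_cat <- other_category(varied_category)
  if (length(fixed_groups) < 12L) {
    stop("need at least 12 ", fixed_cat, " groups, got ", length(fixed_groups))
  }
  determiners <- resolve_determiners(location_determiners,
                                     unlist(groups_location, use.names = FALSE))
  pattern <- fan_pattern()

  design <- with_seed(rng_seed, {
    targets <- NULL
    for (try in seq_len(max_tries)) {
      shuffle_members <- function(m) {
        id <- attr(m, "group_id")
        m <- sample(m)
        attr(m, "group_id") <- id
        m
      }
      vg <- lapply(sample(varied_groups), shuffle_members)
      fg <- lapply(sample(fixed_groups), shuffle_members)
      vsel <- vg[1:8]
      fsel <- fg[1:12]
      names(vsel) <- letters[1:8]
      names(fsel) <- LETTERS[1:12]
      need <- c(a = 2L, b = 2L, c = 2L, d = 2L, e = 4L, f = 4L, g = 4L, h = 4L)
      short <- names(need)[vapply(names(need), function(l) length(vsel[[l]]) < need[[l]], logical(1))]
      if (length(short)) {
        orig <- vapply(short, function(l) attr(vsel[[l]], "group_id") %||% l, character(1))
        stop("group '", paste(orig, collapse = "', '"),
             "' has fewer members than its assigned fan")
      }
      fshort <- names(fsel)[vapply(fsel, length, integer(1)) < 2L]
      if (length(fshort)) {
        orig <- vapply(fshort, function(l) attr(fsel[[l]], "group_id") %||% l, character(1))
        stop("group '", paste(orig, collapse = "', '"),
             "' has fewer members than its assigned fan")
      }
      varied_words <- mapply(function(g, i) vsel[[g]][i],
                             pattern$varied_group, pattern$varied_item)
      fixed_words <- mapply(function(g, i) fsel[[g]][i],
                            pattern$fixed_group, pattern$fixed_item)
      vnames <- vapply(pattern$varied_group,
                       function(l) attr(vsel[[l]], "group_id") %||% l, character(1))
      fnames <- vapply(pattern$fixed_group,
                       function(l) attr(fsel[[l]], "group_id") %||% l, character(1))
      cand <- assemble_targets(pattern, varied_category,
                               unname(varied_words), unname(fixed_words),
                               determiners)
      if (varied_category == "person") {
        cand$group_person <- unname(vnames)
        cand$group_location <- unname(fnames)
      } else {
        cand$group_location <- unname(vnames)
        cand$group_person <- unname(fnames)
      }
      if (det_imbalance(cand$determiner) <= det_balance_tol) {
        targets <- cand
        break
      }
    }
    if (is.null(targets)) {
      stop("could not satisfy determiner balance |#de - #het| <= ",
           det_balance_tol, " within ", max_tries,
           " tries; check location_determiners or raise det_balance_tol")
    }
    d <- new_fan_design(targets, NULL, varied_category, "semantic")
    d$foils <- make_foils(d, rng_seed = sample.int(.Machine$integer.max, 1L))
    d
  })
  validate_fan_design(design)
  design
}

# Accept a named list of character vectors; keep group ids on each element.
normalize_groups <- function(groups, category) {
  if (is.null(groups) || length(groups) == 0L) {
    stop("no ", category, " groups supplied")
  }
  if (!is.list(groups)) stop(category, " groups must be a list of character vectors")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0(substr(category, 1, 1), seq_along(groups))
  }
  mapply(function(members, id) {
    members <- as.character(members)
    attr(members, "group_id") <- id
    members
  }, groups, names(groups), SIMPLIFY = FALSE)
}

resolve_determiners <- function(location_determiners, words) {
  det <- stats::setNames(rep("de", length(words)), words)
  if (!is.null(location_determiners)) {
    known <- intersect(names(location_determiners), words)
    det[known] <- location_determiners[known]
  }
  if (!all(det %in% c("de", "het"))) {
    stop("location determiners must be 'de' or 'het'")
  }
  det
}

as_location_lexicon <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("word", "determiner") %in% names(x))) {
      stop("location lexicon data.frame needs columns 'word' and 'determiner'")
    }
    x <- x[!duplicated(x$word), c("word", "determiner")]
    if (!all(x$determiner %in% c("de", "het"))) {
      stop("location determiners must be 'de' or 'het'")
    }
    return(x)
  }
  data.frame(word = unique(as.character(x)), determiner = "de",
             stringsAsFactors = FALSE)
}

#' Create re-paired foils for a fan design
#'
#' Foils re-pair person and location words that both occur among the targets
#' but never co-occur in any target sentence. The permutation preserves each
#' word's number of occurrences, so foil fan conditions mirror the target fan
#' distribution. A seeded rejection sampler is tried first; if no valid
#' permutation is found within the budget, a deterministic backtracking search
#' runs, and an error is raised only when no valid re-pairing exists at all.
#'
#' @param design A `fan_design` with 24 targets.
#' @param rng_seed Integer seed for the shuffle.
#' @param max_tries Rejection-sampling budget before backtracking.
#' @return A data.frame of 24 foil sentences (same columns as targets,
#'   `kind = "foil"`), fan labels inherited from the constituent words' groups.
#' @export
make_foils <- function(design, rng_seed = 1L, max_tries = 1000L) {
  stopifnot(inherits(design, "fan_design"))
  tg <- design$targets
  if (nrow(tg) == 0L) stop("design has no targets")
  target_pairs <- paste(tg$person, tg$location, sep = "\r")
  persons <- tg$person
  # person-side bookkeeping for fan/group inheritance
  pinfo <- unique(tg[, c("person", "person_fan", "group_person")])
  linfo <- tg[, c("location", "determiner", "location_fan", "group_location")]

  # greedy sequential assignment with random restarts: for each location slot
  # draw a person with remaining multiplicity whose pairing is neither a
  # target pair nor an already-used foil pair; restart when stuck
  greedy_once <- function() {
    pool <- table(persons)
    names_pool <- names(pool)
    counts <- as.integer(pool)
    out <- character(nrow(tg))
    used <- character(0)
    for (slot in sample.int(nrow(tg))) {
      loc <- tg$location[slot]
      cand <- names_pool[counts > 0L]
      cand_pairs <- paste(cand, loc, sep = "\r")
      cand <- cand[!(cand_pairs %in% target_pairs) &
                     !(cand_pairs %in% used)]
      if (length(cand) == 0L) {
        return(NULL)
      }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      out[slot] <- p
      used <- c(used, paste(p, loc, sep = "\r"))
      counts[match(p, names_pool)] <- counts[match(p, names_pool)] - 1L
    }
    out
  }
  perm <- with_seed(rng_seed, {
    res <- NULL
    for (i in seq_len(max_tries)) {
      res <- greedy_once()
      if (!is.null(res)) break
    }
    res %||% backtrack_foils(persons, tg$location, target_pairs)
  })
  if (is.null(perm)) {
    stop("no valid foil re-pairing exists for this design")
  }
  fl <- data.frame(
    sentence_id = nrow(tg) + seq_len(nrow(tg)),
    kind = "foil",
    person = perm,
    location = linfo$location,
    determiner = linfo$determiner,
    person_fan = pinfo$person_fan[match(perm, pinfo$person)],
    location_fan = linfo$location_fan,
    group_person = pinfo$group_person[match(perm, pinfo$person)],
    group_location = linfo$group_location,
    text = render_sentence(perm, linfo$determiner, linfo$location),
    stringsAsFactors = FALSE
  )
  fl
}

# Deterministic depth-first search over person assignments (multiset-aware).
backtrack_foils <- function(persons, locations, target_pairs) {
  n <- length(locations)
  pool <- sort(persons)
  assigned <- character(n)
  used_pairs <- character(0)
  search <- function(slot, pool) {
    if (slot > n) {
      return(TRUE)
    }
    for (p in unique(pool)) {
      pair <- paste(p, locations[slot], sep = "\r")
      if (pair %in% target_pairs || pair %in% used_pairs) next
      assigned[slot] <<- p
      used_pairs <<- c(used_pairs, pair)
      if (search(slot + 1L, pool[-match(p, pool)])) {
        return(TRUE)
      }
      used_pairs <<- used_pairs[-length(used_pairs)]
    }
    FALSE
  }
  if (search(1L, pool)) assigned else NULL
}

#' Convert a fan design into skip-gram training pairs
#'
#' One training pair per target sentence: the varied-category word is the
#' target token; the other-category word and the article preceding the target
#' word are its two context tokens. When the location fan is varied the
#' article is the location's determiner ("de"/"het"); when the person fan is
#' varied it is the sentence-initial article, always "de". Foils contribute
#' no pairs.
#'
#' @param design A `fan_design`.
#' @return A data.frame with one row per target sentence and columns
#'   `sentence_id`, `target`, `context_word`, `article`, `fan_condition`.
#' @export
to_training_pairs <- function(design) {
  stopifnot(inherits(design, "fan_design"))
  tg <- design$targets
  if (is.null(tg) || nrow(tg) == 0L) {
    return(data.frame(sentence_id = integer(0), target = character(0),
                      context_word = character(0), article = character(0),
                      fan_condition = integer(0), stringsAsFactors = FALSE))
  }
  if (design$varied_category == "location") {
    data.frame(sentence_id = tg$sentence_id, target = tg$location,
               context_word = tg$person, article = tg$determiner,
               fan_condition = tg$location_fan, stringsAsFactors = FALSE)
  } else {
    data.frame(sentence_id = tg$sentence_id, target = tg$person,
               context_word = tg$location, article = "de",
               fan_condition = tg$person_fan, stringsAsFactors = FALSE)
  }
}

# Long form: one row per (target, context-token) edge; the training corpus.
training_edges <- function(pairs) {
  rbind(
    data.frame(sentence_id = pairs$sentence_id, target = pairs$target,
               context = pairs$context_word, context_type = "word",
               stringsAsFactors = FALSE),
    data.frame(sentence_id = pairs$sentence_id, target = pairs$target,
               context = pairs$article, context_type = "article",
               stringsAsFactors = FALSE)
  )
}

#' Fan condition of each sentence in a design
#'
#' The condition label of a sentence (target or foil) is the fan of its
#' varied-category word's group.
#'
#' @param design A `fan_design`.
#' @return Named integer vector keyed by `sentence_id`.
#' @export
fan_conditions <- function(design) {
  all <- rbind(design$targets, design$foils)
  fan <- if (design$varied_category == "person") all$person_fan else all$location_fan
  stats::setNames(as.integer(fan), all$sentence_id)
}

#' Validate the structural invariants of a fan design
#'
#' Checks the full invariant set: 24 targets with the 8/16 fan split, per-group
#' sentence counts matching the stored fan labels, word-reuse rules for the
#' classic and semantic modes, foil re-pairing constraints, and determiner
#' balance.
#'
#' @param design A `fan_design`.
#' @param det_balance_tol Determiner-balance tolerance used in the check.
#' @return Invisibly `TRUE`; errors with all violations otherwise.
#' @export
validate_fan_design <- function(design, det_balance_tol = 2L) {
  stopifnot(inherits(design, "fan_design"))
  tg <- design$targets
  fl <- design$foils
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  if (nrow(tg) != 24L) note("design must have 24 targets")
  vfan <- if (design$varied_category == "person") tg$person_fan else tg$location_fan
  ffan <- if (design$varied_category == "person") tg$location_fan else tg$person_fan
  if (sum(vfan == 2L & ffan == 2L) != 8L) note("expected exactly 8 fan 2-2 targets")
  if (sum(vfan == 4L) != 16L) note("expected exactly 16 targets with the varied category at fan 4")
  if (any(tg$person_fan == 4L & tg$location_fan == 4L)) {
    note("at most one of person_fan/location_fan may be 4")
  }
  if (!all(c(tg$person_fan, tg$location_fan) %in% c(2L, 4L))) {
    note("fan values must be 2 or 4")
  }

  vgroup <- if (design$varied_category == "person") tg$group_person else tg$group_location
  fgroup <- if (design$varied_category == "person") tg$group_location else tg$group_person
  counts <- table(vgroup)
  for (g in names(counts)) {
    fan_lab <- unique(vfan[vgroup == g])
    if (length(fan_lab) != 1L || counts[[g]] != fan_lab) {
      note(paste0("varied group '", g, "' contributes ", counts[[g]],
                  " sentences but carries fan label ",
                  paste(fan_lab, collapse = "/")))
    }
  }
  fcounts <- table(fgroup)
  if (!all(fcounts == 2L)) note("every fixed-category group must contribute exactly 2 sentences")

  vwords <- if (design$varied_category == "person") tg$person else tg$location
  fwords <- if (design$varied_category == "person") tg$location else tg$person
  if (design$design_mode == "classic") {
    for (g in unique(vgroup)) {
      if (length(unique(vwords[vgroup == g])) != 1L) {
        note(paste0("classic mode: varied group '", g, "' must reuse one word"))
      }
    }
    for (g in unique(fgroup)) {
      if (length(unique(fwords[fgroup == g])) != 1L) {
        note(paste0("classic mode: fixed group '", g, "' must reuse one word"))
      }
    }
  } else {
    if (anyDuplicated(tg$person)) note("semantic mode: person words must be pairwise distinct")
    if (anyDuplicated(tg$location)) note("semantic mode: location words must be pairwise distinct")
  }

  if (any(tg$text != render_sentence(tg$person, tg$determiner, tg$location))) {
    note("sentence text must match 'De <person> is in <det> <location>'")
  }
  if (det_imbalance(tg$determiner) > det_balance_tol) {
    note(paste0("determiner imbalance exceeds tolerance ", det_balance_tol))
  }

  if (!is.null(fl)) {
    if (nrow(fl) != 24L) note("design must have 24 foils")
    tpairs <- paste(tg$person, tg$location)
    fpairs <- paste(fl$person, fl$location)
    if (any(fpairs %in% tpairs)) note("a foil pair duplicates a target pair")
    if (anyDuplicated(fpairs)) note("duplicate foil pairs")
    if (!all(fl$person %in% tg$person) || !all(fl$location %in% tg$location)) {
      note("foil words must occur among targets")
    }
  }
  if (length(bad)) {
    stop("invalid fan design:\n  - ", paste(bad, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' @export
print.fan_design <- function(x, ...) {
  cat(sprintf("Fan design (%s mode, %s fan varied)\n", x$design_mode,
              x$varied_category))
  vfan <- fan_conditions(x)[as.character(x$targets$sentence_id)]
  cat(sprintf("  %d targets (%d at fan 2, %d at fan 4), %d foils\n",
              nrow(x$targets), sum(vfan == 2L), sum(vfan == 4L),
              if (is.null(x$foils)) 0L else nrow(x$foils)))
  cat("  e.g. ", x$targets$text[1], "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fan_design <- function(x, ...) {
  rbind(x$targets, x$foils)
}

#' Write a fan design to a TSV file
#'
#' @param design A `fan_design`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fan design from a TSV file
#'
#' The varied category is inferred from the fan labels and the design mode
#' from word reuse among targets.
#'
#' @param path File written by [write_design_tsv()].
#' @return A `fan_design`.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tg <- df[df$kind == "target", ]
  fl <- df[df$kind == "foil", ]
  if (nrow(fl) == 0L) fl <- NULL
  varied <- if (any(tg$person_fan == 4L)) "person" else "location"
  vwords <- if (varied == "person") tg$person else tg$location
  mode <- if (anyDuplicated(vwords)) "classic" else "semantic"
  design <- new_fan_design(tg, fl, varied, mode)
  validate_fan_design(design)
  design
}
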