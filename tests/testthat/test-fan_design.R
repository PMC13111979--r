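# Stimulus design construction: classic and semantic modes, foils, pairs.

test_that("classic designs satisfy the full invariant set over many seeds", {
  for (seed in c(1:40, 101:160)) {
    des <- quick_classic(seed, varied = if (seed %% 2) "person" else "location")
    expect_invisible(validate_fan_design(des))
  }
})

test_that("classic design has the 8/16 fan split and correct group counts", {
  des <- quick_classic(3, varied = "person")
  tg <- des$targets
  expect_equal(nrow(tg), 24L)
  expect_equal(sum(tg$person_fan == 2 & tg$location_fan == 2), 8L)
  expect_equal(sum(tg$person_fan == 4), 16L)
  # brute-force recount: sentences per varied group equal the stored fan
  for (g in unique(tg$group_person)) {
    n <- sum(tg$group_person == g)
    expect_equal(n, unique(tg$person_fan[tg$group_person == g]))
  }
  # fixed groups contribute exactly 2 sentences each
  expect_true(all(table(tg$group_location) == 2L))
  # classic reuse: one word per group
  expect_true(all(tapply(tg$person, tg$group_person,
                         function(w) length(unique(w))) == 1L))
})

test_that("varied-location classic design puts fan-4 location groups in 4 sentences", {
  des <- quick_classic(7, varied = "location")
  tg <- des$targets
  counts <- table(tg$group_location)
  fans <- tapply(tg$location_fan, tg$group_location, unique)
  expect_true(all(counts[fans == 4] == 4L))
  expect_true(all(counts[fans == 2] == 2L))
})

test_that("designs are deterministic under a fixed seed", {
  expect_identical(quick_classic(11), quick_classic(11))
  s <- quick_semantic(4)
  s2 <- quick_semantic(4)
  expect_identical(s$design, s2$design)
  expect_false(identical(quick_classic(11), quick_classic(12)))
})

test_that("too-small lexicons raise category-naming errors", {
  expect_error(
    build_classic_design(c("a", "b"), demo_lexicon$locations, "person", 1),
    "lexicon too small.*person"
  )
  expect_error(
    build_classic_design(demo_lexicon$persons,
                         demo_lexicon$locations[1:3, ], "person", 1),
    "lexicon too small.*location"
  )
})

test_that("semantic designs use 48 pairwise-distinct content words", {
  for (seed in 1:20) {
    qs <- quick_semantic(seed, varied = if (seed %% 2) "person" else "location")
    tg <- qs$design$targets
    expect_equal(anyDuplicated(tg$person), 0L)
    expect_equal(anyDuplicated(tg$location), 0L)
    expect_equal(length(unique(c(tg$person, tg$location))), 48L)
    expect_invisible(validate_fan_design(qs$design))
  }
})

test_that("semantic fan-4 groups contribute 4 sentences with 4 distinct words", {
  qs <- quick_semantic(9)
  tg <- qs$design$targets
  fan4_groups <- unique(tg$group_person[tg$person_fan == 4])
  for (g in fan4_groups) {
    words <- tg$person[tg$group_person == g]
    expect_length(words, 4L)
    expect_length(unique(words), 4L)
  }
})

test_that("semantic design rejects empty or undersized group lists", {
  expect_error(build_semantic_design(list(), list(g = c("x", "y")), "person", 1),
               "no person groups")
  sp <- synth_clustered_space(rng_seed = 2)
  few <- sp$groups_person[1:3]
  expect_error(
    build_semantic_design(few, sp$groups_location, "person", 1,
                          location_determiners = sp$determiners),
    "at least 8"
  )
  # a group too small for its assigned fan is named in the error
  small <- lapply(sp$groups_person, function(g) g[1:2])
  expect_error(
    build_semantic_design(small, sp$groups_location, "person", 1,
                          location_determiners = sp$determiners),
    "fewer members than its assigned fan"
  )
})

test_that("foils re-pair target words without duplicating any target pair", {
  for (seed in 1:25) {
    des <- quick_classic(seed)
    tg <- des$targets
    fl <- des$foils
    expect_equal(nrow(fl), 24L)
    tpairs <- paste(tg$person, tg$location)
    fpairs <- paste(fl$person, fl$location)
    expect_false(any(fpairs %in% tpairs))
    expect_equal(anyDuplicated(fpairs), 0L)
    expect_true(all(fl$person %in% tg$person))
    expect_true(all(fl$location %in% tg$location))
    # fan labels inherited from the words' groups
    pinfo <- unique(tg[, c("person", "person_fan")])
    expect_equal(fl$person_fan, pinfo$person_fan[match(fl$person, pinfo$person)])
  }
})

test_that("foil output lies within the brute-force enumeration of valid re-pairings", {
  des <- toy_design_4()
  # all person permutations that avoid every target pair (here: derangements)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:4)), , drop = FALSE]
  valid <- perms[apply(perms, 1, function(p) all(p != 1:4)), , drop = FALSE]
  valid_sets <- apply(valid, 1, function(p) {
    paste(paste0("p", p), paste0("l", 1:4), collapse = ";")
  })
  for (seed in 1:10) {
    fl <- make_foils(des, rng_seed = seed)
    got <- paste(fl$person, fl$location, collapse = ";")
    expect_true(got %in% valid_sets)
  }
})

test_that("foil generation errors when no valid re-pairing exists", {
  des <- toy_design_4()
  des$targets <- des$targets[1, ]  # single pair cannot be re-paired
  expect_error(make_foils(des, 1), "no valid foil re-pairing")
})

test_that("training pairs follow the target/context convention", {
  # location varied: location is the target; person and its article are cues
  des <- quick_classic(2, varied = "location")
  pairs <- to_training_pairs(des)
  expect_equal(nrow(pairs), 24L)
  expect_true(all(pairs$target %in% des$targets$location))
  expect_equal(pairs$context_word, des$targets$person)
  expect_equal(pairs$article, des$targets$determiner)
  # person varied: sentence-initial article is always "de"
  des_p <- quick_classic(2, varied = "person")
  pairs_p <- to_training_pairs(des_p)
  expect_true(all(pairs_p$target %in% des_p$targets$person))
  expect_true(all(pairs_p$article == "de"))
  # 24 pairs expand to 48 (target, context-token) edges; none from foils
  edges <- fanmem:::training_edges(pairs)
  expect_equal(nrow(edges), 48L)
  expect_true(all(edges$sentence_id %in% des$targets$sentence_id))
})

test_that("an empty design yields an empty pair list", {
  des <- toy_design_4()
  des$targets <- des$targets[0, ]
  expect_equal(nrow(to_training_pairs(des)), 0L)
})

test_that("determiner balance holds among target locations", {
  for (seed in 1:15) {
    des <- quick_classic(seed, varied = if (seed %% 2) "person" else "location")
    dets <- des$targets$determiner
    expect_lte(abs(sum(dets == "de") - sum(dets == "het")), 2L)
  }
})

test_that("designs round-trip through TSV serialization", {
  des <- quick_classic(5, varied = "location")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design_tsv(des, path)
  back <- read_design_tsv(path)
  expect_equal(back$targets, des$targets, ignore_attr = TRUE)
  expect_equal(back$foils, des$foils, ignore_attr = TRUE)
  expect_equal(back$varied_category, des$varied_category)
  expect_equal(back$design_mode, des$design_mode)
})

test_that("fan condition labels equal the varied-category fan for all sentences", {
  des <- quick_classic(6, varied = "location")
  fc <- fan_conditions(des)
  all_rows <- rbind(des$targets, des$foils)
  expect_equal(unname(fc[as.character(all_rows$sentence_id)]),
               all_rows$location_fan)
})
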