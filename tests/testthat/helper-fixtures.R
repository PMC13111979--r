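# Shared fixtures: small lexicons, toy designs, and quick model configs.

demo_lexicon <- fanmem_lexicon()

quick_classic <- function(seed = 1L, varied = "person") {
  build_classic_design(demo_lexicon$persons, demo_lexicon$locations,
                       varied_category = varied, rng_seed = seed)
}

quick_semantic <- function(seed = 1L, varied = "person") {
  sp <- synth_clustered_space(n_groups_person = 12L, n_groups_location = 12L,
                              rng_seed = seed)
  list(space = sp,
       design = build_semantic_design(sp$groups_person, sp$groups_location,
                                      varied_category = varied, rng_seed = seed,
                                      location_determiners = sp$determiners))
}

# tiny config for unit tests that do not need convergence
tiny_config <- function(...) {
  args <- utils::modifyList(list(dimension = 12L, epochs = 2L), list(...))
  do.call(sgns_config, args)
}

# hand-made minimal design: 4 targets, distinct words, for foil enumeration
toy_design_4 <- function() {
  tg <- data.frame(
    sentence_id = 1:4,
    kind = "target",
    person = paste0("p", 1:4),
    location = paste0("l", 1:4),
    determiner = "de",
    person_fan = 2L,
    location_fan = 2L,
    group_person = paste0("gp", 1:4),
    group_location = paste0("gl", 1:4),
    text = sprintf("De p%d is in de l%d", 1:4, 1:4),
    stringsAsFactors = FALSE
  )
  structure(list(targets = tg, foils = NULL, varied_category = "person",
                 design_mode = "semantic"),
            class = "fan_design")
}

# two well-separated clusters in the plane, padded to d dims
toy_clustered_store <- function(d = 4) {
  base <- rbind(
    a1 = c(1, 0.05), a2 = c(1, -0.05), a3 = c(0.95, 0),
    b1 = c(0, 1), b2 = c(0.05, 1), b3 = c(-0.05, 0.97)
  )
  cbind(base, matrix(0, nrow(base), d - 2,
                     dimnames = list(rownames(base), NULL)))
}

# trial table with exact, hand-checkable values
toy_trials <- function() {
  data.frame(
    participant_id = rep(c("pp1", "pp2"), each = 3),
    sentence_id = rep(1:3, 2),
    kind = c("target", "target", "foil", "target", "target", "foil"),
    fan_condition = c(2L, 4L, 2L, 2L, 4L, 4L),
    varied_category = "person",
    round = 1L,
    rt_ms = c(1000, 2000, 1500, 1200, 1800, 1600),
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
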