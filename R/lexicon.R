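#' Built-in demo lexicon
#'
#' A small Dutch lexicon of the kind used in person-location fan experiments:
#' occupation words for the person category (all taking the determiner "de")
#' and "in"-compatible location words with their determiners, balanced between
#' "de" and "het". Sufficient for classic designs with either category varied.
#'
#' @return A list with `persons` (character vector, length 16) and `locations`
#'   (data.frame with columns `word`, `determiner`; 8 "de" and 8 "het").
#' @export
fanmem_lexicon <- function() {
  list(
    persons = c("kapitein", "verkoper", "soldaat", "schilder", "cowboy",
                "rechter", "admiraal", "kolonel", "dokter", "wetenschapper",
                "jager", "advocaat", "notaris", "zanger", "monteur",
                "muzikant"),
    locations = data.frame(
      word = c("toren", "grot", "schuur", "afgrond", "fabriek", "woning",
               "faculteit", "tempel",
               "zwembad", "dorp", "ravijn", "fort", "kasteel", "gehucht",
               "bos", "terras"),
      determiner = rep(c("de", "het"), each = 8L),
      stringsAsFactors = FALSE
    )
  )
}
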