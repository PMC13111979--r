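# Word-vector spaces: cosine utilities, nearest neighbors, semantic-group
# validation, synthetic clustered spaces, and word2vec text-format I/O.
#
# A vector store is a plain numeric matrix with one row per token (rownames
# are the tokens) and one column per dimension.

as_store <- function(store) {
  if (!is.matrix(store) || !is.numeric(store) || is.null(rownames(store))) {
    stop("a word-vector store must be a numeric matrix with token rownames")
  }
  if (anyDuplicated(rownames(store))) stop("store tokens must be unique")
  store
}

store_lookup <- function(store, tokens) {
  idx <- match(tokens, rownames(store))
  if (anyNA(idx)) {
    stop("token(s) not in vector store: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all-zero.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have the same length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Nearest neighbors of a token by cosine similarity
#'
#' Ranks all other tokens in the store by cosine similarity to the query,
#' descending; ties are broken lexicographically. The query itself is never
#' returned.
#'
#' @param store Numeric matrix with token rownames.
#' @param query Token present in the store.
#' @param n Number of neighbors (less than the vocabulary size).
#' @return A data.frame with columns `token` and `cosine`, `n` rows.
#' @export
nearest_neighbors <- function(store, query, n = 20L) {
  store <- as_store(store)
  qi <- store_lookup(store, query)
  stopifnot(is_count(n, min = 0L), n < nrow(store))
  if (n == 0L) {
    return(data.frame(token = character(0), cosine = numeric(0)))
  }
  q <- store[qi, ]
  others <- store[-qi, , drop = FALSE]
  norms <- sqrt(rowSums(others^2))
  if (any(norms == 0)) stop("store contains a zero vector")
  cos <- as.numeric(others %*% q) / (norms * sqrt(sum(q^2)))
  ord <- order(-cos, rownames(others))
  top <- ord[seq_len(n)]
  data.frame(token = rownames(others)[top], cosine = cos[top],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Check the in-group versus out-group similarity constraint
#'
#' For every word in every group, its minimum cosine similarity to the other
#' members of its own group must exceed its maximum similarity to any member
#' of any other group (within the same category of groups).
#'
#' @param groups Named list of character vectors (one category at a time).
#' @param store Numeric matrix with token rownames covering all members.
#' @return A data.frame of violations with columns `group`, `token`,
#'   `in_group_min`, `out_group_max`; zero rows when the constraint holds.
#' @export
validate_groups <- function(groups, store) {
  store <- as_store(store)
  groups <- normalize_groups(groups, "similarity")
  tokens <- unlist(groups, use.names = FALSE)
  idx <- store_lookup(store, tokens)
  membership <- rep(names(groups), lengths(groups))
  vecs <- store[idx, , drop = FALSE]
  norms <- sqrt(rowSums(vecs^2))
  if (any(norms == 0)) stop("store contains a zero vector")
  cos <- (vecs %*% t(vecs)) / outer(norms, norms)
  violations <- NULL
  for (i in seq_along(tokens)) {
    own <- membership == membership[i]
    own[i] <- FALSE
    if (!any(own) || !any(!own & membership != membership[i])) next
    in_min <- min(cos[i, own])
    out_max <- max(cos[i, membership != membership[i]])
    if (in_min <= out_max) {
      violations <- rbind(violations, data.frame(
        group = membership[i], token = tokens[i],
        in_group_min = in_min, out_group_max = out_max,
        stringsAsFactors = FALSE
      ))
    }
  }
  violations %||% data.frame(group = character(0), token = character(0),
                             in_group_min = numeric(0),
                             out_group_max = numeric(0))
}

#' Generate a synthetic clustered embedding space
#'
#' Emulates the clustered neighborhoods of pretrained lexical embeddings:
#' group centroids are drawn isotropically at unit-expected norm, members are
#' centroid plus isotropic noise scaled by `within_spread`, and the space is
#' regenerated until every group satisfies the in-group > out-group cosine
#' constraint. Location tokens receive alternating "de"/"het" determiners
#' within each group so that designs built from the space balance easily.
#'
#' @param n_groups_person,n_groups_location Number of semantic groups per
#'   category.
#' @param group_size Words per group (at least 2).
#' @param dimension Vector dimensionality.
#' @param within_spread Expected norm of the within-group noise relative to
#'   the unit centroid norm (must be positive).
#' @param rng_seed Integer seed; output is a deterministic function of it.
#' @param max_tries Regeneration budget for the similarity constraint.
#' @return A list with elements `vectors` (token matrix), `groups_person`,
#'   `groups_location` (named lists of tokens), and `determiners` (named
#'   vector for location tokens).
#' @export
synth_clustered_space <- function(n_groups_person = 8L, n_groups_location = 12L,
                                  group_size = 4L, dimension = 100L,
                                  within_spread = 0.15, rng_seed = 1L,
                                  max_tries = 20L) {
  stopifnot(is_count(n_groups_person), is_count(n_groups_location),
            is_count(group_size, min = 2L), is_count(dimension),
            is_number(within_spread), within_spread > 0)
  make_cat <- function(n_groups, prefix) {
    centroids <- matrix(stats::rnorm(n_groups * dimension, sd = 1 / sqrt(dimension)),
                        nrow = n_groups)
    vecs <- centroids[rep(seq_len(n_groups), each = group_size), , drop = FALSE] +
      matrix(stats::rnorm(n_groups * group_size * dimension,
                          sd = within_spread / sqrt(dimension)),
             nrow = n_groups * group_size)
    tokens <- paste0(prefix, rep(seq_len(n_groups), each = group_size),
                     letters[rep(seq_len(group_size), n_groups)])
    rownames(vecs) <- tokens
    groups <- split(tokens, rep(seq_len(n_groups), each = group_size))
    names(groups) <- paste0(toupper(prefix), seq_len(n_groups))
    list(vectors = vecs, groups = groups)
  }
  with_seed(rng_seed, {
    for (try in seq_len(max_tries)) {
      pers <- make_cat(n_groups_person, "per")
      loc <- make_cat(n_groups_location, "loc")
      ok <- nrow(validate_groups(pers$groups, pers$vectors)) == 0L &&
        nrow(validate_groups(loc$groups, loc$vectors)) == 0L
      if (ok) {
        det <- stats::setNames(
          rep(c("de", "het"), length.out = group_size)[rep(seq_len(group_size),
                                                           n_groups_location)],
          rownames(loc$vectors)
        )
        return(list(vectors = rbind(pers$vectors, loc$vectors),
                    groups_person = pers$groups,
                    groups_location = loc$groups,
                    determiners = det))
      }
    }
    stop("could not generate a space satisfying the in-group > out-group ",
         "constraint in ", max_tries, " tries; use a smaller within_spread")
  })
}

#' Read word vectors in word2vec text format
#'
#' The format is a header line "vocab_size dimension" followed by one line per
#' token: the token and `dimension` whitespace-separated floats. Duplicate
#' tokens keep the first occurrence with a warning; a row whose float count
#' disagrees with the header is an error naming the line.
#'
#' @param path Input file.
#' @return Numeric matrix with token rownames.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty word2vec file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L) stop("malformed word2vec header: ", lines[1])
  vocab_size <- as.integer(header[1])
  dimension <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vocab_size) {
    warning("word2vec header declares ", vocab_size, " tokens but file has ",
            length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  tokens <- vapply(parts, `[`, character(1), 1L)
  mat <- matrix(NA_real_, nrow = length(body), ncol = dimension)
  for (i in seq_along(parts)) {
    vals <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (length(vals) != dimension || anyNA(vals)) {
      stop("line ", i + 1L, ": expected ", dimension, " floats for token '",
           tokens[i], "', got ", length(vals))
    }
    mat[i, ] <- vals
  }
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning("duplicate token(s) in word2vec file, keeping first occurrence: ",
            paste(unique(tokens[dup]), collapse = ", "))
    mat <- mat[!dup, , drop = FALSE]
    tokens <- tokens[!dup]
  }
  rownames(mat) <- tokens
  mat
}

#' Write word vectors in word2vec text format
#'
#' @param store Numeric matrix with token rownames.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_word2vec <- function(store, path) {
  store <- as_store(store)
  rows <- vapply(seq_len(nrow(store)), function(i) {
    paste(rownames(store)[i],
          paste(formatC(store[i, ], format = "g", digits = 9), collapse = " "))
  }, character(1))
  writeLines(c(paste(nrow(store), ncol(store)), rows), path)
  invisible(path)
}
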