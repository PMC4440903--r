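#' Design constants of the deviance-based conformity paradigm
#'
#' The paradigm uses a 6-point Likert scale (1 = lowest, 6 = highest) and a
#' fixed per-participant schedule of 180 group-judgment deviations: -2, -1,
#' +1 and +2 occur 30 times each and 0 occurs 60 times, in randomized order.
#'
#' @format `rating_scale()` returns a list with integer elements `minimum`
#'   and `maximum`; `deviation_counts()` returns a named integer vector
#'   giving the number of scheduled occurrences of each deviation level.
#' @examples
#' rating_scale()
#' deviation_counts()
#' @export
rating_scale <- function() {
  list(minimum = 1L, maximum = 6L)
}

#' @rdname rating_scale
#' @export
deviation_counts <- function() {
  c(`-2` = 30L, `-1` = 30L, `0` = 60L, `1` = 30L, `2` = 30L)
}

#' Draw a randomized deviation schedule
#'
#' Returns a uniformly random permutation of the fixed deviation multiset
#' \{-2 x30, -1 x30, 0 x60, +1 x30, +2 x30\} (180 values). The same seed
#' always yields the same order; different seeds permute the same multiset.
#'
#' @param seed Optional integer seed. When supplied, the permutation is drawn
#'   from a local RNG state so the caller's RNG stream is untouched; when
#'   `NULL` the current RNG stream is used (and advanced).
#' @return Integer vector of length 180 with values in -2..2.
#' @examples
#' s <- make_deviation_schedule(seed = 1)
#' table(s)
#' @export
make_deviation_schedule <- function(seed = NULL) {
  counts <- deviation_counts()
  pool <- rep(as.integer(names(counts)), counts)
  if (is.null(seed)) {
    return(sample(pool))
  }
  with_local_seed(seed, sample(pool))
}

#' Apply the boundary-reflection rule to a drawn deviation
#'
#' The presented group judgment is the participant's initial rating plus the
#' drawn deviation. When that sum would leave the rating scale, the deviation
#' is multiplied by -1 before presentation (e.g. an initial rating of 5 with
#' drawn deviation +2 implies an off-scale judgment of 7, so -2 is presented
#' and the group judgment shown is 3). A zero deviation is never reflected.
#' On the 1-6 scale with |deviation| <= 2 the reflected judgment is always in
#' bounds; this is asserted rather than handled.
#'
#' @param initial_rating Integer (or integer-valued) vector of ratings within
#'   the scale bounds.
#' @param drawn_deviation Integer vector in -2..2, recycled against
#'   `initial_rating`.
#' @return A data.frame with columns `presented_deviation` and
#'   `group_judgment`.
#' @examples
#' apply_reflection(5, 2)   # judgment 3, presented deviation -2
#' apply_reflection(1, -2)  # judgment 3, presented deviation +2
#' @export
apply_reflection <- function(initial_rating, drawn_deviation) {
  scale <- rating_scale()
  if (any(!is.finite(initial_rating)) ||
      any(initial_rating < scale$minimum) || any(initial_rating > scale$maximum)) {
    stop("`initial_rating` must lie within the rating scale [",
         scale$minimum, ", ", scale$maximum, "]", call. = FALSE)
  }
  if (any(!drawn_deviation %in% (-2L:2L))) {
    stop("`drawn_deviation` must be in -2..2", call. = FALSE)
  }
  n <- max(length(initial_rating), length(drawn_deviation))
  initial_rating <- rep_len(initial_rating, n)
  drawn_deviation <- rep_len(as.integer(drawn_deviation), n)
  raw <- initial_rating + drawn_deviation
  reflect <- raw < scale$minimum | raw > scale$maximum
  presented <- ifelse(reflect, -drawn_deviation, drawn_deviation)
  judgment <- initial_rating + presented
  stopifnot(all(judgment >= scale$minimum & judgment <= scale$maximum))
  data.frame(presented_deviation = as.integer(presented),
             group_judgment = judgment)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
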