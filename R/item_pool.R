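#' The 27-item pool of five-category ordered items
#'
#' Returns the pool of 27 Likert-type items used throughout the simulation
#' study. Each item is defined by four strictly ascending category boundaries
#' (`b1` < `b2` < `b3` < `b4`) on the latent 0--100 continuum. The first
#' response category covers all positions below `b1`; category `k + 1` begins
#' at boundary `k` (so a position exactly at `b4` scores 5). The pool spans
#' items that differ in location and in the spacing of their boundaries, so
#' that randomly drawn item subsets vary in popularity and skew.
#'
#' @return A data frame with columns `item_id`, `b1`, `b2`, `b3`, `b4`.
#' @examples
#' pool <- likert_pool()
#' nrow(pool)          # 27
#' pool[pool$item_id == 1, ]
#' @export
likert_pool <- function() {
  path <- system.file("extdata", "item_pool.csv",
                      package = "likertdim", mustWork = TRUE)
  pool <- utils::read.csv(path)
  validate_pool(pool)
  pool
}

#' Validate an item pool
#'
#' Checks that a data frame is a usable item pool: columns `item_id` and
#' `b1`..`b4`, distinct item ids, and strictly increasing boundaries per item.
#'
#' @param pool A data frame of item definitions.
#' @return The pool, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_pool <- function(pool) {
  need <- c("item_id", "b1", "b2", "b3", "b4")
  if (!all(need %in% names(pool))) {
    stop("item pool must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(pool$item_id)) stop("item ids must be distinct")
  b <- as.matrix(pool[, c("b1", "b2", "b3", "b4")])
  if (any(t(apply(b, 1, diff)) <= 0)) {
    stop("category boundaries must be strictly increasing within each item")
  }
  invisible(pool)
}

#' Deterministic ('true') response category for a latent position
#'
#' Maps a respondent's position on the latent continuum to the error-free
#' response category of an item: 1 plus the number of category boundaries at
#' or below the position. A position below the first boundary scores 1; a
#' position at or above the fourth boundary scores 5.
#'
#' @param position Numeric vector of latent positions.
#' @param boundaries Numeric vector of 4 strictly increasing boundaries, or a
#'   one-row slice of [likert_pool()].
#' @return Integer vector of categories in 1..5.
#' @examples
#' pool <- likert_pool()
#' true_score(33, pool[pool$item_id == 1, ])   # 4
#' true_score(33, pool[pool$item_id == 12, ])  # 1
#' @export
true_score <- function(position, boundaries) {
  b <- as_boundaries(boundaries)
  1L + findInterval(position, b)
}

as_boundaries <- function(boundaries) {
  if (is.data.frame(boundaries)) {
    stopifnot(nrow(boundaries) == 1)
    boundaries <- as.numeric(boundaries[, c("b1", "b2", "b3", "b4")])
  }
  b <- as.numeric(boundaries)
  if (length(b) != 4 || any(diff(b) <= 0)) {
    stop("an item needs 4 strictly increasing boundaries")
  }
  b
}
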