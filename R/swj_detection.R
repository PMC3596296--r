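#' Square-wave jerk classification parameters
#'
#' An ideal SWJ is two saccades of equal magnitude, exactly opposite
#' direction, separated by a short interval of about 200 ms. The index
#' scores a consecutive saccade pair against this ideal.
#'
#' @param ideal_interval Ideal intra-SWJ interval in seconds (default 0.2).
#' @param max_interval Intervals beyond this score zero (default 0.5 s).
#' @param index_threshold Pairs with index strictly above this are
#'   classified as SWJs (default 0.6).
#' @param max_magnitude Saccades larger than this (deg) are never SWJ
#'   components (default 5).
#' @return A list of class `swj_params`.
#' @export
swj_params <- function(ideal_interval = 0.2, max_interval = 0.5,
                       index_threshold = 0.6, max_magnitude = 5) {
  stopifnot(ideal_interval > 0, ideal_interval < max_interval,
            index_threshold > 0, index_threshold < 1, max_magnitude > 0)
  structure(list(ideal_interval = ideal_interval,
                 max_interval = max_interval,
                 index_threshold = index_threshold,
                 max_magnitude = max_magnitude),
            class = "swj_params")
}

#' SWJ similarity index for a saccade pair
#'
#' Three component scores, each in \[0, 1\], capture the defining SWJ
#' characteristics:
#' \describe{
#'   \item{direction dissimilarity}{`s_dir = (1 - cos(theta2 - theta1)) / 2`
#'     — 1 for exactly opposite saccades, 0 for parallel ones.}
#'   \item{magnitude similarity}{`s_mag = 1 - |m1 - m2| / (m1 + m2)`.}
#'   \item{temporal proximity}{`s_time = max(0, 1 - |dt - ideal| / ideal)`
#'     for `dt <= max_interval`, else 0, with `dt` the offset-of-first to
#'     onset-of-second interval.}
#' }
#' The index is their geometric mean `(s_dir * s_mag * s_time)^(1/3)`, so
#' the ideal pair scores exactly 1 and any degenerate pair scores 0.
#'
#' @param s1,s2 One-row saccade data.frames, `s2` following `s1`.
#' @param params An `swj_params` list.
#' @return Named numeric vector `c(index, s_dir, s_mag, s_time)`.
#' @export
swj_index <- function(s1, s2, params = swj_params()) {
  if (s1$magnitude <= 0 || s2$magnitude <= 0) {
    warning("zero-magnitude saccade: undefined direction, pair scored 0")
    return(c(index = 0, s_dir = 0, s_mag = 0, s_time = 0))
  }
  s_dir <- (1 - cos((s2$direction - s1$direction) * pi / 180)) / 2
  s_mag <- 1 - abs(s1$magnitude - s2$magnitude) / (s1$magnitude + s2$magnitude)
  dt <- s2$onset_t - s1$offset_t
  s_time <- if (dt > params$max_interval) 0 else
    max(0, 1 - abs(dt - params$ideal_interval) / params$ideal_interval)
  c(index = (s_dir * s_mag * s_time)^(1 / 3),
    s_dir = s_dir, s_mag = s_mag, s_time = s_time)
}

#' Classify square-wave jerks among detected saccades
#'
#' Every pair of consecutive saccades whose magnitudes are both at most
#' `max_magnitude` is scored with [swj_index()]; pairs scoring strictly
#' above `index_threshold` become SWJ candidates. Each saccade may belong
#' to at most one SWJ: when a saccade qualifies both as the second member
#' of one pair and the first of the next, the higher-index pair wins, ties
#' going to the earlier pair.
#'
#' @param saccades A saccade data.frame sorted by onset.
#' @param params An `swj_params` list.
#' @return A data.frame with one row per SWJ: `first`, `second` (row
#'   indices into `saccades`), `index`, `s_dir`, `s_mag`, `s_time`,
#'   `interval` (s), sorted by the first saccade's onset.
#' @export
detect_swjs <- function(saccades, params = swj_params()) {
  empty <- data.frame(first = integer(), second = integer(),
                      index = numeric(), s_dir = numeric(),
                      s_mag = numeric(), s_time = numeric(),
                      interval = numeric())
  n <- nrow(saccades)
  if (n < 2) return(empty)
  if (is.unsorted(saccades$onset_t)) stop("saccades must be sorted by onset")
  cand <- list()
  for (i in seq_len(n - 1)) {
    s1 <- saccades[i, ]; s2 <- saccades[i + 1, ]
    if (s1$magnitude > params$max_magnitude ||
        s2$magnitude > params$max_magnitude) next
    if (s1$magnitude <= 0 || s2$magnitude <= 0) next
    sc <- swj_index(s1, s2, params)
    if (sc[["index"]] > params$index_threshold)
      cand[[length(cand) + 1L]] <-
        data.frame(first = i, second = i + 1, index = sc[["index"]],
                   s_dir = sc[["s_dir"]], s_mag = sc[["s_mag"]],
                   s_time = sc[["s_time"]],
                   interval = s2$onset_t - s1$offset_t)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # conflict resolution: greedy by descending index, ties by earlier pair
  ord <- order(-cand$index, cand$first)
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (k in ord) {
    if (!used[cand$first[k]] && !used[cand$second[k]]) {
      keep[k] <- TRUE
      used[c(cand$first[k], cand$second[k])] <- TRUE
    }
  }
  out <- cand[keep, ]
  out <- out[order(out$first), ]
  rownames(out) <- NULL
  out
}

#' Flag saccades that belong to a square-wave jerk
#'
#' @param saccades The saccade data.frame the SWJs were detected from.
#' @param swjs The output of [detect_swjs()].
#' @return Logical vector, one element per saccade; exactly `2 * nrow(swjs)`
#'   elements are `TRUE`.
#' @export
coupling_flags <- function(saccades, swjs) {
  flags <- logical(nrow(saccades))
  if (nrow(swjs)) flags[c(swjs$first, swjs$second)] <- TRUE
  flags
}
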