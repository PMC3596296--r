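#' Construct an eye-position trace
#'
#' An `eye_trace` holds a uniformly sampled 2D gaze recording for one eye:
#' horizontal (`x`, positive rightward) and vertical (`y`, positive upward)
#' position in degrees, a per-sample validity mask, and recording metadata.
#' Invalid samples (blinks, tracker dropouts) are kept in place so the time
#' base stays uniform; all analysis functions ignore them.
#'
#' @param x,y Numeric vectors of gaze position in degrees. Non-finite values
#'   are marked invalid automatically.
#' @param rate Sampling rate in samples/s (e.g. 500).
#' @param t0 Time of the first sample in seconds.
#' @param eye `"left"` or `"right"`.
#' @param valid Logical validity mask (default: finite `x` and `y`).
#' @param subject,group Free-text metadata labels.
#' @return An object of class `eye_trace` with fields `time`, `x`, `y`,
#'   `rate`, `eye`, `valid`, `meta`.
#' @export
eye_trace <- function(x, y, rate, t0 = 0, eye = "left",
                      valid = NULL, subject = "", group = "") {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  n <- length(x)
  x <- as.numeric(x)
  y <- as.numeric(y)
  finite <- is.finite(x) & is.finite(y)
  if (is.null(valid)) valid <- finite else valid <- as.logical(valid) & finite
  tr <- structure(list(
    time  = t0 + (seq_len(n) - 1) / rate,
    x     = x,
    y     = y,
    rate  = rate,
    eye   = match.arg(eye, c("left", "right")),
    valid = valid,
    meta  = list(subject = subject, group = group)
  ), class = "eye_trace")
  tr
}

#' @export
print.eye_trace <- function(x, ...) {
  dur <- length(x$x) / x$rate
  cat(sprintf("<eye_trace> %s eye, %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              x$eye, length(x$x), x$rate, dur, 100 * mean(x$valid)))
  if (nzchar(x$meta$subject))
    cat(sprintf("  subject: %s  group: %s\n", x$meta$subject, x$meta$group))
  invisible(x)
}

#' @export
plot.eye_trace <- function(x, ...) {
  ok <- x$valid
  graphics::matplot(x$time, cbind(ifelse(ok, x$x, NA), ifelse(ok, x$y, NA)),
                    type = "l", lty = 1, col = c("black", "grey50"),
                    xlab = "time (s)", ylab = "gaze position (deg)", ...)
  graphics::legend("topright", c("horizontal", "vertical"),
                   lty = 1, col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Pair two eyes into a binocular trace
#'
#' @param left,right `eye_trace` objects sharing the same time base and rate.
#' @return An object of class `binocular_trace` with fields `left`, `right`.
#' @export
binocular_trace <- function(left, right) {
  stopifnot(inherits(left, "eye_trace"), inherits(right, "eye_trace"))
  if (left$rate != right$rate || length(left$x) != length(right$x) ||
      abs(left$time[1] - right$time[1]) > 1e-9)
    stop("left and right traces must share the same time base and rate")
  structure(list(left = left, right = right), class = "binocular_trace")
}

#' @export
print.binocular_trace <- function(x, ...) {
  cat("<binocular_trace>\n  ")
  print(x$left)
  cat("  ")
  print(x$right)
  invisible(x)
}

is_binocular <- function(trace) inherits(trace, "binocular_trace")

# duration of the valid portion of a trace, in seconds
valid_duration <- function(trace) sum(trace$valid) / trace$rate

assert_eye_trace <- function(trace) {
  if (!inherits(trace, "eye_trace")) stop("expected an eye_trace")
  dt <- diff(trace$time)
  if (length(dt) && any(abs(dt - 1 / trace$rate) > 1e-9))
    stop("trace time base is not uniform at 1/rate")
  if (any(!is.finite(trace$x[trace$valid])) ||
      any(!is.finite(trace$y[trace$valid])))
    stop("non-finite position at samples flagged valid")
  invisible(trace)
}

#' Read an eye-position recording from CSV
#'
#' The format is plain CSV with a two-line header: the first line holds
#' `key=value` metadata pairs (at minimum `rate`; optionally `eye`,
#' `subject`, `group`, `t0`) separated by commas; the second line holds
#' column names. Columns `t,x,y` give a monocular trace; `t,x,y,x2,y2`
#' gives a binocular one (x/y = left eye). Missing or blink samples are
#' encoded as `NA`/`NaN` and become invalid samples.
#'
#' @param path Path to a CSV file written by [write_trace()] or conforming
#'   to the format above.
#' @return An `eye_trace` or, for 5-column files, a `binocular_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!grepl("=", hdr, fixed = TRUE))
    stop("malformed header: expected key=value metadata line, got: ", hdr)
  kv <- strsplit(strsplit(hdr, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, function(p) if (length(p) >= 2) p[2] else "", ""),
    vapply(kv, `[`, "", 1)
  )
  if (!"rate" %in% names(meta))
    stop("malformed header: missing rate=")
  rate <- as.numeric(meta[["rate"]])
  if (!is.finite(rate) || rate <= 0) stop("malformed header: bad rate")
  dat <- utils::read.csv(path, skip = 1L)
  need <- c("t", "x", "y")
  if (!all(need %in% names(dat)))
    stop("malformed header: expected columns t,x,y")
  # timestamps must agree with a uniform grid at the declared rate
  t0 <- dat$t[1]
  grid <- t0 + (seq_len(nrow(dat)) - 1) / rate
  if (any(abs(dat$t - grid) > 1e-6))
    stop("non-uniform timestamps: samples deviate from 1/rate grid")
  eye <- if ("eye" %in% names(meta)) meta[["eye"]] else "left"
  subj <- if ("subject" %in% names(meta)) meta[["subject"]] else ""
  grp <- if ("group" %in% names(meta)) meta[["group"]] else ""
  left <- eye_trace(dat$x, dat$y, rate, t0 = t0,
                    eye = if (eye %in% c("left", "right")) eye else "left",
                    subject = subj, group = grp)
  if (all(c("x2", "y2") %in% names(dat))) {
    right <- eye_trace(dat$x2, dat$y2, rate, t0 = t0, eye = "right",
                       subject = subj, group = grp)
    left$eye <- "left"
    return(binocular_trace(left, right))
  }
  left
}

#' Write a trace to CSV
#'
#' Inverse of [read_trace()]: `read_trace(write_trace(tr, path))` reproduces
#' the trace exactly for finite values; invalid samples are written as `NA`.
#'
#' @param trace An `eye_trace` or `binocular_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (is_binocular(trace)) {
    l <- trace$left; r <- trace$right
    hdr <- sprintf("rate=%.10g,eye=both,subject=%s,group=%s",
                   l$rate, l$meta$subject, l$meta$group)
    dat <- data.frame(t = l$time,
                      x = ifelse(l$valid, l$x, NA_real_),
                      y = ifelse(l$valid, l$y, NA_real_),
                      x2 = ifelse(r$valid, r$x, NA_real_),
                      y2 = ifelse(r$valid, r$y, NA_real_))
  } else {
    assert_eye_trace(trace)
    hdr <- sprintf("rate=%.10g,eye=%s,subject=%s,group=%s",
                   trace$rate, trace$eye, trace$meta$subject, trace$meta$group)
    dat <- data.frame(t = trace$time,
                      x = ifelse(trace$valid, trace$x, NA_real_),
                      y = ifelse(trace$valid, trace$y, NA_real_))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(dat, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Widen invalid spans with a guard band
#'
#' Samples adjacent to blinks carry lid-artifact velocities; a symmetric
#' guard band of `max_gap_ms` on each side of every invalid run is also
#' marked invalid. The pre-guard mask is kept in `valid_raw`, so the
#' operation is idempotent: applying it twice equals applying it once.
#'
#' @param trace An `eye_trace` (or `binocular_trace`, applied to both eyes).
#' @param max_gap_ms Guard band half-width in milliseconds (default 10).
#' @return The trace with the widened validity mask.
#' @export
mask_gaps <- function(trace, max_gap_ms = 10) {
  stopifnot(max_gap_ms >= 0)
  if (is_binocular(trace))
    return(binocular_trace(mask_gaps(trace$left, max_gap_ms),
                           mask_gaps(trace$right, max_gap_ms)))
  base <- if (!is.null(trace$valid_raw)) trace$valid_raw else trace$valid
  trace$valid_raw <- base
  bad <- !base
  if (!any(bad)) return(trace)
  k <- round(max_gap_ms / 1000 * trace$rate)
  if (k > 0) {
    idx <- which(bad)
    grow <- unique(unlist(lapply(idx, function(i)
      max(1L, i - k):min(length(bad), i + k))))
    bad[grow] <- TRUE
  }
  trace$valid <- !bad
  trace
}
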