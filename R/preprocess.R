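#' Membrane-potential series container
#'
#' A preprocessed 1 Hz trace: values on the uniform grid `t = 0, 1, ...`
#' seconds since stimulation onset, plus its condition and (once estimated)
#' the observation-noise s.d. `sigma`.
#'
#' @param values potential, mV, one value per second starting at t = 0.
#' @param condition_label one of `"control"`, `"DNDS"`, `"STX"`, `"KT5823"`.
#' @param series_id identifier.
#' @param condition optional `condition_params` (derived from the label
#'   when omitted).
#' @param sigma observation-noise s.d., mV (NA until estimated).
#' @param annotations optional list of step-artifact annotations.
#' @return Object of class `mp_series`.
#' @export
mp_series <- function(values, condition_label = "control",
                      series_id = "s1", condition = NULL, sigma = NA_real_,
                      annotations = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("invalid-input: series needs at least 1 point")
  if (is.null(condition)) condition <- condition_from_label(condition_label)
  structure(list(series_id = series_id, condition_label = condition_label,
                 values = values, sigma = sigma, condition = condition,
                 annotations = annotations),
            class = "mp_series")
}

#' @export
print.mp_series <- function(x, ...) {
  cat(sprintf("mp_series '%s' (%s): T = %d s, sigma = %s mV\n",
              x$series_id, x$condition_label, length(x$values),
              ifelse(is.na(x$sigma), "unset", sprintf("%.2f", x$sigma))))
  invisible(x)
}

#' Dataset of membrane-potential series
#'
#' @param series list of `mp_series`.
#' @return Object of class `mp_dataset` (list with element `series`).
#' @export
mp_dataset <- function(series) {
  ids <- vapply(series, function(s) s$series_id, character(1))
  if (anyDuplicated(ids)) stop("invalid-input: duplicated series ids")
  structure(list(series = series), class = "mp_dataset")
}

#' @export
length.mp_dataset <- function(x) length(x$series)

#' @export
`[.mp_dataset` <- function(x, i) mp_dataset(x$series[i])

#' @export
print.mp_dataset <- function(x, ...) {
  labs <- table(vapply(x$series, function(s) s$condition_label, character(1)))
  cat(sprintf("mp_dataset: %d series (%s)\n", length(x),
              paste(names(labs), labs, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Decimate a raw recording to the 1 Hz analysis grid
#'
#' Picks, for every integer second covered by the recording, the raw sample
#' nearest in time (decimation, not averaging): single-sample spikes falling
#' between grid points are dropped by construction, which is how the
#' spike-like system noise is removed.
#'
#' @param times raw sample times, s, strictly increasing.
#' @param values raw potentials, mV.
#' @param condition_label,series_id,condition passed to [mp_series()].
#' @return `mp_series` with `sigma` unset.
#' @export
downsample_to_1hz <- function(times, values, condition_label = "control",
                              series_id = "s1", condition = NULL) {
  if (length(times) != length(values) || length(times) < 2)
    stop("invalid-input: need matching times/values of length >= 2")
  if (any(diff(times) <= 0))
    stop("invalid-input: raw times must be strictly increasing")
  if (max(times) - min(times) < 2)
    stop("invalid-input: raw trace must span at least 2 s")
  grid <- seq(ceiling(min(times)), floor(max(times)))
  idx <- findInterval(grid, times, all.inside = TRUE)
  # findInterval gives the left neighbour; take whichever side is closer
  right <- pmin(idx + 1L, length(times))
  use_right <- (times[right] - grid) < (grid - times[idx])
  idx[use_right] <- right[use_right]
  mp_series(values[idx], condition_label, series_id, condition)
}

#' Correct step-like recording artifacts
#'
#' Within each annotated window the trace is replaced by the straight line
#' connecting the onset and end points; any offset persisting after the
#' window (a non-returning step) is removed by subtracting the detected
#' step height from all later samples.  With `annotations = NULL` windows
#' are detected automatically: first differences exceeding
#' `max(5 mV, 6 MAD)` mark level-shift boundaries, and a shift is treated
#' as an artifact only if the new level persists for at least 10 s.
#'
#' @param series `mp_series`.
#' @param annotations list of `list(onset_index, end_index, offset)` with
#'   1-based indices into the 1 Hz grid (`offset` may be NA to estimate the
#'   persisting height from the data), or NULL for automatic detection.
#' @return Corrected `mp_series`.
#' @export
correct_step_artifacts <- function(series, annotations = NULL) {
  v <- series$values
  if (is.null(annotations)) annotations <- detect_step_artifacts(v)
  if (length(annotations) == 0) return(series)
  ann <- annotations[order(vapply(annotations, `[[`, numeric(1), "onset_index"))]
  on <- vapply(ann, `[[`, numeric(1), "onset_index")
  en <- vapply(ann, `[[`, numeric(1), "end_index")
  if (any(on >= en)) stop("invalid-input: artifact onset must precede end")
  if (any(on < 1) || any(en > length(v)))
    stop("invalid-input: artifact annotation outside series range")
  if (length(ann) > 1 && any(on[-1] <= en[-length(en)]))
    stop("invalid-input: overlapping step-artifact annotations")
  for (a in ann) {
    i <- a$onset_index; j <- a$end_index
    off <- a$offset
    if (is.null(off) || is.na(off)) {
      pre <- median(v[max(1, i - 10):i])
      post <- median(v[j:min(length(v), j + 10)])
      off <- post - pre
      if (abs(off) < 2) off <- 0   # pulse that returned to baseline
    }
    if (off != 0 && j < length(v)) v[(j + 1):length(v)] <- v[(j + 1):length(v)] - off
    v[j] <- v[j] - off
    if (j > i + 1) {
      k <- (i + 1):(j - 1)
      v[k] <- v[i] + (v[j] - v[i]) * (k - i) / (j - i)
    }
  }
  out <- series
  out$values <- v
  out
}

# Automatic step detection: boundaries where |diff| is an outlier, windows
# formed between consecutive boundaries whose level shift persists >= 10 s.
detect_step_artifacts <- function(v, min_jump = 5, k_mad = 6,
                                  persist_s = 10) {
  d <- diff(v)
  thr <- max(min_jump, k_mad * mad(d))
  cand <- which(abs(d) > thr)   # jump between cand and cand+1
  if (length(cand) == 0) return(list())
  ann <- list()
  i <- 1
  while (i <= length(cand)) {
    on <- cand[i]
    # level before vs after the jump, measured over the persistence window
    pre <- median(v[max(1, on - persist_s):on])
    post_end <- min(length(v), on + persist_s)
    post <- median(v[(on + 1):post_end])
    if (abs(post - pre) < thr / 2) { i <- i + 1; next }
    # find a return jump of opposite sign, else the step persists to the end
    ret <- cand[cand > on & sign(d[cand]) == -sign(d[on])]
    if (length(ret) > 0) {
      en <- ret[1] + 1L
      ann[[length(ann) + 1L]] <- list(onset_index = on, end_index = en,
                                      offset = NA_real_)
      i <- which(cand > en)[1]
      if (is.na(i)) break
    } else {
      ann[[length(ann) + 1L]] <- list(onset_index = on,
                                      end_index = min(on + 2L, length(v)),
                                      offset = post - pre)
      i <- i + 1
    }
  }
  ann
}

#' Centered moving-average smoothing
#'
#' Window shrinks symmetrically at the edges so the output has the length
#' of the input.
#'
#' @param values numeric trace.
#' @param window_s odd window width, s, at least 3.
#' @return Smoothed values.
#' @export
smooth_trace <- function(values, window_s = 31) {
  n <- length(values)
  if (window_s < 3 || window_s %% 2 == 0)
    stop("invalid-input: window must be an odd integer >= 3")
  if (window_s > n) stop("invalid-input: window larger than series")
  half <- (window_s - 1) / 2
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  # shrink symmetrically so edge estimates stay centered
  shrink <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - shrink
  hi <- seq_len(n) + shrink
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate the observation-noise s.d. of a series
#'
#' The small observation noise is modelled as white Gaussian; its s.d. is
#' the unbiased sample s.d. of the residual between the sampled trace and
#' its smoothed time average, and standardizes the likelihood of that
#' series.
#'
#' @param series `mp_series`.
#' @param window_s smoothing window (see [smooth_trace()]).
#' @return The series with `sigma` set.
#' @export
estimate_noise_sd <- function(series, window_s = 31) {
  sm <- smooth_trace(series$values, window_s)
  out <- series
  out$sigma <- sd(series$values - sm)
  out
}
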