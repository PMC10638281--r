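# Chromatographic peak detection and light/heavy peak-pair screening.
#
# A genuine labeled analyte appears as a pair of co-eluting peaks of
# similar height in the light (DMED) and heavy (d4-DMED) channels of one
# family, because equal volumes of the two derivatives are mixed before
# injection.  Single-channel signals and pairs with skewed height ratios
# are artifacts and are screened out.

#' Construct an MRM chromatogram trace
#'
#' @param channel_id unique channel identifier; the convention
#'   `"<family>|<light|heavy>"` lets `family` and `channel` be derived.
#' @param time acquisition times in minutes, strictly increasing, at least
#'   8 samples, near-uniform spacing (max/min step at most 1.5).
#' @param intensity non-negative intensities, same length as `time`.
#' @param family,channel optional explicit family key and channel name;
#'   derived from `channel_id` when it contains `"|"`.
#' @return an object of class `mrm_trace`.
#' @export
mrm_trace <- function(channel_id, time, intensity, family = NULL, channel = NULL) {
  stopifnot(length(time) == length(intensity))
  if (length(time) < 8L) stop("trace ", channel_id, ": fewer than 8 samples")
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("trace ", channel_id, ": time not strictly increasing at index ",
         which(dt <= 0)[1] + 1L)
  }
  if (max(dt) / min(dt) > 1.5) {
    stop("trace ", channel_id, ": sampling spacing too irregular (max/min step > 1.5)")
  }
  if (any(intensity < 0)) stop("trace ", channel_id, ": negative intensities")
  if (is.null(family) || is.null(channel)) {
    parts <- strsplit(channel_id, "|", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[2] %in% c("light", "heavy")) {
      family <- parts[1]
      channel <- parts[2]
    }
  }
  structure(
    list(channel_id = channel_id,
         family = if (is.null(family)) NA_character_ else family,
         channel = if (is.null(channel)) NA_character_ else channel,
         time = as.numeric(time), intensity = as.numeric(intensity)),
    class = "mrm_trace"
  )
}

#' @export
print.mrm_trace <- function(x, ...) {
  cat(sprintf("<mrm_trace> %s: %d points, %.2f-%.2f min, max intensity %.3g\n",
              x$channel_id, length(x$time), min(x$time), max(x$time),
              max(x$intensity)))
  invisible(x)
}

# centered moving average, window must be odd; edges keep raw values
.smooth_ma <- function(y, window = 5L) {
  if (length(y) < window) return(y)
  sm <- stats::filter(y, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

# log-parabolic apex interpolation: exact for a noiseless Gaussian
.interpolate_apex <- function(t, y, i) {
  if (i <= 1L || i >= length(y) || any(y[(i - 1L):(i + 1L)] <= 0)) {
    return(list(rt = t[i], height = y[i]))
  }
  ly <- log(y[(i - 1L):(i + 1L)])
  denom <- ly[1] - 2 * ly[2] + ly[3]
  if (denom >= 0) return(list(rt = t[i], height = y[i]))
  delta <- 0.5 * (ly[1] - ly[3]) / denom
  delta <- max(-0.5, min(0.5, delta))
  step <- (t[i + 1L] - t[i - 1L]) / 2
  list(rt = t[i] + delta * step,
       height = exp(ly[2] - 0.25 * (ly[1] - ly[3]) * delta))
}

#' Detect peaks in one chromatogram trace
#'
#' Local maxima of the lightly smoothed trace (5-point moving average)
#' above `min_height`; peak boundaries extend to the nearest valley or
#' baseline crossing; the apex retention time and height are refined by
#' log-parabolic interpolation of the raw trace.  Peaks narrower than
#' `min_width` are discarded.
#'
#' @param trace an [mrm_trace].
#' @param min_height minimum apex intensity (counts).
#' @param min_width minimum peak base width (minutes).
#' @param snr minimum apex signal-to-noise ratio; the baseline noise level
#'   is estimated robustly from the first differences of the raw trace
#'   (median absolute deviation), so the effective height threshold is
#'   `max(min_height, snr * noise)` and adapts to noisy channels.
#' @return data frame with columns `apex_rt`, `height`, `area`, `left_rt`,
#'   `right_rt`, sorted by `apex_rt`; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(trace, min_height = 50, min_width = 0.01, snr = 5) {
  stopifnot(inherits(trace, "mrm_trace"))
  y <- .smooth_ma(trace$intensity)
  t <- trace$time
  n <- length(y)
  noise <- stats::mad(diff(trace$intensity)) / sqrt(2)
  threshold <- max(min_height, snr * noise)
  empty <- data.frame(apex_rt = numeric(0), height = numeric(0),
                      area = numeric(0), left_rt = numeric(0),
                      right_rt = numeric(0))
  if (n < 3L || max(y) < threshold) return(empty)
  # strict-left / non-strict-right comparison resolves plateaus to one apex
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max & y >= threshold)
  if (length(idx) == 0L) return(empty)
  baseline <- 0.5 * threshold
  rows <- lapply(idx, function(i) {
    l <- i
    while (l > 1L && y[l - 1L] < y[l] && y[l - 1L] > baseline) l <- l - 1L
    if (l > 1L && y[l - 1L] <= baseline) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] < y[r] && y[r + 1L] > baseline) r <- r + 1L
    if (r < n && y[r + 1L] <= baseline) r <- r + 1L
    apex <- .interpolate_apex(t, trace$intensity, i)
    area <- if (r > l) {
      sum(diff(t[l:r]) * (trace$intensity[l:(r - 1L)] +
                            trace$intensity[(l + 1L):r]) / 2)
    } else 0
    data.frame(apex_rt = apex$rt, height = apex$height, area = area,
               left_rt = t[l], right_rt = t[r])
  })
  out <- do.call(rbind, rows)
  out <- out[out$height >= threshold & out$right_rt - out$left_rt >= min_width, ,
             drop = FALSE]
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair light and heavy peaks of one family
#'
#' Greedy nearest-RT matching of the light against the heavy peak list:
#' candidate pairs within `rt_tol` are accepted in order of increasing RT
#' difference (ties broken by the height ratio nearest 1), each peak used
#' at most once; pairs whose light/heavy height ratio falls outside
#' `ratio_window` are dropped.
#'
#' @param light,heavy peak data frames from [detect_peaks()].
#' @param rt_tol maximum apex RT difference (minutes).
#' @param ratio_window numeric `c(lo, hi)` with `0 < lo < 1 < hi`; accepted
#'   range for the light/heavy height ratio.  The default `[0.5, 2]`
#'   reflects the 1:1 mixing of the light and heavy derivatives.
#' @return data frame with columns `apex_rt` (light apex), `heavy_rt`,
#'   `light_height`, `heavy_height`, `rt_delta`, `height_ratio`, sorted by
#'   `apex_rt`.
#' @export
pair_channels <- function(light, heavy, rt_tol = 0.05, ratio_window = c(0.5, 2)) {
  stopifnot(rt_tol > 0, length(ratio_window) == 2L,
            ratio_window[1] > 0, ratio_window[1] < 1, ratio_window[2] > 1)
  empty <- data.frame(apex_rt = numeric(0), heavy_rt = numeric(0),
                      light_height = numeric(0), heavy_height = numeric(0),
                      rt_delta = numeric(0), height_ratio = numeric(0))
  if (nrow(light) == 0L || nrow(heavy) == 0L) return(empty)
  cand <- expand.grid(i = seq_len(nrow(light)), j = seq_len(nrow(heavy)))
  cand$delta <- abs(light$apex_rt[cand$i] - heavy$apex_rt[cand$j])
  cand <- cand[cand$delta <= rt_tol, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand$ratio <- light$height[cand$i] / heavy$height[cand$j]
  cand <- cand[order(cand$delta, abs(log(cand$ratio))), , drop = FALSE]
  used_l <- logical(nrow(light)); used_h <- logical(nrow(heavy))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_l[i] && !used_h[j]) {
      used_l[i] <- TRUE; used_h[j] <- TRUE; keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[cand$ratio >= ratio_window[1] & cand$ratio <= ratio_window[2], ,
               drop = FALSE]
  out <- data.frame(
    apex_rt = light$apex_rt[cand$i],
    heavy_rt = heavy$apex_rt[cand$j],
    light_height = light$height[cand$i],
    heavy_height = heavy$height[cand$j],
    rt_delta = cand$delta,
    height_ratio = cand$ratio
  )
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a whole run for FAHFA candidate peak pairs
#'
#' Groups the traces of one run by family, detects peaks in each light and
#' heavy channel, and keeps the co-eluting similar-height pairs.  Families
#' with only one channel present are logged (message) and skipped.
#'
#' @param traces list of [mrm_trace] objects (any order; the result does
#'   not depend on it).
#' @param min_height,min_width,snr passed to [detect_peaks()].
#' @param rt_tol,ratio_window passed to [pair_channels()].
#' @return data frame of candidates: `family`, `apex_rt`, `light_height`,
#'   `heavy_height`, `height_ratio`, `rt_delta`, sorted by family then RT.
#' @export
screen_run <- function(traces, min_height = 50, min_width = 0.01, snr = 5,
                       rt_tol = 0.05, ratio_window = c(0.5, 2)) {
  fams <- vapply(traces, function(tr) tr$family, character(1))
  chans <- vapply(traces, function(tr) tr$channel, character(1))
  ok <- !is.na(fams) & chans %in% c("light", "heavy")
  traces <- traces[ok]; fams <- fams[ok]; chans <- chans[ok]
  out <- list()
  for (fam in sort(unique(fams))) {
    li <- which(fams == fam & chans == "light")
    hi <- which(fams == fam & chans == "heavy")
    if (length(li) != 1L || length(hi) != 1L) {
      message("family ", fam, ": light/heavy channel missing or duplicated; skipped")
      next
    }
    pairs <- pair_channels(
      detect_peaks(traces[[li]], min_height, min_width, snr),
      detect_peaks(traces[[hi]], min_height, min_width, snr),
      rt_tol = rt_tol, ratio_window = ratio_window
    )
    if (nrow(pairs)) {
      out[[fam]] <- data.frame(family = fam, pairs, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(family = character(0), apex_rt = numeric(0),
                      heavy_rt = numeric(0), light_height = numeric(0),
                      heavy_height = numeric(0), rt_delta = numeric(0),
                      height_ratio = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$family, res$apex_rt), , drop = FALSE]
  rownames(res) <- NULL
  res
}
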