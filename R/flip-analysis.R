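#' Regions of interest on a single plane
#'
#' ROIs delimit the zones whose mean intensity is followed over a FLIP or
#' photoconversion movie. Rectangles are given by inclusive pixel bounds,
#' polygons by their vertices; both live on one Z plane and are
#' channel-agnostic. Pixel coordinates are 1-based array indices
#' (`y` = row, `x` = column).
#'
#' @param y0,y1,x0,x1 Inclusive pixel bounds of the rectangle.
#' @param plane Z plane (1-based), default 1.
#' @param id Optional ROI identifier.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(y0, y1, x0, x1, plane = 1L, id = NULL) {
  if (y1 < y0 || x1 < x0) abort("Empty rectangle: need y1 >= y0, x1 >= x0.")
  structure(list(shape = "rectangle", y0 = y0, y1 = y1, x0 = x0, x1 = x1,
                 plane = as.integer(plane), id = id),
            class = "roi")
}

#' @rdname roi_rect
#' @param vertices Two-column matrix (x, y) of polygon vertices in pixels.
#' @export
roi_polygon <- function(vertices, plane = 1L, id = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    abort("`vertices` must be an n x 2 (x, y) matrix with n >= 3.")
  }
  structure(list(shape = "polygon", vertices = vertices,
                 plane = as.integer(plane), id = id),
            class = "roi")
}

# Even-odd rule point-in-polygon for pixel centres; vertices are (x, y).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Logical Y x X mask of an ROI on its plane, optionally shifted by whole
# pixels in x (drift correction).
roi_mask <- function(roi, ny, nx, x_shift = 0L) {
  m <- matrix(FALSE, ny, nx)
  if (roi$shape == "rectangle") {
    y0 <- roi$y0; y1 <- roi$y1
    x0 <- roi$x0 + x_shift; x1 <- roi$x1 + x_shift
    if (y0 < 1 || x0 < 1 || y1 > ny || x1 > nx) {
      abort("ROI lies outside the image bounds.")
    }
    m[y0:y1, x0:x1] <- TRUE
  } else {
    px <- rep(seq_len(nx), each = ny) + 0 - x_shift
    py <- rep(seq_len(ny), nx)
    v <- roi$vertices
    if (min(v[, 1]) + x_shift < 1 || max(v[, 1]) + x_shift > nx ||
        min(v[, 2]) < 1 || max(v[, 2]) > ny) {
      abort("ROI lies outside the image bounds.")
    }
    m[] <- points_in_polygon(px, py, v[, 1], v[, 2])
  }
  if (!any(m)) abort("ROI covers no pixels.")
  m
}

#' Mean-intensity trace of an ROI
#'
#' Per-frame arithmetic mean of the pixel intensities inside the ROI on
#' its plane, for one channel — the I_MEAN series on which %FL is
#' computed.
#'
#' @param movie A `synthetic_movie` (or loaded movie of the same shape).
#' @param roi An [roi_rect()] or [roi_polygon()].
#' @param channel Channel name.
#' @param x_shift Optional per-frame integer x-shift of the ROI (scalar or
#'   length-T vector), mirroring a manual drift correction.
#' @return Tibble with columns `frame` (0-based), `time_s`, `i_mean`, and
#'   attributes `roi_id`, `channel`.
#' @export
measure_zone_trace <- function(movie, roi, channel, x_shift = 0L) {
  ch <- match(channel, movie$channels)
  if (is.na(ch)) abort(sprintf("Unknown channel \"%s\".", channel))
  d <- dim(movie$data)
  nf <- d[1]
  if (roi$plane < 1 || roi$plane > d[2]) abort("ROI plane out of bounds.")
  x_shift <- as.integer(rep_len(x_shift, nf))
  same <- length(unique(x_shift)) == 1L
  mask <- roi_mask(roi, d[3], d[4], x_shift[1])
  i_mean <- numeric(nf)
  for (f in seq_len(nf)) {
    if (!same && f > 1L && x_shift[f] != x_shift[f - 1L]) {
      mask <- roi_mask(roi, d[3], d[4], x_shift[f])
    }
    img <- movie$data[f, roi$plane, , , ch]
    i_mean[f] <- mean(img[mask])
  }
  out <- tibble(frame = seq_len(nf) - 1L,
                time_s = (seq_len(nf) - 1L) * movie$frame_interval,
                i_mean = i_mean)
  attr(out, "roi_id") <- roi$id
  attr(out, "channel") <- channel
  out
}

#' Percentage of fluorescence loss (\%FL)
#'
#' The FLIP statistic: `%FL = (I_start - I_end) / I_start`, where
#' `I_start` is the mean of the trace over the `t_start` frames (the
#' pre-bleach baseline, averaged for robustness to single-frame noise)
#' and `I_end` is the trace value at `t_end` (default: last frame).
#' Expressed as a fraction in `(-Inf, 1]`; multiply by 100 for percent.
#' \%FL is invariant to a multiplicative gain but not to a background
#' offset — background subtraction is the caller's responsibility.
#'
#' @param trace A trace from [measure_zone_trace()], or any tibble with
#'   columns `frame` and `i_mean`.
#' @param t_start Integer vector of 0-based baseline frames (averaged).
#' @param t_end Single 0-based end frame; default last frame.
#' @return One-row tibble with `roi`, `channel`, `t_start`, `t_end`,
#'   `i_start`, `i_end`, `percent_loss`.
#' @examples
#' tr <- tibble::tibble(frame = 0:1, i_mean = c(100, 50))
#' percent_fluorescence_loss(tr, t_start = 0, t_end = 1)$percent_loss # 0.5
#' @export
percent_fluorescence_loss <- function(trace, t_start = 0L,
                                      t_end = max(trace$frame)) {
  if (any(!t_start %in% trace$frame) || !all(t_end %in% trace$frame)) {
    abort("`t_start`/`t_end` frames must exist in the trace.")
  }
  if (length(t_end) != 1L) abort("`t_end` must be a single frame.")
  if (max(t_start) >= t_end) abort("`t_start` must precede `t_end`.")
  i_start <- mean(trace$i_mean[match(t_start, trace$frame)])
  i_end <- trace$i_mean[match(t_end, trace$frame)]
  if (!is.finite(i_start) || i_start <= 0) {
    abort("Starting intensity must be positive.")
  }
  tibble(
    roi = attr(trace, "roi_id") %||% NA_character_,
    channel = attr(trace, "channel") %||% NA_character_,
    t_start = list(as.integer(t_start)), t_end = as.integer(t_end),
    i_start = i_start, i_end = i_end,
    percent_loss = (i_start - i_end) / i_start
  )
}

#' Monte-Carlo null distribution of \%FL
#'
#' Imaging decay, slow tissue movement and cross-channel effects produce
#' fluorescence loss even without FLIP. Following the random-square
#' procedure, `n_squares` squares of side `square_size_um` are placed
#' uniformly at random, fully inside the field on the analysis plane, in
#' the stated channel (typically the unbleached fluorophore); \%FL is
#' computed for each square with the same `t_start`/`t_end` convention as
#' the test ROI, and the significance threshold is the empirical quantile
#' of those samples at the chosen confidence level (nearest-rank method).
#' A measured \%FL above the threshold cannot be explained by chance at
#' that confidence and is attributed to the photomanipulation.
#'
#' @param movie Movie to sample.
#' @param channel Channel to sample \%FL in.
#' @param n_squares Number of random squares (default 10,000; >= 1000).
#' @param square_size_um Square side in \eqn{\mu m} (default 10); converted
#'   to pixels by rounding to the nearest integer >= 1.
#' @param confidence Quantile level of the threshold (default 0.95).
#' @param seed Integer seed; placement is deterministic given the seed.
#' @param t_start,t_end Frame convention as in
#'   [percent_fluorescence_loss()].
#' @param plane Analysis plane (default 1).
#' @param exclusion_mask Optional logical `Y x X` mask; squares
#'   overlapping `TRUE` pixels are rejected and resampled.
#' @return An object of class `flip_null` with the sampled \%FL values
#'   and the threshold; see [tidy.flip_null()] / [glance.flip_null()].
#' @export
monte_carlo_null <- function(movie, channel, n_squares = 10000L,
                             square_size_um = 10, confidence = 0.95,
                             seed = 1L, t_start = 0L,
                             t_end = dim(movie$data)[1] - 1L,
                             plane = 1L, exclusion_mask = NULL) {
  ch <- match(channel, movie$channels)
  if (is.na(ch)) abort(sprintf("Unknown channel \"%s\".", channel))
  if (n_squares < 1000L) abort("`n_squares` must be at least 1000.")
  d <- dim(movie$data)
  side <- max(1L, as.integer(round(square_size_um / movie$pixel_size)))
  ny <- d[3]; nx <- d[4]
  if (side > ny || side > nx) {
    abort("Null square is larger than the imaged field.")
  }
  start_img <- matrix(0, ny, nx)
  for (f in t_start) start_img <- start_img + movie$data[f + 1L, plane, , , ch]
  start_img <- start_img / length(t_start)
  end_img <- movie$data[t_end + 1L, plane, , , ch]
  sat_start <- summed_area_table(start_img)
  sat_end <- summed_area_table(end_img)
  max_r <- ny - side + 1L
  max_c <- nx - side + 1L
  sat_excl <- if (!is.null(exclusion_mask)) {
    summed_area_table(exclusion_mask * 1)
  }
  samples <- with_seed(seed, {
    rows <- integer(0); cols <- integer(0)
    need <- n_squares
    while (need > 0L) {
      r <- sample.int(max_r, need, replace = TRUE)
      c <- sample.int(max_c, need, replace = TRUE)
      if (!is.null(sat_excl)) {
        hit <- square_means(sat_excl, r, c, side) > 0
        r <- r[!hit]; c <- c[!hit]
      }
      rows <- c(rows, r); cols <- c(cols, c)
      need <- n_squares - length(rows)
    }
    m_start <- square_means(sat_start, rows, cols, side)
    m_end <- square_means(sat_end, rows, cols, side)
    1 - m_end / m_start
  })
  samples <- samples[is.finite(samples)]  # squares on zero-signal regions
  if (length(samples) < 1000L) {
    abort("Fewer than 1000 finite null samples; field has too little signal.")
  }
  sorted <- sort(samples)
  threshold <- sorted[ceiling(confidence * length(samples))] # nearest rank
  structure(
    list(channel = channel, samples = samples, threshold = threshold,
         confidence = confidence, n_squares = length(samples),
         square_size_um = square_size_um, square_px = side,
         t_start = as.integer(t_start), t_end = as.integer(t_end),
         seed = as.integer(seed)),
    class = "flip_null"
  )
}

#' @export
print.flip_null <- function(x, ...) {
  cat(sprintf(
    "<flip_null> channel %s: threshold %.4f (%.0f%% confidence, %d squares of %d px)\n",
    x$channel, x$threshold, 100 * x$confidence, x$n_squares, x$square_px))
  invisible(x)
}

#' Tidiers for Monte-Carlo null distributions
#'
#' `tidy()` returns the sampled \%FL values, `glance()` a one-row summary
#' with the threshold.
#'
#' @param x A `flip_null`.
#' @param ... Unused.
#' @export
tidy.flip_null <- function(x, ...) {
  tibble(channel = x$channel, sample = seq_along(x$samples),
         percent_loss = x$samples)
}

#' @rdname tidy.flip_null
#' @export
glance.flip_null <- function(x, ...) {
  tibble(channel = x$channel, n_squares = x$n_squares,
         square_size_um = x$square_size_um, square_px = x$square_px,
         confidence = x$confidence, threshold = x$threshold,
         coverage = mean(x$samples <= x$threshold))
}

#' Retain the most stringent threshold across movies
#'
#' When the null is sampled from several movies of the same fluorophore,
#' the largest (most stringent) threshold is kept.
#'
#' @param ... `flip_null` objects for the same channel.
#' @return The input with the largest threshold.
#' @export
most_stringent_null <- function(...) {
  nulls <- list(...)
  if (!length(nulls)) abort("Need at least one null distribution.")
  chans <- unique(vapply(nulls, `[[`, "", "channel"))
  if (length(chans) != 1L) {
    abort("All null distributions must share one channel.")
  }
  nulls[[which.max(vapply(nulls, `[[`, 0, "threshold"))]]
}

#' Call significance of a fluorescence loss
#'
#' A loss is significant if and only if its \%FL strictly exceeds the null
#' threshold (values at or below the threshold remain attributable to
#' chance).
#'
#' @param measurements Tibble from [percent_fluorescence_loss()] (one or
#'   more rows bound together).
#' @param null A `flip_null` for the same channel, or a bare numeric
#'   threshold.
#' @return The measurements with `threshold` and `significant` columns.
#' @export
classify_loss <- function(measurements, null) {
  if (inherits(null, "flip_null")) {
    chans <- unique(measurements$channel)
    chans <- chans[!is.na(chans)]
    if (length(chans) && !all(chans == null$channel)) {
      abort("Channel mismatch between measurements and null distribution.")
    }
    thr <- null$threshold
  } else {
    thr <- null
  }
  dplyr::mutate(measurements, threshold = thr,
                significant = .data$percent_loss > thr)
}

#' Count nuclei connected to a bleached region
#'
#' After a FLIP experiment has been evaluated zone by zone, the nuclei
#' lying in the bleached zone plus every zone with a significant loss are
#' in cytoplasmic continuity with the bleach point.
#'
#' @param calls Tibble with columns `zone` and `significant`.
#' @param nuclei Tibble with columns `id` and `zone` (one row per
#'   nucleus); every nucleus must be assigned to a zone present in
#'   `calls` or be the bleached zone.
#' @param bleached_zone Zone id that was bleached (always counted).
#' @return Integer number of connected nuclei.
#' @export
count_connected_nuclei <- function(calls, nuclei, bleached_zone) {
  known <- union(calls$zone, bleached_zone)
  if (!all(nuclei$zone %in% known)) {
    abort(paste0("Nuclei assigned to unknown zones: ",
                 paste(setdiff(unique(nuclei$zone), known), collapse = ", ")))
  }
  sig_zones <- union(bleached_zone, calls$zone[calls$significant])
  sum(nuclei$zone %in% sig_zones)
}

#' Detect converted-Kaede signal in a distal region
#'
#' After pulsed photoconversion, converted protein reaching a distal zone
#' is detected when the mean converted-channel intensity in that zone
#' exceeds the background mean by more than three background standard
#' deviations, both estimated over the detection frames.
#'
#' @param movie Movie containing a converted channel.
#' @param distal_roi ROI over the candidate recipient zone.
#' @param background_roi ROI over signal-free background.
#' @param channel Converted channel name (default `"kaede_converted"`).
#' @param frames 0-based frames over which to test; default the final
#'   quarter of the movie.
#' @return One-row tibble with `distal_mean`, `background_mean`,
#'   `background_sd`, `detected`.
#' @export
detect_conversion_crossing <- function(movie, distal_roi, background_roi,
                                       channel = "kaede_converted",
                                       frames = NULL) {
  nf <- dim(movie$data)[1]
  frames <- frames %||% seq.int(floor(3 * nf / 4), nf - 1L)
  tr_d <- measure_zone_trace(movie, distal_roi, channel)
  tr_b <- measure_zone_trace(movie, background_roi, channel)
  dm <- mean(tr_d$i_mean[tr_d$frame %in% frames])
  bm <- mean(tr_b$i_mean[tr_b$frame %in% frames])
  bs <- sd(tr_b$i_mean[tr_b$frame %in% frames])
  tibble(distal_mean = dm, background_mean = bm, background_sd = bs,
         detected = dm > bm + 3 * bs)
}

#' Fraction of adjacent clones reached by converted signal
#'
#' Percentage of adjacent clones in which converted Kaede was detected
#' after photoconversion of one unit — the propagation measure for
#' neighbourhood connectivity.
#'
#' @param converted_detected Logical vector, one entry per adjacent clone.
#' @return Percentage in `[0, 100]`.
#' @examples
#' propagation_fraction(c(TRUE, FALSE, TRUE)) # 66.7
#' @export
propagation_fraction <- function(converted_detected) {
  if (length(converted_detected) == 0L) {
    abort("At least one adjacent clone is required.")
  }
  100 * mean(as.logical(converted_detected))
}
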