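#' Binary pixel pattern
#'
#' A pattern is a row-major binary pixel vector on a `width` by `height`
#' grid; active pixels map one-to-one onto network neurons.
#'
#' @param pixels binary vector (0/1) of length `width * height`, row-major.
#' @param width,height grid dimensions.
#' @return An object of class `memstdp_pattern`.
#' @export
pattern <- function(pixels, width, height = width) {
  pixels <- as.integer(pixels)
  if (!all(pixels %in% c(0L, 1L)))
    stop("pixels must be binary (0/1)", call. = FALSE)
  if (length(pixels) != width * height)
    stop("pixel vector length must equal width * height", call. = FALSE)
  structure(list(pixels = pixels, width = as.integer(width),
                 height = as.integer(height)),
            class = "memstdp_pattern")
}

#' @export
print.memstdp_pattern <- function(x, ...) {
  cat(sprintf("%d x %d binary pattern, %d active pixel(s)\n",
              x$width, x$height, sum(x$pixels)))
  m <- as_matrix(x)
  for (r in seq_len(x$height))
    cat(paste(ifelse(m[r, ] == 1, "#", "."), collapse = ""), "\n")
  invisible(x)
}

#' @rdname pattern
#' @param x a `memstdp_pattern`.
#' @export
as_matrix <- function(x) {
  matrix(x$pixels, nrow = x$height, ncol = x$width, byrow = TRUE)
}

#' Indices of the active pixels (neurons) of a pattern
#' @param x a `memstdp_pattern`.
#' @return Integer vector of row-major pixel indices.
#' @export
active_pixels <- function(x) which(x$pixels == 1L)

#' The two canonical 3 x 3 test patterns of the nine-neuron network
#'
#' Two overlapping binary patterns on the 3 x 3 pixel grid, fixed in code
#' as the fixtures for the nine-neuron connectivity experiments: an
#' L-shaped pattern along the left column plus bottom row, and the
#' diagonal with the center pixel shared between the two.
#'
#' @return A list of two `memstdp_pattern` objects.
#' @export
make_grid_patterns <- function() {
  p1 <- pattern(c(1, 0, 0,
                  1, 0, 0,
                  1, 1, 1), 3)
  p2 <- pattern(c(0, 0, 1,
                  0, 1, 0,
                  1, 0, 0), 3)
  list(p1, p2)
}

center_pattern <- function(p) {
  act <- active_pixels(p)
  if (length(act) == 0) return(p)
  m <- as_matrix(p)
  rc <- which(m == 1, arr.ind = TRUE)
  shift_r <- round((p$height + 1) / 2 - mean(rc[, 1]))
  shift_c <- round((p$width + 1) / 2 - mean(rc[, 2]))
  r2 <- rc[, 1] + shift_r
  c2 <- rc[, 2] + shift_c
  keep <- r2 >= 1 & r2 <= p$height & c2 >= 1 & c2 <= p$width
  m2 <- matrix(0L, p$height, p$width)
  m2[cbind(r2[keep], c2[keep])] <- 1L
  pattern(as.integer(t(m2)), p$width, p$height)
}

#' Synthetic centered contour image
#'
#' Renders the one-pixel-wide outline of a closed shape (circle, regular
#' polygon or a smoothly deformed blob) onto a binary square grid and
#' centers it.  These synthetic contours stand in for edge-detected object
#' photographs as network training patterns in the scalable benchmarks.
#'
#' @param shape `"circle"`, `"polygon"` or `"blob"`.
#' @param size grid side length in pixels (>= 8; default 32).
#' @param seed integer seed controlling the shape parameters.
#' @param radius_frac outer radius as a fraction of `size/2`.
#' @return A `memstdp_pattern`.
#' @export
synth_contour_image <- function(shape = c("circle", "polygon", "blob"),
                                size = 32, seed = 1L, radius_frac = 0.7) {
  shape <- match.arg(shape)
  if (size < 8) stop("size must be >= 8", call. = FALSE)
  if (radius_frac <= 0 || radius_frac > 1)
    stop("degenerate shape: radius_frac must be in (0, 1]", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  r0 <- radius_frac * size / 2
  th <- seq(0, 2 * pi, length.out = 16 * size + 1)[-1]
  r <- switch(shape,
    circle = rep(r0, length(th)),
    polygon = {
      k <- sample(3:7, 1)
      rot <- stats::runif(1, 0, 2 * pi)
      # radius of a regular k-gon with circumradius r0
      a <- (th + rot) %% (2 * pi / k) - pi / k
      r0 * cos(pi / k) / cos(a)
    },
    blob = {
      amp <- stats::runif(3, 0.05, 0.18)
      ph <- stats::runif(3, 0, 2 * pi)
      r0 * (0.85 + amp[1] * cos(2 * th + ph[1]) +
              amp[2] * cos(3 * th + ph[2]) + amp[3] * cos(5 * th + ph[3]))
    })
  cx <- (size + 1) / 2
  col <- pmin(size, pmax(1, round(cx + r * cos(th))))
  row <- pmin(size, pmax(1, round(cx + r * sin(th))))
  m <- matrix(0L, size, size)
  m[cbind(row, col)] <- 1L
  center_pattern(pattern(as.integer(t(m)), size, size))
}

#' Binary contour extraction by neighbor intensity differences
#'
#' Sets a pixel to one whenever the intensity difference to any of its
#' four neighbors exceeds `threshold`; the resulting binary pattern is
#' centered on the grid.  This is the compression step turning a
#' grayscale object image into a network input pattern.
#'
#' @param image numeric matrix of grayscale intensities.
#' @param threshold positive intensity-difference threshold.
#' @param center center the active pixels on the grid (default TRUE).
#' @return A `memstdp_pattern`.  An empty result (threshold too high) is
#'   returned with a warning, not an error.
#' @export
edge_detect <- function(image, threshold, center = TRUE) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  edge <- matrix(FALSE, nr, nc)
  dh <- abs(image[, -1, drop = FALSE] - image[, -nc, drop = FALSE]) > threshold
  dv <- abs(image[-1, , drop = FALSE] - image[-nr, , drop = FALSE]) > threshold
  edge[, -nc] <- edge[, -nc] | dh
  edge[, -1] <- edge[, -1] | dh
  edge[-nr, ] <- edge[-nr, ] | dv
  edge[-1, ] <- edge[-1, ] | dv
  p <- pattern(as.integer(t(edge)), nc, nr)
  if (sum(p$pixels) == 0)
    warning("no intensity difference exceeds the threshold; empty pattern")
  if (center) center_pattern(p) else p
}

#' Keep a random fraction of a pattern's active pixels
#'
#' Retains `ceiling(fraction * a)` of the `a` active pixels, drawn
#' uniformly without replacement under `seed`; used to build the
#' fragmented recall cues.  Fractions are nested: for the same seed a
#' smaller fraction keeps a subset of a larger fraction's pixels.
#'
#' @param p a `memstdp_pattern`.
#' @param fraction fraction of active pixels to keep, in `(0, 1]`.
#' @param seed integer seed.
#' @return A `memstdp_pattern` with the reduced active set.
#' @export
fragment_pattern <- function(p, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  act <- active_pixels(p)
  keep_n <- ceiling(fraction * length(act))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ord <- sample(act)                       # seed-fixed ranking of pixels
  keep <- ord[seq_len(keep_n)]
  px <- integer(length(p$pixels))
  px[keep] <- 1L
  pattern(px, p$width, p$height)
}

#' Rate-coded stimulus program for static patterns
#'
#' Presents the given binary patterns cyclically, one per time window, as
#' constant external currents to the active pixels' neurons (all active
#' neurons of a pattern are driven simultaneously: rate coding).
#'
#' @param patterns a `memstdp_pattern` or list of patterns (equal sizes).
#' @param I0_ext drive per active neuron, amperes.  Either given directly
#'   or derived from `rate_hz`.
#' @param rate_hz if supplied, the drive is [current_for_rate()] at this
#'   target firing rate.
#' @param window_ms presentation window per pattern, ms (default 19.2).
#' @param cycles number of times the pattern set is cycled.
#' @param neuron a [neuron_params()] object (for `rate_hz`).
#' @param dt integration step used for the rate calibration, ms.
#' @return A [stimulus_program()].
#' @export
rate_program <- function(patterns, I0_ext = NULL, rate_hz = NULL,
                         window_ms = 19.2, cycles = 1L,
                         neuron = neuron_params(), dt = 0.05) {
  if (inherits(patterns, "memstdp_pattern")) patterns <- list(patterns)
  if (is.null(I0_ext)) {
    if (is.null(rate_hz))
      stop("supply I0_ext or rate_hz", call. = FALSE)
    I0_ext <- current_for_rate(rate_hz, neuron, dt)
  }
  cur <- do.call(rbind, lapply(patterns, function(p)
    external_current(p, I0_ext)))
  stimulus_program(rep(window_ms, length(patterns)), cur, cycles)
}

#' Temporally-coded stimulus program
#'
#' Presents sequence items (single pixels of one pattern, or whole
#' patterns) successively: item `s` is driven from `(s-1) * stride_ms`
#' for `item_ms` milliseconds.  With `item_ms > stride_ms` consecutive
#' items overlap, so that a leading item is still firing while its
#' successor depolarizes - the temporal-order signal from which the
#' plasticity rule builds unidirectional chain connections.  Successive
#' sweeps are separated by a quiescent gap so that each presentation of
#' the sequence is a distinct episode.
#'
#' @param items a `memstdp_pattern` (its active pixels in row-major order
#'   become the sequence) or a list of patterns.
#' @param n_neurons total network size (defaults to the pattern grid
#'   size).
#' @param stride_ms onset-to-onset interval between items, ms (default
#'   17).
#' @param item_ms stimulation duration of one item, ms (default
#'   `2 * stride_ms`).
#' @param I0_ext drive per active neuron, amperes, or `NULL` to derive
#'   from `rate_hz`.
#' @param rate_hz target firing rate of a driven neuron (default 60 Hz).
#' @param loops number of sweeps through the sequence.
#' @param gap_ms quiescent time after each sweep, ms (default `item_ms`).
#' @param neuron,dt passed to [current_for_rate()].
#' @return A [stimulus_program()].
#' @export
temporal_program <- function(items, n_neurons = NULL, stride_ms = 17,
                             item_ms = 2 * stride_ms, I0_ext = NULL,
                             rate_hz = 60, loops = 1L,
                             gap_ms = item_ms,
                             neuron = neuron_params(), dt = 0.05) {
  if (stride_ms <= 0 || item_ms <= 0)
    stop("stride_ms and item_ms must be > 0", call. = FALSE)
  if (loops < 1) stop("loops must be >= 1", call. = FALSE)
  if (inherits(items, "memstdp_pattern")) {
    n_def <- length(items$pixels)
    sets <- as.list(active_pixels(items))
  } else {
    n_def <- length(items[[1]]$pixels)
    sets <- lapply(items, active_pixels)
  }
  n <- if (is.null(n_neurons)) n_def else n_neurons
  if (is.null(I0_ext)) I0_ext <- current_for_rate(rate_hz, neuron, dt)
  n_items <- length(sets)
  starts <- (seq_len(n_items) - 1) * stride_ms
  ends <- starts + item_ms
  bounds <- sort(unique(c(starts, ends)))
  seg_dur <- diff(bounds)
  cur <- matrix(0, length(seg_dur), n)
  for (s in seq_along(seg_dur)) {
    mid <- (bounds[s] + bounds[s + 1]) / 2
    on <- which(starts <= mid & mid < ends)
    for (it in on) cur[s, sets[[it]]] <- I0_ext   # overlap does not add up
  }
  if (gap_ms > 0) {
    seg_dur <- c(seg_dur, gap_ms)
    cur <- rbind(cur, 0)
  }
  stimulus_program(seg_dur, cur, loops)
}

#' Firing rates over a time window from a spike raster
#'
#' @param result a `simulation_result`.
#' @param window `c(from_ms, to_ms)`; default the full run.
#' @return Per-neuron firing rates, Hz.
#' @export
firing_rates <- function(result, window = NULL) {
  n <- result$config$n
  sp <- result$spikes
  if (!is.null(window)) {
    sp <- sp[sp$t_ms >= window[1] & sp$t_ms < window[2], ]
    dur <- window[2] - window[1]
  } else dur <- result$duration_ms
  counts <- tabulate(sp$neuron, nbins = n)
  counts / (dur / 1000)
}

#' Completion quality of a recall run
#'
#' \deqn{Q(e) = \frac{1}{a f_{max}} \sum_{n=1}^{a} f_n(e)}
#' with `a` the number of internally activated target neurons (active
#' pattern pixels that were not stimulated externally), \eqn{f_n} their
#' recall-window firing rates and `f_max` the maximal internal firing
#' rate of the network.
#'
#' @param result a `simulation_result` of the recall run.
#' @param target the trained `memstdp_pattern`.
#' @param externally_stimulated neuron indices driven externally during
#'   recall.
#' @param f_max normalization rate, Hz (> 0); typically measured with
#'   [measure_f_max()].
#' @param window recall measurement window `c(from_ms, to_ms)`.
#' @return `Q` in `[0, 1]`.
#' @export
completion_quality <- function(result, target, externally_stimulated,
                               f_max, window = NULL) {
  if (!is.numeric(f_max) || f_max <= 0)
    stop("f_max must be > 0", call. = FALSE)
  internal <- setdiff(active_pixels(target), externally_stimulated)
  if (length(internal) == 0)
    stop("no internal target neurons: the whole pattern was stimulated",
         call. = FALSE)
  rates <- firing_rates(result, window)[internal]
  min(1, mean(rates) / f_max)
}

#' Maximal internal firing rate of a trained network
#'
#' Stimulates the complete target pattern and returns the maximum
#' recall-window firing rate across all neurons driven only internally,
#' i.e. the empirical `f_max` used to normalize [completion_quality()].
#' Because every target neuron is externally driven in this measurement,
#' the maximum is taken over the remaining (internally recruited)
#' neurons.
#'
#' @param weights trained weight matrix.
#' @param target the trained pattern.
#' @param recall_ms recall duration, ms.
#' @param I0_ext external drive, amperes.
#' @param ... further arguments passed to [run_network()].
#' @return Rate in Hz.
#' @export
measure_f_max <- function(weights, target, recall_ms = 1000,
                          I0_ext = 0.43025, ...) {
  n <- nrow(weights)
  cur <- numeric(n)
  cur[active_pixels(target)] <- I0_ext
  prog <- stimulus_program(recall_ms, matrix(cur, nrow = 1))
  res <- run_network(weights, prog, ...)
  rates <- firing_rates(res)
  internal <- setdiff(seq_len(n), active_pixels(target))
  if (length(internal) == 0) max(rates) else max(rates[internal])
}

#' Pattern-completion curve of a trained network
#'
#' For each cue size `e` a fragment of `e` target pixels is stimulated
#' externally for `recall_ms` and the recall is scored by the completion
#' quality `Q(e)` and by the binary completion fraction (share of
#' non-stimulated target neurons whose rate exceeds
#' `criterion * f_max`).  Also reports the onset threshold (smallest cue
#' fraction with any internal target activation) and the
#' perfect-completion threshold (smallest cue fraction at which every
#' internal target neuron meets the rate criterion).
#'
#' @param weights trained weight matrix.
#' @param target the trained `memstdp_pattern`.
#' @param e_grid cue sizes (numbers of stimulated target pixels),
#'   increasing.
#' @param recall_ms recall duration per cue, ms.
#' @param I0_ext external drive, amperes.
#' @param f_max normalization rate, Hz; measured via [measure_f_max()]
#'   when `NULL`.
#' @param criterion completed-neuron rate criterion as a fraction of
#'   `f_max` (default 0.5).
#' @param seed seed for the nested cue fragments.
#' @param ... passed to [run_network()] (e.g. `plast`, `neuron`, `leak`).
#' @return A `completion_curve` data frame with columns `e`,
#'   `e_fraction`, `Q`, `completed_fraction`, and attributes
#'   `onset_fraction`, `perfect_fraction`, `f_max`.
#' @export
completion_curve <- function(weights, target, e_grid, recall_ms = 2000,
                             I0_ext = 0.43025, f_max = NULL,
                             criterion = 0.5, seed = 1L, ...) {
  act <- active_pixels(target)
  a <- length(act)
  if (any(e_grid > a))
    stop("cue size exceeds the number of target pixels", call. = FALSE)
  if (is.null(f_max))
    f_max <- measure_f_max(weights, target, recall_ms, I0_ext, ...)
  if (f_max <= 0) stop("measured f_max is zero; network does not fire",
                       call. = FALSE)
  n <- nrow(weights)
  rows <- lapply(e_grid, function(e) {
    frag <- if (e == 0) integer(0)
      else active_pixels(fragment_pattern(target, e / a, seed))
    cur <- numeric(n); cur[frag] <- I0_ext
    prog <- stimulus_program(recall_ms, matrix(cur, nrow = 1))
    res <- run_network(weights, prog, ...)
    internal <- setdiff(act, frag)
    rates <- firing_rates(res)[internal]
    data.frame(e = e, e_fraction = e / a,
               Q = if (length(internal)) min(1, mean(rates) / f_max) else 1,
               completed_fraction =
                 if (length(internal)) mean(rates >= criterion * f_max) else 1,
               any_internal = if (length(internal)) any(rates > 0) else TRUE)
  })
  df <- do.call(rbind, rows)
  onset <- df$e_fraction[df$any_internal][1]
  perfect <- df$e_fraction[df$completed_fraction >= 1][1]
  structure(df[, c("e", "e_fraction", "Q", "completed_fraction")],
            class = c("completion_curve", "data.frame"),
            onset_fraction = if (is.na(onset)) NA_real_ else onset,
            perfect_fraction = if (is.na(perfect)) NA_real_ else perfect,
            f_max = f_max, criterion = criterion)
}

#' Census of strong connections in a weight matrix
#'
#' An ordered pair `(i, j)` is a strong edge iff
#' `w[i, j] >= strong_threshold`.  A neuron pair is bidirectional when
#' both directions are strong, unidirectional when exactly one is.  The
#' symmetry index is
#' \eqn{1 - \sum_{i<j} |\omega_{ij} - \omega_{ji}| /
#'          \sum_{i<j} (\omega_{ij} + \omega_{ji})}.
#'
#' @param w weight matrix.
#' @param strong_threshold weight threshold for a strong edge; default
#'   the midpoint of the weight bounds, `(0.05 + 1) / 2 = 0.525`.
#' @param subset optional neuron indices restricting the census to a
#'   submatrix.
#' @return A list with `bidirectional`, `unidirectional`,
#'   `symmetry_index`, `strong_edges` (two-column matrix of strong
#'   ordered pairs) and the threshold used.
#' @export
connection_census <- function(w, strong_threshold = 0.525,
                              subset = NULL) {
  if (!is.null(subset)) w <- w[subset, subset, drop = FALSE]
  n <- nrow(w)
  strong <- (w >= strong_threshold) & (row(w) != col(w))
  both <- strong & t(strong)
  bidir <- sum(both[upper.tri(both)])
  unidir <- sum(strong & !t(strong))
  up <- upper.tri(w)
  denom <- sum((w + t(w))[up])
  sym <- if (denom > 0) 1 - sum(abs(w - t(w))[up]) / denom else 1
  idx <- which(strong, arr.ind = TRUE)
  list(bidirectional = as.integer(bidir),
       unidirectional = as.integer(unidir),
       symmetry_index = sym,
       strong_edges = unname(idx),
       strong_threshold = strong_threshold)
}

#' Read and write binary patterns as plain-text images
#'
#' Patterns are stored either as plain PBM/PGM (`P1`/`P2` magic,
#' whitespace-separated ASCII samples; `P2` images are binarized at half
#' the maximum value on read) or as bare 0/1 text grids.
#'
#' @param p a `memstdp_pattern`.
#' @param path file path; format chosen by extension (`.pbm`/`.pgm` or
#'   anything else for the bare grid).
#' @return `read_pattern` returns a `memstdp_pattern`; `write_pattern`
#'   returns `path` invisibly.
#' @export
write_pattern <- function(p, path) {
  m <- as_matrix(p)
  ext <- tolower(tools::file_ext(path))
  lines <- if (ext == "pbm") {
    c("P1", paste(p$width, p$height),
      apply(m, 1, paste, collapse = " "))
  } else if (ext == "pgm") {
    c("P2", paste(p$width, p$height), "1",
      apply(m, 1, paste, collapse = " "))
  } else {
    apply(m, 1, paste, collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- scan(text = paste(lines, collapse = "\n"), what = character(),
               quiet = TRUE)
  if (toks[1] %in% c("P1", "P2")) {
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    if (toks[1] == "P1") {
      vals <- as.integer(toks[-(1:3)])
    } else {
      maxv <- as.numeric(toks[4])
      vals <- as.integer(as.numeric(toks[-(1:4)]) > maxv / 2)
    }
  } else {
    vals <- as.integer(toks)
    h <- length(lines[nzchar(trimws(lines))])
    w <- length(vals) / h
  }
  pattern(vals, w, h)
}
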