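# Spike-train analysis: evoked rates, von Frey thresholds, the adaptation
# ratio R, exact 1-D 2-means classification and the binomial ratio test.
# All spike-counting windows are half-open [t0, t1).

#' von Frey filament force table
#'
#' Index-to-force map (grams) of the calibrated filament series used for
#' static-touch stimulation: 1 = 0.008 g up to 10 = 2 g.
#' @return Named numeric vector, names `"1"`..`"10"`.
#' @export
vf_filament_table <- function() {
  stats::setNames(c(0.008, 0.02, 0.04, 0.07, 0.16, 0.40, 0.60, 1, 1.7, 2),
                  as.character(1:10))
}

count_in_window <- function(spike_times, t0, t1) {
  sum(spike_times >= t0 & spike_times < t1)
}

#' Firing rate over a window
#'
#' @param recording a [cell_recording].
#' @param window numeric `(t0, t1)`; the window is half-open `[t0, t1)`.
#' @return Rate in Hz: spike count divided by window duration.
#' @export
firing_rate <- function(recording, window) {
  stopifnot(inherits(recording, "cell_recording"), length(window) == 2L)
  if (window[2] <= window[1]) stop("empty window: t1 must exceed t0")
  count_in_window(recording$spike_times, window[1], window[2]) /
    (window[2] - window[1])
}

matching_epochs <- function(recording, kind, filament = NULL) {
  ep <- recording$epochs
  sel <- ep$kind == kind
  if (!is.null(filament)) sel <- sel & !is.na(ep$filament_index) &
      ep$filament_index == filament
  ep[sel, , drop = FALSE]
}

#' Evoked response to a stimulus
#'
#' Spike rate over the first `analysis_window` seconds of each matching
#' stimulus application, averaged over trials. No baseline subtraction.
#'
#' @param recording a [cell_recording].
#' @param kind stimulus kind, `"vf"` or `"brush"`.
#' @param filament filament index (vf only).
#' @param analysis_window s analyzed from each onset (default 1).
#' @return Mean rate in Hz across trials.
#' @export
evoked_response <- function(recording, kind = "vf", filament = NULL,
                            analysis_window = 1) {
  ep <- matching_epochs(recording, kind, filament)
  if (nrow(ep) == 0L)
    stop(sprintf("no epochs of kind '%s'%s", kind,
                 if (is.null(filament)) "" else paste0(" filament ", filament)))
  if (nrow(ep) != 3L)
    warning(sprintf("expected 3 trials, found %d", nrow(ep)), call. = FALSE)
  rates <- vapply(seq_len(nrow(ep)), function(i)
    count_in_window(recording$spike_times, ep$onset[i],
                    ep$onset[i] + analysis_window) / analysis_window, 0)
  mean(rates)
}

#' von Frey threshold of a cell
#'
#' The first filament in ascending order whose evoked response reaches
#' `rate_criterion` (default 10 Hz, inclusive).
#'
#' @param recording a [cell_recording] with vf epochs.
#' @param rate_criterion Hz (default 10).
#' @param analysis_window s (default 1).
#' @return Smallest qualifying filament index, or `NA_integer_` if no
#'   filament qualifies.
#' @export
vf_threshold <- function(recording, rate_criterion = 10, analysis_window = 1) {
  ep <- matching_epochs(recording, "vf")
  if (nrow(ep) == 0L) stop("no vf epochs in recording")
  for (f in sort(unique(ep$filament_index))) {
    r <- suppressWarnings(evoked_response(recording, "vf", f, analysis_window))
    if (r >= rate_criterion) return(as.integer(f))
  }
  NA_integer_
}

#' Adaptation ratio R of a threshold response
#'
#' R is the number of spikes fired 0.5-1 s into the threshold stimulus
#' divided by the number fired 0-0.5 s in. Counts are pooled across the
#' trials of the threshold filament before taking the ratio, which keeps R
#' defined when a single trial has an empty first half. A cell whose pooled
#' first-half count is zero has undefined R and is excluded upstream.
#'
#' @param recording a [cell_recording].
#' @param filament the threshold filament index; defaults to
#'   [vf_threshold()] of the recording.
#' @return R (>= 0), or `NA_real_` when the denominator is zero (a warning
#'   is logged).
#' @export
adaptive_ratio <- function(recording, filament = NULL) {
  if (is.null(filament)) filament <- vf_threshold(recording)
  if (is.na(filament)) stop("no threshold filament for this recording")
  ep <- matching_epochs(recording, "vf", filament)
  if (nrow(ep) == 0L) stop("no epochs for filament ", filament)
  if (any(ep$duration < 1)) stop("epoch shorter than 1 s: R undefined")
  first <- sum(vapply(ep$onset, function(t0)
    count_in_window(recording$spike_times, t0, t0 + 0.5), 0))
  second <- sum(vapply(ep$onset, function(t0)
    count_in_window(recording$spike_times, t0 + 0.5, t0 + 1), 0))
  if (first == 0L) {
    warning("denominator count 0: R undefined, cell excluded", call. = FALSE)
    return(NA_real_)
  }
  second / first
}

#' Exact two-cluster split of 1-D values
#'
#' Globally optimal 1-D 2-means: every split of the sorted values into a
#' low and a high cluster is scored by within-cluster sum of squares and
#' the minimiser chosen. The boundary is the midpoint of the two cluster
#' centroids; values below the boundary are "adapting", values at or above
#' it "nonadapting".
#'
#' @param r_values numeric, at least 2 finite distinct values.
#' @return List with `boundary`, `centroids` (low, high), `labels`
#'   (character, aligned with input order) and `split_sse`.
#' @export
kmeans_boundary <- function(r_values) {
  x <- r_values[is.finite(r_values)]
  if (length(x) < 2L) stop("need >= 2 finite values")
  if (length(unique(x)) < 2L)
    stop("all values identical: no boundary exists")
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); css <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  sse_lo <- css[k] - cs[k]^2 / k
  sse_hi <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  sse <- sse_lo + sse_hi
  kbest <- which.min(sse)
  mu_lo <- cs[kbest] / kbest
  mu_hi <- (cs[n] - cs[kbest]) / (n - kbest)
  boundary <- (mu_lo + mu_hi) / 2
  labels <- ifelse(is.finite(r_values),
                   ifelse(r_values < boundary, "adapting", "nonadapting"),
                   NA_character_)
  list(boundary = boundary, centroids = c(mu_lo, mu_hi), labels = labels,
       split_sse = sse[kbest])
}

#' Exact binomial ratio test
#'
#' Two-sided exact test of `k` successes in `n` trials against null
#' probability `p0`, with the minimum-likelihood rule: the p-value sums
#' `P(X = j)` over all outcomes `j` no more likely than the observed `k`.
#' Used to test the nonadapting:adapting cell ratio against the expected
#' 1:2 inhibitory:excitatory split (`p0 = 1/3`).
#'
#' @param k observed successes (nonadapting cells).
#' @param n total trials (cells).
#' @param p0 null probability (default 1/3).
#' @return Two-sided p-value.
#' @examples
#' ratio_binomial_test(8, 30)   # ~0.56
#' ratio_binomial_test(5, 28)   # ~0.11
#' @export
ratio_binomial_test <- function(k, n, p0 = 1 / 3) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  d <- stats::dbinom(0:n, n, p0)
  # likelihood ties compared with a small relative tolerance, the standard
  # convention for exact two-sided tests
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

# segment intersection test for polygon simplicity (excluding shared ends)
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  (o1 != o2) && (o3 != o4)
}

#' Area of a receptive field polygon
#'
#' Absolute shoelace area of a simple polygon mapped on the plantar paw
#' surface; orientation-independent.
#'
#' @param vertices numeric matrix, columns `(x, y)` in mm, >= 3 rows,
#'   non-self-intersecting.
#' @return Area in mm^2.
#' @export
receptive_field_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("polygon needs >= 3 vertices")
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  # simplicity: non-adjacent edges must not cross
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || j == (i %% n) + 1L || i == (j %% n) + 1L) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        stop("self-intersecting polygon")
    }
  }
  abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
}

#' Classify a cohort of recordings into adapting and nonadapting cells
#'
#' Computes R for every cell at its von Frey threshold filament, excludes
#' cells with undefined R, and labels the rest either by the exact 1-D
#' 2-means boundary fitted to the cohort or by a fixed configured boundary
#' (the published convention is 0.33; R >= boundary means nonadapting).
#'
#' @param recordings list of [cell_recording] objects.
#' @param boundary `"kmeans"` (default) or a fixed numeric boundary.
#' @param rate_criterion threshold rule in Hz (default 10).
#' @param fallback_strongest when no filament reaches the rate criterion
#'   (rapidly adapting cells can stay under 10 Hz averaged over the first
#'   second), compute R at the strongest filament applied instead of
#'   excluding the cell -- in an ascending protocol that is the stimulus
#'   the experimenter stopped at; flagged with a QC warning and an `NA`
#'   `vf_threshold` (default `TRUE`).
#' @return List of class `adaptive_classification`: `cells` (data.frame
#'   with `r`, `label`, `vf_threshold`, `rf_area_mm2`, `depth`),
#'   `boundary`, `boundary_mode`, `excluded` (indices with undefined R)
#'   and `counts` (adapting, nonadapting).
#' @export
classify_cohort <- function(recordings, boundary = "kmeans",
                            rate_criterion = 10,
                            fallback_strongest = TRUE) {
  if (length(recordings) == 0L) stop("empty cohort")
  stopifnot(all(vapply(recordings, inherits, TRUE, "cell_recording")))
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    thr <- suppressWarnings(vf_threshold(rec, rate_criterion))
    fil <- thr
    if (is.na(fil) && fallback_strongest) {
      ep <- matching_epochs(rec, "vf")
      fil <- max(ep$filament_index)
      warning(sprintf(
        "QC: cell %d reaches no filament at %g Hz; using strongest filament %d",
        i, rate_criterion, fil), call. = FALSE)
    }
    r <- if (is.na(fil)) NA_real_ else
      suppressWarnings(adaptive_ratio(rec, fil))
    rf <- if (is.null(rec$receptive_field)) NA_real_ else
      receptive_field_area(rec$receptive_field)
    data.frame(cell = i, r = r, vf_threshold = thr, rf_area_mm2 = rf,
               depth = rec$depth, stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  excluded <- which(!is.finite(cells$r))
  ok <- is.finite(cells$r)
  if (!any(ok)) stop("no cell has a defined R")
  if (identical(boundary, "kmeans")) {
    km <- kmeans_boundary(cells$r[ok])
    b <- km$boundary
    mode <- "kmeans"
  } else {
    b <- as.numeric(boundary)
    mode <- "fixed"
  }
  cells$label <- NA_character_
  cells$label[ok] <- ifelse(cells$r[ok] < b, "adapting", "nonadapting")
  structure(list(cells = cells, boundary = b, boundary_mode = mode,
                 excluded = excluded,
                 counts = c(adapting = sum(cells$label == "adapting",
                                           na.rm = TRUE),
                            nonadapting = sum(cells$label == "nonadapting",
                                              na.rm = TRUE))),
            class = "adaptive_classification")
}

#' @export
print.adaptive_classification <- function(x, ...) {
  cat(sprintf("<adaptive_classification> %d cells (%d excluded), boundary %s = %.3f\n",
              nrow(x$cells), length(x$excluded), x$boundary_mode, x$boundary))
  cat(sprintf("  adapting: %d, nonadapting: %d\n",
              x$counts["adapting"], x$counts["nonadapting"]))
  invisible(x)
}
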