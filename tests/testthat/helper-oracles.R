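# Independent oracles, deliberately naive: these recompute expectations by
# enumeration/simulation and never share code with the implementation.

# triple-loop voxel count of the AND of three logical arrays
oracle_triple_overlap <- function(a, b, c) {
  d <- dim(a)
  n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (a[z, y, x] && b[z, y, x] && c[z, y, x]) n <- n + 1L
  n
}

# naive exhaustive 1-D 2-means: score every sorted split by recomputing SSE
oracle_best_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  sse <- vapply(seq_len(n - 1L), function(k) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, 0)
  k <- which.min(sse)
  list(k = k, sse = sse[k],
       boundary = (mean(xs[1:k]) + mean(xs[(k + 1):n])) / 2)
}

# Monte-Carlo polygon area by point-in-polygon sampling on a bounding box
oracle_polygon_area_mc <- function(v, n = 2e5, seed = 99) {
  set.seed(seed)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  # even-odd ray casting
  inside <- logical(n)
  m <- nrow(v)
  j <- m
  for (i in seq_len(m)) {
    cr <- (v[i, 2] > py) != (v[j, 2] > py)
    xin <- px < (v[j, 1] - v[i, 1]) * (py - v[i, 2]) /
      (v[j, 2] - v[i, 2]) + v[i, 1]
    inside <- xor(inside, cr & xin)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# deterministic recording with given spike times and a vf epoch table
make_recording <- function(spikes, epochs) {
  cell_recording(spikes, epochs)
}

vf_epochs <- function(filaments, onsets, duration = 2, trials = NULL) {
  data.frame(kind = "vf", filament_index = filaments, onset = onsets,
             duration = duration,
             trial = if (is.null(trials)) seq_along(onsets) else trials,
             stringsAsFactors = FALSE)
}

# closed-form expected adaptation ratio of the decaying-rate simulator
oracle_expected_R <- function(tau)
  (exp(-0.5 / tau) - exp(-1 / tau)) / (1 - exp(-0.5 / tau))

random_mask <- function(dims, p = 0.5) {
  array(runif(prod(dims)) < p, dims)
}
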