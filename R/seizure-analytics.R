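#' Detect seizure events by hysteresis thresholding
#'
#' Per-node onset/offset detection on the fast variable x1.  A node enters
#' the ictal state when x1 crosses `on_level` upward; the event ends once
#' x1 has stayed below `off_level` for `min_ictal / 5` consecutive time
#' units.  Events shorter than `min_ictal` are discarded.  The hysteresis
#' gap makes the detector robust to the fast spiking that rides on the
#' ictal plateau.
#'
#' @param traj an `epi_trajectory`, or a numeric matrix of x1 series
#'   (samples x nodes) with an attached sample spacing `dt`.
#' @param on_level onset threshold (default -0.5).
#' @param off_level offset threshold (default -1.0); must be below
#'   `on_level`.
#' @param min_ictal minimum event duration in model time units.
#' @param dt sample spacing; taken from the trajectory when omitted.
#' @return An `epi_events` object: a list with one `data.frame(onset,
#'   offset)` per node.
#' @export
detect_events <- function(traj, on_level = -0.5, off_level = -1.0,
                          min_ictal = 50, dt = NULL) {
  if (inherits(traj, "epi_trajectory")) {
    x1 <- traj$x1
    dt <- traj$dt
    t0 <- traj$times[1]
  } else {
    x1 <- as.matrix(traj)
    if (is.null(dt)) stop("dt must be supplied for a plain matrix")
    t0 <- 0
  }
  if (nrow(x1) < 2) stop("series too short for event detection")
  if (on_level <= off_level) stop("need on_level > off_level (hysteresis)")
  quiet_run_needed <- max(1L, as.integer(round(min_ictal / 5 / dt)))

  per_node <- lapply(seq_len(ncol(x1)), function(i) {
    v <- x1[, i]
    onsets <- numeric(0); offsets <- numeric(0)
    state <- "inter"; onset_t <- NA_real_; quiet <- 0L
    for (s in 2:length(v)) {
      if (state == "inter") {
        if (v[s] > on_level && v[s - 1] <= on_level) {
          state <- "ictal"; onset_t <- t0 + (s - 1) * dt; quiet <- 0L
        }
      } else {
        if (v[s] < off_level) {
          quiet <- quiet + 1L
          if (quiet >= quiet_run_needed) {
            off_t <- t0 + (s - quiet_run_needed) * dt
            if (off_t - onset_t >= min_ictal) {
              onsets <- c(onsets, onset_t); offsets <- c(offsets, off_t)
            }
            state <- "inter"
          }
        } else quiet <- 0L
      }
    }
    data.frame(onset = onsets, offset = offsets)
  })
  structure(list(events = per_node, n = ncol(x1)), class = "epi_events")
}

#' @export
print.epi_events <- function(x, ...) {
  counts <- vapply(x$events, nrow, integer(1))
  cat(sprintf("Seizure events: %d nodes, %d events total (%d nodes with events)\n",
              x$n, sum(counts), sum(counts > 0)))
  invisible(x)
}

#' Mean seizure oscillation period
#'
#' Pools consecutive onset-to-onset intervals over a node subset, after
#' discarding each node's first onset as an initial-condition transient,
#' and returns their mean.
#'
#' @param events an `epi_events` table.
#' @param node_subset node indices to pool (default: all nodes).
#' @return Mean onset-to-onset interval (model time units).
#' @export
mean_period <- function(events, node_subset = seq_len(events$n)) {
  stopifnot(inherits(events, "epi_events"))
  intervals <- unlist(lapply(node_subset, function(i) {
    on <- events$events[[i]]$onset
    if (length(on) < 3) return(numeric(0))  # need >= 2 post-transient onsets
    diff(on[-1])
  }))
  if (length(intervals) < 2)
    stop("fewer than 2 usable onset intervals in the subset")
  mean(intervals)
}

#' Onset delays of recruited non-focal nodes
#'
#' Time from the earliest focal onset to each non-focal node's first
#' onset.  Nodes without any event are reported as not recruited
#' (`NA` delay).
#'
#' @param events an `epi_events` table.
#' @param focal_indices focal node indices.
#' @return `data.frame(node, recruited, delay)` over non-focal nodes.
#' @export
onset_delays <- function(events, focal_indices) {
  stopifnot(inherits(events, "epi_events"))
  focal_indices <- as.integer(focal_indices)
  focal_onsets <- unlist(lapply(focal_indices,
                                function(i) events$events[[i]]$onset))
  if (!length(focal_onsets))
    stop("no focal node has any event; delay reference undefined")
  ref <- min(focal_onsets)
  nonfocal <- setdiff(seq_len(events$n), focal_indices)
  delay <- vapply(nonfocal, function(i) {
    on <- events$events[[i]]$onset
    if (length(on)) on[1] - ref else NA_real_
  }, numeric(1))
  data.frame(node = nonfocal, recruited = !is.na(delay), delay = delay)
}

#' Fraction of non-focal nodes recruited
#'
#' @param events an `epi_events` table.
#' @param focal_indices focal node indices.
#' @return Fraction of non-focal nodes with at least one event.
#' @export
recruitment_fraction <- function(events, focal_indices) {
  stopifnot(inherits(events, "epi_events"))
  nonfocal <- setdiff(seq_len(events$n), as.integer(focal_indices))
  if (!length(nonfocal)) return(NA_real_)
  mean(vapply(nonfocal, function(i) nrow(events$events[[i]]) > 0,
              logical(1)))
}

#' Mean pairwise synchrony of node signals
#'
#' Mean off-diagonal Pearson correlation over a node subset's signals.
#' Channels with zero variance are excluded; the number excluded is
#' attached as the `"n_excluded"` attribute (with a warning).
#'
#' @param signals numeric matrix, samples x nodes.
#' @param subset node indices (default all).
#' @return Mean pairwise correlation in \\[-1, 1\\].
#' @export
mean_pairwise_synchrony <- function(signals, subset = seq_len(ncol(signals))) {
  signals <- as.matrix(signals)[, subset, drop = FALSE]
  if (ncol(signals) < 2) stop("need at least 2 nodes")
  sds <- apply(signals, 2, stats::sd)
  keep <- sds > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warning(sprintf("%d zero-variance channel(s) excluded", n_excluded))
    signals <- signals[, keep, drop = FALSE]
    if (ncol(signals) < 2) stop("fewer than 2 channels with variance")
  }
  cm <- cor(signals)
  out <- mean(cm[upper.tri(cm)])
  attr(out, "n_excluded") <- n_excluded
  out
}
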