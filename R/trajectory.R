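# Trajectory statistics: inter-domain COM distances, smoothing, block
# averaging, kernel density estimation, open/closed classification and
# RMSD-versus-start series.

#' Wrap a multi-model structure as a trajectory
#'
#' @param s a `papp_structure` whose models are time-ordered frames.
#' @param frame_spacing time between frames in ns (default 0.1).
#' @param times explicit frame times in ns (overrides `frame_spacing`); must
#'   be strictly increasing with uniform spacing.
#' @return An object of class `papp_trajectory`.
#' @export
as_trajectory <- function(s, frame_spacing = 0.1, times = NULL) {
  stopifnot(inherits(s, "papp_structure"))
  m <- s$n_models
  if (is.null(times)) {
    times <- (seq_len(m) - 1) * frame_spacing
  }
  if (length(times) != m) stop("times length != frame count")
  if (m > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
      stop("frame times must be strictly increasing with uniform spacing")
    }
  }
  structure(list(structure = s, times = as.numeric(times), n_frames = m),
            class = "papp_trajectory")
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path multi-model PDB file.
#' @param frame_spacing time between frames in ns.
#' @return A `papp_trajectory`.
#' @export
read_trajectory <- function(path, frame_spacing = 0.1) {
  as_trajectory(read_structure(path), frame_spacing = frame_spacing)
}

#' @export
print.papp_trajectory <- function(x, ...) {
  cat("papp_trajectory:", x$n_frames, "frames,",
      nrow(x$structure$atoms), "atoms, span",
      sprintf("%.1f ns\n", max(x$times) - min(x$times)))
  invisible(x)
}

.frame_dt <- function(traj) {
  if (traj$n_frames < 2) stop("trajectory has a single frame")
  traj$times[2] - traj$times[1]
}

new_distance_series <- function(times, values, pair) {
  stopifnot(length(times) == length(values))
  if (!all(is.finite(values))) stop("non-finite distance values")
  structure(list(times = times, values = values, pair = pair),
            class = "distance_series")
}

#' Inter-domain center-of-mass distance series
#'
#' Per frame, the unweighted mean of the C-alpha coordinates of each domain
#' selection (the convention of the M1/M2 analysis) and the Euclidean
#' distance between the two means.
#'
#' @param traj a `papp_trajectory`.
#' @param a,b [domain_definition()] selections.
#' @return An object of class `distance_series` (`times` in ns, `values` in
#'   Angstrom).
#' @export
com_distance_series <- function(traj, a, b) {
  stopifnot(inherits(traj, "papp_trajectory"))
  s <- traj$structure
  rows_a <- .calpha_rows(s, a)
  rows_b <- .calpha_rows(s, b)
  if (length(rows_a) == 0) stop("empty selection for domain '", a$name,
                                "' in every frame")
  if (length(rows_b) == 0) stop("empty selection for domain '", b$name,
                                "' in every frame")
  com <- function(rows) {
    x <- s$coords[rows, , , drop = FALSE]
    apply(x, 3, colMeans)  # 3 x n_frames
  }
  d <- sqrt(colSums((com(rows_a) - com(rows_b))^2))
  new_distance_series(traj$times, d, pair = c(a$name, b$name))
}

#' Exponential moving average of a distance series
#'
#' Smoothing factor alpha = 2 / (span_in_frames + 1); the first output
#' equals the first input.
#'
#' @param d a `distance_series`.
#' @param span smoothing span in ns (default 10).
#' @return The smoothed `distance_series`.
#' @export
exponential_moving_average <- function(d, span = 10) {
  stopifnot(inherits(d, "distance_series"))
  if (span <= 0) stop("span must be > 0")
  dt <- if (length(d$times) > 1) d$times[2] - d$times[1] else NA_real_
  if (!is.na(dt) && span < dt) {
    stop("span (", span, " ns) smaller than the frame spacing (", dt, " ns)")
  }
  alpha <- 2 / (span / dt + 1)
  v <- as.numeric(stats::filter(alpha * d$values, 1 - alpha,
                                method = "recursive",
                                init = d$values[1]))
  out <- new_distance_series(d$times, v, d$pair)
  out$span <- span
  out
}

#' Block-averaged mean and standard deviation of a series tail
#'
#' The final `tail_len` ns are partitioned into `n_blocks` contiguous
#' equal-length blocks; the mean and sample standard deviation of the block
#' means are returned. Blocking reduces the bias autocorrelation induces in
#' naive standard errors; discarding the head removes initial transients.
#' Defaults follow the production analysis: eight 50-ns blocks over the
#' final 400 ns.
#'
#' @param d a `distance_series`.
#' @param n_blocks number of blocks (default 8).
#' @param block_len block length in ns (default 50).
#' @param tail_len analysed tail length in ns (default 400); must equal
#'   `n_blocks * block_len` and divide evenly into frames.
#' @return An object of class `block_stats`: `block_means`, `mean`, `sd`,
#'   `n_blocks`, `block_len`, `tail_len`.
#' @export
block_average <- function(d, n_blocks = 8, block_len = 50, tail_len = 400) {
  stopifnot(inherits(d, "distance_series"))
  if (abs(n_blocks * block_len - tail_len) > 1e-9) {
    stop("non-divisible partition: n_blocks * block_len (",
         n_blocks * block_len, " ns) must equal tail_len (", tail_len, " ns)")
  }
  if (length(d$times) < 2) stop("series too short")
  dt <- d$times[2] - d$times[1]
  n_tail <- tail_len / dt
  if (abs(n_tail - round(n_tail)) > 1e-6) {
    stop("non-divisible partition: tail_len is not a whole number of frames")
  }
  n_tail <- round(n_tail)
  if (n_tail > length(d$values)) {
    stop("series (", sprintf("%.1f", length(d$values) * dt),
         " ns) shorter than the requested tail (", tail_len, " ns)")
  }
  fpb <- n_tail / n_blocks
  if (abs(fpb - round(fpb)) > 1e-6) {
    stop("non-divisible partition: blocks do not align with frames")
  }
  v <- utils::tail(d$values, n_tail)
  bm <- colMeans(matrix(v, nrow = round(fpb)))
  structure(
    list(block_means = bm, mean = mean(bm),
         sd = if (n_blocks > 1) stats::sd(bm) else NA_real_,
         n_blocks = n_blocks, block_len = block_len, tail_len = tail_len),
    class = "block_stats"
  )
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf("block_stats: %.2f +/- %.2f A (%d blocks of %g ns, %g ns tail)\n",
              x$mean, x$sd, x$n_blocks, x$block_len, x$tail_len))
  invisible(x)
}

#' Pool block statistics across replicates
#'
#' Pools the block means of several replicates (same blocking scheme) and
#' reports their overall mean and sample standard deviation. The mean of the
#' per-replicate standard deviations is also reported, since either
#' convention can be meant by an "overall" figure.
#'
#' @param stats list of [block_average()] results.
#' @return An object of class `replicate_summary`: `mean`, `sd` (of the
#'   pooled block means), `n_replicates`, `block_means` (pooled),
#'   `per_replicate` (data.frame of each replicate's mean and sd), and
#'   `mean_of_replicate_sds`.
#' @export
aggregate_replicates <- function(stats) {
  if (inherits(stats, "block_stats")) stats <- list(stats)
  if (length(stats) < 1) stop("need at least one replicate")
  ok <- vapply(stats, inherits, logical(1), "block_stats")
  if (!all(ok)) stop("all elements must be block_stats")
  scheme <- vapply(stats, function(s) {
    paste(s$n_blocks, s$block_len, s$tail_len)
  }, character(1))
  if (length(unique(scheme)) > 1) {
    stop("mismatched block schemes across replicates: ",
         paste(unique(scheme), collapse = " vs "))
  }
  pooled <- unlist(lapply(stats, `[[`, "block_means"))
  per <- data.frame(
    replicate = seq_along(stats),
    mean = vapply(stats, `[[`, numeric(1), "mean"),
    sd = vapply(stats, `[[`, numeric(1), "sd")
  )
  structure(
    list(mean = mean(pooled),
         sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
         n_replicates = length(stats), block_means = pooled,
         per_replicate = per,
         mean_of_replicate_sds = mean(per$sd)),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate_summary: %.2f +/- %.2f A pooled over %d replicate(s)\n",
              x$mean, x$sd, x$n_replicates))
  invisible(x)
}

#' Fixed-bandwidth Gaussian kernel density estimate
#'
#' Evaluates the Gaussian KDE with a fixed kernel standard deviation (the
#' "covariance factor" convention, 3 Angstrom by default) exactly on a
#' regular grid, then renormalises so the trapezoidal integral over the grid
#' is 1.
#'
#' @param values numeric samples (Angstrom).
#' @param bandwidth kernel standard deviation in Angstrom (default 3).
#' @param from,to grid limits (default: sample range widened by 4
#'   bandwidths).
#' @param n grid size (default 512).
#' @return An object of class `kde_estimate`: `grid`, `density`,
#'   `bandwidth`.
#' @export
kde_density <- function(values, bandwidth = 3, from = NULL, to = NULL,
                        n = 512) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    stop("need at least one finite sample")
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(from)) from <- min(values) - 4 * bandwidth
  if (is.null(to)) to <- max(values) + 4 * bandwidth
  grid <- seq(from, to, length.out = n)
  dens <- colMeans(stats::dnorm(outer(values, grid, "-") / bandwidth)) /
    bandwidth
  z <- sum(diff(grid) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2)
  structure(list(grid = grid, density = dens / z, bandwidth = bandwidth),
            class = "kde_estimate")
}

#' Modes of a KDE estimate
#'
#' @param k a [kde_density()] result.
#' @return Numeric vector of grid positions of the local density maxima.
#' @export
kde_modes <- function(k) {
  stopifnot(inherits(k, "kde_estimate"))
  d <- k$density
  s <- sign(diff(d))
  pos <- which(s != 0)
  nz <- s[pos]
  out <- numeric(0)
  for (j in seq_along(nz)[-1]) {
    if (nz[j - 1] > 0 && nz[j] < 0) {
      # rising-to-falling transition; a flat top reports its midpoint
      out <- c(out, mean(k$grid[c(pos[j - 1] + 1, pos[j])]))
    }
  }
  out
}

#' Classify frames as open or closed
#'
#' The cutoff is `reference_distance + 0.5 * reference_sd` - a region
#' extending beyond the closed-reference state by half a standard deviation,
#' so the closed label tolerates the spread of the distribution. Frames with
#' distances above the cutoff are labelled open.
#'
#' @param d a `distance_series`.
#' @param reference_distance closed-state reference distance in Angstrom
#'   (e.g. the predicted-model M1-M2 distance of 54).
#' @param reference_sd spread term in Angstrom (>= 0).
#' @return An object of class `state_classification`: `cutoff`, `labels`
#'   (per frame, `"open"`/`"closed"`), `open_fraction`,
#'   `reference_distance`, `reference_sd`.
#' @export
classify_states <- function(d, reference_distance, reference_sd) {
  stopifnot(inherits(d, "distance_series"))
  if (reference_sd < 0) stop("reference_sd must be >= 0")
  cutoff <- reference_distance + 0.5 * reference_sd
  labels <- ifelse(d$values > cutoff, "open", "closed")
  structure(
    list(cutoff = cutoff, labels = labels,
         open_fraction = mean(labels == "open"),
         reference_distance = reference_distance,
         reference_sd = reference_sd, n_frames = length(labels)),
    class = "state_classification"
  )
}

#' @export
print.state_classification <- function(x, ...) {
  cat(sprintf(
    "state_classification: cutoff %.2f A (ref %.2f + 0.5 * %.2f); open fraction %.3f of %d frames\n",
    x$cutoff, x$reference_distance, x$reference_sd, x$open_fraction,
    x$n_frames))
  invisible(x)
}

#' C-alpha RMSD of every frame against the first
#'
#' Each frame's selected C-alpha atoms are Kabsch-superposed onto frame 1
#' before computing the RMSD, so rigid-body motion does not register.
#'
#' @param traj a `papp_trajectory`.
#' @param selection a [domain_definition()].
#' @return A `distance_series` of RMSD values (Angstrom); the first value
#'   is 0.
#' @export
rmsd_vs_start <- function(traj, selection) {
  stopifnot(inherits(traj, "papp_trajectory"))
  s <- traj$structure
  rows <- .calpha_rows(s, selection)
  if (length(rows) == 0) {
    stop("empty selection for domain '", selection$name, "'")
  }
  ref <- s$coords[rows, , 1, drop = FALSE]
  dim(ref) <- c(length(rows), 3)
  vals <- vapply(seq_len(traj$n_frames), function(m) {
    x <- s$coords[rows, , m, drop = FALSE]
    dim(x) <- c(length(rows), 3)
    kabsch(x, ref)$rmsd
  }, numeric(1))
  new_distance_series(traj$times, vals,
                      pair = c(selection$name, "frame1"))
}

#' Write a distance series (with optional state labels) as TSV
#'
#' @param d a `distance_series`.
#' @param path output file.
#' @param classification optional [classify_states()] result supplying a
#'   label column.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(d, path, classification = NULL) {
  stopifnot(inherits(d, "distance_series"))
  out <- data.frame(time_ns = d$times, distance_A = d$values)
  if (!is.null(classification)) out$label <- classification$labels
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
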