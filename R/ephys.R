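#' Construct a single-channel current trace
#'
#' @param samples Current samples in pA.
#' @param sampling_rate Sampling rate in Hz (study value 50000).
#' @param holding_potential Holding potential in mV (study value +50).
#' @param label Text label.
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate = 50000,
                          holding_potential = 50, label = "trace") {
  stopifnot(sampling_rate > 0, is.numeric(samples))
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 holding_potential = holding_potential,
                 label = label),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s: %d samples @ %g kHz, %+g mV (%.3g s)\n",
              x$label, length(x$samples), x$sampling_rate / 1000,
              x$holding_potential, length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' All-points histogram of a current trace
#'
#' Histogram of every sample in the trace; modes correspond to the closed
#' (baseline) and open conductance levels.
#'
#' @param trace A `current_trace`.
#' @param bin_width Bin width in pA (default 0.05).
#' @return List with `breaks`, `mids`, `counts`; counts sum to the sample
#'   count.
#' @export
all_points_histogram <- function(trace, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  x <- trace$samples
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts)
}

#' Detect discrete conductance levels
#'
#' Identifies the baseline (closed) level as the most populated mode of
#' the sample density and reports open levels as amplitudes above the
#' baseline. The default method picks local maxima of a kernel density
#' estimate and refines each amplitude as the mean of the samples assigned
#' to that mode; `method = "gmm"` fits Gaussian mixtures with BIC model
#' selection instead.
#'
#' @param trace A `current_trace`.
#' @param max_levels Maximum number of open levels to report.
#' @param method "histogram" (default) or "gmm".
#' @param bin_width Density bandwidth / histogram resolution in pA.
#' @param min_density_frac Local maxima below this fraction of the tallest
#'   mode are ignored (histogram method).
#' @importFrom mclust Mclust mclustBIC me meV unmap bic
#' @return data.frame of class `conductance_levels` with one row per open
#'   level, ascending amplitude: `level_index`, `mean_amplitude` (pA above
#'   baseline), `amplitude_sd`, `occupancy`, `conductance` (pS),
#'   `broad` (TRUE when the mode is over 1.25x wider than the baseline
#'   noise, the signature of two unresolved levels merged into one mode).
#'   Attributes: `baseline` (pA), `baseline_sd`. Zero rows for a quiet
#'   trace.
#' @export
detect_levels <- function(trace, max_levels = 5,
                          method = c("histogram", "gmm"),
                          bin_width = 0.05, min_density_frac = 1e-3) {
  method <- match.arg(method)
  stopifnot(max_levels >= 1)
  x <- trace$samples
  if (method == "gmm") {
    # unequal-variance Gaussian mixture per component count, EM started
    # from evenly spaced k-means centres (hierarchical initialization can
    # swallow rarely occupied levels), BIC selects the component count
    xs <- if (length(x) > 50000) x[seq(1, length(x), length.out = 50000)] else x
    best <- NULL; best_bic <- -Inf
    for (G in 1:(max_levels + 1)) {
      z <- if (G == 1) matrix(1, length(xs), 1) else {
        cen <- seq(min(xs), max(xs), length.out = G)
        mclust::unmap(stats::kmeans(xs, centers = cen,
                                    iter.max = 50)$cluster)
      }
      fit <- mclust::me(data = xs, modelName = "V", z = z)
      if (is.null(fit$loglik) || is.na(fit$loglik)) next
      b <- mclust::bic("V", fit$loglik, n = length(xs), d = 1, G = G)
      if (b > best_bic) { best_bic <- b; best <- fit }
    }
    centers <- as.numeric(best$parameters$mean)
    mass <- as.numeric(best$parameters$pro)
  } else {
    d <- stats::density(x, bw = bin_width, n = 4096)
    y <- d$y
    is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                  y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
    is_max <- is_max & y > min_density_frac * max(y)
    centers <- d$x[is_max]
    mass <- y[is_max]
    if (!length(centers)) return(empty_levels())
  }
  ord <- order(centers)
  centers <- centers[ord]; mass <- mass[ord]
  # assign samples to nearest mode (boundaries at mode midpoints), refine
  bounds <- if (length(centers) > 1)
    (centers[-1] + centers[-length(centers)]) / 2 else numeric(0)
  grp <- findInterval(x, bounds) + 1L
  amp <- vapply(seq_along(centers), function(g) mean(x[grp == g]), 0)
  sds <- vapply(seq_along(centers), function(g) stats::sd(x[grp == g]), 0)
  occ <- tabulate(grp, length(centers)) / length(x)
  base_i <- which.max(occ)
  baseline <- amp[base_i]; base_sd <- sds[base_i]
  open <- which(amp > baseline)
  if (!length(open))
    return(empty_levels(baseline, base_sd))
  # keep the most occupied open levels if over max_levels
  if (length(open) > max_levels)
    open <- sort(open[order(occ[open], decreasing = TRUE)[1:max_levels]])
  out <- data.frame(
    level_index = seq_along(open),
    mean_amplitude = amp[open] - baseline,
    amplitude_sd = sds[open],
    occupancy = occ[open],
    broad = sds[open] > 1.25 * base_sd)
  out$conductance <- conductance(out$mean_amplitude, trace$holding_potential)
  attr(out, "baseline") <- baseline
  attr(out, "baseline_sd") <- base_sd
  class(out) <- c("conductance_levels", "data.frame")
  out
}

empty_levels <- function(baseline = NA_real_, baseline_sd = NA_real_) {
  out <- data.frame(level_index = integer(), mean_amplitude = numeric(),
                    amplitude_sd = numeric(), occupancy = numeric(),
                    broad = logical(), conductance = numeric())
  attr(out, "baseline") <- baseline
  attr(out, "baseline_sd") <- baseline_sd
  class(out) <- c("conductance_levels", "data.frame")
  out
}

#' Conductance from current amplitude and holding potential
#'
#' G = I / V; pA / mV gives nS, reported in pS.
#'
#' @param amplitude Current amplitude(s) in pA.
#' @param potential Holding potential in mV (non-zero).
#' @return Conductance in pS.
#' @export
conductance <- function(amplitude, potential) {
  if (any(potential == 0)) stop("holding potential must be non-zero")
  amplitude / potential * 1000
}

#' Pore radius from single-channel conductance
#'
#' Cylindrical-pore model: G = kappa * pi * r^2 / l, so
#' r = sqrt(G * l / (pi * kappa)). The access-resistance variant adds the
#' convergence resistance at the two pore mouths,
#' 1/G = l / (kappa * pi * r^2) + 1 / (2 * kappa * r), and solves the
#' resulting quadratic in 1/r for its positive root. Electrolyte
#' conductivity defaults to 3.5 S/m (250 mM KCl + 50 mM MgCl2 at room
#' temperature) and pore length to 4 nm (a lipid bilayer span); both are
#' report metadata, not universal constants.
#'
#' @param conductance_pS Conductance in pS; non-positive values give 0.
#' @param conductivity Electrolyte conductivity, S/m.
#' @param pore_length Pore length, nm.
#' @param model "cylinder" (default) or "cylinder_access".
#' @return Pore radius in nm.
#' @export
pore_radius <- function(conductance_pS, conductivity = 3.5, pore_length = 4,
                        model = c("cylinder", "cylinder_access")) {
  model <- match.arg(model)
  stopifnot(conductivity > 0, pore_length > 0)
  G <- pmax(conductance_pS, 0) * 1e-12     # S
  l <- pore_length * 1e-9                  # m
  r <- if (model == "cylinder") {
    sqrt(G * l / (pi * conductivity))
  } else {
    # 1/G = (l/(kappa*pi)) u^2 + (1/(2*kappa)) u, u = 1/r; positive root
    a <- l / (conductivity * pi)
    b <- 1 / (2 * conductivity)
    u <- ifelse(G > 0, (-b + sqrt(b^2 + 4 * a / G)) / (2 * a), Inf)
    1 / u
  }
  r * 1e9
}

#' Idealize a trace into discrete level-dwell events
#'
#' Assigns each sample to a level by half-amplitude thresholding between
#' adjacent levels (baseline = level 0), then merges runs shorter than
#' `min_samples` into the preceding event so that single-sample noise
#' spikes are suppressed.
#'
#' @param trace A `current_trace`.
#' @param levels A `conductance_levels` object from [detect_levels()], or
#'   a numeric vector of open amplitudes above baseline.
#' @param baseline Baseline current in pA (taken from `levels` when
#'   available).
#' @param min_samples Minimum event duration in samples (default 2).
#' @return data.frame of class `event_idealization`: `level_index` (0 =
#'   closed), `start_time` (s), `dwell_time` (s), `n_samples`.
#' @export
idealize <- function(trace, levels, baseline = NULL, min_samples = 2) {
  amps <- if (is.data.frame(levels)) levels$mean_amplitude else
    sort(as.numeric(levels))
  if (!length(amps)) stop("at least one open level required")
  if (is.null(baseline))
    baseline <- if (is.data.frame(levels) &&
                    is.finite(attr(levels, "baseline")))
      attr(levels, "baseline") else 0
  lev <- c(0, amps)                       # amplitudes above baseline
  thr <- (lev[-1] + lev[-length(lev)]) / 2
  cls <- findInterval(trace$samples - baseline, thr)
  r <- rle(cls)
  # single pass: absorb sub-minimum runs into the preceding event (the
  # first retained event at the trace start), coalescing equal-level
  # neighbours; run lengths are judged on their own, never inflated by
  # absorbed samples
  nr <- length(r$values)
  v <- integer(nr); l <- integer(nr); k <- 0L; pend <- 0L
  for (i in seq_len(nr)) {
    raw <- r$lengths[i]
    if (raw < min_samples && i < nr) {
      if (k) l[k] <- l[k] + raw else pend <- pend + raw
    } else if (k && (r$values[i] == v[k] ||
                     (raw < min_samples && i == nr))) {
      l[k] <- l[k] + raw
    } else {
      k <- k + 1L
      v[k] <- r$values[i]; l[k] <- raw + pend; pend <- 0L
    }
  }
  v <- v[seq_len(k)]; l <- l[seq_len(k)]
  ends <- cumsum(l)
  starts <- ends - l + 1L
  out <- data.frame(level_index = v,
                    start_time = (starts - 1L) / trace$sampling_rate,
                    dwell_time = l / trace$sampling_rate,
                    n_samples = l)
  class(out) <- c("event_idealization", "data.frame")
  out
}

#' Latency to first conductance event
#'
#' Time from trace start to the first idealized open event. A quiet trace
#' (no detected open level, or no event) returns NA with attribute
#' `quiet = TRUE`. Onset detection runs on a 3-sample moving average of
#' the trace (timing is unaffected: the average first clears the
#' half-amplitude threshold at the opening's first sample) and the first
#' event must last at least `min_event_samples` samples (default 5, i.e.
#' 0.1 ms at 50 kHz); together these stop isolated noise excursions or
#' single sub-threshold dips inside a genuine opening from corrupting the
#' onset time.
#'
#' @param trace A `current_trace`.
#' @param levels Optional `conductance_levels` or numeric open amplitudes;
#'   detected from the trace when NULL.
#' @param min_event_samples Minimum duration of the first event, samples.
#' @param ... Passed to [detect_levels()] when levels are detected here.
#' @return First open-event start time in seconds, or NA (quiet).
#' @export
latency <- function(trace, levels = NULL, min_event_samples = 5, ...) {
  if (is.null(levels)) levels <- detect_levels(trace, ...)
  n_open <- if (is.data.frame(levels)) nrow(levels) else length(levels)
  if (!n_open) return(structure(NA_real_, quiet = TRUE))
  sm <- as.numeric(stats::filter(trace$samples, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- trace$samples[is.na(sm)]
  smooth_trace <- current_trace(sm, trace$sampling_rate,
                                trace$holding_potential, trace$label)
  ev <- idealize(smooth_trace, levels, min_samples = min_event_samples)
  open <- ev$start_time[ev$level_index >= 1L]
  if (!length(open)) return(structure(NA_real_, quiet = TRUE))
  # refine on the raw trace: the moving average can fire one sample late,
  # so step back while raw samples already clear the lowest threshold
  amps <- if (is.data.frame(levels)) levels$mean_amplitude else
    sort(as.numeric(levels))
  baseline <- if (is.data.frame(levels) &&
                  is.finite(attr(levels, "baseline")))
    attr(levels, "baseline") else 0
  thr1 <- amps[1] / 2
  i <- round(open[1] * trace$sampling_rate) + 1L
  while (i > 1L && trace$samples[i - 1L] - baseline > thr1) i <- i - 1L
  (i - 1L) / trace$sampling_rate
}

#' Table of conductance levels with pore radii
#'
#' Convenience wrapper shaping [detect_levels()] output as a summary table
#' (level, amplitude +/- sd, conductance, estimated pore radius) with the
#' pore-model parameters echoed as attributes.
#'
#' @inheritParams detect_levels
#' @inheritParams pore_radius
#' @return data.frame with pore radius column added; attributes `kappa`,
#'   `pore_length`, `pore_model`.
#' @export
channel_summary <- function(trace, max_levels = 5,
                            method = c("histogram", "gmm"),
                            bin_width = 0.05,
                            conductivity = 3.5, pore_length = 4,
                            model = c("cylinder", "cylinder_access")) {
  lv <- detect_levels(trace, max_levels, method, bin_width)
  lv$pore_radius_nm <- pore_radius(lv$conductance, conductivity,
                                   pore_length, model)
  attr(lv, "kappa") <- conductivity
  attr(lv, "pore_length") <- pore_length
  attr(lv, "pore_model") <- match.arg(model)
  lv
}

## ---- trace I/O -------------------------------------------------------------

#' Read a current trace
#'
#' Delimited format: two columns (time_s, current_pA) with a header line;
#' sampling rate is inferred from the time column. Raw format: little-
#' endian float32 samples with a JSON sidecar `<path>.json` giving
#' `sampling_rate`, `holding_potential` and optional `label`.
#'
#' @param path File path.
#' @param format "delimited" or "float32".
#' @param holding_potential Used for delimited input (mV).
#' @return A `current_trace`.
#' @export
read_current_trace <- function(path, format = c("delimited", "float32"),
                               holding_potential = 50) {
  format <- match.arg(format)
  if (format == "delimited") {
    d <- utils::read.delim(path)
    rate <- 1 / stats::median(diff(d[[1]]))
    current_trace(d[[2]], sampling_rate = rate,
                  holding_potential = holding_potential,
                  label = basename(path))
  } else {
    hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- file.info(path)$size / 4
    x <- readBin(path, "numeric", n = n, size = 4, endian = "little")
    current_trace(x, sampling_rate = hdr$sampling_rate,
                  holding_potential = hdr$holding_potential,
                  label = if (is.null(hdr$label)) basename(path) else hdr$label)
  }
}

#' Write a current trace as delimited text
#'
#' @param trace A `current_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_current_trace <- function(trace, path) {
  t_s <- (seq_along(trace$samples) - 1L) / trace$sampling_rate
  utils::write.table(
    data.frame(time_s = t_s, current_pA = trace$samples),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
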