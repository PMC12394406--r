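#' Construct a droplet FRET-ratio trace
#'
#' @param droplet_id Identifier.
#' @param time_min Sampling times, minutes, strictly increasing.
#' @param ratio FRET ratio values (dimensionless, finite).
#' @param radius_um Droplet radius, micrometers.
#' @param temperature_C Droplet temperature, degrees Celsius.
#' @return An object of class `"fret_trace"`: data.frame of samples with
#'   droplet metadata attached as attributes (`droplet_id`, `radius_um`,
#'   `temperature_C`, `t_start` = first sample time).
#' @export
fret_trace <- function(droplet_id, time_min, ratio, radius_um,
                       temperature_C) {
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(ratio))) stop("ratio values must be finite")
  structure(data.frame(time_min = time_min, ratio = ratio),
            droplet_id = droplet_id, radius_um = radius_um,
            temperature_C = temperature_C, t_start = time_min[1],
            class = c("fret_trace", "data.frame"))
}

trace_meta <- function(tr, what) attr(tr, what)

#' Droplet quality filter
#'
#' Retains exactly the traces from droplets with radius strictly below
#' `max_radius` (default 100 um) whose track starts strictly before
#' `max_start` (default 60 min).
#'
#' @param traces List of [fret_trace()] objects.
#' @param max_radius Radius cut-off, micrometers (strict inequality).
#' @param max_start Track-start cut-off, minutes (strict inequality).
#' @return The retained sub-list.
#' @export
filter_droplets <- function(traces, max_radius = 100, max_start = 60) {
  keep <- vapply(traces, function(tr)
    trace_meta(tr, "radius_um") < max_radius &&
      trace_meta(tr, "t_start") < max_start, logical(1))
  traces[keep]
}

#' Annotate oscillation cycles in a FRET trace
#'
#' Peaks and troughs are auto-selected by local-extremum detection with a
#' minimum prominence (default 20\% of the trace's interquartile
#' amplitude) and minimum separation (default 5 min, suited to 3-7 min
#' sampling); the peak/trough sequence is then forced to alternate by
#' merging same-kind neighbours, keeping the more extreme one. Each
#' trough-peak-trough triplet becomes one annotated cycle.
#'
#' Raw traces are lightly smoothed (centered running mean over
#' `smooth_window` samples) before extremum detection; together with the
#' merge rules this replaces the manual peak correction used in
#' interactive analyses.
#'
#' @param trace A [fret_trace()] (or any data.frame with `time_min` and
#'   `ratio`).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   interquartile range of the ratio.
#' @param min_separation Minimum extremum separation, minutes.
#' @param smooth_window Running-mean window (samples; 1 disables
#'   smoothing).
#' @return An object of classes `"cycle_annotation"`/`"data.frame"`: one
#'   row per complete cycle with `cycle`, `trough_time`, `peak_time`,
#'   `next_trough_time`, `rising`, `falling`, `total` (minutes). Empty
#'   when no full trough-peak-trough triplet exists.
#' @export
annotate_cycles <- function(trace, min_prominence_frac = 0.2,
                            min_separation = 5, smooth_window = 3) {
  tt <- trace$time_min
  x <- trace$ratio
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing")
  if (smooth_window > 1 && length(x) >= smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(x, k, sides = 2)
    x <- ifelse(is.na(sm), x, as.numeric(sm))
  }
  prom <- min_prominence_frac * stats::IQR(x)
  peaks <- find_peaks(x, tt, min_prominence = prom,
                      min_separation = min_separation)
  troughs <- find_peaks(-x, tt, min_prominence = prom,
                        min_separation = min_separation)
  ann <- merge_alternating(tt, x, peaks, troughs)
  class(ann) <- c("cycle_annotation", "data.frame")
  attr(ann, "temperature_C") <- trace_meta(trace, "temperature_C")
  attr(ann, "droplet_id") <- trace_meta(trace, "droplet_id")
  ann
}

# enforce trough/peak alternation, merging same-kind runs by extremal value
merge_alternating <- function(tt, x, peaks, troughs) {
  ev <- rbind(
    if (length(peaks)) data.frame(i = peaks, kind = "peak"),
    if (length(troughs)) data.frame(i = troughs, kind = "trough"))
  if (is.null(ev) || nrow(ev) < 3) return(empty_annotation())
  ev <- ev[order(ev$i), ]
  out <- ev[1, ]
  for (r in 2:nrow(ev)) {
    last <- nrow(out)
    if (ev$kind[r] != out$kind[last]) {
      out <- rbind(out, ev[r, ])
    } else {
      # same kind: keep the more extreme
      better <- if (ev$kind[r] == "peak") x[ev$i[r]] > x[out$i[last]]
      else x[ev$i[r]] < x[out$i[last]]
      if (better) out$i[last] <- ev$i[r]
    }
  }
  phases_from_extrema(tt[out$i[out$kind == "trough"]],
                      tt[out$i[out$kind == "peak"]])
}

empty_annotation <- function() {
  data.frame(cycle = integer(0), trough_time = numeric(0),
             peak_time = numeric(0), next_trough_time = numeric(0),
             rising = numeric(0), falling = numeric(0), total = numeric(0))
}

#' Select cycles for analysis
#'
#' Two selection conventions: cycles 2-4 of each droplet, or every cycle
#' completed within the first 300 minutes. Both are provided so their
#' agreement can be checked on any dataset.
#'
#' @param ann A [annotate_cycles()] result.
#' @param mode `"cycles_2_to_4"` or `"first_300min"`.
#' @param window Time horizon for `"first_300min"`, minutes.
#' @return The selected subset (possibly empty).
#' @export
select_cycles <- function(ann, mode = c("cycles_2_to_4", "first_300min"),
                          window = 300) {
  mode <- match.arg(mode)
  keep <- switch(mode,
                 cycles_2_to_4 = ann$cycle >= 2 & ann$cycle <= 4,
                 first_300min = ann$next_trough_time <= window)
  ann[keep, , drop = FALSE]
}

#' Interphase slope of a Cdk1 FRET trace
#'
#' Ordinary least-squares slope of ratio versus time over the central
#' 60\% of each trough-to-peak (rising) segment, trimming both ends;
#' a proxy for the cyclin synthesis rate.
#'
#' @param trace A [fret_trace()].
#' @param ann Its [annotate_cycles()] annotation (any subset).
#' @param trim_frac Fraction of the rising segment trimmed in total
#'   (split equally between the two ends).
#' @return List with `per_cycle` (data.frame `cycle`, `slope`, `n`) and
#'   `median` (median slope across usable cycles).
#' @export
interphase_slope <- function(trace, ann, trim_frac = 0.4) {
  if (!nrow(ann)) stop("need at least one annotated cycle")
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    t0 <- ann$trough_time[i]; t1 <- ann$peak_time[i]
    lo <- t0 + trim_frac / 2 * (t1 - t0)
    hi <- t1 - trim_frac / 2 * (t1 - t0)
    sel <- trace$time_min >= lo & trace$time_min <= hi
    if (sum(sel) < 3) {
      warning("cycle ", ann$cycle[i], " has < 3 samples in its central window; skipped")
      return(NULL)
    }
    sl <- stats::cov(trace$time_min[sel], trace$ratio[sel]) /
      stats::var(trace$time_min[sel])
    data.frame(cycle = ann$cycle[i], slope = sl, n = sum(sel))
  })
  per_cycle <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(per_cycle) || !nrow(per_cycle))
    stop("no cycle had enough samples for a slope fit")
  list(per_cycle = per_cycle, median = stats::median(per_cycle$slope))
}

#' Average normalized single-cycle waveform
#'
#' Each annotated cycle (trough to next trough) is rescaled to unit
#' phase and unit amplitude, resampled on a common grid, and averaged
#' pointwise across cycles and droplets.
#'
#' @param traces List of [fret_trace()] objects at one temperature.
#' @param anns Matching list of annotations (defaults to annotating each
#'   trace).
#' @param n_grid Number of phase grid points.
#' @return data.frame with `phase` (0-1), `mean`, `sd`, `n_cycles`.
#' @export
average_waveform <- function(traces, anns = lapply(traces, annotate_cycles),
                             n_grid = 100) {
  grid <- seq(0, 1, length.out = n_grid)
  curves <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]; ann <- anns[[k]]
    for (i in seq_len(nrow(ann))) {
      t0 <- ann$trough_time[i]; t1 <- ann$next_trough_time[i]
      sel <- tr$time_min >= t0 & tr$time_min <= t1
      if (sum(sel) < 4) next
      ph <- (tr$time_min[sel] - t0) / (t1 - t0)
      y <- tr$ratio[sel]
      y <- (y - min(y)) / max(max(y) - min(y), .Machine$double.eps)
      curves[[length(curves) + 1]] <-
        stats::approx(ph, y, xout = grid, rule = 2)$y
    }
  }
  if (length(curves) < 3)
    stop("need at least 3 annotated cycles to average")
  m <- do.call(rbind, curves)
  data.frame(phase = grid, mean = colMeans(m), sd = apply(m, 2, stats::sd),
             n_cycles = nrow(m))
}

#' Construct a biochemical assay time series
#'
#' @param kind One of `"synthesis"`, `"apc_degradation"`, `"kinase"`,
#'   `"phosphatase"`.
#' @param time_min Sampling times (increasing, >= 3 samples).
#' @param signal Measured signal.
#' @param temperature_C Assay temperature.
#' @return An object of class `"assay_series"`.
#' @export
assay_series <- function(kind = c("synthesis", "apc_degradation", "kinase",
                                  "phosphatase"),
                         time_min, signal, temperature_C = NA_real_) {
  kind <- match.arg(kind)
  if (length(time_min) < 3) stop("need >= 3 samples")
  if (any(diff(time_min) <= 0)) stop("times must be increasing")
  structure(list(kind = kind, time_min = time_min, signal = signal,
                 temperature_C = temperature_C), class = "assay_series")
}

#' Fit a reaction rate from a biochemical assay time series
#'
#' Synthesis, kinase and phosphatase assays use the initial-rate
#' convention: the least-squares linear slope of signal versus time.
#' APC/C degradation assays are normalized to their starting intensity
#' and fitted with a single-exponential decay
#' `signal = A exp(-rate t)`; the decay rate constant is returned. An
#' increasing signal in a decay assay yields a fit with a sign warning.
#'
#' @param series An [assay_series()].
#' @return List with `kind`, `rate` (signal units/min, or 1/min for
#'   decay), `r_squared`, `temperature_C`.
#' @export
fit_assay_rate <- function(series) {
  stopifnot(inherits(series, "assay_series"))
  tt <- series$time_min
  y <- series$signal
  if (series$kind == "apc_degradation") {
    y0 <- y / y[1] # normalize to starting intensity
    if (y0[length(y0)] > y0[1])
      warning("signal increases over time in a decay assay; rate will be negative")
    pos <- pmax(y0, 1e-12)
    init <- stats::coef(stats::lm(log(pos) ~ tt))
    fit <- minpack.lm::nlsLM(y0 ~ A * exp(-k * tt),
                             start = list(A = exp(init[[1]]),
                                          k = -init[[2]]))
    k <- stats::coef(fit)[["k"]]
    ss_res <- sum(stats::resid(fit)^2)
    r2 <- 1 - ss_res / sum((y0 - mean(y0))^2)
    list(kind = series$kind, rate = k, r_squared = r2,
         temperature_C = series$temperature_C)
  } else {
    fit <- stats::lm(y ~ tt)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
    list(kind = series$kind, rate = unname(stats::coef(fit)[2]),
         r_squared = r2, temperature_C = series$temperature_C)
  }
}

#' Read / write droplet traces as tidy delimited text
#'
#' The on-disk schema is one row per sample:
#' `droplet_id, time_min, ratio, radius_um, temperature_C`.
#'
#' @param path CSV file path.
#' @param traces List of [fret_trace()] objects.
#' @return `read_droplet_traces()`: a list of traces;
#'   `write_droplet_traces()`: `path`, invisibly.
#' @export
read_droplet_traces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("droplet_id", "time_min", "ratio", "radius_um", "temperature_C")
  if (!all(need %in% names(df)))
    stop("droplet CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$droplet_id), function(d) {
    d <- d[order(d$time_min), ]
    fret_trace(d$droplet_id[1], d$time_min, d$ratio, d$radius_um[1],
               d$temperature_C[1])
  })
}

#' @rdname read_droplet_traces
#' @export
write_droplet_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(droplet_id = trace_meta(tr, "droplet_id"),
               time_min = tr$time_min, ratio = tr$ratio,
               radius_um = trace_meta(tr, "radius_um"),
               temperature_C = trace_meta(tr, "temperature_C")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read / write duration datasets as delimited text
#'
#' Schema: `temperature_C, duration_min, replicate, event, label`.
#'
#' @param path CSV file path.
#' @param data data.frame in the same schema.
#' @return `read_duration_data()`: data.frame;
#'   `write_duration_data()`: `path`, invisibly.
#' @export
read_duration_data <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("temperature_C", "duration_min") %in% names(df)))
    stop("duration CSV must have columns temperature_C, duration_min")
  df
}

#' @rdname read_duration_data
#' @export
write_duration_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
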