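#' AFM approach force curve
#'
#' @param separation Tip-substrate separation (nm), descending during the
#'   approach toward (and possibly past) hard contact.
#' @param force Measured force (nN).
#' @param metadata Optional list (condition, location index, ...).
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(separation, force, metadata = list()) {
  stopifnot(length(separation) == length(force))
  structure(list(separation = separation, force = force, metadata = metadata),
            class = "force_curve")
}

# Baseline (and noise sd) from the far-from-surface 20% of points
.afm_baseline <- function(s, f) {
  far <- s >= stats::quantile(s, 0.8)
  list(offset = stats::median(f[far]), noise_sd = stats::sd(f[far]))
}

# Hard-contact zero from a linear fit to the steep constant-compliance region
.afm_contact_zero <- function(s, f) {
  n <- length(s)
  sel <- which(s <= stats::quantile(s, 0.08))
  if (length(sel) < 4) sel <- order(s)[seq_len(min(6, n))]
  fit <- stats::lm(f[sel] ~ s[sel])
  slope <- stats::coef(fit)[[2]]
  if (!is.finite(slope) || slope >= -1e-6 ||
      max(f[sel]) < 5 * max(stats::sd(f[s >= stats::quantile(s, 0.8)]), 1e-6))
    stop("hard-contact region not identifiable (no steep compliance rise)")
  -stats::coef(fit)[[1]] / slope
}

#' Detect breakthrough events in a force curve
#'
#' Locates sudden force drops during the approach: the force must fall by at
#' least `drop_threshold` within `window` points while the separation
#' decreases. The curve is baseline-subtracted, lightly Savitzky-Golay
#' smoothed for detection (raw values are used for the force readout), and
#' referenced to the hard-contact zero obtained from a linear fit to the
#' steep constant-compliance region.
#'
#' @param curve A [force_curve()].
#' @param drop_threshold Minimum force drop (nN); default 5x the baseline
#'   noise sd.
#' @param window Detection window in points.
#' @return data.frame of class `breakthrough_events` with columns `f_b` (nN,
#'   force immediately before the drop), `e_b` (nm, separation at the drop
#'   relative to hard contact), ordered by occurrence; zero rows if no event.
#' @export
detect_breakthroughs <- function(curve, drop_threshold = NULL, window = 5) {
  stopifnot(inherits(curve, "force_curve"))
  o <- order(curve$separation, decreasing = TRUE)
  s <- curve$separation[o]
  f_raw <- curve$force[o]
  base <- .afm_baseline(s, f_raw)
  f_raw <- f_raw - base$offset
  if (is.null(drop_threshold))
    drop_threshold <- 5 * max(base$noise_sd, 1e-6)
  if (drop_threshold <= 0) stop("drop_threshold must be positive")
  s0 <- .afm_contact_zero(s, f_raw)
  sz <- s - s0
  f <- .smooth_signal(f_raw, n = 5)
  n <- length(f)
  events <- list()
  i <- 1
  while (i <= n - window) {
    if (sz[i] <= 0) break
    ahead <- f[(i + 1):min(i + window, n)]
    drop <- f[i] - min(ahead)
    if (drop >= drop_threshold && f[i] >= f[i + 1] && f_raw[i] > 0) {
      events[[length(events) + 1]] <-
        data.frame(f_b = max(f_raw[max(1, i - 1):i]), e_b = sz[i])
      i <- i + which.min(ahead) + window  # skip past this drop
    } else {
      i <- i + 1
    }
  }
  out <- if (length(events) > 0) do.call(rbind, events)
  else data.frame(f_b = numeric(0), e_b = numeric(0))
  class(out) <- c("breakthrough_events", "data.frame")
  out
}

#' Summarize breakthrough events over a force-volume map
#'
#' Partitions curves into no-event, one-step and two-step classes and reports
#' per-class statistics of breakthrough force and rupture distance,
#' separately for the first and second events of two-step curves.
#'
#' @param event_list List of [detect_breakthroughs()] results (one per curve).
#' @return List with `classes` (data.frame: class, n, prop) and `stats`
#'   (data.frame: class, event, f_b_mean, f_b_sd, e_b_mean, e_b_sd).
#' @export
summarize_events <- function(event_list) {
  if (length(event_list) < 1) stop("at least one analyzed curve required")
  n_ev <- vapply(event_list, nrow, numeric(1))
  cls <- cut(pmin(n_ev, 2), breaks = c(-1, 0, 1, 2),
             labels = c("none", "one_step", "two_step"))
  classes <- as.data.frame(table(cls))
  names(classes) <- c("class", "n")
  classes$prop <- classes$n / length(event_list)

  stat_row <- function(class, event, fb, eb) {
    data.frame(class = class, event = event,
               f_b_mean = mean(fb), f_b_sd = if (length(fb) > 1) stats::sd(fb) else 0,
               e_b_mean = mean(eb), e_b_sd = if (length(eb) > 1) stats::sd(eb) else 0)
  }
  stats_list <- list()
  one <- event_list[cls == "one_step"]
  if (length(one) > 0) {
    fb <- vapply(one, function(e) e$f_b[1], numeric(1))
    eb <- vapply(one, function(e) e$e_b[1], numeric(1))
    stats_list[[length(stats_list) + 1]] <- stat_row("one_step", "single", fb, eb)
  }
  two <- event_list[cls == "two_step"]
  if (length(two) > 0) {
    for (k in 1:2) {
      fb <- vapply(two, function(e) e$f_b[k], numeric(1))
      eb <- vapply(two, function(e) e$e_b[k], numeric(1))
      stats_list[[length(stats_list) + 1]] <-
        stat_row("two_step", c("first", "second")[k], fb, eb)
    }
  }
  stats <- if (length(stats_list) > 0) do.call(rbind, stats_list)
  else data.frame(class = character(0), event = character(0),
                  f_b_mean = numeric(0), f_b_sd = numeric(0),
                  e_b_mean = numeric(0), e_b_sd = numeric(0))
  list(classes = classes, stats = stats)
}
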