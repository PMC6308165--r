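## Annexin V / propidium iodide quadrant analysis and the
## necrosis-vs-apoptosis kinetic signature.

.QUADRANTS <- c("viable", "early_apoptotic", "late_apoptotic_necrotic",
                "av_neg_pi_pos")

#' Quadrant gates for two-channel AV/PI data
#'
#' Fixed fluorescence thresholds separating annexin V-negative/-positive and
#' PI-negative/-positive events.  Events exactly on a threshold are counted
#' as negative (positivity is strict `>`), a deterministic tie-break.
#'
#' @param av_threshold,pi_threshold strictly positive intensities (AU).
#' @return a list of class `"QuadrantGates"`.
#' @export
quadrantGates <- function(av_threshold, pi_threshold) {
  if (!is.numeric(av_threshold) || !is.numeric(pi_threshold) ||
      av_threshold <= 0 || pi_threshold <= 0)
    stop("gate thresholds must be strictly positive")
  structure(list(av = av_threshold, pi = pi_threshold),
            class = "QuadrantGates")
}

#' Estimate gates from an unstained-control cloud
#'
#' Sets each channel's threshold at a high quantile (default 99.5%) of the
#' unstained control events, so essentially all control events fall in the
#' double-negative quadrant.
#'
#' @param events data.frame with `av` and `pi` columns (unstained control).
#' @param q quantile used per channel.
#' @return a [quadrantGates()] object.
#' @export
estimateGates <- function(events, q = 0.995) {
  stopifnot(is.data.frame(events), all(c("av", "pi") %in% names(events)))
  quadrantGates(quantile(events$av, q, names = FALSE),
                quantile(events$pi, q, names = FALSE))
}

#' Classify stained events into AV/PI quadrants
#'
#' Assigns every event to exactly one quadrant: viable (AV- PI-), early
#' apoptotic (AV+ PI-), late apoptotic / necrotic (AV+ PI+), and AV- PI+
#' (kept as its own reported class).  Positivity is strict (`> threshold`).
#'
#' @param events data.frame with numeric `av` and `pi` columns, one row per
#'   event; intensities must be finite and non-negative.
#' @param gates a [quadrantGates()] object.
#' @return named numeric vector of the four quadrant fractions (summing to
#'   1) with attributes `counts` (integer per quadrant) and `n` (events).
#' @examples
#' ev <- genCytometry(c(0.6, 0.1, 0.25, 0.05), n_events = 5000, seed = 7)
#' classifyEvents(ev, quadrantGates(178, 178))
#' @export
classifyEvents <- function(events, gates) {
  stopifnot(is.data.frame(events), all(c("av", "pi") %in% names(events)),
            inherits(gates, "QuadrantGates"))
  if (nrow(events) == 0L) stop("no events to classify")
  if (any(!is.finite(events$av)) || any(!is.finite(events$pi)) ||
      any(events$av < 0) || any(events$pi < 0))
    stop("event intensities must be finite and non-negative")
  avp <- events$av > gates$av
  pip <- events$pi > gates$pi
  counts <- c(
    viable = sum(!avp & !pip),
    early_apoptotic = sum(avp & !pip),
    late_apoptotic_necrotic = sum(avp & pip),
    av_neg_pi_pos = sum(!avp & pip))
  frac <- counts / nrow(events)
  attr(frac, "counts") <- counts
  attr(frac, "n") <- nrow(events)
  frac
}

.deadFraction <- function(fractions) {
  ## "dead" = anything not double-negative; matches aggregate phrasing like
  ## "dead double-stained cells".
  1 - unname(fractions["viable"])
}

#' Percent trypan-stained (dead) cells
#'
#' @param stained count of trypan-positive (dead) cells.
#' @param total total cells counted (>= 1).
#' @return percent dead, `100 * stained / total`.
#' @export
trypanDeadFraction <- function(stained, total) {
  if (any(total < 1) || any(stained < 0) || any(stained != round(stained)) ||
      any(total != round(total)))
    stop("counts must be non-negative integers with total >= 1")
  if (any(stained > total)) stop("stained count exceeds total count")
  100 * stained / total
}

#' Kinetic death-mode signature over a time x concentration panel
#'
#' Distinguishes a necrosis-like pattern -- dead fraction set within minutes
#' and essentially flat over subsequent incubation, but strongly dose-
#' dependent -- from an apoptosis-like pattern in which the dead fraction
#' keeps growing with incubation time.  The rule set:
#' \itemize{
#'   \item `necrosis_like`: at every concentration the dead-fraction range
#'     across time is at most `time_tol` points, and at some time point the
#'     range across concentrations is at least `conc_min_effect` points;
#'   \item `apoptosis_like`: at some concentration the dead fraction rises
#'     monotonically with time by more than `time_tol` points overall;
#'   \item otherwise `inconclusive` (includes flat-at-control panels).
#' }
#'
#' @param panel data.frame with columns `concentration`, `time`, `dead`
#'   (percent dead, e.g. `100 * (1 - viable fraction)`); needs at least two
#'   distinct concentrations and two distinct times.
#' @param time_tol tolerance on time dependence, percentage points.
#' @param conc_min_effect minimum concentration effect, percentage points.
#' @return `"necrosis_like"`, `"apoptosis_like"` or `"inconclusive"`, with
#'   attributes `max_time_range` and `max_conc_range` (points).
#' @examples
#' panel <- expand.grid(concentration = c(3, 6), time = c(1, 2, 4))
#' panel$dead <- c(62, 95, 63, 96, 64, 96)
#' deathModeSignature(panel)  # "necrosis_like"
#' @export
deathModeSignature <- function(panel, time_tol = 10, conc_min_effect = 20) {
  stopifnot(is.data.frame(panel),
            all(c("concentration", "time", "dead") %in% names(panel)))
  if (length(unique(panel$concentration)) < 2L ||
      length(unique(panel$time)) < 2L)
    stop("panel needs at least 2 concentrations and 2 time points")
  panel <- panel[order(panel$concentration, panel$time), ]

  timeRange <- tapply(panel$dead, panel$concentration,
                      function(v) diff(range(v)))
  concRange <- tapply(panel$dead, panel$time, function(v) diff(range(v)))
  flatInTime <- max(timeRange) <= time_tol
  doseEffect <- max(concRange) >= conc_min_effect

  call <- if (flatInTime && doseEffect) {
    "necrosis_like"
  } else {
    risesWithTime <- vapply(split(panel, panel$concentration), function(d) {
      d <- d[order(d$time), ]
      all(diff(d$dead) >= 0) && diff(range(d$dead)) > time_tol
    }, logical(1))
    if (any(risesWithTime)) "apoptosis_like" else "inconclusive"
  }
  structure(call, max_time_range = max(timeRange),
            max_conc_range = max(concRange))
}

#' Caspase-independence of killing
#'
#' Compares the dead fraction (1 - viable) with and without a pan-caspase
#' inhibitor (Z-VAD-FMK) at matched peptide/concentration/time.  Killing is
#' called caspase-independent when the inhibitor changes the dead fraction
#' by at most `tol` percentage points; caspase-driven apoptosis (e.g.
#' camptothecin) is abrogated by the inhibitor and fails the test.
#'
#' @param without,with_inhibitor quadrant-fraction vectors from
#'   [classifyEvents()] (or any named vector with a `viable` element).
#' @param tol tolerance in percentage points (default 5).
#' @return list with `independent` (logical) and `delta` (points, signed:
#'   positive when the inhibitor reduced killing).
#' @export
caspaseIndependence <- function(without, with_inhibitor, tol = 5) {
  d0 <- .deadFraction(without)
  d1 <- .deadFraction(with_inhibitor)
  delta <- 100 * (d0 - d1)
  list(independent = abs(delta) <= tol, delta = delta)
}
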