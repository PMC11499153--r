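## Experiment-level aggregation and the percent-change summaries used to
## report potassium-evoked ECS and volume changes.

#' Aggregate per-cell (or per-slice) time courses into a group summary
#'
#' Computes the per-timepoint mean, standard error of the mean
#' (sd / sqrt(n)) and unit count across a set of time courses sharing one
#' time grid. With a single series the SEM is reported as 0 and flagged.
#'
#' @param series list of \code{\linkS4class{VolumeTimecourse}} objects, or
#'   a list of numeric vectors, or a matrix (units in rows).
#' @param t time grid; taken from the first VolumeTimecourse when omitted.
#' @param label group name.
#' @param value which tracked quantity to aggregate when \code{series} are
#'   VolumeTimecourses: \code{"vol_pct"}, \code{"fi"} or \code{"ss"}.
#' @return data.frame with columns \code{t}, \code{mean}, \code{sem},
#'   \code{n}; the group label is kept in attribute \code{"label"}, and a
#'   single-series aggregate carries attribute \code{"sem_degenerate"}.
#' @examples
#' aggregateGroup(list(c(100, 200), c(100, 100)), t = c(0, 5))
#' @export
aggregateGroup <- function(series, t = NULL, label = "group",
                           value = c("vol_pct", "fi", "ss")) {
  value <- match.arg(value)
  if (is.matrix(series))
    series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
  if (length(series) && is(series[[1]], "VolumeTimecourse")) {
    if (is.null(t)) t <- series[[1]]@t
    if (!all(vapply(series, function(s) isTRUE(all.equal(s@t, t)), TRUE)))
      stop("all time courses must share one time grid")
    series <- lapply(series, function(s) slot(s, value))
  }
  len <- lengths(series)
  if (length(unique(len)) != 1)
    stop("all series must share one time grid")
  if (is.null(t)) t <- seq_len(len[1])
  if (length(t) != len[1]) stop("t does not match the series length")
  m <- do.call(rbind, series)
  n <- nrow(m)
  out <- data.frame(t = t, mean = colMeans(m),
                    sem = if (n > 1) apply(m, 2, sd) / sqrt(n) else 0,
                    n = n)
  attr(out, "label") <- label
  if (n == 1) attr(out, "sem_degenerate") <- TRUE
  rownames(out) <- NULL
  out
}

#' Percent drop from an initial value
#'
#' Signed relative decrease, \eqn{100 (x_0 - x_t)/x_0} percent: positive
#' for a drop, negative for an increase. Reported values are conventionally
#' rounded to the nearest integer percent; set \code{rounded = TRUE} for
#' that display form.
#'
#' @param initial value before the challenge, > 0.
#' @param at_time value at the timepoint of interest.
#' @param rounded round to the nearest integer percent.
#' @return percent decrease (numeric).
#' @examples
#' percentDrop(0.196, 0.171, rounded = TRUE)  # 13
#' percentDrop(0.193, 0.130)                  # 32.64
#' @export
percentDrop <- function(initial, at_time, rounded = FALSE) {
  if (any(initial <= 0)) stop("initial value must be > 0")
  out <- 100 * (initial - at_time) / initial
  if (rounded) round(out) else out
}

#' Washout recovery relative to the peak change
#'
#' Quantifies how far a quantity returns towards its initial value during
#' washout, after reaching \code{peak} at the end of the challenge. Two
#' conventions are in use and both are provided, with the choice recorded
#' on the result:
#' \describe{
#'   \item{\code{fraction-of-deficit}}{\eqn{100 (x_{end} - x_{peak}) /
#'     (x_0 - x_{peak})}: 0\% = still at peak, 100\% = fully back to the
#'     initial value, >100\% = overshoot.}
#'   \item{\code{ratio-to-peak}}{\eqn{100\, x_{end} / x_{peak}}: the end
#'     value as a percentage of the peak value (the peak set to 100\%).}
#' }
#'
#' @param initial value before the challenge.
#' @param peak value at the end of the challenge (must differ from
#'   \code{initial} for the deficit convention).
#' @param end_value value at the end of washout.
#' @param convention which definition to use.
#' @return percent recovery, with the convention in attribute
#'   \code{"convention"}.
#' @examples
#' washoutRecovery(0.193, 0.130, 0.189)  # 93.7% of the deficit recovered
#' @export
washoutRecovery <- function(initial, peak, end_value,
                            convention = c("fraction-of-deficit",
                                           "ratio-to-peak")) {
  convention <- match.arg(convention)
  val <- switch(convention,
    "fraction-of-deficit" = {
      if (peak == initial)
        stop("peak equals initial: deficit is zero")
      100 * (end_value - peak) / (initial - peak)
    },
    "ratio-to-peak" = {
      if (peak == 0) stop("peak value is zero")
      100 * end_value / peak
    })
  structure(val, convention = convention)
}

#' Export time courses as a tidy table
#'
#' One row per unit and timepoint, ready for external statistical tools
#' (the inferential analysis -- ANOVA, multiple-comparison corrections --
#' is deliberately left to dedicated statistics software).
#'
#' @param series named list of \code{\linkS4class{VolumeTimecourse}}
#'   objects.
#' @param group group label stored with every row.
#' @return data.frame with columns \code{group}, \code{unit}, \code{t},
#'   \code{vol_pct}, \code{fi}, \code{ss}.
#' @export
tidyTimecourses <- function(series, group = "group") {
  if (is.null(names(series)))
    names(series) <- paste0("unit", seq_along(series))
  do.call(rbind, lapply(names(series), function(nm) {
    s <- series[[nm]]
    data.frame(group = group, unit = nm, t = s@t, vol_pct = s@vol_pct,
               fi = s@fi, ss = s@ss, row.names = NULL)
  }))
}
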