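#' @keywords internal
# Pool glucose samples from a trace, a list of traces, or a numeric
# vector; NAs (QC gaps) are dropped.
pool_glucose <- function(x) {
  g <- if (inherits(x, "glucose_trace")) {
    x$glucose
  } else if (is.list(x)) {
    unlist(lapply(x, function(s)
      if (inherits(s, "glucose_trace")) s$glucose else as.numeric(s)),
      use.names = FALSE)
  } else {
    as.numeric(x)
  }
  g[!is.na(g)]
}

#' Mean and SD of glucose over retained CGM data
#'
#' Arithmetic mean and sample SD (n - 1 denominator) over all retained
#' samples pooled per subject.
#'
#' @param segments a `glucose_trace`, a list of retained trace segments,
#'   or a numeric vector of samples (mmol/l).
#' @return list with `mean`, `sd` and `n` (samples used).
#' @export
basic_stats <- function(segments) {
  g <- pool_glucose(segments)
  if (length(g) < 2)
    stop("insufficient data: need >= 2 glucose samples")
  list(mean = mean(g), sd = stats::sd(g), n = length(g))
}

# Turning points of a series after collapsing plateaus and monotone
# runs; returns indices into the de-plateaued value vector together with
# the values.  Endpoints are included.
turning_points <- function(g) {
  keep <- c(TRUE, diff(g) != 0)      # collapse plateaus
  v <- g[keep]
  if (length(v) < 3) return(v)
  s <- sign(diff(v))
  turn <- c(TRUE, s[-1] != s[-length(s)], TRUE)
  v[turn]
}

#' Mean amplitude of glycaemic excursions (MAGE)
#'
#' Turning points are identified after collapsing plateaus and monotone
#' runs; an excursion between consecutive turning points qualifies when
#' its amplitude exceeds one SD of the whole series.  MAGE is the mean
#' qualifying amplitude, counted consistently in the direction
#' (peak-to-nadir or nadir-to-peak) of the first qualifying excursion.
#' Returns `NA` when no excursion qualifies (e.g. a constant trace).
#'
#' @param segments as for [basic_stats()].
#' @return MAGE in mmol/l, or `NA_real_` if undefined.
#' @export
mage <- function(segments) {
  g <- pool_glucose(segments)
  if (length(g) < 2)
    stop("insufficient data: need >= 2 glucose samples")
  s <- stats::sd(g)
  tp <- turning_points(g)
  if (length(tp) < 2 || s == 0) return(NA_real_)
  amp <- diff(tp)
  qual <- abs(amp) > s
  if (!any(qual)) return(NA_real_)
  dir <- sign(amp[which(qual)[1]])
  mean(abs(amp[qual & sign(amp) == dir]))
}

#' Low blood glucose index (LBGI)
#'
#' Kovatchev's symmetrising transform of the glucose scale: samples are
#' converted to mg/dl (x 18.016), f = 1.509 ((ln g)^1.084 - 5.381),
#' per-sample risk = 10 f^2 when f < 0 and 0 otherwise, and LBGI is the
#' mean risk over all retained samples.
#'
#' @param segments as for [basic_stats()]; samples in mmol/l.
#' @return LBGI (dimensionless, >= 0).
#' @export
lbgi <- function(segments) {
  g <- pool_glucose(segments)
  if (!length(g)) stop("insufficient data: need >= 1 glucose sample")
  if (any(g <= 0)) stop("input error: glucose samples must be > 0")
  g_mgdl <- g * 18.016
  f <- 1.509 * (log(g_mgdl)^1.084 - 5.381)
  risk <- ifelse(f < 0, 10 * f^2, 0)
  mean(risk)
}

#' Per-subject glycaemic variability metric set
#'
#' @param segments retained trace segments for one subject.
#' @param subject_id subject identifier (defaults to the first segment's).
#' @return one-row data frame: `subject_id`, `mean_glucose`, `sd_glucose`,
#'   `mage`, `lbgi`, `hours` of data used.
#' @export
compute_metrics <- function(segments, subject_id = NULL) {
  if (inherits(segments, "glucose_trace")) segments <- list(segments)
  if (is.null(subject_id)) subject_id <- segments[[1]]$subject_id
  hours <- sum(vapply(segments, function(s)
    sum(!is.na(s$glucose)) * s$interval_min, numeric(1))) / 60
  bs <- basic_stats(segments)
  data.frame(subject_id = subject_id,
             mean_glucose = bs$mean, sd_glucose = bs$sd,
             mage = mage(segments), lbgi = lbgi(segments),
             hours = hours)
}
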