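# Plate-reader kinetics: growth rate, production rates, maximal ("capacity")
# rates. Time is in hours throughout; fluorescence in arbitrary units.
# All three rate statistics share the same centered +/- 0.5 h window, so
# growth rate and production rates evaluated at the same t2 are mutually
# consistent.

#' Assemble a plate-reader time series
#'
#' @param time Sample times in hours, strictly increasing.
#' @param gfp GFP fluorescence (arbitrary units).
#' @param rfp Optional RFP fluorescence.
#' @param od,od600,od700 Optional optical density channels. In vivo
#'   statistics need at least one; OD700 is preferred for growth when both
#'   numbered channels are present.
#' @param well,sample,condition Labels.
#' @return A tibble with class `ribocap_plate`.
#' @export
plate_time_series <- function(time, gfp, rfp = NULL, od = NULL,
                              od600 = NULL, od700 = NULL,
                              well = "A1", sample = "sample",
                              condition = "default") {
  n <- length(time)
  if (n < 2 || any(diff(time) <= 0)) {
    stop_input("time must be strictly increasing with >= 2 points")
  }
  cols <- list(time = as.numeric(time), gfp = as.numeric(gfp))
  for (ch in c("rfp", "od", "od600", "od700")) {
    v <- switch(ch, rfp = rfp, od = od, od600 = od600, od700 = od700)
    if (!is.null(v)) cols[[ch]] <- as.numeric(v)
  }
  lens <- lengths(cols)
  if (any(lens != n)) {
    stop_input("all channels must have the same length as time")
  }
  out <- as_tibble(cols)
  out$well <- well
  out$sample <- sample
  out$condition <- condition
  class(out) <- unique(c("ribocap_plate", class(out)))
  out
}

# pick the OD channel: OD700 preferred, then OD600, then plain od
od_channel <- function(ts) {
  for (ch in c("od700", "od600", "od")) {
    if (ch %in% names(ts) && !all(is.na(ts[[ch]]))) return(ch)
  }
  stop_input("series has no optical density channel")
}

nearest_index <- function(time, t) which.min(abs(time - t))

check_window <- function(time, t2, half_width) {
  if (t2 - half_width < time[1] - 1e-9 || t2 + half_width > tail(time, 1) + 1e-9) {
    stop_input(sprintf(
      "window t2 +/- %g h around t2 = %g h falls outside the series [%g, %g]",
      half_width, t2, time[1], tail(time, 1)))
  }
}

#' Specific growth rate at a time point
#'
#' Centered log-OD difference: `[ln OD(t3) - ln OD(t1)] / (t3 - t1)` with
#' `t1 = t2 - 0.5 h` and `t3 = t2 + 0.5 h`, evaluated at the sample times
#' nearest t1 and t3.
#'
#' @param ts A plate time series with an OD channel.
#' @param t2 Centre of the window, hours (typically mid-exponential; see
#'   [find_mid_exponential()]).
#' @param half_width Window half-width in hours (default 0.5).
#' @return Growth rate in h^-1.
#' @examples
#' ts <- plate_time_series(time = seq(0, 8, 1 / 6),
#'                         gfp = 0 * seq(0, 8, 1 / 6),
#'                         od = 0.05 * exp(0.5 * seq(0, 8, 1 / 6)))
#' growth_rate(ts, t2 = 4) # 0.5
#' @export
growth_rate <- function(ts, t2, half_width = 0.5) {
  ch <- od_channel(ts)
  check_window(ts$time, t2, half_width)
  i1 <- nearest_index(ts$time, t2 - half_width)
  i3 <- nearest_index(ts$time, t2 + half_width)
  od1 <- ts[[ch]][i1]
  od3 <- ts[[ch]][i3]
  if (od1 <= 0 || od3 <= 0) stop_input("OD must be positive inside the window")
  (log(od3) - log(od1)) / (ts$time[i3] - ts$time[i1])
}

#' Locate the mid-exponential phase
#'
#' Returns the time point maximizing the centered log-OD slope over
#' +/- `half_width` windows (edge windows excluded). Errors when the series
#' shows no appreciable growth.
#'
#' @inheritParams growth_rate
#' @param min_rate Slope below which the culture is declared non-growing
#'   (default 0.01 h^-1).
#' @return The time t2 in hours.
#' @export
find_mid_exponential <- function(ts, half_width = 0.5, min_rate = 0.01) {
  ch <- od_channel(ts)
  tt <- ts$time
  if (tail(tt, 1) - tt[1] < 2 * half_width) {
    stop_input("series too short to place a centered window")
  }
  ok <- which(tt - half_width >= tt[1] - 1e-9 &
                tt + half_width <= tail(tt, 1) + 1e-9)
  if (length(ok) == 0) stop_input("no admissible window centres")
  slopes <- vapply(tt[ok], function(t2) growth_rate(ts, t2, half_width),
                   numeric(1))
  if (max(slopes) < min_rate) {
    stop_input("no growth detected (maximal log-OD slope below threshold)",
               class = "ribocap_no_growth_error")
  }
  tt[ok][which.max(slopes)]
}

#' Per-OD protein production rate (in vivo)
#'
#' `[(F(t3) - F(t1)) / (t3 - t1)] / OD(t2)` with the same +/- 0.5 h window
#' convention as [growth_rate()].
#'
#' @inheritParams growth_rate
#' @param channel `"gfp"` or `"rfp"`.
#' @return Rate in fluorescence h^-1 OD^-1.
#' @export
production_rate_in_vivo <- function(ts, t2, channel = "gfp",
                                    half_width = 0.5) {
  ch_od <- od_channel(ts)
  rate <- production_rate_in_vitro(ts, t2, channel, half_width)
  od2 <- ts[[ch_od]][nearest_index(ts$time, t2)]
  if (od2 <= 0) stop_input("OD at t2 must be positive")
  rate / od2
}

#' Protein production rate (in vitro / lysate)
#'
#' `(F(t3) - F(t1)) / (t3 - t1)`, no OD division.
#'
#' @inheritParams production_rate_in_vivo
#' @return Rate in fluorescence h^-1.
#' @export
production_rate_in_vitro <- function(ts, t2, channel = "gfp",
                                     half_width = 0.5) {
  if (!channel %in% names(ts)) {
    stop_input(sprintf("channel '%s' not present in series", channel))
  }
  check_window(ts$time, t2, half_width)
  i1 <- nearest_index(ts$time, t2 - half_width)
  i3 <- nearest_index(ts$time, t2 + half_width)
  (ts[[channel]][i3] - ts[[channel]][i1]) / (ts$time[i3] - ts$time[i1])
}

#' Maximal production rate of a kinetic trace ("capacity")
#'
#' The maximum of the windowed production-rate series over all admissible
#' window centres; the first and last admissible windows are excluded to
#' avoid edge artifacts. For `mode = "in_vivo"` each rate is divided by the
#' OD at its window centre.
#'
#' @inheritParams production_rate_in_vivo
#' @param mode `"lysate"` (fluorescence h^-1) or `"in_vivo"`
#'   (fluorescence h^-1 OD^-1).
#' @return The raw maximal rate.
#' @export
capacity <- function(ts, mode = c("lysate", "in_vivo"), channel = "gfp",
                     half_width = 0.5) {
  mode <- match.arg(mode)
  tt <- ts$time
  ok <- which(tt - half_width >= tt[1] - 1e-9 &
                tt + half_width <= tail(tt, 1) + 1e-9)
  if (length(ok) > 2) ok <- ok[-c(1, length(ok))]
  if (length(ok) < 1) {
    stop_input("series too short: need at least 3 admissible windows")
  }
  rate_fn <- if (mode == "in_vivo") production_rate_in_vivo else
    production_rate_in_vitro
  rates <- vapply(tt[ok], function(t2) rate_fn(ts, t2, channel, half_width),
                  numeric(1))
  max(rates)
}

#' Normalize a raw maximal rate against the monitor-alone reference
#'
#' @param raw_max_rate Raw maximal production rate (from [capacity()]).
#' @param reference_rate Monitor-alone maximal rate in the same units.
#' @param mode `"lysate"` or `"in_vivo"`.
#' @param condition Condition label carried into the result.
#' @return A one-row tibble: `value` (dimensionless normalized capacity),
#'   `raw_max_rate`, `reference_rate`, `mode`, `condition`.
#' @export
normalize_capacity <- function(raw_max_rate, reference_rate,
                               mode = c("lysate", "in_vivo"),
                               condition = "default") {
  mode <- match.arg(mode)
  if (!is.finite(reference_rate) || reference_rate <= 0) {
    stop_input("reference_rate must be positive")
  }
  tibble(value = raw_max_rate / reference_rate,
         raw_max_rate = raw_max_rate, reference_rate = reference_rate,
         mode = mode, condition = condition)
}

#' Read a plate export CSV
#'
#' Accepts the two common export schemas. Long format has columns
#' `time`, `well`, `channel`, `value` (plus optional `sample`, `condition`)
#' and is pivoted so each channel becomes a column. Wide format already has
#' one column per channel (`gfp`, and optionally `rfp`, `od`, `od600`,
#' `od700`) next to `time` and `well`.
#'
#' @param path CSV file path.
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @return A tibble, one row per well and time point, channels as columns.
#' @export
read_plate_csv <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_input(sprintf("plate file '%s' does not exist", path))
  }
  raw <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (format == "auto") {
    format <- if (all(c("channel", "value") %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    required <- c("time", "well", "channel", "value")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop_input(paste0("long plate CSV lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
    }
    raw <- tidyr::pivot_wider(raw, names_from = "channel",
                              values_from = "value")
  }
  if (!all(c("time", "well", "gfp") %in% names(raw))) {
    stop_input("plate table needs columns time, well, gfp")
  }
  if (!"sample" %in% names(raw)) raw$sample <- raw$well
  if (!"condition" %in% names(raw)) raw$condition <- "default"
  dplyr::arrange(raw, .data$well, .data$time)
}

#' Write a plate table in the long CSV schema
#'
#' @param plate A plate tibble as returned by [read_plate_csv()] or built
#'   from [plate_time_series()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  channels <- intersect(c("gfp", "rfp", "od", "od600", "od700"), names(plate))
  long <- tidyr::pivot_longer(plate, dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  long <- dplyr::select(long, dplyr::any_of(
    c("time", "well", "sample", "condition", "channel", "value")))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Per-well summary statistics for a whole plate
#'
#' Applies [capacity()] (and, in vivo, [find_mid_exponential()] and
#' [growth_rate()]) to every well of a plate table.
#'
#' @param plate A plate tibble (long-read result; multiple wells).
#' @param mode `"lysate"` or `"in_vivo"`.
#' @param channel Fluorescence channel.
#' @return A tibble with one row per well: labels, `raw_max_rate`, and for
#'   in vivo mode `t_mid` and `growth_rate`.
#' @export
well_statistics <- function(plate, mode = c("lysate", "in_vivo"),
                            channel = "gfp") {
  mode <- match.arg(mode)
  plate |>
    dplyr::group_by(.data$well, .data$sample, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      ts <- df[order(df$time), ]
      out <- tibble(raw_max_rate = capacity(ts, mode = mode,
                                            channel = channel))
      if (mode == "in_vivo") {
        t_mid <- find_mid_exponential(ts)
        out$t_mid <- t_mid
        out$growth_rate <- growth_rate(ts, t_mid)
      }
      out
    }) |>
    dplyr::ungroup()
}
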