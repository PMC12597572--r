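#' Dosing schedules
#'
#' A dosing schedule is a tibble with columns `time` (min), `amount` (mg)
#' and `duration` (min; 0 means an instantaneous bolus into the remimazolam
#' central compartment). `dose_bolus()` and `dose_infusion()` build single
#' events; `dose_schedule()` validates, sorts and combines them.
#' Overlapping infusions are allowed and sum their rates.
#'
#' @param time start time in min, >= 0.
#' @param amount dose in mg, >= 0.
#' @param duration infusion duration in min, > 0.
#' @param rate infusion rate in mg/min (alternative to `amount`).
#' @param ... events (data frames) to combine.
#' @return A tibble of class `dose_schedule`.
#' @export
#' @examples
#' dose_schedule(dose_bolus(0, 10), dose_infusion(5, duration = 30, rate = 1))
dose_schedule <- function(...) {
  sch <- dplyr::bind_rows(...)
  if (nrow(sch) == 0) {
    sch <- tibble::tibble(time = numeric(), amount = numeric(),
                          duration = numeric())
  }
  stopifnot(all(c("time", "amount", "duration") %in% names(sch)))
  if (any(sch$time < 0) || any(sch$amount < 0) || any(sch$duration < 0)) {
    stop("time, amount and duration must be non-negative", call. = FALSE)
  }
  sch <- dplyr::arrange(sch, .data$time, .data$duration)
  sch <- tibble::as_tibble(sch[, c("time", "amount", "duration")])
  class(sch) <- c("dose_schedule", class(sch))
  sch
}

#' @rdname dose_schedule
#' @export
dose_bolus <- function(time, amount) {
  tibble::tibble(time = time, amount = amount, duration = 0)
}

#' @rdname dose_schedule
#' @export
dose_infusion <- function(time, amount = rate * duration, duration, rate) {
  tibble::tibble(time = time, amount = amount, duration = duration)
}

#' Merge near-contiguous infusion records
#'
#' TCI administration produces long runs of short infusion records with
#' nearly identical rates. Consecutive infusion records are merged into a
#' single record with the summed dose over the combined duration when all
#' three criteria hold: they are separated by less than `max_gap` (default
#' 1 s), their rates differ by less than `max_rate_diff` (default
#' 50 ug/min = 0.05 mg/min), and each record's duration is shorter than
#' `max_duration` (default 2 min). Merging iterates until no records can be
#' combined. Total administered dose is exactly preserved; boluses are
#' never merged.
#'
#' @param schedule a [dose_schedule()].
#' @param max_gap min; @param max_rate_diff mg/min; @param max_duration min.
#' @return A merged `dose_schedule`.
#' @export
merge_dose_records <- function(schedule, max_gap = 1 / 60,
                               max_rate_diff = 0.05, max_duration = 2) {
  sch <- dose_schedule(schedule)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(sch)) {
      a <- sch[i, ]; b <- sch[i + 1, ]
      if (a$duration > 0 && b$duration > 0 &&
          a$duration < max_duration && b$duration < max_duration &&
          abs(b$time - (a$time + a$duration)) < max_gap &&
          abs(a$amount / a$duration - b$amount / b$duration) < max_rate_diff) {
        sch$amount[i] <- a$amount + b$amount
        sch$duration[i] <- (b$time + b$duration) - a$time
        sch <- sch[-(i + 1), ]
        merged <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged) break
  }
  dose_schedule(sch)
}

# piecewise-constant input profile: breakpoints + rate on each interval;
# boluses returned separately
schedule_profile <- function(schedule) {
  sch <- dose_schedule(schedule)
  inf <- sch[sch$duration > 0, ]
  bol <- sch[sch$duration == 0 & sch$amount > 0, ]
  brk <- sort(unique(c(0, inf$time, inf$time + inf$duration, bol$time)))
  rate_at <- function(t) {
    if (nrow(inf) == 0) return(rep(0, length(t)))
    vapply(t, function(tt) {
      sum(inf$amount[inf$time <= tt & tt < inf$time + inf$duration] /
            inf$duration[inf$time <= tt & tt < inf$time + inf$duration])
    }, numeric(1))
  }
  list(breaks = brk, rate_at = rate_at, boluses = bol)
}

# cumulative administered dose at times t (mg)
cumulative_dose <- function(schedule, t) {
  sch <- dose_schedule(schedule)
  out <- numeric(length(t))
  for (i in seq_len(nrow(sch))) {
    if (sch$duration[i] == 0) {
      out <- out + ifelse(t >= sch$time[i], sch$amount[i], 0)
    } else {
      frac <- pmin(pmax((t - sch$time[i]) / sch$duration[i], 0), 1)
      out <- out + sch$amount[i] * frac
    }
  }
  out
}
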