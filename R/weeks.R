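#' @include AllClasses.R
NULL

## Monday-to-Sunday week arithmetic. A date belongs to the week containing
## it; window ends are always Sundays.

#' Monday of the week containing a date
#' @param date a Date (vectorized).
#' @return The Monday on or before `date`.
#' @export
weekMonday <- function(date) {
  date <- as.Date(date)
  wd <- as.integer(format(date, "%u"))  # 1 = Monday .. 7 = Sunday
  date - (wd - 1L)
}

#' Snap a date to the end of a week
#'
#' Returns `date` itself when it already is a Sunday, otherwise the previous
#' Sunday (the end of the last complete Monday-Sunday week).
#' @param date a Date (vectorized).
#' @return A Sunday on or before `date`.
#' @export
snapToSunday <- function(date) {
  date <- as.Date(date)
  wd <- as.integer(format(date, "%u"))
  date - ifelse(wd == 7L, 0L, wd)
}

## 1-based index of the week containing `date` in a grid of `weeks` slots
## ending at `windowEnd` (a Sunday); values outside 1..weeks mean the date
## falls outside the window.
weekIndex <- function(date, windowEnd, weeks) {
  weeks - as.integer(as.numeric(as.Date(windowEnd) - as.Date(date)) %/% 7)
}
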