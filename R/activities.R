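#' Activity label vocabulary
#'
#' The six activity codes used throughout the package: sitting (`SI`),
#' standing (`ST`), walking (`WK`), ascending (`AS`), running (`RU`) and
#' post-exercise rest (`REST`).  Activity recognition uses the five
#' ambulatory labels; energy-expenditure estimation uses all six.
#'
#' @return Character vector of the six activity codes.
#' @export
activity_labels <- function() c("SI", "ST", "WK", "AS", "RU", "REST")

#' @rdname activity_labels
#' @export
recognition_labels <- function() c("SI", "ST", "WK", "AS", "RU")

#' @rdname activity_labels
#' @export
static_labels <- function() c("SI", "ST", "REST")

#' @rdname activity_labels
#' @export
dynamic_labels <- function() c("WK", "AS", "RU")

#' Category (static/dynamic) of an activity code
#'
#' @param activity character vector of activity codes.
#' @return Character vector, `"static"` or `"dynamic"`.
#' @export
activity_category <- function(activity) {
  check_activity(activity)
  ifelse(activity %in% static_labels(), "static", "dynamic")
}

check_activity <- function(activity) {
  bad <- setdiff(activity, activity_labels())
  if (length(bad))
    stop("unknown activity code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(activity)
}

#' Session schedule
#'
#' An ordered list of (activity, minutes) pairs describing one subject's
#' laboratory session.  The default protocol performs each static activity
#' for 5 min and each dynamic activity for 10 min; an optional 5-min REST
#' block (seated recovery) directly follows the last dynamic activity.
#'
#' @param include_rest add the 5-min REST block after running.
#' @return A data.frame with columns `activity` and `minutes`.
#' @export
default_schedule <- function(include_rest = FALSE) {
  sched <- data.frame(
    activity = c("SI", "ST", "WK", "AS", "RU"),
    minutes  = c(5L, 5L, 10L, 10L, 10L),
    stringsAsFactors = FALSE
  )
  if (include_rest)
    sched <- rbind(sched, data.frame(activity = "REST", minutes = 5L))
  validate_schedule(sched)
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule), all(c("activity", "minutes") %in% names(schedule)))
  check_activity(schedule$activity)
  if (any(schedule$minutes <= 0) || any(schedule$minutes != round(schedule$minutes)))
    stop("schedule minutes must be positive integers", call. = FALSE)
  rest <- which(schedule$activity == "REST")
  for (i in rest) {
    if (i == 1L || !(schedule$activity[i - 1L] %in% dynamic_labels()))
      stop("REST entries must directly follow a dynamic activity", call. = FALSE)
  }
  schedule
}
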