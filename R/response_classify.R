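#' Classify validated breakpoints into disturbance-response durations
#'
#' Translates the breakpoints of the selected piecewise model into the three
#' biologically meaningful durations. With release at 0 h:
#'
#' * capture-recovery duration: the earliest validated breakpoint — the time
#'   at which post-release behaviour returns to baseline;
#' * a noise-induced response is declared iff some validated breakpoint
#'   `psi_j` coincides with the exposure time (within `tolerance` hours, or
#'   its bootstrap 95% CI contains the exposure time) and a slope adjacent
#'   to `psi_j` after it is validated; then
#' * noise-response duration = `psi_{j+1} - psi_j` and noise-recovery
#'   duration = `psi_{j+2} - psi_{j+1}` when those later breakpoints exist
#'   (and, in strict mode, are themselves validated).
#'
#' Absence of any response is a valid outcome: animals may show none, some,
#' or entirely different behavioural changes.
#'
#' @param estimates a [bootstrap_breakpoints()] result (or any data.frame
#'   with `psi`, `lo`, `hi`, `validated`, sorted by `psi`).
#' @param exposure_time hours since release (> 0).
#' @param tolerance coincidence tolerance in hours (default 2).
#' @param strict require breakpoints j+1 and j+2 to be validated before
#'   reporting the corresponding durations (default TRUE).
#' @return list of class `response_summary`: `capture_recovery_h` (NA if no
#'   validated breakpoint), `noise_response` (logical),
#'   `noise_breakpoint_id`, `noise_response_h`, `noise_recovery_h`.
#' @export
classify_response <- function(estimates, exposure_time, tolerance = 2,
                              strict = TRUE) {
  stopifnot(is.data.frame(estimates), exposure_time > 0, tolerance >= 0)
  need <- c("psi", "lo", "hi", "validated")
  stopifnot(all(need %in% names(estimates)))
  est <- estimates[order(estimates$psi), ]
  val <- which(est$validated)

  out <- list(capture_recovery_h = NA_real_, noise_response = FALSE,
              noise_breakpoint_id = NA_integer_,
              noise_response_h = NA_real_, noise_recovery_h = NA_real_)
  class(out) <- "response_summary"
  if (!length(val)) return(out)
  out$capture_recovery_h <- est$psi[val[1]]

  ci_lo <- ifelse(is.na(est$lo), est$psi, est$lo)
  ci_hi <- ifelse(is.na(est$hi), est$psi, est$hi)
  coincides <- est$validated &
    (abs(est$psi - exposure_time) <= tolerance |
       (ci_lo <= exposure_time & exposure_time <= ci_hi))
  # the post-breakpoint slope must carry the change: require the right-hand
  # adjacent slope to be significant when that information is available
  right_sig <- attr(estimates, "right_sig")
  if (!is.null(right_sig)) {
    right_sig <- right_sig[order(estimates$psi)]
    coincides <- coincides & right_sig
  }
  hits <- which(coincides)
  if (!length(hits)) return(out)
  j <- hits[which.min(abs(est$psi[hits] - exposure_time))]
  out$noise_response <- TRUE
  out$noise_breakpoint_id <- j
  usable <- function(i) {
    i <= nrow(est) && (!strict || est$validated[i])
  }
  if (usable(j + 1)) {
    out$noise_response_h <- est$psi[j + 1] - est$psi[j]
    if (usable(j + 2))
      out$noise_recovery_h <- est$psi[j + 2] - est$psi[j + 1]
  }
  out
}

#' @export
print.response_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f h", v)
  cat("Response summary\n")
  cat("  capture-recovery duration :", fmt(x$capture_recovery_h), "\n")
  cat("  noise-induced response    :",
      if (x$noise_response) "present" else "absent", "\n")
  if (x$noise_response) {
    cat("  noise-response duration   :", fmt(x$noise_response_h), "\n")
    cat("  noise-recovery duration   :", fmt(x$noise_recovery_h), "\n")
  }
  invisible(x)
}
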