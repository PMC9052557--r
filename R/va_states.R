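#' Visual-acuity health states
#'
#' The on-treatment phase of the model is stratified into six visual-acuity
#' states defined by ETDRS letter score in the treated (study) eye, ordered
#' from best to worst. The worst band (25 letters or fewer) is classed as
#' blindness and attracts blindness costs; the next band (26-40 letters)
#' attracts low-vision costs by default.
#'
#' @format A character vector of the six state labels, best first.
#' @export
va_states <- c("86-100", "71-85", "56-70", "41-55", "26-40", "<=25")

#' @rdname va_states
#' @export
n_va_states <- length(va_states)

#' @rdname va_states
#' @export
blindness_state <- "<=25"

#' @rdname va_states
#' @export
low_vision_state <- "26-40"

#' Letter-change cutoffs mapping BCVA change to state moves
#'
#' A gain or loss of at least 7.5 letters corresponds to moving one
#' 15-letter state; at least 22.5 letters to moving two states. Movement is
#' capped at two states per annual cycle.
#'
#' @return Named numeric vector with elements `one_state` and `two_state`.
#' @export
letter_cutoffs <- function() c(one_state = 7.5, two_state = 22.5)
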