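#' Lagged-count (Markov) covariates for one subject's series
#'
#' Builds the previous-, twice-previous- and thrice-previous-month count
#' covariates (PDV, PPDV, PPPDV) and the binary indicator used by the PMAK1
#' model (1 if the previous month had at least one lesion). Lags that would
#' refer to pre-study months are set to 0, i.e. the likelihood conditions on
#' an assumed lesion-free run-in; `drop_initial` instead marks the first
#' `max_order` months for exclusion from the likelihood (sensitivity
#' analysis).
#'
#' @param counts Integer vector of monthly counts, months assumed
#'   consecutive from 1.
#' @param max_order Highest lag order to build (1, 2 or 3).
#' @param drop_initial If `TRUE`, the returned `use` column flags the first
#'   `max_order` months as excluded.
#' @return A data.frame with columns `pdv`, `ppdv`, `pppdv`, `pmak1_ind`,
#'   `use`, one row per month.
#' @examples
#' build_lags(c(0, 2, 5, 0))$pdv   # 0 0 2 5
#' @export
build_lags <- function(counts, max_order = 3L, drop_initial = FALSE) {
  if (!max_order %in% 1:3) stop("max_order must be 1, 2 or 3", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  T <- length(counts)
  lag0 <- function(k) c(rep(0, min(k, T)), counts[seq_len(max(T - k, 0))])
  out <- data.frame(
    pdv = lag0(1),
    ppdv = if (max_order >= 2) lag0(2) else rep(0, T),
    pppdv = if (max_order >= 3) lag0(3) else rep(0, T)
  )
  out$pmak1_ind <- as.integer(out$pdv > 0)
  out$use <- TRUE
  if (drop_initial) out$use[seq_len(min(max_order, T))] <- FALSE
  out
}

#' Steroid-month flags, optionally carried to the following month
#'
#' The primary steroid model modifies the first-order Markov coefficient in
#' the month the dose is given (`carryover = FALSE`). The tested
#' next-month (delayed) effect instead uses the previous month's dose flag
#' (`carryover = TRUE`).
#'
#' @param steroid 0/1 vector of dose flags per month.
#' @param carryover Shift the effect to the month after administration?
#' @return 0/1 integer vector of effect-month flags.
#' @export
steroid_flags <- function(steroid, carryover = FALSE) {
  if (!all(steroid %in% c(0, 1)))
    stop("steroid flags must be 0 or 1", call. = FALSE)
  s <- as.integer(steroid)
  if (carryover) s <- c(0L, s[-length(s)])
  s
}
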