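## Clinical decision protocol over the corrected AHI estimate. The bands
## mirror the severity cutoffs: below 1 e/h OSA is ruled out (with PSG
## referral advised if symptoms persist), the uncertain 1-5 e/h band is
## referred to full polysomnography, 5 e/h and above warrants treatment, and
## 10 e/h and above additional post-treatment follow-up.

.SCREENING_ACTIONS <- c("rule_out", "refer_psg", "treat", "treat_and_follow_up")

#' Screening recommendation from a predicted AHI
#'
#' Partition of the non-negative AHI axis: \code{[0, 1)} rule out,
#' \code{[1, 5)} refer to PSG, \code{[5, 10)} treat, \code{[10, Inf)} treat
#' and follow up. Boundaries are left-closed, consistent with
#' \code{\link{classifySeverity}}. Rule-out decisions carry the caveat that
#' persisting symptoms warrant PSG referral (returned as an attribute
#' \code{"note"}, not modelled as a symptom input).
#'
#' @param ahiPred predicted AHI value(s), events/hour, >= 0
#' @return character vector of actions
#' @export
recommendScreening <- function(ahiPred) {
    if (any(ahiPred < 0)) stop("predicted AHI must be non-negative")
    out <- ifelse(ahiPred < 1, "rule_out",
           ifelse(ahiPred < 5, "refer_psg",
           ifelse(ahiPred < 10, "treat", "treat_and_follow_up")))
    attr(out, "note") <-
        "rule_out: if symptoms persist, referral to PSG is recommended"
    out
}

#' Reduction in full polysomnography referrals
#'
#' Percentage of the cohort whose screening action is anything other than a
#' PSG referral, i.e. the fraction of full PSGs the protocol avoids.
#'
#' @param actions character vector of screening actions
#' @return percentage in [0, 100]
#' @export
psgReduction <- function(actions) {
    if (!length(actions)) stop("empty decision list")
    bad <- setdiff(unique(actions), .SCREENING_ACTIONS)
    if (length(bad)) stop("unknown action(s): ", paste(bad, collapse = ", "))
    100 * sum(actions != "refer_psg") / length(actions)
}
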