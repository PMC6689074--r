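# Agreement among in silico predicted affinity, in vitro measured relative
# binding, and in vivo expression calls across construct variants.

#' Rank concordance between predicted and measured binding
#'
#' Kendall rank correlation (tau-b convention for ties, via
#' `stats::cor(method = "kendall")`) between in silico predicted affinities
#' and measured relative binding across construct variants for one factor.
#' Invariant under strictly monotone transforms of either variable and
#' antisymmetric under reversing one ranking. No significance testing is
#' attached.
#'
#' @param records Either a data.frame with columns `variant`, `factor`,
#'   `predicted`, `measured` (one row per variant x factor), or a numeric
#'   vector of predictions (then `measured` must be given).
#' @param factor Factor name to subset when `records` is a data.frame.
#' @param measured Numeric vector of measurements when `records` is a
#'   numeric vector.
#' @return Kendall tau in [-1, 1].
#' @export
#' @examples
#' rankConcordance(c(1, 2, 3, 4), measured = c(0.1, 0.2, 0.3, 0.4))  # 1
#' rankConcordance(c(1, 2, 3, 4), measured = c(4, 3, 2, 1))          # -1
rankConcordance <- function(records, factor = NULL, measured = NULL) {
  if (is.data.frame(records)) {
    need <- c("variant", "factor", "predicted", "measured")
    if (!all(need %in% names(records)))
      stop("analysis error: records need columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!is.null(factor)) records <- records[records$factor == factor, ]
    pred <- records$predicted
    meas <- records$measured
  } else {
    pred <- records
    meas <- measured
  }
  ok <- is.finite(pred) & is.finite(meas)
  pred <- pred[ok]; meas <- meas[ok]
  if (length(pred) < 2L)
    stop("analysis error: need at least two variants with both predicted ",
         "and measured values", call. = FALSE)
  cor(pred, meas, method = "kendall")
}

#' Agreement between predicted and observed expression calls
#'
#' Fraction of (variant, segment) cells whose predicted ternary call
#' (off / weak / strong) matches the observed call, with the full confusion
#' table attached. Formalizes the visual comparison of predicted and
#' embryonic expression across construct variants.
#'
#' @param observed,predicted data.frames with columns `variant`, `segment`,
#'   `call`; cells are matched on (variant, segment).
#' @return List with `agreement` (fraction in [0, 1]), `n` (cells
#'   compared) and `confusion` (observed x predicted table).
#' @export
expressionAgreement <- function(observed, predicted) {
  need <- c("variant", "segment", "call")
  if (!all(need %in% names(observed)) || !all(need %in% names(predicted)))
    stop("analysis error: inputs need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  m <- merge(observed, predicted, by = c("variant", "segment"),
             suffixes = c("_obs", "_pred"))
  if (nrow(m) == 0L)
    stop("analysis error: no (variant, segment) cells shared between ",
         "observed and predicted", call. = FALSE)
  lv <- c("off", "weak", "strong")
  obs <- factor(as.character(m$call_obs), levels = lv)
  pred <- factor(as.character(m$call_pred), levels = lv)
  list(agreement = mean(obs == pred), n = nrow(m),
       confusion = table(observed = obs, predicted = pred))
}
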