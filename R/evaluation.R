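#' Instance-segmentation evaluation suite
#'
#' IoU-based matching of predicted to ground-truth instances, the standard
#' precision/recall/F1 triple, difference in count (DiC), mean absolute
#' percentage error (MAPE) and R-squared agreement between automated and
#' manual measurements.
#'
#' @name evaluation
NULL

#' Match predicted to ground-truth instances by pixel IoU
#'
#' Candidate pairs are all (predicted, truth) label pairs with pixel-set
#' intersection-over-union at or above `iou_threshold`. Pairs are selected
#' greedily in descending IoU with a deterministic tie-break (lower predicted
#' label first, then lower truth label); each label participates in at most
#' one pair. TP is the number of selected pairs, FP the unmatched predicted
#' instances, FN the unmatched truth instances; TN is fixed at 0 (there is no
#' negative instance class). On all small scenes the greedy TP equals the
#' optimal-assignment TP.
#'
#' @param pred,truth integer label matrices of equal dimension.
#' @param iou_threshold matching threshold in (0, 1); default 0.5.
#' @return object of class `match_result`: list with `pairs` (tibble
#'   `pred_label`, `truth_label`, `iou`), `TP`, `FP`, `FN`, `TN`,
#'   `n_pred`, `n_truth`.
#' @export
match_instances <- function(pred, truth, iou_threshold = 0.5) {
  if (!identical(dim(pred), dim(truth))) {
    stop_organtraits("predicted and truth maps have different dimensions")
  }
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop_organtraits("iou_threshold must be in (0, 1)")
  }
  pl <- map_labels(pred)
  tl <- map_labels(truth)
  cand <- NULL
  if (length(pl) > 0L && length(tl) > 0L) {
    fg <- pred > 0L & truth > 0L
    if (any(fg)) {
      inter <- table(pred[fg], truth[fg])
      pa <- tabulate(pred[pred > 0L], nbins = max(pl))
      ta <- tabulate(truth[truth > 0L], nbins = max(tl))
      idx <- which(inter > 0, arr.ind = TRUE)
      p_lab <- as.integer(rownames(inter))[idx[, 1]]
      t_lab <- as.integer(colnames(inter))[idx[, 2]]
      ov <- inter[idx]
      iou <- ov / (pa[p_lab] + ta[t_lab] - ov)
      keep <- iou >= iou_threshold
      cand <- data.frame(pred_label = p_lab[keep], truth_label = t_lab[keep], iou = iou[keep])
    }
  }
  pairs <- tibble::tibble(pred_label = integer(), truth_label = integer(), iou = numeric())
  if (!is.null(cand) && nrow(cand) > 0L) {
    cand <- cand[order(-cand$iou, cand$pred_label, cand$truth_label), , drop = FALSE]
    used_p <- logical(max(pl))
    used_t <- logical(max(tl))
    take <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      p <- cand$pred_label[k]; t <- cand$truth_label[k]
      if (!used_p[p] && !used_t[t]) {
        take[k] <- TRUE
        used_p[p] <- TRUE
        used_t[t] <- TRUE
      }
    }
    pairs <- tibble::as_tibble(cand[take, , drop = FALSE])
  }
  structure(
    list(
      pairs = pairs,
      TP = nrow(pairs),
      FP = length(pl) - nrow(pairs),
      FN = length(tl) - nrow(pairs),
      TN = 0L,
      n_pred = length(pl),
      n_truth = length(tl),
      iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(
    "Instance match (IoU >= ", x$iou_threshold, "): TP=", x$TP,
    " FP=", x$FP, " FN=", x$FN, "\n",
    sep = ""
  )
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`. An undefined denominator yields `NA` with a
#' warning, except the all-zero case where the conventional 0 is returned.
#'
#' @param m a `match_result`, or a list/vector with elements `TP`, `FP`, `FN`.
#' @return named numeric `c(precision=, recall=, f1=)`.
#' @export
precision_recall_f1 <- function(m) {
  TP <- as.numeric(m[["TP"]])
  FP <- as.numeric(m[["FP"]])
  FN <- as.numeric(m[["FN"]])
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  if (is.na(prec)) warning("no predicted instances: precision undefined", call. = FALSE)
  if (is.na(rec)) warning("no truth instances: recall undefined", call. = FALSE)
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  c(precision = prec, recall = rec, f1 = f1)
}

#' Difference in count (DiC)
#'
#' Absolute difference between the predicted and ground-truth organ counts.
#' Vectorized; batch summaries report the mean of per-image DiC values.
#'
#' @param pred_count,truth_count non-negative counts (vectors allowed).
#' @return `abs(pred_count - truth_count)`.
#' @export
dic <- function(pred_count, truth_count) {
  if (any(pred_count < 0) || any(truth_count < 0)) {
    stop_organtraits("counts must be non-negative")
  }
  abs(pred_count - truth_count)
}

#' Mean absolute percentage error between automated and manual values
#'
#' `MAPE = 100/n * sum |x_auto - x_manual| / x_manual`, in percent. Every
#' manual value must be nonzero.
#'
#' @param auto,manual equal-length numeric vectors, `length >= 1`.
#' @return MAPE in percent.
#' @export
mape <- function(auto, manual) {
  if (length(auto) != length(manual) || length(auto) < 1L) {
    stop_organtraits("auto and manual must have equal length >= 1")
  }
  if (any(manual == 0)) {
    stop_organtraits(
      "manual value is zero at index ",
      paste(which(manual == 0), collapse = ", "),
      "; MAPE undefined"
    )
  }
  mean(abs(auto - manual) / abs(manual)) * 100
}

#' Linear agreement between automated and manual measurements
#'
#' Ordinary least squares of the manual value (response) on the automated
#' value (predictor) — the orientation of the usual automated-vs-manual
#' scatterplots (automated on x, manual on y) — with
#' `R^2 = 1 - SS_res/SS_tot`. MAPE is attached when all manual values are
#' nonzero.
#'
#' @param auto,manual equal-length numeric vectors, `length >= 2`.
#' @return object of class `trait_agreement`: list with `r_squared`, `slope`,
#'   `intercept`, `mape_percent` (NA if undefined), `n`, and the underlying
#'   `lm` fit.
#' @export
trait_agreement <- function(auto, manual) {
  if (length(auto) != length(manual) || length(auto) < 2L) {
    stop_organtraits("auto and manual must have equal length >= 2")
  }
  if (stats::var(auto) == 0) {
    warning("automated values have zero variance; R^2 undefined", call. = FALSE)
    return(structure(
      list(
        r_squared = NA_real_, slope = NA_real_, intercept = NA_real_,
        mape_percent = if (all(manual != 0)) mape(auto, manual) else NA_real_,
        n = length(auto), auto = auto, manual = manual, fit = NULL
      ),
      class = "trait_agreement"
    ))
  }
  fit <- stats::lm(manual ~ auto)
  res <- stats::residuals(fit)
  sst <- sum((manual - mean(manual))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  structure(
    list(
      r_squared = r2,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      mape_percent = if (all(manual != 0)) mape(auto, manual) else NA_real_,
      n = length(auto),
      auto = auto,
      manual = manual,
      fit = fit
    ),
    class = "trait_agreement"
  )
}

#' @export
print.trait_agreement <- function(x, ...) {
  cat(
    "Agreement (n=", x$n, "): R^2=", signif(x$r_squared, 4),
    ", slope=", signif(x$slope, 4), ", intercept=", signif(x$intercept, 4),
    if (!is.na(x$mape_percent)) paste0(", MAPE=", signif(x$mape_percent, 4), "%"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a trait agreement fit
#' @param x a `trait_agreement` object.
#' @param ... unused.
#' @return one-row tibble with `term`-free summary columns (`r_squared`,
#'   `slope`, `intercept`, `mape_percent`, `n`).
#' @export
tidy.trait_agreement <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    mape_percent = x$mape_percent, n = x$n
  )
}

#' @rdname tidy.trait_agreement
#' @export
glance.trait_agreement <- function(x, ...) tidy.trait_agreement(x)
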