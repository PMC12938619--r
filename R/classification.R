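## Stratification of samples by mean H3/H5, with an explicit indeterminate
## band between the empirical benign and malignant ranges.

#' Classification thresholds
#'
#' Empirical bands: benign samples cluster below about 2.0 (the highest
#' benign reference value is 2.002) and malignant samples above 2.2, with
#' tumor-adjacent tissue transitional at 2.166. The default benign ceiling is
#' set at 2.1 — above the highest benign observation and below the
#' transitional value — and the malignant floor at 2.2. These are empirical
#' observations from a small pilot cohort, not validated diagnostic cut-offs;
#' [stratification_report()] documents the label sensitivity to both values.
#'
#' @param benign_max Upper edge of the benign band (exclusive). Default 2.1.
#' @param malignant_min Lower edge of the malignant band (exclusive).
#'   Default 2.2.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(benign_max = 2.1, malignant_min = 2.2) {
  stopifnot(is.numeric(benign_max), length(benign_max) == 1L,
            is.numeric(malignant_min), length(malignant_min) == 1L)
  if (!(benign_max > 0 && benign_max <= malignant_min)) {
    stop("need 0 < benign_max <= malignant_min", call. = FALSE)
  }
  structure(list(benign_max = benign_max, malignant_min = malignant_min),
            class = "threshold_config")
}

#' Classify a mean harmonic ratio
#'
#' `benign` when R < `benign_max`, `malignant` when R > `malignant_min`,
#' `indeterminate` otherwise. Values exactly on a threshold are
#' indeterminate — the conservative call for a diagnostic. Raising R never
#' moves a label from malignant toward benign.
#'
#' @param mean_ratio Positive ratio value(s).
#' @param thresholds [threshold_config()].
#' @return Character vector in {"benign", "indeterminate", "malignant"}.
#' @export
classify_ratio <- function(mean_ratio, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  if (!is.numeric(mean_ratio) || anyNA(mean_ratio) || any(mean_ratio <= 0)) {
    stop("`mean_ratio` must be positive numeric", call. = FALSE)
  }
  ifelse(mean_ratio < thresholds$benign_max, "benign",
         ifelse(mean_ratio > thresholds$malignant_min, "malignant",
                "indeterminate"))
}

#' Percent increase of a ratio over a baseline
#'
#' @param r Ratio value.
#' @param baseline Positive baseline ratio.
#' @return List with `percent` (`100 * (r - baseline) / baseline`) and
#'   `rounded` (nearest integer percent).
#' @examples
#' percent_increase(2.744, 1.898)$rounded # 45
#' @export
percent_increase <- function(r, baseline) {
  stopifnot(is.numeric(r), is.numeric(baseline))
  if (any(baseline <= 0)) stop("`baseline` must be > 0", call. = FALSE)
  p <- 100 * (r - baseline) / baseline
  list(percent = p, rounded = round(p))
}

#' Difference between two ratios
#'
#' @param a,b Ratio values.
#' @return `a - b` (antisymmetric).
#' @export
ratio_differential <- function(a, b) a - b

#' Strict monotone-gradient check
#'
#' Tests whether an ordered sequence of ratios (e.g. normal -> adjacent ->
#' tumor core) is strictly increasing.
#'
#' @param ordered_ratios Numeric vector, length >= 2.
#' @return `TRUE` iff each element strictly exceeds its predecessor.
#' @export
gradient_check <- function(ordered_ratios) {
  if (!is.numeric(ordered_ratios) || length(ordered_ratios) < 2L) {
    stop("`ordered_ratios` must be numeric with length >= 2", call. = FALSE)
  }
  all(diff(ordered_ratios) > 0)
}

#' Stratification report
#'
#' Per-group summary, labels under the configured bands, a benign-versus-
#' malignant separation summary, threshold sensitivity (the range of each
#' threshold over which the assigned labels are unchanged), and — when a
#' ground-truth table is supplied — per-sample target-ratio recovery error
#' and label agreement.
#'
#' @param results A `ratio_results` object from [analyze_traces()], or its
#'   `samples` data frame.
#' @param truth Optional ground-truth data frame with columns `sample_id`,
#'   `group`, `target_ratio` (as produced by [generate_tissue_panel()]).
#' @param thresholds [threshold_config()].
#' @return Object of class `stratification_report`: list with `samples`,
#'   `groups`, `separation`, `threshold_sensitivity` and (optionally)
#'   `agreement`.
#' @export
stratification_report <- function(results, truth = NULL,
                                  thresholds = threshold_config()) {
  samples <- if (inherits(results, "ratio_results")) results$samples else
    as.data.frame(results)
  if (nrow(samples) == 0L) stop("`results` is empty", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample ids in results", call. = FALSE)
  }
  if (!is.null(truth) && nrow(as.data.frame(truth)) == 0L) truth <- NULL
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    samples <- merge(samples, truth[, intersect(names(truth),
                                                c("sample_id", "group", "target_ratio"))],
                     by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  if (is.null(samples$group)) samples$group <- samples$sample_id
  samples$label <- classify_ratio(samples$mean_ratio, thresholds)

  groups <- do.call(rbind, lapply(split(samples, samples$group), function(gg) {
    data.frame(group = gg$group[1L], n_samples = nrow(gg),
               mean_ratio = mean(gg$mean_ratio),
               std_ratio = mean(gg$std_ratio),
               label = classify_ratio(mean(gg$mean_ratio), thresholds))
  }))
  groups <- groups[order(groups$mean_ratio), ]
  rownames(groups) <- NULL

  benign <- samples$mean_ratio[samples$label == "benign"]
  malignant <- samples$mean_ratio[samples$label == "malignant"]
  separation <- list(
    max_benign = if (length(benign)) max(benign) else NA_real_,
    min_malignant = if (length(malignant)) min(malignant) else NA_real_,
    gap = if (length(benign) && length(malignant))
      min(malignant) - max(benign) else NA_real_)

  ## label-preserving threshold ranges given the observed means
  not_benign <- samples$mean_ratio[samples$label != "benign"]
  not_malig <- samples$mean_ratio[samples$label != "malignant"]
  sens <- list(
    benign_max_range = c(if (length(benign)) max(benign) else 0,
                         if (length(not_benign)) min(not_benign) else Inf),
    malignant_min_range = c(if (length(not_malig)) max(not_malig) else 0,
                            if (length(malignant)) min(malignant) else Inf))

  out <- list(samples = samples, groups = groups, separation = separation,
              threshold_sensitivity = sens, thresholds = thresholds)
  if (!is.null(truth) && !is.null(samples$target_ratio)) {
    agr <- samples[!is.na(samples$target_ratio), ]
    agr$recovery_error <- (agr$mean_ratio - agr$target_ratio) / agr$target_ratio
    agr$target_label <- classify_ratio(agr$target_ratio, thresholds)
    agr$label_agrees <- agr$label == agr$target_label
    out$agreement <- agr[, c("sample_id", "group", "target_ratio", "mean_ratio",
                             "recovery_error", "target_label", "label",
                             "label_agrees")]
  }
  structure(out, class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("Stratification by mean H3/H5 ratio\n")
  cat(sprintf("  bands: benign < %g, malignant > %g (boundary values indeterminate)\n",
              x$thresholds$benign_max, x$thresholds$malignant_min))
  print(x$groups, digits = 4)
  if (!is.na(x$separation$gap)) {
    cat(sprintf("  benign/malignant separation: max benign %.3f, min malignant %.3f (gap %.3f)\n",
                x$separation$max_benign, x$separation$min_malignant,
                x$separation$gap))
  }
  s <- x$threshold_sensitivity
  cat(sprintf("  labels unchanged for benign_max in (%.3f, %.3f], malignant_min in [%.3f, %.3f)\n",
              s$benign_max_range[1], s$benign_max_range[2],
              s$malignant_min_range[1], s$malignant_min_range[2]))
  if (!is.null(x$agreement)) {
    cat(sprintf("  ground truth: %d/%d labels agree, max |recovery error| %.2e\n",
                sum(x$agreement$label_agrees), nrow(x$agreement),
                max(abs(x$agreement$recovery_error))))
  }
  invisible(x)
}
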