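## Predictor benchmarking: binarization at published thresholds, confusion
## counts, sensitivity/specificity/MCC/ACC, ROC curves, AUC and
## Youden-optimal thresholds.

#' Read a predictor tool configuration
#'
#' The YAML lists one entry per tool with fields `direction`
#' (`damaging_if_greater` or `damaging_if_less`), `threshold` (numeric, for
#' score-valued tools) and optionally `categorical_map` (named map from
#' reported category labels to `Damaging`/`Tolerated`, for tools that also
#' report classes). The configuration shipped with the package
#' (`system.file("extdata", "tool_config.yaml", package = "vustriage")`)
#' covers 22 widely used predictors at their published deleterious
#' thresholds.
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return Named list of tool configs.
#' @export
read_tool_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tool_config.yaml", package = "vustriage")
  }
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    cfg[[nm]]$name <- nm
    dir <- cfg[[nm]]$direction
    if (!dir %in% c("damaging_if_greater", "damaging_if_less")) {
      stop("tool ", nm, ": unknown direction '", dir, "'")
    }
    if (is.null(cfg[[nm]]$threshold) && is.null(cfg[[nm]]$categorical_map)) {
      stop("tool ", nm, ": needs a threshold or a categorical_map")
    }
  }
  cfg
}

#' Binarize predictor output
#'
#' Numeric scores are compared strictly against the tool threshold
#' (`Damaging` iff `score > threshold` for `damaging_if_greater`, iff
#' `score < threshold` for `damaging_if_less`). Character labels are
#' resolved through the tool's `categorical_map`; merged classes (e.g.
#' "probably damaging" and "possibly damaging" both mapping to `Damaging`,
#' or assessor categories H/M vs L/N) are expressed in that map. Absent
#' values yield `Missing`.
#'
#' @param x Numeric scores or character labels.
#' @param config One tool's config entry (see [read_tool_config()]).
#' @return Character vector in `{"Damaging", "Tolerated", "Missing"}`.
#' @export
binarize <- function(x, config) {
  out <- rep("Missing", length(x))
  if (is.numeric(x)) {
    if (is.null(config$threshold)) stop("tool ", config$name, ": numeric scores but no threshold")
    ok <- !is.na(x)
    dam <- if (config$direction == "damaging_if_greater") x > config$threshold else x < config$threshold
    out[ok] <- ifelse(dam[ok], "Damaging", "Tolerated")
  } else {
    lab <- as.character(x)
    ok <- !is.na(lab) & nzchar(lab)
    map <- config$categorical_map
    if (is.null(map)) stop("tool ", config$name, ": categorical labels but no categorical_map")
    hit <- match(lab[ok], names(map))
    if (anyNA(hit)) {
      stop("tool ", config$name, ": label(s) not in categorical_map: ",
           paste(unique(lab[ok][is.na(hit)]), collapse = ", "))
    }
    out[ok] <- unlist(map)[hit]
  }
  out
}

#' Confusion counts against LPP/BENIGN truth
#'
#' TP counts disease-causing (LPP) variants predicted `Damaging`, FN those
#' predicted `Tolerated`; TN counts benign variants predicted `Tolerated`,
#' FP those predicted `Damaging`. `Missing` predictions are dropped from
#' the counts and reported separately.
#'
#' @param truth Character vector in `{"LPP", "BENIGN"}`.
#' @param prediction Character vector in `{"Damaging", "Tolerated", "Missing"}`.
#' @return List with `TP`, `FP`, `TN`, `FN`, `n_dropped`.
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  if (!all(truth %in% c("LPP", "BENIGN"))) {
    stop("truth labels must be 'LPP' or 'BENIGN'")
  }
  keep <- prediction != "Missing"
  if (!any(keep)) stop("no scored variants overlap the labelled set")
  t <- truth[keep]; p <- prediction[keep]
  list(TP = sum(t == "LPP" & p == "Damaging"),
       FN = sum(t == "LPP" & p == "Tolerated"),
       TN = sum(t == "BENIGN" & p == "Tolerated"),
       FP = sum(t == "BENIGN" & p == "Damaging"),
       n_dropped = sum(!keep))
}

#' Binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, Matthews
#' correlation coefficient and accuracy `(TP+TN)/(TP+FP+TN+FN)`. An MCC
#' denominator of zero returns 0 by the standard convention.
#'
#' @param counts A list with `TP`, `FP`, `TN`, `FN` (see [confusion_counts()]).
#' @return Named list `sensitivity`, `specificity`, `mcc`, `acc`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  acc <- (TP + TN) / (TP + FP + TN + FN)
  list(sensitivity = sens, specificity = spec, mcc = mcc, acc = acc)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score cut point (midpoints between consecutive
#' distinct scores, plus sentinels below and above the observed range) and
#' records sensitivity against 1 - specificity; the curve therefore always
#' contains the (0,0) and (1,1) endpoints. The AUC equals the
#' Mann-Whitney concordance probability: the probability that a random
#' positive outscores a random negative, with ties counted half.
#'
#' @param scores Numeric scores (`NA` dropped).
#' @param labels Parallel truth labels in `{"LPP", "BENIGN"}`.
#' @param direction Score orientation (see [read_tool_config()]).
#' @return List with `curve` (data.frame `threshold`, `fpr`, `sensitivity`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels, direction = "damaging_if_greater") {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == "LPP"; neg <- labels == "BENIGN"
  if (!any(pos) || !any(neg)) stop("both classes must be present among scored variants")
  s <- if (direction == "damaging_if_less") -scores else scores

  r <- rank(s, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(neg)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  u <- sort(unique(s))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(t) sum(s[pos] > t) / n_pos, 0)
  fpr <- vapply(cand, function(t) sum(s[neg] > t) / n_neg, 0)
  thr <- if (direction == "damaging_if_less") -cand else cand
  curve <- data.frame(threshold = thr, fpr = fpr, sensitivity = sens)
  curve <- curve[order(curve$fpr, curve$sensitivity), ]
  rownames(curve) <- NULL
  list(curve = curve, auc = auc, direction = direction)
}

#' Youden-optimal deleterious threshold
#'
#' Returns the cut point maximizing Youden's J (sensitivity + specificity
#' - 1) on a ROC object from [roc_curve()]; ties are broken toward higher
#' specificity.
#'
#' @param roc Result of [roc_curve()].
#' @return Numeric threshold on the tool's original score scale.
#' @export
optimal_threshold <- function(roc) {
  cv <- roc$curve
  if (nrow(cv) == 0L) stop("empty ROC curve")
  j <- cv$sensitivity - cv$fpr
  best <- which(j == max(j))
  best <- best[which.min(cv$fpr[best])]
  cv$threshold[best]
}

#' Coverage filter over a score table
#'
#' Retains tools whose fraction of scored (non-missing) variants strictly
#' exceeds `min_fraction` (default 0.30).
#'
#' @param scores Score table: data.frame with a `variant_id` column and one
#'   column per tool.
#' @param min_fraction Coverage threshold in (0, 1].
#' @return Character vector of retained tool names.
#' @export
coverage_filter <- function(scores, min_fraction = 0.30) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  tools <- setdiff(names(scores), "variant_id")
  frac <- vapply(tools, function(t) mean(!is.na(scores[[t]])), 0)
  tools[frac > min_fraction]
}

#' Variant identifier used to join catalogs and score tables
#' @param catalog A `variant_catalog` (or data.frame with `gene`, `label`).
#' @return Character vector `"<gene>:<label>"`.
#' @export
variant_id <- function(catalog) paste0(catalog$gene, ":", catalog$label)

#' Benchmark predictors on the labelled catalog
#'
#' Restricts the catalog to its LPP and BENIGN records (the benchmark set;
#' VUS and conflicting-interpretation records never enter benchmarking),
#' applies the coverage filter, binarizes each retained tool at its
#' configured threshold, and reports confusion-derived metrics, AUC and the
#' Youden-optimal threshold per tool.
#'
#' @param catalog A `variant_catalog`.
#' @param scores Score table (`variant_id` column + one column per tool).
#' @param config Tool configuration from [read_tool_config()].
#' @param min_coverage Coverage filter threshold (default 0.30).
#' @return A `predictor_benchmark` data.frame sorted by decreasing AUC,
#'   with columns `tool`, `threshold`, `sensitivity`, `specificity`, `mcc`,
#'   `acc`, `auc`, `youden_threshold`, `coverage`, `n_used`, `n_missing`.
#' @export
benchmark_predictors <- function(catalog, scores, config = read_tool_config(),
                                 min_coverage = 0.30) {
  bench <- catalog[catalog$class %in% c("LPP", "BENIGN"), , drop = FALSE]
  if (nrow(bench) == 0L) stop("catalog has no LPP/BENIGN records to benchmark on")
  idx <- match(variant_id(bench), scores$variant_id)
  sub <- scores[idx, , drop = FALSE]
  keep_tools <- intersect(coverage_filter(sub, min_coverage), names(config))

  rows <- lapply(keep_tools, function(tl) {
    x <- sub[[tl]]
    pred <- binarize(x, config[[tl]])
    cc <- confusion_counts(bench$class, pred)
    m <- classification_metrics(cc)
    auc <- you <- NA_real_
    if (is.numeric(x) && length(unique(bench$class[!is.na(x)])) == 2L) {
      roc <- roc_curve(x, bench$class, config[[tl]]$direction)
      auc <- roc$auc
      you <- optimal_threshold(roc)
    }
    data.frame(tool = tl,
               threshold = if (is.null(config[[tl]]$threshold)) NA_real_ else config[[tl]]$threshold,
               sensitivity = m$sensitivity, specificity = m$specificity,
               mcc = m$mcc, acc = m$acc, auc = auc, youden_threshold = you,
               coverage = mean(!is.na(x)),
               n_used = cc$TP + cc$FP + cc$TN + cc$FN, n_missing = cc$n_dropped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$tool), ]
  rownames(out) <- NULL
  class(out) <- c("predictor_benchmark", "data.frame")
  attr(out, "catalog_hash") <- attr(catalog, "catalog_hash")
  out
}

#' @export
print.predictor_benchmark <- function(x, digits = 3, ...) {
  cat("Predictor benchmark on", x$n_used[1L] + x$n_missing[1L],
      "labelled variants,", nrow(x), "tools retained\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df)
  invisible(x)
}
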