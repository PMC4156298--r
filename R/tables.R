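# Relative-activity and purification accounting.

#' Relative activity as percent of a reference condition
#'
#' Converts raw activities to percent of a designated reference (the
#' untreated control defined as 100 percent).  `NA` activities
#' (precipitated / not determinable entries, read as the literal `"ND"`)
#' propagate to `NA`.  With a grouping column (e.g. concentration) the
#' reference is taken within each group.
#'
#' @param table data.frame with columns `label` and `activity` (numeric,
#'   `NA` allowed), plus optionally the column named by `by`.
#' @param reference label of the reference condition (default
#'   `"Control"`).
#' @param by optional name of a grouping column; the reference activity
#'   is looked up per group.
#' @return the input with a `relative` column (percent); the reference
#'   rows are exactly 100.
#' @examples
#' tab <- data.frame(label = c("Control", "IAA"),
#'                   activity = c(4.28, 4.28 * 0.123))
#' relativeActivity(tab)
#' @export
relativeActivity <- function(table, reference = "Control", by = NULL) {
  stopifnot(all(c("label", "activity") %in% names(table)))
  groups <- if (is.null(by)) rep(1L, nrow(table)) else table[[by]]
  rel <- rep(NA_real_, nrow(table))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    refIdx <- idx[table$label[idx] == reference]
    if (!length(refIdx))
      stop("reference '", reference, "' missing",
           if (!is.null(by)) paste0(" in group ", g) else "")
    refVal <- table$activity[refIdx[1L]]
    if (is.na(refVal) || refVal <= 0)
      stop("reference activity must be positive")
    rel[idx] <- 100 * table$activity[idx] / refVal
  }
  table$relative <- rel
  table
}

#' Read an activity table with ND entries
#'
#' Delimited text with header columns `label`, `concentration_mM`,
#' `activity`; the literal `ND` (not determinable, e.g. ion-precipitated
#' enzyme) becomes `NA`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame with numeric `activity`.
#' @export
readActivityTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "ND")
  need <- c("label", "concentration_mM", "activity")
  if (!all(need %in% names(df)))
    stop("activity table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df$activity <- as.numeric(df$activity)
  df
}

#' Purification summary: specific activity, yield and fold
#'
#' From step-wise totals, derives per step: specific activity =
#' total activity / total protein (U/mg), yield = 100 x total activity /
#' total activity of the yield reference step, and fold purification =
#' specific activity / the fold reference.  Steps without a measured
#' activity (`NA`) keep `NA` derived values.
#'
#' Both references are designated explicitly because conventions differ:
#' yield is usually anchored at the first step with a measured activity,
#' while the fold baseline may be a specific activity that was never
#' tabulated directly (e.g. a crude-extract value known only through the
#' printed, rounded specific activity of a later step).  `foldRef` may
#' therefore be a step label or a numeric specific activity in U/mg.
#'
#' @param steps data.frame with columns `label`, `total_protein` (mg) and
#'   `total_activity` (U, `NA` allowed).
#' @param yieldRef label of the step defining 100 percent yield (default:
#'   first step with measured activity).
#' @param foldRef step label, or a numeric specific activity (U/mg),
#'   defining fold = 1 (default: same step as `yieldRef`).
#' @return data.frame with added `specific_activity`, `yield_pct`,
#'   `fold` columns.
#' @examples
#' steps <- data.frame(
#'   label = c("Heat incubation", "Sephacryl S-200"),
#'   total_protein = c(672.5, 50.2),
#'   total_activity = c(1670.4, 997.474))
#' purificationSummary(steps)
#' @export
purificationSummary <- function(steps, yieldRef = NULL, foldRef = NULL) {
  need <- c("label", "total_protein", "total_activity")
  if (!all(need %in% names(steps)))
    stop("steps must have columns: ", paste(need, collapse = ", "))
  if (any(!is.na(steps$total_protein) & steps$total_protein <= 0))
    stop("total protein must be positive")
  steps$specific_activity <- steps$total_activity / steps$total_protein

  measured <- which(!is.na(steps$total_activity))
  if (!length(measured)) stop("no step has a measured activity")
  yieldRef <- yieldRef %||% steps$label[measured[1L]]
  yi <- match(yieldRef, steps$label)
  if (is.na(yi) || is.na(steps$total_activity[yi]))
    stop("yield reference step '", yieldRef, "' has no measured activity")
  steps$yield_pct <- 100 * steps$total_activity /
    steps$total_activity[yi]

  if (is.null(foldRef)) foldRef <- yieldRef
  if (is.numeric(foldRef)) {
    baseline <- foldRef
  } else {
    fi <- match(foldRef, steps$label)
    if (is.na(fi) || is.na(steps$specific_activity[fi]))
      stop("fold reference step '", foldRef,
           "' has no measurable specific activity")
    baseline <- steps$specific_activity[fi]
  }
  if (!is.finite(baseline) || baseline <= 0)
    stop("fold baseline specific activity must be positive")
  steps$fold <- steps$specific_activity / baseline
  steps
}
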