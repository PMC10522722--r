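#' Two-class confusion matrix (rows = identified, columns = surveyed)
#'
#' Counts follow the identified-by-surveyed convention used throughout crop
#' mapping validation: `tp` identified maize that surveys confirm as maize,
#' `fp` identified maize that surveys call other, `fn` surveyed maize
#' identified as other, `tn` other/other.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return An object of class `maize_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers.")
  }
  structure(as.list(counts), n_excluded = 0L, class = "maize_confusion")
}

#' @export
print.maize_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(identified = c("maize", "other"),
                              surveyed = c("maize", "other")))
  print(m)
  invisible(x)
}

#' @export
as_tibble.maize_confusion <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
         n_excluded = attr(x, "n_excluded") %||% 0L)
}

#' Confusion matrix of a map against surveyed samples
#'
#' Samples are resolved to grid cells; samples landing on nodata (`NA`)
#' cells are excluded from the counts and reported in the `n_excluded`
#' attribute.
#'
#' @param map a [maize_map()].
#' @param samples samples tibble (surveyed labels `maize`/`other`).
#' @return A [confusion_matrix()] with an `n_excluded` attribute.
#' @export
confusion_from_samples <- function(map, samples) {
  stopifnot(inherits(map, "maize_map"))
  s <- resolve_cells(samples, map$geotransform,
                     nrow(map$values), ncol(map$values))
  if (!nrow(s)) abort("no samples resolve onto the map's grid.")
  pred <- map$values[cbind(s$row, s$col)]
  keep <- !is.na(pred)
  pred <- pred[keep]
  truth <- s$label[keep] == "maize"
  cm <- confusion_matrix(
    tp = sum(pred == 1L & truth), fp = sum(pred == 1L & !truth),
    fn = sum(pred == 0L & truth), tn = sum(pred == 0L & !truth))
  attr(cm, "n_excluded") <- sum(!keep)
  cm
}

#' Accuracy metrics from a confusion matrix
#'
#' Computes the three percentages as printed in the validation tables this
#' package reproduces: `pa = tp / (tp + fp) * 100`, `ua = tp / (tp + fn) *
#' 100`, `oa = (tp + tn) / total * 100`. Note that under the
#' rows=identified / columns=surveyed convention these `pa`/`ua` labels are
#' swapped relative to the conventional producer's/user's accuracy; the
#' conventionally named `precision` (`tp/(tp+fp)`) and `recall`
#' (`tp/(tp+fn)`) columns are therefore provided alongside, as are the
#' other-class accuracies (`ua_other`, `pa_other`). A zero denominator
#' yields `NA`, never 0.
#'
#' @param cm a [confusion_matrix()].
#' @return A one-row tibble with columns `pa`, `ua`, `oa`, `ua_other`,
#'   `pa_other`, `precision`, `recall` (all percentages, full precision).
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "maize_confusion"))
  pct <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  tibble(
    pa = pct(cm$tp, cm$tp + cm$fp),
    ua = pct(cm$tp, cm$tp + cm$fn),
    oa = pct(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn),
    ua_other = pct(cm$tn, cm$tn + cm$fp),
    pa_other = pct(cm$tn, cm$tn + cm$fn),
    precision = pct(cm$tp, cm$tp + cm$fp),
    recall = pct(cm$tp, cm$tp + cm$fn))
}

#' Aggregate per-region overall accuracies
#'
#' The multi-region summary accuracy is the unweighted arithmetic mean of
#' the per-region OA values.
#'
#' @param oa numeric vector of per-region OA percentages.
#' @return Mean OA (percent).
#' @export
aggregate_overall <- function(oa) {
  if (!length(oa)) abort("need at least one OA value.")
  mean(oa)
}

#' County-level agreement between identified and statistical areas
#'
#' Agreement-form coefficient of determination
#' `R^2 = 1 - sum((IA - SA)^2) / sum((mean(SA) - SA)^2)` (computable below
#' zero), relative mean absolute error `RMAE = sum(|SA - IA|) / sum(SA)`,
#' and the ordinary least-squares slope of identified on statistical area.
#'
#' @param records either a tibble with columns `statistical_area_ha` and
#'   `identified_area_ha` (as emitted by [area_constrained_select()]), or a
#'   numeric vector of statistical areas when `identified` is given.
#' @param identified optional numeric vector of identified areas.
#' @return An object of class `county_agreement` (also a one-row tibble)
#'   with `r_squared`, `rmae`, `slope`, `n`.
#' @export
county_agreement <- function(records, identified = NULL) {
  if (is.data.frame(records)) {
    sa <- records$statistical_area_ha
    ia <- records$identified_area_ha
  } else {
    sa <- records
    ia <- identified
  }
  if (length(sa) < 2) abort("need at least two regions.")
  if (length(sa) != length(ia)) abort("area vectors differ in length.")
  if (sum(sa) <= 0) abort("total statistical area must be positive.")
  ss_tot <- sum((mean(sa) - sa)^2)
  r2 <- if (ss_tot > 0) 1 - sum((ia - sa)^2) / ss_tot else {
    warn("statistical areas have zero variance; R^2 is undefined.")
    NA_real_
  }
  slope <- unname(coef(lm(ia ~ sa))[2])
  out <- tibble(r_squared = r2,
                rmae = sum(abs(sa - ia)) / sum(sa),
                slope = slope, n = length(sa))
  class(out) <- c("county_agreement", class(out))
  out
}

#' @describeIn county_agreement one row per metric (name, value).
#' @param x a `county_agreement`.
#' @param ... unused.
#' @export
tidy.county_agreement <- function(x, ...) {
  tibble(metric = c("r_squared", "rmae", "slope"),
         value = c(x$r_squared, x$rmae, x$slope))
}

#' @describeIn county_agreement the one-row summary itself.
#' @export
glance.county_agreement <- function(x, ...) {
  tibble(r_squared = x$r_squared, rmae = x$rmae, slope = x$slope, n = x$n)
}

#' Bundled provincial confusion counts
#'
#' Confusion-matrix counts from a published national maize-mapping
#' validation campaign: 22 provinces validated against field-survey and
#' interpreted samples (`set` values `"north"` and `"south"`) plus 3
#' Northeast provinces re-validated against an independent external sample
#' set (`set = "independent"`). Used as a regression fixture for
#' [accuracy_metrics()] and as ready-made example data.
#'
#' @return A tibble with columns `province`, `set`, `tp`, `fp`, `fn`, `tn`.
#' @export
province_confusion <- function() {
  path <- system.file("extdata", "province_confusion.csv",
                      package = "phenomaize")
  readr::read_csv(path, show_col_types = FALSE)
}
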