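# Inter-rater reliability: two-way random-effects, absolute-agreement,
# single-measures intraclass correlation ("Model 2", ICC(2,1)).

#' Subjects-by-raters measurement table
#'
#' @param values numeric n x k matrix (n subjects, k raters), same units
#'   throughout, no missing cells.
#' @param measure_name label for reports.
#' @return An object of class `hab_rater_table`.
#' @export
rater_table <- function(values, measure_name = "measure") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 subjects and 2 raters")
  if (anyNA(values))
    stop("incomplete design: missing cells are not supported")
  structure(list(values = values, measure_name = measure_name),
            class = "hab_rater_table")
}

#' ICC(2,1): two-way random absolute-agreement single-measures ICC
#'
#' Decomposes the table by two-way random-effects ANOVA (rows = subjects,
#' columns = raters) and returns
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with the F-based 95% confidence interval for this model
#' (McGraw & Wong 1996, ICC(A,1)). Systematic offsets between raters count
#' against agreement. Negative estimates are reported as computed, not
#' floored at zero.
#'
#' @param table a [rater_table()] or plain n x k matrix.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `hab_icc`: `estimate`, `ci_low`, `ci_high`,
#'   mean squares `ms_rows`/`ms_cols`/`ms_error`, design sizes `n`/`k`, and
#'   the qualitative `band` (see [band_icc()]).
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  if (!inherits(table, "hab_rater_table")) table <- rater_table(table)
  x <- table$values
  n <- nrow(x); k <- ncol(x)
  if (max(x) - min(x) < 1e-12)
    stop("undefined ICC: the table is constant (zero total variance)")
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  ms_rows <- k * sum((rm - grand)^2) / (n - 1)
  ms_cols <- n * sum((cm - grand)^2) / (k - 1)
  resid <- sweep(sweep(x, 1, rm), 2, cm) + grand
  ms_error <- sum(resid^2) / ((n - 1) * (k - 1))
  est <- (ms_rows - ms_error) /
    (ms_rows + (k - 1) * ms_error + (k / n) * (ms_cols - ms_error))

  alpha <- 1 - conf_level
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * ms_cols + b * ms_error)^2 /
    ((a * ms_cols)^2 / (k - 1) + (b * ms_error)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (ms_rows - f_l * ms_error) /
    (f_l * (k * ms_cols + (k * n - k - n) * ms_error) + n * ms_rows)
  ci_high <- n * (f_u * ms_rows - ms_error) /
    (k * ms_cols + (k * n - k - n) * ms_error + n * f_u * ms_rows)

  structure(list(estimate = est,
                 ci_low = min(ci_low, est), ci_high = max(ci_high, est),
                 ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
                 n = n, k = k, conf_level = conf_level,
                 measure_name = table$measure_name,
                 band = band_icc(est)),
            class = "hab_icc")
}

#' @export
print.hab_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) [%s]: %.3f (%.0f%% CI %.3f-%.3f), '%s'\n",
              x$measure_name, x$estimate, 100 * x$conf_level,
              x$ci_low, x$ci_high, x$band))
  cat(sprintf("  n = %d subjects, k = %d raters; MS rows %.4g, cols %.4g, error %.4g\n",
              x$n, x$k, x$ms_rows, x$ms_cols, x$ms_error))
  invisible(x)
}

#' Qualitative agreement band for an ICC estimate
#'
#' Bands follow the conventional ranges 0.00-0.20 "slight", 0.21-0.40
#' "fair", 0.41-0.60 "moderate", 0.61-0.80 "substantial" and 0.81-1.00
#' "almost perfect". Values between adjacent printed ranges belong to the
#' upper band. Negative estimates are banded "slight".
#'
#' @param estimate ICC estimate in `[-1, 1]`.
#' @return One of `"slight"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
band_icc <- function(estimate) {
  if (estimate < -1 || estimate > 1) stop("estimate must lie in [-1, 1]")
  if (estimate > 0.80) "almost perfect"
  else if (estimate > 0.60) "substantial"
  else if (estimate > 0.40) "moderate"
  else if (estimate > 0.20) "fair"
  else "slight"
}

#' Inter-rater reliability report from per-subject masks
#'
#' Computes left, right and combined habenula volumes per subject for each
#' rater, optionally centre-of-mass coordinates, and runs [icc_2_1()] on
#' each measure.
#'
#' @param masks_rater1,masks_rater2 lists (one entry per subject) of
#'   `list(left = hab_mask, right = hab_mask)`.
#' @param centroids also report per-axis centre-of-mass ICCs (default
#'   `FALSE`).
#' @return A data.frame with one row per measure: `measure`, `estimate`,
#'   `ci_low`, `ci_high`, `band`, `ms_rows`, `ms_cols`, `ms_error`, `n`,
#'   `k`.
#' @export
reliability_report <- function(masks_rater1, masks_rater2, centroids = FALSE) {
  if (length(masks_rater1) != length(masks_rater2))
    stop("alignment error: the two raters cover different subject lists")
  n <- length(masks_rater1)
  if (n < 2) stop("need at least 2 subjects")
  vol_side <- function(masks, side) vapply(masks, function(m) mask_volume(m[[side]]), double(1))
  tables <- list(
    left_volume = cbind(vol_side(masks_rater1, "left"), vol_side(masks_rater2, "left")),
    right_volume = cbind(vol_side(masks_rater1, "right"), vol_side(masks_rater2, "right"))
  )
  tables$combined_volume <- tables$left_volume + tables$right_volume
  if (centroids) {
    for (side in c("left", "right")) for (a in 1:3) {
      nm <- paste0(side, "_com_", c("x", "y", "z")[a])
      tables[[nm]] <- cbind(
        vapply(masks_rater1, function(m) mask_center_of_mass(m[[side]])[a], double(1)),
        vapply(masks_rater2, function(m) mask_center_of_mass(m[[side]])[a], double(1)))
    }
  }
  do.call(rbind, lapply(names(tables), function(nm) {
    r <- icc_2_1(rater_table(tables[[nm]], measure_name = nm))
    data.frame(measure = nm, estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, band = r$band, ms_rows = r$ms_rows,
               ms_cols = r$ms_cols, ms_error = r$ms_error, n = r$n, k = r$k,
               row.names = NULL)
  }))
}
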