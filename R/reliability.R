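# Inter-rater reliability statistics: two-way random-effects intraclass
# correlation (Shrout & Fleiss form 2) with F-based confidence intervals,
# Fleiss' multi-rater kappa and Cohen's kappa with large-sample z tests,
# and the Landis-Koch verbal interpretation scale.

new_agreement_estimate <- function(statistic, value, ci_low = NA_real_,
                                   ci_high = NA_real_, p_value = NA_real_,
                                   degenerate = FALSE, n_subjects = NA,
                                   n_raters = NA, detail = list()) {
  structure(
    list(statistic = statistic, value = value, ci_low = ci_low,
         ci_high = ci_high, p_value = p_value,
         label = if (is.na(value)) NA_character_ else landis_koch(value),
         degenerate = degenerate, n_subjects = n_subjects,
         n_raters = n_raters, detail = detail),
    class = "agreement_estimate")
}

two_way_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Two-way random-effects intraclass correlation
#'
#' ICC for absolute agreement under the two-way random-effects model
#' (subjects and raters both random), computed from the two-way ANOVA mean
#' squares. `type = "single"` gives ICC(2,1), the reliability of a single
#' rater's measurement (default); `type = "average"` gives ICC(2,k), the
#' reliability of the k-rater mean. The 95% confidence interval uses the
#' F-distribution interval with a Satterthwaite degrees-of-freedom
#' approximation for the single-measure form.
#'
#' @param m Numeric subjects x raters matrix, no missing cells, at least
#'   2 subjects and 2 raters.
#' @param type `"single"` (ICC(2,1)) or `"average"` (ICC(2,k)).
#' @param conf_level Confidence level (default 0.95).
#' @return An `agreement_estimate` with `value`, `ci_low`, `ci_high` and a
#'   Landis-Koch `label`. If the between-subject variance is zero the ICC
#'   is undefined: a `pelvimetrix_degenerate` warning is signalled and the
#'   estimate carries `value = NA`, `degenerate = TRUE`.
#' @export
icc_two_way_random <- function(m, type = c("single", "average"),
                               conf_level = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  check_finite(m, "ratings matrix")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_pelvimetrix("need at least 2 subjects and 2 raters")
  }
  ms <- two_way_mean_squares(m)
  n <- ms$n; k <- ms$k
  if (ms$msr <= .Machine$double.eps * max(1, mean(m)^2)) {
    warn_degenerate(
      "zero between-subject variance: ICC undefined for this matrix")
    return(new_agreement_estimate("icc", NA_real_, degenerate = TRUE,
      n_subjects = n, n_raters = k, detail = ms))
  }
  icc1 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf_level
  if (ms$mse <= .Machine$double.eps * ms$msr) {
    ci1 <- c(icc1, icc1) # exact agreement: interval collapses
  } else {
    # Shrout-Fleiss interval for ICC(2,1)
    fj <- ms$msc / ms$mse
    vn <- (k - 1) * (n - 1) *
      ((k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1))^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    ci1 <- c(lo, hi)
  }
  if (type == "single") {
    value <- icc1; ci <- ci1
  } else {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    value <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    ci <- sb(ci1)
  }
  new_agreement_estimate("icc", value, ci_low = min(ci, value),
    ci_high = max(ci, value), n_subjects = n, n_raters = k,
    detail = c(ms, list(type = type)))
}

category_counts <- function(m, levels) {
  t(apply(m, 1, function(row) {
    tab <- table(factor(row, levels = levels))
    as.numeric(tab)
  }))
}

fleiss_kappa <- function(m) {
  n <- nrow(m); k <- ncol(m)
  levels <- sort(unique(as.vector(m)))
  cnt <- category_counts(m, levels)
  pj <- colSums(cnt) / (n * k)
  pi_ <- (rowSums(cnt^2) - k) / (k * (k - 1))
  pbar <- mean(pi_)
  pe <- sum(pj^2)
  kap <- (pbar - pe) / (1 - pe)
  qj <- 1 - pj
  spq <- sum(pj * qj)
  var0 <- 2 * (spq^2 - sum(pj * qj * (qj - pj))) / (n * k * (k - 1) * spq^2)
  z <- kap / sqrt(var0)
  list(kappa = kap, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

cohen_kappa <- function(r1, r2) {
  levels <- sort(unique(c(r1, r2)))
  tab <- table(factor(r1, levels = levels), factor(r2, levels = levels))
  nn <- sum(tab)
  p <- tab / nn
  po <- sum(diag(p))
  prow <- rowSums(p); pcol <- colSums(p)
  pe <- sum(prow * pcol)
  kap <- (po - pe) / (1 - pe)
  # large-sample SE under the null of chance agreement (Fleiss, Cohen & Everitt)
  se0 <- sqrt((pe + pe^2 - sum(prow * pcol * (prow + pcol))) /
              (nn * (1 - pe)^2))
  z <- kap / se0
  list(kappa = kap, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Chance-corrected categorical agreement (kappa)
#'
#' Multi-rater agreement on categorical outcomes. The default is Fleiss'
#' kappa with its large-sample z test under the no-agreement null;
#' `mode = "pairwise_cohen_mean"` instead averages Cohen's kappa over all
#' rater pairs (with the z test available only for exactly 2 raters).
#'
#' @param m Character/factor subjects x raters matrix, no missing cells.
#' @param mode `"fleiss"` or `"pairwise_cohen_mean"`.
#' @return An `agreement_estimate` with `value`, `p_value` and a
#'   Landis-Koch `label`. If every rating falls in a single category the
#'   statistic is undefined: a `pelvimetrix_degenerate` warning is
#'   signalled and the estimate carries `value = NA`, `degenerate = TRUE`.
#' @export
kappa_categorical <- function(m, mode = c("fleiss", "pairwise_cohen_mean")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (anyNA(m)) stop_pelvimetrix("ratings matrix must have no missing cells")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_pelvimetrix("need at least 2 subjects and 2 raters")
  }
  m <- matrix(as.character(m), nrow(m), ncol(m))
  if (length(unique(as.vector(m))) < 2L) {
    warn_degenerate(
      "all ratings fall in a single category: kappa undefined")
    return(new_agreement_estimate("kappa", NA_real_, degenerate = TRUE,
      n_subjects = nrow(m), n_raters = ncol(m)))
  }
  if (mode == "fleiss") {
    fk <- fleiss_kappa(m)
    return(new_agreement_estimate("kappa", fk$kappa, p_value = fk$p_value,
      n_subjects = nrow(m), n_raters = ncol(m),
      detail = list(mode = mode, z = fk$z)))
  }
  pairs <- utils::combn(ncol(m), 2)
  ks <- apply(pairs, 2, function(ij) cohen_kappa(m[, ij[1]], m[, ij[2]])$kappa)
  pv <- if (ncol(m) == 2L) cohen_kappa(m[, 1], m[, 2])$p_value else NA_real_
  new_agreement_estimate("kappa", mean(ks), p_value = pv,
    n_subjects = nrow(m), n_raters = ncol(m),
    detail = list(mode = mode, pairwise = ks))
}

LANDIS_KOCH_BREAKS <- c(0, 0.205, 0.405, 0.605, 0.805)
LANDIS_KOCH_LABELS <- c("poor", "slight", "fair", "moderate", "substantial",
                        "almost perfect")

#' Landis-Koch verbal interpretation of an agreement coefficient
#'
#' Bands: below 0 poor; `[0, 0.205)` slight; `[0.205, 0.405)` fair;
#' `[0.405, 0.605)` moderate; `[0.605, 0.805)` substantial; `[0.805, 1]`
#' almost perfect. The published scale lists closed decade bands with gaps
#' (0.20 then 0.21, ...); the half-open breakpoints above sit midway inside
#' each gap so that every printed bound lands in the band whose printed
#' range contains it, and the labelling is total and monotone on
#' `(-Inf, 1]`.
#'
#' @param value Numeric vector of agreement coefficients, each `<= 1`.
#' @return Character vector of labels.
#' @export
#' @examples
#' landis_koch(c(0.10, 0.30, 0.50, 0.70, 0.90))
landis_koch <- function(value) {
  check_finite(value, "agreement value")
  if (any(value > 1)) {
    stop_pelvimetrix("agreement coefficients cannot exceed 1")
  }
  LANDIS_KOCH_LABELS[findInterval(value, LANDIS_KOCH_BREAKS) + 1L]
}

RELIABILITY_CONTINUOUS <- c("vertical_mm", "ap_mm", "transverse_mm",
                            "sagittal_mm", "inlet_mm", "outlet_mm")
RELIABILITY_CATEGORICAL <- c("sagittal_class", "inlet_class", "outlet_class")

ratings_matrix <- function(measurements, column) {
  subjects <- sort(unique(as.character(measurements$subject_id)))
  raters <- sort(unique(as.character(measurements$rater)))
  m <- matrix(NA, length(subjects), length(raters),
    dimnames = list(subjects, raters))
  idx <- cbind(match(as.character(measurements$subject_id), subjects),
               match(as.character(measurements$rater), raters))
  m[idx] <- measurements[[column]]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop_pelvimetrix(sprintf(
      "unbalanced rater x subject grid; missing cell(s): %s",
      paste(sprintf("(%s, %s)", subjects[miss[, 1]], raters[miss[, 2]]),
            collapse = ", ")))
  }
  m
}

#' Inter-rater reliability report across displacement parameters
#'
#' Computes the ICC (with 95% CI) for each of the six continuous
#' displacement parameters (three translations, three rotational
#' indicators) and the kappa statistic (with p-value) for the three
#' rotational class outcomes, each with its Landis-Koch label.
#'
#' @param measurements Long data frame with one row per rater x subject,
#'   as produced by [measure_study()] or by row-binding per-rater
#'   [as.data.frame.displacement_report()] outputs with a `rater` column.
#'   Every rater must have measured every subject.
#' @param icc_type `"single"` or `"average"` (see [icc_two_way_random()]).
#' @param kappa_mode `"fleiss"` or `"pairwise_cohen_mean"`.
#' @param conf_level Confidence level for ICC intervals.
#' @return An object of class `reliability_report`: a data frame with one
#'   row per parameter (`parameter`, `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `label`, `degenerate`). Degenerate parameters
#'   (e.g. no between-subject variance) carry `NA` estimates and
#'   `degenerate = TRUE`, after signalling a `pelvimetrix_degenerate`
#'   warning.
#' @export
reliability_report <- function(measurements,
                               icc_type = c("single", "average"),
                               kappa_mode = c("fleiss", "pairwise_cohen_mean"),
                               conf_level = 0.95) {
  icc_type <- match.arg(icc_type)
  kappa_mode <- match.arg(kappa_mode)
  need <- c("rater", "subject_id", RELIABILITY_CONTINUOUS,
            RELIABILITY_CATEGORICAL)
  if (!all(need %in% names(measurements))) {
    stop_pelvimetrix(sprintf("measurements must have columns: %s",
      paste(setdiff(need, names(measurements)), collapse = ", ")))
  }
  rows <- list()
  for (p in RELIABILITY_CONTINUOUS) {
    est <- icc_two_way_random(ratings_matrix(measurements, p),
      type = icc_type, conf_level = conf_level)
    rows[[p]] <- data.frame(parameter = p, statistic = "icc",
      estimate = est$value, ci_low = est$ci_low, ci_high = est$ci_high,
      p_value = NA_real_, label = est$label, degenerate = est$degenerate,
      stringsAsFactors = FALSE)
  }
  for (p in RELIABILITY_CATEGORICAL) {
    est <- kappa_categorical(ratings_matrix(measurements, p),
      mode = kappa_mode)
    rows[[p]] <- data.frame(parameter = p, statistic = "kappa",
      estimate = est$value, ci_low = NA_real_, ci_high = NA_real_,
      p_value = est$p_value, label = est$label, degenerate = est$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("reliability_report", "data.frame"),
    icc_type = icc_type, kappa_mode = kappa_mode,
    n_subjects = length(unique(measurements$subject_id)),
    n_raters = length(unique(measurements$rater)))
}

#' @export
print.agreement_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<agreement_estimate> %s: degenerate (undefined)\n",
      x$statistic))
    return(invisible(x))
  }
  if (x$statistic == "icc") {
    cat(sprintf("ICC = %.3f (95%% CI %.3f-%.3f), %s [n = %d, raters = %d]\n",
      x$value, x$ci_low, x$ci_high, x$label, x$n_subjects, x$n_raters))
  } else {
    cat(sprintf("kappa = %.3f (p = %.3g), %s [n = %d, raters = %d]\n",
      x$value, x$p_value, x$label, x$n_subjects, x$n_raters))
  }
  invisible(x)
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "Reliability report: %s subjects, %s raters (ICC %s, kappa %s)\n",
    attr(x, "n_subjects"), attr(x, "n_raters"),
    attr(x, "icc_type"), attr(x, "kappa_mode")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
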