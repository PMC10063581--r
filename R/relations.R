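#' Pearson correlation with t-test p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list: r, p (two-sided, t distribution with n - 2 df), n.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_bws("need equal lengths >= 3", class = "bws_relations_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_bws("zero variance input", class = "bws_relations_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation matrix between concept score tables of one group
#'
#' @param score_tables named list of `bws_score_table` (names = concepts)
#'   over a common stimulus set.
#' @param group group label for the report.
#' @return object of class `concept_correlations`: `r`, `p` (symmetric
#'   matrices with unit/NA diagonals), `n`, `group`.
#' @export
concept_correlations <- function(score_tables, group = NA_character_) {
  concepts <- names(score_tables)
  ids <- names(score_tables[[1]]$scores)
  m <- vapply(score_tables, function(st) st$scores[ids], numeric(length(ids)))
  r <- diag(length(concepts)); p <- matrix(NA_real_, length(concepts), length(concepts))
  dimnames(r) <- dimnames(p) <- list(concepts, concepts)
  for (i in seq_along(concepts)) {
    for (j in seq_along(concepts)) {
      if (i < j) {
        pr <- pearson_r(m[, i], m[, j])
        r[i, j] <- r[j, i] <- pr$r
        p[i, j] <- p[j, i] <- pr$p
      }
    }
  }
  structure(list(r = r, p = p, n = length(ids), group = group),
            class = "concept_correlations")
}

#' @export
print.concept_correlations <- function(x, ...) {
  cat(sprintf("<concept_correlations %s (n = %d)>\n", x$group, x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' Steiger's test for two dependent correlations
#'
#' Compares two correlation coefficients measured on the same sample via
#' Fisher-z transforms with Steiger's (1980) pooled covariance correction.
#' Two dependence structures are supported: `overlapping` (the
#' correlations share one variable, r_jk vs r_jh; supply the one
#' cross-correlation r_kh) and `nonoverlapping` (r_jk vs r_hm on four
#' distinct variables; supply r_jh, r_jm, r_kh, r_km). With all
#' cross-correlations zero the nonoverlapping statistic reduces to the
#' classical two-sample Fisher-z comparison at equal n.
#'
#' @param r_ab first correlation.
#' @param r_cd second correlation.
#' @param cross_correlations named numeric: `r_kh` for `overlapping`;
#'   `r_jh`, `r_jm`, `r_kh`, `r_km` for `nonoverlapping`.
#' @param n sample size (number of stimuli).
#' @param variant `"overlapping"` or `"nonoverlapping"`.
#' @return object of class `steiger_result`: z, p (two-sided), n, variant.
#' @export
steiger_compare <- function(r_ab, r_cd, cross_correlations, n,
                            variant = c("overlapping", "nonoverlapping")) {
  variant <- match.arg(variant)
  for (r in c(r_ab, r_cd, cross_correlations)) {
    if (abs(r) >= 1) stop_bws("correlations must lie in (-1, 1)",
                              class = "bws_relations_error")
  }
  if (n < 4) stop_bws("n must be >= 4", class = "bws_relations_error")
  z1 <- atanh(r_ab)
  z2 <- atanh(r_cd)
  rbar <- (r_ab + r_cd) / 2
  cc <- cross_correlations
  if (variant == "overlapping") {
    if (!"r_kh" %in% names(cc)) {
      stop_bws("overlapping variant needs cross correlation r_kh",
               class = "bws_relations_error")
    }
    r_kh <- cc[["r_kh"]]
    psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
      (1 - 2 * rbar^2 - r_kh^2)
    s <- psi / (1 - rbar^2)^2
  } else {
    need <- c("r_jh", "r_jm", "r_kh", "r_km")
    if (!all(need %in% names(cc))) {
      stop_bws("nonoverlapping variant needs cross correlations %s",
               paste(need, collapse = ", "), class = "bws_relations_error")
    }
    r_jh <- cc[["r_jh"]]; r_jm <- cc[["r_jm"]]
    r_kh <- cc[["r_kh"]]; r_km <- cc[["r_km"]]
    # Pearson-Filon covariance with Steiger's pooled-r substitution
    psi <- 0.5 * rbar * rbar * (r_jh^2 + r_jm^2 + r_kh^2 + r_km^2) +
      r_jh * r_km + r_jm * r_kh -
      (rbar * r_jh * r_jm + rbar * r_kh * r_km +
         rbar * r_jh * r_kh + rbar * r_jm * r_km)
    s <- psi / (1 - rbar^2)^2
  }
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  structure(list(z = z, p = 2 * pnorm(-abs(z)), n = n, variant = variant),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  # df rendered as n - 1 in the usual reporting style
  cat(sprintf("Steiger Z(%d) = %.3f, p = %.4g [%s]\n",
              x$n - 1, x$z, x$p, x$variant))
  invisible(x)
}

#' Correlation between group consistency and model accuracy
#'
#' Pearson correlation over the group x concept grid between mean
#' compliance and mean cross-validated R^2 — the coupling between how
#' consistent a population is and how well its scores can be predicted
#' from acoustics.
#'
#' @param compliance_by_cell named numeric: `"group.concept"` -> mean
#'   compliance.
#' @param r2_by_cell named numeric over the identical cells.
#' @return list: r, p, n (number of cells).
#' @export
consistency_accuracy_correlation <- function(compliance_by_cell, r2_by_cell) {
  if (!setequal(names(compliance_by_cell), names(r2_by_cell))) {
    stop_bws("cell sets differ", class = "bws_relations_error")
  }
  cells <- names(compliance_by_cell)
  pearson_r(unname(compliance_by_cell[cells]), unname(r2_by_cell[cells]))
}
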