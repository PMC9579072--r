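#' Convert Cohen's f to proportion of variance
#'
#' The effect size \eqn{f} used in ANOVA power analysis maps to the
#' proportion of variance (PV) attributable to the effect via
#' \eqn{PV = f^2 / (1 + f^2)}. The conventional benthic-monitoring
#' boundaries f = 0.2, 0.5 and 0.8 correspond to PV of roughly 4\%, 20\%
#' and 39\%.
#'
#' @param f Non-negative numeric vector of Cohen's f effect sizes.
#' @return Proportion(s) of variance in `[0, 1)`.
#' @seealso [f_from_pv()], [me_test()]
#' @export
#' @examples
#' pv_from_f(c(0.2, 0.5, 0.8))
pv_from_f <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    stop("`f` must be finite and >= 0", call. = FALSE)
  }
  f^2 / (1 + f^2)
}

#' Convert proportion of variance to Cohen's f
#'
#' Inverse of [pv_from_f()]: \eqn{f = \sqrt{PV / (1 - PV)}}.
#'
#' @param pv Numeric vector of proportions in `[0, 1)`.
#' @return Effect size(s) f.
#' @export
#' @examples
#' f_from_pv(0.20) # 0.5
f_from_pv <- function(pv) {
  if (!is.numeric(pv) || any(!is.finite(pv)) || any(pv < 0) || any(pv >= 1)) {
    stop("`pv` must be in [0, 1)", call. = FALSE)
  }
  sqrt(pv / (1 - pv))
}

#' Define a minimum-effects boundary
#'
#' @param label Short name for the boundary (e.g. "small").
#' @param f Cohen's f at the boundary (>= 0).
#' @return An `effect_size_spec`: list with `label`, `f` and implied `pv`.
#' @export
effect_size_spec <- function(label, f) {
  stopifnot(is.character(label), length(label) == 1L, length(f) == 1L)
  structure(list(label = label, f = f, pv = pv_from_f(f)),
            class = "effect_size_spec")
}

#' Default minimum-effects boundaries for benthic monitoring
#'
#' Small (f = 0.2, natural variability), medium (f = 0.5, transition across
#' an ecological boundary) and large (f = 0.8, disturbance-scale change).
#'
#' @return Named list of [effect_size_spec()] objects ordered by f.
#' @export
default_effect_sizes <- function() {
  list(small  = effect_size_spec("small", 0.2),
       medium = effect_size_spec("medium", 0.5),
       large  = effect_size_spec("large", 0.8))
}

#' Noncentrality parameter for a minimum-effects boundary
#'
#' Approximates the noncentrality of the F reference distribution at a
#' boundary effect size, \eqn{\lambda = df_2 \cdot PV/(1-PV) = df_2 f^2}
#' (`form = "standard"`, appropriate for large samples). An alternative
#' `form = "printed"` evaluates \eqn{df_2 \cdot PV / (1/PV) = df_2 PV^2},
#' the literal reading of a widely circulated typo of the same formula;
#' it is provided for audit only.
#'
#' @param df2 Error (denominator) degrees of freedom, > 0.
#' @param f Boundary effect size, >= 0.
#' @param form `"standard"` (default) or `"printed"`.
#' @return Noncentrality \eqn{\lambda \ge 0}.
#' @export
#' @examples
#' me_noncentrality(100, 0.5) # 25
me_noncentrality <- function(df2, f, form = c("standard", "printed")) {
  form <- match.arg(form)
  if (!is.numeric(df2) || any(!is.finite(df2)) || any(df2 <= 0)) {
    stop("`df2` must be finite and > 0", call. = FALSE)
  }
  pv <- pv_from_f(f)
  switch(form,
         standard = df2 * f^2,
         printed  = df2 * pv^2)
}

.check_f_args <- function(df1, df2, lam, alpha) {
  if (any(!is.finite(df1)) || any(df1 <= 0)) stop("`df1` must be > 0", call. = FALSE)
  if (any(!is.finite(df2)) || any(df2 <= 0)) stop("`df2` must be > 0", call. = FALSE)
  if (any(!is.finite(lam)) || any(lam < 0)) stop("`lam` must be >= 0", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Minimum-effects critical value
#'
#' Upper \eqn{1-\alpha} quantile of the noncentral F distribution with
#' `df1`, `df2` degrees of freedom and noncentrality `lam`. At `lam = 0`
#' this is the usual central-F critical value; it increases strictly with
#' `lam`.
#'
#' @inheritParams me_noncentrality
#' @param df1 Hypothesis (numerator) degrees of freedom, > 0.
#' @param lam Noncentrality parameter, >= 0.
#' @param alpha Test level in (0, 1); default 0.05.
#' @return Critical value F_crit.
#' @export
me_critical_value <- function(df1, df2, lam, alpha = 0.05) {
  .check_f_args(df1, df2, lam, alpha)
  stats::qf(1 - alpha, df1, df2, ncp = lam)
}

#' Minimum-effects hypothesis test on an observed F statistic
#'
#' Tests the interval null that the true effect is no larger than the
#' boundary effect size `spec$f` against the alternative that it exceeds
#' it, by referring `F_obs` to the noncentral F distribution with
#' \eqn{\lambda = df_2 f^2}. An observed F exactly at the critical value
#' does not reject (the null is stated as F_obs <= F_crit).
#'
#' @param F_obs Observed F statistic(s), >= 0 (vectorised).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param spec An [effect_size_spec()] giving the boundary.
#' @param alpha Test level; default 0.05.
#' @param form Noncentrality form, see [me_noncentrality()].
#' @return Data frame of class `me_test` with one row per `F_obs`:
#'   `effect_label`, `F_obs`, `df1`, `df2`, `lam`, `F_crit`, `p_me`,
#'   `alpha`, `rejected`.
#' @export
#' @examples
#' me_test(8.1, df1 = 2, df2 = 120, spec = default_effect_sizes()$small)
me_test <- function(F_obs, df1, df2, spec, alpha = 0.05,
                    form = c("standard", "printed")) {
  stopifnot(inherits(spec, "effect_size_spec"))
  if (any(!is.finite(F_obs)) || any(F_obs < 0)) {
    stop("`F_obs` must be finite and >= 0", call. = FALSE)
  }
  lam <- me_noncentrality(df2, spec$f, form = match.arg(form))
  .check_f_args(df1, df2, lam, alpha)
  F_crit <- stats::qf(1 - alpha, df1, df2, ncp = lam)
  p_me <- stats::pf(F_obs, df1, df2, ncp = lam, lower.tail = FALSE)
  out <- data.frame(effect_label = spec$label, F_obs = F_obs,
                    df1 = df1, df2 = df2, lam = lam, F_crit = F_crit,
                    p_me = p_me, alpha = alpha,
                    rejected = F_obs > F_crit)
  class(out) <- c("me_test", "data.frame")
  out
}

#' Classify an observed F against ordered minimum-effects boundaries
#'
#' Runs the ME test at each boundary in `specs` (which must be strictly
#' increasing in f) and reports the largest boundary rejected:
#' `"negligible-to-small"` if none, else `"exceeds-<label>"`.
#' Because critical values increase with f, rejections always form a
#' prefix of the boundary sequence, so the classification is monotone in
#' `F_obs`.
#'
#' @inheritParams me_test
#' @param specs List of [effect_size_spec()]s, strictly increasing in f.
#' @return Character vector of labels, one per `F_obs`.
#' @export
classify_effect <- function(F_obs, df1, df2, specs = default_effect_sizes(),
                            alpha = 0.05) {
  fs <- vapply(specs, function(s) s$f, numeric(1))
  if (length(fs) < 1L || any(diff(fs) <= 0)) {
    stop("`specs` must be strictly increasing in f", call. = FALSE)
  }
  rej <- vapply(specs, function(s) {
    me_test(F_obs, df1, df2, s, alpha)$rejected
  }, logical(length(F_obs)))
  rej <- matrix(rej, nrow = length(F_obs))
  k <- rowSums(rej)
  labels <- c("negligible-to-small",
              paste0("exceeds-", vapply(specs, `[[`, "", "label")))
  labels[k + 1L]
}

#' Post hoc power of the classical F test
#'
#' Probability that a noncentral F variate with noncentrality `lam`
#' exceeds the central-F critical value: equals `alpha` at `lam = 0` and
#' increases to 1 as `lam` grows.
#'
#' @inheritParams me_critical_value
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' post_hoc_power(2, 100, lam = 10)
post_hoc_power <- function(df1, df2, lam, alpha = 0.05) {
  .check_f_args(df1, df2, lam, alpha)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lam, lower.tail = FALSE)
}

#' Batch minimum-effects testing of an F table
#'
#' Applies [me_test()] at every boundary in `specs` to each row of a table
#' of observed F statistics, and appends the [classify_effect()] label --
#' the machine-readable version of the asterisk annotations used in
#' published ANCOVA tables.
#'
#' @param tbl Data frame with columns `F_obs`, `df1`, `df2`, and
#'   optionally an identifier column carried through.
#' @param specs Ordered boundary list; default [default_effect_sizes()].
#' @param alpha Test level.
#' @return Data frame: one row per (input row, boundary) with ME test
#'   fields, plus `classification` per input row.
#' @export
me_test_table <- function(tbl, specs = default_effect_sizes(), alpha = 0.05) {
  stopifnot(is.data.frame(tbl), all(c("F_obs", "df1", "df2") %in% names(tbl)))
  id_cols <- setdiff(names(tbl), c("F_obs", "df1", "df2"))
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    res <- do.call(rbind, lapply(specs, function(s) {
      me_test(r$F_obs, r$df1, r$df2, s, alpha)
    }))
    res$classification <- classify_effect(r$F_obs, r$df1, r$df2, specs, alpha)
    for (cc in id_cols) res[[cc]] <- r[[cc]]
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c(id_cols, setdiff(names(out), id_cols))]
}
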