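test_that("f <-> PV conversions reproduce the boundary values and invert", {
  expect_identical(pv_from_f(0), 0)
  expect_equal(pv_from_f(0.2), 0.04 / 1.04, tolerance = 1e-12)
  expect_lt(abs(pv_from_f(0.2) - 0.0385), 5e-5)   # printed 4-dp value
  expect_equal(pv_from_f(0.5), 0.20, tolerance = 1e-12)
  expect_lt(abs(pv_from_f(0.8) - 0.3902), 5e-5)
  expect_identical(f_from_pv(0), 0)
  expect_equal(f_from_pv(0.20), 0.5, tolerance = 1e-12)
  expect_equal(f_from_pv(0.5), 1.0, tolerance = 1e-12)
  # exact inverses across the domain
  f <- seq(0, 5, by = 0.07)
  expect_equal(f_from_pv(pv_from_f(f)), f, tolerance = 1e-10)
  pv <- seq(0, 0.99, by = 0.013)
  expect_equal(pv_from_f(f_from_pv(pv)), pv, tolerance = 1e-10)
  expect_error(pv_from_f(-0.1), "f")
  expect_error(f_from_pv(1), "pv")
  expect_error(f_from_pv(-0.2), "pv")
})

test_that("noncentrality approximation follows lambda = df2 * f^2", {
  expect_equal(me_noncentrality(100, 0.5), 25)
  expect_equal(me_noncentrality(50, 0.2), 2)
  expect_equal(me_noncentrality(77, 0), 0)
  # audit-only literal form DF * PV / (1/PV) = DF * PV^2
  expect_equal(me_noncentrality(100, 0.5, form = "printed"), 100 * 0.2^2)
  expect_error(me_noncentrality(0, 0.5), "df2")
  expect_error(me_noncentrality(10, -1), "f")
})

test_that("ME critical values sit on the noncentral F quantile", {
  # central case: published F table value
  expect_equal(me_critical_value(1, 10, lam = 0), 4.9646, tolerance = 1e-3)
  expect_equal(me_critical_value(1, 10, lam = 0), qf(0.95, 1, 10),
               tolerance = 1e-10)
  # strictly increasing in the noncentrality
  lams <- seq(0, 20, by = 2.5)
  crits <- vapply(lams, function(l) me_critical_value(2, 40, l), numeric(1))
  expect_true(all(diff(crits) > 0))
  # Monte-Carlo oracle: quantile of the ratio-of-chi-squares construction
  set.seed(101)
  n <- 1e6
  Fmc <- (rchisq(n, 2, ncp = 2.4) / 2) / (rchisq(n, 60) / 60)
  expect_lt(abs(me_critical_value(2, 60, lam = 2.4) -
                  unname(quantile(Fmc, 0.95))), 0.03)
  expect_error(me_critical_value(2, 60, lam = -1), "lam")
  expect_error(me_critical_value(2, 60, 1, alpha = 1.2), "alpha")
})

test_that("ME test reduces to the classical F test at f = 0 and handles limits", {
  null_spec <- effect_size_spec("null", 0)
  Fs <- c(0.3, 1, 2.7, 6.1)
  res <- me_test(Fs, df1 = 3, df2 = 42, spec = null_spec)
  expect_equal(res$p_me, pf(Fs, 3, 42, lower.tail = FALSE), tolerance = 1e-10)
  sm <- default_effect_sizes()$small
  expect_equal(me_test(0, 2, 50, sm)$p_me, 1)
  expect_false(me_test(0, 2, 50, sm)$rejected)
  big <- lapply(default_effect_sizes(), function(s) me_test(1e6, 2, 50, s))
  expect_true(all(vapply(big, function(r) r$rejected, logical(1))))
  # tie rule: F exactly at the critical value does not reject
  crit <- me_critical_value(2, 50, me_noncentrality(50, 0.2))
  expect_false(me_test(crit, 2, 50, sm)$rejected)
  expect_true(me_test(crit + 1e-6, 2, 50, sm)$rejected)
  # p_me strictly decreasing in F_obs
  expect_true(all(diff(me_test(seq(0.1, 30, by = 0.5), 2, 50, sm)$p_me) < 0))
})

test_that("effect classification is monotone and respects boundary order", {
  specs <- default_effect_sizes()
  crit_small <- me_critical_value(2, 60, me_noncentrality(60, 0.2))
  crit_med <- me_critical_value(2, 60, me_noncentrality(60, 0.5))
  expect_identical(classify_effect(0.5, 2, 60), "negligible-to-small")
  # above central crit but below the small boundary is still negligible-to-small
  expect_identical(classify_effect(qf(0.95, 2, 60) + 0.1, 2, 60),
                   "negligible-to-small")
  expect_identical(classify_effect((crit_small + crit_med) / 2, 2, 60),
                   "exceeds-small")
  expect_identical(classify_effect(1e5, 2, 60), "exceeds-large")
  lev <- c("negligible-to-small", "exceeds-small", "exceeds-medium",
           "exceeds-large")
  ord <- match(classify_effect(seq(0, 60, by = 0.25), 2, 60), lev)
  expect_true(all(diff(ord) >= 0))
  bad <- list(effect_size_spec("a", 0.5), effect_size_spec("b", 0.2))
  expect_error(classify_effect(1, 2, 60, specs = bad), "increasing")
})

test_that("post hoc power equals alpha at the null and grows to one", {
  expect_equal(post_hoc_power(2, 100, lam = 0), 0.05, tolerance = 1e-12)
  expect_equal(post_hoc_power(2, 100, lam = 0, alpha = 0.17), 0.17,
               tolerance = 1e-12)
  pows <- vapply(c(0, 2, 5, 10, 25, 80), function(l)
    post_hoc_power(2, 100, l), numeric(1))
  expect_true(all(diff(pows) > 0))
  expect_gt(post_hoc_power(2, 100, lam = 500), 0.9999)
})

test_that("batch ME table is consistent with single tests and classification", {
  tbl <- data.frame(effect = c("zone", "depth"), F_obs = c(3.2, 18),
                    df1 = c(2, 1), df2 = c(120, 118))
  out <- me_test_table(tbl)
  expect_equal(nrow(out), 6)
  for (i in seq_len(nrow(tbl))) {
    sub <- out[out$effect == tbl$effect[i], ]
    expect_setequal(sub$effect_label, c("small", "medium", "large"))
    expect_identical(unique(sub$classification),
                     classify_effect(tbl$F_obs[i], tbl$df1[i], tbl$df2[i]))
    one <- me_test(tbl$F_obs[i], tbl$df1[i], tbl$df2[i],
                   default_effect_sizes()$medium)
    expect_equal(sub$p_me[sub$effect_label == "medium"], one$p_me)
  }
})
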