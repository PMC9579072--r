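test_that("biomass transform and depth standardization are exact", {
  expect_identical(transform_biomass(0), 0)
  expect_equal(transform_biomass(exp(1) - 1), 1, tolerance = 1e-12)
  # the survey's maximum observed amphipod biomass
  expect_equal(transform_biomass(296), log(297), tolerance = 1e-12)
  expect_equal(transform_biomass(296), 5.6937, tolerance = 1e-4)
  expect_error(transform_biomass(-0.5), "biomass")

  s <- standardize_depth(c(9, 13))
  expect_equal(s$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)  # n-1 SD
  expect_equal(mean(s$z), 0, tolerance = 1e-12)
  expect_equal(s$z2[1], s$z2[2])  # symmetric depths share z^2
  z <- standardize_depth(rnorm(50, 11, 2))$z
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(standardize_depth(rep(9, 5)), "constant")
})

test_that("with zero station variance the mixed fit matches the OLS ANCOVA oracle", {
  skip_if_not_installed("car")
  d <- make_design(small_spec(per_zone = c(North = 6L, Middle = 6L,
                                           South = 6L)))
  p <- flat_params(mu = 2.5, sigma_station = 0, sigma_resid = 0.7,
                   beta1 = 0.4, groups = "Amphipoda")
  tab <- simulate_biomass(d, p, seed = 1)
  fit <- fit_mixed_ancova(tab, "Amphipoda")
  # equivalence requires the REML station variance at its boundary;
  # under a true zero component this is the typical outcome
  expect_identical(fit$varcomp[["sigma_station2"]], 0)

  sub <- tab[tab$design == "grid" & tab$taxon_group == "Amphipoda", ]
  std <- standardize_depth(sub$depth_m)
  dat <- data.frame(y = transform_biomass(sub$biomass_wet_g_per_m2),
                    zone = factor(sub$zone), period = factor(sub$period),
                    z = std$z, z2 = std$z2)
  ols <- lm(y ~ zone + period + zone:period + z + z2, data = dat,
            contrasts = list(zone = "contr.sum", period = "contr.sum"))
  a3 <- car::Anova(ols, type = 3)
  map <- c(zone = "zone", period = "period", `zone:period` = "zone:period",
           z = "depth", z2 = "depth2")
  for (term in names(map)) {
    F_mixed <- fit$anova_table$F_obs[fit$anova_table$effect == map[[term]]]
    F_ols <- a3[term, "F value"]
    expect_lt(abs(F_mixed - F_ols) / F_ols, 0.01)
  }
})

test_that("fits are invariant to row order and refuse singular designs", {
  d <- make_design(small_spec())
  tab <- simulate_biomass(d, flat_params(beta1 = 0.3), seed = 8)
  f1 <- fit_mixed_ancova(tab, "Bivalvia")
  set.seed(99)
  tab2 <- tab[sample(nrow(tab)), ]
  f2 <- fit_mixed_ancova(tab2, "Bivalvia")
  expect_equal(f1$anova_table, f2$anova_table, tolerance = 1e-8)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-8)
  # Satterthwaite df stay within sane bounds
  expect_true(all(f1$anova_table$df2 > 0))
  expect_true(all(f1$anova_table$df2 <= f1$n_obs))

  gone <- tab[!(tab$zone == "Middle" & tab$period == 2), ]
  expect_error(fit_mixed_ancova(gone, "Bivalvia"),
               "singular design: zone Middle x period 2")
  expect_error(fit_mixed_ancova(tab, "no-such-group"), "no grid rows")
})

test_that("ANCOVA report carries consistent significance and ME marks", {
  d <- make_design(small_spec(per_zone = c(North = 5L, Middle = 5L,
                                           South = 5L)))
  p <- flat_params(mu = 2, sigma_station = 0.3, sigma_resid = 0.6,
                   beta1 = 0.8, groups = c("Amphipoda", "Bivalvia",
                                           "Cumacea", "Isopoda",
                                           "Polychaeta", "Actinopterygii"))
  tab <- simulate_biomass(d, p, seed = 31)
  fits <- lapply(c("Amphipoda", "Bivalvia"),
                 function(g) fit_mixed_ancova(tab, g))
  rep <- ancova_report(fits)
  expect_equal(nrow(rep), 10)  # 2 taxa x 5 effects
  expect_setequal(unique(rep$effect),
                  c("zone", "period", "zone:period", "depth", "depth2"))
  for (i in seq_len(nrow(rep))) {
    expect_identical(rep$me_class[i],
                     classify_effect(rep$F_obs[i], rep$df1[i], rep$df2[i]))
  }
  expect_identical(rep$me_mark[rep$me_class == "negligible-to-small"],
                   rep("", sum(rep$me_class == "negligible-to-small")))
  expect_identical(rep$significant, rep$p <= 0.05)
  wide <- format_ancova_report(rep)
  expect_equal(dim(wide), c(2, 6))
})

test_that("total prey rows are appended per grab and fit like a taxon", {
  d <- make_design(small_spec())
  tab <- simulate_biomass(d, flat_params(mu = 1.5), seed = 4)
  tab2 <- add_total_prey(tab)
  expect_true("Total prey" %in% tab2$taxon_group)
  one <- tab2[tab2$station_id == tab2$station_id[1] & tab2$period == 1 &
                tab2$replicate_index == 1, ]
  expect_equal(one$biomass_wet_g_per_m2[one$taxon_group == "Total prey"],
               sum(one$biomass_wet_g_per_m2[one$taxon_group %in%
                                              prey_groups()]))
  fit <- fit_mixed_ancova(tab2, "Total prey")
  expect_equal(nrow(fit$anova_table), 5)
})
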