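test_that("method-4 effects equal the constrained least-squares solution", {
  for (seed in 1:20) {
    p <- sample(4:9, 1)
    x <- random_cross_means(p, "method4", seed = seed)
    fit <- griffing_effects(x)
    ora <- ls_oracle(x, "method4")
    expect_equal(unname(fit$gca), ora$g, tolerance = 1e-10)
    off <- upper.tri(x)
    expect_equal(fit$sca[off], ora$s[off], tolerance = 1e-10)
    expect_equal(fit$mean, ora$m, tolerance = 1e-10)
    # constraints and saturated reconstruction
    expect_lt(abs(sum(fit$gca)), 1e-10)
    s0 <- fit$sca; diag(s0) <- 0
    expect_lt(max(abs(rowSums(s0))), 1e-10)
    recon <- fitted(fit)
    expect_equal(recon[off], unclass(x)[off], tolerance = 1e-10)
  }
})

test_that("method-2 effects match the oracle and behave on special tables", {
  for (seed in 1:10) {
    p <- sample(4:8, 1)
    x <- random_cross_means(p, "method2", seed = 100 + seed)
    fit <- griffing_effects(x)
    ora <- ls_oracle(x, "method2")
    expect_equal(unname(fit$gca), ora$g, tolerance = 1e-10)
    cells <- upper.tri(x, diag = TRUE)
    expect_equal(fit$sca[cells], ora$s[cells], tolerance = 1e-10)
    expect_lt(abs(sum(fit$gca)), 1e-10)
    recon <- fitted(fit)
    expect_equal(recon[cells], unclass(x)[cells], tolerance = 1e-10)
  }

  # purely additive table: s = 0 and g = a - mean(a)
  p <- 6
  a <- seq(-1, 1.5, length.out = p)
  m <- outer(a, a, "+") + 5
  dimnames(m) <- list(paste0("P", 1:p), paste0("P", 1:p))
  d2 <- make_design(p, "method2")
  cells <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  x <- as_cross_means(tibble::tibble(parent_a = rownames(m)[cells[, 1]],
                                     parent_b = colnames(m)[cells[, 2]],
                                     value = m[cells]), d2)
  fit <- griffing_effects(x)
  expect_equal(unname(fit$gca), a - mean(a), tolerance = 1e-10)
  expect_lt(max(abs(fit$sca)), 1e-10)

  # constant table: everything zero
  xc <- as_cross_means(tibble::tibble(parent_a = rownames(m)[cells[, 1]],
                                      parent_b = colnames(m)[cells[, 2]],
                                      value = 4), d2)
  fitc <- griffing_effects(xc)
  expect_equal(max(abs(fitc$gca)), 0)
  expect_equal(max(abs(fitc$sca)), 0)
})

test_that("method-4 effects reproduce the published melon GCA/SCA tables", {
  parents <- melon_parents()
  d <- diallel_design(parents, method = "method4", n_blocks = 3,
                      environments = "LT2015")
  x <- as_cross_means(melon_lsm_lt2015(), d, value = "lsm")
  an <- as_diallel_anova(melon_single_ms("yield", "LT2015"), p = 8, r = 3)
  fit <- griffing_effects(x, anova = an)

  published_gca <- c(-0.971, -0.084, -0.537, -0.798, -0.105, -0.551,
                     1.437, 1.609)
  expect_equal(unname(fit$gca), published_gca, tolerance = 0.005)
  expect_equal(fit$sca["PI414723", "PI161375"], 0.555, tolerance = 0.01)
  expect_equal(fit$se$se_s, 0.981, tolerance = 0.001)
  expect_equal(fit$se$se_g, sqrt(7 * 4.04 / (8 * 6 * 3)), tolerance = 1e-12)

  rk <- rank_effects(fit, "higher_better")
  expect_equal(rk$gca$parent_a[1], "PI161375")
  expect_equal(rk$gca$parent_a[2], "PI414723")
  expect_equal(rk$gca$rank[rk$gca$parent_a == "Vedrantais"], 8)
})

test_that("rankings honour trait direction and flag ties", {
  fit <- new_effects_for_test(g = c(P1 = -3, P2 = 0, P3 = 3))
  rk_hi <- rank_effects(fit, "higher_better")
  expect_equal(rk_hi$gca$parent_a[1], "P3")
  rk_lo <- rank_effects(fit, "lower_better")
  expect_equal(rk_lo$gca$parent_a[1], "P1")

  fit_tied <- new_effects_for_test(g = c(P1 = 1, P2 = 1, P3 = -2))
  rk <- rank_effects(fit_tied, "higher_better")
  expect_true(any(rk$gca$tied))
  expect_equal(rk$gca$rank, 1:3)
})

test_that("single-environment ANOVA has the published df layout and exact SS split", {
  d <- make_design(8, "method4", r = 3)
  sim <- simulate_diallel(diallel_sim_spec(d, sigma2_g = 2, sigma2_s = 0.5,
                                           sigma2_e = 1), seed = 21)
  an <- anova_single_env(sim$records, d, "trait", "E1")
  get <- function(t) an$df[an$term == t]
  expect_identical(c(get("Entries"), get("GCA"), get("SCA"), get("Error")),
                   c(27, 7, 20, 54))

  ss <- function(t) an$sumsq[an$term == t]
  expect_equal(ss("GCA") + ss("SCA"), ss("Entries"), tolerance = 1e-8)

  # independent oracle: entry SS from aov() on the plot data
  plot_df <- sim$records
  plot_df$entry <- paste(plot_df$parent_a, plot_df$parent_b)
  fit <- stats::aov(value ~ block + entry, data = plot_df)
  ss_aov <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(ss("Entries"), ss_aov[2], tolerance = 1e-8)
  expect_equal(ss("Error"), ss_aov[3], tolerance = 1e-8)

  # all-constant data: every SS is zero
  const <- sim$records
  const$value <- 5
  an0 <- anova_single_env(const, d, "trait", "E1")
  expect_equal(max(an0$sumsq), 0)
})

test_that("method-2 ANOVA splits entries into GCA + SCA with the right df", {
  d <- make_design(8, "method2", r = 3)
  sim <- simulate_diallel(diallel_sim_spec(d), seed = 31)
  an <- anova_single_env(sim$records, d, "trait", "E1")
  get <- function(t) an$df[an$term == t]
  expect_identical(c(get("Entries"), get("GCA"), get("SCA"), get("Error")),
                   c(35, 7, 28, 70))
  ss <- function(t) an$sumsq[an$term == t]
  expect_equal(ss("GCA") + ss("SCA"), ss("Entries"), tolerance = 1e-8)
})

test_that("combined ANOVA df, SS decomposition and interaction oracle agree", {
  d <- make_design(8, "method4", r = 3, E = 6)
  sim <- simulate_diallel(diallel_sim_spec(d, sigma2_g = 2, sigma2_s = 0.5,
                                           sigma2_gE = 0.2, sigma2_sE = 0.4,
                                           sigma2_e = 3), seed = 41)
  an <- anova_combined(sim$records, d, "trait")
  get <- function(t) an$df[an$term == t]
  expect_identical(
    c(get("Environments"), get("Entries"), get("GCA"), get("SCA"),
      get("Env x Entries"), get("Env x GCA"), get("Env x SCA"),
      get("Error")),
    c(5, 27, 7, 20, 135, 35, 100, 324))

  ss <- function(t) an$sumsq[an$term == t]
  expect_equal(ss("GCA") + ss("SCA"), ss("Entries"), tolerance = 1e-8)
  expect_equal(ss("Env x GCA") + ss("Env x SCA"), ss("Env x Entries"),
               tolerance = 1e-8)

  # interaction SS equals the per-environment sum minus the main effect
  per_env_entries <- sum(purrr::map_dbl(paste0("E", 1:6), function(e) {
    a <- anova_single_env(sim$records, make_design(8, "method4", 3), "trait", e)
    a$sumsq[a$term == "Entries"]
  }))
  expect_equal(ss("Env x Entries"), per_env_entries - ss("Entries"),
               tolerance = 1e-8)

  # independent oracle: two-way aov with blocks nested in environments
  plot_df <- sim$records
  plot_df$entry <- paste(plot_df$parent_a, plot_df$parent_b)
  fit <- stats::aov(value ~ env + env:block + entry + env:entry,
                    data = plot_df)
  tab <- summary(fit)[[1]]
  ss_aov <- setNames(tab[["Sum Sq"]], trimws(rownames(tab)))
  expect_equal(ss("Entries"), unname(ss_aov["entry"]), tolerance = 1e-8)
  expect_equal(ss("Env x Entries"), unname(ss_aov["env:entry"]),
               tolerance = 1e-8)
  expect_equal(ss("Error"), unname(ss_aov["Residuals"]), tolerance = 1e-8)

  expect_error(anova_combined(sim$records[sim$records$env == "E1", ], d,
                              "trait"),
               "at least 2")
})

test_that("duplicating one environment zeroes every interaction SS", {
  d1 <- make_design(6, "method4", r = 2, E = 1)
  sim <- simulate_diallel(diallel_sim_spec(d1), seed = 51)
  twice <- dplyr::bind_rows(
    sim$records,
    dplyr::mutate(sim$records, env = "E2")
  )
  d2 <- make_design(6, "method4", r = 2, E = 2)
  an <- anova_combined(twice, d2, "trait")
  inter <- an$sumsq[an$term %in% c("Env x Entries", "Env x GCA",
                                   "Env x SCA", "Environments")]
  expect_lt(max(abs(inter)), 1e-8)
})

test_that("hybrids-vs-parents contrast estimates the pool difference", {
  d <- make_design(6, "method2", r = 3)
  sim <- simulate_diallel(diallel_sim_spec(d, sigma2_g = 0, sigma2_s = 0,
                                           sigma2_e = 0, sigma2_block = 0,
                                           sigma2_env = 0), seed = 61)
  # all entries equal: estimate 0, p = 1
  con0 <- parents_vs_hybrids(sim$records, d, "trait", "E1")
  expect_equal(con0$estimate, 0)
  expect_equal(con0$p.value, 1)

  # hybrids shifted +2 over parents
  shift <- sim$records
  hyb <- shift$parent_a != shift$parent_b
  shift$value[hyb] <- shift$value[hyb] + 2
  con2 <- parents_vs_hybrids(shift, d, "trait", "E1")
  expect_equal(con2$estimate, 2, tolerance = 1e-10)

  # negative self-penalty on a lower-better trait: hybrids ripen later?
  # no - delta on selfs means parents shift, hybrids - parents = -delta
  dly <- simulate_diallel(diallel_sim_spec(d, delta_self = 1.5,
                                           sigma2_e = 0.2), seed = 63)
  con3 <- parents_vs_hybrids(dly$records, d, "trait", "E1")
  expect_lt(con3$estimate, 0)

  # selfs are required
  d4 <- make_design(6, "method4", r = 3)
  sim4 <- simulate_diallel(diallel_sim_spec(d4), seed = 64)
  expect_error(parents_vs_hybrids(sim4$records, d4, "trait", "E1"),
               "selfed")
})

test_that("method 4 refuses tiny parent sets", {
  x <- random_cross_means(4, "method4", seed = 5)
  expect_no_error(griffing_effects(x))
  d3 <- make_design(3, "method4")
  x3 <- as_cross_means(tibble::tibble(parent_a = c("P1", "P1", "P2"),
                                      parent_b = c("P2", "P3", "P3"),
                                      value = c(1, 2, 3)), d3)
  expect_error(griffing_effects(x3), "p >= 4")
})
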