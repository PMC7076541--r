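test_that("tester centering zeroes column sums and nothing else", {
  set.seed(7)
  m <- matrix(rnorm(36, 10), 6, 6)
  cm <- center_by_tester(m)
  expect_lt(max(abs(colSums(cm))), 1e-10)
  # no double centering: row means stay nonzero in general
  expect_gt(max(abs(rowMeans(cm))), 1e-3)

  # identical rows collapse to the zero matrix
  m_id <- matrix(1:6, 6, 6, byrow = TRUE)  # every row is 1..6
  expect_equal(max(abs(center_by_tester(m_id))), 0)
})

test_that("the biplot needs selfs and reconstructs the centered table", {
  d4 <- make_design(6, "method4", r = 2)
  sim4 <- simulate_diallel(diallel_sim_spec(d4), seed = 90)
  m4 <- entry_means(sim4$records, d4, "trait", "E1")
  expect_error(gge_biplot(m4), "diagonal")

  d2 <- make_design(6, "method2", r = 2)
  sim2 <- simulate_diallel(diallel_sim_spec(d2, sigma2_s = 0.5), seed = 91)
  m2 <- entry_means(sim2$records, d2, "trait", "E1")
  model <- gge_biplot(m2)
  expect_lt(max(abs(colSums(model$centered))), 1e-10)
  expect_lte(sum(model$var_explained), 1 + 1e-12)

  # full SVD reconstruction of the centered matrix
  sv <- svd(model$centered)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_equal(recon, model$centered, tolerance = 1e-8, ignore_attr = TRUE)

  # rank-2 error never increases when adding a component
  err_k <- function(k) {
    approx <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sqrt(sum((model$centered - approx)^2))
  }
  errs <- vapply(1:5, err_k, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_equal(model$var_explained[1] + model$var_explained[2],
               sum(sv$d[1:2]^2) / sum(sv$d^2), tolerance = 1e-12)
})

test_that("inner products are invariant to the singular-value partition", {
  d2 <- make_design(6, "method2", r = 2)
  sim <- simulate_diallel(diallel_sim_spec(d2, sigma2_s = 0.4), seed = 92)
  m <- entry_means(sim$records, d2, "trait", "E1")
  m0 <- gge_biplot(m, f = 0)
  m1 <- gge_biplot(m, f = 1)
  ip0 <- m0$entry_scores %*% t(m0$tester_scores)
  ip1 <- m1$entry_scores %*% t(m1$tester_scores)
  expect_equal(ip0, ip1, tolerance = 1e-10)
})

test_that("an additive diallel table is rank one with GCA on the ATC abscissa", {
  d2 <- make_design(8, "method2", r = 3)
  spec <- diallel_sim_spec(d2, sigma2_g = 2, sigma2_s = 0, sigma2_gE = 0,
                           sigma2_sE = 0, sigma2_e = 1e-6,
                           sigma2_block = 0, sigma2_env = 0)
  sim <- simulate_diallel(spec, seed = 93)
  m <- entry_means(sim$records, d2, "trait", "E1")
  model <- gge_biplot(m)
  expect_gt(model$var_explained[1], 0.999)
  expect_lt(max(abs(model$projections$atc_ordinate)) /
              max(abs(model$projections$atc_abscissa)), 0.05)
  eff <- griffing_effects(m)
  rho <- cor(model$projections$atc_abscissa, unname(eff$gca))
  expect_gt(abs(rho), 0.95)
})

test_that("ATC projections track Griffing GCA when additive variance dominates", {
  d2 <- make_design(8, "method2", r = 3)
  set.seed(94)
  rhos <- replicate(25, {
    sim <- simulate_diallel(diallel_sim_spec(
      d2, sigma2_g = 2, sigma2_s = 0.05, sigma2_gE = 0, sigma2_sE = 0,
      sigma2_e = 0.1, sigma2_block = 0, sigma2_env = 0))
    m <- entry_means(sim$records, d2, "trait", "E1")
    model <- gge_biplot(m)
    eff <- griffing_effects(m)
    abs(cor(model$projections$atc_abscissa, unname(eff$gca),
            method = "spearman"))
  })
  expect_true(all(rhos >= 0.9))
})

test_that("symmetric pre-centered tables give matching entry and tester scores", {
  set.seed(95)
  s <- matrix(rnorm(25), 5, 5); s <- s + t(s)
  # double centering keeps symmetry and zeroes the column sums, so the
  # tester centering inside gge_biplot() is a no-op here
  s <- s - outer(rowMeans(s), rep(1, 5)) - outer(rep(1, 5), colMeans(s)) +
    mean(s)
  dimnames(s) <- list(paste0("G", 1:5), paste0("G", 1:5))
  # tester scores are centered here, so the ATC direction is undefined
  model <- suppressWarnings(gge_biplot(s, f = 0.5))
  # same subspace: |entry| == |tester| coordinates columnwise
  expect_equal(abs(model$entry_scores), abs(model$tester_scores),
               tolerance = 1e-8)
})

test_that("polygon sectors assign testers to their inner-product winner", {
  # square of four entries, testers at the entry positions
  es <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  rownames(es) <- paste0("G", 1:4)
  model <- structure(list(entry_scores = es, tester_scores = es),
                     class = "gge_biplot")
  pv <- polygon_view(model)
  expect_setequal(pv$vertices, rownames(es))
  expect_true(all(pv$sectors$own_sector))

  # random configurations: the sector winner maximizes the inner product
  set.seed(96)
  for (i in 1:10) {
    es <- matrix(rnorm(16), 8, 2)
    es <- sweep(es, 2, colMeans(es))  # origin inside the cloud
    rownames(es) <- paste0("G", 1:8)
    ts <- matrix(rnorm(12, sd = 0.8), 6, 2)
    rownames(ts) <- paste0("T", 1:6)
    model <- structure(list(entry_scores = es, tester_scores = ts),
                       class = "gge_biplot")
    pv <- polygon_view(model)
    hull_names <- pv$vertices
    for (j in seq_len(nrow(ts))) {
      ips <- drop(es[hull_names, ] %*% ts[j, ])
      expect_equal(pv$sectors$winner[j], hull_names[which.max(ips)])
    }
  }

  # collinear entries have no polygon
  es_line <- cbind(1:4, (1:4) * 2)
  rownames(es_line) <- paste0("G", 1:4)
  model_line <- structure(list(entry_scores = es_line,
                               tester_scores = es_line),
                          class = "gge_biplot")
  expect_error(polygon_view(model_line), "collinear")
})

test_that("a two-group heterotic pattern puts selfed testers in opposite sectors", {
  # parents 1-4 and 5-8; crossing between groups is strongly superior
  p <- 8
  groups <- rep(c("A", "B"), each = 4)
  m <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    m[i, j] <- 10 + ifelse(groups[i] != groups[j], 4, 0)
  }
  diag(m) <- 7
  dimnames(m) <- list(paste0("P", 1:p), paste0("P", 1:p))
  model <- suppressWarnings(gge_biplot(m))  # symmetric pattern: no ATC
  pv <- polygon_view(model)
  winners_a <- unique(pv$sectors$winner[groups == "A"])
  winners_b <- unique(pv$sectors$winner[groups == "B"])
  # testers of one pool are won by entries of the other pool
  expect_true(all(winners_a %in% paste0("P", 5:8)))
  expect_true(all(winners_b %in% paste0("P", 1:4)))
})

test_that("degenerate tables are flagged", {
  m <- matrix(5, 4, 4, dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
  w <- testthat::capture_warnings(model <- gge_biplot(m))
  expect_match(w, "degenerate|zero", all = FALSE)
  expect_true(model$degenerate)
})
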