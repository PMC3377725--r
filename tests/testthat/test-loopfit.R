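test_that("a noise-free consistent system is solved exactly", {
  d <- loop_design(
    data.frame(unit_id = c("A", "B", "C"), individual = c("A", "B", "C")),
    data.frame(array_id = c("a1", "a2", "a3", "a4"),
               tail = c("A", "B", "C", "B"), head = c("B", "C", "A", "A")))
  fit <- fit_gene(c(a1 = 2.0, a2 = 0.5, a3 = -1.0, a4 = -1.0), d)
  expect_false(fit$singular)
  expect_equal(fit$gamma_hat, 0.5, tolerance = 1e-12)
  expect_equal(fit$lambda_hat[c("A", "B", "C")],
               c(A = 1, B = -0.5, C = -0.5), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(fit$df, 1L)
  expect_equal(fit$sigma_hat, 0)
})

test_that("a saturated fit has df 0 and no sigma estimate", {
  fit <- fit_gene(c(a1 = 2.0, a2 = 0.5, a3 = -1.0), toy_triangle())
  expect_equal(fit$gamma_hat, 0.5, tolerance = 1e-12)
  expect_equal(fit$lambda_hat, c(A = 1, B = -0.5, C = -0.5),
               tolerance = 1e-12)
  expect_equal(fit$df, 0L)
  expect_true(is.na(fit$sigma_hat))
})

test_that("acyclic or empty observation sets are flagged singular", {
  # one arrow: gamma and the lambda difference are confounded
  fit <- fit_gene(c(a1 = 1.0), toy_triangle())
  expect_true(fit$singular)
  expect_null(fit$lambda_hat)
  # no observations at all
  fit <- fit_gene(c(a1 = NA_real_, a2 = NA_real_, a3 = NA_real_),
                  toy_triangle())
  expect_true(fit$singular)
})

test_that("fit matches the Lagrange normal-equations oracle on random instances", {
  set.seed(10)
  for (rep in 1:40) {
    d <- if (rep %% 2) fig1$design else random_design(sample(4:8, 1))
    m <- setNames(rnorm(d$n_arrows), d$arrays$array_id)
    # random missingness, keeping the instance non-singular per the oracle
    m[runif(d$n_arrows) < 0.15] <- NA
    obs <- !is.na(m)
    orc <- oracle_constrained_ls(d$arrays$tail[obs], d$arrays$head[obs],
                                 m[obs])
    fit <- fit_gene(m, d)
    if (is.null(orc)) {
      expect_true(fit$singular)
    } else {
      expect_false(fit$singular)
      expect_equal(fit$gamma_hat, orc$gamma, tolerance = 1e-8)
      expect_equal(fit$lambda_hat[names(orc$lambda)], orc$lambda,
                   tolerance = 1e-8)
      expect_equal(fit$rss, orc$rss, tolerance = 1e-8)
    }
  }
})

test_that("lambda estimates sum to zero over fitted units", {
  set.seed(11)
  cfg <- sim_config(n_genes = 60, seed = 12L, flag_prob = 0.1)
  tr <- simulate_truth(cfg, fig1$design, fig1$hierarchy)
  sp <- simulate_spots(tr, fig1$design, cfg)
  fit <- loop_fit(normalize_arrays(sp), fig1$design)
  sums <- rowSums(fit$lambda, na.rm = TRUE)
  expect_lt(max(abs(sums[!fit$singular])), 1e-9)
})

test_that("zero-noise simulation is recovered exactly (gauge-aligned)", {
  cfg <- sim_config(n_genes = 80, sigma_resid = 0, sigma_spot = 0,
                    dye_bias_coeffs = 0, flag_prob = 0, seed = 13L)
  tr <- simulate_truth(cfg, fig1$design, fig1$hierarchy)
  sp <- simulate_spots(tr, fig1$design, cfg)
  # aggregate the raw log ratios directly: the LOWESS step would also absorb
  # the array-wide mean dye effect, which is part of gamma here
  mmat <- sapply(sp, function(s) {
    tapply(log2(s$f_num / s$f_den), factor(s$gene_id, rownames(tr$lambda)),
           mean)
  })
  fit <- loop_fit(mmat, fig1$design)
  expect_equal(fit$n_fit, 80L)
  lam_true <- tr$lambda - rowMeans(tr$lambda)  # unit-level sum-zero gauge
  expect_lt(max(abs(fit$lambda - lam_true)), 1e-10)
  expect_lt(max(abs(fit$gamma - tr$gamma)), 1e-10)
})

test_that("estimates are invariant to unit renaming and array reordering", {
  set.seed(14)
  d <- fig1$design
  m <- setNames(rnorm(d$n_arrows), d$arrays$array_id)
  fit <- fit_gene(m, d)

  perm <- sample(d$n_arrows)
  d_shuf <- loop_design(d$units, d$arrays[perm, ], d$groups)
  fit_shuf <- fit_gene(m[perm], d_shuf)
  expect_equal(fit_shuf$gamma_hat, fit$gamma_hat, tolerance = 1e-10)
  expect_equal(fit_shuf$lambda_hat[names(fit$lambda_hat)], fit$lambda_hat,
               tolerance = 1e-10)

  ren <- setNames(sprintf("unit_%02d", seq_len(nrow(d$units))),
                  d$units$unit_id)
  d_ren <- loop_design(
    data.frame(unit_id = unname(ren[d$units$unit_id]),
               individual = d$units$individual),
    data.frame(array_id = d$arrays$array_id,
               tail = unname(ren[d$arrays$tail]),
               head = unname(ren[d$arrays$head])))
  fit_ren <- fit_gene(m, d_ren)
  expect_equal(unname(fit_ren$lambda_hat[ren[names(fit$lambda_hat)]]),
               unname(fit$lambda_hat), tolerance = 1e-10)
})

test_that("fit_all counts singular genes and matches fit_gene", {
  cfg <- sim_config(n_genes = 25, seed = 15L)
  tr <- simulate_truth(cfg, fig1$design, fig1$hierarchy)
  sp <- simulate_spots(tr, fig1$design, cfg)
  nr <- normalize_arrays(sp)
  nr$M[nr$gene_id == "g0003"] <- NA  # gene missing on every array
  fit <- loop_fit(nr, fig1$design)
  expect_equal(fit$n_fit, 24L)
  expect_true(fit$singular["g0003"])
  g7 <- fit_gene(setNames(nr$M[nr$gene_id == "g0007"], nr$array_id[nr$gene_id == "g0007"]),
                 fig1$design)
  expect_equal(unname(fit$gamma["g0007"]), g7$gamma_hat, tolerance = 1e-12)
  expect_equal(fit$lambda["g0007", names(g7$lambda_hat)], g7$lambda_hat,
               tolerance = 1e-12)
  expect_equal(unname(fit$sigma["g0007"]), g7$sigma_hat, tolerance = 1e-12)
})

test_that("model methods are mutually consistent", {
  cfg <- sim_config(n_genes = 30, seed = 16L)
  tr <- simulate_truth(cfg, fig1$design, fig1$hierarchy)
  sp <- simulate_spots(tr, fig1$design, cfg)
  fit <- loop_fit(normalize_arrays(sp), fig1$design)
  expect_equal(dim(coef(fit)), c(30L, 13L))
  r <- residuals(fit)
  expect_equal(fit$m - r, fitted(fit))
  expect_equal(unname(rowSums(r^2, na.rm = TRUE)), unname(fit$rss),
               tolerance = 1e-9)
  pr <- predict(fit, arrows = data.frame(tail = "1", head = "2"))
  expect_equal(unname(pr[, 1]),
               unname(fit$gamma + fit$lambda[, "1"] - fit$lambda[, "2"]))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(fit$m))
})

test_that("composite lambda averages children bottom-up", {
  lam <- matrix(c(0.2, 0.4, 0.1, 0.3), 1,
                dimnames = list("g1", c("8-3_1", "8-3_2", "8-1", "8-2")))
  h <- sample_hierarchy(list(`8-3` = c("8-3_1", "8-3_2"),
                             `8` = c("8-1", "8-2", "8-3")))
  comp <- composite_lambda(lam, h)
  expect_equal(unname(comp[, "8-3"]), 0.3)
  expect_equal(unname(comp[, "8"]), mean(c(0.1, 0.3, 0.3)))

  # equal children pass through
  lam2 <- matrix(c(0.7, 0.7, 0.7, 0.7), 1,
                 dimnames = list("g1", c("8-3_1", "8-3_2", "8-1", "8-2")))
  expect_equal(unname(composite_lambda(lam2, h)[, "8"]), 0.7)

  # a missing child propagates missingness upward
  lam[1, "8-3_2"] <- NA
  comp <- composite_lambda(lam, h)
  expect_true(is.na(comp[, "8-3"]))
  expect_true(is.na(comp[, "8"]))
})
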