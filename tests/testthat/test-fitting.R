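# The multi-model fitting path: averaging, sub-model fits, F tests, and
# equivalence with independent full-decomposition oracles.

test_that("averaging produces per-subject means and flags incomplete data", {
  d <- design_2w_mixed(a = 2, b = 2, n = 3)
  spec <- sim_spec(d, variance = c(sigma2 = 1, `Subject(B)` = 1), seed = 5)
  dat <- simulate_dataset(spec)
  av <- average_over(dat, "A", d)
  expect_identical(nrow(av), 6L)  # one record per subject
  m <- tapply(dat$y, dat$Subject, mean)
  expect_equal(av$y, as.numeric(m[as.character(seq_len(6))]))
  # averaging over nothing is the identity on the response
  av0 <- average_over(dat, character(), d)
  expect_equal(av0$y, dat$y)
  expect_error(average_over(dat[-1, ], "A", d),
               class = "peranova_incomplete_data")
  expect_error(average_over(dat, "B", d),
               class = "peranova_unsupported_design")
})

test_that("sub-model residual df equal the planned error df", {
  d <- design_232()
  spec <- spec_232(seed = 8)
  dat <- simulate_dataset(spec)
  plan <- plan_models(derive_ems(d))
  f_res <- fit_submodel(average_over(dat, character(), d),
                        plan$entries[["Residual"]], d)
  expect_identical(f_res$df_resid, 56L)
  f_tex <- fit_submodel(average_over(dat, "Location", d),
                        plan$entries[["Subject(Drink):Texture"]], d)
  expect_identical(f_tex$df_resid, 56L)
  f_bet <- fit_submodel(average_over(dat, c("Location", "Texture"), d),
                        plan$entries[["Subject(Drink)"]], d)
  expect_identical(f_bet$df_resid, 28L)
  # trivial paired design: n = 2 subjects, one 2-level within factor
  dp <- rm_design(within = c(A = 2), n = 2)
  dd <- simulate_dataset(sim_spec(dp, variance = c(sigma2 = 1), seed = 1))
  fp <- fit_submodel(dd, "Residual", dp)
  expect_identical(fp$df_resid, 1L)
})

test_that("rank-1 contrasts give F = t^2 against the paired t-test", {
  d <- rm_design(within = c(A = 2), n = 12)
  dat <- simulate_dataset(sim_spec(d, effects = list(A = c(-0.4, 0.4)),
                                   variance = c(sigma2 = 1,
                                                Subject = 2), seed = 31))
  fit <- run_partitioned_anova(dat, d)
  Fv <- fit$table$F[fit$table$effect == "A"]
  tt <- t.test(dat$y[dat$A == 1], dat$y[dat$A == 2], paired = TRUE)
  expect_equal(Fv, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$table$p[fit$table$effect == "A"], tt$p.value,
               tolerance = 1e-10)
})

test_that("F statistics are invariant to the design-matrix coding", {
  d <- design_2w_mixed(a = 2, b = 2, n = 6)
  dat <- simulate_dataset(sim_spec(d, effects = list(A = c(-0.4, 0.4)),
                                   variance = c(sigma2 = 1,
                                                `Subject(B)` = 1),
                                   seed = 13))
  fits <- lapply(c("overparameterized", "treatment", "sigma_restricted"),
                 function(cod) run_partitioned_anova(dat, d, coding = cod))
  ref <- fits[[1L]]$table$F
  for (f in fits[-1L]) expect_equal(f$table$F, ref, tolerance = 1e-10)
})

test_that("the pipeline matches the full-decomposition oracles exactly", {
  d <- design_232(n = 8)
  spec <- spec_232(n = 8, seed = 17)
  dat <- simulate_dataset(spec)
  fit <- run_partitioned_anova(dat, d)
  orc <- oracle_3way_mixed(dat)
  tab <- fit$table
  for (nm in c("A", "B", "C", "AB", "AC", "BC", "ABC")) {
    Fv <- tab$F[tab$effect == oracle_label_map[nm]]
    expect_equal(Fv, unname(orc$F[nm]), tolerance = 1e-8)
    expect_equal(tab$SS[tab$effect == oracle_label_map[nm]],
                 unname(orc$SS[nm]), tolerance = 1e-8)
  }
  # cross-check the hand oracle itself against aov on the same data
  adat <- data.frame(L = factor(dat$Location), T = factor(dat$Texture),
                     D = factor(dat$Drink), S = factor(dat$Subject),
                     y = dat$y)
  ao <- summary(aov(y ~ L * T * D + Error(S / (L * T)), data = adat))
  aF <- ao[["Error: S"]][[1L]]["D", "F value"]
  expect_equal(unname(orc$F["C"]), aF, tolerance = 1e-10)
})

test_that("averaged sub-model SS scale by the averaged level count, F unchanged", {
  d <- design_232(n = 8)
  dat <- simulate_dataset(spec_232(n = 8, seed = 23))
  fit <- run_partitioned_anova(dat, d)
  orc <- oracle_3way_mixed(dat)
  plan <- fit$plan
  # the table reports full-decomposition-scale SS; the raw sub-model SS
  # differ by exactly the averaging factor (2, 3, and 6 here)
  for (en in names(plan$entries)) {
    scale <- prod(vapply(plan$entries[[en]]$average_over, function(f)
      d$factors[[f]]$levels[1L], 0))
    if (!length(plan$entries[[en]]$average_over)) scale <- 1
    fs <- fit_submodel(average_over(dat, plan$entries[[en]]$average_over, d),
                       plan$entries[[en]], d)
    onm <- names(oracle_label_map)[oracle_label_map == en]
    expect_equal(fs$rss * scale, unname(orc$SS[onm]), tolerance = 1e-8)
  }
  expect_identical(
    vapply(plan$entries, function(e) {
      s <- vapply(e$average_over, function(f) d$factors[[f]]$levels[1L], 0)
      prod(s)
    }, 0)[c("Subject(Drink)", "Subject(Drink):Location",
            "Subject(Drink):Texture", "Residual")],
    c(`Subject(Drink)` = 6, `Subject(Drink):Location` = 3,
      `Subject(Drink):Texture` = 2, Residual = 1))
})

test_that("zero within-subject variance yields an infinite F flag", {
  d <- rm_design(within = c(A = 2), n = 4)
  obs <- expand.grid(A = 1:2, Subject = 1:4)
  obs$y <- c(1, 2)[obs$A] + obs$Subject  # no noise around the A effect
  fit <- run_partitioned_anova(obs, d)
  expect_identical(fit$table$F[fit$table$effect == "A"], Inf)
})

test_that("unbalanced groups: between test equals the unweighted t on subject means", {
  d <- rm_design(within = c(A = 3), between = c(B = 2), n = c(5, 9))
  dat <- simulate_dataset(sim_spec(d, effects = list(B = c(-0.5, 0.5)),
                                   variance = c(sigma2 = 1,
                                                `Subject(B)` = 1),
                                   seed = 41))
  fit <- run_partitioned_anova(dat, d)
  sm <- aggregate(y ~ Subject + B, dat, mean)
  tt <- t.test(y ~ B, sm, var.equal = TRUE)
  expect_equal(fit$table$F[fit$table$effect == "B"],
               unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("partitioned within-subject tests outpower the pooled-error test", {
  d <- design_2w_mixed(a = 2, b = 2, n = 8)
  set.seed(99)
  n_rep <- 200
  part_rej <- pool_rej <- 0
  for (i in seq_len(n_rep)) {
    dat <- simulate_dataset(sim_spec(d, effects = list(A = c(-0.35, 0.35)),
                                     variance = c(sigma2 = 0.6,
                                                  `Subject(B)` = 2)))
    fit <- run_partitioned_anova(dat, d)
    tab <- fit$table
    part_rej <- part_rej + (tab$p[tab$effect == "A"] < 0.05)
    # pooled-error test: single model, all random strata lumped together
    errs <- tab[startsWith(tab$effect, "Error"), ]
    ssp <- sum(errs$SS); dfp <- sum(errs$df)
    Fp <- tab$MS[tab$effect == "A"] / (ssp / dfp)
    pool_rej <- pool_rej + (pf(Fp, 1, dfp, lower.tail = FALSE) < 0.05)
  }
  expect_gte(part_rej, pool_rej)
})

test_that("run_partitioned_anova table is ordered stratum-wise as published", {
  dat <- simulate_dataset(spec_232(seed = 3))
  fit <- run_partitioned_anova(dat, design_232())
  expect_identical(fit$table$effect,
                   c("Drink", "Error: Subject(Drink)",
                     "Location", "Location:Drink",
                     "Error: Subject(Drink):Location",
                     "Texture", "Texture:Drink",
                     "Error: Subject(Drink):Texture",
                     "Location:Texture", "Location:Texture:Drink",
                     "Error: Residual"))
  expect_equal(fit$table$df,
               c(1, 28, 1, 1, 28, 2, 2, 56, 2, 2, 56))
})
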