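# The EMS bookkeeping tables for the three canonical layouts: every
# coefficient cell is asserted (rows are model-term variances, columns the
# EMS they enter).

expected_matrix <- function(labs, cells) {
  M <- matrix("0", length(labs), length(labs), dimnames = list(labs, labs))
  M["Residual", ] <- "1"
  for (cl in cells) M[cl[1L], cl[2L]] <- cl[3L]
  M
}

test_that("EMS table of the two-way between-subjects layout", {
  d <- rm_design(between = c(A = 3, B = 2), n = 4)
  M <- ems_table_matrix(derive_ems(d))
  labs <- c("A", "B", "A:B", "Residual")
  exp <- expected_matrix(labs, list(
    c("A", "A", "bn"), c("B", "B", "an"), c("A:B", "A:B", "n")))
  expect_identical(M, exp)
})

test_that("EMS table of the single-within single-between mixed layout", {
  d <- design_2w_mixed(a = 2, b = 2, n = 5)
  M <- ems_table_matrix(derive_ems(d))
  labs <- c("A", "B", "A:B", "Subject(B)", "Residual")
  exp <- expected_matrix(labs, list(
    c("A", "A", "bn"), c("B", "B", "an"), c("A:B", "A:B", "n"),
    c("Subject(B)", "B", "a"), c("Subject(B)", "Subject(B)", "a")))
  expect_identical(M, exp)
})

test_that("EMS table of the two-within one-between mixed layout", {
  d <- design_232()
  M <- ems_table_matrix(derive_ems(d))
  S <- "Subject(Drink)"; SA <- "Subject(Drink):Location"
  SB <- "Subject(Drink):Texture"
  labs <- c("Location", "Texture", "Drink", "Location:Texture",
            "Location:Drink", "Texture:Drink", "Location:Texture:Drink",
            S, SA, SB, "Residual")
  expect_identical(rownames(M), labs)
  exp <- expected_matrix(labs, list(
    c("Location", "Location", "bcn"),
    c("Texture", "Texture", "acn"),
    c("Drink", "Drink", "abn"),
    c("Location:Texture", "Location:Texture", "cn"),
    c("Location:Drink", "Location:Drink", "bn"),
    c("Texture:Drink", "Texture:Drink", "an"),
    c("Location:Texture:Drink", "Location:Texture:Drink", "n"),
    c(S, "Drink", "ab"), c(S, S, "ab"),
    c(SA, "Location", "b"), c(SA, "Location:Drink", "b"), c(SA, SA, "b"),
    c(SB, "Texture", "a"), c(SB, "Texture:Drink", "a"), c(SB, SB, "a")))
  expect_identical(M, exp)
})

test_that("degenerate one-way fixed ANOVA EMS", {
  d <- rm_design(between = c(A = 4), n = 3)
  M <- ems_table_matrix(derive_ems(d))
  expect_identical(M["A", "A"], "n")  # replicates-per-cell coefficient only
  expect_identical(M["Residual", ], c(A = "1", Residual = "1"))
})

test_that("error-term selection reproduces the F-ratio assignments", {
  e1 <- derive_ems(rm_design(between = c(A = 3, B = 2), n = 4))
  for (eff in c("A", "B", "A:B")) {
    expect_identical(select_error_term(e1, eff), "Residual")
  }
  e2 <- derive_ems(design_2w_mixed())
  expect_identical(select_error_term(e2, "A"), "Residual")
  expect_identical(select_error_term(e2, "B"), "Subject(B)")
  expect_identical(select_error_term(e2, "A:B"), "Residual")
  e3 <- derive_ems(design_232())
  expect_identical(select_error_term(e3, "Location"),
                   "Subject(Drink):Location")
  expect_identical(select_error_term(e3, "Texture"),
                   "Subject(Drink):Texture")
  expect_identical(select_error_term(e3, "Drink"), "Subject(Drink)")
  expect_identical(select_error_term(e3, "Location:Texture"), "Residual")
  expect_identical(select_error_term(e3, "Location:Drink"),
                   "Subject(Drink):Location")
  expect_identical(select_error_term(e3, "Texture:Drink"),
                   "Subject(Drink):Texture")
  expect_identical(select_error_term(e3, "Location:Texture:Drink"),
                   "Residual")
})

test_that("a fixed factor crossed with two random factors has no exact denominator", {
  d <- rm_design(factors = list(
    rm_factor("A", 3, "fixed", "between"),
    rm_factor("B", 4, "random", "between"),
    rm_factor("C", 2, "random", "between")), reps = 5)
  e <- derive_ems(d)
  expect_error(select_error_term(e, "A"), class = "peranova_quasi_f")
  expect_error(plan_models(e), class = "peranova_quasi_f")
  # brute-force confirmation: no term's EMS equals EMS_A minus its own Q
  rem <- setdiff(ems_keys(e, "A"), "B*C*.rep|Q_A")
  for (lab in setdiff(names(e$rows), "A")) {
    expect_false(identical(ems_keys(e, lab), sort(rem)))
  }
})

test_that("EMS identity: EMS(effect) = EMS(error term) + own component", {
  designs <- list(design_232(), design_2w_mixed(3, 2, 6),
                  rm_design(between = c(A = 2, B = 3), n = 4),
                  rm_design(within = c(A = 4), n = 10))
  for (d in designs) {
    e <- derive_ems(d)
    fixed <- names(e$terms)[!vapply(e$terms, `[[`, TRUE, "random")]
    for (eff in fixed) {
      err <- select_error_term(e, eff)
      own <- paste0(paste(sort(e$rows[[eff]][[
        which(vapply(e$rows[[eff]], function(cm)
          cm$symbol == e$terms[[eff]]$symbol, TRUE))]]$coef),
        collapse = "*"), "|", e$terms[[eff]]$symbol)
      expect_identical(ems_keys(e, eff), sort(c(ems_keys(e, err), own)))
    }
    # every EMS row carries the residual variance with coefficient 1
    for (lab in names(e$rows)) {
      expect_true("|sigma2" %in% ems_keys(e, lab))
    }
  }
})

test_that("model plans have one entry per stratum and cover each fixed effect once", {
  p3 <- plan_models(derive_ems(design_232()))
  expect_length(p3$entries, 4L)
  expect_identical(p3$entries[["Subject(Drink)"]]$average_over,
                   c("Location", "Texture"))
  expect_identical(p3$entries[["Subject(Drink)"]]$effects_tested, "Drink")
  expect_identical(p3$entries[["Subject(Drink):Location"]]$average_over,
                   "Texture")
  expect_identical(p3$entries[["Subject(Drink):Location"]]$effects_tested,
                   c("Location", "Location:Drink"))
  expect_identical(p3$entries[["Subject(Drink):Texture"]]$average_over,
                   "Location")
  expect_identical(p3$entries[["Residual"]]$average_over, character())
  expect_identical(p3$entries[["Residual"]]$effects_tested,
                   c("Location:Texture", "Location:Texture:Drink"))
  p2 <- plan_models(derive_ems(design_2w_mixed()))
  expect_length(p2$entries, 2L)
  expect_identical(p2$entries[["Subject(B)"]]$average_over, "A")
  expect_identical(p2$entries[["Residual"]]$effects_tested, c("A", "A:B"))
  p1 <- plan_models(derive_ems(rm_design(between = c(A = 2, B = 2), n = 5)))
  expect_length(p1$entries, 1L)
  expect_identical(p1$entries[["Residual"]]$average_over, character())
  # coverage: every fixed effect tested exactly once
  for (p in list(p3, p2, p1)) {
    eff <- unlist(lapply(p$entries, `[[`, "effects_tested"))
    fixed <- names(p$ems$terms)[!vapply(p$ems$terms, `[[`, TRUE, "random")]
    expect_setequal(eff, fixed)
    expect_false(anyDuplicated(eff) > 0)
  }
})

test_that("degrees of freedom match the worked ANOVA and ANCOVA tables", {
  d <- design_232()
  df <- compute_df(d)
  expect_identical(unname(df[c("Drink", "Subject(Drink)", "Location",
                               "Location:Drink",
                               "Subject(Drink):Location",
                               "Texture", "Texture:Drink",
                               "Subject(Drink):Texture",
                               "Location:Texture",
                               "Location:Texture:Drink", "Residual")]),
                   c(1, 28, 1, 1, 28, 2, 2, 56, 2, 2, 56))
  dfc <- compute_df(d, covariates = list(
    covariate_spec("x", varies_over = c("Location", "Texture"))))
  expect_identical(unname(dfc[c("Subject(Drink)",
                                "Subject(Drink):Location",
                                "Subject(Drink):Texture", "Residual")]),
                   c(27, 27, 54, 54))
  # a covariate varying over one within factor only
  dfl <- compute_df(d, covariates = list(
    covariate_spec("x", varies_over = "Location")))
  expect_identical(unname(dfl[c("Subject(Drink)",
                                "Subject(Drink):Location",
                                "Subject(Drink):Texture", "Residual")]),
                   c(27, 27, 56, 56))
  # paired-comparison limit
  dp <- rm_design(within = c(A = 2), n = 9)
  dfp <- compute_df(dp)
  expect_identical(unname(dfp[c("A", "Residual")]), c(1, 8))
  # degenerate: one subject per group
  expect_error(compute_df(design_232(n = 1)),
               class = "peranova_degenerate_design")
})

test_that("Monte-Carlo mean squares recover the EMS predictions", {
  d <- rm_design(within = c(A = 3), between = c(B = 2), n = 20)
  spec <- sim_spec(d, variance = c(sigma2 = 1, `Subject(B)` = 2),
                   seed = 2024)
  mc <- monte_carlo_ems_check(spec, n_reps = 400)
  expect_equal(mc$ems[mc$term == "Subject(B)"], 1 + 3 * 2)
  expect_true(all(abs(mc$z) < 3.5))
})
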