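# Contrast derivation from design-matrix rows: the printed weight vectors
# for the 2 x 2 mixed design with two subjects per group, across codings.

d22 <- rm_design(within = c(A = 2), between = c(B = 2), n = 2)

test_that("overparameterized design matrix rows and marginal-mean weights", {
  X <- build_design_matrix(d22)
  expect_identical(dim(unclass(X)), c(8L, 13L))
  expect_equal(unname(unclass(X)[1, ]),
               c(1, 1, 0, 1, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  GA1 <- marginal_mean_weights(X, list(A = 1))
  expect_equal(as.numeric(GA1),
               c(1, 1, 0, 1/2, 1/2, 1/2, 0, 1/2, 0, 1/4, 1/4, 1/4, 1/4))
  GB1 <- marginal_mean_weights(X, list(B = 1))
  expect_equal(as.numeric(GB1),
               c(1, 1/2, 1/2, 1, 0, 1/2, 1/2, 0, 0, 1/2, 1/2, 0, 0))
  # exact rational bookkeeping
  expect_equal(attr(GA1, "den"), 4)
  expect_error(marginal_mean_weights(X, list(A = 3)),
               class = "peranova_incomplete_data")
  # intercept-only degenerate case
  d1 <- rm_design(between = c(G = 1), n = 4)
  X1 <- build_design_matrix(d1, coding = "cell_means")
  expect_equal(as.numeric(marginal_mean_weights(X1, list())), c(1, 1))
})

test_that("main-effect weights: subject terms cancel within, not between", {
  X <- build_design_matrix(d22)
  LA <- derive_effect_contrast(X, "A")
  expect_equal(unname(LA$weights[1, ]),
               c(0, 1, -1, 0, 0, 1/2, -1/2, 1/2, -1/2, 0, 0, 0, 0))
  expect_true(LA$subject_zero)
  expect_true(LA$estimable)
  expect_identical(LA$required_error, "Residual")
  LB <- derive_effect_contrast(X, "B")
  expect_equal(unname(LB$weights[1, ]),
               c(0, 0, 0, 1, -1, 1/2, 1/2, -1/2, -1/2, 1/2, 1/2, -1/2, -1/2))
  expect_false(LB$subject_zero)
  expect_true(LB$estimable)
  expect_identical(LB$required_error, "Subject(B)")
})

test_that("constrained codings give the printed weights", {
  Xb <- build_design_matrix(d22, coding = "treatment")
  expect_identical(ncol(Xb), 6L)
  expect_equal(unname(derive_effect_contrast(Xb, "A")$weights[1, ]),
               c(0, 1, 0, 1/2, 0, 0))
  expect_equal(unname(derive_effect_contrast(Xb, "B")$weights[1, ]),
               c(0, 0, 1, 1/2, 1/2, -1/2))
  Xc <- build_design_matrix(d22, coding = "sigma_restricted")
  expect_identical(ncol(Xc), 6L)
  LAc <- derive_effect_contrast(Xc, "A")
  expect_equal(unname(LAc$weights[1, ]), c(0, 2, 0, 0, 0, 0))
  expect_true(LAc$subject_zero)
  LBc <- derive_effect_contrast(Xc, "B")
  expect_equal(unname(LBc$weights[1, ]), c(0, 0, 2, 0, 1/2, -1/2))
  expect_false(LBc$subject_zero)
})

test_that("simple-effect weights carry the error-term caveat", {
  X <- build_design_matrix(d22)
  s1 <- derive_simple_effect_contrast(X, "A", at = list(B = 1))
  expect_equal(unname(s1$weights[1, ]),
               c(0, 1, -1, 0, 0, 1, -1, 0, 0, 0, 0, 0, 0))
  expect_true(s1$subject_zero)
  s2 <- derive_simple_effect_contrast(X, "B", at = list(A = 1))
  expect_equal(unname(s2$weights[1, ]),
               c(0, 0, 0, 1, -1, 1, 0, -1, 0, 1/2, 1/2, -1/2, -1/2))
  expect_false(s2$subject_zero)
  expect_identical(s2$required_error, "Subject(B)")
  expect_match(s2$note, "A=1")
  # one-group within design: simple effect reduces to the main effect
  dw <- rm_design(within = c(A = 2), n = 3)
  Xw <- build_design_matrix(dw)
  expect_equal(derive_simple_effect_contrast(Xw, "A")$weights,
               derive_effect_contrast(Xw, "A")$weights)
})

test_that("estimability detects hand-zeroed subject weights", {
  X <- build_design_matrix(d22)
  LB <- derive_effect_contrast(X, "B")
  expect_true(check_estimable(X, LB$weights))
  zeroed <- LB$weights
  zeroed[, attr(X, "col_info")$is_subject] <- 0
  expect_false(check_estimable(X, zeroed))
  expect_true(check_estimable(X, rep(0, ncol(X))))
})

test_that("unique-row reduction is stable and idempotent", {
  X <- build_design_matrix(d22)
  U <- reduce_unique_rows(X, drop_subject_columns = TRUE)
  expect_identical(nrow(U), 4L)
  expect_identical(ncol(U), 9L)
  # first-occurrence order: rows of subject 1 then the first novel rows
  expect_equal(unname(unclass(U)[1, ]), c(1, 1, 0, 1, 0, 1, 0, 0, 0))
  expect_identical(unclass(reduce_unique_rows(U)), unclass(U))
})

test_that("contrast row sums vanish over effect blocks and balance over others", {
  X <- build_design_matrix(design_232(n = c(3, 4)))
  ci <- attr(X, "col_info")
  for (eff in c("Location", "Texture", "Drink", "Location:Texture",
                "Texture:Drink")) {
    L <- derive_effect_contrast(X, eff, rows = "unique")
    for (blk in unique(ci$term[!ci$is_subject])) {
      s <- rowSums(L$weights[, ci$term == blk, drop = FALSE])
      expect_equal(unname(s), rep(0, nrow(L$weights)), tolerance = 1e-12)
    }
  }
})

test_that("subject_zero agrees with the EMS across the three-way design", {
  d <- design_232(n = 4)
  X <- build_design_matrix(d)
  e <- derive_ems(d)
  fixed <- names(e$terms)[!vapply(e$terms, `[[`, TRUE, "random")]
  for (eff in fixed) {
    L <- derive_effect_contrast(X, eff)
    pure_sigma <- identical(select_error_term(e, eff), "Residual")
    expect_identical(L$subject_zero, pure_sigma)
  }
})
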