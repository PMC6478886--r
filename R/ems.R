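#' Derive expected mean squares for a design
#'
#' Applies the classical tabular bookkeeping for expected mean squares (EMS)
#' to every term of the model implied by a design specification. Each term's
#' EMS is a linear combination of variance components (for random terms) and
#' fixed-effect quadratic forms `Q_<term>` (shorthand for the sum of squared
#' effects divided by the term's degrees of freedom), with coefficients that
#' are products of the level counts of the absent subscripts. The table is
#' symbolic: coefficients are stored as the set of factors whose level
#' counts multiply, so it can be printed with level-count symbols or
#' evaluated numerically on demand. Unbalanced group sizes are handled by
#' deriving the EMS on the balanced template, which is sufficient for
#' identifying error terms.
#'
#' @param design An [rm_design()] object.
#' @return An object of class `"ems_table"`: for every model term, the list
#'   of `(coefficient, symbol)` components of its EMS.
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 10)
#' derive_ems(d)
#' @export
derive_ems <- function(design) {
  stopifnot(inherits(design, "rm_design"))
  if (!is.na(design$unit)) {
    others <- setdiff(names(design$factors), design$unit)
    if (any(vapply(design$factors[others], `[[`, "", "kind") == "random")) {
      pe_stop("random factors crossed with the subject factor are not supported",
              "peranova_unsupported_design")
    }
    if (any(design$reps > 1L)) {
      pe_stop("replicates within subject-cells are not supported",
              "peranova_unsupported_design")
    }
  }
  terms <- design_terms(design)
  # table entry for term U at index column s
  entry <- function(U, s) {
    if (s %in% U$bracketed) return("1")
    if (s %in% U$subscripts) {
      return(if (index_random(design, s)) "1" else "0")
    }
    s  # absent index contributes its level count
  }
  all_idx <- terms[["Residual"]]$subscripts
  rows <- list()
  for (T in terms) {
    comps <- list()
    for (U in terms) {
      if (!all(T$subscripts %in% U$subscripts)) next
      es <- vapply(setdiff(all_idx, T$subscripts),
                   function(s) entry(U, s), "")
      if (any(es == "0")) next
      coef <- sort(es[es != "1"])
      comps[[length(comps) + 1L]] <- list(coef = coef, symbol = U$symbol,
                                          term = U$label)
    }
    rows[[T$label]] <- comps
  }
  structure(list(design = design, terms = terms, rows = rows),
            class = "ems_table")
}

# canonical string form of one EMS component / row, used for the
# "differ only by the effect's own component" comparison
comp_key <- function(comp) {
  paste0(paste(comp$coef, collapse = "*"), "|", comp$symbol)
}
row_keys <- function(comps) sort(vapply(comps, comp_key, ""))

coef_string <- function(design, coef) {
  if (!length(coef)) return("")
  paste0(paste(vapply(coef, function(s) index_symbol(design, s), ""),
               collapse = ""), "*")
}

#' EMS coefficients in tabular form
#'
#' Returns the classical EMS bookkeeping table as a character matrix: one
#' row per model term, one column per term's EMS, each cell holding the
#' symbolic coefficient ("bn", "a", "1", ...) with which the row term's
#' variance (or quadratic form) enters the column term's EMS, or "0" when
#' it is absent.
#'
#' @param ems An `"ems_table"` from [derive_ems()].
#' @return Character matrix with model-term dimnames.
#' @export
ems_table_matrix <- function(ems) {
  stopifnot(inherits(ems, "ems_table"))
  design <- ems$design
  labs <- names(ems$terms)
  ord <- c(setdiff(names(design$factors), design$unit), design$unit, ".rep")
  out <- matrix("0", length(labs), length(labs),
                dimnames = list(labs, labs))
  for (Tl in labs) {
    for (cm in ems$rows[[Tl]]) {
      coef <- cm$coef[order(match(cm$coef, ord))]
      out[cm$term, Tl] <- if (!length(coef)) "1"
        else paste(vapply(coef, function(s) index_symbol(design, s), ""),
                   collapse = "")
    }
  }
  out
}

#' @export
print.ems_table <- function(x, ...) {
  cat("Expected mean squares\n")
  for (lab in names(x$rows)) {
    comps <- rev(x$rows[[lab]])  # residual variance first, own term last
    txt <- vapply(comps, function(cm) {
      paste0(coef_string(x$design, cm$coef), cm$symbol)
    }, "")
    cat(sprintf("  EMS[%s] = %s\n", lab, paste(txt, collapse = " + ")))
  }
  invisible(x)
}

#' Select the exact error term for an effect
#'
#' An F-ratio tests an effect exactly when numerator and denominator EMS
#' differ only by the effect's own component. This function removes the
#' effect's own variance/quadratic-form component from its EMS row and
#' searches the table for the unique term whose EMS equals the remainder.
#' If no term matches, no exact denominator exists (a quasi-F ratio would be
#' required) and an error of class `"peranova_quasi_f"` is raised naming the
#' unmatched components; the function never silently falls back to the
#' residual.
#'
#' @param ems An `"ems_table"` from [derive_ems()].
#' @param effect Label of a non-residual model term (e.g. `"A"`,
#'   `"A:B"`).
#' @return The label of the error term.
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 10)
#' e <- derive_ems(d)
#' select_error_term(e, "B")   # the subject stratum
#' select_error_term(e, "A")   # the residual
#' @export
select_error_term <- function(ems, effect) {
  stopifnot(inherits(ems, "ems_table"))
  if (!effect %in% names(ems$rows) || identical(effect, "Residual")) {
    pe_stop(sprintf("'%s' is not a testable model term", effect),
            "peranova_unsupported_design")
  }
  own_sym <- ems$terms[[effect]]$symbol
  row <- ems$rows[[effect]]
  own <- vapply(row, function(cm) cm$symbol == own_sym, TRUE)
  remainder <- row_keys(row[!own])
  cand <- character()
  for (lab in names(ems$rows)) {
    if (lab == effect) next
    if (identical(row_keys(ems$rows[[lab]]), remainder)) cand <- c(cand, lab)
  }
  if (length(cand) == 0L) {
    pe_stop(sprintf(
      "no exact error term for '%s': no mean square has EMS matching %s (a quasi-F ratio would be required)",
      effect, paste(remainder, collapse = " + ")),
      "peranova_quasi_f")
  }
  if (length(cand) > 1L) {
    pe_stop(sprintf("ambiguous error term for '%s': %s all match",
                    effect, paste(cand, collapse = ", ")),
            "peranova_ambiguous_error_term")
  }
  cand
}

#' Plan the set of sub-models implied by the error structure
#'
#' A single-error-term GLM can only use its own residual as the F-test
#' denominator. Each distinct error stratum therefore requires its own
#' sub-model, in which the within-subject factors *not* tested under that
#' stratum are averaged over: after averaging, the stratum's random term
#' becomes perfectly collinear with the residuals and is thereby enforced as
#' the model's error. The plan lists, per stratum, the factors to average
#' over and the effects tested there.
#'
#' @param ems An `"ems_table"` from [derive_ems()].
#' @param design Optional design (defaults to the one in `ems`).
#' @return An object of class `"model_plan"`; one entry per error stratum,
#'   ordered subject stratum first, residual last.
#' @examples
#' d <- rm_design(within = c(Location = 2, Texture = 3),
#'                between = c(Drink = 2), n = c(14, 16))
#' plan_models(derive_ems(d))
#' @export
plan_models <- function(ems, design = ems$design) {
  stopifnot(inherits(ems, "ems_table"))
  terms <- ems$terms
  strata <- names(terms)[vapply(terms, function(t)
    t$random && (t$is_residual || !is.na(design$unit) &&
                   design$unit %in% t$subscripts), TRUE)]
  fixed <- names(terms)[!vapply(terms, `[[`, TRUE, "random")]
  err <- vapply(fixed, function(e) select_error_term(ems, e), "")
  bad <- setdiff(err, strata)
  if (length(bad)) {
    pe_stop(sprintf("effects tested against non-stratum term(s): %s",
                    paste(bad, collapse = ", ")),
            "peranova_unsupported_design")
  }
  entries <- lapply(strata, function(s) {
    W <- terms[[s]]$within_part
    list(error_term = s,
         within_kept = W,
         average_over = setdiff(design$within, W),
         effects_tested = fixed[err == s])
  })
  names(entries) <- strata
  plan <- structure(list(design = design, ems = ems, entries = entries),
                    class = "model_plan")
  if (!any(is.na(unlist(design_levels(design))))) {
    df <- compute_df(design, plan)
    for (s in strata) plan$entries[[s]]$df_error <- unname(df[s])
  }
  plan
}

#' @export
print.model_plan <- function(x, ...) {
  cat(sprintf("Model plan: %d sub-model(s)\n", length(x$entries)))
  for (e in x$entries) {
    avg <- if (length(e$average_over))
      paste(e$average_over, collapse = ", ") else "(nothing)"
    eff <- if (length(e$effects_tested))
      paste(e$effects_tested, collapse = ", ") else "(none)"
    dfe <- if (!is.null(e$df_error)) sprintf(" [error df %g]", e$df_error)
           else ""
    cat(sprintf("  error: %-35s average over: %-20s tests: %s%s\n",
                e$error_term, avg, eff, dfe))
  }
  invisible(x)
}

#' Degrees of freedom for every effect and error stratum
#'
#' Fixed-effect df are products of (levels - 1) over the effect's factors;
#' the subject stratum has (total subjects - number of groups) df; a
#' subject-by-within stratum multiplies the subject df by the within
#' factors' (levels - 1). Group sizes may be unbalanced. Continuous
#' covariates are charged one df at the subject level of every stratum in
#' which a distinct regression slope exists (i.e. every stratum whose
#' within-factor set the covariate varies over), so a fully within-subject
#' covariate reduces the subject df entering each stratum by one before the
#' within multiplication.
#'
#' @param design An [rm_design()] object with numeric level counts.
#' @param plan Optional `"model_plan"` (recomputed if missing).
#' @param covariates Optional list of covariate specifications as returned
#'   by [covariate_spec()], used to adjust the error df.
#' @return Named integer vector: effects and error strata in reporting
#'   order.
#' @examples
#' d <- rm_design(within = c(Location = 2, Texture = 3),
#'                between = c(Drink = 2), n = c(14, 16))
#' compute_df(d)
#' @export
compute_df <- function(design, plan = NULL, covariates = NULL) {
  stopifnot(inherits(design, "rm_design"))
  lev <- design_levels(design)
  if (any(is.na(unlist(lev)))) {
    pe_stop("numeric level counts are required to compute df",
            "peranova_degenerate_design")
  }
  if (is.null(plan)) plan <- plan_models(derive_ems(design), design)
  terms <- plan$ems$terms
  fdf <- function(fs) prod(vapply(fs, function(f) lev[[f]][1L] - 1L, 0))
  gn <- design_group_n(design)
  sdf <- if (!is.null(gn)) sum(gn) - length(gn) else NA_integer_
  cov_in_stratum <- function(W) {
    if (is.null(covariates)) return(0L)
    sum(vapply(covariates, function(cv) all(W %in% cv$varies_over), TRUE))
  }
  out <- numeric(0)
  for (e in plan$entries) {
    for (eff in e$effects_tested) {
      out[eff] <- fdf(terms[[eff]]$fixed_factors)
    }
    if (terms[[e$error_term]]$is_residual && is.na(design$unit)) {
      ncell <- prod(vapply(setdiff(names(design$factors), design$unit),
                           function(f) lev[[f]][1L], 0))
      N <- sum(rep(design$reps, length.out = ncell))
      out[e$error_term] <- N - ncell - cov_in_stratum(e$within_kept)
    } else {
      out[e$error_term] <- (sdf - cov_in_stratum(e$within_kept)) *
        fdf(e$within_kept)
    }
  }
  if (any(out <= 0)) {
    pe_stop(sprintf("non-positive degrees of freedom for: %s",
                    paste(names(out)[out <= 0], collapse = ", ")),
            "peranova_degenerate_design")
  }
  out
}
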