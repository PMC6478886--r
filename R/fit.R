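## Partitioned-error fitting: each error stratum gets its own sub-model in
## which the within-subject factors not tested there are averaged over; the
## stratum's random term is then perfectly collinear with the residuals and
## becomes the enforced error term.  All sums of squares are computed as
## contrast quadratic forms against pseudoinverse fits, which keeps one code
## path for balanced and unbalanced group sizes (Type III).

#' Average a long dataset over within-subject factors
#'
#' Per subject and per retained cell, the response (and any numeric
#' covariate columns) is replaced by its arithmetic mean over the levels of
#' the averaged factors. Averaging is the device that enforces an error
#' stratum in a single-error-term GLM. Factor columns in the result are
#' 1-based level indices; rows are ordered subject-major with retained
#' within cells varying first-factor-fastest.
#'
#' @param data Long-format data frame (subject column, one column per
#'   factor, response, optional covariates).
#' @param factors Character vector of within-subject factors to average
#'   over (may be empty, in which case the data are returned in normalized
#'   form unchanged).
#' @param design An [rm_design()] object.
#' @param response Name of the response column.
#' @return A data frame with one row per subject and retained within-cell.
#' @export
average_over <- function(data, factors, design, response = "y") {
  bad <- setdiff(factors, design$within)
  if (length(bad)) {
    pe_stop(paste("not within-subject factors:", paste(bad, collapse = ", ")),
            "peranova_unsupported_design")
  }
  obs <- normalize_obs(design, data)
  lev <- design_levels(design)
  keepw <- setdiff(design$within, factors)
  nw <- if (length(keepw))
    prod(vapply(keepw, function(f) lev[[f]][1L], 0)) else 1L
  wcell <- if (length(keepw))
    interaction_index(obs[keepw], vapply(keepw, function(f) lev[[f]][1L], 0L))
  else rep(1L, nrow(obs))
  sid <- obs[[design$unit]]
  tidx <- (sid - 1L) * nw + wcell
  nsub <- max(sid)
  counts <- tabulate(tidx, nbins = nsub * nw)
  need <- prod(vapply(factors, function(f) lev[[f]][1L], 0))
  if (!length(factors)) need <- 1L
  if (any(counts != need)) {
    pe_stop("incomplete within-subject data: every subject needs a complete crossing of within-factor levels",
            "peranova_incomplete_data")
  }
  valcols <- c(response,
               setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                       c(response, names(design$factors))))
  out <- data.frame(rep(seq_len(nsub), each = nw))
  names(out) <- design$unit
  if (length(keepw)) {
    combos <- expand.grid(lapply(lev[keepw], function(m) seq_len(m[1L])))
    for (f in keepw) out[[f]] <- rep(combos[[f]], times = nsub)
  }
  grp <- subject_groups(design, obs)
  if (length(design$between)) {
    gcells <- expand.grid(lapply(lev[design$between],
                                 function(m) seq_len(m[1L])))
    for (b in design$between) out[[b]] <- gcells[[b]][grp[out[[design$unit]]]]
  }
  for (v in valcols) {
    out[[v]] <- as.vector(rowsum(data[[v]], tidx)) / counts
  }
  out
}

# design restricted to the factors kept in a sub-model
sub_design_for <- function(design, keep_within) {
  lev <- design_levels(design)
  w <- if (length(keep_within))
    vapply(keep_within, function(f) lev[[f]][1L], 0L) else NULL
  b <- if (length(design$between))
    vapply(design$between, function(f) lev[[f]][1L], 0L) else NULL
  gn <- design_group_n(design)
  if (!is.null(w)) {
    rm_design(within = w, between = b, n = gn, subject = design$unit)
  } else if (!is.null(b)) {
    rm_design(between = b, n = gn)
  } else {
    NULL  # intercept-only sub-model (single group, fully averaged)
  }
}

#' Fit one sub-model of a partitioned-error plan
#'
#' Fits, by pseudoinverse, the GLM for one error stratum on data already
#' averaged over the stratum's absent within factors. The model contains
#' the intercept, all fixed terms of the retained factors, the subject
#' blocks, and every subject-by-within block short of the stratum itself
#' (which would be perfectly collinear with the residuals and is thereby
#' the enforced error term).
#'
#' @param data Averaged long-format data (see [average_over()]).
#' @param entry One entry of a [plan_models()] plan (or the name of its
#'   error stratum).
#' @param design The full [rm_design()].
#' @param response Response column name.
#' @param coding Design-matrix coding.
#' @param extra_columns Optional numeric matrix of extra regressors
#'   (e.g. decomposed covariates), appended after the factor columns.
#' @return A `"pe_submodel"`: design matrix, pseudoinverse fit,
#'   residual sum of squares and df, and the averaging scale factor.
#' @export
fit_submodel <- function(data, entry, design, response = "y",
                         coding = "overparameterized",
                         extra_columns = NULL) {
  if (is.character(entry)) {
    plan <- plan_models(derive_ems(design), design)
    entry <- plan$entries[[entry]]
    if (is.null(entry)) {
      pe_stop("unknown error stratum", "peranova_unsupported_design")
    }
  }
  sdes <- sub_design_for(design, entry$within_kept)
  if (is.null(sdes)) {
    X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "mu"))
    attr(X, "col_info") <- data.frame(label = "mu", term = "(Intercept)",
                                      is_subject = FALSE)
    class(X) <- c("rm_design_matrix", "matrix", "array")
  } else {
    X <- build_design_matrix(sdes, coding = coding, data = data)
  }
  Xm <- unclass(X)
  if (!is.null(extra_columns)) {
    Xm <- cbind(Xm, extra_columns)
  }
  y <- data[[response]]
  sv <- svd(Xm)
  rank <- sum(sv$d > max(dim(Xm)) * .Machine$double.eps * sv$d[1L])
  Xp <- MASS::ginv(Xm)
  beta <- drop(Xp %*% y)
  fitted <- drop(Xm %*% beta)
  rss <- sum((y - fitted)^2)
  df_resid <- nrow(Xm) - rank
  if (df_resid <= 0) {
    pe_stop("degenerate fit: no residual degrees of freedom",
            "peranova_degenerate_design")
  }
  scale <- if (length(entry$average_over)) {
    prod(vapply(entry$average_over,
                function(f) design$factors[[f]]$levels[1L], 0))
  } else 1
  structure(list(X = X, Xm = Xm, Xp = Xp, Gp = MASS::ginv(crossprod(Xm)),
                 beta = beta, fitted = fitted, residuals = y - fitted,
                 rss = rss, df_resid = df_resid, rank = rank,
                 df_planned = entry$df_error %||% df_resid,
                 scale = scale, entry = entry, design = design,
                 sub_design = sdes, response = response),
            class = "pe_submodel")
}

#' @export
print.pe_submodel <- function(x, ...) {
  cat(sprintf("Sub-model for error stratum %s: %d obs, rank %d, residual df %d (RSS %.4g)\n",
              x$entry$error_term, nrow(x$Xm), x$rank, x$df_resid, x$rss))
  invisible(x)
}

#' F test of a contrast against a sub-model's residual
#'
#' Computes `F = [(Lb)' (L (X'X)^- L')^{-1} (Lb) / rank(L)] / MS_residual`
#' with a p-value from the upper tail of the F distribution. The contrast
#' must be estimable, and — when the sub-model contains subject blocks —
#' must carry zero weight on every subject column: a contrast with non-zero
#' subject weights tested against the model residual does not test the
#' intended effect but the effect plus the subject variance, artificially
#' inflating the F statistic, so the function refuses.
#'
#' @param fit A `"pe_submodel"` from [fit_submodel()].
#' @param L A `"contrast_weights"` object or a numeric weight matrix over
#'   the sub-model's columns (zero-padded over any extra columns).
#' @param df_den Denominator df (defaults to the sub-model's planned
#'   residual df).
#' @return List with `F`, `df_num`, `df_den`, `p`, and the numerator `SS`.
#' @export
f_test <- function(fit, L, df_den = fit$df_planned) {
  W <- if (inherits(L, "contrast_weights")) L$weights else L
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  if (ncol(W) < ncol(fit$Xm)) {
    W <- cbind(W, matrix(0, nrow(W), ncol(fit$Xm) - ncol(W)))
  }
  if (!check_estimable(fit$Xm, W)) {
    pe_stop("contrast is not estimable in this sub-model",
            "peranova_nonestimable")
  }
  ci <- attr(fit$X, "col_info")
  if (!is.null(ci) && any(ci$is_subject)) {
    subj <- which(ci$is_subject)
    if (any(abs(W[, subj, drop = FALSE]) > 1e-12)) {
      pe_stop(paste("contrast has non-zero weights on subject columns but the",
                    "sub-model denominator is the residual, which does not",
                    "contain the subject variance; testing it here would",
                    "artificially inflate the F statistic"),
              "peranova_wrong_stratum")
    }
  }
  q <- drop(W %*% fit$beta)
  Mi <- solve(W %*% fit$Gp %*% t(W))
  ss <- drop(t(q) %*% Mi %*% q)
  r <- qr(W)$rank
  msr <- fit$rss / df_den
  Fv <- if (msr > (ss / r) * 1e-12 && msr > 0) (ss / r) / msr
        else if (ss > 0) Inf else NA_real_
  list(F = Fv, df_num = r, df_den = df_den,
       p = stats::pf(Fv, r, df_den, lower.tail = FALSE), SS = ss)
}

## ---- engine: precompute everything reusable across responses ---------------

# The engine factors the analysis into response-independent structure
# (averaging maps, design matrices, contrast operators) and a cheap
# per-response pass; voxel-wise analysis and Monte-Carlo loops reuse it.
pe_build_engine <- function(design, data, response = "y",
                            covariates = NULL, coding = "overparameterized") {
  ems <- derive_ems(design)
  plan <- plan_models(ems, design)
  covariates <- normalize_covariates(covariates, design, data)
  df_all <- compute_df(design, plan, covariates = covariates)
  entries <- list()
  for (e in plan$entries) {
    avdata <- average_over(data, e$average_over, design, response = response)
    extra <- NULL
    cov_tests <- list()
    if (length(covariates)) {
      dec <- stratum_covariate_columns(avdata, covariates, design,
                                       e$within_kept)
      extra <- dec$columns
      cov_tests <- dec$tests
    }
    fit0 <- fit_submodel(avdata, e, design, response = response,
                         coding = coding, extra_columns = extra)
    fit0$df_planned <- unname(df_all[e$error_term])
    effs <- list()
    for (eff in e$effects_tested) {
      L <- derive_effect_contrast(fit0$X, eff, rows = "unique")
      Wm <- L$weights
      if (ncol(Wm) < ncol(fit0$Xm)) {
        Wm <- cbind(Wm, matrix(0, nrow(Wm), ncol(fit0$Xm) - ncol(Wm)))
      }
      if (!check_estimable(fit0$Xm, Wm)) {
        pe_stop(sprintf("contrast for '%s' is not estimable", eff),
                "peranova_nonestimable")
      }
      Mi <- solve(Wm %*% fit0$Gp %*% t(Wm))
      effs[[eff]] <- list(label = eff, W = Wm, Mi = Mi,
                          Cop = Wm %*% fit0$Xp, r = qr(Wm)$rank,
                          contrast = L)
    }
    ncol_base <- ncol(fit0$Xm) - (if (is.null(extra)) 0L else ncol(extra))
    for (ct in cov_tests) {
      Wm <- matrix(0, 1L, ncol(fit0$Xm))
      Wm[1L, ncol_base + ct$index] <- 1
      if (!check_estimable(fit0$Xm, Wm)) {
        pe_stop(sprintf("covariate '%s' is aliased with model terms", ct$label),
                "peranova_nonestimable")
      }
      Mi <- solve(Wm %*% fit0$Gp %*% t(Wm))
      effs[[ct$label]] <- list(label = ct$label, W = Wm, Mi = Mi,
                               Cop = Wm %*% fit0$Xp, r = 1L,
                               is_covariate = TRUE)
    }
    entries[[e$error_term]] <- list(
      plan_entry = e, fit = fit0, effects = effs,
      avg_info = avg_map(design, data, e$average_over),
      avdata = avdata)
  }
  list(design = design, ems = ems, plan = plan, entries = entries,
       covariates = covariates, response = response, coding = coding,
       df_all = df_all, data = data)
}

# index map for fast response averaging (mirrors average_over ordering)
avg_map <- function(design, data, factors) {
  obs <- normalize_obs(design, data)
  lev <- design_levels(design)
  keepw <- setdiff(design$within, factors)
  nw <- if (length(keepw))
    prod(vapply(keepw, function(f) lev[[f]][1L], 0)) else 1L
  wcell <- if (length(keepw))
    interaction_index(obs[keepw], vapply(keepw, function(f) lev[[f]][1L], 0L))
  else rep(1L, nrow(obs))
  sid <- obs[[design$unit]]
  tidx <- (sid - 1L) * nw + wcell
  list(tidx = tidx, counts = tabulate(tidx, nbins = max(sid) * nw))
}

# one full pass over a response vector; returns per-entry SS pieces
pe_engine_pass <- function(engine, y) {
  out <- list()
  for (nm in names(engine$entries)) {
    en <- engine$entries[[nm]]
    yav <- as.vector(rowsum(y, en$avg_info$tidx)) / en$avg_info$counts
    fit <- en$fit
    res <- yav - drop(fit$Xm %*% (fit$Xp %*% yav))
    rss <- sum(res^2)
    effs <- lapply(en$effects, function(ef) {
      q <- drop(ef$Cop %*% yav)
      list(SS = drop(t(q) %*% ef$Mi %*% q), r = ef$r,
           is_covariate = isTRUE(ef$is_covariate))
    })
    out[[nm]] <- list(rss = rss, df = fit$df_planned, scale = fit$scale,
                      effects = effs)
  }
  out
}

pe_assemble_table <- function(engine, pass) {
  rows <- list()
  for (nm in names(engine$entries)) {
    en <- engine$entries[[nm]]
    p <- pass[[nm]]
    msr <- p$rss / p$df
    covs <- names(en$effects)[vapply(en$effects, function(e)
      isTRUE(e$is_covariate), TRUE)]
    effs <- setdiff(names(en$effects), covs)
    for (lab in c(covs, effs)) {
      e <- p$effects[[lab]]
      mse <- e$SS / e$r
      Fv <- if (msr > mse * 1e-12 && msr > 0) mse / msr
            else if (mse > 0) Inf else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        effect = lab, SS = e$SS * p$scale, df = e$r,
        MS = e$SS / e$r * p$scale, F = Fv,
        p = stats::pf(Fv, e$r, p$df, lower.tail = FALSE),
        error_term = nm, error_SS = p$rss * p$scale, error_df = p$df,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      effect = paste0("Error: ", nm), SS = p$rss * p$scale, df = p$df,
      MS = p$rss / p$df * p$scale, F = NA_real_, p = NA_real_,
      error_term = nm, error_SS = NA_real_, error_df = NA_integer_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Run a partitioned-error repeated-measures ANOVA/ANCOVA
#'
#' Executes the full multi-model procedure on a long-format dataset:
#' derives the expected mean squares and the model plan, averages the data
#' per error stratum, fits each sub-model by pseudoinverse, derives Type
#' III contrasts from unique design-matrix rows, tests every effect against
#' its matching error stratum, and assembles a single ANOVA table. Sums of
#' squares are reported on the scale of the full decomposition (sub-model
#' sums of squares are multiplied by the number of averaged levels, which
#' leaves every F ratio unchanged).
#'
#' @param data Long-format data frame: subject column, one column per
#'   factor, the response, and optional covariate columns.
#' @param design An [rm_design()] object consistent with `data`.
#' @param response Response column name.
#' @param covariates Optional character vector of covariate column names,
#'   or list of [covariate_spec()] objects.
#' @param correction Sphericity df correction applied to within-subject
#'   tests: `"none"`, `"gg"` (Greenhouse-Geisser) or `"hf"` (Huynh-Feldt).
#' @param coding Design-matrix coding for the sub-models.
#' @return An object of class `"peranova"`.
#' @seealso [peranova()] for the formula interface.
#' @export
run_partitioned_anova <- function(data, design, response = "y",
                                  covariates = NULL,
                                  correction = c("none", "gg", "hf"),
                                  coding = "overparameterized") {
  correction <- match.arg(correction)
  engine <- pe_build_engine(design, data, response = response,
                            covariates = covariates, coding = coding)
  pass <- pe_engine_pass(engine, data[[response]])
  tab <- pe_assemble_table(engine, pass)
  fit <- structure(list(table = tab, design = design, ems = engine$ems,
                        plan = engine$plan, engine = engine,
                        data = data, response = response,
                        covariates = engine$covariates,
                        correction = "none",
                        call = match.call()),
                   class = "peranova")
  fit$sphericity <- fit_sphericity_reports(fit)
  if (correction != "none") fit <- adjust_df(fit, method = correction)
  fit
}

#' Partitioned-error repeated-measures ANOVA (formula interface)
#'
#' Builds the design specification from the data (factor levels and group
#' sizes are read off the supplied columns) and runs the partitioned-error
#' analysis. All right-hand-side variables of the formula are treated as
#' crossed fixed factors; those named in `within` are within-subject, the
#' rest between-subjects. The subject factor is random and nested in the
#' between factors.
#'
#' @param formula Model formula such as `y ~ Location * Texture * Drink`
#'   (only the variable set is used: all factors are fully crossed).
#' @param data Long-format data frame.
#' @param within Character vector naming the within-subject factors.
#' @param subject Name of the subject identifier column.
#' @param covariates Optional covariate column names or [covariate_spec()]
#'   list.
#' @param correction Sphericity correction (see
#'   [run_partitioned_anova()]).
#' @param ... Passed to [run_partitioned_anova()].
#' @return An object of class `"peranova"` with `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' spec <- sim_spec(rm_design(within = c(A = 2), between = c(B = 2), n = 8),
#'                  variance = c(sigma2 = 1, `Subject(B)` = 0.5), seed = 1)
#' dat <- simulate_dataset(spec)
#' peranova(y ~ A * B, dat, within = "A")
#' @export
peranova <- function(formula, data, within, subject = "Subject",
                     covariates = NULL,
                     correction = c("none", "gg", "hf"), ...) {
  correction <- match.arg(correction)
  response <- all.vars(formula[[2L]])
  vars <- all.vars(formula[[3L]])
  covnames <- if (is.character(covariates)) covariates
              else vapply(covariates, `[[`, "", "name")
  factors <- setdiff(vars, covnames)
  miss <- setdiff(c(factors, subject, response), names(data))
  if (length(miss)) {
    pe_stop(paste("columns not in data:", paste(miss, collapse = ", ")),
            "peranova_incomplete_data")
  }
  between <- setdiff(factors, within)
  nlev <- function(v) length(unique(data[[v]]))
  wv <- if (length(within)) {
    w <- vapply(within, nlev, 0L); names(w) <- within; w
  } else NULL
  bv <- if (length(between)) {
    b <- vapply(between, nlev, 0L); names(b) <- between; b
  } else NULL
  # group sizes in between-cell order (first factor fastest)
  n <- 1
  if (!is.null(bv)) {
    subs <- data[!duplicated(data[[subject]]), c(subject, between)]
    bidx <- lapply(between, function(b)
      as.integer(factor(subs[[b]],
                        levels = if (is.factor(data[[b]]))
                          levels(data[[b]]) else sort(unique(data[[b]])))))
    names(bidx) <- between
    gi <- interaction_index(as.data.frame(bidx), bv)
    n <- tabulate(gi, nbins = prod(bv))
  } else if (!is.null(wv)) {
    n <- length(unique(data[[subject]]))
  }
  design <- rm_design(within = wv, between = bv, n = n, subject = subject)
  fit <- run_partitioned_anova(data, design, response = response,
                               covariates = covariates,
                               correction = correction, ...)
  fit$call <- match.call()
  fit
}

## ---- methods ---------------------------------------------------------------

#' @export
print.peranova <- function(x, digits = 4, ...) {
  cat("Partitioned-error repeated-measures ANOVA\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  if (x$correction != "none") {
    cat(sprintf("Within-subject df corrected (%s epsilon)\n",
                toupper(x$correction)))
  }
  tab <- x$table
  out <- data.frame(Effect = tab$effect,
                    SS = signif(tab$SS, digits),
                    df = round(tab$df, 2),
                    MS = signif(tab$MS, digits),
                    F = ifelse(is.na(tab$F), "", format(signif(tab$F, digits))),
                    p = ifelse(is.na(tab$p), "",
                               format.pval(tab$p, digits = digits)))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.peranova <- function(object, ...) {
  structure(list(fit = object,
                 variance_components = variance_components(object)),
            class = "summary.peranova")
}

#' @export
print.summary.peranova <- function(x, ...) {
  print(x$fit)
  cat("\nMethod-of-moments variance components (from error-stratum mean squares):\n")
  print(signif(x$variance_components, 4))
  if (length(x$fit$sphericity)) {
    cat("\nSphericity by stratum:\n")
    for (r in x$fit$sphericity) {
      cat(sprintf("  %-32s eps_GG = %.3f, eps_HF = %.3f, Mauchly W = %.3f (p = %.3g)\n",
                  r$stratum, r$epsilon_gg, r$epsilon_hf, r$mauchly_W,
                  r$mauchly_p))
    }
  }
  invisible(x)
}

#' Estimate variance components from the error-stratum mean squares
#'
#' Solves the expected-mean-square identities of the random strata for the
#' variance components (method of moments): the residual mean square
#' estimates the error variance, and each subject stratum's excess over it,
#' divided by its EMS coefficient, estimates that stratum's component.
#' Negative estimates are reported as computed (a known feature of
#' moment estimators).
#'
#' @param object A `"peranova"` fit.
#' @return Named numeric vector of variance-component estimates.
#' @export
variance_components <- function(object) {
  stopifnot(inherits(object, "peranova"))
  tab <- object$table
  err <- tab[startsWith(tab$effect, "Error: "), ]
  ms <- err$MS
  names(ms) <- sub("^Error: ", "", err$effect)
  ems <- object$ems
  out <- c(sigma2 = unname(ms["Residual"]))
  for (nm in setdiff(names(ms), "Residual")) {
    comps <- ems$rows[[nm]]
    own <- Filter(function(cm) cm$symbol == ems$terms[[nm]]$symbol, comps)[[1L]]
    coef <- prod(vapply(own$coef, function(s)
      index_levels(object$design, s), 0))
    out[ems$terms[[nm]]$symbol] <- (ms[[nm]] - out[["sigma2"]]) / coef
  }
  nm2 <- sub("^sigma2_", "", names(out))
  nm2[1L] <- "sigma2"
  names(out) <- ifelse(nm2 == "sigma2", "sigma2", nm2)
  out
}

#' @export
coef.peranova <- function(object, ...) {
  # estimable cell means from the residual-stratum (full) sub-model
  en <- object$engine$entries[["Residual"]] %||%
    object$engine$entries[[length(object$engine$entries)]]
  fit <- en$fit
  Xu <- reduce_unique_rows(fit$X, TRUE)
  W <- matrix(0, nrow(Xu), ncol(fit$Xm))
  W[, seq_len(ncol(Xu))] <- unclass(Xu)
  mu <- drop(W %*% fit$beta)
  obs <- attr(Xu, "obs")
  fcols <- setdiff(names(obs), object$design$unit)
  labs <- apply(obs[fcols], 1L, function(r) paste(fcols, r, sep = "",
                                                  collapse = ":"))
  names(mu) <- labs
  mu
}

#' @export
fitted.peranova <- function(object, ...) {
  en <- object$engine$entries[["Residual"]] %||%
    object$engine$entries[[length(object$engine$entries)]]
  en$fit$fitted
}

#' @export
residuals.peranova <- function(object, stratum = NULL, ...) {
  ens <- object$engine$entries
  if (is.null(stratum)) {
    en <- ens[["Residual"]] %||% ens[[length(ens)]]
    return(en$fit$residuals)
  }
  if (!stratum %in% names(ens)) {
    pe_stop("unknown error stratum", "peranova_unsupported_design")
  }
  ens[[stratum]]$fit$residuals
}

#' @export
plot.peranova <- function(x, ...) {
  ens <- x$engine$entries
  k <- length(ens)
  op <- graphics::par(mfrow = c(ceiling(k / 2), min(k, 2)))
  on.exit(graphics::par(op))
  for (nm in names(ens)) {
    r <- ens[[nm]]$fit$residuals
    stats::qqnorm(r, main = paste("Residuals:", nm), ...)
    stats::qqline(r)
  }
  invisible(x)
}

#' @export
simulate.peranova <- function(object, nsim = 1, seed = NULL, ...) {
  vc <- variance_components(object)
  vc[vc < 0] <- 0
  variance <- c(sigma2 = unname(vc[["sigma2"]]))
  for (nm in setdiff(names(vc), "sigma2")) variance[nm] <- vc[[nm]]
  mu <- coef(object)
  spec <- sim_spec(object$design, cell_means = unname(mu),
                   variance = variance, seed = seed)
  out <- vector("list", nsim)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nsim)) {
    spec$seed <- NULL
    out[[i]] <- simulate_dataset(spec)
  }
  if (nsim == 1L) out[[1L]] else out
}
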