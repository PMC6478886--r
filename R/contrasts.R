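## Exact rational helpers.  Marginal-mean weights are averages of integer
## design-matrix rows; keeping them as integer numerators over a common
## denominator makes the derived contrast vectors exact (halves, quarters,
## thirds) rather than accumulations of floating averages.

int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
int_lcm <- function(a, b) a / int_gcd(a, b) * b

rat_reduce <- function(num, den) {
  g <- den
  for (v in num) g <- int_gcd(g, v)
  if (g > 1) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}

#' Build a repeated-measures design matrix
#'
#' Constructs the observation-level design matrix for a design, with one row
#' per observation and columns for the intercept, every fixed-effect term,
#' and the random subject blocks (subject indicators and subject-by-within
#' interaction blocks, i.e. every random stratum short of the residual).
#' Column order is intercept, factor main-effect blocks in declaration
#' order, interaction blocks by ascending order, subject blocks last; within
#' a block, level combinations are enumerated with the earlier-declared
#' factor varying fastest.
#'
#' Codings: `"overparameterized"` uses full 0/1 indicator blocks (each
#' factor's block sums to one across each row); `"treatment"` keeps the
#' indicators of all but the last level; `"sigma_restricted"` codes fixed
#' factors as deviations from the last level (+1/-1 for two-level factors);
#' `"cell_means"` replaces all fixed terms by one indicator per design cell.
#' In the constrained codings the subject blocks are nested 0/1 indicators
#' of all but the last subject of each group. All codings span the same row
#' space, so contrasts derived from any of them test the same hypotheses.
#'
#' @param design An [rm_design()] object with numeric levels.
#' @param coding Design-matrix coding (see Details).
#' @param data Optional long-format data frame supplying the observation
#'   rows (columns named after the factors plus the subject column). When
#'   omitted a balanced observation table is synthesized from the design,
#'   ordered subject-major with within cells varying first-factor-fastest.
#' @return A numeric matrix of class `"rm_design_matrix"` with attributes
#'   `design`, `coding`, `obs` (the observation table) and `col_info` (per
#'   column: the term it codes and whether it is a subject block).
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 2)
#' X <- build_design_matrix(d)
#' X[1, ]  # subject 1, cell A1B1
#' @export
build_design_matrix <- function(design,
                                coding = c("overparameterized", "treatment",
                                           "sigma_restricted", "cell_means"),
                                data = NULL) {
  coding <- match.arg(coding)
  obs <- if (is.null(data)) synth_obs(design) else normalize_obs(design, data)
  terms <- design_terms(design)
  include <- terms[!vapply(terms, `[[`, TRUE, "is_residual")]
  build_X(design, obs, coding, include)
}

# balanced observation table implied by the design
synth_obs <- function(design) {
  lev <- design_levels(design)
  nonunit <- setdiff(names(design$factors), design$unit)
  if (!is.na(design$unit)) {
    bet <- design$between
    gcells <- if (length(bet))
      expand.grid(lapply(lev[bet], seq_len)) else data.frame(row.names = 1)
    gn <- design_group_n(design)
    wit <- design$within
    wcells <- if (length(wit))
      expand.grid(lapply(lev[wit], seq_len)) else data.frame(row.names = 1)
    rows <- list()
    sid <- 0L
    for (g in seq_len(max(nrow(gcells), 1L))) {
      for (s in seq_len(gn[g])) {
        sid <- sid + 1L
        blk <- wcells[rep(seq_len(max(nrow(wcells), 1L))), , drop = FALSE]
        blk[[design$unit]] <- sid
        for (b in bet) blk[[b]] <- gcells[[b]][g]
        rows[[length(rows) + 1L]] <- blk
      }
    }
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    obs
  } else {
    cells <- expand.grid(lapply(lev[nonunit], seq_len))
    reps <- rep(design$reps, length.out = nrow(cells))
    obs <- cells[rep(seq_len(nrow(cells)), times = reps), , drop = FALSE]
    obs <- obs[order(rep(seq_len(nrow(cells)), times = reps)), , drop = FALSE]
    rownames(obs) <- NULL
    obs
  }
}

# coerce user data columns to 1-based level indices, preserving factor
# level order (or sorted unique order otherwise)
normalize_obs <- function(design, data) {
  cols <- setdiff(names(design$factors), design$unit)
  need <- c(cols, if (!is.na(design$unit)) design$unit)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    pe_stop(paste("data is missing design columns:",
                  paste(miss, collapse = ", ")), "peranova_incomplete_data")
  }
  obs <- data.frame(row.names = seq_len(nrow(data)))
  for (f in cols) {
    v <- data[[f]]
    idx <- if (is.factor(v)) as.integer(v) else as.integer(factor(v))
    m <- design$factors[[f]]$levels[1L]
    if (max(idx) > m) {
      pe_stop(sprintf("column '%s' has more levels than the design declares", f),
              "peranova_unsupported_design")
    }
    obs[[f]] <- idx
  }
  if (!is.na(design$unit)) {
    v <- data[[design$unit]]
    obs[[design$unit]] <- as.integer(factor(v, levels = unique(v)))
  }
  obs
}

# per-factor column set under a coding; list of column vectors + labels
factor_cols <- function(design, obs, f, coding) {
  m <- design$factors[[f]]$levels[1L]
  idx <- obs[[f]]
  ind <- function(l) as.numeric(idx == l)
  switch(coding,
    overparameterized = ,
    cell_means = list(cols = lapply(seq_len(m), ind),
                      labels = paste0(f, seq_len(m))),
    treatment = list(cols = lapply(seq_len(m - 1L), ind),
                     labels = paste0(f, seq_len(m - 1L))),
    sigma_restricted = list(
      cols = lapply(seq_len(m - 1L), function(l) ind(l) - ind(m)),
      labels = paste0(f, seq_len(m - 1L)))
  )
}

# subject columns: full indicators (overparameterized / cell_means) or
# nested indicators of all but the last subject per group
subject_cols <- function(design, obs, coding) {
  sid <- obs[[design$unit]]
  nsub <- max(sid)
  if (coding %in% c("overparameterized", "cell_means")) {
    keep <- seq_len(nsub)
  } else {
    # last subject of each between group is the reference
    grp <- subject_groups(design, obs)
    keep <- unlist(lapply(split(seq_len(nsub), grp), function(s)
      s[-length(s)]), use.names = FALSE)
    keep <- sort(keep)
  }
  list(cols = lapply(keep, function(s) as.numeric(sid == s)),
       labels = paste0(design$unit, keep))
}

# between-group index of each subject, in subject order
subject_groups <- function(design, obs) {
  sid <- obs[[design$unit]]
  if (!length(design$between)) return(rep(1L, max(sid)))
  gidx <- interaction_index(obs[design$between],
                            vapply(design$factors[design$between],
                                   function(f) f$levels[1L], 0L))
  g <- integer(max(sid))
  g[sid] <- gidx
  g
}

# 1-based cell index of a level-index table, first column fastest
interaction_index <- function(df, nlev) {
  idx <- rep(1L, nrow(df))
  mult <- 1L
  for (j in seq_along(df)) {
    idx <- idx + (df[[j]] - 1L) * mult
    mult <- mult * nlev[j]
  }
  idx
}

# product block over a set of per-factor column lists, first factor fastest
cross_cols <- function(parts) {
  cols <- parts[[1L]]$cols
  labels <- parts[[1L]]$labels
  if (length(parts) > 1L) {
    for (k in 2L:length(parts)) {
      newc <- list(); newl <- character()
      for (j in seq_along(parts[[k]]$cols)) {
        for (i in seq_along(cols)) {
          newc[[length(newc) + 1L]] <- cols[[i]] * parts[[k]]$cols[[j]]
          newl <- c(newl, paste0(labels[i], ":", parts[[k]]$labels[j]))
        }
      }
      cols <- newc; labels <- newl
    }
  }
  list(cols = cols, labels = labels)
}

build_X <- function(design, obs, coding, include) {
  n <- nrow(obs)
  cols <- list(rep(1, n))
  labels <- "mu"
  term_of <- "(Intercept)"
  is_subj <- FALSE
  add_block <- function(blk, term, subj) {
    cols <<- c(cols, blk$cols)
    labels <<- c(labels, blk$labels)
    term_of <<- c(term_of, rep(term, length(blk$cols)))
    is_subj <<- c(is_subj, rep(subj, length(blk$cols)))
  }
  if (coding == "cell_means") {
    nonunit <- setdiff(names(design$factors), design$unit)
    parts <- lapply(nonunit, function(f)
      factor_cols(design, obs, f, "overparameterized"))
    add_block(cross_cols(parts), paste(nonunit, collapse = ":"), FALSE)
  } else {
    for (t in include) {
      if (!length(t$fixed_factors) || t$random) next
      parts <- lapply(t$fixed_factors, function(f)
        factor_cols(design, obs, f, coding))
      add_block(cross_cols(parts), t$label, FALSE)
    }
  }
  for (t in include) {
    if (!t$random || t$is_residual) next
    sc <- subject_cols(design, obs, coding)
    if (length(t$within_part)) {
      parts <- c(list(sc), lapply(t$within_part, function(f)
        factor_cols(design, obs, f,
                    if (coding == "cell_means") "overparameterized" else coding)))
      sc <- cross_cols(parts)
    }
    add_block(sc, t$label, TRUE)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  structure(X,
            design = design, coding = coding, obs = obs,
            col_info = data.frame(label = labels, term = term_of,
                                  is_subject = is_subj,
                                  stringsAsFactors = FALSE),
            class = c("rm_design_matrix", class(X)))
}

#' @export
print.rm_design_matrix <- function(x, ...) {
  ci <- attr(x, "col_info")
  cat(sprintf("Design matrix (%s coding): %d rows x %d columns, %d subject column(s)\n",
              attr(x, "coding"), nrow(x), ncol(x), sum(ci$is_subject)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Reduce a design matrix to its unique rows
#'
#' Returns the first-occurrence-ordered unique rows, optionally after
#' removing the subject block columns. Reduction to unique rows of the
#' fixed-effect columns is the basis for deriving Type III contrast weights
#' that are invariant to group-size imbalance: each design cell contributes
#' exactly one row regardless of how many observations fall in it.
#'
#' @param X An `"rm_design_matrix"`.
#' @param drop_subject_columns Remove subject-block columns first?
#' @return An `"rm_design_matrix"` of unique rows (attributes updated).
#' @export
reduce_unique_rows <- function(X, drop_subject_columns = FALSE) {
  ci <- attr(X, "col_info")
  obs <- attr(X, "obs")
  M <- unclass(X)
  if (drop_subject_columns) {
    keep <- !ci$is_subject
    M <- M[, keep, drop = FALSE]
    ci <- ci[keep, , drop = FALSE]
  }
  dup <- duplicated(as.data.frame(M))
  M <- M[!dup, , drop = FALSE]
  structure(M, design = attr(X, "design"), coding = attr(X, "coding"),
            obs = obs[!dup, , drop = FALSE], col_info = ci,
            class = c("rm_design_matrix", "matrix", "array"))
}

# average the design-matrix rows selected by a condition; exact rationals
row_average <- function(X, cond) {
  obs <- attr(X, "obs")
  sel <- rep(TRUE, nrow(X))
  for (f in names(cond)) {
    if (identical(cond[[f]], "average")) next
    sel <- sel & obs[[f]] == cond[[f]]
  }
  if (!any(sel)) {
    pe_stop("condition selects no design rows", "peranova_incomplete_data")
  }
  list(num = colSums(unclass(X)[sel, , drop = FALSE]), den = sum(sel))
}

#' Marginal-mean weights from design-matrix rows
#'
#' Averages the design-matrix rows selected by a condition, yielding the
#' weight vector whose inner product with the parameter vector is the
#' corresponding (marginal or cell) mean. Because every row is an estimable
#' function of the parameters and averages of estimable functions are
#' estimable, these weights are always estimable - including their non-zero
#' entries on the subject columns, which must not be zeroed by hand.
#'
#' @param X An `"rm_design_matrix"`.
#' @param condition Named list mapping factor names to a level index, or to
#'   `"average"` (equivalent to omitting the factor).
#' @return Numeric weight vector with exact-rational bookkeeping in
#'   attributes `num` (integer numerators) and `den` (common denominator).
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 2)
#' X <- build_design_matrix(d)
#' marginal_mean_weights(X, list(A = 1))
#' @export
marginal_mean_weights <- function(X, condition = list()) {
  r <- row_average(X, condition)
  r <- rat_reduce(r$num, r$den)
  w <- r$num / r$den
  names(w) <- colnames(X)
  structure(w, num = r$num, den = r$den)
}

# (m-1) x m successive-difference operator
diff_op <- function(m) {
  D <- matrix(0, m - 1L, m)
  for (i in seq_len(m - 1L)) { D[i, i] <- 1; D[i, i + 1L] <- -1 }
  D
}

# contrast rows for a set of factors: apply a difference operator on each
# factor's levels to the matrix of (marginal) cell-mean weights
contrast_rows <- function(X, factors, at = list()) {
  design <- attr(X, "design")
  mlev <- vapply(factors, function(f) design$factors[[f]]$levels[1L], 0L)
  combos <- expand.grid(lapply(mlev, seq_len))
  names(combos) <- factors
  Gs <- lapply(seq_len(nrow(combos)), function(i) {
    cond <- c(as.list(combos[i, , drop = FALSE]), at)
    row_average(X, cond)
  })
  den <- Reduce(int_lcm, vapply(Gs, `[[`, 0, "den"))
  num <- do.call(rbind, lapply(Gs, function(g) g$num * (den / g$den)))
  op <- Reduce(kronecker, rev(lapply(mlev, diff_op)))
  Lnum <- op %*% num
  r <- rat_reduce(as.vector(Lnum), den)
  L <- matrix(r$num, nrow = nrow(Lnum)) / r$den
  colnames(L) <- colnames(X)
  list(L = L, num = matrix(r$num, nrow = nrow(Lnum)), den = r$den)
}

contrast_result <- function(X, L, target, required_error = NULL,
                            subset = NULL, note = NULL) {
  ci <- attr(X, "col_info")
  subj_zero <- if (any(ci$is_subject))
    all(L$L[, ci$is_subject, drop = FALSE] == 0) else TRUE
  est <- check_estimable(X, L$L)
  structure(list(weights = L$L, num = L$num, den = L$den, target = target,
                 estimable = est, subject_zero = subj_zero,
                 required_error = required_error, subset = subset,
                 note = note),
            class = "contrast_weights")
}

#' @export
print.contrast_weights <- function(x, ...) {
  cat(sprintf("Contrast for %s: %d row(s), estimable=%s, subject_zero=%s\n",
              x$target, nrow(x$weights), x$estimable, x$subject_zero))
  if (!is.null(x$required_error))
    cat("  required error stratum:", x$required_error,
        if (!is.null(x$note)) paste0(" (", x$note, ")") else "", "\n")
  print(x$weights)
  invisible(x)
}

#' Derive Type III contrast weights for an ANOVA effect
#'
#' Builds the weight matrix testing a main effect or interaction from the
#' rows of the design matrix: marginal-mean weights are formed by row
#' averaging, and the effect weights by (differences of) differences across
#' the effect's factor levels. Main effects span (levels - 1) rows;
#' interactions apply a difference operator on every participating factor.
#' With `rows = "unique"` the matrix is first reduced to unique rows of the
#' fixed-effect columns (subject blocks removed, zeros re-inserted), which
#' makes the weights invariant to unequal group sizes (Type III); the
#' default `"all"` averages the observed rows as printed derivations do.
#'
#' The result records whether the weights are estimable, whether every
#' subject-block weight is zero (`subject_zero`; when false the contrast
#' must not be tested against the model residual), and the error stratum
#' whose EMS matches the effect.
#'
#' @param X An `"rm_design_matrix"`.
#' @param effect Effect label, e.g. `"A"` or `"A:B"`.
#' @param rows `"all"` (average observed rows) or `"unique"` (Type III).
#' @return A `"contrast_weights"` object.
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 2)
#' X <- build_design_matrix(d)
#' derive_effect_contrast(X, "A")  # subject weights cancel
#' derive_effect_contrast(X, "B")  # they do not: between stratum needed
#' @export
derive_effect_contrast <- function(X, effect, rows = c("all", "unique")) {
  rows <- match.arg(rows)
  design <- attr(X, "design")
  factors <- strsplit(effect, ":", fixed = TRUE)[[1L]]
  bad <- setdiff(factors, names(design$factors))
  if (length(bad)) {
    pe_stop(paste("unknown factor(s):", paste(bad, collapse = ", ")),
            "peranova_unsupported_design")
  }
  Xd <- if (rows == "unique") reduce_unique_rows(X, TRUE) else X
  L <- contrast_rows(Xd, factors)
  if (rows == "unique") {
    # re-embed with zero weights on the removed subject columns
    full <- matrix(0, nrow(L$L), ncol(X), dimnames = list(NULL, colnames(X)))
    fnum <- matrix(0, nrow(L$L), ncol(X))
    keep <- !attr(X, "col_info")$is_subject
    full[, keep] <- L$L
    fnum[, keep] <- L$num
    L <- list(L = full, num = fnum, den = L$den)
  }
  req <- tryCatch(select_error_term(derive_ems(design), effect),
                  error = function(e) NA_character_)
  contrast_result(X, L, effect, required_error = req)
}

#' Derive simple-effect contrast weights
#'
#' Weights for the effect of one factor with the remaining factors held at
#' fixed levels (a simple main effect used to follow up an interaction).
#' The error term appropriate for a simple effect is not necessarily the
#' one used for the omnibus effect: a between-subjects comparison at a
#' fixed within-subject level retains non-zero subject weights and must be
#' tested in a between-subjects model restricted to the data at those
#' levels; this is surfaced in the `required_error`, `subset` and `note`
#' fields.
#'
#' @param X An `"rm_design_matrix"`.
#' @param effect Name of the factor whose simple effect is wanted.
#' @param at Named list fixing levels of the other factors.
#' @return A `"contrast_weights"` object.
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 2)
#' X <- build_design_matrix(d)
#' derive_simple_effect_contrast(X, "A", at = list(B = 1))
#' @export
derive_simple_effect_contrast <- function(X, effect, at = list()) {
  design <- attr(X, "design")
  stopifnot(effect %in% names(design$factors))
  L <- contrast_rows(X, effect, at = at)
  scope <- design$factors[[effect]]$scope
  within_at <- at[intersect(names(at), design$within)]
  if (scope == "between" || effect %in% design$between) {
    req <- if (!is.na(design$unit)) unit_label(design) else "Residual"
    note <- if (length(within_at))
      paste0("between-subjects comparison: fit a between model on the data at ",
             paste(sprintf("%s=%s", names(within_at), unlist(within_at)),
                   collapse = ", "), " only")
    else NULL
  } else {
    req <- tryCatch(select_error_term(derive_ems(design), effect),
                    error = function(e) NA_character_)
    note <- NULL
  }
  out <- contrast_result(X, L, paste0(effect, " at ",
                                      paste(sprintf("%s=%s", names(at),
                                                    unlist(at)),
                                            collapse = ", ")),
                         required_error = req,
                         subset = if (length(within_at)) within_at else NULL,
                         note = note)
  if (out$subject_zero && identical(req, unit_label(design))) {
    out$required_error <- "Residual"
    out$note <- NULL
  }
  out
}

#' Check estimability of contrast weights
#'
#' A weight vector defines an estimable function exactly when it lies in
#' the row space of the design matrix, i.e. `L == L %*% ginv(X) %*% X`
#' within tolerance. Weights constructed by zeroing the subject entries of
#' a between-effect contrast fail this check: they are not estimable in an
#' overparameterized repeated-measures model.
#'
#' @param X Design matrix.
#' @param L Weight vector or matrix over the columns of `X`.
#' @param tol Maximum absolute projection residual tolerated.
#' @return `TRUE` if every row of `L` is estimable.
#' @export
check_estimable <- function(X, L, tol = 1e-8) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (ncol(L) != ncol(X)) {
    pe_stop("weight columns do not match the design matrix",
            "peranova_nonestimable")
  }
  M <- unclass(X)
  proj <- L %*% MASS::ginv(M) %*% M
  max(abs(proj - L)) < tol
}
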