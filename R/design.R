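#' @keywords internal
pe_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "peranova_error")))
}

#' Declare a single design factor
#'
#' A factor is described by its number of levels, whether its effects are
#' fixed or random, and its scope: `"between"` (varies over experimental
#' units), `"within"` (repeated over units), or `"unit"` (the random subject
#' factor itself). The subject factor may be nested in between-subject
#' factors, in which case subject index `k` refers to a different subject in
#' each group.
#'
#' @param name Factor name (must match a column name in any data supplied
#'   later).
#' @param levels Number of levels. For a `"unit"` factor this is the number
#'   of subjects per between-subjects group (a vector when groups are
#'   unbalanced). May be `NA` for purely symbolic use.
#' @param kind `"fixed"` or `"random"`.
#' @param scope `"between"`, `"within"`, or `"unit"`.
#' @param nested_in Character vector of factor names this factor is nested
#'   in (only supported for the unit factor, nested in between factors).
#' @param symbol Single-letter symbol used for this factor's level count in
#'   symbolic expected-mean-square expressions (assigned automatically by
#'   [rm_design()] when omitted).
#' @return An object of class `"rm_factor"`.
#' @seealso [rm_design()]
#' @export
rm_factor <- function(name, levels, kind = c("fixed", "random"),
                      scope = c("between", "within", "unit"),
                      nested_in = character(), symbol = NULL) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (scope == "unit" && kind != "random") {
    pe_stop("the unit (subject) factor must be random",
            "peranova_unsupported_design")
  }
  if (!all(is.na(levels))) {
    if (!is.numeric(levels) || any(levels < 1) ||
        any(levels != round(levels))) {
      pe_stop(sprintf("factor '%s': levels must be positive integers", name),
              "peranova_unsupported_design")
    }
  }
  structure(list(name = name, levels = as.integer(levels), kind = kind,
                 scope = scope, nested_in = as.character(nested_in),
                 symbol = symbol),
            class = "rm_factor")
}

#' Specify a repeated-measures design
#'
#' The design specification is the single source of truth for the analysis:
#' which factors exist, how many levels each has, which vary within subject,
#' which between subjects, and how many subjects each group contains. From
#' it the package derives the expected mean squares, the error term for
#' every effect, the set of sub-models required, and all degrees of freedom.
#'
#' Two interfaces are offered. The compact form names within and between
#' factors with their level counts and gives per-group subject counts; a
#' random subject factor nested in the between factors is added
#' automatically. The general form takes a list of [rm_factor()] objects
#' (needed, e.g., to declare crossed random factors, for which the engine
#' will report that no exact F denominator exists).
#'
#' @param within Named integer vector of within-subject factors and their
#'   level counts, e.g. `c(Location = 2, Texture = 3)`.
#' @param between Named integer vector of between-subject factors.
#' @param n Subjects per between-subjects group, in the order of the
#'   between-cell crossing (first factor varying fastest); recycled if
#'   scalar. With no between factors, the total number of subjects.
#' @param subject Name of the subject (unit) factor.
#' @param factors Alternatively, a list of [rm_factor()] objects.
#' @param reps Observations per cell for designs without a subject factor.
#' @return An object of class `"rm_design"`.
#' @examples
#' # the 2 x 3 x 2 mixed design: two within factors, one between factor,
#' # 14 + 16 subjects
#' d <- rm_design(within = c(Location = 2, Texture = 3),
#'                between = c(Drink = 2), n = c(14, 16))
#' d
#' @export
rm_design <- function(within = NULL, between = NULL, n = 1,
                      subject = "Subject", factors = NULL, reps = 1) {
  if (is.null(factors)) {
    factors <- list()
    add <- function(v, scope) {
      for (i in seq_along(v)) {
        factors[[length(factors) + 1L]] <<-
          rm_factor(names(v)[i], v[i], "fixed", scope)
      }
    }
    if (!is.null(within)) {
      if (is.null(names(within)) || any(!nzchar(names(within))))
        pe_stop("'within' must be a named vector", "peranova_unsupported_design")
      add(within, "within")
    }
    if (!is.null(between)) {
      if (is.null(names(between)) || any(!nzchar(names(between))))
        pe_stop("'between' must be a named vector", "peranova_unsupported_design")
      add(between, "between")
    }
    if (!is.null(within)) {
      ngroups <- if (is.null(between)) 1L else prod(between)
      n <- as.integer(rep(n, length.out = ngroups))
      factors[[length(factors) + 1L]] <-
        rm_factor(subject, n, "random", "unit",
                  nested_in = if (is.null(between)) character()
                              else names(between))
    } else if (!is.null(between)) {
      reps <- n  # replicates per cell in a pure between design
    }
  }
  names(factors) <- vapply(factors, `[[`, "", "name")
  validate_design(factors)
  scopes <- vapply(factors, `[[`, "", "scope")
  unit <- names(factors)[scopes == "unit"]
  nonunit <- names(factors)[scopes != "unit"]
  # level-count symbols: letters for non-unit factors, n for unit/replicates
  syms <- character(0)
  for (i in seq_along(nonunit)) {
    f <- factors[[nonunit[i]]]
    syms[nonunit[i]] <- if (!is.null(f$symbol)) f$symbol else letters[i]
  }
  if (length(unit)) syms[unit] <- "n"
  des <- structure(list(
    factors = factors,
    unit = if (length(unit)) unit else NA_character_,
    within = names(factors)[scopes == "within"],
    between = names(factors)[scopes == "between"],
    reps = as.integer(reps),
    symbols = syms
  ), class = "rm_design")
  des$balanced <- design_is_balanced(des)
  des
}

validate_design <- function(factors) {
  nm <- names(factors)
  if (anyDuplicated(nm)) {
    pe_stop("duplicate factor names", "peranova_unsupported_design")
  }
  scopes <- vapply(factors, `[[`, "", "scope")
  if (sum(scopes == "unit") > 1L) {
    pe_stop("more than one unit (subject) factor declared",
            "peranova_unsupported_design")
  }
  if (any(scopes == "within") && !any(scopes == "unit")) {
    pe_stop("within-subject factors require a unit (subject) factor",
            "peranova_unsupported_design")
  }
  for (f in factors) {
    bad <- setdiff(f$nested_in, nm)
    if (length(bad)) {
      pe_stop(sprintf("'%s' is nested in undeclared factor(s): %s",
                      f$name, paste(bad, collapse = ", ")),
              "peranova_unsupported_design")
    }
    if (f$name %in% f$nested_in) {
      pe_stop(sprintf("nesting cycle: '%s' nested in itself", f$name),
              "peranova_unsupported_design")
    }
    if (f$scope != "unit" && length(f$nested_in)) {
      pe_stop("nesting of non-unit factors is not supported",
              "peranova_unsupported_design")
    }
    if (f$scope == "unit") {
      between <- nm[scopes == "between"]
      if (!all(f$nested_in %in% between)) {
        pe_stop("the unit factor may only be nested in between factors",
                "peranova_unsupported_design")
      }
    }
  }
  invisible(TRUE)
}

design_is_balanced <- function(design) {
  ok <- TRUE
  if (!is.na(design$unit)) {
    nlev <- design$factors[[design$unit]]$levels
    ok <- ok && length(unique(nlev)) == 1L
  }
  ok && length(unique(design$reps)) == 1L
}

#' Number of levels of each factor (named list)
#' @keywords internal
design_levels <- function(design) {
  lapply(design$factors, `[[`, "levels")
}

#' Subjects per between-subjects group
#' @keywords internal
design_group_n <- function(design) {
  if (is.na(design$unit)) return(NULL)
  n <- design$factors[[design$unit]]$levels
  ngroups <- if (length(design$between))
    prod(vapply(design$factors[design$between], `[[`, 1L, "levels")) else 1L
  rep(n, length.out = ngroups)
}

#' @export
print.rm_design <- function(x, ...) {
  cat("Repeated-measures design specification\n")
  for (f in x$factors) {
    lev <- if (all(is.na(f$levels))) f$symbol %||% "?"
           else paste(f$levels, collapse = "/")
    nest <- if (length(f$nested_in))
      paste0(", nested in ", paste(f$nested_in, collapse = ":")) else ""
    cat(sprintf("  %-12s %s, %s, levels: %s%s\n",
                f$name, f$kind, f$scope, lev, nest))
  }
  if (is.na(x$unit) && length(x$between)) {
    cat("  replicates per cell:", paste(x$reps, collapse = "/"), "\n")
  }
  cat(if (isTRUE(x$balanced)) "  balanced\n" else "  unbalanced groups\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- model terms -----------------------------------------------------------

# A model term records the live and bracketed (nesting) subscripts that the
# classical EMS bookkeeping operates on, plus its variance / quadratic-form
# symbol.  The residual is the highest-order interaction of subject with the
# within-subject factors (or the replicate error in pure between designs).
make_term <- function(label, subscripts, bracketed, random, symbol,
                      fixed_factors = character(), within_part = character(),
                      is_residual = FALSE) {
  list(label = label, subscripts = subscripts, bracketed = bracketed,
       random = random, symbol = symbol, fixed_factors = fixed_factors,
       within_part = within_part, is_residual = is_residual)
}

unit_label <- function(design) {
  if (length(design$between))
    paste0(design$unit, "(", paste(design$between, collapse = ":"), ")")
  else design$unit
}

# All model terms of a supported design, in reporting order: crossed
# (fixed-side) terms by ascending order, then subject strata by ascending
# within-order, then the residual.
design_terms <- function(design) {
  nonunit <- setdiff(names(design$factors), design$unit)
  kinds <- vapply(design$factors, `[[`, "", "kind")
  terms <- list()
  for (size in seq_along(nonunit)) {
    sets <- utils::combn(nonunit, size, simplify = FALSE)
    for (s in sets) {
      lab <- paste(s, collapse = ":")
      rnd <- any(kinds[s] == "random")
      sym <- if (rnd) paste0("sigma2_", lab) else paste0("Q_", lab)
      terms[[lab]] <- make_term(lab, subscripts = s, bracketed = character(),
                                random = rnd, symbol = sym,
                                fixed_factors = s)
    }
  }
  if (!is.na(design$unit) && length(design$within)) {
    ulab <- unit_label(design)
    subsets <- list(character())
    if (length(design$within) > 1L) {
      for (size in seq_len(length(design$within) - 1L)) {
        subsets <- c(subsets,
                     utils::combn(design$within, size, simplify = FALSE))
      }
    }
    for (W in subsets) {
      lab <- if (length(W)) paste(c(ulab, W), collapse = ":") else ulab
      terms[[lab]] <- make_term(
        lab,
        subscripts = c(W, design$between, design$unit),
        bracketed = design$between,
        random = TRUE,
        symbol = paste0("sigma2_", lab),
        within_part = W)
    }
  }
  res_sub <- names(design$factors)
  res_brk <- setdiff(res_sub, design$unit)
  if (is.na(design$unit) || any(design$reps > 1L)) {
    res_sub <- c(res_sub, ".rep")
    res_brk <- setdiff(res_sub, ".rep")
  }
  terms[["Residual"]] <- make_term(
    "Residual", subscripts = res_sub, bracketed = res_brk,
    random = TRUE, symbol = "sigma2",
    within_part = design$within, is_residual = TRUE)
  terms
}

# level count used in EMS coefficients for an index name
index_levels <- function(design, idx) {
  if (idx == ".rep") return(design$reps[1L])
  lv <- design$factors[[idx]]$levels
  lv[1L]  # balanced template (per-group vector collapses to its first entry)
}

index_symbol <- function(design, idx) {
  if (idx == ".rep") return("n")
  design$symbols[[idx]]
}

index_random <- function(design, idx) {
  if (idx == ".rep") return(TRUE)
  design$factors[[idx]]$kind == "random"
}
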