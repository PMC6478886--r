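## Sphericity: the F ratios of within-subject tests are exact only when the
## variances of all pairwise differences among the repeated measurements are
## equal.  Departures are quantified per stratum from the pooled
## within-group covariance of the subject-by-cell matrix, projected onto an
## orthonormal basis of the stratum's contrast space.

# orthonormal contrast rows for one factor: (m-1) x m, rows orthonormal and
# orthogonal to the unit vector
ortho_contrasts <- function(m) {
  H <- stats::contr.helmert(m)
  t(H) / sqrt(colSums(H^2))
}

#' Assess sphericity for a within-subject stratum
#'
#' Computes, from the pooled within-group covariance of the per-subject
#' cell means over the given within-subject factor(s), the pairwise
#' difference variances, Mauchly's W with its chi-square p-value, and the
#' Greenhouse-Geisser and Huynh-Feldt epsilons. For a crossing of several
#' factors the interaction contrast space (Kronecker product of the
#' per-factor orthonormal contrasts) is used, matching the space tested in
#' that stratum. Other within factors are averaged over first.
#'
#' @param data Long-format data frame.
#' @param within Character vector of within-subject factor(s) defining the
#'   stratum.
#' @param design An [rm_design()] object.
#' @param response Response column name.
#' @return An object of class `"sphericity_report"` with elements
#'   `pair_var`, `mauchly_W`, `mauchly_p`, `epsilon_gg`, `epsilon_hf` (both
#'   1 exactly when the contrast space is one-dimensional) and
#'   `lambda_check` (maximum deviation of the difference variances from
#'   their mean).
#' @export
assess_sphericity <- function(data, within, design, response = "y") {
  bad <- setdiff(within, design$within)
  if (length(bad)) {
    pe_stop(paste("not within-subject factors:", paste(bad, collapse = ", ")),
            "peranova_unsupported_design")
  }
  avdata <- average_over(data, setdiff(design$within, within), design,
                         response = response)
  lev <- design_levels(design)
  m <- prod(vapply(within, function(f) lev[[f]][1L], 0))
  nsub <- max(avdata[[design$unit]])
  # rows of avdata are subject-major, cells fastest
  Yw <- matrix(avdata[[response]], nrow = m)  # cells x subjects
  Yw <- t(Yw)                                  # subjects x cells
  grp <- if (length(design$between)) {
    gi <- interaction_index(
      avdata[design$between],
      vapply(design$between, function(f) lev[[f]][1L], 0L))
    gi[!duplicated(avdata[[design$unit]])]
  } else rep(1L, nsub)
  g <- length(unique(grp))
  f_err <- nsub - g
  if (f_err < m) {
    pe_stop("too few subjects for a non-singular within-cell covariance",
            "peranova_degenerate_design")
  }
  centered <- Yw
  for (gg in unique(grp)) {
    sel <- grp == gg
    centered[sel, ] <- sweep(Yw[sel, , drop = FALSE], 2L,
                             colMeans(Yw[sel, , drop = FALSE]))
  }
  S <- crossprod(centered) / f_err
  pairs <- utils::combn(m, 2L)
  pv <- apply(pairs, 2L, function(ij)
    S[ij[1L], ij[1L]] + S[ij[2L], ij[2L]] - 2 * S[ij[1L], ij[2L]])
  names(pv) <- apply(pairs, 2L, paste, collapse = "-")
  Cm <- Reduce(kronecker, rev(lapply(within, function(f)
    ortho_contrasts(lev[[f]][1L]))))
  sph <- epsilons_from_cov(S, Cm, f_err)
  structure(c(list(stratum = paste(within, collapse = ":"), within = within,
                   pair_var = pv,
                   lambda_check = max(abs(pv - mean(pv))),
                   n_subjects = nsub, f_error = f_err),
              sph),
            class = "sphericity_report")
}

# Mauchly W / GG / HF from a covariance matrix and orthonormal contrasts
epsilons_from_cov <- function(S, Cm, f_err) {
  Sc <- Cm %*% S %*% t(Cm)
  d <- nrow(Cm)
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  gg <- sum(ev)^2 / (d * sum(ev^2))
  hf_raw <- ((f_err + 1) * d * gg - 2) / (d * (f_err - d * gg))
  hf <- min(1, hf_raw)
  if (d == 1L) {
    gg <- 1; hf <- 1; hf_raw <- 1
    W <- 1; p <- NA_real_
  } else {
    W <- prod(ev) / (sum(ev) / d)^d
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * f_err)
    stat <- -f_err * rho * log(max(W, .Machine$double.xmin))
    p <- stats::pchisq(stat, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  }
  list(mauchly_W = W, mauchly_p = p, epsilon_gg = gg, epsilon_hf = hf,
       epsilon_hf_uncapped = hf_raw, d = d)
}

#' @export
print.sphericity_report <- function(x, ...) {
  cat(sprintf("Sphericity for %s (%d-dimensional contrast space)\n",
              x$stratum, x$d))
  cat("  pairwise difference variances:\n")
  print(signif(x$pair_var, 4))
  cat(sprintf("  Mauchly W = %.4f (p = %s)\n", x$mauchly_W,
              format.pval(x$mauchly_p)))
  cat(sprintf("  epsilon: GG = %.4f, HF = %.4f\n",
              x$epsilon_gg, x$epsilon_hf))
  invisible(x)
}

# sphericity reports for every within stratum of a fitted model
fit_sphericity_reports <- function(fit) {
  out <- list()
  for (nm in names(fit$engine$entries)) {
    W <- fit$engine$entries[[nm]]$plan_entry$within_kept
    if (!length(W)) next
    rep <- tryCatch(
      assess_sphericity(fit$data, W, fit$design, response = fit$response),
      error = function(e) NULL)
    if (!is.null(rep)) {
      rep$stratum <- nm
      out[[nm]] <- rep
    }
  }
  out
}

#' Apply a sphericity correction to the degrees of freedom
#'
#' Multiplies the numerator and denominator df of every within-subject test
#' by the stratum's epsilon and recomputes the p-values; the F statistics
#' are unchanged. `method = "none"` returns the input untouched, which is
#' the behaviour needed to compare against software operating under the
#' sphericity assumption.
#'
#' @param x A `"peranova"` fit, or an ANOVA table data frame.
#' @param report For the data-frame method, a `"sphericity_report"` (or
#'   list of them) whose `stratum` matches the table's `error_term`
#'   entries.
#' @param method `"none"`, `"gg"` or `"hf"`.
#' @param ... Unused.
#' @return Same class as `x`, with adjusted `df` and `p`.
#' @export
adjust_df <- function(x, ...) UseMethod("adjust_df")

#' @rdname adjust_df
#' @export
adjust_df.peranova <- function(x, method = c("none", "gg", "hf"),
                               report = x$sphericity, ...) {
  method <- match.arg(method)
  if (method == "none") return(x)
  for (r in report) {
    x$table <- adjust_df(x$table, r, method = method)
  }
  x$correction <- method
  x
}

#' @rdname adjust_df
#' @export
adjust_df.data.frame <- function(x, report, method = c("none", "gg", "hf"),
                                 ...) {
  method <- match.arg(method)
  if (method == "none") return(x)
  if (inherits(report, "sphericity_report")) report <- list(report)
  for (r in report) {
    eps <- if (method == "gg") r$epsilon_gg else r$epsilon_hf
    rows <- x$error_term == r$stratum & !startsWith(x$effect, "Error: ")
    errow <- x$effect == paste0("Error: ", r$stratum)
    x$df[rows] <- x$df[rows] * eps
    x$error_df[rows] <- x$error_df[rows] * eps
    x$df[errow] <- x$df[errow] * eps
    x$p[rows] <- stats::pf(x$F[rows], x$df[rows], x$error_df[rows],
                           lower.tail = FALSE)
  }
  x
}
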