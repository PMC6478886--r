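#' Specify a simulation with the variance-component structure of a
#' mixed-measures model
#'
#' Responses are generated as the sum of the grand mean, fixed cell
#' effects, a Gaussian draw for every random stratum (subject,
#' subject-by-within-factor), and residual noise. Fixed effects must sum
#' to zero over every margin of their term (the sigma-restricted truth).
#' The `"spherical"` covariance mode is exactly this variance-component
#' construction; `"compound_symmetric"` and `"ar1"` instead draw each
#' subject's residual vector from the corresponding within-subject
#' covariance, to exercise sphericity diagnostics.
#'
#' @param design An [rm_design()] object.
#' @param mu Grand mean.
#' @param effects Named list of fixed-effect arrays: one entry per term
#'   label (e.g. `"A"`, `"A:B"`), a vector over the term's level
#'   combinations with the first factor varying fastest.
#' @param cell_means Optional vector of full cell means (non-unit crossing,
#'   first factor fastest) used instead of `mu` + `effects`.
#' @param variance Named vector: `sigma2` (residual) plus one entry per
#'   random stratum label (e.g. `"Subject(Drink)"`,
#'   `"Subject(Drink):Location"`); missing components are zero.
#' @param covariate Optional list with elements `name`, `varies_over`
#'   (within factors the covariate varies over), and `slopes`, a named
#'   vector with entries `"subject"` (per-subject mean slope), one per
#'   within factor (per-level-mean slope), and `"raw"`.
#' @param mode Residual covariance mode.
#' @param rho Correlation parameter for `"compound_symmetric"`/`"ar1"`.
#' @param seed Optional seed applied at the start of each simulation call.
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(design, mu = 0, effects = list(), cell_means = NULL,
                     variance = c(sigma2 = 1), covariate = NULL,
                     mode = c("spherical", "compound_symmetric", "ar1"),
                     rho = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (any(variance < 0)) {
    pe_stop("variance components must be non-negative",
            "peranova_degenerate_design")
  }
  lev <- design_levels(design)
  for (nm in names(effects)) {
    fs <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    sz <- vapply(fs, function(f) lev[[f]][1L], 0L)
    e <- array(effects[[nm]], dim = sz)
    if (length(e) != prod(sz)) {
      pe_stop(sprintf("effect '%s' must have %d values", nm, prod(sz)),
              "peranova_degenerate_design")
    }
    for (k in seq_along(fs)) {
      s <- if (length(sz) == 1L) sum(e)
           else apply(e, setdiff(seq_along(sz), k), sum)
      if (max(abs(s)) > 1e-8) {
        pe_stop(sprintf("effect '%s' must sum to zero over factor '%s'",
                        nm, fs[k]),
                "peranova_degenerate_design")
      }
    }
    effects[[nm]] <- e
  }
  structure(list(design = design, mu = mu, effects = effects,
                 cell_means = cell_means, variance = variance,
                 covariate = covariate, mode = mode, rho = rho, seed = seed),
            class = "sim_spec")
}

# fixed part of the response for an observation table
sim_fixed_part <- function(spec, obs) {
  design <- spec$design
  lev <- design_levels(design)
  nonunit <- setdiff(names(design$factors), design$unit)
  if (!is.null(spec$cell_means)) {
    ci <- interaction_index(obs[nonunit],
                            vapply(nonunit, function(f) lev[[f]][1L], 0L))
    return(spec$cell_means[ci])
  }
  y <- rep(spec$mu, nrow(obs))
  for (nm in names(spec$effects)) {
    fs <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    idx <- interaction_index(obs[fs],
                             vapply(fs, function(f) lev[[f]][1L], 0L))
    y <- y + as.vector(spec$effects[[nm]])[idx]
  }
  y
}

# Subject-by-within draws follow the restricted mixed-model convention
# (the one under which the classical EMS tables hold): each subject's
# interaction effects sum to zero over the within-factor levels, enforced
# by centering the Gaussian draws within subject.
center_draws <- function(E, nw) {
  if (nw <= 1L) return(E)
  M <- as.matrix(E)
  blk <- rep(seq_len(nrow(M) / nw), each = nw)
  M <- M - (rowsum(M, blk) / nw)[blk, , drop = FALSE]
  if (is.matrix(E)) M else drop(M)
}

sim_stratum_draw <- function(g, nvox = 1L) {
  E <- matrix(stats::rnorm(g$n * nvox, sd = g$sd), g$n, nvox)
  center_draws(E, g$nw)
}

# indicator structure of the random strata (excluding the residual)
sim_random_groups <- function(spec, obs) {
  design <- spec$design
  if (is.na(design$unit)) return(list())
  lev <- design_levels(design)
  terms <- design_terms(design)
  out <- list()
  for (t in terms) {
    if (!t$random || t$is_residual) next
    sd2 <- spec$variance[t$label]
    idx <- obs[[design$unit]]
    ngrp <- max(idx)
    nw <- 1L
    if (length(t$within_part)) {
      w <- interaction_index(obs[t$within_part],
                             vapply(t$within_part,
                                    function(f) lev[[f]][1L], 0L))
      nw <- prod(vapply(t$within_part, function(f) lev[[f]][1L], 0L))
      idx <- (idx - 1L) * nw + w
      ngrp <- ngrp * nw
    }
    out[[t$label]] <- list(idx = idx, n = ngrp, nw = nw,
                           sd = sqrt(if (is.na(sd2)) 0 else sd2))
  }
  out
}

# residual draw under the requested covariance mode
sim_residuals <- function(spec, obs) {
  design <- spec$design
  sigma2 <- spec$variance[["sigma2"]]
  n <- nrow(obs)
  if (spec$mode == "spherical" || is.na(design$unit) ||
      !length(design$within)) {
    return(stats::rnorm(n, sd = sqrt(sigma2)))
  }
  lev <- design_levels(design)
  m <- prod(vapply(design$within, function(f) lev[[f]][1L], 0L))
  wcell <- interaction_index(obs[design$within],
                             vapply(design$within,
                                    function(f) lev[[f]][1L], 0L))
  Sg <- if (spec$mode == "compound_symmetric") {
    sigma2 * ((1 - spec$rho) * diag(m) + spec$rho)
  } else {
    sigma2 * spec$rho^abs(outer(seq_len(m), seq_len(m), "-"))
  }
  R <- chol(Sg)
  sid <- obs[[design$unit]]
  nsub <- max(sid)
  E <- matrix(stats::rnorm(nsub * m), nsub, m) %*% R
  E[cbind(sid, wcell)]
}

#' Simulate a long-format dataset
#'
#' @param spec A [sim_spec()] object.
#' @return Data frame with the subject column, one level-index column per
#'   factor, the response `y`, and the covariate column if requested.
#' @examples
#' d <- rm_design(within = c(A = 2), between = c(B = 2), n = 6)
#' spec <- sim_spec(d, effects = list(A = c(-0.5, 0.5)),
#'                  variance = c(sigma2 = 1, `Subject(B)` = 2), seed = 42)
#' head(simulate_dataset(spec))
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  obs <- synth_obs(spec$design)
  y <- sim_fixed_part(spec, obs)
  for (g in sim_random_groups(spec, obs)) {
    if (g$sd > 0) y <- y + sim_stratum_draw(g)[g$idx]
  }
  y <- y + sim_residuals(spec, obs)
  dat <- obs
  if (!is.null(spec$covariate)) {
    cv <- spec$covariate
    x <- sim_covariate_raw(spec, obs)
    dat[[cv$name]] <- x
    y <- y + sim_covariate_effect(spec, obs, x)
  }
  dat$y <- y
  dat
}

# raw covariate at the resolution of varies_over
sim_covariate_raw <- function(spec, obs) {
  design <- spec$design
  cv <- spec$covariate
  lev <- design_levels(design)
  idx <- obs[[design$unit]]
  n <- max(idx)
  vo <- cv$varies_over %||% character()
  if (length(vo)) {
    w <- interaction_index(obs[vo],
                           vapply(vo, function(f) lev[[f]][1L], 0L))
    nw <- prod(vapply(vo, function(f) lev[[f]][1L], 0L))
    idx <- (idx - 1L) * nw + w
    n <- n * nw
  }
  stats::rnorm(n)[idx]
}

# stratum-decomposed covariate contribution (per-stratum slopes)
sim_covariate_effect <- function(spec, obs, x) {
  design <- spec$design
  cv <- spec$covariate
  slopes <- cv$slopes
  lev <- design_levels(design)
  sid <- obs[[design$unit]]
  contrib <- rep(0, nrow(obs))
  has <- function(nm) nm %in% names(slopes) && !is.na(slopes[[nm]])
  if (has("subject")) {
    contrib <- contrib + slopes[["subject"]] * stats::ave(x, sid, FUN = mean)
  }
  for (w in design$within) {
    if (!has(w)) next
    key <- interaction(sid, obs[[w]])
    contrib <- contrib + slopes[[w]] * stats::ave(x, key, FUN = mean)
  }
  if (has("raw")) contrib <- contrib + slopes[["raw"]] * x
  contrib
}

#' Simulate an image stack with a known effect location
#'
#' Generates independent voxel-wise datasets sharing the design's random
#' structure (each voxel gets its own subject and stratum draws), with the
#' fixed effects injected only inside `effect_mask`. One volume is produced
#' per observation row (per subject and within-cell). With `out_dir` the
#' volumes are written as NIfTI files and the observation table as CSV.
#'
#' @param spec A [sim_spec()] object.
#' @param shape Volume dimensions.
#' @param effect_mask Logical array of dimension `shape` marking where the
#'   fixed effects are present (default: nowhere, a null stack).
#' @param out_dir Optional directory to write NIfTI volumes + table to.
#' @return List with `images` (array `shape` x observations),
#'   `obs_table`, `effect_mask`, and (if written) `paths` and
#'   `table_path`.
#' @export
simulate_images <- function(spec, shape = c(8, 8, 8), effect_mask = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  obs <- synth_obs(spec$design)
  nobs <- nrow(obs)
  nvox <- prod(shape)
  if (is.null(effect_mask)) effect_mask <- array(FALSE, dim = shape)
  fx <- sim_fixed_part(spec, obs) - spec$mu
  Y <- matrix(spec$mu, nobs, nvox) + outer(fx, as.numeric(effect_mask))
  for (g in sim_random_groups(spec, obs)) {
    if (g$sd > 0) {
      Y <- Y + sim_stratum_draw(g, nvox)[g$idx, , drop = FALSE]
    }
  }
  Y <- Y + matrix(sim_residuals_matrix(spec, obs, nvox), nobs, nvox)
  images <- array(t(Y), dim = c(shape, nobs))
  out <- list(images = images, obs_table = obs, effect_mask = effect_mask)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nobs)
    for (i in seq_len(nobs)) {
      paths[i] <- file.path(out_dir, sprintf("obs%03d.nii.gz", i))
      RNifti::writeNifti(RNifti::asNifti(array(Y[i, ], dim = shape)),
                         paths[i])
    }
    tp <- file.path(out_dir, "observations.csv")
    utils::write.csv(cbind(obs, file = basename(paths)), tp,
                     row.names = FALSE)
    out$paths <- paths
    out$table_path <- tp
  }
  out
}

sim_residuals_matrix <- function(spec, obs, nvox) {
  if (spec$mode == "spherical") {
    return(stats::rnorm(nrow(obs) * nvox,
                        sd = sqrt(spec$variance[["sigma2"]])))
  }
  vapply(seq_len(nvox), function(v) sim_residuals(spec, obs),
         numeric(nrow(obs)))
}

#' Monte-Carlo check of the expected mean squares
#'
#' Repeatedly simulates data from a balanced specification, fits the
#' partitioned-error model, and compares the empirical mean of every mean
#' square with the numeric evaluation of its symbolic EMS row (variance
#' components plus fixed-effect quadratic forms). This is the keystone
#' cross-module validation: the EMS derivation, the simulator and the
#' fitting engine must all agree for the means to match.
#'
#' @param spec A balanced [sim_spec()].
#' @param n_reps Number of simulated datasets.
#' @return Data frame with one row per model term: empirical mean MS, its
#'   standard error, the predicted EMS value, and the z-discrepancy.
#' @export
monte_carlo_ems_check <- function(spec, n_reps = 2000) {
  stopifnot(inherits(spec, "sim_spec"))
  design <- spec$design
  if (!isTRUE(design$balanced)) {
    pe_stop("EMS Monte-Carlo check requires a balanced design",
            "peranova_unsupported_design")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  obs <- synth_obs(design)
  template <- obs
  template$y <- 0
  engine <- pe_build_engine(design, template, response = "y")
  fx <- sim_fixed_part(spec, obs)
  rg <- sim_random_groups(spec, obs)
  ms <- NULL
  for (i in seq_len(n_reps)) {
    y <- fx
    for (g in rg) if (g$sd > 0) y <- y + sim_stratum_draw(g)[g$idx]
    y <- y + sim_residuals(spec, obs)
    tab <- pe_assemble_table(engine, pe_engine_pass(engine, y))
    if (is.null(ms)) {
      ms <- matrix(NA_real_, n_reps, nrow(tab),
                   dimnames = list(NULL, tab$effect))
    }
    ms[i, ] <- tab$MS
  }
  term <- sub("^Error: ", "", colnames(ms))
  pred <- vapply(term, function(t) ems_value(engine$ems, t, spec), 0)
  data.frame(term = term,
             mean_MS = colMeans(ms),
             se = apply(ms, 2L, stats::sd) / sqrt(n_reps),
             ems = pred,
             z = (colMeans(ms) - pred) / (apply(ms, 2L, stats::sd) /
                                            sqrt(n_reps)),
             row.names = NULL)
}

# numeric value of one EMS row under a simulation spec
ems_value <- function(ems, term, spec) {
  design <- ems$design
  comps <- ems$rows[[term]]
  if (is.null(comps)) return(NA_real_)
  val <- 0
  for (cm in comps) {
    coef <- prod(vapply(cm$coef, function(s) index_levels(design, s), 0))
    sym <- cm$symbol
    v <- if (sym == "sigma2") {
      spec$variance[["sigma2"]]
    } else if (startsWith(sym, "sigma2_")) {
      s2 <- spec$variance[sub("^sigma2_", "", sym)]
      if (is.na(s2)) 0 else unname(s2)
    } else {  # Q_<term>: sum of squared effects over the term's df
      lab <- sub("^Q_", "", sym)
      e <- spec$effects[[lab]]
      if (is.null(e)) 0 else {
        fs <- strsplit(lab, ":", fixed = TRUE)[[1L]]
        dfq <- prod(vapply(fs, function(f)
          design$factors[[f]]$levels[1L] - 1L, 0L))
        sum(e^2) / dfq
      }
    }
    val <- val + coef * v
  }
  val
}
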