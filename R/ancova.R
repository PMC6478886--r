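#' Declare a continuous covariate
#'
#' A covariate is characterised by the within-subject factors it varies
#' over: an empty `varies_over` is a between-subjects (time-invariant)
#' covariate with one value per subject; a covariate that varies over every
#' within factor has one value per design cell. The set governs which error
#' strata receive a regression slope when the covariate is decomposed.
#'
#' @param name Covariate column name.
#' @param varies_over Character vector of within-subject factor names the
#'   covariate varies over (empty for a between-subjects covariate).
#' @param center `"grand_mean"` (default) or `"none"`: grand-mean centering
#'   keeps the intercept at the grand mean so cell-mean contrasts remain
#'   interpretable.
#' @return An object of class `"covariate_spec"`.
#' @export
covariate_spec <- function(name, varies_over = character(),
                           center = c("grand_mean", "none")) {
  structure(list(name = name, varies_over = as.character(varies_over),
                 center = match.arg(center)),
            class = "covariate_spec")
}

# accept character names, infer varies_over from the data
normalize_covariates <- function(covariates, design, data) {
  if (is.null(covariates)) return(list())
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  if (is.character(covariates)) {
    covariates <- lapply(covariates, function(nm)
      covariate_spec(nm, infer_varies_over(data, nm, design)))
  }
  for (cv in covariates) {
    if (!cv$name %in% names(data)) {
      pe_stop(sprintf("covariate column '%s' not found", cv$name),
              "peranova_incomplete_data")
    }
    if (stats::var(data[[cv$name]]) < 1e-24) {
      pe_stop(sprintf("covariate '%s' is constant", cv$name),
              "peranova_degenerate_design")
    }
  }
  covariates
}

# a covariate varies over a within factor if, for some subject, its mean
# differs across that factor's levels
infer_varies_over <- function(data, name, design) {
  obs <- normalize_obs(design, data)
  x <- data[[name]]
  sid <- obs[[design$unit]]
  out <- character()
  for (w in design$within) {
    m <- tapply(x, list(sid, obs[[w]]), mean)
    spread <- apply(m, 1L, function(r) max(r) - min(r))
    if (any(spread > 1e-10, na.rm = TRUE)) out <- c(out, w)
  }
  out
}

subsets_of <- function(x) {
  out <- list(character())
  for (k in seq_along(x)) {
    out <- c(out, utils::combn(x, k, simplify = FALSE))
  }
  out
}

#' Decompose a covariate into stratum-matched columns
#'
#' In a partitioned-error analysis there are as many covariate regression
#' coefficients as error strata. The raw covariate is decomposed into one
#' column per stratum: the per-subject mean (between stratum), the
#' per-subject means at each level of each within factor (the
#' subject-by-factor strata), and the raw values (residual stratum).
#' Columns that are identical after averaging — as happens when the
#' covariate is constant over some within factor — are redundant and
#' dropped, keeping the first (coarsest) occurrence.
#'
#' @param data Long-format data frame.
#' @param cov A [covariate_spec()] or covariate column name.
#' @param design An [rm_design()] object.
#' @return A data frame of derived columns; attribute `"strata"` maps each
#'   kept column to the within-factor subset indexing its stratum.
#' @export
decompose_covariate <- function(data, cov, design) {
  if (is.character(cov)) cov <- covariate_spec(cov,
                                               infer_varies_over(data, cov,
                                                                 design))
  cov <- normalize_covariates(list(cov), design, data)[[1L]]
  obs <- normalize_obs(design, data)
  dec <- covariate_columns(data[[cov$name]], obs, design, cov,
                           within_set = design$within)
  out <- as.data.frame(dec$cols)
  attr(out, "strata") <- dec$strata
  out
}

# derived columns of one covariate over the subsets of `within_set`,
# redundancy-filtered by exact column equality
covariate_columns <- function(x, obs, design, cov, within_set) {
  sid <- obs[[design$unit]]
  cols <- list()
  strata <- list()
  for (V in subsets_of(within_set)) {
    key <- if (length(V)) {
      interaction(sid, interaction_index(
        obs[V], vapply(V, function(f) design$factors[[f]]$levels[1L], 0L)),
        drop = FALSE)
    } else sid
    col <- stats::ave(x, key, FUN = mean)
    dup <- any(vapply(cols, function(cc) max(abs(cc - col)) < 1e-10, TRUE))
    if (dup) next
    nm <- if (!length(V)) paste0(cov$name, ".subj")
          else if (setequal(V, within_set)) cov$name
          else paste0(cov$name, ".subj.", paste(V, collapse = "."))
    cols[[nm]] <- col
    strata[[nm]] <- V
  }
  list(cols = cols, strata = strata)
}

# covariate columns entering the sub-model for stratum S x W, built from
# the already-averaged data; returns rank-filtered centered columns and the
# list of columns to test in this stratum
stratum_covariate_columns <- function(avdata, covariates, design, W) {
  obs <- avdata
  cols <- NULL
  tests <- list()
  labels <- character()
  for (cv in covariates) {
    dec <- covariate_columns(avdata[[cv$name]], avdata, design, cv,
                             within_set = W)
    for (nm in names(dec$cols)) {
      col <- dec$cols[[nm]]
      if (cv$center == "grand_mean") col <- col - mean(col)
      cols <- cbind(cols, col)
      labels <- c(labels, nm)
      if (setequal(dec$strata[[nm]], W) && all(W %in% cv$varies_over)) {
        lab <- if (!length(W)) paste0(cv$name, ".subj")
               else if (setequal(W, design$within)) cv$name
               else paste0(cv$name, ".", paste(W, collapse = "."))
        tests[[length(tests) + 1L]] <- list(label = lab, name = cv$name,
                                            index = length(labels))
      }
    }
  }
  if (is.null(cols)) return(list(columns = NULL, tests = list()))
  colnames(cols) <- labels
  list(columns = cols, tests = tests)
}
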