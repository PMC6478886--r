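#' Load a stack of per-subject summary images
#'
#' Reads one volume per observation row (one image per subject per
#' within-subject cell), checks that all volumes share shape and
#' orientation, masks out non-finite voxels, and returns the in-mask data
#' as an observations-by-voxels matrix.
#'
#' @param paths Character vector of NIfTI file paths (one per row of
#'   `obs_table`), or a 4-D array with the observation index last.
#' @param obs_table Data frame with the subject column and one column per
#'   factor, rows aligned with `paths`.
#' @param mask Optional logical array (or NIfTI path) selecting voxels;
#'   defaults to all voxels, minus any with non-finite values (dropped
#'   with a warning).
#' @return An object of class `"voxel_dataset"`: `Y` (observations x
#'   in-mask voxels), `obs`, `mask`, `dim`, `ref` (reference image for
#'   geometry).
#' @export
load_image_stack <- function(paths, obs_table, mask = NULL) {
  if (is.array(paths) && length(dim(paths)) == 4L) {
    dims <- dim(paths)[1:3]
    nobs <- dim(paths)[4L]
    Y <- t(matrix(paths, prod(dims), nobs))
    ref <- RNifti::asNifti(array(paths[, , , 1L], dim = dims))
  } else {
    imgs <- lapply(paths, RNifti::readNifti)
    dims <- dim(imgs[[1L]])
    ref <- imgs[[1L]]
    x0 <- RNifti::xform(imgs[[1L]])
    for (i in seq_along(imgs)) {
      if (!identical(dim(imgs[[i]]), dims) ||
          max(abs(RNifti::xform(imgs[[i]]) - x0)) > 1e-4) {
        pe_stop(sprintf("image %d does not match the stack's shape/orientation",
                        i),
                "peranova_geometry")
      }
    }
    nobs <- length(imgs)
    Y <- t(vapply(imgs, as.numeric, numeric(prod(dims))))
  }
  if (nobs != nrow(obs_table)) {
    pe_stop("observation table rows do not match the number of images",
            "peranova_geometry")
  }
  if (is.character(mask)) mask <- RNifti::readNifti(mask) > 0
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!identical(dim(mask), as.integer(dims)) &&
      !identical(dim(mask), dims)) {
    pe_stop("mask dimensions do not match the images", "peranova_geometry")
  }
  mvec <- as.vector(mask)
  bad <- colSums(!is.finite(Y)) > 0
  if (any(bad & mvec)) {
    warning(sprintf("%d voxel(s) with non-finite values removed from the mask",
                    sum(bad & mvec)))
    mvec <- mvec & !bad
  }
  structure(list(Y = Y[, mvec, drop = FALSE], obs = obs_table,
                 mask = array(mvec, dim = dims), dim = dims, ref = ref),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("Voxel dataset: %d observations x %d in-mask voxels (volume %s)\n",
              nrow(x$Y), ncol(x$Y), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Voxel-wise partitioned-error ANOVA
#'
#' Runs the full multi-model analysis independently at every in-mask voxel.
#' The plan, sub-model design matrices, and contrast operators are computed
#' once and applied to all voxels by matrix algebra; per-voxel results are
#' identical to running [run_partitioned_anova()] on each voxel's data.
#' Optionally applies a per-voxel sphericity correction and Benjamini-
#' Hochberg FDR across in-mask voxels, per effect.
#'
#' @param vd A `"voxel_dataset"` from [load_image_stack()].
#' @param design An [rm_design()] consistent with the observation table.
#' @param covariates Optional covariates (columns of the observation
#'   table).
#' @param correction Per-voxel sphericity df correction (`"none"`, `"gg"`,
#'   `"hf"`).
#' @param fdr Optional FDR level; adds BH-adjusted p maps and a
#'   significance map per effect.
#' @return An object of class `"voxelwise_results"`: per effect, 3-D `F`,
#'   `p` (and `p_fdr`) maps plus the df pair; per within stratum, an
#'   epsilon map when a correction is requested.
#' @export
run_voxelwise <- function(vd, design, covariates = NULL,
                          correction = c("none", "gg", "hf"), fdr = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(vd, "voxel_dataset"))
  template <- vd$obs
  template$.pe_y <- vd$Y[, 1L]
  engine <- pe_build_engine(design, template, response = ".pe_y",
                            covariates = covariates)
  nv <- ncol(vd$Y)
  to_map <- function(v) {
    arr <- array(NA_real_, dim = vd$dim)
    arr[vd$mask] <- v
    arr
  }
  maps <- list()
  eps_maps <- list()
  for (nm in names(engine$entries)) {
    en <- engine$entries[[nm]]
    fit <- en$fit
    Yav <- rowsum(vd$Y, en$avg_info$tidx) / en$avg_info$counts
    rss <- colSums((Yav - fit$Xm %*% (fit$Xp %*% Yav))^2)
    dfe <- fit$df_planned
    eps <- rep(1, nv)
    W <- en$plan_entry$within_kept
    if (correction != "none" && length(W)) {
      eps <- voxel_epsilons(Yav, engine, nm, correction)
      eps_maps[[nm]] <- to_map(eps)
    }
    for (ef in en$effects) {
      Q <- ef$Cop %*% Yav
      ss <- colSums(Q * (ef$Mi %*% Q))
      Fv <- (ss / ef$r) / (rss / dfe)
      p <- stats::pf(Fv, ef$r * eps, dfe * eps, lower.tail = FALSE)
      res <- list(F = to_map(Fv), p = to_map(p),
                  df = c(ef$r, dfe), error_term = nm)
      if (!is.null(fdr)) {
        padj <- stats::p.adjust(p, method = "BH")
        res$p_fdr <- to_map(padj)
        res$significant <- to_map(as.numeric(padj < fdr))
      }
      maps[[ef$label]] <- res
    }
  }
  structure(list(maps = maps, epsilon = eps_maps, design = design,
                 plan = engine$plan, mask = vd$mask, dim = vd$dim,
                 ref = vd$ref, correction = correction, fdr = fdr,
                 df_all = engine$df_all),
            class = "voxelwise_results")
}

# per-voxel GG/HF epsilon for one stratum from the averaged responses
voxel_epsilons <- function(Yav, engine, stratum, method) {
  en <- engine$entries[[stratum]]
  design <- engine$design
  W <- en$plan_entry$within_kept
  lev <- design_levels(design)
  m <- prod(vapply(W, function(f) lev[[f]][1L], 0L))
  nsub <- nrow(Yav) / m
  grp <- subject_groups(design, en$avdata)
  g <- length(unique(grp))
  Cm <- Reduce(kronecker, rev(lapply(W, function(f)
    ortho_contrasts(lev[[f]][1L]))))
  vapply(seq_len(ncol(Yav)), function(v) {
    Yw <- t(matrix(Yav[, v], nrow = m))  # subjects x cells
    for (gg in unique(grp)) {
      sel <- grp == gg
      Yw[sel, ] <- sweep(Yw[sel, , drop = FALSE], 2L,
                         colMeans(Yw[sel, , drop = FALSE]))
    }
    S <- crossprod(Yw) / (nsub - g)
    e <- epsilons_from_cov(S, Cm, nsub - g)
    if (method == "gg") e$epsilon_gg else e$epsilon_hf
  }, 0)
}

#' @export
print.voxelwise_results <- function(x, ...) {
  cat(sprintf("Voxel-wise partitioned-error ANOVA: %d effect(s), %d in-mask voxels\n",
              length(x$maps), sum(x$mask)))
  for (nm in names(x$maps)) {
    m <- x$maps[[nm]]
    cat(sprintf("  %-28s df (%g, %g), error: %s, max F = %.2f\n",
                nm, m$df[1L], m$df[2L], m$error_term,
                max(m$F, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write statistic maps and a design sidecar
#'
#' One NIfTI volume per effect and statistic type, named
#' `<effect>_<stat>.nii.gz` (with `:` replaced by `x` in effect names),
#' carrying the geometry of the input images, plus a JSON sidecar recording
#' the design, the model plan, the df of every effect and the package
#' version.
#'
#' @param results A `"voxelwise_results"` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_stat_maps <- function(results, out_dir) {
  stopifnot(inherits(results, "voxelwise_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(arr, name) {
    path <- file.path(out_dir, paste0(gsub(":", "x", name, fixed = TRUE),
                                      ".nii.gz"))
    img <- RNifti::asNifti(arr, reference = results$ref)
    RNifti::writeNifti(img, path)
    written <<- c(written, path)
  }
  for (nm in names(results$maps)) {
    m <- results$maps[[nm]]
    for (s in intersect(c("F", "p", "p_fdr", "significant"), names(m))) {
      emit(m[[s]], paste0(nm, "_", s))
    }
  }
  for (nm in names(results$epsilon)) {
    emit(results$epsilon[[nm]], paste0(gsub(":", "x", nm), "_epsilon"))
  }
  side <- list(
    package = "peranova",
    version = as.character(utils::packageVersion("peranova")),
    correction = results$correction,
    fdr = results$fdr,
    design = lapply(results$design$factors, function(f)
      list(name = f$name, levels = f$levels, kind = f$kind,
           scope = f$scope, nested_in = f$nested_in)),
    plan = lapply(results$plan$entries, function(e)
      list(error_term = e$error_term, average_over = e$average_over,
           effects_tested = e$effects_tested, df_error = e$df_error)),
    df = as.list(results$df_all),
    effects = lapply(results$maps, function(m)
      list(df = m$df, error_term = m$error_term))
  )
  sp <- file.path(out_dir, "analysis.json")
  jsonlite::write_json(side, sp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, sp))
}
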