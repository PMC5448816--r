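## Flux variability analysis over the community steady-state polytope at a
## fixed growth rate, including abundance variability and pairwise abundance
## dependency scans.

## Turn a target specification into a named objective-coefficient vector.
## A target is either an organism id (abundance target, weight 1) or a list
## with components `X` (named weights over organism abundances) and/or `V`
## (data frame organism/reaction/weight over aggregate fluxes).
target_coef <- function(cm, lp, target) {
  vmap <- attr(lp, "vmap")
  coef <- numeric(0)
  if (is.character(target) && length(target) == 1L) {
    if (!target %in% names(cm$organisms)) stop("unknown organism: ", target)
    target <- list(X = stats::setNames(1, target))
  }
  stopifnot(is.list(target))
  if (!is.null(target$X)) {
    if (!all(names(target$X) %in% names(cm$organisms)))
      stop("abundance target names unknown organisms")
    ix <- vmap$X[names(target$X)]
    coef <- c(coef, stats::setNames(as.numeric(target$X), lp$var_id[ix]))
  }
  if (!is.null(target$V)) {
    v <- as.data.frame(target$V)
    stopifnot(all(c("organism", "reaction", "weight") %in% names(v)))
    for (r in seq_len(nrow(v))) {
      ix <- vmap$V[[v$organism[r]]][[v$reaction[r]]]
      if (is.null(ix) || is.na(ix))
        stop("unknown flux target: ", v$organism[r], "/", v$reaction[r])
      coef <- c(coef, stats::setNames(v$weight[r], lp$var_id[ix]))
    }
  }
  if (!length(coef)) stop("empty FVA target")
  coef
}

minmax_target <- function(lp, coef) {
  out <- c(min = NA_real_, max = NA_real_)
  for (dir in c("min", "max")) {
    s <- solve_lp(lp_set_objective(lp, coef, maximize = dir == "max"))
    out[dir] <- switch(s$status,
                       optimal = s$objval,
                       unbounded = if (dir == "max") Inf else -Inf,
                       infeasible = NA_real_,
                       stop("FVA LP failed"))
  }
  out
}

#' Flux variability analysis at a fixed community growth rate
#'
#' For each target (a weighted sum over aggregate fluxes and/or organism
#' abundances) computes the minimum and maximum over the community
#' steady-state polytope at growth rate `mu0`, with total biomass fixed at
#' `X0`.  Directions in which the target is unconstrained are reported as
#' infinite.
#'
#' @param cm a [build_community()] model.
#' @param mu0 fixed community growth rate, `0 <= mu0 <= mu_max`.
#' @param targets list of targets; each is an organism id (its abundance) or
#'   a list with `X` (named abundance weights) and/or `V` (data frame with
#'   columns `organism`, `reaction`, `weight`).  A named list names the
#'   output rows.
#' @return A data frame with columns `target`, `mu0`, `min`, `max`.
#' @export
steadycom_fva <- function(cm, mu0, targets) {
  stopifnot(inherits(cm, "community_model"), mu0 >= 0)
  lp <- assemble_steadycom_lp(cm, mu0, fix_total_biomass = TRUE)
  if (solve_lp(lp)$status != "optimal")
    stop("community model is infeasible at mu0 = ", mu0,
         " (growth rate above the community maximum?)")
  if (!is.list(targets) || is.data.frame(targets)) targets <- list(targets)
  nms <- names(targets)
  if (is.null(nms)) nms <- rep("", length(targets))
  res <- lapply(seq_along(targets), function(i) {
    coef <- target_coef(cm, lp, targets[[i]])
    mm <- minmax_target(lp, coef)
    nm <- if (nzchar(nms[i])) nms[i] else
      if (is.character(targets[[i]])) paste0("X[", targets[[i]], "]") else
        paste0("target", i)
    data.frame(target = nm, mu0 = mu0, min = mm[["min"]], max = mm[["max"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Abundance variability across community growth rates
#'
#' Convenience wrapper over [steadycom_fva()]: for each fraction in
#' `mu_fracs` computes every organism's feasible abundance range at
#' `mu = frac * mu_max`.
#'
#' @param cm a [build_community()] model.
#' @param mu_fracs numeric vector of growth-rate fractions in `[0, 1]`.
#' @param mu_max the maximal community growth rate (from [steadycom()]).
#' @return A data frame with columns `organism`, `frac`, `mu`, `min`, `max`.
#' @export
abundance_fva <- function(cm, mu_fracs, mu_max) {
  stopifnot(all(mu_fracs >= 0), all(mu_fracs <= 1), mu_max >= 0)
  orgs <- names(cm$organisms)
  out <- lapply(mu_fracs, function(f) {
    r <- steadycom_fva(cm, f * mu_max, as.list(orgs))
    data.frame(organism = orgs, frac = f, mu = f * mu_max,
               min = r$min, max = r$max, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise abundance dependency scan
#'
#' Fixes the abundance of one organism at each value of a grid and computes
#' the feasible abundance range of a second organism at a fixed fraction of
#' the maximal community growth rate.  The scan is classified as
#' `"competitive"` when the maximal dependent abundance is non-increasing
#' along the grid (one organism's gain is the other's loss), and
#' `"conditionally mutualistic"` when a region of positive slope exists
#' (raising one abundance enlarges the other's feasible range).
#'
#' @param cm a [build_community()] model.
#' @param orgA id of the organism whose abundance is fixed.
#' @param orgB id of the dependent organism.
#' @param grid abundance values for `orgA`; default 30 log-spaced points
#'   from `1e-3 * X0` to `X0`.
#' @param mu_frac fraction of `mu_max` at which to scan, in `(0, 1]`.
#' @param mu_max the maximal community growth rate.
#' @param slope_tol tolerance on finite differences of the upper range when
#'   classifying, default `1e-6 * X0` (LP degeneracy noise).
#' @return An object of class `pairwise_scan`: a list with the scan table
#'   (`fixed_value`, `dep_min`, `dep_max`, `feasible`) and the
#'   classification.
#' @export
pairwise_fva <- function(cm, orgA, orgB, grid = NULL, mu_frac = 0.9,
                         mu_max, slope_tol = 1e-6 * cm$X0) {
  stopifnot(orgA %in% names(cm$organisms), orgB %in% names(cm$organisms),
            orgA != orgB, mu_frac > 0, mu_frac <= 1, mu_max >= 0)
  if (is.null(grid))
    grid <- exp(seq(log(1e-3 * cm$X0), log(cm$X0), length.out = 30))
  stopifnot(all(grid > 0), all(grid <= cm$X0))
  mu0 <- mu_frac * mu_max
  lp <- assemble_steadycom_lp(cm, mu0, fix_total_biomass = TRUE)
  coefB <- target_coef(cm, lp, orgB)
  xA <- lp$var_id[attr(lp, "vmap")$X[[orgA]]]
  rows <- lapply(grid, function(a) {
    lpa <- lp_set_var_bounds(lp, xA, a, a)
    if (solve_lp(lpa)$status != "optimal")
      return(data.frame(fixed_value = a, dep_min = NA_real_,
                        dep_max = NA_real_, feasible = FALSE))
    mm <- minmax_target(lpa, coefB)
    data.frame(fixed_value = a, dep_min = mm[["min"]], dep_max = mm[["max"]],
               feasible = TRUE)
  })
  ranges <- do.call(rbind, rows)
  rownames(ranges) <- NULL
  feas <- ranges[ranges$feasible, , drop = FALSE]
  if (!nrow(feas))
    stop("no feasible grid point: mu_frac too high or grid outside the ",
         "feasible composition range")
  classification <- if (nrow(feas) >= 2 &&
                        any(diff(feas$dep_max) > slope_tol))
    "conditionally mutualistic" else "competitive"
  structure(list(fixed_organism = orgA, dependent_organism = orgB,
                 grid = grid, mu_frac = mu_frac, mu0 = mu0,
                 ranges = ranges, classification = classification),
            class = "pairwise_scan")
}

#' @export
print.pairwise_scan <- function(x, ...) {
  cat(sprintf("Pairwise abundance scan: %s (fixed) vs %s (dependent)\n",
              x$fixed_organism, x$dependent_organism))
  cat(sprintf("  at mu = %g (fraction %g of mu_max); %d/%d grid points feasible\n",
              x$mu0, x$mu_frac, sum(x$ranges$feasible), nrow(x$ranges)))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}
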