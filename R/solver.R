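#' Options for the community growth-rate search
#'
#' @param mu_tol absolute tolerance on the maximal community growth rate
#'   (1/h); the search stops when the feasibility bracket is narrower than
#'   this.  Default `1e-6`.
#' @param feas_tol feasibility tolerance on the total-biomass test
#'   `X_T(mu) >= X0`; default `1e-9`.
#' @param mu_guess initial growth-rate guess (1/h).  Default 0.1, within the
#'   0.02-0.25 1/h range reported for intestinal microbes.
#' @param max_iter maximum number of LPs solved during the search.
#' @param bracket_growth_factor multiplicative step used to expand the
#'   search upward while no infeasible growth rate has been found.
#' @param zero_tol biomass below which an organism is reported absent.
#' @return A list of class `steadycom_options`.
#' @export
steadycom_options <- function(mu_tol = 1e-6, feas_tol = 1e-9, mu_guess = 0.1,
                              max_iter = 50L, bracket_growth_factor = 2,
                              zero_tol = 1e-8) {
  stopifnot(mu_tol > 0, feas_tol > 0, mu_guess > 0, max_iter >= 1,
            bracket_growth_factor > 1, zero_tol > 0)
  structure(list(mu_tol = mu_tol, feas_tol = feas_tol, mu_guess = mu_guess,
                 max_iter = as.integer(max_iter),
                 bracket_growth_factor = bracket_growth_factor,
                 zero_tol = zero_tol),
            class = "steadycom_options")
}

## Pull the (abundance, flux, uptake, export) blocks out of an LP solution.
extract_blocks <- function(lp, x) {
  vmap <- attr(lp, "vmap")
  Xix <- if (!is.null(vmap$X)) vmap$X else NULL
  flux_block <- if (!is.null(vmap$V)) vmap$V else vmap$v
  list(abundance = if (!is.null(Xix)) stats::setNames(x[Xix], names(Xix)),
       flux = lapply(flux_block, function(ix) stats::setNames(x[ix], names(ix))),
       uptake = stats::setNames(x[vmap$u], names(vmap$u)),
       export = stats::setNames(x[vmap$e], names(vmap$e)))
}

#' Maximum total community biomass at a fixed growth rate
#'
#' Solves the community steady-state LP at fixed growth rate `mu` with the
#' total-biomass equality replaced by the objective `max X_T = sum_k X^k`.
#' The resulting scalar function `X_T(mu)` is non-increasing in `mu`, and
#' `X_T(mu) >= X0` holds exactly when the community constraints at growth
#' `mu` are satisfiable with total biomass `X0` — this equivalence drives
#' the growth-rate search in [steadycom()].
#'
#' @param cm a [build_community()] model.
#' @param mu fixed community growth rate (1/h), non-negative.
#' @return A list with `XT` (the maximal total biomass, 0 if infeasible),
#'   `status`, and `solution` (abundances, aggregate fluxes, community
#'   uptake/export at the maximizing point).
#' @export
max_total_biomass <- function(cm, mu) {
  lp <- assemble_steadycom_lp(cm, mu, fix_total_biomass = FALSE)
  vmap <- attr(lp, "vmap")
  obj <- stats::setNames(rep(1, length(vmap$X)), lp$var_id[vmap$X])
  lp <- lp_set_objective(lp, obj, maximize = TRUE)
  sol <- solve_lp(lp)
  if (sol$status == "unbounded") {
    inf_up <- names(cm$uptake_ub)[!is.finite(cm$uptake_ub)]
    stop("total biomass is unbounded at mu = ", mu,
         ": a growth-limiting resource is missing a community uptake bound",
         if (length(inf_up))
           paste0(" (unbounded uptakes: ", paste(inf_up, collapse = ", "), ")")
         else "")
  }
  if (sol$status != "optimal")
    return(list(XT = 0, status = sol$status, solution = NULL))
  list(XT = sol$objval, status = sol$status,
       solution = extract_blocks(lp, sol$x))
}

## Secant step on z(mu) = 1/X_T(mu), targeting z = 1/X0.  For communities
## limited by a single scalable resource X_T(mu) is proportional to 1/mu, so
## z is exactly linear in mu and the step lands on mu_max directly.
secant_mu <- function(mu1, XT1, mu2, XT2, X0) {
  z1 <- 1 / XT1
  z2 <- 1 / XT2
  if (!is.finite(z1) || !is.finite(z2) || z1 == z2) return(NA_real_)
  mu1 + (1 / X0 - z1) * (mu2 - mu1) / (z2 - z1)
}

#' Maximal community growth rate and abundances under community steady-state
#'
#' Finds the largest community growth rate `mu_max` at which all member
#' organisms can grow at the same specific rate while holding total biomass
#' `X0`, together with the member abundances and aggregate fluxes at that
#' rate.  The bilinear growth-coupling constraint becomes linear once `mu`
#' is fixed, so `mu_max = sup { mu : X_T(mu) >= X0 }` is located by an
#' iterated LP feasibility search on the monotone function
#' [max_total_biomass()]: upward expansion from `mu_guess` until an
#' infeasible rate brackets the optimum, then interpolated bisection
#' (secant steps on `1/X_T`, clamped to the bracket, with plain bisection
#' as fallback) until the bracket is narrower than `mu_tol`.
#'
#' Because the abundance profile at `mu_max` may be degenerate, the reported
#' abundances come from one final LP at `mu_max` with the total biomass
#' fixed at `X0` and community uptake minimized as a reproducible secondary
#' objective; the actual variability should be assessed with
#' [abundance_fva()].
#'
#' @param cm a [build_community()] model.
#' @param options a [steadycom_options()] list.
#' @return An object of class `steadycom` with components `mu_max`,
#'   `abundance` (gdw per organism), `aggregate_flux` (mmol/h; the biomass
#'   entry is in gdw/h), `community_uptake`, `community_export`,
#'   `iterations` (number of LPs solved in the search), `status`
#'   (`"optimal"`, `"zero_growth"` or `"infeasible"`) and `search_log`.
#' @examples
#' cm <- make_single_organism_toy(uptake = 10, yield = 1)
#' fit <- steadycom(cm)
#' fit$mu_max     # 10: uptake bound times biomass yield
#' coef(fit)      # all biomass in the single organism
#' @export
steadycom <- function(cm, options = steadycom_options()) {
  stopifnot(inherits(cm, "community_model"))
  X0 <- cm$X0
  tol <- options$mu_tol
  nlp <- 0L
  log_mu <- numeric(0); log_XT <- numeric(0)
  XT_at <- function(mu) {
    nlp <<- nlp + 1L
    XT <- max_total_biomass(cm, mu)$XT
    log_mu <<- c(log_mu, mu); log_XT <<- c(log_XT, XT)
    XT
  }
  feas_lim <- X0 - options$feas_tol * max(1, X0)
  empty_result <- function(status) {
    orgs <- names(cm$organisms)
    structure(list(mu_max = 0,
                   abundance = stats::setNames(rep(NA_real_, length(orgs)), orgs),
                   aggregate_flux = NULL,
                   community_uptake = NULL, community_export = NULL,
                   iterations = nlp, status = status,
                   search_log = data.frame(mu = log_mu, XT = log_XT),
                   options = options, X0 = X0, model = cm),
              class = "steadycom")
  }

  ## screen: can the community hold X0 biomass at (essentially) zero growth?
  ## At mu = mu_tol the max-biomass LP can be declared unbounded for purely
  ## numerical reasons (the growth-coupling coefficient mu drops below the
  ## solver's pivot tolerance while X_T ~ 1/mu explodes); that still means
  ## "feasible here", and a genuinely unconstrained model is caught by the
  ## same error at the ordinary growth rates probed next.
  XT_screen <- tryCatch(XT_at(tol), error = function(e) {
    ## nlp was already counted inside XT_at before the solve failed
    log_mu <<- c(log_mu, tol); log_XT <<- c(log_XT, Inf)
    Inf
  })
  if (XT_screen < feas_lim) {
    lp0 <- assemble_steadycom_lp(cm, 0, fix_total_biomass = TRUE)
    s0 <- solve_lp(lp0)
    if (s0$status != "optimal") return(empty_result("infeasible"))
    fin <- final_solve(cm, 0)
    res <- build_result(cm, 0, fin, nlp, "zero_growth",
                        data.frame(mu = log_mu, XT = log_XT), options)
    return(res)
  }

  lo <- tol; XT_lo <- XT_screen
  hi <- NA_real_; XT_hi <- NA_real_
  prev <- NULL
  mu_next <- max(options$mu_guess, lo * options$bracket_growth_factor)
  force_bisect <- FALSE

  while (nlp < options$max_iter) {
    XT <- XT_at(mu_next)
    if (XT >= feas_lim) {
      lo <- mu_next; XT_lo <- XT
    } else {
      if (is.na(hi) || mu_next < hi) { hi <- mu_next; XT_hi <- XT }
    }
    if (!is.na(hi) && hi - lo <= tol) break

    if (is.na(hi)) {
      ## still unbracketed: secant through the last two points; with only
      ## one point take the fixed-point guess mu * XT / X0 (exact when
      ## growth is limited by a single scalable resource)
      cand <- if (is.null(prev)) {
        if (is.finite(XT) && XT > X0) mu_next * XT / X0 else NA_real_
      } else secant_mu(prev[["mu"]], prev[["XT"]], mu_next, XT, X0)
      prev <- c(mu = mu_next, XT = XT)
      if (!is.finite(cand)) cand <- lo * options$bracket_growth_factor
      cand <- min(cand, lo * 1e3)  # keep expansion steps sane
      if (cand <= lo + tol) {
        ## the interpolant believes lo is already the optimum: probe just
        ## above it once; if the probe proves feasible the prediction was
        ## wrong, so fall back to multiplicative expansion
        cand <- if (force_bisect) lo * options$bracket_growth_factor
                else lo + tol
        force_bisect <- TRUE
      } else force_bisect <- FALSE
      mu_next <- cand
    } else {
      prev <- c(mu = mu_next, XT = XT)
      w <- hi - lo
      cand <- secant_mu(lo, XT_lo, hi, XT_hi, X0)
      if (force_bisect || !is.finite(cand)) {
        cand <- lo + w / 2
        force_bisect <- FALSE
      } else if (cand <= lo + 0.5 * tol) {
        ## interpolant points at the feasible edge: probe just above it,
        ## never twice in a row (guards against tolerance-stepping)
        cand <- min(lo + tol, lo + w / 2)
        force_bisect <- TRUE
      } else if (cand >= hi - 0.5 * tol) {
        cand <- max(hi - tol, lo + w / 2)
        force_bisect <- TRUE
      } else if (cand <= lo || cand >= hi) {
        cand <- lo + w / 2
        force_bisect <- FALSE
      } else force_bisect <- FALSE
      mu_next <- cand
    }
  }
  if (is.na(hi) || hi - lo > tol)
    stop("growth-rate search did not converge within max_iter = ",
         options$max_iter, " LPs (bracket [", lo, ", ",
         if (is.na(hi)) "unbounded" else hi, "])")

  mu_max <- lo
  fin <- final_solve(cm, mu_max)
  build_result(cm, mu_max, fin, nlp, "optimal",
               data.frame(mu = log_mu, XT = log_XT), options)
}

#' @rdname steadycom
#' @export
solve_steadycom <- steadycom

## Final LP at the located growth rate: total biomass fixed at X0 and total
## community uptake minimized, a reproducible tie-break among degenerate
## abundance profiles.
final_solve <- function(cm, mu) {
  lp <- assemble_steadycom_lp(cm, mu, fix_total_biomass = TRUE)
  vmap <- attr(lp, "vmap")
  obj <- stats::setNames(rep(1, length(vmap$u)), lp$var_id[vmap$u])
  if (length(obj)) lp <- lp_set_objective(lp, obj, maximize = FALSE)
  sol <- solve_lp(lp)
  if (sol$status != "optimal" && mu > 0) {
    ## marginal infeasibility at the bracket edge: retreat by one tolerance
    lp <- assemble_steadycom_lp(cm, max(0, mu * (1 - 1e-9)),
                                fix_total_biomass = TRUE)
    if (length(obj)) lp <- lp_set_objective(lp, obj, maximize = FALSE)
    sol <- solve_lp(lp)
  }
  if (sol$status != "optimal")
    stop("final abundance LP unexpectedly ", sol$status, " at mu = ", mu)
  extract_blocks(lp, sol$x)
}

build_result <- function(cm, mu_max, blocks, nlp, status, search_log,
                         options) {
  structure(list(mu_max = mu_max,
                 abundance = blocks$abundance,
                 aggregate_flux = blocks$flux,
                 community_uptake = blocks$uptake,
                 community_export = blocks$export,
                 iterations = nlp, status = status,
                 search_log = search_log,
                 options = options, X0 = cm$X0, model = cm),
            class = "steadycom")
}

#' @export
print.steadycom <- function(x, digits = 6, ...) {
  cat("Community steady-state fit\n")
  cat("  status:    ", x$status, "\n")
  cat("  mu_max:    ", format(x$mu_max, digits = digits), "1/h\n")
  cat("  iterations:", x$iterations, "LPs\n")
  if (!is.null(x$abundance) && !anyNA(x$abundance)) {
    cat("  abundances (gdw, total", format(x$X0), "):\n")
    print(round(x$abundance, digits))
  }
  invisible(x)
}

#' @export
summary.steadycom <- function(object, zero_tol = object$options$zero_tol, ...) {
  sf <- if (object$status %in% c("optimal", "zero_growth"))
    specific_fluxes(object, zero_tol) else NULL
  structure(list(fit = object, specific = sf,
                 absent = if (!is.null(sf)) attr(sf, "absent")),
            class = "summary.steadycom")
}

#' @export
print.summary.steadycom <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$community_uptake)) {
    up <- x$fit$community_uptake[x$fit$community_uptake > 1e-9]
    if (length(up)) {
      cat("  community uptake (mmol/h):\n")
      print(round(up, 6))
    }
    ex <- x$fit$community_export[x$fit$community_export > 1e-9]
    if (length(ex)) {
      cat("  community export (mmol/h):\n")
      print(round(ex, 6))
    }
  }
  if (length(x$absent))
    cat("  absent organisms:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.steadycom <- function(object, ...) object$abundance

#' Joint flux balance analysis of a community
#'
#' The direct FBA extension used as a baseline: maximizes the weighted sum
#' of the organisms' specific biomass fluxes subject to each organism's
#' steady state, the original flux bounds (not scaled by abundance), and the
#' community-space balance.  No common growth rate is imposed, so organisms
#' may carry flux without growing.
#'
#' @param cm a [build_community()] model.
#' @param weights named numeric vector of per-organism objective weights;
#'   default 1 for all.
#' @return An object of class `joint_fba` with components `objective` (the
#'   weighted biomass sum), `growth` (specific biomass flux per organism),
#'   `fluxes`, `community_uptake`, `community_export`.
#' @export
joint_fba <- function(cm, weights = NULL) {
  lp <- assemble_joint_fba_lp(cm, weights)
  sol <- solve_lp(lp)
  if (sol$status == "unbounded")
    stop("joint FBA is unbounded: a growth-limiting resource is missing ",
         "a community uptake bound")
  if (sol$status != "optimal")
    stop("joint FBA LP ", sol$status)
  blocks <- extract_blocks(lp, sol$x)
  growth <- vapply(names(cm$organisms), function(k)
    blocks$flux[[k]][[cm$organisms[[k]]$biomass_reaction]], numeric(1))
  structure(list(objective = sol$objval,
                 growth = growth,
                 fluxes = blocks$flux,
                 community_uptake = blocks$uptake,
                 community_export = blocks$export,
                 weights = weights, status = sol$status),
            class = "joint_fba")
}

#' @rdname joint_fba
#' @export
solve_joint_fba <- joint_fba

#' @export
print.joint_fba <- function(x, digits = 6, ...) {
  cat("Joint FBA solution\n")
  cat("  weighted biomass objective:", format(x$objective, digits = digits),
      "\n  per-organism growth (1/h):\n")
  print(round(x$growth, digits))
  invisible(x)
}

#' @export
coef.joint_fba <- function(object, ...) object$growth

#' Maximum individual growth rate within the community environment
#'
#' Maximizes one organism's specific biomass flux under joint FBA (weight 1
#' for that organism, 0 for the rest).  Other organisms may still carry
#' flux, e.g. to supply cross-fed metabolites, so this is the organism's
#' best case given the community uptake bounds, not a mono-culture rate.
#'
#' @param cm a [build_community()] model.
#' @param k organism id.
#' @return The maximal specific growth rate (1/h) of organism `k`.
#' @export
max_individual_growth <- function(cm, k) {
  stopifnot(k %in% names(cm$organisms))
  w <- stats::setNames(numeric(length(cm$organisms)), names(cm$organisms))
  w[k] <- 1
  joint_fba(cm, w)$growth[[k]]
}
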