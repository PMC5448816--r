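#' Construct a single-organism metabolic model
#'
#' The per-organism container used throughout the package: stoichiometry,
#' flux bounds, and the identities of the biomass reaction, the optional
#' non-growth-associated ATP maintenance (ATPM) reaction, and the exchange
#' reactions connecting the organism to the shared community space.
#'
#' Sign convention for exchange fluxes: positive flux exports the metabolite
#' from the organism to the community space, negative flux is uptake.  Each
#' exchange reaction must involve exactly one metabolite of the organism
#' (the extracellular species), with stoichiometric coefficient -1 for the
#' canonical "metabolite -> (outside)" form.
#'
#' @param id organism identifier (unique within a community).
#' @param stoich data frame with columns `metabolite`, `reaction`, `coef`
#'   giving the nonzero stoichiometric coefficients.
#' @param lb,ub named numeric vectors of flux bounds, one entry per reaction
#'   (mmol/gdw/h; the biomass reaction is in 1/h).  `-Inf`/`Inf` allowed.
#' @param biomass_reaction id of the biomass reaction.
#' @param exchange_map named character vector mapping community-metabolite
#'   ids to exchange reaction ids.
#' @param atpm_reaction optional id of the ATPM reaction.
#' @return An object of class `organism_model`.
#' @examples
#' om <- organism_model(
#'   id = "org1",
#'   stoich = data.frame(metabolite = c("s_e", "s_e"),
#'                       reaction   = c("EX_s_e", "biomass"),
#'                       coef       = c(-1, -1)),
#'   lb = c(EX_s_e = -Inf, biomass = 0),
#'   ub = c(EX_s_e = Inf, biomass = Inf),
#'   biomass_reaction = "biomass",
#'   exchange_map = c(s = "EX_s_e"))
#' @export
organism_model <- function(id, stoich, lb, ub, biomass_reaction,
                           exchange_map, atpm_reaction = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- as.data.frame(stoich)
  stopifnot(all(c("metabolite", "reaction", "coef") %in% names(stoich)))
  reactions <- unique(c(names(lb), names(ub)))
  metabolites <- unique(as.character(stoich$metabolite))
  om <- structure(list(id = id,
                       metabolites = metabolites,
                       reactions = reactions,
                       stoich = data.frame(
                         metabolite = as.character(stoich$metabolite),
                         reaction = as.character(stoich$reaction),
                         coef = as.numeric(stoich$coef),
                         stringsAsFactors = FALSE),
                       lb = lb[reactions], ub = ub[reactions],
                       biomass_reaction = biomass_reaction,
                       atpm_reaction = atpm_reaction,
                       exchange_map = exchange_map),
                  class = "organism_model")
  validate_organism_model(om)
}

#' Validate an organism model
#'
#' Checks the structural invariants: the biomass reaction is declared, all
#' bounds satisfy `lb <= ub`, the stoichiometry references declared
#' reactions only, and every exchange reaction involves exactly one
#' metabolite of the organism.
#'
#' @param om an [organism_model()].
#' @return `om`, invisibly usable, after validation; errors otherwise.
#' @export
validate_organism_model <- function(om) {
  stopifnot(inherits(om, "organism_model"))
  if (!om$biomass_reaction %in% om$reactions)
    stop("organism '", om$id, "': biomass reaction '", om$biomass_reaction,
         "' is not a declared reaction")
  if (!is.null(om$atpm_reaction) && !om$atpm_reaction %in% om$reactions)
    stop("organism '", om$id, "': ATPM reaction not declared")
  if (anyNA(om$lb) || anyNA(om$ub))
    stop("organism '", om$id, "': missing flux bound")
  if (any(om$lb > om$ub))
    stop("organism '", om$id, "': lower bound exceeds upper bound for ",
         paste(om$reactions[om$lb > om$ub], collapse = ", "))
  if (!all(om$stoich$reaction %in% om$reactions))
    stop("organism '", om$id, "': stoichiometry references unknown reaction")
  ex <- unname(om$exchange_map)
  if (!all(ex %in% om$reactions))
    stop("organism '", om$id, "': exchange map references unknown reaction")
  nmet <- vapply(ex, function(r)
    length(unique(om$stoich$metabolite[om$stoich$reaction == r])), integer(1))
  if (any(nmet != 1L))
    stop("organism '", om$id, "': exchange reaction ",
         paste(ex[nmet != 1L], collapse = ", "),
         " must involve exactly one metabolite")
  om
}

#' @export
print.organism_model <- function(x, ...) {
  cat(sprintf("Organism model '%s': %d metabolites, %d reactions, %d exchanges\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$exchange_map)))
  cat("  biomass:", x$biomass_reaction,
      if (!is.null(x$atpm_reaction)) paste0("  ATPM: ", x$atpm_reaction) else "",
      "\n")
  invisible(x)
}

#' Assemble a community model from organism models
#'
#' Connects the extracellular compartments of the member organisms through a
#' shared community space.  The community metabolites are the union of the
#' organisms' exchange-map keys.  Community uptake of each metabolite is
#' bounded by `uptake_ub` (mmol/h per total biomass `X0`); metabolites
#' absent from `uptake_ub` get an uptake bound of zero, while community
#' export always remains free (non-negative).
#'
#' @param models list of [organism_model()] objects with unique ids.
#' @param uptake_ub named non-negative numeric vector of community uptake
#'   bounds, keyed by community metabolite.
#' @param X0 total community biomass in gdw (default 1, so organism biomass
#'   variables read directly as relative abundances).
#' @param organism_uptake_ub optional data frame with columns `organism`,
#'   `metabolite`, `max_uptake` giving per-organism limits on the specific
#'   uptake rate (mmol/gdw/h) of a community metabolite.  These are applied
#'   as abundance-scaled constraints on the exchange flux.
#' @return An object of class `community_model`.
#' @export
build_community <- function(models, uptake_ub = numeric(0), X0 = 1,
                            organism_uptake_ub = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  models <- lapply(models, validate_organism_model)
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate organism id: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  names(models) <- ids
  if (!is.numeric(X0) || length(X0) != 1L || !is.finite(X0) || X0 <= 0)
    stop("X0 must be a single positive number")
  cmets <- unique(unlist(lapply(models, function(m) names(m$exchange_map)),
                         use.names = FALSE))
  ub <- stats::setNames(numeric(length(cmets)), cmets)
  if (length(uptake_ub)) {
    if (is.null(names(uptake_ub)) || !all(nzchar(names(uptake_ub))))
      stop("uptake_ub must be a named vector")
    unknown <- setdiff(names(uptake_ub), cmets)
    if (length(unknown))
      stop("uptake_ub names not exchanged by any organism: ",
           paste(unknown, collapse = ", "))
    if (any(uptake_ub < 0)) stop("negative community uptake bound")
    ub[names(uptake_ub)] <- uptake_ub
  }
  if (!is.null(organism_uptake_ub)) {
    o <- as.data.frame(organism_uptake_ub)
    stopifnot(all(c("organism", "metabolite", "max_uptake") %in% names(o)))
    if (!all(o$organism %in% ids))
      stop("organism_uptake_ub references unknown organism")
    for (r in seq_len(nrow(o)))
      if (!o$metabolite[r] %in% names(models[[o$organism[r]]]$exchange_map))
        stop("organism '", o$organism[r], "' has no exchange for metabolite '",
             o$metabolite[r], "'")
    if (any(o$max_uptake < 0)) stop("negative organism uptake bound")
    organism_uptake_ub <- o
  }
  structure(list(organisms = models,
                 community_metabolites = cmets,
                 uptake_ub = ub,
                 X0 = X0,
                 organism_uptake_ub = organism_uptake_ub),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("Community model: %d organisms, %d community metabolites, X0 = %g gdw\n",
              length(x$organisms), length(x$community_metabolites), x$X0))
  cat("  organisms:", paste(names(x$organisms), collapse = ", "), "\n")
  nz <- x$uptake_ub[x$uptake_ub > 0]
  if (length(nz))
    cat("  uptake bounds > 0:",
        paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

## Variable naming used by the LP assemblers; kept in one place so that the
## solver, FVA and tests extract solution components consistently.
var_V <- function(org, rxn) paste0("V[", org, "][", rxn, "]")
var_X <- function(org) paste0("X[", org, "]")
var_u <- function(met) paste0("u[", met, "]")
var_e <- function(met) paste0("e[", met, "]")

#' Assemble the community steady-state linear program at fixed growth rate
#'
#' Builds the LP in aggregate fluxes `V` (mmol/h), organism biomasses `X`
#' (gdw), and community uptake/export rates `u`, `e` (mmol/h), at a fixed
#' community growth rate `mu`:
#' per-organism mass balance `sum_j S_ij V_j = 0`; abundance-scaled flux
#' capacity `lb_j * X <= V_j <= ub_j * X` (each finite bound contributes one
#' one-sided row, so reversible reactions stay coupled to abundance; rows for
#' infinite bounds are omitted); growth coupling `V_biomass = mu * X`;
#' community-space balance `u_i - e_i + sum_k V_ex(i) = 0`; and optionally
#' the total-biomass row `sum_k X = X0`.  Variable domains are `X >= 0`,
#' `0 <= u_i <= uptake_ub_i`, `e_i >= 0`, `V` free.  Per-organism uptake
#' limits `r` enter as rows `V_ex(i) + r * X >= 0` (uptake is negative flux).
#'
#' The objective is left at zero; callers set it with [lp_set_objective()].
#'
#' @param cm a [build_community()] model.
#' @param mu fixed community growth rate (1/h), must be non-negative; fixing
#'   `mu` is what makes the otherwise bilinear problem an LP.
#' @param fix_total_biomass if `TRUE` (default) include the row
#'   `sum_k X = X0`; the growth-rate search replaces this row by the
#'   objective `max sum_k X`.
#' @return A [linear_program()] with attribute `vmap` holding the index maps
#'   for the `V`, `X`, `u` and `e` variable blocks.
#' @export
assemble_steadycom_lp <- function(cm, mu, fix_total_biomass = TRUE) {
  stopifnot(inherits(cm, "community_model"))
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("mu must be a single finite non-negative number")
  orgs <- cm$organisms
  cmets <- cm$community_metabolites

  ## variable layout: all V blocks, then X, u, e
  vid <- character(0); vlb <- numeric(0); vub <- numeric(0)
  vmap <- list(V = list(), X = integer(0), u = integer(0), e = integer(0))
  for (om in orgs) {
    idx <- length(vid) + seq_along(om$reactions)
    vmap$V[[om$id]] <- stats::setNames(idx, om$reactions)
    vid <- c(vid, var_V(om$id, om$reactions))
    vlb <- c(vlb, rep(-Inf, length(om$reactions)))
    vub <- c(vub, rep(Inf, length(om$reactions)))
  }
  vmap$X <- stats::setNames(length(vid) + seq_along(orgs), names(orgs))
  vid <- c(vid, var_X(names(orgs)))
  vlb <- c(vlb, rep(0, length(orgs)))
  vub <- c(vub, rep(Inf, length(orgs)))
  vmap$u <- stats::setNames(length(vid) + seq_along(cmets), cmets)
  vid <- c(vid, var_u(cmets))
  vlb <- c(vlb, rep(0, length(cmets)))
  vub <- c(vub, unname(cm$uptake_ub[cmets]))
  vmap$e <- stats::setNames(length(vid) + seq_along(cmets), cmets)
  vid <- c(vid, var_e(cmets))
  vlb <- c(vlb, rep(0, length(cmets)))
  vub <- c(vub, rep(Inf, length(cmets)))

  ri <- list(); rj <- list(); rx <- list(); rlb <- list(); rub <- list()
  nr <- 0L
  add_rows <- function(i, j, x, lb, ub) {
    k <- length(ri) + 1L
    ri[[k]] <<- as.integer(i + nr); rj[[k]] <<- as.integer(j)
    rx[[k]] <<- as.numeric(x)
    rlb[[k]] <<- as.numeric(lb); rub[[k]] <<- as.numeric(ub)
    nr <<- nr + length(lb)
  }

  for (om in orgs) {
    Vix <- vmap$V[[om$id]]
    Xix <- vmap$X[[om$id]]
    ## per-organism steady state: sum_j S_ij V_j = 0
    mrow <- match(om$stoich$metabolite, om$metabolites)
    add_rows(mrow, Vix[om$stoich$reaction], om$stoich$coef,
             rep(0, length(om$metabolites)), rep(0, length(om$metabolites)))
    ## abundance-scaled capacity: V - ub*X <= 0 ; V - lb*X >= 0
    fu <- which(is.finite(om$ub))
    if (length(fu))
      add_rows(rep(seq_along(fu), 2L),
               c(Vix[fu], rep(Xix, length(fu))),
               c(rep(1, length(fu)), -om$ub[fu]),
               rep(-Inf, length(fu)), rep(0, length(fu)))
    fl <- which(is.finite(om$lb))
    if (length(fl))
      add_rows(rep(seq_along(fl), 2L),
               c(Vix[fl], rep(Xix, length(fl))),
               c(rep(1, length(fl)), -om$lb[fl]),
               rep(0, length(fl)), rep(Inf, length(fl)))
    ## growth coupling: V_biomass - mu*X = 0
    add_rows(c(1L, 1L), c(Vix[om$biomass_reaction], Xix), c(1, -mu), 0, 0)
  }

  ## per-organism specific uptake limits: V_ex + r*X >= 0
  if (!is.null(cm$organism_uptake_ub)) {
    o <- cm$organism_uptake_ub
    for (r in seq_len(nrow(o))) {
      om <- orgs[[o$organism[r]]]
      exr <- om$exchange_map[[o$metabolite[r]]]
      add_rows(c(1L, 1L),
               c(vmap$V[[om$id]][exr], vmap$X[[om$id]]),
               c(1, o$max_uptake[r]), 0, Inf)
    }
  }

  ## community-space balance: u_i - e_i + sum_k V_ex(i) = 0
  for (i in seq_along(cmets)) {
    met <- cmets[i]
    j <- c(vmap$u[[met]], vmap$e[[met]])
    x <- c(1, -1)
    for (om in orgs) {
      if (met %in% names(om$exchange_map)) {
        j <- c(j, vmap$V[[om$id]][om$exchange_map[[met]]])
        x <- c(x, 1)
      }
    }
    add_rows(rep(1L, length(j)), j, x, 0, 0)
  }

  if (fix_total_biomass)
    add_rows(rep(1L, length(orgs)), vmap$X, rep(1, length(orgs)),
             cm$X0, cm$X0)

  lp <- linear_program(vid, vlb, vub,
                       unlist(ri), unlist(rj), unlist(rx),
                       unlist(rlb), unlist(rub))
  attr(lp, "vmap") <- vmap
  attr(lp, "mu") <- mu
  lp
}

#' Assemble the joint-FBA linear program
#'
#' The direct multi-organism extension of FBA: variables are the specific
#' fluxes `v` (mmol/gdw/h) of each organism plus community uptake/export
#' rates; constraints are each organism's steady state, the original
#' (abundance-unscaled) flux bounds, and the community-space balance where
#' the specific exchange fluxes enter directly.  The objective maximizes the
#' weighted sum of biomass fluxes.  Per-organism uptake limits tighten the
#' exchange lower bound directly.
#'
#' @param cm a [build_community()] model.
#' @param weights named numeric vector of objective weights per organism;
#'   defaults to 1 for every organism.
#' @return A [linear_program()] with attribute `vmap` (blocks `v`, `u`, `e`).
#' @export
assemble_joint_fba_lp <- function(cm, weights = NULL) {
  stopifnot(inherits(cm, "community_model"))
  orgs <- cm$organisms
  cmets <- cm$community_metabolites
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(orgs)), names(orgs))
  if (is.null(names(weights)) || !all(names(weights) %in% names(orgs)))
    stop("weights must be named by organism id")
  w <- stats::setNames(numeric(length(orgs)), names(orgs))
  w[names(weights)] <- weights

  vid <- character(0); vlb <- numeric(0); vub <- numeric(0)
  vmap <- list(v = list(), u = integer(0), e = integer(0))
  for (om in orgs) {
    lb <- om$lb; ub <- om$ub
    if (!is.null(cm$organism_uptake_ub)) {
      o <- cm$organism_uptake_ub[cm$organism_uptake_ub$organism == om$id, ,
                                 drop = FALSE]
      for (r in seq_len(nrow(o))) {
        exr <- om$exchange_map[[o$metabolite[r]]]
        lb[exr] <- max(lb[exr], -o$max_uptake[r])
      }
    }
    idx <- length(vid) + seq_along(om$reactions)
    vmap$v[[om$id]] <- stats::setNames(idx, om$reactions)
    vid <- c(vid, var_V(om$id, om$reactions))
    vlb <- c(vlb, unname(lb)); vub <- c(vub, unname(ub))
  }
  vmap$u <- stats::setNames(length(vid) + seq_along(cmets), cmets)
  vid <- c(vid, var_u(cmets))
  vlb <- c(vlb, rep(0, length(cmets)))
  vub <- c(vub, unname(cm$uptake_ub[cmets]))
  vmap$e <- stats::setNames(length(vid) + seq_along(cmets), cmets)
  vid <- c(vid, var_e(cmets))
  vlb <- c(vlb, rep(0, length(cmets)))
  vub <- c(vub, rep(Inf, length(cmets)))

  ri <- integer(0); rj <- integer(0); rx <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0)
  nr <- 0L
  for (om in orgs) {
    vix <- vmap$v[[om$id]]
    mrow <- match(om$stoich$metabolite, om$metabolites)
    ri <- c(ri, mrow + nr)
    rj <- c(rj, vix[om$stoich$reaction])
    rx <- c(rx, om$stoich$coef)
    rlb <- c(rlb, rep(0, length(om$metabolites)))
    rub <- c(rub, rep(0, length(om$metabolites)))
    nr <- nr + length(om$metabolites)
  }
  for (met in cmets) {
    nr <- nr + 1L
    ri <- c(ri, nr, nr); rj <- c(rj, vmap$u[[met]], vmap$e[[met]])
    rx <- c(rx, 1, -1)
    for (om in orgs) {
      if (met %in% names(om$exchange_map)) {
        ri <- c(ri, nr)
        rj <- c(rj, vmap$v[[om$id]][om$exchange_map[[met]]])
        rx <- c(rx, 1)
      }
    }
    rlb <- c(rlb, 0); rub <- c(rub, 0)
  }

  obj <- numeric(length(vid))
  for (om in orgs)
    obj[vmap$v[[om$id]][om$biomass_reaction]] <- w[[om$id]]

  lp <- linear_program(vid, vlb, vub, ri, rj, rx, rlb, rub,
                       obj = obj, maximize = TRUE)
  attr(lp, "vmap") <- vmap
  lp
}

#' Specific fluxes from a community steady-state solution
#'
#' Converts aggregate fluxes `V` (mmol/h) back to specific fluxes
#' `v = V / X` (mmol/gdw/h).  Organisms whose biomass does not exceed
#' `zero_tol` are flagged absent and report all-zero specific fluxes (the
#' abundance-scaled capacity constraints force their aggregate fluxes to
#' zero anyway).
#'
#' @param res a [steadycom()] result with status `"optimal"` or
#'   `"zero_growth"`.
#' @param zero_tol biomass (gdw) below which an organism counts as absent;
#'   default `1e-8`, the scale of LP solver tolerances.
#' @return Named list of named numeric vectors (per organism, per reaction)
#'   with attribute `absent` listing the absent organisms.
#' @export
specific_fluxes <- function(res, zero_tol = 1e-8) {
  stopifnot(inherits(res, "steadycom"))
  if (!res$status %in% c("optimal", "zero_growth"))
    stop("no solution available (status: ", res$status, ")")
  absent <- character(0)
  out <- lapply(names(res$abundance), function(org) {
    X <- res$abundance[[org]]
    V <- res$aggregate_flux[[org]]
    if (X <= zero_tol) {
      absent <<- c(absent, org)
      return(stats::setNames(numeric(length(V)), names(V)))
    }
    V / X
  })
  names(out) <- names(res$abundance)
  attr(out, "absent") <- absent
  out
}
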