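## Randomized organism-specific uptake-bound ensembles and conversion of a
## diet table into community uptake bounds.

#' Convert a diet table into community uptake bounds
#'
#' Each diet component contributes
#' `mass (g/day) * composition (mmol/g) * (1 - absorption)` to its
#' metabolite, converted from daily to hourly rates and normalized per `X0`
#' of community biomass:
#' `bound = sum(mass * composition) * (1 - absorption) / 24 / (total_biomass / X0)`.
#'
#' Default host absorption fractions: 0.97 for carbohydrates (0.95 and 0.99
#' are common alternatives), 0.90 for amino acids, 0.90 for fatty acids and
#' 0 for dietary fiber, which reaches the large intestine undigested.  The
#' default `total_biomass` of 10 gdw is a standard estimate for the human
#' gut microbiota.
#'
#' @param diet data frame with columns `component`, `category` (one of the
#'   names of `absorption`), `mass_g_per_day`, `mmol_per_g`, `metabolite`.
#' @param absorption named fractions in `[0, 1]` per category.
#' @param total_biomass community dry weight the daily intake feeds (gdw).
#' @param X0 total biomass of the community model the bounds are meant for.
#' @param hours_per_day day-to-hour conversion, 24 by default.
#' @return Named numeric vector of community uptake bounds (mmol/h per `X0`).
#' @examples
#' diet <- data.frame(component = "starch", category = "carbohydrate",
#'                    mass_g_per_day = 240, mmol_per_g = 1,
#'                    metabolite = "glc")
#' diet_to_uptake_bounds(diet)  # 240 * 0.03 / 24 / 10 = 0.03
#' @export
diet_to_uptake_bounds <- function(diet,
                                  absorption = c(carbohydrate = 0.97,
                                                 "amino acid" = 0.90,
                                                 fiber = 0,
                                                 "fatty acid" = 0.90),
                                  total_biomass = 10, X0 = 1,
                                  hours_per_day = 24) {
  diet <- as.data.frame(diet)
  need <- c("component", "category", "mass_g_per_day", "mmol_per_g",
            "metabolite")
  stopifnot(all(need %in% names(diet)), total_biomass > 0, X0 > 0,
            hours_per_day > 0)
  if (any(absorption < 0 | absorption > 1))
    stop("absorption fractions must lie in [0, 1]")
  unknown <- setdiff(unique(diet$category), names(absorption))
  if (length(unknown))
    stop("unknown diet category: ", paste(unknown, collapse = ", "))
  if (any(diet$mass_g_per_day < 0)) stop("negative daily mass")
  rate <- diet$mass_g_per_day * diet$mmol_per_g *
    (1 - absorption[diet$category]) / hours_per_day / (total_biomass / X0)
  out <- tapply(rate, diet$metabolite, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Sample randomized organism-specific uptake bounds
#'
#' Draws `n_sets` assignments of maximum specific uptake rates
#' (mmol/gdw/h) for each carbon source of each organism.  For every set and
#' organism, the total carbon uptake capacity (C-mmol/gdw/h) is drawn from
#' the chosen law — exponential with mean `mean_total_c`, or uniform on
#' `[0, 2 * mean_total_c]` — and partitioned across the organism's carbon
#' sources proportionally to i.i.d. unit-exponential draws; dividing each
#' share by the source's carbon count converts it to a metabolite rate.  So
#' the expected carbon-weighted total per organism equals `mean_total_c`
#' while individual sources still vary.  Fiber-type substrates are simply
#' omitted from `carbon_sources` (they are bounded separately through
#' per-organism uptake limits).
#'
#' @param cm a [build_community()] model.
#' @param carbon_sources named numeric vector: carbon atoms per molecule for
#'   each community metabolite that counts as a carbon source.
#' @param mean_total_c mean total carbon uptake per organism
#'   (C-mmol/gdw/h).
#' @param distribution `"exponential"` or `"uniform"`.
#' @param n_sets number of bound sets to draw.
#' @param seed integer seed; identical seeds give identical sets.
#' @return A list of `uptake_bound_set` objects, each holding a data frame
#'   `bounds` (`organism`, `metabolite`, `max_uptake`) plus the sampling
#'   metadata.
#' @export
sample_uptake_bounds <- function(cm, carbon_sources, mean_total_c,
                                 distribution = c("exponential", "uniform"),
                                 n_sets, seed) {
  stopifnot(inherits(cm, "community_model"),
            is.numeric(carbon_sources), !is.null(names(carbon_sources)),
            all(carbon_sources >= 1), mean_total_c > 0)
  distribution <- match.arg(distribution)
  if (n_sets < 1) stop("n_sets must be at least 1")
  unknown <- setdiff(names(carbon_sources), cm$community_metabolites)
  if (length(unknown))
    stop("carbon source not a community metabolite: ",
         paste(unknown, collapse = ", "))
  orgs <- cm$organisms
  pairs <- do.call(rbind, lapply(orgs, function(om) {
    mets <- intersect(names(om$exchange_map), names(carbon_sources))
    if (!length(mets)) return(NULL)
    data.frame(organism = om$id, metabolite = mets,
               carbons = unname(carbon_sources[mets]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || !nrow(pairs))
    stop("no organism exchanges any of the given carbon sources")
  rownames(pairs) <- NULL
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    bounds <- pairs
    bounds$max_uptake <- NA_real_
    for (org in unique(pairs$organism)) {
      sel <- pairs$organism == org
      total <- switch(distribution,
                      exponential = stats::rexp(1, rate = 1 / mean_total_c),
                      uniform = stats::runif(1, 0, 2 * mean_total_c))
      share <- stats::rexp(sum(sel), rate = 1)
      share <- share / sum(share)
      bounds$max_uptake[sel] <- total * share / pairs$carbons[sel]
    }
    structure(list(bounds = bounds[, c("organism", "metabolite", "max_uptake")],
                   seed = seed, set = s, distribution = distribution,
                   mean_total_c = mean_total_c),
              class = "uptake_bound_set")
  })
}

#' @export
print.uptake_bound_set <- function(x, ...) {
  cat(sprintf("Uptake bound set %d (%s, mean total C %g, seed %d): %d bounds\n",
              x$set, x$distribution, x$mean_total_c, x$seed, nrow(x$bounds)))
  invisible(x)
}

#' Solve a community model over an ensemble of uptake-bound sets
#'
#' Applies each bound set from [sample_uptake_bounds()] as per-organism
#' uptake limits, solves with the requested method, and summarizes the
#' resulting abundance distributions.  For joint FBA — which carries no
#' abundance variables — compositions are taken as the ratio of the
#' organisms' biomass fluxes, scaled to `X0`.  Failed or zero-growth sets
#' are counted and excluded from the summary.
#'
#' @param cm a [build_community()] model.
#' @param sets list of `uptake_bound_set` objects.
#' @param method `"steadycom"` or `"joint_fba"`.
#' @param taxa optional named character vector mapping organism ids to taxa;
#'   adds a taxon-level summary of summed abundances.
#' @param options [steadycom_options()] for the steady-state solves.
#' @return An object of class `ensemble_summary` with the per-set abundance
#'   matrix, per-organism summary statistics (mean, sd, quartiles, 95%
#'   interval), the failure count, and the optional taxon summary.
#' @export
run_ensemble <- function(cm, sets, method = c("steadycom", "joint_fba"),
                         taxa = NULL, options = steadycom_options()) {
  method <- match.arg(method)
  stopifnot(length(sets) >= 1)
  orgs <- names(cm$organisms)
  ab <- matrix(NA_real_, nrow = length(sets), ncol = length(orgs),
               dimnames = list(NULL, orgs))
  n_failed <- 0L
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    stopifnot(inherits(s, "uptake_bound_set"))
    cmi <- cm
    cmi$organism_uptake_ub <- s$bounds
    res <- tryCatch({
      if (method == "steadycom") {
        fit <- steadycom(cmi, options)
        if (fit$status != "optimal") NULL else fit$abundance
      } else {
        fit <- joint_fba(cmi)
        tot <- sum(fit$growth)
        if (tot <= 0) NULL else fit$growth / tot * cm$X0
      }
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else ab[i, orgs] <- res[orgs]
  }
  ok <- ab[stats::complete.cases(ab), , drop = FALSE]
  summarize <- function(m) {
    t(apply(m, 2, function(x)
      c(mean = mean(x), sd = stats::sd(x), q025 = unname(stats::quantile(x, 0.025)),
        q25 = unname(stats::quantile(x, 0.25)), median = stats::median(x),
        q75 = unname(stats::quantile(x, 0.75)),
        q975 = unname(stats::quantile(x, 0.975)))))
  }
  taxon_summary <- NULL
  if (!is.null(taxa) && nrow(ok)) {
    stopifnot(all(orgs %in% names(taxa)))
    groups <- split(orgs, taxa[orgs])
    tx <- vapply(groups, function(g) rowSums(ok[, g, drop = FALSE]),
                 numeric(nrow(ok)))
    if (is.null(dim(tx))) tx <- matrix(tx, nrow = 1, dimnames = list(NULL, names(groups)))
    taxon_summary <- summarize(tx)
  }
  structure(list(method = method,
                 abundance = ab,
                 summary = if (nrow(ok)) summarize(ok) else NULL,
                 n_sets = length(sets), n_failed = n_failed,
                 taxon_summary = taxon_summary),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Ensemble of %d uptake-bound sets (%s); %d failed/zero-growth\n",
              x$n_sets, x$method, x$n_failed))
  if (!is.null(x$summary)) {
    cat("Abundance summary:\n")
    print(round(x$summary, digits))
  }
  if (!is.null(x$taxon_summary)) {
    cat("Taxon-level summary:\n")
    print(round(x$taxon_summary, digits))
  }
  invisible(x)
}
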