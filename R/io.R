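## Reading and writing: SBML Level 3 (+ FBC flux bounds) for organism
## models, a compact JSON dialect for toy models and results, TSV for
## tables.  Only the SBML constructs needed for flux-balance models are
## handled: compartments, species, stoichiometry, FBC bounds and the FBC
## objective.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

fmt_bound <- function(x) {
  if (x == Inf) "INF" else if (x == -Inf) "-INF" else
    format(x, digits = 17, scientific = FALSE)
}

parse_bound <- function(s) {
  if (is.na(s)) return(NA_real_)
  if (s == "INF") Inf else if (s == "-INF") -Inf else as.numeric(s)
}

## compartment of a metabolite id: trailing "_e" marks the extracellular
## space shared with the community, anything else is intracellular
met_compartment <- function(met) ifelse(grepl("_e$", met), "e", "c")

#' Write an organism model as SBML Level 3 with FBC bounds
#'
#' Species ids get an `M_` prefix and reaction ids an `R_` prefix, following
#' common SBML practice; metabolites ending in `_e` are placed in the
#' extracellular compartment.  Flux bounds become FBC bound parameters and
#' the biomass reaction becomes the active FBC objective.
#'
#' @param om an [organism_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_organism_sbml <- function(om, path) {
  om <- validate_organism_model(om)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = om$id, "fbc:strict" = "true")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in unique(met_compartment(om$metabolites)))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")

  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in om$metabolites)
    xml2::xml_add_child(spl, "species",
                        id = paste0("M_", m),
                        compartment = met_compartment(m),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (r in om$reactions) {
    xml2::xml_add_child(pars, "parameter", id = paste0("bnd_", r, "_lb"),
                        value = fmt_bound(om$lb[[r]]), constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("bnd_", r, "_ub"),
                        value = fmt_bound(om$ub[[r]]), constant = "true")
  }

  rxl <- xml2::xml_add_child(model, "listOfReactions")
  for (r in om$reactions) {
    rn <- xml2::xml_add_child(rxl, "reaction", id = paste0("R_", r),
                              reversible = if (om$lb[[r]] < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("bnd_", r, "_lb"),
                              "fbc:upperFluxBound" = paste0("bnd_", r, "_ub"))
    sto <- om$stoich[om$stoich$reaction == r, , drop = FALSE]
    rea <- sto[sto$coef < 0, , drop = FALSE]
    pro <- sto[sto$coef > 0, , drop = FALSE]
    if (nrow(rea)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_len(nrow(rea)))
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", rea$metabolite[i]),
                            stoichiometry = format(-rea$coef[i], digits = 17),
                            constant = "true")
    }
    if (nrow(pro)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_len(nrow(pro)))
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", pro$metabolite[i]),
                            stoichiometry = format(pro$coef[i], digits = 17),
                            constant = "true")
    }
  }

  objs <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  fol <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fol, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", om$biomass_reaction),
                      "fbc:coefficient" = "1")

  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

xattr <- function(node, name) {
  a <- xml2::xml_attr(node, name)
  if (is.na(a)) a <- xml2::xml_attr(node, paste0("fbc:", name))
  a
}

#' Read an organism model from SBML
#'
#' Supports SBML Level 3 with FBC flux bounds.  The biomass reaction is
#' taken from the active FBC objective; if none is declared, the first
#' reaction whose id matches "biomass" (case-insensitive) is used with a
#' warning.  Exchange reactions are detected as reactions involving exactly
#' one species in the extracellular compartment (`e`) and no other species,
#' or with an `EX_` id prefix; an `EX_` reaction touching two or more
#' species is an error.  A reaction id matching "ATPM" (after prefix
#' stripping) is recorded as the maintenance reaction.  Conventional `M_` /
#' `R_` id prefixes are stripped.
#'
#' @param path an SBML file.
#' @return An [organism_model()].
#' @export
read_organism_sbml <- function(path) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model))) stop("no <model> element in ", path)
  org_id <- xml2::xml_attr(model, "id")
  if (is.na(org_id)) org_id <- tools::file_path_sans_ext(basename(path))

  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  names(sp_comp) <- sp_id

  par <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  par_val <- vapply(xml2::xml_attr(par, "value"), parse_bound, numeric(1))
  names(par_val) <- xml2::xml_attr(par, "id")

  rx <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (!length(rx)) stop("no reactions in ", path)
  rx_id_raw <- xml2::xml_attr(rx, "id")
  rx_id <- strip_prefix(rx_id_raw, "R_")

  sto <- list(); lb <- numeric(0); ub <- numeric(0)
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    lbp <- xattr(r, "lowerFluxBound")
    ubp <- xattr(r, "upperFluxBound")
    lbv <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else {
      lba <- parse_bound(xattr(r, "lowerBound"))
      if (!is.na(lba)) lba else
        if (xml2::xml_attr(r, "reversible") %in% "true") -Inf else 0
    }
    ubv <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else {
      uba <- parse_bound(xattr(r, "upperBound"))
      if (!is.na(uba)) uba else Inf
    }
    lb[rx_id[i]] <- lbv
    ub[rx_id[i]] <- ubv
    rea <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    pro <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    entry <- function(nodes, sign) {
      if (!length(nodes)) return(NULL)
      s <- xml2::xml_attr(nodes, "stoichiometry")
      s[is.na(s)] <- "1"
      data.frame(metabolite = strip_prefix(xml2::xml_attr(nodes, "species"), "M_"),
                 reaction = rx_id[i],
                 coef = sign * as.numeric(s),
                 stringsAsFactors = FALSE)
    }
    sto[[i]] <- rbind(entry(rea, -1), entry(pro, 1))
  }
  sto <- do.call(rbind, sto)
  ## drop boundary species from the stoichiometry (source/sink pools)
  if (any(sp_boundary)) {
    bnd <- sp_id[sp_boundary]
    sto <- sto[!sto$metabolite %in% strip_prefix(bnd, "M_"), , drop = FALSE]
  }

  ## biomass: FBC active objective, else id pattern fallback
  ## (FBC elements keep their prefix even after namespace stripping)
  fobj <- xml2::xml_find_first(
    model,
    ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (!is.na(xml2::xml_name(fobj))) {
    biomass <- strip_prefix(xattr(fobj, "reaction"), "R_")
  } else {
    cand <- rx_id[grepl("biomass", rx_id, ignore.case = TRUE)]
    if (!length(cand))
      stop("no biomass reaction identifiable in ", path,
           " (no FBC objective, no id matching 'biomass')")
    biomass <- cand[1]
    warning("no FBC objective in ", basename(path),
            "; using reaction '", biomass, "' matched by id")
  }

  atpm <- rx_id[toupper(rx_id) == "ATPM"]
  atpm <- if (length(atpm)) atpm[1] else NULL

  ## exchange detection
  met_comp <- stats::setNames(sp_comp[paste0("M_", unique(sto$metabolite))],
                              unique(sto$metabolite))
  miss <- is.na(met_comp)
  met_comp[miss] <- met_compartment(names(met_comp)[miss])
  exchange_map <- character(0)
  for (i in seq_along(rx_id)) {
    if (rx_id[i] == biomass) next  # a biomass sink is never an exchange
    mets <- unique(sto$metabolite[sto$reaction == rx_id[i]])
    is_ex_id <- grepl("^EX_", rx_id[i])
    if (is_ex_id && length(mets) > 1)
      stop("exchange reaction '", rx_id[i], "' involves ", length(mets),
           " metabolites")
    is_ex <- is_ex_id ||
      (length(mets) == 1 && met_comp[[mets]] == "e")
    if (is_ex && length(mets) == 1) {
      cmet <- sub("_e$", "", mets)
      exchange_map[cmet] <- rx_id[i]
    }
  }

  organism_model(id = org_id, stoich = sto, lb = lb, ub = ub,
                 biomass_reaction = biomass,
                 atpm_reaction = atpm,
                 exchange_map = exchange_map)
}

om_to_list <- function(om) {
  list(id = om$id,
       stoich = om$stoich,
       lb = as.list(stats::setNames(vapply(om$lb, fmt_bound, character(1)),
                                    names(om$lb))),
       ub = as.list(stats::setNames(vapply(om$ub, fmt_bound, character(1)),
                                    names(om$ub))),
       biomass_reaction = om$biomass_reaction,
       atpm_reaction = om$atpm_reaction,
       exchange_map = as.list(om$exchange_map))
}

om_from_list <- function(x) {
  organism_model(
    id = x$id,
    stoich = as.data.frame(x$stoich),
    lb = vapply(x$lb, function(v) parse_bound(as.character(v)), numeric(1)),
    ub = vapply(x$ub, function(v) parse_bound(as.character(v)), numeric(1)),
    biomass_reaction = x$biomass_reaction,
    atpm_reaction = x$atpm_reaction,
    exchange_map = unlist(x$exchange_map))
}

#' Write a model in the compact JSON dialect
#'
#' Serializes an [organism_model()] or a whole [build_community()] model to
#' JSON.  Infinite bounds are stored as the strings `"INF"` / `"-INF"`.
#'
#' @param x an `organism_model` or `community_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toy_json <- function(x, path) {
  payload <- if (inherits(x, "organism_model")) {
    c(list(type = "organism_model"), om_to_list(x))
  } else if (inherits(x, "community_model")) {
    list(type = "community_model",
         X0 = x$X0,
         uptake_ub = as.list(x$uptake_ub),
         organism_uptake_ub = x$organism_uptake_ub,
         organisms = lapply(x$organisms, om_to_list))
  } else stop("unsupported object for the JSON dialect")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model from the compact JSON dialect
#'
#' @param path a file written by [write_toy_json()].
#' @return An `organism_model` or `community_model`, matching what was
#'   written.
#' @export
read_toy_json <- function(path) {
  if (!file.exists(path)) stop("cannot read JSON model: ", path)
  x <- jsonlite::read_json(path)
  x$stoich <- rectangularize(x$stoich)
  if (identical(x$type, "organism_model")) return(om_from_list(x))
  if (!identical(x$type, "community_model"))
    stop("not a model JSON file: ", path)
  oms <- lapply(x$organisms, function(o) {
    o$stoich <- rectangularize(o$stoich)
    om_from_list(o)
  })
  build_community(
    oms,
    uptake_ub = vapply(x$uptake_ub, as.numeric, numeric(1)),
    X0 = x$X0,
    organism_uptake_ub = if (!is.null(x$organism_uptake_ub))
      rectangularize(x$organism_uptake_ub))
}

## jsonlite::read_json returns data frames as lists of row-lists
rectangularize <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(row)
    as.data.frame(row, stringsAsFactors = FALSE)))
}

#' Read a community uptake-bound table
#'
#' Tab-separated with header columns `metabolite` and `uptake`
#' (mmol/h per `X0`).
#'
#' @param path TSV file path.
#' @return Named numeric vector of uptake bounds.
#' @export
read_uptake_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "uptake") %in% names(tb)))
  stats::setNames(as.numeric(tb$uptake), tb$metabolite)
}

#' Assemble a community model from a configuration
#'
#' The configuration is a list (or path to a JSON file) with fields:
#' \describe{
#'   \item{model_paths}{named list, organism id to model file (`.xml`/`.sbml`
#'     read as SBML, `.json` as the JSON dialect).}
#'   \item{X0}{total community biomass, default 1.}
#'   \item{uptake_table}{optional TSV path, see [read_uptake_table()].}
#'   \item{mapping_table}{optional TSV path with columns `organism`,
#'     `metabolite`, `community_id`, aliasing organisms' extracellular
#'     metabolites onto shared community metabolites when plain id matching
#'     (the default: equal ids after stripping the compartment suffix) does
#'     not apply.}
#'   \item{organism_uptake_table}{optional TSV path with columns `organism`,
#'     `metabolite`, `max_uptake` of per-organism uptake limits.}
#' }
#' Relative paths are resolved against the directory of the configuration
#' file when `config` is a path.
#'
#' @param config list or JSON file path.
#' @return A [build_community()] model.
#' @export
read_community <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- jsonlite::read_json(config)
  }
  stopifnot(is.list(config))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  ## shortcut: a self-contained community JSON written by write_toy_json()
  if (!is.null(config$community_json)) {
    cm <- read_toy_json(resolve(config$community_json))
    if (!inherits(cm, "community_model"))
      stop("community_json does not contain a community model")
    if (!is.null(config$X0)) cm$X0 <- as.numeric(config$X0)
    return(cm)
  }
  if (is.null(config$model_paths))
    stop("config needs either model_paths or community_json")
  ids <- names(config$model_paths)
  if (is.null(ids) || anyDuplicated(ids))
    stop("model_paths must be uniquely named by organism id")
  models <- lapply(ids, function(org) {
    p <- resolve(config$model_paths[[org]])
    om <- if (grepl("\\.json$", p, ignore.case = TRUE)) read_toy_json(p)
          else read_organism_sbml(p)
    if (!inherits(om, "organism_model"))
      stop("model file for '", org, "' does not contain a single organism")
    om$id <- org
    om
  })

  if (!is.null(config$mapping_table)) {
    mp <- utils::read.delim(resolve(config$mapping_table),
                            stringsAsFactors = FALSE)
    stopifnot(all(c("organism", "metabolite", "community_id") %in% names(mp)))
    if (!all(mp$organism %in% ids))
      stop("mapping table references unknown organism")
    models <- lapply(models, function(om) {
      rows <- mp[mp$organism == om$id, , drop = FALSE]
      if (nrow(rows)) {
        key <- sub("_e$", "", rows$metabolite)
        hit <- match(key, names(om$exchange_map))
        if (anyNA(hit))
          stop("mapping table entry not matched for organism '", om$id,
               "': ", paste(rows$metabolite[is.na(hit)], collapse = ", "))
        names(om$exchange_map)[hit] <- rows$community_id
      }
      om
    })
  }

  uptake_ub <- numeric(0)
  if (!is.null(config$uptake_table))
    uptake_ub <- read_uptake_table(resolve(config$uptake_table))
  if (!is.null(config$uptake_ub))
    uptake_ub <- vapply(config$uptake_ub, as.numeric, numeric(1))

  org_ub <- NULL
  if (!is.null(config$organism_uptake_table))
    org_ub <- utils::read.delim(resolve(config$organism_uptake_table),
                                stringsAsFactors = FALSE)

  X0 <- if (!is.null(config$X0)) as.numeric(config$X0) else 1
  build_community(models, uptake_ub = uptake_ub, X0 = X0,
                  organism_uptake_ub = org_ub)
}

#' Write an analysis result to disk
#'
#' JSON output is a faithful machine-readable rendering (round-trippable
#' for [steadycom()] fits through [read_result()]).  TSV output is a flat
#' table: for a fit, columns `record` (`mu_max`, `abundance`, `flux`,
#' `uptake`, `export`), `organism`, `id`, `value`; FVA tables
#' ([steadycom_fva()], [abundance_fva()]) are written as-is; a
#' [pairwise_fva()] scan writes its `fixed_value`/`dep_min`/`dep_max`/
#' `feasible` table.
#'
#' @param x a `steadycom` fit, an FVA data frame, or a `pairwise_scan`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "steadycom")) {
    if (format == "json") {
      payload <- list(type = "steadycom_result",
                      mu_max = x$mu_max, status = x$status,
                      iterations = x$iterations, X0 = x$X0,
                      abundance = as.list(x$abundance),
                      aggregate_flux = lapply(x$aggregate_flux, as.list),
                      community_uptake = as.list(x$community_uptake),
                      community_export = as.list(x$community_export))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null")
    } else {
      rows <- data.frame(record = "mu_max", organism = "", id = "",
                         value = x$mu_max, stringsAsFactors = FALSE)
      add <- function(rows, record, organism, id, value)
        rbind(rows, data.frame(record = record, organism = organism, id = id,
                               value = value, stringsAsFactors = FALSE))
      if (!is.null(x$abundance) && !anyNA(x$abundance))
        rows <- add(rows, "abundance", names(x$abundance), "",
                    unname(x$abundance))
      for (org in names(x$aggregate_flux))
        rows <- add(rows, "flux", org, names(x$aggregate_flux[[org]]),
                    unname(x$aggregate_flux[[org]]))
      if (!is.null(x$community_uptake))
        rows <- add(rows, "uptake", "", names(x$community_uptake),
                    unname(x$community_uptake))
      if (!is.null(x$community_export))
        rows <- add(rows, "export", "", names(x$community_export),
                    unname(x$community_export))
      utils::write.table(rows, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else if (inherits(x, "pairwise_scan")) {
    if (format == "json") {
      jsonlite::write_json(
        list(type = "pairwise_scan",
             fixed_organism = x$fixed_organism,
             dependent_organism = x$dependent_organism,
             mu0 = x$mu0, mu_frac = x$mu_frac,
             classification = x$classification,
             ranges = x$ranges),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    } else {
      utils::write.table(x$ranges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else if (is.data.frame(x)) {
    if (format == "json")
      jsonlite::write_json(x, path, digits = NA, na = "null")
    else
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  } else stop("unsupported result object")
  invisible(path)
}

#' Read a result written by [write_result()] (JSON only)
#'
#' @param path JSON file path.
#' @return For a fit, an object of class `steadycom` (without the model and
#'   search log); otherwise the parsed list.
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path)
  if (identical(x$type, "steadycom_result")) {
    num <- function(l) if (is.null(l)) NULL else
      stats::setNames(vapply(l, as.numeric, numeric(1)), names(l))
    return(structure(list(mu_max = x$mu_max, status = x$status,
                          iterations = x$iterations, X0 = x$X0,
                          abundance = num(x$abundance),
                          aggregate_flux = lapply(x$aggregate_flux, num),
                          community_uptake = num(x$community_uptake),
                          community_export = num(x$community_export)),
                     class = "steadycom"))
  }
  x
}
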