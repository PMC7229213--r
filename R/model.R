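#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` bundles the stoichiometric matrix `S` (metabolites in
#' rows, reactions in columns), finite flux bounds, the position of the
#' biomass reaction, the tagged reactions used by the ratio constraints
#' (RuBisCO carboxylation and oxygenation, starch and sucrose synthesis) and
#' the set of exchange reactions crossing the system boundary.
#'
#' Default bounds are -1000/1000 for reversible and 0/1000 for irreversible
#' reactions; fluxes are in mmol per gram dry weight per day. Import exchange
#' reactions have a single +1 stoichiometric entry, so positive exchange flux
#' imports the metabolite into the network.
#'
#' @param metabolite_ids character vector of metabolite identifiers (rows).
#' @param reaction_ids character vector of reaction identifiers (columns).
#' @param S numeric matrix, `length(metabolite_ids)` x `length(reaction_ids)`.
#' @param lb,ub numeric vectors of lower/upper flux bounds per reaction.
#' @param biomass reaction id (or column index) of the biomass reaction.
#' @param tags named character vector mapping a subset of
#'   `c("carboxylation","oxygenation","starch_synthesis","sucrose_synthesis")`
#'   to reaction ids; each tag maps to exactly one reaction.
#' @param exchange_ids reaction ids of boundary exchanges. If `NULL`, detected
#'   as reactions whose column has a single non-zero entry.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, lb, ub,
                            biomass, tags = character(), exchange_ids = NULL) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids", call. = FALSE)
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != length(metabolite_ids) || ncol(S) != length(reaction_ids))
    stop("S must be length(metabolite_ids) x length(reaction_ids)", call. = FALSE)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != ncol(S) || length(ub) != ncol(S))
    stop("bounds must have one entry per reaction", call. = FALSE)
  if (any(lb > ub)) stop("lb > ub for some reaction", call. = FALSE)
  names(lb) <- names(ub) <- reaction_ids
  if (is.character(biomass)) {
    biomass_index <- match(biomass, reaction_ids)
    if (is.na(biomass_index))
      stop("biomass reaction '", biomass, "' is not among the reaction ids",
           call. = FALSE)
  } else {
    biomass_index <- as.integer(biomass)
    if (is.na(biomass_index) || biomass_index < 1L || biomass_index > ncol(S))
      stop("biomass index out of range", call. = FALSE)
  }
  tags <- unlist(tags)
  if (length(tags)) {
    allowed <- c("carboxylation", "oxygenation",
                 "starch_synthesis", "sucrose_synthesis")
    bad <- setdiff(names(tags), allowed)
    if (length(bad)) stop("unknown tags: ", paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(tags))) stop("each tag maps to exactly one reaction", call. = FALSE)
    missing <- setdiff(tags, reaction_ids)
    if (length(missing))
      stop("tagged reactions absent from model: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (is.null(exchange_ids)) {
    exchange_ids <- reaction_ids[colSums(S != 0) == 1L]
    exchange_ids <- setdiff(exchange_ids, reaction_ids[biomass_index])
  } else {
    missing <- setdiff(exchange_ids, reaction_ids)
    if (length(missing))
      stop("exchange ids absent from model: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  structure(list(metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
                 S = S, lb = lb, ub = ub, biomass_index = biomass_index,
                 tags = tags, exchange_ids = as.character(exchange_ids)),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model: ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions\n", sep = "")
  cat("  biomass: ", x$reaction_ids[x$biomass_index], "\n", sep = "")
  if (length(x$tags))
    cat("  tags: ", paste(names(x$tags), x$tags, sep = "=", collapse = ", "), "\n",
        sep = "")
  cat("  exchanges: ", paste(x$exchange_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.tag_index <- function(model, tag) {
  id <- unname(model$tags[tag])
  if (is.na(id) || is.null(id)) return(NA_integer_)
  match(id, model$reaction_ids)
}

#' Ratio constraints on carboxylation:oxygenation and starch:sucrose fluxes
#'
#' Either fixed values (used for the reference flux distribution:
#' carboxylation = 2.88 x oxygenation, starch synthesis = 2.58 x sucrose
#' synthesis) or intervals (used for all genotype-specific programs:
#' carboxylation/oxygenation in \[0.94, 3.81\], starch/sucrose in
#' \[0.79, 3.37\]).
#'
#' @param carb_oxy single value or `c(low, high)` interval.
#' @param starch_sucrose single value or `c(low, high)` interval.
#' @return object of class `ratio_constraints` with a `mode` field
#'   (`"fixed"` or `"interval"`).
#' @export
ratio_constraints <- function(carb_oxy = 2.88, starch_sucrose = 2.58) {
  chk <- function(x, what) {
    x <- as.numeric(x)
    if (!length(x) %in% c(1L, 2L) || any(!is.finite(x)) || any(x <= 0))
      stop(what, " must be one positive value or a positive [low, high] interval",
           call. = FALSE)
    if (length(x) == 2L && x[1] > x[2]) stop(what, ": low > high", call. = FALSE)
    x
  }
  carb_oxy <- chk(carb_oxy, "carb_oxy")
  starch_sucrose <- chk(starch_sucrose, "starch_sucrose")
  if (length(carb_oxy) != length(starch_sucrose))
    stop("both ratios must be fixed or both intervals", call. = FALSE)
  structure(list(carb_oxy = carb_oxy, starch_sucrose = starch_sucrose,
                 mode = if (length(carb_oxy) == 1L) "fixed" else "interval"),
            class = "ratio_constraints")
}

#' Default interval ratio constraints
#'
#' Intervals around the reference ratios: carboxylation/oxygenation in
#' \[0.94, 3.81\] and starch/sucrose synthesis in \[0.79, 3.37\].
#' @return a `ratio_constraints` object in interval mode.
#' @export
ratio_constraints_interval <- function() {
  ratio_constraints(c(0.94, 3.81), c(0.79, 3.37))
}

# Build constraint rows for the tagged ratio pairs. mode "fixed" uses the
# scalar ratios as equalities (with optional two-sided slack eps), "interval"
# uses the interval rows. Untagged pairs are silently skipped.
.ratio_rows <- function(model, ratios, eps = 0) {
  if (is.null(ratios)) return(NULL)
  n <- length(model$reaction_ids)
  parts <- list()
  pairs <- list(c("carboxylation", "oxygenation", "carb_oxy"),
                c("starch_synthesis", "sucrose_synthesis", "starch_sucrose"))
  for (p in pairs) {
    i_num <- .tag_index(model, p[1]); i_den <- .tag_index(model, p[2])
    if (is.na(i_num) || is.na(i_den)) next
    r <- ratios[[p[3]]]
    parts[[length(parts) + 1L]] <-
      if (ratios$mode == "fixed") .ratio_fixed_rows(n, i_num, i_den, r, eps)
      else .ratio_interval_rows(n, i_num, i_den, r[1], r[2])
  }
  if (!length(parts)) return(NULL)
  do.call(.stack_rows, parts)
}

#' Construct a flux distribution
#'
#' A named numeric vector of reaction fluxes (mmol gDW^-1 d^-1) tied to a
#' model by reaction order.
#'
#' @param values numeric vector, one flux per model reaction.
#' @param model the `metabolic_model` the fluxes refer to.
#' @param label free-text label (genotype/environment).
#' @param objective optional objective value attached by the solver.
#' @return object of class `flux_distribution`.
#' @export
flux_distribution <- function(values, model, label = "", objective = NA_real_) {
  values <- as.numeric(values)
  if (length(values) != length(model$reaction_ids))
    stop("flux vector length does not match the model", call. = FALSE)
  names(values) <- model$reaction_ids
  structure(list(values = values, model_ref = model$reaction_ids[model$biomass_index],
                 reaction_ids = model$reaction_ids, label = label,
                 objective = objective),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$values), " reactions, ",
      sum(abs(x$values) > 1e-9), " non-zero\n", sep = "")
  invisible(x)
}

#' Maximum steady-state residual of a flux distribution
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_distribution` or numeric vector.
#' @return `max(abs(S %*% v))`.
#' @export
steady_state_residual <- function(model, flux) {
  v <- if (inherits(flux, "flux_distribution")) flux$values else as.numeric(flux)
  max(abs(model$S %*% v))
}

#' Construct a biomass composition
#'
#' Coefficients are amounts of biomass precursors per gram dry weight
#' (positive = consumed when the biomass reaction runs). Substituting a
#' composition into a model negates the coefficients into the biomass column.
#'
#' @param coefficients named numeric vector, metabolite id -> amount per gDW.
#' @param accession_id,environment_id free-text provenance labels.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(coefficients, accession_id = "",
                                environment_id = "") {
  coefficients <- unlist(coefficients)
  if (!length(coefficients) || is.null(names(coefficients)))
    stop("coefficients must be a non-empty named vector", call. = FALSE)
  if (any(!is.finite(coefficients))) stop("non-finite coefficient", call. = FALSE)
  if (all(coefficients == 0)) stop("all coefficients are zero", call. = FALSE)
  structure(list(coefficients = coefficients,
                 accession_id = accession_id, environment_id = environment_id),
            class = "biomass_composition")
}

#' Extract the biomass composition currently encoded in a model
#'
#' @param model a `metabolic_model`.
#' @return a `biomass_composition` with the (negated) non-zero entries of the
#'   biomass column.
#' @export
model_biomass_composition <- function(model) {
  col <- model$S[, model$biomass_index]
  nz <- col != 0
  biomass_composition(-col[nz])
}

#' Substitute a genotype-specific biomass reaction into a model
#'
#' Replaces the biomass column of the stoichiometric matrix with the negated
#' composition coefficients (consumed precursors get negative entries). The
#' input model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param comp a `biomass_composition`; every metabolite must exist in the model.
#' @return a new `metabolic_model` differing only in the biomass column.
#' @export
set_biomass <- function(model, comp) {
  stopifnot(inherits(model, "metabolic_model"), inherits(comp, "biomass_composition"))
  unknown <- setdiff(names(comp$coefficients), model$metabolite_ids)
  if (length(unknown))
    stop("composition metabolites absent from model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  model$S[, model$biomass_index] <- 0
  model$S[names(comp$coefficients), model$biomass_index] <- -comp$coefficients
  model
}

# ---------------------------------------------------------------------------
# Readers / writers. The tabular dialect (reactions.tsv + metabolites.tsv) is
# canonical; JSON and SBML Level 3 (fbc-style bounds) are layered over the
# same in-memory representation.

.parse_equation <- function(eq, id) {
  arrow <- regmatches(eq, regexpr("<?->", eq))[1]
  sides <- strsplit(eq, "<?->")[[1]]
  if (length(sides) > 2L)
    stop("reaction '", id, "': cannot parse equation '", eq, "'", call. = FALSE)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.eE+-]+\\s+)?(\\S+)$", trimws(t)))[[1]]
      if (length(m) != 3L || !nzchar(m[3]))
        stop("reaction '", id, "': cannot parse term '", t, "'", call. = FALSE)
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      if (is.na(coef))
        stop("reaction '", id, "': bad coefficient in '", t, "'", call. = FALSE)
      out[m[3]] <- sign * coef + ifelse(is.na(out[m[3]]), 0, out[m[3]])
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2], +1) else numeric(0)
  coefs <- c(lhs, rhs)
  tapply(coefs, names(coefs), sum)
}

.format_equation <- function(col, metabolite_ids) {
  nz <- which(col != 0)
  fmt <- function(ids, coefs) {
    if (!length(ids)) return("")
    paste(ifelse(coefs == 1, ids,
                 paste(format(coefs, digits = 17, trim = TRUE, scientific = FALSE),
                       ids)),
          collapse = " + ")
  }
  lhs <- nz[col[nz] < 0]; rhs <- nz[col[nz] > 0]
  paste(fmt(metabolite_ids[lhs], -col[lhs]), "->", fmt(metabolite_ids[rhs], col[rhs]))
}

#' Read a metabolic model
#'
#' Dialects: `"tsv"` expects `<path>/reactions.tsv` (columns id, equation,
#' lb, ub, tag) and `<path>/metabolites.tsv` (column id); `"json"` a single
#' file with `metabolites`, `reactions` (id, metabolites map, lower_bound,
#' upper_bound, tag) and `biomass`; `"sbml"` an SBML Level 3 file with
#' fbc-style bound parameters and an active objective naming the biomass
#' reaction. Exactly one reaction must carry the `biomass` tag (tsv/json) or
#' be the active objective (sbml). Reaction order is preserved from the file.
#'
#' @param path file (json/sbml) or directory (tsv).
#' @param dialect one of `"tsv"`, `"json"`, `"sbml"`; default guessed from
#'   the path.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("guess", "tsv", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "guess") {
    dialect <- if (dir.exists(path)) "tsv"
      else if (grepl("\\.json$", path)) "json"
      else if (grepl("\\.(xml|sbml)$", path)) "sbml"
      else stop("cannot guess dialect of '", path, "'", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(dialect,
         tsv = .read_model_tsv(path),
         json = .read_model_json(path),
         sbml = .read_model_sbml(path))
}

.model_from_tables <- function(met_ids, rxn) {
  rxn$id <- as.character(rxn$id)
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids in file", call. = FALSE)
  tags <- character()
  biomass_id <- NULL
  stoich <- lapply(seq_len(nrow(rxn)), function(i) rxn$coefs[[i]])
  for (i in seq_len(nrow(rxn))) {
    tg <- rxn$tag[i]
    if (is.na(tg) || !nzchar(tg)) next
    if (tg == "biomass") {
      if (!is.null(biomass_id)) stop("more than one biomass reaction", call. = FALSE)
      biomass_id <- rxn$id[i]
    } else tags[tg] <- rxn$id[i]
  }
  if (is.null(biomass_id))
    stop("no reaction tagged as biomass", call. = FALSE)
  used <- unique(unlist(lapply(stoich, names)))
  unknown <- setdiff(used, met_ids)
  if (length(unknown))
    stop("equation references unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  S <- matrix(0, length(met_ids), nrow(rxn), dimnames = list(met_ids, rxn$id))
  for (i in seq_len(nrow(rxn))) S[names(stoich[[i]]), i] <- stoich[[i]]
  metabolic_model(met_ids, rxn$id, S, rxn$lb, rxn$ub, biomass_id, tags)
}

.read_model_tsv <- function(path) {
  rf <- file.path(path, "reactions.tsv"); mf <- file.path(path, "metabolites.tsv")
  for (f in c(rf, mf)) if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  rxn <- utils::read.delim(rf, stringsAsFactors = FALSE, colClasses = "character")
  met <- utils::read.delim(mf, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "equation", "lb", "ub", "tag")
  if (!all(need %in% names(rxn)))
    stop("reactions.tsv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"id" %in% names(met)) stop("metabolites.tsv must have column 'id'", call. = FALSE)
  rxn$lb <- as.numeric(rxn$lb); rxn$ub <- as.numeric(rxn$ub)
  if (any(is.na(rxn$lb)) || any(is.na(rxn$ub)))
    stop("non-numeric bound in reactions.tsv", call. = FALSE)
  rxn$coefs <- lapply(seq_len(nrow(rxn)),
                      function(i) .parse_equation(rxn$equation[i], rxn$id[i]))
  .model_from_tables(as.character(met$id), rxn)
}

.read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("JSON model needs 'metabolites' and 'reactions'", call. = FALSE)
  met_ids <- vapply(doc$metabolites, function(m)
    if (is.list(m)) as.character(m$id) else as.character(m), character(1))
  rxn <- data.frame(id = vapply(doc$reactions, function(r) as.character(r$id),
                                character(1)),
                    lb = vapply(doc$reactions, function(r) as.numeric(r$lower_bound),
                                numeric(1)),
                    ub = vapply(doc$reactions, function(r) as.numeric(r$upper_bound),
                                numeric(1)),
                    tag = vapply(doc$reactions, function(r)
                      if (is.null(r$tag)) "" else as.character(r$tag), character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(doc$biomass)) {
    hit <- rxn$id == as.character(doc$biomass)
    if (!any(hit)) stop("biomass reaction '", doc$biomass,
                        "' is absent from the reaction list", call. = FALSE)
    rxn$tag[hit] <- "biomass"
  }
  rxn$coefs <- lapply(doc$reactions, function(r) {
    v <- unlist(r$metabolites); v[v != 0]
  })
  .model_from_tables(met_ids, rxn)
}

.read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # fbc-prefixed nodes keep their prefix after stripping; match local names
  ln <- function(x) sprintf(".//*[local-name()='%s']", x)
  mets <- xml2::xml_find_all(doc, ln("species"))
  met_ids <- xml2::xml_attr(mets, "id")
  params <- xml2::xml_find_all(doc, ln("parameter"))
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  objs <- xml2::xml_find_all(doc, ln("fluxObjective"))
  biomass_id <- if (length(objs)) xml2::xml_attr(objs[[1]], "reaction") else NULL
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rnodes)) stop("SBML file has no reactions", call. = FALSE)
  get_bound <- function(node, attr, rev_default) {
    ref <- xml2::xml_attr(node, attr)
    if (!is.na(ref) && ref %in% names(pvals)) return(unname(pvals[ref]))
    rev_default
  }
  rows <- lapply(rnodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- get_bound(node, "lowerFluxBound", if (rev) -1000 else 0)
    ub <- get_bound(node, "upperFluxBound", 1000)
    tag <- xml2::xml_attr(node, "tag")
    coefs <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry")); if (is.na(st)) st <- 1
      coefs[sp] <- -st
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry")); if (is.na(st)) st <- 1
      coefs[sp] <- st + ifelse(is.na(coefs[sp]), 0, coefs[sp])
    }
    list(id = id, lb = lb, ub = ub, tag = if (is.na(tag)) "" else tag,
         coefs = coefs)
  })
  rxn <- data.frame(id = vapply(rows, `[[`, character(1), "id"),
                    lb = vapply(rows, `[[`, numeric(1), "lb"),
                    ub = vapply(rows, `[[`, numeric(1), "ub"),
                    tag = vapply(rows, `[[`, character(1), "tag"),
                    stringsAsFactors = FALSE)
  if (!is.null(biomass_id)) {
    hit <- rxn$id == biomass_id
    if (!any(hit)) stop("objective reaction '", biomass_id,
                        "' is absent from the reaction list", call. = FALSE)
    rxn$tag[hit] <- "biomass"
  }
  rxn$coefs <- lapply(rows, `[[`, "coefs")
  .model_from_tables(met_ids, rxn)
}

#' Write a metabolic model
#'
#' Inverse of [read_model()]; `read_model(write_model(m, ...))` restores the
#' model field by field.
#'
#' @param model a `metabolic_model`.
#' @param path output file (json/sbml) or directory (tsv; created).
#' @param dialect one of `"tsv"`, `"json"`, `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("tsv", "json", "sbml")) {
  dialect <- match.arg(dialect)
  tag_of <- function(i) {
    if (i == model$biomass_index) return("biomass")
    hit <- which(model$tags == model$reaction_ids[i])
    if (length(hit)) names(model$tags)[hit[1]] else ""
  }
  tags <- vapply(seq_along(model$reaction_ids), tag_of, character(1))
  if (dialect == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    eqs <- vapply(seq_along(model$reaction_ids), function(i)
      .format_equation(model$S[, i], model$metabolite_ids), character(1))
    utils::write.table(
      data.frame(id = model$reaction_ids, equation = eqs,
                 lb = format(model$lb, digits = 17, trim = TRUE, scientific = FALSE),
                 ub = format(model$ub, digits = 17, trim = TRUE, scientific = FALSE),
                 tag = tags),
      file.path(path, "reactions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(data.frame(id = model$metabolite_ids),
                       file.path(path, "metabolites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (dialect == "json") {
    rxns <- lapply(seq_along(model$reaction_ids), function(i) {
      nz <- which(model$S[, i] != 0)
      list(id = model$reaction_ids[i],
           metabolites = as.list(stats::setNames(model$S[nz, i],
                                                 model$metabolite_ids[nz])),
           lower_bound = unname(model$lb[i]), upper_bound = unname(model$ub[i]),
           tag = tags[i])
    })
    jsonlite::write_json(list(metabolites = as.list(model$metabolite_ids),
                              reactions = rxns,
                              biomass = model$reaction_ids[model$biomass_index]),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    .write_model_sbml(model, path, tags)
  }
  invisible(path)
}

.write_model_sbml <- function(model, path, tags) {
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" fbc:required="false">',
             '<model id="netgs_model" fbc:strict="true">',
             '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
             '<listOfSpecies>')
  lines <- c(lines, sprintf(
    '<species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    model$metabolite_ids))
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  bnd_ids <- character(0)
  for (i in seq_along(model$reaction_ids)) {
    for (side in c("lb", "ub")) {
      pid <- paste0(side, "_", i)
      val <- if (side == "lb") model$lb[i] else model$ub[i]
      lines <- c(lines, sprintf('<parameter id="%s" value="%s" constant="true"/>',
                                pid, num(val)))
    }
  }
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  for (i in seq_along(model$reaction_ids)) {
    col <- model$S[, i]
    rev <- model$lb[i] < 0
    tagattr <- if (nzchar(tags[i]) && tags[i] != "biomass")
      sprintf(' tag="%s"', tags[i]) else ""
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" lowerFluxBound="lb_%d" upperFluxBound="ub_%d"%s>',
      model$reaction_ids[i], tolower(rev), i, i, tagattr))
    reac <- which(col < 0); prod <- which(col > 0)
    if (length(reac)) {
      lines <- c(lines, '<listOfReactants>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model$metabolite_ids[reac], num(-col[reac])),
                 '</listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '<listOfProducts>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model$metabolite_ids[prod], num(col[prod])),
                 '</listOfProducts>')
    }
    lines <- c(lines, '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>',
             '<fbc:listOfObjectives fbc:activeObjective="obj">',
             '<fbc:objective fbc:id="obj" fbc:type="maximize">',
             '<fbc:listOfFluxObjectives>',
             sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     model$reaction_ids[model$biomass_index]),
             '</fbc:listOfFluxObjectives>', '</fbc:objective>',
             '</fbc:listOfObjectives>', '</model>', '</sbml>')
  writeLines(lines, path)
}

#' Read / write biomass compositions (biomass.csv)
#'
#' The CSV has columns `metabolite`, `coefficient`, `accession`,
#' `environment`; coefficients are amounts per gram dry weight.
#'
#' @param path CSV file.
#' @return `read_biomass_csv`: a list of `biomass_composition`, named
#'   `accession.environment`.
#' @export
read_biomass_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "coefficient", "accession", "environment")
  if (!all(need %in% names(df)))
    stop("biomass.csv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (key in unique(paste(df$accession, df$environment, sep = "."))) {
    sub <- df[paste(df$accession, df$environment, sep = ".") == key, ]
    out[[key]] <- biomass_composition(
      stats::setNames(sub$coefficient, sub$metabolite),
      accession_id = sub$accession[1], environment_id = sub$environment[1])
  }
  out
}

#' @rdname read_biomass_csv
#' @param comps list of `biomass_composition` objects.
#' @export
write_biomass_csv <- function(comps, path) {
  if (inherits(comps, "biomass_composition")) comps <- list(comps)
  rows <- do.call(rbind, lapply(comps, function(cp)
    data.frame(metabolite = names(cp$coefficients),
               coefficient = unname(cp$coefficients),
               accession = cp$accession_id, environment = cp$environment_id)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble an accession-specific biomass composition from measurements
#'
#' Converts measured soluble-metabolite amounts to micromol per gram dry
#' weight, adds protein-bound amino acids computed from the amino-acid
#' fractions of the total protein, and merges invariant components (cell-wall
#' and lipid precursors, nucleotides, ATP) assumed identical across
#' accessions.
#'
#' @param measured data.frame with columns `metabolite`, `amount`, `unit`;
#'   units among `"umol_per_gDW"`, `"mg_per_gDW"`, `"g_per_gDW"`.
#' @param protein_total total protein in mg per gDW.
#' @param aa_fractions named vector of mass fractions of the 20 amino acids
#'   in total protein; must sum to 1 within 1e-6. Use `NULL` with
#'   `protein_total = 0`.
#' @param fixed_components `biomass_composition` (or named vector, umol/gDW)
#'   of the invariant precursors.
#' @param molar_masses named vector of molar masses (g/mol) or path to a CSV
#'   with columns `metabolite`, `molar_mass`; defaults to the table shipped
#'   with the package. Mass-unit metabolites without a molar mass fail.
#' @param accession_id,environment_id provenance labels.
#' @return a `biomass_composition` in umol per gDW.
#' @export
assemble_biomass <- function(measured, protein_total = 0, aa_fractions = NULL,
                             fixed_components = NULL, molar_masses = NULL,
                             accession_id = "", environment_id = "") {
  if (is.null(molar_masses))
    molar_masses <- system.file("extdata", "molar_masses.csv", package = "netgs")
  if (is.character(molar_masses)) {
    mm <- utils::read.csv(molar_masses, stringsAsFactors = FALSE)
    molar_masses <- stats::setNames(mm$molar_mass, mm$metabolite)
  }
  coefs <- numeric(0)
  if (!is.null(measured) && nrow(measured)) {
    need <- c("metabolite", "amount", "unit")
    if (!all(need %in% names(measured)))
      stop("measured needs columns: ", paste(need, collapse = ", "), call. = FALSE)
    if (any(measured$amount < 0)) stop("negative measured amount", call. = FALSE)
    for (i in seq_len(nrow(measured))) {
      met <- measured$metabolite[i]; amt <- measured$amount[i]
      u <- measured$unit[i]
      val <- switch(u,
        umol_per_gDW = amt,
        mg_per_gDW = ,
        g_per_gDW = {
          if (!met %in% names(molar_masses))
            stop("no molar mass for metabolite '", met, "'", call. = FALSE)
          mg <- if (u == "g_per_gDW") amt * 1000 else amt
          mg / molar_masses[[met]] * 1000       # mg / (g/mol) -> umol
        },
        stop("unknown unit '", u, "'", call. = FALSE))
      coefs[met] <- val + ifelse(is.na(coefs[met]), 0, coefs[met])
    }
  }
  if (protein_total < 0) stop("negative protein_total", call. = FALSE)
  if (protein_total > 0) {
    if (is.null(aa_fractions)) stop("aa_fractions required when protein_total > 0",
                                    call. = FALSE)
    if (abs(sum(aa_fractions) - 1) > 1e-6)
      stop("aa_fractions must sum to 1", call. = FALSE)
    for (aa in names(aa_fractions)) {
      if (!aa %in% names(molar_masses))
        stop("no molar mass for amino acid '", aa, "'", call. = FALSE)
      val <- protein_total * aa_fractions[[aa]] / molar_masses[[aa]] * 1000
      coefs[aa] <- val + ifelse(is.na(coefs[aa]), 0, coefs[aa])
    }
  } else if (!is.null(aa_fractions)) {
    for (aa in names(aa_fractions)) coefs[aa] <- ifelse(is.na(coefs[aa]), 0, coefs[aa])
  }
  if (!is.null(fixed_components)) {
    fx <- if (inherits(fixed_components, "biomass_composition"))
      fixed_components$coefficients else unlist(fixed_components)
    for (met in names(fx)) coefs[met] <- fx[[met]] + ifelse(is.na(coefs[met]), 0, coefs[met])
  }
  coefs <- coefs[order(names(coefs))]            # invariant to input ordering
  biomass_composition(coefs, accession_id, environment_id)
}
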