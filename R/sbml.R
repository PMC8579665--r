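# SBML reading/writing (xml2-based, core subset + fbc bounds).
#
# Stoichiometric coefficients are taken from the attribute *strings* and
# parsed digit-exactly into rationals; no float intermediate ever occurs, so
# a model written and re-read round-trips to rational equality.

.SBML_BIGM <- 1000  # |bound| >= this is treated as unbounded (COBRA default)

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 2/3 core plus the fbc flux-bound attributes. Boundary
#' species (`boundaryCondition="true"`) are excluded from the stoichiometric
#' rows. When fbc bounds are present a reaction is flagged reversible iff
#' its lower bound is negative; otherwise the SBML `reversible` flag is
#' used. Bounds with magnitude >= 1000 (the conventional COBRA "unbounded"
#' default) are treated as absent.
#'
#' @param path SBML file path.
#' @return `"MetabolicModel"`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("invalid SBML file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) {
    stop("invalid SBML: no <model> element in '", path, "'", call. = FALSE)
  }

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  if (any(is.na(sp_id))) stop("invalid SBML: <species> without id", call. = FALSE)
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  boundary <- !is.na(boundary) & boundary == "true"
  met_ids <- sp_id[!boundary]

  # fbc parameters (bound values live in <parameter> elements)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(xml2::xml_attr(par_nodes, "value"),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("invalid SBML: model has no reactions", call. = FALSE)
  rxn_ids <- xml2::xml_attr(rx_nodes, "id")
  if (any(is.na(rxn_ids))) stop("invalid SBML: <reaction> without id", call. = FALSE)

  m <- length(met_ids); n <- length(rx_nodes)
  Sn <- matrix(0, m, n); Sd <- matrix(1, m, n)
  rev <- logical(n)
  lb_n <- numeric(n); lb_d <- rep(1, n); lb_fin <- rep(FALSE, n)
  ub_n <- numeric(n); ub_d <- rep(1, n); ub_fin <- rep(FALSE, n)

  parse_coef <- function(s, what, rid) {
    v <- tryCatch(rq_parse(s), error = function(e) NULL)
    if (is.null(v)) stop("invalid SBML: non-numeric ", what, " '", s,
                         "' in reaction ", rid, call. = FALSE)
    v
  }

  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    rid <- rxn_ids[j]
    rv <- xml2::xml_attr(node, "reversible")
    rev[j] <- is.na(rv) || rv == "true"
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        if (is.na(st)) st <- "1"
        coef <- parse_coef(st, "stoichiometry", rid)
        i <- match(sp, met_ids)
        if (is.na(i)) {
          if (sp %in% sp_id) next  # boundary species: skip row
          stop("invalid SBML: speciesReference to unknown species '", sp,
               "' in reaction ", rid, call. = FALSE)
        }
        add <- .rq_add0(Sn[i, j], Sd[i, j], sgn * coef$n, coef$d)
        Sn[i, j] <- add$n; Sd[i, j] <- add$d
      }
    }
    # fbc bounds
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(par_val)) {
      v <- parse_coef(par_val[[lbref]], "lower bound", rid)
      rev[j] <- rq_sign(v) < 0
      if (abs(rq_to_double(v)) < .SBML_BIGM) {
        lb_n[j] <- v$n; lb_d[j] <- v$d; lb_fin[j] <- TRUE
      }
    }
    if (!is.na(ubref) && ubref %in% names(par_val)) {
      v <- parse_coef(par_val[[ubref]], "upper bound", rid)
      if (abs(rq_to_double(v)) < .SBML_BIGM) {
        ub_n[j] <- v$n; ub_d[j] <- v$d; ub_fin[j] <- TRUE
      }
    }
  }

  # irreversible reactions default to lb = 0 (finite)
  lb_fin[!rev & !lb_fin] <- TRUE
  lb <- .mkrq(lb_n, lb_d); attr(lb, "finite") <- lb_fin
  ub <- .mkrq(ub_n, ub_d); attr(ub, "finite") <- ub_fin
  metabolic_model(.mkrq(Sn, Sd), met_ids, rxn_ids, rev, lb = lb, ub = ub)
}

# exact decimal expansion of p/q, q = 2^a * 5^b; NULL if not expressible
.rq_decimal_string <- function(n, d) {
  if (d == 1) return(sprintf("%.0f", n))
  k <- 0; dd <- d
  while (dd %% 2 == 0) { dd <- dd / 2; k <- k + 1 }
  while (dd %% 5 == 0) { dd <- dd / 5; k <- k + 1 }
  if (dd != 1) return(NULL)
  # smallest k with 10^k divisible by d, then scale numerator
  k <- 0; t <- 1
  while (t %% d != 0) { t <- t * 10; k <- k + 1; if (k > 20) return(NULL) }
  v <- n * (t / d)
  s <- sprintf("%.0f", abs(v))
  if (nchar(s) <= k) s <- paste0(strrep("0", k - nchar(s) + 1), s)
  out <- paste0(substr(s, 1, nchar(s) - k), ".", substr(s, nchar(s) - k + 1, nchar(s)))
  if (v < 0) out <- paste0("-", out)
  out
}

#' Write a metabolic model as SBML
#'
#' Emits SBML Level 3 Version 1 core: one compartment, the model's species,
#' and reactions with exact decimal stoichiometries and `reversible` flags.
#' Finite bounds are written as fbc-style flux-bound parameters. A
#' stoichiometry whose denominator has a prime factor other than 2 or 5 has
#' no exact decimal form and raises an error rather than being rounded.
#'
#' @param model `"MetabolicModel"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "MetabolicModel"))
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="model">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_along(model$metabolite_ids)) {
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(model$metabolite_ids[i])))
  }
  lines <- c(lines, '    </listOfSpecies>')

  # bound parameters
  params <- character(0)
  lbref <- ubref <- rep(NA_character_, length(model$reaction_ids))
  for (j in seq_along(model$reaction_ids)) {
    if (model$lb_finite[j] && !(rq_sign(rq_index(model$lb, j)) == 0 && !model$rev[j])) {
      v <- rq_index(model$lb, j)
      s <- .rq_decimal_string(v$n, v$d)
      if (!is.null(s) && !(s == "0" && !model$rev[j])) {
        id <- sprintf("lb_%s", model$reaction_ids[j])
        params <- c(params, sprintf(
          '      <parameter id="%s" value="%s" constant="true"/>', esc(id), s))
        lbref[j] <- id
      }
    }
    if (model$ub_finite[j]) {
      v <- rq_index(model$ub, j)
      s <- .rq_decimal_string(v$n, v$d)
      if (!is.null(s)) {
        id <- sprintf("ub_%s", model$reaction_ids[j])
        params <- c(params, sprintf(
          '      <parameter id="%s" value="%s" constant="true"/>', esc(id), s))
        ubref[j] <- id
      }
    }
  }
  if (length(params)) {
    lines <- c(lines, '    <listOfParameters>', params, '    </listOfParameters>')
  }

  lines <- c(lines, '    <listOfReactions>')
  for (j in seq_along(model$reaction_ids)) {
    sn <- model$S$n[, j]; sd <- model$S$d[, j]
    attrs <- sprintf('id="%s" reversible="%s" fast="false"',
                     esc(model$reaction_ids[j]),
                     if (model$rev[j]) "true" else "false")
    if (!is.na(lbref[j])) attrs <- paste0(attrs, sprintf(' lowerFluxBound="%s"', lbref[j]))
    if (!is.na(ubref[j])) attrs <- paste0(attrs, sprintf(' upperFluxBound="%s"', ubref[j]))
    lines <- c(lines, sprintf('      <reaction %s>', attrs))
    for (side in c(-1, 1)) {
      idx <- which(sign(sn) == side)
      if (!length(idx)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf('        <%s>', tag))
      for (i in idx) {
        s <- .rq_decimal_string(abs(sn[i]), sd[i])
        if (is.null(s)) stop("stoichiometry ", rq_format(rq_elt(model$S, i, j)),
                             " has no exact decimal form; cannot write SBML")
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(model$metabolite_ids[i]), s))
      }
      lines <- c(lines, sprintf('        </%s>', tag))
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
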