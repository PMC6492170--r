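# SBML input/output.
#
# Two dialects are supported on input: Level 3 + fbc (bounds as parameter
# references, GPRs as geneProductAssociation trees) and the older Level 2
# COBRA convention (bounds as LOWER_BOUND/UPPER_BOUND kinetic-law
# parameters, GPRs in GENE_ASSOCIATION notes, the objective as an
# OBJECTIVE_COEFFICIENT parameter).  Output is always Level 3 + fbc v2 with
# SBO terms on species, which is what current constraint-based tooling
# expects.  Events, rules and kinetics are out of scope.

SBO_BY_CATEGORY <- c(metabolite = "SBO:0000247",
                     enzyme_species = "SBO:0000252",
                     pseudo_metabolite = "SBO:0000409")

category_from_sbo <- function(sbo) {
  if (is.na(sbo) || !nzchar(sbo)) return("metabolite")
  hit <- names(SBO_BY_CATEGORY)[match(sbo, SBO_BY_CATEGORY)]
  if (is.na(hit)) "metabolite" else hit
}

num_attr <- function(attrs, ...) {
  for (k in c(...)) if (k %in% names(attrs)) return(as.numeric(attrs[[k]]))
  NA_real_
}
chr_attr <- function(attrs, ...) {
  for (k in c(...)) if (k %in% names(attrs)) return(attrs[[k]])
  NA_character_
}

#' Write a model as SBML Level 3 + fbc
#'
#' Species carry SBO terms (pseudo-metabolites `SBO:0000409`), bounds are
#' written as per-reaction parameters, GPRs as `fbc:geneProductAssociation`
#' trees over `fbc:geneProduct` entries (ids prefixed `G_`, labels carrying
#' the raw gene id), and the objective as the active `fbc:objective`.  The
#' emitted document re-reads to an equivalent model.  Output is
#' deterministic: identical models give byte-identical files.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  fmt <- function(v) sprintf("%.17g", v)
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add('  <model id="', esc(model$id), '" fbc:strict="false">')
  add('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments)))
    add('      <compartment id="', esc(model$compartments$id[i]), '" name="',
        esc(model$compartments$name[i]), '" constant="true"/>')
  add('    </listOfCompartments>')
  if (nrow(model$species)) {
    add('    <listOfSpecies>')
    for (i in seq_len(nrow(model$species))) {
      sbo <- model$species$sbo[i]
      if (is.na(sbo)) sbo <- SBO_BY_CATEGORY[[model$species$category[i]]]
      add('      <species id="', esc(model$species$id[i]), '" name="',
          esc(model$species$name[i]), '" compartment="',
          esc(model$species$compartment[i]), '" sboTerm="', sbo,
          '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
          'constant="false"/>')
    }
    add('    </listOfSpecies>')
  }
  if (nrow(model$reactions)) {
    add('    <listOfParameters>')
    for (i in seq_len(nrow(model$reactions))) {
      rid <- model$reactions$id[i]
      add('      <parameter id="lb_', esc(rid), '" value="',
          fmt(model$reactions$lb[i]), '" constant="true"/>')
      add('      <parameter id="ub_', esc(rid), '" value="',
          fmt(model$reactions$ub[i]), '" constant="true"/>')
    }
    add('    </listOfParameters>')
    add('    <listOfReactions>')
    for (i in seq_len(nrow(model$reactions))) {
      rid <- model$reactions$id[i]
      col <- model$S[, i]
      subs <- which(col < 0); prods <- which(col > 0)
      add('      <reaction id="', esc(rid), '" name="',
          esc(model$reactions$name[i]), '" reversible="',
          tolower(model$reactions$lb[i] < 0), '" fast="false" ',
          'fbc:lowerFluxBound="lb_', esc(rid),
          '" fbc:upperFluxBound="ub_', esc(rid), '">')
      add('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      if (model$reactions$membrane_spanning[i])
        add('          <p>MEMBRANE_SPANNING: true</p>')
      add('          <p>EXCHANGE_REACTION: ',
          tolower(model$reactions$is_exchange[i]), '</p>')
      add('        </body></notes>')
      if (length(subs)) {
        add('        <listOfReactants>')
        for (s in subs)
          add('          <speciesReference species="', esc(rownames(model$S)[s]),
              '" stoichiometry="', fmt(-col[s]), '" constant="true"/>')
        add('        </listOfReactants>')
      }
      if (length(prods)) {
        add('        <listOfProducts>')
        for (s in prods)
          add('          <speciesReference species="', esc(rownames(model$S)[s]),
              '" stoichiometry="', fmt(col[s]), '" constant="true"/>')
        add('        </listOfProducts>')
      }
      g <- model$reactions$gpr[i]
      if (nzchar(trimws(g))) {
        add('        <fbc:geneProductAssociation>')
        add(gpr_to_fbc(gpr_parse(g), indent = "          "))
        add('        </fbc:geneProductAssociation>')
      }
      add('      </reaction>')
    }
    add('    </listOfReactions>')
  }
  if (!is.na(model$objective)) {
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    add('          <fbc:fluxObjective fbc:reaction="', esc(model$objective),
        '" fbc:coefficient="1"/>')
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes)
      add('      <fbc:geneProduct fbc:id="G_', esc(g), '" fbc:label="',
          esc(g), '"/>')
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(L), con, sep = "\n")
  invisible(path)
}

gpr_to_fbc <- function(ast, indent = "") {
  if (ast$op == "gene")
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="G_',
                  ast$gene, '"/>'))
  tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(ast$args, gpr_to_fbc, character(1),
                  indent = paste0(indent, "  "))
  paste0(indent, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", indent, "</", tag, ">")
}

fbc_to_gpr <- function(node, gene_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    attrs <- xml2::xml_attrs(node)
    gid <- chr_attr(attrs, "geneProduct", "fbc:geneProduct")
    lab <- gene_labels[[gid]]
    return(if (!is.null(lab)) lab else sub("^G_", "", gid))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_gpr, character(1), gene_labels = gene_labels)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read an SBML model (Level 3 + fbc or Level 2 COBRA conventions)
#'
#' Bounds are taken from fbc parameter references when present, else from
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, else from the
#' `reversible` attribute (-1000/1000 or 0/1000).  GPRs come from
#' `fbc:geneProductAssociation` trees or `GENE_ASSOCIATION:` notes.  Species
#' categories are inferred from SBO terms (`SBO:0000409` pseudo-metabolite,
#' `SBO:0000252` enzyme species, anything else a metabolite).  Species with
#' `boundaryCondition="true"` are dropped from the stoichiometry (they are
#' unbalanced medium species).
#'
#' @param path SBML file path.
#' @param strict_objective error when no objective can be found (default);
#'   with `FALSE` the model is returned with an unset objective.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, strict_objective = TRUE) {
  doc <- xml2::read_xml(path)   # malformed XML raises an error naming the line
  find_all <- function(node, name)
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  find_first <- function(node, name)
    xml2::xml_find_first(node, paste0(".//*[local-name()='", name, "']"))
  modnode <- find_first(doc, "model")
  if (inherits(modnode, "xml_missing")) stop("no <model> element in ", path)
  mattrs <- xml2::xml_attrs(modnode)
  mid <- chr_attr(mattrs, "id"); if (is.na(mid)) mid <- "model"

  comps <- find_all(modnode, "compartment")
  cids <- vapply(comps, function(x) chr_attr(xml2::xml_attrs(x), "id"),
                 character(1))
  cnames <- vapply(comps, function(x) {
    a <- xml2::xml_attrs(x); v <- chr_attr(a, "name")
    if (is.na(v)) chr_attr(a, "id") else v
  }, character(1))
  if (!length(cids)) { cids <- "default"; cnames <- "default" }
  model <- metabolic_model(mid, compartments = stats::setNames(cnames, cids))

  # global parameters (fbc bound references)
  params <- c()
  for (p in find_all(modnode, "parameter")) {
    a <- xml2::xml_attrs(p)
    pid <- chr_attr(a, "id")
    if (!is.na(pid)) params[pid] <- num_attr(a, "value")
  }

  boundary <- character()
  splist <- find_first(modnode, "listOfSpecies")
  if (!inherits(splist, "xml_missing")) {
    for (sp in xml2::xml_children(splist)) {
      a <- xml2::xml_attrs(sp)
      sid <- chr_attr(a, "id")
      if (identical(chr_attr(a, "boundaryCondition"), "true")) {
        boundary <- c(boundary, sid); next
      }
      comp <- chr_attr(a, "compartment")
      if (is.na(comp) || !comp %in% model$compartments$id)
        stop("species '", sid, "' placed in undeclared compartment '",
             comp, "'")
      sbo <- chr_attr(a, "sboTerm")
      nm <- chr_attr(a, "name"); if (is.na(nm)) nm <- sid
      model <- add_species(model, sid, nm, comp,
                           category = category_from_sbo(sbo),
                           sbo = if (is.na(sbo)) NA_character_ else sbo)
    }
  }

  # gene product labels
  gene_labels <- list()
  for (gp in find_all(modnode, "geneProduct")) {
    a <- xml2::xml_attrs(gp)
    gid <- chr_attr(a, "id", "fbc:id")
    lab <- chr_attr(a, "label", "fbc:label")
    if (!is.na(gid)) gene_labels[[gid]] <- if (is.na(lab)) sub("^G_", "", gid) else lab
  }

  objective <- NA_character_
  fo <- find_first(modnode, "fluxObjective")
  if (!inherits(fo, "xml_missing"))
    objective <- chr_attr(xml2::xml_attrs(fo), "reaction", "fbc:reaction")

  rxlist <- find_first(modnode, "listOfReactions")
  if (!inherits(rxlist, "xml_missing")) {
    for (rx in xml2::xml_children(rxlist)) {
      if (xml2::xml_name(rx) != "reaction") next
      a <- xml2::xml_attrs(rx)
      rid <- chr_attr(a, "id")
      nm <- chr_attr(a, "name"); if (is.na(nm)) nm <- rid
      stoich <- c()
      for (side in c("listOfReactants", "listOfProducts")) {
        ln <- xml2::xml_find_first(rx, paste0("./*[local-name()='", side, "']"))
        if (inherits(ln, "xml_missing")) next
        sgn <- if (side == "listOfReactants") -1 else 1
        for (sr in xml2::xml_children(ln)) {
          sa <- xml2::xml_attrs(sr)
          sid <- chr_attr(sa, "species")
          if (sid %in% boundary) next
          st <- num_attr(sa, "stoichiometry"); if (is.na(st)) st <- 1
          stoich[sid] <- (if (is.null(stoich[sid]) || is.na(stoich[sid])) 0
                          else stoich[sid]) + sgn * st
        }
      }
      stoich <- stoich[stoich != 0]
      # bounds: fbc refs, kinetic-law parameters, then reversibility default
      lb <- ub <- NA_real_
      lbref <- chr_attr(a, "lowerFluxBound", "fbc:lowerFluxBound")
      ubref <- chr_attr(a, "upperFluxBound", "fbc:upperFluxBound")
      if (!is.na(lbref) && lbref %in% names(params)) lb <- params[[lbref]]
      if (!is.na(ubref) && ubref %in% names(params)) ub <- params[[ubref]]
      obj_coef <- 0
      kl <- xml2::xml_find_first(rx, "./*[local-name()='kineticLaw']")
      if (!inherits(kl, "xml_missing")) {
        for (p in find_all(kl, "parameter")) {
          pa <- xml2::xml_attrs(p)
          pid <- chr_attr(pa, "id")
          val <- num_attr(pa, "value")
          if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- val
          if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- val
          if (identical(pid, "OBJECTIVE_COEFFICIENT") && !is.na(val) && val != 0)
            obj_coef <- val
        }
      }
      rev <- identical(chr_attr(a, "reversible"), "true")
      if (is.na(lb)) lb <- if (rev) -1000 else 0
      if (is.na(ub)) ub <- 1000
      # GPR: fbc association or notes
      gpr <- ""
      gpa <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
      if (!inherits(gpa, "xml_missing")) {
        kids <- xml2::xml_children(gpa)
        if (length(kids)) gpr <- fbc_to_gpr(kids[[1]], gene_labels)
      }
      notes_txt <- ""
      nt <- xml2::xml_find_first(rx, "./*[local-name()='notes']")
      if (!inherits(nt, "xml_missing"))
        notes_txt <- paste(xml2::xml_text(find_all(nt, "p")), collapse = "\n")
      if (!nzchar(gpr)) {
        mg <- regmatches(notes_txt,
                         regexpr("GENE_ASSOCIATION:[^\n]*", notes_txt))
        if (length(mg)) gpr <- trimws(sub("GENE_ASSOCIATION:", "", mg))
      }
      membrane <- grepl("MEMBRANE_SPANNING: true", notes_txt, fixed = TRUE)
      exch <- if (grepl("EXCHANGE_REACTION:", notes_txt, fixed = TRUE))
        grepl("EXCHANGE_REACTION: true", notes_txt, fixed = TRUE)
      else length(stoich) == 1L
      model <- add_reaction(model, rid, stoich, lb = lb, ub = ub, gpr = gpr,
                            name = nm, is_exchange = exch,
                            membrane_spanning = membrane)
      if (is.na(objective) && obj_coef != 0) objective <- rid
    }
  }
  if (!is.na(objective)) {
    model <- set_objective(model, objective)
  } else if (strict_objective && nrow(model$reactions) > 0) {
    stop("no objective reaction declared in ", path,
         "; set one with set_objective() after reading with ",
         "strict_objective = FALSE")
  }
  model
}
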