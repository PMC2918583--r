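#' @keywords internal
parse_side <- function(side, line_no) {
  terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
  # a dangling "+" (separated by whitespace) marks an empty component;
  # ion names like NAD+ keep their plus sign because it is not free-standing
  if (length(terms) == 0 || any(terms == "") ||
      any(grepl("(^|\\s)\\+(\\s|$)", terms))) {
    stop("malformed equation side at line ", line_no, call. = FALSE)
  }
  coefs <- numeric(length(terms))
  mets <- character(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i], regexec("^([0-9]+)\\s+(.*)$", terms[i]))[[1]]
    if (length(m) == 3) {
      coefs[i] <- as.numeric(m[2]); mets[i] <- m[3]
    } else {
      coefs[i] <- 1; mets[i] <- terms[i]
    }
  }
  stats::setNames(coefs, mets)
}

#' @keywords internal
parse_equation <- function(eq, line_no = NA) {
  if (grepl(" => ", eq, fixed = TRUE)) {
    sides <- strsplit(eq, " => ", fixed = TRUE)[[1]]
    rev <- FALSE
  } else if (grepl(" = ", eq, fixed = TRUE)) {
    sides <- strsplit(eq, " = ", fixed = TRUE)[[1]]
    rev <- TRUE
  } else {
    stop("equation without ' = ' or ' => ' at line ", line_no, call. = FALSE)
  }
  if (length(sides) != 2) {
    stop("equation with multiple arrows at line ", line_no, call. = FALSE)
  }
  list(substrates = parse_side(sides[1], line_no),
       products = parse_side(sides[2], line_no), reversible = rev)
}

#' @keywords internal
equation_string <- function(rxn) {
  fmt <- function(df) {
    paste(ifelse(df$coef == 1, df$metabolite,
                 paste(df$coef, df$metabolite)), collapse = " + ")
  }
  paste(fmt(rxn$substrates), if (rxn$reversible) "=" else "=>",
        fmt(rxn$products))
}

#' @keywords internal
read_tsv <- function(path, cols) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(basename(path), " lacks column(s): ", paste(missing, collapse = ","),
         call. = FALSE)
  }
  df
}

#' Read a network from reaction and link tables
#'
#' The reaction table is a TSV with columns `id`, `equation` (KEGG-style:
#' `"A + 2 B = C"` is reversible, `" => "` irreversible, coefficients as
#' leading integers), `pathways` (comma-joined), `ec`. The link table has
#' columns `protein`, `reaction` and optionally `active`. Metabolites are
#' auto-registered from the equations; proteins mentioned only in the link
#' table start unannotated (`{U}`).
#'
#' @param reaction_path,link_path TSV file paths.
#' @return A `metnet` object passing [validate_network()].
#' @export
read_network <- function(reaction_path, link_path = NULL) {
  rt <- read_tsv(reaction_path, c("id", "equation", "pathways", "ec"))
  rxns <- list()
  for (i in seq_len(nrow(rt))) {
    eq <- parse_equation(rt$equation[i], line_no = i + 1)
    rxns[[rt$id[i]]] <- reaction(
      rt$id[i], eq$substrates, eq$products, eq$reversible,
      pathways = setdiff(strsplit(rt$pathways[i], ",")[[1]], ""),
      ec = rt$ec[i])
  }
  links <- NULL
  prots <- list()
  if (!is.null(link_path)) {
    lt <- read_tsv(link_path, c("protein", "reaction"))
    links <- data.frame(protein = lt$protein, reaction = lt$reaction,
                        active = if (is.null(lt$active)) TRUE else
                          lt$active %in% c("TRUE", "true", "1"),
                        stringsAsFactors = FALSE)
    for (p in unique(links$protein)) prots[[p]] <- protein(p)
  }
  new_network(rxns, prots, links)
}

#' Read a protein-term association table
#'
#' TSV with columns `protein` and `term` (one annotation per row; `#`
#' comment lines ignored).
#' @param path File path.
#' @return Data frame (`protein`, `term`).
#' @export
read_association_table <- function(path) {
  read_tsv(path, c("protein", "term"))[, c("protein", "term")]
}

#' Read a keyword-location table
#'
#' TSV with columns `protein` and `keyword`. Keywords are resolved to
#' compartment codes through `keyword_map`; unknown keywords are dropped
#' with a warning. The default map covers the six organelle locations
#' shared between keyword vocabularies and the ontology targets.
#'
#' @param path File path.
#' @param keyword_map Named character vector keyword -> compartment code.
#' @return Data frame (`protein`, `compartment`).
#' @export
read_keyword_table <- function(path, keyword_map = default_keyword_map()) {
  df <- read_tsv(path, c("protein", "keyword"))
  kw <- tolower(df$keyword)
  known <- kw %in% names(keyword_map)
  if (any(!known)) {
    warning("dropping unknown location keyword(s): ",
            paste(unique(df$keyword[!known]), collapse = ", "),
            call. = FALSE)
  }
  data.frame(protein = df$protein[known],
             compartment = unname(keyword_map[kw[known]]),
             stringsAsFactors = FALSE)
}

#' Default keyword-to-compartment map
#'
#' The six organelle locations present in both the keyword vocabulary and
#' the ontology target set. Compartment codes are also accepted verbatim.
#' @return Named character vector.
#' @export
default_keyword_map <- function() {
  c("nucleus" = "N", "endoplasmic reticulum" = "ER",
    "golgi apparatus" = "GA", "peroxisome" = "X", "lysosome" = "L",
    "mitochondrion" = "M",
    "n" = "N", "er" = "ER", "ga" = "GA", "x" = "X", "l" = "L", "m" = "M")
}

#' Read a currency-metabolite list
#' @param path Text file, one metabolite id per line, `#` comments allowed.
#' @return Character vector.
#' @export
read_currency_set <- function(path) {
  x <- trimws(readLines(path))
  x[!grepl("^#", x) & x != ""]
}

#' Read a reference transport table
#'
#' TSV with columns `metabolite`, `from`, `to`, `score` (0-3 or
#' `annotation`), `proteins` (comma-joined or empty), `reversible`.
#' @param path File path.
#' @return Data frame in the layout [import_reference_transports()] expects.
#' @export
read_reference_transports <- function(path) {
  df <- read_tsv(path, c("metabolite", "from", "to", "score"))
  df$proteins <- if (is.null(df$proteins)) "" else df$proteins
  df$reversible <- if (is.null(df$reversible)) TRUE else
    df$reversible %in% c("TRUE", "true", "1")
  df
}

#' Read a curation-edit table
#'
#' TSV with columns `order`, `kind`, `reaction`, `protein`, `compartments`,
#' `citation`; see [apply_edits()].
#' @param path File path.
#' @return Data frame of edits, `order` as integer.
#' @export
read_curation_edits <- function(path) {
  df <- read_tsv(path, c("order", "kind", "reaction"))
  df$order <- as.integer(df$order)
  for (col in c("protein", "compartments", "citation")) {
    if (is.null(df[[col]])) df[[col]] <- ""
  }
  df
}

#' Write the network tables of a `metnet` object
#'
#' Emits `reactions.tsv` (id, equation, pathways, ec), `locations.tsv`
#' (reaction, compartment, provenance), `links.tsv` (protein, reaction,
#' active), `proteins.tsv` (protein, compartment, source),
#' `metabolites.tsv` and `transports.tsv`.
#'
#' @param net A `metnet` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_network_tables <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  rids <- sort(names(net$reactions))
  rx <- data.frame(
    id = rids,
    equation = vapply(rids, function(r) equation_string(net$reactions[[r]]), ""),
    pathways = vapply(rids, function(r) {
      paste(sort(net$reactions[[r]]$pathways), collapse = ",")
    }, ""),
    ec = vapply(rids, function(r) net$reactions[[r]]$ec, ""),
    stringsAsFactors = FALSE)
  loc_rows <- Filter(Negate(is.null), lapply(rids, function(r) {
    l <- net$reactions[[r]]$locations
    if (nrow(l) == 0) return(NULL)
    cbind(reaction = r, l[order(l$compartment), , drop = FALSE])
  }))
  locs <- if (length(loc_rows) > 0) do.call(rbind, loc_rows) else
    data.frame(reaction = character(), compartment = character(),
               provenance = character(), stringsAsFactors = FALSE)
  pids <- sort(names(net$proteins))
  pl <- do.call(rbind, lapply(pids, function(p) {
    l <- net$proteins[[p]]$locations
    cbind(protein = p, l[order(l$compartment, l$source), , drop = FALSE])
  }))
  if (is.null(pl)) {
    pl <- data.frame(protein = character(), compartment = character(),
                     source = character(), stringsAsFactors = FALSE)
  }
  lk <- net$links[order(net$links$protein, net$links$reaction), , drop = FALSE]
  trs <- do.call(rbind, lapply(net$transports, function(tr) {
    data.frame(id = tr$id, metabolite = tr$metabolite, from = tr$from,
               to = tr$to, reversible = tr$reversible, source = tr$source,
               proteins = paste(tr$proteins, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(trs)) {
    trs <- data.frame(id = character(), metabolite = character(),
                      from = character(), to = character(),
                      reversible = logical(), source = character(),
                      proteins = character(), stringsAsFactors = FALSE)
  }
  trs <- trs[order(trs$id), , drop = FALSE]
  paths <- c(w(rx, "reactions.tsv"), w(locs, "locations.tsv"),
             w(lk, "links.tsv"), w(pl, "proteins.tsv"),
             w(net$metabolites[order(net$metabolites$id), , drop = FALSE],
               "metabolites.tsv"),
             w(trs, "transports.tsv"))
  invisible(paths)
}

#' Export a pathway graph in DOT format
#'
#' @param graph A [build_pathway_graph()] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dot <- function(graph, path) {
  lines <- c(sprintf("graph \"%s_%s\" {", graph$pathway, graph$compartment),
             sprintf("  \"%s\";", graph$nodes))
  for (i in seq_len(nrow(graph$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                              graph$edges$from[i], graph$edges$to[i],
                              graph$edges$metabolites[i]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' @keywords internal
sbml_suffix <- function(code) {
  c(E = "_e", U = "_u", N = "_n", C = "_c", ER = "_er", GA = "_ga",
    X = "_x", L = "_l", M = "_m")[[code]]
}

#' @keywords internal
sbml_sanitize <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("M_", x), x)
}

#' Export a compartmentalized network as SBML Level 3
#'
#' Each located reaction is instantiated once per compartment it carries;
#' species ids are compartment-suffixed (`_e`, `_n`, `_c`, `_er`, `_ga`,
#' `_x`, `_l`, `_m`, following the usual genome-scale-model convention),
#' and transports appear as distinct reactions spanning two compartments.
#'
#' @param net A `metnet` object (ideally after transport addition; any
#'   remaining `U` locations are exported into an explicit `u`
#'   compartment).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "compartnet_model")
  used <- sort(unique(c(
    unlist(lapply(net$reactions, function(r) r$locations$compartment)),
    unlist(lapply(net$transports, function(tr) c(tr$from, tr$to))))))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cc in used) {
    xml2::xml_add_child(lc, "compartment",
                        id = sub("^_", "", sbml_suffix(cc)),
                        name = compartments()$name[compartments()$code == cc],
                        constant = "true")
  }
  species <- character()
  specie_id <- function(m, cc) paste0(sbml_sanitize(m), sbml_suffix(cc))
  collect <- function(m, cc) {
    sid <- specie_id(m, cc)
    if (!(sid %in% names(species))) {
      species[[sid]] <<- sub("^_", "", sbml_suffix(cc))
    }
    sid
  }
  rxn_entries <- list()
  for (r in net$reactions) {
    for (cc in r$locations$compartment) {
      subs <- vapply(seq_len(nrow(r$substrates)), function(i) {
        collect(r$substrates$metabolite[i], cc)
      }, "")
      prods <- vapply(seq_len(nrow(r$products)), function(i) {
        collect(r$products$metabolite[i], cc)
      }, "")
      rxn_entries[[length(rxn_entries) + 1]] <- list(
        id = paste0("R_", sbml_sanitize(r$id), sbml_suffix(cc)),
        reversible = r$reversible,
        subs = stats::setNames(r$substrates$coef, subs),
        prods = stats::setNames(r$products$coef, prods))
    }
  }
  for (tr in net$transports) {
    rxn_entries[[length(rxn_entries) + 1]] <- list(
      id = paste0("R_", sbml_sanitize(tr$id)),
      reversible = tr$reversible,
      subs = stats::setNames(1, collect(tr$metabolite, tr$from)),
      prods = stats::setNames(1, collect(tr$metabolite, tr$to)))
  }
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (sid in sort(names(species))) {
    xml2::xml_add_child(ls, "species", id = sid,
                        compartment = species[[sid]],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (e in rxn_entries[order(vapply(rxn_entries, `[[`, "", "id"))]) {
    rn <- xml2::xml_add_child(lr, "reaction", id = e$id,
                              reversible = tolower(as.character(e$reversible)),
                              fast = "false")
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in names(e$subs)) {
      xml2::xml_add_child(lre, "speciesReference", species = s,
                          stoichiometry = as.character(e$subs[[s]]),
                          constant = "true")
    }
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    for (s in names(e$prods)) {
      xml2::xml_add_child(lpr, "speciesReference", species = s,
                          stoichiometry = as.character(e$prods[[s]]),
                          constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write an ontology in OBO format
#'
#' @param ontology An `ontology` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(ontology, path) {
  lines <- "format-version: 1.2"
  for (t in ontology) {
    lines <- c(lines, "", "[Term]", paste0("id: ", t$id),
               paste0("name: ", t$name))
    if (!is.na(t$namespace)) {
      lines <- c(lines, paste0("namespace: ", t$namespace))
    }
    for (i in seq_len(nrow(t$parents))) {
      lines <- c(lines, if (t$parents$relation[i] == "is_a") {
        paste0("is_a: ", t$parents$parent[i])
      } else {
        paste0("relationship: part_of ", t$parents$parent[i])
      })
    }
    if (t$obsolete) lines <- c(lines, "is_obsolete: true")
  }
  writeLines(lines, path)
  invisible(path)
}
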