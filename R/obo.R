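#' Read a cellular-component ontology from an OBO file
#'
#' Minimal reader for the OBO 1.2/1.4 flat-file dialect. Only `[Term]`
#' stanzas are consumed; the tags used are `id`, `name`, `namespace`,
#' `is_a`, `relationship: part_of`, and `is_obsolete`. All other stanzas,
#' tags and relationship types (e.g. `regulates`, `occurs_in`) are ignored:
#' location backtracking ascends `is_a` and `part_of` edges only, because
#' those are the relations along which membership in a compartment is
#' inherited (a membrane is part of its organelle).
#'
#' @param path Path to an OBO file, or a character vector of lines.
#' @param namespace If non-`NULL`, keep only terms in this namespace (terms
#'   lacking a namespace tag are kept). Default `"cellular_component"`;
#'   use `NULL` for synthetic mini-ontologies.
#' @return An `ontology` object: a named list of terms, each a list with
#'   `id`, `name`, `parents` (data frame `parent`, `relation`) and
#'   `obsolete`.
#' @export
read_obo <- function(path, namespace = "cellular_component") {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- unname(lines)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id)) stop("OBO [Term] stanza without id", call. = FALSE)
      terms[[cur$id]] <<- cur
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(sub("!.*$", "", lines[i]))
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = "", namespace = NA_character_,
                    parents = data.frame(parent = character(),
                                         relation = character(),
                                         stringsAsFactors = FALSE),
                    obsolete = FALSE)
      }
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed OBO line ", i, ": ", lines[i],
                             call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") {
      cur$parents <- rbind(cur$parents,
                           data.frame(parent = strsplit(val, "\\s")[[1]][1],
                                      relation = "is_a",
                                      stringsAsFactors = FALSE))
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$parents <- rbind(cur$parents,
                             data.frame(parent = parts[2],
                                        relation = "part_of",
                                        stringsAsFactors = FALSE))
      }
    }
  }
  flush()
  if (!is.null(namespace)) {
    keep <- vapply(terms, function(t) {
      is.na(t$namespace) || t$namespace == namespace
    }, logical(1))
    terms <- terms[keep]
  }
  structure(terms, class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  n_obs <- sum(vapply(x, `[[`, logical(1), "obsolete"))
  cat(sprintf("<ontology> %d terms (%d obsolete)\n", length(x), n_obs))
  invisible(x)
}

#' Backtrack an ontology term to the target compartments
#'
#' Ascends `is_a` and `part_of` edges from the term (the term itself counts
#' as reachable) and returns every target compartment encountered. Obsolete
#' terms are skipped: they neither match a target nor pass traversal
#' through. If no target is reachable the fallback `"U"` is returned; if at
#' least one target is reachable, only-above-target ancestors contribute
#' nothing and `U` is not added (U is a fallback, not a location).
#'
#' @param term_id Term id to start from.
#' @param ontology An [read_obo()] ontology.
#' @param target_map Named character vector mapping term ids to compartment
#'   codes; defaults to [default_target_map()].
#' @return Character vector of compartment codes (sorted), or `"U"`.
#' @export
backtrack_term <- function(term_id, ontology, target_map = default_target_map()) {
  if (is.null(ontology[[term_id]])) {
    stop("unknown ontology term: ", term_id, call. = FALSE)
  }
  seen <- character()
  queue <- term_id
  hits <- character()
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    node <- ontology[[t]]
    if (is.null(node) || isTRUE(node$obsolete)) next
    if (t %in% names(target_map)) hits <- c(hits, target_map[[t]])
    queue <- c(queue, node$parents$parent)
  }
  hits <- sort(unique(hits))
  if (length(hits) == 0) "U" else hits
}

#' Resolve one protein's location assignment
#'
#' Merges ontology-derived and keyword-derived compartments. The union of
#' both sources is kept (a protein reported in different locations by the
#' two resources is assigned to all of them); `U` is dropped as soon as any
#' real compartment is present from either source, and `{U}` is the result
#' only when both sources resolve to nothing.
#'
#' @param term_ids Character vector of ontology term ids annotated to the
#'   protein (may be empty).
#' @param keyword_comps Character vector of compartment codes from the
#'   keyword source (may be empty).
#' @param ontology,target_map Passed to [backtrack_term()].
#' @return Data frame (`compartment`, `source`) with source `GO` or
#'   `keyword`; `{U}` rows carry source `GO`.
#' @export
localize_protein <- function(term_ids, keyword_comps, ontology,
                             target_map = default_target_map()) {
  go <- character()
  for (t in term_ids) go <- c(go, backtrack_term(t, ontology, target_map))
  go <- sort(unique(go))
  kw <- sort(unique(as.character(keyword_comps)))
  check_compartment(kw)
  real <- union(setdiff(go, "U"), setdiff(kw, "U"))
  if (length(real) == 0) {
    return(data.frame(compartment = "U", source = "GO",
                      stringsAsFactors = FALSE))
  }
  go_real <- setdiff(go, "U")
  kw_real <- setdiff(kw, "U")
  rows <- rbind(
    data.frame(compartment = go_real, source = rep("GO", length(go_real)),
               stringsAsFactors = FALSE),
    data.frame(compartment = kw_real,
               source = rep("keyword", length(kw_real)),
               stringsAsFactors = FALSE))
  rows[order(rows$compartment, rows$source), , drop = FALSE]
}

#' Localize every protein in the annotation tables
#'
#' @param assoc Data frame (`protein`, `term`): one ontology annotation per
#'   row. Duplicate rows are merged.
#' @param keywords Data frame (`protein`, `compartment`): keyword-derived
#'   locations already resolved to compartment codes by the reader.
#' @param ontology,target_map Passed to [backtrack_term()].
#' @return List with `assignments` (named list of per-protein location data
#'   frames) and `summary` (data frame `compartment`, `n`): a protein is
#'   counted once in every compartment it holds, so multi-location proteins
#'   appear in several rows.
#' @export
localize_proteins <- function(assoc, keywords, ontology,
                              target_map = default_target_map()) {
  ids <- sort(unique(c(assoc$protein, keywords$protein)))
  assignments <- list()
  for (pid in ids) {
    terms <- unique(assoc$term[assoc$protein == pid])
    kw <- unique(keywords$compartment[keywords$protein == pid])
    assignments[[pid]] <- localize_protein(terms, kw, ontology, target_map)
  }
  all_codes <- unlist(lapply(assignments, function(a) unique(a$compartment)))
  tab <- table(factor(all_codes, levels = compartment_codes()))
  summary <- data.frame(compartment = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(assignments = assignments, summary = summary)
}

#' Attach protein location assignments to a network
#'
#' @param net A `metnet` object.
#' @param assignments Named list as returned by [localize_proteins()];
#'   proteins absent from the list keep their current locations.
#' @return The updated network.
#' @export
set_protein_locations <- function(net, assignments) {
  for (pid in names(assignments)) {
    if (!is.null(net$proteins[[pid]])) {
      net$proteins[[pid]]$locations <- assignments[[pid]]
    }
  }
  net
}
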