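#' @keywords internal
loc_df <- function(compartment = character(), provenance = character()) {
  provenance <- rep(as.character(provenance),
                    length.out = length(compartment))
  data.frame(compartment = as.character(compartment),
             provenance = as.character(provenance),
             stringsAsFactors = FALSE)
}

#' @keywords internal
side_df <- function(x) {
  # x: named numeric vector (names = metabolite ids) or a ready data frame
  if (is.data.frame(x)) {
    stopifnot(all(c("metabolite", "coef") %in% names(x)))
    return(data.frame(metabolite = as.character(x$metabolite),
                      coef = as.numeric(x$coef), stringsAsFactors = FALSE))
  }
  data.frame(metabolite = names(x), coef = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id Reaction identifier.
#' @param substrates,products Named numeric vectors (names are metabolite ids,
#'   values are stoichiometric coefficients, which must be positive), or data
#'   frames with columns `metabolite` and `coef`. Stoichiometry is stored but
#'   the structural analyses are purely topological and use only the
#'   substrate/product roles.
#' @param reversible Logical.
#' @param pathways Character vector of pathway names the reaction belongs to.
#' @param ec EC number string, or `""`.
#' @param locations Optional data frame (`compartment`, `provenance`) of
#'   pre-assigned locations; usually left empty and filled by
#'   [assign_reaction_locations()].
#' @return A `reaction` object (list).
#' @export
reaction <- function(id, substrates, products, reversible = FALSE,
                     pathways = character(), ec = "",
                     locations = loc_df()) {
  structure(list(id = as.character(id),
                 substrates = side_df(substrates),
                 products = side_df(products),
                 reversible = isTRUE(reversible),
                 pathways = as.character(pathways),
                 ec = as.character(ec),
                 locations = locations),
            class = "metnet_reaction")
}

#' Construct a protein
#'
#' @param id Protein identifier.
#' @param locations Data frame (`compartment`, `source` in `GO`/`keyword`),
#'   or a character vector of compartment codes (source defaults to `GO`).
#'   A protein with no resolvable annotation has locations `{U}`.
#' @return A `protein` object (list).
#' @export
protein <- function(id, locations = character()) {
  if (!is.data.frame(locations)) {
    locations <- data.frame(compartment = as.character(locations),
                            source = rep("GO", length(locations)),
                            stringsAsFactors = FALSE)
  }
  if (nrow(locations) == 0) {
    locations <- data.frame(compartment = "U", source = "GO",
                            stringsAsFactors = FALSE)
  }
  structure(list(id = as.character(id), locations = locations),
            class = "metnet_protein")
}

#' Assemble a metabolic network
#'
#' The in-memory container every pipeline stage transforms. Metabolites are
#' auto-registered from reaction equations unless supplied explicitly. Links
#' between proteins and reactions carry an `active` flag: curation never
#' removes a link, it deactivates it, so an audit trail of deleted
#' protein-reaction relationships is always reportable.
#'
#' @param reactions List of [reaction()] objects.
#' @param proteins List of [protein()] objects.
#' @param links Data frame with columns `protein`, `reaction` and optionally
#'   `active` (defaults to `TRUE`).
#' @param metabolites Optional data frame (`id`, `name`).
#' @param transports List of transport reactions (normally empty at
#'   construction; see [import_reference_transports()]).
#' @return A `metnet` object.
#' @export
new_network <- function(reactions = list(), proteins = list(),
                        links = NULL, metabolites = NULL,
                        transports = list()) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  names(proteins) <- vapply(proteins, `[[`, "", "id")
  if (is.null(links)) {
    links <- data.frame(protein = character(), reaction = character(),
                        active = logical(), stringsAsFactors = FALSE)
  }
  if (is.null(links$active)) links$active <- TRUE
  links$protein <- as.character(links$protein)
  links$reaction <- as.character(links$reaction)
  if (is.null(metabolites)) {
    ids <- sort(unique(unlist(lapply(reactions, function(r) {
      c(r$substrates$metabolite, r$products$metabolite)
    }), use.names = FALSE)))
    metabolites <- data.frame(id = as.character(ids), name = as.character(ids),
                              stringsAsFactors = FALSE)
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 proteins = proteins, links = links, transports = transports),
            class = "metnet")
}

#' @export
print.metnet <- function(x, ...) {
  cat(sprintf(
    "<metnet> %d reactions, %d metabolites, %d proteins, %d links (%d active), %d transports\n",
    length(x$reactions), nrow(x$metabolites), length(x$proteins),
    nrow(x$links), sum(x$links$active), length(x$transports)))
  pw <- pathway_index(x)
  if (length(pw) > 0) {
    cat(sprintf("  pathways: %s\n", paste(names(pw), collapse = ", ")))
  }
  invisible(x)
}

#' Pathway index of a network
#'
#' @param net A `metnet` object.
#' @param exclude_isolated Drop the pathway literally named `"isolated"`,
#'   which is excluded from all structural analyses.
#' @return Named list mapping pathway name to a sorted character vector of
#'   reaction ids.
#' @export
pathway_index <- function(net, exclude_isolated = FALSE) {
  idx <- list()
  for (r in net$reactions) {
    for (p in r$pathways) idx[[p]] <- c(idx[[p]], r$id)
  }
  idx <- lapply(idx, function(v) sort(unique(v)))
  if (exclude_isolated) idx[["isolated"]] <- NULL
  idx[order(names(idx))]
}

#' @keywords internal
reaction_location_codes <- function(net, rid) {
  net$reactions[[rid]]$locations$compartment
}

#' @keywords internal
reaction_mets <- function(rxn, currency = character(), side = "both") {
  m <- switch(side,
              both = c(rxn$substrates$metabolite, rxn$products$metabolite),
              substrate = rxn$substrates$metabolite,
              product = rxn$products$metabolite)
  setdiff(unique(m), currency)
}

#' @keywords internal
active_links <- function(net) net$links[net$links$active, , drop = FALSE]

#' @keywords internal
reaction_proteins <- function(net, rid, active_only = TRUE) {
  l <- net$links
  if (active_only) l <- l[l$active, , drop = FALSE]
  sort(unique(l$protein[l$reaction == rid]))
}

#' @keywords internal
protein_reactions <- function(net, pid, active_only = TRUE) {
  l <- net$links
  if (active_only) l <- l[l$active, , drop = FALSE]
  sort(unique(l$reaction[l$protein == pid]))
}

#' @keywords internal
set_reaction_locations <- function(net, rid, codes, provenance) {
  net$reactions[[rid]]$locations <- loc_df(codes, provenance)
  net
}

#' Recompute a reaction's protein-derived locations
#'
#' Re-derives the location rows whose provenance is `protein` or
#' `default-uncertain` from the currently active protein-reaction links,
#' keeping rows that came from later pipeline stages (`gap-filled`,
#' `curated`, `cytosol-default`). Used after links are deactivated.
#' @keywords internal
recompute_reaction_locations <- function(net, rid) {
  kept <- net$reactions[[rid]]$locations
  kept <- kept[!(kept$provenance %in% c("protein", "default-uncertain")), ,
               drop = FALSE]
  pids <- reaction_proteins(net, rid)
  codes <- character()
  for (p in pids) codes <- c(codes, net$proteins[[p]]$locations$compartment)
  codes <- unique(codes)
  if (length(setdiff(codes, "U")) > 0) codes <- setdiff(codes, "U")
  fresh <- if (length(pids) == 0 || identical(codes, "U") || length(codes) == 0) {
    if (nrow(kept) > 0) loc_df() else loc_df("U", "default-uncertain")
  } else {
    loc_df(setdiff(codes, kept$compartment), "protein")
  }
  net$reactions[[rid]]$locations <- rbind(kept, fresh)
  if (nrow(net$reactions[[rid]]$locations) == 0) {
    net$reactions[[rid]]$locations <- loc_df("U", "default-uncertain")
  }
  net
}

#' Validate a network
#'
#' Reporting-only structural check: referential integrity of links and
#' equations, non-empty reaction sides, uniqueness of metabolite ids and
#' (protein, reaction) pairs, at most one row per compartment in any location
#' set, and known compartment codes. Returns a data frame of violations;
#' a clean network yields zero rows. Idempotent and side-effect free.
#'
#' @param net A `metnet` object.
#' @param require_locations Also flag reactions with an empty location set
#'   (an invariant only after the localization stage).
#' @return Data frame with columns `entity`, `rule`, `message`.
#' @export
validate_network <- function(net, require_locations = FALSE) {
  v <- list()
  flag <- function(entity, rule, message) {
    v[[length(v) + 1]] <<- data.frame(entity = entity, rule = rule,
                                      message = message,
                                      stringsAsFactors = FALSE)
  }
  met_ids <- net$metabolites$id
  if (anyDuplicated(met_ids)) {
    flag(paste(met_ids[duplicated(met_ids)], collapse = ","),
         "metabolite-id-unique", "duplicated metabolite id")
  }
  for (r in net$reactions) {
    if (nrow(r$substrates) == 0 || nrow(r$products) == 0) {
      flag(r$id, "reaction-sides-nonempty",
           "reaction must have substrates and products")
    }
    bad <- setdiff(c(r$substrates$metabolite, r$products$metabolite), met_ids)
    if (length(bad) > 0) {
      flag(r$id, "metabolite-resolves",
           paste("unknown metabolite:", paste(bad, collapse = ",")))
    }
    if (any(c(r$substrates$coef, r$products$coef) <= 0)) {
      flag(r$id, "stoichiometry-positive", "coefficients must be > 0")
    }
    if (anyDuplicated(r$locations$compartment)) {
      flag(r$id, "location-unique", "compartment repeated in location set")
    }
    unknown <- setdiff(r$locations$compartment, compartment_codes())
    if (length(unknown) > 0) {
      flag(r$id, "location-known",
           paste("unknown compartment:", paste(unknown, collapse = ",")))
    }
    if (require_locations && nrow(r$locations) == 0) {
      flag(r$id, "location-nonempty", "reaction has no location after localization")
    }
  }
  for (p in net$proteins) {
    if (nrow(p$locations) == 0) {
      flag(p$id, "protein-location-nonempty",
           "unannotated protein must hold {U}")
    }
    unknown <- setdiff(p$locations$compartment, compartment_codes())
    if (length(unknown) > 0) {
      flag(p$id, "location-known",
           paste("unknown compartment:", paste(unknown, collapse = ",")))
    }
  }
  l <- net$links
  bad_r <- setdiff(l$reaction, names(net$reactions))
  for (b in bad_r) flag(b, "link-reaction-resolves", "link to unknown reaction")
  bad_p <- setdiff(l$protein, names(net$proteins))
  for (b in bad_p) flag(b, "link-protein-resolves", "link to unknown protein")
  if (anyDuplicated(paste(l$protein, l$reaction))) {
    flag("links", "link-unique", "duplicated (protein, reaction) pair")
  }
  if (length(v) == 0) {
    return(data.frame(entity = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
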