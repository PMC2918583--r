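#' Default currency-metabolite set
#'
#' Ubiquitous cofactors and carriers excluded from reaction linking: using
#' them as connecting metabolites would join nearly every reaction pair and
#' inflate connectivity. The set is configurable; this default is the
#' canonical list used by connectivity analyses of metabolic networks.
#'
#' @return Character vector of metabolite ids.
#' @export
default_currency <- function() {
  c("ATP", "ADP", "AMP", "NAD+", "NADH", "NADP+", "NADPH", "FAD", "FADH2",
    "CoA", "H2O", "CO2", "O2", "NH3", "Orthophosphate", "Pyrophosphate", "H+")
}

#' @keywords internal
can_produce <- function(rxn, m) {
  m %in% rxn$products$metabolite ||
    (rxn$reversible && m %in% rxn$substrates$metabolite)
}

#' @keywords internal
can_consume <- function(rxn, m) {
  m %in% rxn$substrates$metabolite ||
    (rxn$reversible && m %in% rxn$products$metabolite)
}

#' Build a per-pathway, per-compartment reaction graph
#'
#' Nodes are the pathway's reactions whose location set contains the
#' compartment; an undirected edge joins two reactions when a shared main
#' (non-currency) metabolite can flow from one to the other — produced by
#' one and consumed by the other under at least one permitted direction,
#' reversible reactions permitting both. A co-occurrence variant (edge on
#' any shared main metabolite, regardless of role) is available for
#' sensitivity analysis.
#'
#' @param net A `metnet` object after reaction localization.
#' @param pathway Pathway name; must exist and must not be `"isolated"`.
#' @param compartment Compartment code, not `"U"`.
#' @param currency Character vector of currency metabolite ids.
#' @param edge_rule `"flow"` (default, producer/consumer-aware) or
#'   `"cooccurrence"`.
#' @return A `pathway_graph` object: list with `pathway`, `compartment`,
#'   `nodes`, `edges` (data frame `from`, `to`, `metabolites`),
#'   `components` (list of sorted node-id sets, ordered by smallest member)
#'   and the currency set used.
#' @export
build_pathway_graph <- function(net, pathway, compartment,
                                currency = default_currency(),
                                edge_rule = c("flow", "cooccurrence")) {
  edge_rule <- match.arg(edge_rule)
  check_compartment(compartment, allow_u = FALSE)
  idx <- pathway_index(net)
  if (is.null(idx[[pathway]])) stop("unknown pathway: ", pathway, call. = FALSE)
  nodes <- sort(Filter(function(r) {
    compartment %in% reaction_location_codes(net, r)
  }, idx[[pathway]]))
  edges <- list()
  if (length(nodes) > 1) {
    for (i in seq_along(nodes)) {
      for (j in seq_len(i - 1)) {
        r1 <- net$reactions[[nodes[j]]]; r2 <- net$reactions[[nodes[i]]]
        shared <- intersect(reaction_mets(r1, currency),
                            reaction_mets(r2, currency))
        linking <- if (edge_rule == "cooccurrence") shared else {
          Filter(function(m) {
            (can_produce(r1, m) && can_consume(r2, m)) ||
              (can_produce(r2, m) && can_consume(r1, m))
          }, shared)
        }
        if (length(linking) > 0) {
          edges[[length(edges) + 1]] <- data.frame(
            from = nodes[j], to = nodes[i],
            metabolites = paste(sort(linking), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               metabolites = character(), stringsAsFactors = FALSE)
  g <- structure(list(pathway = pathway, compartment = compartment,
                      nodes = nodes, edges = edges, currency = currency),
                 class = "pathway_graph")
  g$components <- graph_components(g)
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s @ %s: %d reactions, %d edges, %d components\n",
              x$pathway, x$compartment, length(x$nodes), nrow(x$edges),
              length(x$components)))
  invisible(x)
}

#' Connected components of a pathway graph
#'
#' @param graph A [build_pathway_graph()] object.
#' @return List of sorted character vectors partitioning the nodes, in
#'   canonical order (by smallest member id).
#' @export
graph_components <- function(graph) {
  if (length(graph$nodes) == 0) return(list())
  ig <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = graph$nodes)
  memb <- igraph::components(ig)$membership
  comps <- lapply(split(names(memb), memb), sort)
  comps <- unname(comps)
  comps[order(vapply(comps, `[`, "", 1))]
}

#' Main metabolites of one component
#'
#' @param net A `metnet` object.
#' @param graph A [build_pathway_graph()] object.
#' @param component One element of `graph$components` (or its index).
#' @return Sorted character vector of all non-currency metabolites
#'   appearing in any member reaction.
#' @export
component_metabolites <- function(net, graph, component) {
  if (is.numeric(component)) component <- graph$components[[component]]
  sort(unique(unlist(lapply(component, function(r) {
    reaction_mets(net$reactions[[r]], graph$currency)
  }), use.names = FALSE)))
}

#' @keywords internal
all_pathway_graphs <- function(net, currency, compartments = NULL,
                               edge_rule = "flow") {
  idx <- pathway_index(net, exclude_isolated = TRUE)
  if (is.null(compartments)) compartments <- compartment_codes(real_only = TRUE)
  out <- list()
  for (pw in names(idx)) {
    for (cc in compartments) {
      g <- build_pathway_graph(net, pw, cc, currency, edge_rule)
      if (length(g$nodes) > 0) out[[paste(pw, cc, sep = "\r")]] <- g
    }
  }
  out
}

#' Search a shortest cross-compartment route between two metabolites
#'
#' Finds a shortest (by reaction count) directed route in which each
#' metabolic step consumes the previous step's product within one
#' compartment, and transport reactions change compartment without changing
#' the metabolite. Currency metabolites cannot carry a step. Intended for
#' validating a compartmentalized network after transport addition: the
#' route shows in which compartment each conversion happens.
#'
#' @param net A `metnet` object (transports included).
#' @param from,to Length-2 character vectors `c(metabolite, compartment)`.
#'   Each endpoint metabolite must occur in a located reaction (or
#'   transport) in the stated compartment.
#' @param currency Currency metabolite ids (non-traversable carriers).
#' @return Data frame (`step`, `reaction`, `compartment`, `metabolite`)
#'   describing the route — `metabolite` is the carrier produced by the
#'   step — or `NULL` when the target is unreachable.
#' @export
find_path <- function(net, from, to, currency = default_currency()) {
  state <- function(m, cc) paste(m, cc, sep = "@")
  edges <- list()  # from-state, to-state, reaction, compartment
  add <- function(s1, s2, rid, cc) {
    edges[[length(edges) + 1]] <<- data.frame(from = s1, to = s2,
                                              reaction = rid, compartment = cc,
                                              stringsAsFactors = FALSE)
  }
  for (r in net$reactions) {
    subs <- setdiff(r$substrates$metabolite, currency)
    prods <- setdiff(r$products$metabolite, currency)
    for (cc in setdiff(r$locations$compartment, "U")) {
      for (a in subs) for (b in prods) {
        add(state(a, cc), state(b, cc), r$id, cc)
        if (r$reversible) add(state(b, cc), state(a, cc), r$id, cc)
      }
    }
  }
  for (tr in net$transports) {
    add(state(tr$metabolite, tr$from), state(tr$metabolite, tr$to),
        tr$id, tr$to)
    if (tr$reversible) {
      add(state(tr$metabolite, tr$to), state(tr$metabolite, tr$from),
          tr$id, tr$from)
    }
  }
  src <- state(from[1], from[2]); dst <- state(to[1], to[2])
  edf <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), reaction = character(),
               compartment = character(), stringsAsFactors = FALSE)
  verts <- sort(unique(c(edf$from, edf$to, src, dst)))
  for (ep in c(src, dst)) {
    mc <- strsplit(ep, "@", fixed = TRUE)[[1]]
    present <- any(edf$from == ep | edf$to == ep)
    if (!present) {
      stop("metabolite ", mc[1], " does not occur in compartment ", mc[2],
           call. = FALSE)
    }
  }
  ig <- igraph::graph_from_data_frame(edf, directed = TRUE,
                                      vertices = data.frame(name = verts))
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, src, dst, mode = "out", output = "epath"))
  ep <- sp$epath[[1]]
  if (length(ep) == 0) {
    if (src == dst) {
      return(data.frame(step = integer(), reaction = character(),
                        compartment = character(), metabolite = character(),
                        stringsAsFactors = FALSE))
    }
    return(NULL)
  }
  rows <- lapply(seq_along(ep), function(i) {
    e <- ep[i]
    head <- igraph::head_of(ig, e)$name
    mc <- strsplit(head, "@", fixed = TRUE)[[1]]
    data.frame(step = i,
               reaction = igraph::edge_attr(ig, "reaction", e),
               compartment = igraph::edge_attr(ig, "compartment", e),
               metabolite = mc[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
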