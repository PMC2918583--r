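#' Identify gaps in the compartmentalized network
#'
#' A gap is a missing reaction-location relationship, not a missing
#' reaction: for each pathway (excluding `"isolated"`) and each real
#' compartment, every pathway reaction *not* located in that compartment is
#' checked against the compartment's pathway graph — if the reaction's main
#' metabolites intersect the metabolite lists of two distinct connected
#' components, the reaction could bridge them and is recorded as a gap.
#' One record is emitted per bridged component pair, so a reaction joining
#' three components yields three records (but a single fill); a reaction
#' may be a gap in several compartments.
#'
#' @param net A `metnet` object after reaction localization.
#' @param currency Currency metabolite ids.
#' @param edge_rule Passed to [build_pathway_graph()].
#' @return Data frame, one row per gap record, sorted by (pathway,
#'   compartment, reaction): `reaction`, `pathway`, `compartment`,
#'   `component_a`, `component_b` (smallest member ids of the bridged
#'   components), `current_locations` (comma-joined), `action` (initially
#'   `""`), `citation`.
#' @export
identify_gaps <- function(net, currency = default_currency(),
                          edge_rule = "flow") {
  idx <- pathway_index(net, exclude_isolated = TRUE)
  recs <- list()
  for (pw in names(idx)) {
    for (cc in compartment_codes(real_only = TRUE)) {
      g <- build_pathway_graph(net, pw, cc, currency, edge_rule)
      if (length(g$components) < 2) next
      comp_mets <- lapply(seq_along(g$components), function(i) {
        component_metabolites(net, g, i)
      })
      outside <- setdiff(idx[[pw]], g$nodes)
      for (rid in outside) {
        mets <- reaction_mets(net$reactions[[rid]], currency)
        touching <- which(vapply(comp_mets, function(cm) {
          length(intersect(cm, mets)) > 0
        }, logical(1)))
        if (length(touching) < 2) next
        for (i in seq_along(touching)) {
          for (j in seq_len(i - 1)) {
            a <- g$components[[touching[j]]][1]
            b <- g$components[[touching[i]]][1]
            recs[[length(recs) + 1]] <- data.frame(
              reaction = rid, pathway = pw, compartment = cc,
              component_a = min(a, b), component_b = max(a, b),
              current_locations = paste(sort(reaction_location_codes(net, rid)),
                                        collapse = ","),
              action = "", citation = "", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(reaction = character(), pathway = character(),
               compartment = character(), component_a = character(),
               component_b = character(), current_locations = character(),
               action = character(), citation = character(),
               stringsAsFactors = FALSE)
  out[order(out$pathway, out$compartment, out$reaction,
            out$component_a, out$component_b), , drop = FALSE]
}

#' Fill identified gaps
#'
#' A gap reaction currently located only in `U` is assigned the target
#' compartment directly (`U` is a placeholder, not a location; the reaction
#' may accumulate several compartments from gaps in different locations).
#' A gap reaction that already has real locations is filled only when the
#' evidence table has a supporting row for (reaction, compartment); the
#' evidence row may also name new catalyzing proteins, whose links are
#' added. All fills of one reaction into one compartment are deduplicated
#' across component pairs and pathways.
#'
#' @param net A `metnet` object.
#' @param gaps Output of [identify_gaps()].
#' @param evidence Optional data frame (`reaction`, `compartment`,
#'   `proteins` — comma-joined protein ids or `""`, `citation`).
#' @return List with `network`, `gaps` (the input with `action` and
#'   `citation` filled: `auto-filled`, `evidence-filled` or `unfilled`) and
#'   `counts` (named integer vector per action, counting gap records).
#' @export
fill_gaps <- function(net, gaps, evidence = NULL) {
  if (is.null(evidence)) {
    evidence <- data.frame(reaction = character(), compartment = character(),
                           proteins = character(), citation = character(),
                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(evidence))) {
    if (is.null(net$reactions[[evidence$reaction[i]]])) {
      stop("gap evidence references unknown reaction: ", evidence$reaction[i],
           call. = FALSE)
    }
    prots <- setdiff(strsplit(evidence$proteins[i], ",")[[1]], "")
    bad <- setdiff(prots, names(net$proteins))
    if (length(bad) > 0) {
      stop("gap evidence references unknown protein: ",
           paste(bad, collapse = ","), call. = FALSE)
    }
  }
  gaps$action <- ""
  done <- character()  # "rid@cc" pairs already filled
  for (i in seq_len(nrow(gaps))) {
    rid <- gaps$reaction[i]; cc <- gaps$compartment[i]
    key <- paste(rid, cc, sep = "@")
    cur <- reaction_location_codes(net, rid)
    if (key %in% done) {
      gaps$action[i] <- if (cc %in% reaction_location_codes(net, rid))
        gaps$action[match(key, paste(gaps$reaction, gaps$compartment,
                                     sep = "@"))] else "unfilled"
      next
    }
    ev <- evidence[evidence$reaction == rid & evidence$compartment == cc, ,
                   drop = FALSE]
    # auto-fill eligibility is judged on the state recorded at detection
    # time, so one uncertain reaction can absorb gaps in several locations
    at_detect <- strsplit(gaps$current_locations[i], ",")[[1]]
    if (identical(at_detect, "U")) {
      locs <- net$reactions[[rid]]$locations
      locs <- locs[locs$compartment != "U", , drop = FALSE]
      net$reactions[[rid]]$locations <- rbind(locs, loc_df(cc, "gap-filled"))
      gaps$action[i] <- "auto-filled"
      done <- c(done, key)
    } else if (nrow(ev) > 0) {
      if (!(cc %in% cur)) {
        net$reactions[[rid]]$locations <-
          rbind(net$reactions[[rid]]$locations, loc_df(cc, "gap-filled"))
      }
      prots <- setdiff(strsplit(ev$proteins[1], ",")[[1]], "")
      for (p in prots) {
        if (!any(net$links$protein == p & net$links$reaction == rid)) {
          net$links <- rbind(net$links,
                             data.frame(protein = p, reaction = rid,
                                        active = TRUE, stringsAsFactors = FALSE))
        }
      }
      gaps$action[i] <- "evidence-filled"
      gaps$citation[i] <- ev$citation[1]
      done <- c(done, key)
    } else {
      gaps$action[i] <- "unfilled"
    }
  }
  counts <- table(factor(gaps$action,
                         levels = c("auto-filled", "evidence-filled",
                                    "unfilled")))
  list(network = net, gaps = gaps,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Identify isolated reaction-location relationships (IRLRs)
#'
#' An IRLR is a (reaction, compartment) pair where the reaction forms a
#' one-node connected component in the compartment-specific pathway graph.
#' A reaction can be isolated in one compartment and well connected in
#' another. By default a pair is reported only when the reaction is a
#' singleton in *every* pathway containing it for that compartment
#' (a reaction connected in any pathway context is functional there);
#' `scope = "any"` reports per-pathway singletons instead.
#'
#' @param net A `metnet` object (run after gap filling).
#' @param currency Currency metabolite ids.
#' @param scope `"all"` (default) or `"any"`; see above.
#' @param edge_rule Passed to [build_pathway_graph()].
#' @return Data frame sorted by (pathway, compartment, reaction):
#'   `reaction`, `pathway` (comma-joined pathways where it is singleton),
#'   `compartment`, `proteins` (active catalyzing proteins located in that
#'   compartment), `other_locations` (those proteins' other compartments),
#'   `other_reactions` (those proteins' other active reactions),
#'   `decision` (initially `""`), `citation`.
#' @export
identify_irlrs <- function(net, currency = default_currency(),
                           scope = c("all", "any"), edge_rule = "flow") {
  scope <- match.arg(scope)
  idx <- pathway_index(net, exclude_isolated = TRUE)
  # singleton status per (reaction, compartment) across pathways
  status <- list()  # key -> list(singleton = chr pathways, connected = chr)
  for (pw in names(idx)) {
    for (cc in compartment_codes(real_only = TRUE)) {
      g <- build_pathway_graph(net, pw, cc, currency, edge_rule)
      if (length(g$nodes) == 0) next
      singles <- unlist(Filter(function(comp) length(comp) == 1,
                               g$components), use.names = FALSE)
      for (rid in g$nodes) {
        key <- paste(rid, cc, sep = "@")
        st <- status[[key]]
        if (is.null(st)) st <- list(singleton = character(),
                                    connected = character())
        if (rid %in% singles) st$singleton <- c(st$singleton, pw)
        else st$connected <- c(st$connected, pw)
        status[[key]] <- st
      }
    }
  }
  recs <- list()
  for (key in names(status)) {
    st <- status[[key]]
    if (length(st$singleton) == 0) next
    if (scope == "all" && length(st$connected) > 0) next
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    rid <- parts[1]; cc <- parts[2]
    pids <- Filter(function(p) {
      cc %in% net$proteins[[p]]$locations$compartment
    }, reaction_proteins(net, rid))
    other_locs <- sort(unique(unlist(lapply(pids, function(p) {
      setdiff(net$proteins[[p]]$locations$compartment, cc)
    }), use.names = FALSE)))
    other_rxns <- sort(unique(unlist(lapply(pids, function(p) {
      setdiff(protein_reactions(net, p), rid)
    }), use.names = FALSE)))
    recs[[length(recs) + 1]] <- data.frame(
      reaction = rid, pathway = paste(sort(st$singleton), collapse = ","),
      compartment = cc, proteins = paste(pids, collapse = ","),
      other_locations = paste(other_locs, collapse = ","),
      other_reactions = paste(other_rxns, collapse = ","),
      decision = "", citation = "", stringsAsFactors = FALSE)
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(reaction = character(), pathway = character(),
               compartment = character(), proteins = character(),
               other_locations = character(), other_reactions = character(),
               decision = character(), citation = character(),
               stringsAsFactors = FALSE)
  out[order(out$pathway, out$compartment, out$reaction), , drop = FALSE]
}

#' Decide the fate of each IRLR
#'
#' Applies the decision rules in order; the first matching rule wins:
#' \enumerate{
#'   \item evidence row with verdict `keep` — the relationship stands
#'     (`keep-evidence`);
#'   \item evidence row with verdict `bad-link` — the named protein-reaction
#'     link was wrong: it is deactivated, the reaction's locations are
#'     recomputed (`remove-bad-link`);
#'   \item some catalyzing protein has that compartment as its *only*
#'     location and catalyzes no other reaction network-wide — removing the
#'     relationship would orphan the protein, so it is kept
#'     (`keep-unique-protein`);
#'   \item otherwise the compartment is deleted from the reaction's
#'     location set (`remove`): a multi-location protein may simply be
#'     inactive here, and a multi-reaction protein may act elsewhere.
#' }
#' Removal never leaves a reaction without locations: if it would, the
#' reaction reverts to `{U}` (logged in the record's decision as `remove`).
#'
#' @param net A `metnet` object.
#' @param irlrs Output of [identify_irlrs()].
#' @param evidence Optional data frame (`reaction`, `compartment`,
#'   `verdict` in `keep`/`bad-link`, `protein` — required for `bad-link`,
#'   `citation`).
#' @return List with `network`, `irlrs` (decisions and citations filled)
#'   and `counts` per decision.
#' @export
decide_irlrs <- function(net, irlrs, evidence = NULL) {
  if (is.null(evidence)) {
    evidence <- data.frame(reaction = character(), compartment = character(),
                           verdict = character(), protein = character(),
                           citation = character(), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(irlrs))) {
    rid <- irlrs$reaction[i]; cc <- irlrs$compartment[i]
    ev <- evidence[evidence$reaction == rid & evidence$compartment == cc, ,
                   drop = FALSE]
    if (nrow(ev) > 0 && length(unique(ev$verdict)) > 1) {
      stop("conflicting IRLR evidence for ", rid, " in ", cc, call. = FALSE)
    }
    if (nrow(ev) > 0 && ev$verdict[1] == "keep") {
      irlrs$decision[i] <- "keep-evidence"
      irlrs$citation[i] <- ev$citation[1]
      next
    }
    if (nrow(ev) > 0 && ev$verdict[1] == "bad-link") {
      pid <- ev$protein[1]
      sel <- net$links$protein == pid & net$links$reaction == rid
      if (!any(sel)) {
        stop("bad-link evidence names a missing link: ", pid, "-", rid,
             call. = FALSE)
      }
      net$links$active[sel] <- FALSE
      net <- recompute_reaction_locations(net, rid)
      irlrs$decision[i] <- "remove-bad-link"
      irlrs$citation[i] <- ev$citation[1]
      next
    }
    pids <- setdiff(strsplit(irlrs$proteins[i], ",")[[1]], "")
    unique_prot <- any(vapply(pids, function(p) {
      locs <- unique(net$proteins[[p]]$locations$compartment)
      identical(locs, cc) && length(protein_reactions(net, p)) == 1
    }, logical(1)))
    if (unique_prot) {
      irlrs$decision[i] <- "keep-unique-protein"
      next
    }
    locs <- net$reactions[[rid]]$locations
    locs <- locs[locs$compartment != cc, , drop = FALSE]
    if (nrow(locs) == 0) locs <- loc_df("U", "default-uncertain")
    net$reactions[[rid]]$locations <- locs
    irlrs$decision[i] <- "remove"
  }
  counts <- table(factor(irlrs$decision,
                         levels = c("keep-evidence", "keep-unique-protein",
                                    "remove", "remove-bad-link")))
  list(network = net, irlrs = irlrs,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
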