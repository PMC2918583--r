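#' Assign locations to every reaction from its proteins
#'
#' A reaction's location set is the union of its active catalyzing
#' proteins' compartments, with `U` dropped whenever any real compartment
#' is present. Non-enzymatic reactions (no active links) and reactions
#' whose proteins are all uncertain are assigned `{U}` with provenance
#' `default-uncertain`.
#'
#' @param net A `metnet` object whose proteins carry location assignments
#'   (see [set_protein_locations()]).
#' @return The network with every reaction's `locations` populated
#'   (provenance `protein` or `default-uncertain`).
#' @export
assign_reaction_locations <- function(net) {
  for (rid in names(net$reactions)) {
    pids <- reaction_proteins(net, rid)
    codes <- character()
    for (p in pids) codes <- c(codes, net$proteins[[p]]$locations$compartment)
    codes <- sort(unique(codes))
    real <- setdiff(codes, "U")
    if (length(real) > 0) {
      net <- set_reaction_locations(net, rid, real, "protein")
    } else {
      net <- set_reaction_locations(net, rid, "U", "default-uncertain")
    }
  }
  net
}

#' Classify a reaction's protein-reaction-location relationship
#'
#' Types follow the standard four-way scheme: `a` = exactly one informative
#' protein; `b` = two or more proteins with identical location sets; `c` =
#' two or more proteins partitionable into groups with pairwise disjoint
#' location sets; `d` = proteins sharing at least one common compartment
#' while at least one carries an extra compartment, and any mixture that is
#' neither all-equal nor fully disjoint. Proteins whose location set is
#' `{U}` carry no location information and are excluded from the
#' comparison; if every protein is uncertain the classification is
#' `"unknown"`.
#'
#' @param net A `metnet` object with protein locations set.
#' @param rid Reaction id; must have at least one active link.
#' @return One of `"a"`, `"b"`, `"c"`, `"d"`, `"unknown"`.
#' @export
classify_reaction <- function(net, rid) {
  pids <- reaction_proteins(net, rid)
  if (length(pids) == 0) {
    stop("reaction ", rid, " has no active protein links; unclassified",
         call. = FALSE)
  }
  locsets <- lapply(pids, function(p) {
    sort(unique(net$proteins[[p]]$locations$compartment))
  })
  names(locsets) <- pids
  informative <- vapply(locsets, function(s) !identical(s, "U"), logical(1))
  locsets <- locsets[informative]
  if (length(locsets) == 0) return("unknown")
  if (length(pids) == 1) return("a")
  if (length(locsets) == 1) return("a")
  keys <- vapply(locsets, paste, "", collapse = ",")
  if (length(unique(keys)) == 1) return("b")
  # group proteins by identical location set, then test pairwise disjointness
  parts <- split(names(locsets), keys)
  part_sets <- lapply(split(locsets, keys), `[[`, 1)
  disjoint <- TRUE
  for (i in seq_along(part_sets)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(part_sets[[i]], part_sets[[j]])) > 0) {
        disjoint <- FALSE
      }
    }
  }
  if (disjoint) "c" else "d"
}

#' Classify every linked reaction in a network
#'
#' @param net A `metnet` object with protein locations set.
#' @return Data frame (`reaction`, `type`), one row per reaction with at
#'   least one active link, sorted by reaction id. Each reaction is counted
#'   once network-wide regardless of how many pathways it belongs to.
#' @export
classify_reactions <- function(net) {
  rids <- sort(names(net$reactions))
  rids <- rids[vapply(rids, function(r) length(reaction_proteins(net, r)) > 0,
                      logical(1))]
  data.frame(reaction = rids,
             type = vapply(rids, function(r) classify_reaction(net, r), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
partition_key <- function(net, rid) {
  pids <- reaction_proteins(net, rid)
  locsets <- lapply(pids, function(p) {
    sort(unique(net$proteins[[p]]$locations$compartment))
  })
  names(locsets) <- pids
  locsets <- locsets[vapply(locsets, function(s) !identical(s, "U"), logical(1))]
  keys <- vapply(locsets, paste, "", collapse = ",")
  parts <- lapply(split(names(locsets), keys), sort)
  parts <- parts[order(names(parts))]
  list(key = paste(vapply(seq_along(parts), function(i) {
    paste0(names(parts)[i], "=", paste(parts[[i]], collapse = "+"))
  }, ""), collapse = "|"),
  parts = unname(parts),
  locsets = lapply(sort(names(parts)), function(k) strsplit(k, ",")[[1]]))
}

#' Find complementary protein groups
#'
#' Proteins catalyzing the same reaction while active in pairwise disjoint
#' compartments ("complementary proteins", the type-c relationship).
#' Type-c reactions sharing the same protein partition are aggregated into
#' one group listing all reactions it covers.
#'
#' @param net A `metnet` object with protein locations set.
#' @return List of groups; each a list with `reactions` (sorted ids),
#'   `parts` (list of protein-id vectors) and `locations` (per-part
#'   compartment sets, pairwise disjoint). Sorted by first reaction id.
#' @export
find_complementary_groups <- function(net) {
  cls <- classify_reactions(net)
  crids <- cls$reaction[cls$type == "c"]
  if (length(crids) == 0) return(list())
  keys <- vapply(crids, function(r) partition_key(net, r)$key, "")
  groups <- lapply(split(crids, keys), function(rids) {
    pk <- partition_key(net, rids[1])
    list(reactions = sort(rids), parts = pk$parts, locations = pk$locsets)
  })
  groups <- unname(groups)
  groups[order(vapply(groups, function(g) g$reactions[1], ""))]
}

#' Resolve a complementary group against a location verdict
#'
#' The verdict (which compartment the reactions truly occur in) comes from
#' curation evidence, not from the algorithm. Links from proteins whose
#' location set excludes the verdict compartment are deactivated for every
#' reaction of the group, and the affected reactions' locations are
#' recomputed from the remaining active links.
#'
#' @param net A `metnet` object.
#' @param group One group from [find_complementary_groups()].
#' @param verdict Compartment code naming the correct part.
#' @param citation Free-text evidence reference recorded in the deletion
#'   report.
#' @return List with `network` (updated) and `deletions` (data frame
#'   `protein`, `reaction`, `reason`).
#' @export
resolve_type_c <- function(net, group, verdict, citation = "") {
  check_compartment(verdict, allow_u = FALSE)
  holds <- vapply(group$locations, function(s) verdict %in% s, logical(1))
  if (!any(holds)) {
    stop("verdict ", verdict, " is not among any part's locations",
         call. = FALSE)
  }
  wrong_prots <- unlist(group$parts[!holds], use.names = FALSE)
  deletions <- list()
  for (rid in group$reactions) {
    for (pid in intersect(wrong_prots, reaction_proteins(net, rid))) {
      sel <- net$links$protein == pid & net$links$reaction == rid
      net$links$active[sel] <- FALSE
      deletions[[length(deletions) + 1]] <- data.frame(
        protein = pid, reaction = rid,
        reason = paste0("complementary-group verdict ", verdict,
                        if (nzchar(citation)) paste0(": ", citation) else ""),
        stringsAsFactors = FALSE)
    }
    net <- recompute_reaction_locations(net, rid)
    # the surviving location is curation-backed
    sel <- net$reactions[[rid]]$locations$compartment == verdict
    net$reactions[[rid]]$locations$provenance[sel] <- "curated"
  }
  deletions <- if (length(deletions) > 0) do.call(rbind, deletions) else
    data.frame(protein = character(), reaction = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(network = net, deletions = deletions)
}
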