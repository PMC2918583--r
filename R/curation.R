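#' Apply declarative curation edits
#'
#' Literature-derived revisions enter the network as citation-bearing edit
#' records rather than code, so every change is replayable and auditable.
#' Supported kinds: `delete-link` (deactivate a protein-reaction link and
#' recompute the reaction's protein-derived locations), `add-link`,
#' `set-locations` (replace the reaction's location set, provenance
#' `curated`), `add-location`, `remove-location`. Edits are applied
#' atomically in `order` sequence.
#'
#' @param net A `metnet` object; [validate_network()] should be clean.
#' @param edits Data frame with columns `order`, `kind`, `reaction`,
#'   `protein` (link edits; else `""`), `compartments` (comma-joined,
#'   location edits; else `""`), `citation`.
#' @param strict If `TRUE`, an edit referencing a missing entity aborts;
#'   otherwise it is rejected, logged, and processing continues.
#' @return List with `network`, `log` (data frame `order`, `kind`,
#'   `reaction`, `status`, `before`, `after`, `citation`) and counts
#'   `accepted`/`rejected`.
#' @export
apply_edits <- function(net, edits, strict = FALSE) {
  log <- list()
  note <- function(e, status, before, after) {
    log[[length(log) + 1]] <<- data.frame(
      order = e$order, kind = e$kind, reaction = e$reaction, status = status,
      before = before, after = after, citation = e$citation,
      stringsAsFactors = FALSE)
  }
  edits <- edits[order(edits$order), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    locs_str <- function() {
      paste(sort(reaction_location_codes(net, e$reaction)), collapse = ",")
    }
    fail <- function(msg) {
      if (strict) stop("curation edit ", e$order, ": ", msg, call. = FALSE)
      note(e, paste("rejected:", msg), "", "")
    }
    if (is.null(net$reactions[[e$reaction]])) {
      fail(paste("unknown reaction", e$reaction)); next
    }
    comps <- setdiff(strsplit(as.character(e$compartments), ",")[[1]], "")
    before <- locs_str()
    if (e$kind %in% c("delete-link", "add-link")) {
      if (is.null(net$proteins[[e$protein]])) {
        fail(paste("unknown protein", e$protein)); next
      }
      sel <- net$links$protein == e$protein & net$links$reaction == e$reaction
      if (e$kind == "delete-link") {
        if (!any(sel)) { fail("no such link"); next }
        net$links$active[sel] <- FALSE
      } else {
        if (any(sel)) net$links$active[sel] <- TRUE
        else net$links <- rbind(net$links, data.frame(
          protein = e$protein, reaction = e$reaction, active = TRUE,
          stringsAsFactors = FALSE))
      }
      net <- recompute_reaction_locations(net, e$reaction)
    } else if (e$kind == "set-locations") {
      if (length(comps) == 0) { fail("set-locations payload empty"); next }
      bad <- setdiff(comps, compartment_codes())
      if (length(bad) > 0) { fail(paste("unknown compartment", bad[1])); next }
      net <- set_reaction_locations(net, e$reaction, sort(comps), "curated")
    } else if (e$kind == "add-location") {
      bad <- setdiff(comps, compartment_codes())
      if (length(bad) > 0) { fail(paste("unknown compartment", bad[1])); next }
      cur <- net$reactions[[e$reaction]]$locations
      add <- setdiff(comps, cur$compartment)
      net$reactions[[e$reaction]]$locations <- rbind(cur, loc_df(add, "curated"))
    } else if (e$kind == "remove-location") {
      cur <- net$reactions[[e$reaction]]$locations
      cur <- cur[!(cur$compartment %in% comps), , drop = FALSE]
      if (nrow(cur) == 0) cur <- loc_df("U", "default-uncertain")
      net$reactions[[e$reaction]]$locations <- cur
    } else {
      fail(paste("unknown edit kind", e$kind)); next
    }
    note(e, "accepted", before, locs_str())
  }
  log <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(order = integer(), kind = character(), reaction = character(),
               status = character(), before = character(), after = character(),
               citation = character(), stringsAsFactors = FALSE)
  list(network = net, log = log,
       accepted = sum(log$status == "accepted"),
       rejected = sum(log$status != "accepted"))
}

#' Check advisory location rules
#'
#' Screens the network against simple biochemical location criteria of the
#' kind used for beta-oxidation pathways: a reaction involving a marker
#' metabolite (for example hydrogen peroxide, pointing to the peroxisome)
#' should carry the required compartment, and a reaction consuming an acyl
#' chain longer than a threshold should be peroxisomal. Violations are
#' reported, never auto-edited — the criteria admit curated exceptions.
#'
#' @param net A `metnet` object.
#' @param rules Data frame (`metabolite`, `compartment`): reactions
#'   involving `metabolite` should include `compartment`.
#' @param chain_rules Optional data frame (`min_carbons`, `compartment`):
#'   reactions consuming a metabolite with more than `min_carbons` carbons
#'   should include `compartment`. Requires `carbons`.
#' @param carbons Optional data frame (`metabolite`, `carbons`) supplying
#'   per-metabolite carbon counts; chain length is never inferred from
#'   names.
#' @return Data frame (`reaction`, `rule`, `suggested`) of violations.
#' @export
check_rules <- function(net, rules, chain_rules = NULL, carbons = NULL) {
  v <- list()
  for (r in net$reactions) {
    locs <- setdiff(r$locations$compartment, "U")
    mets <- unique(c(r$substrates$metabolite, r$products$metabolite))
    for (i in seq_len(nrow(rules))) {
      if (rules$metabolite[i] %in% mets &&
          !(rules$compartment[i] %in% locs)) {
        v[[length(v) + 1]] <- data.frame(
          reaction = r$id,
          rule = paste0("metabolite ", rules$metabolite[i], " requires ",
                        rules$compartment[i]),
          suggested = rules$compartment[i], stringsAsFactors = FALSE)
      }
    }
    if (!is.null(chain_rules) && !is.null(carbons)) {
      for (i in seq_len(nrow(chain_rules))) {
        sub_c <- carbons$carbons[match(r$substrates$metabolite,
                                       carbons$metabolite)]
        if (any(!is.na(sub_c) & sub_c > chain_rules$min_carbons[i]) &&
            !(chain_rules$compartment[i] %in% locs)) {
          v[[length(v) + 1]] <- data.frame(
            reaction = r$id,
            rule = paste0("chain length > C-", chain_rules$min_carbons[i],
                          " requires ", chain_rules$compartment[i]),
            suggested = chain_rules$compartment[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(v) == 0) {
    return(data.frame(reaction = character(), rule = character(),
                      suggested = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  out[order(out$reaction, out$rule), , drop = FALSE]
}
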