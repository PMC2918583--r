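#' @keywords internal
transport_id <- function(metabolite, a, b) {
  pair <- sort(c(a, b))
  paste0("T_", metabolite, "_", pair[1], "_", pair[2])
}

#' @keywords internal
new_transport <- function(metabolite, from, to, reversible = TRUE,
                          source = "dead-end-inferred",
                          proteins = character()) {
  list(id = transport_id(metabolite, from, to), metabolite = metabolite,
       from = from, to = to, reversible = isTRUE(reversible),
       source = source, proteins = as.character(proteins))
}

#' Reassign uncertain reactions to the cytosol
#'
#' A transport reaction involving the placeholder location `U` would be
#' meaningless, so before transport addition every reaction whose location
#' set is exactly `{U}` is reassigned to the cytosol (provenance
#' `cytosol-default`), the convention also used by compartmentalized
#' reference reconstructions. A `U` co-occurring with a real location is
#' simply dropped. After this step no `U` remains in the network.
#'
#' @param net A `metnet` object after the structural revisions.
#' @return The updated network.
#' @export
reassign_uncertain <- function(net) {
  for (rid in names(net$reactions)) {
    locs <- net$reactions[[rid]]$locations
    if (all(locs$compartment == "U")) {
      net$reactions[[rid]]$locations <- loc_df("C", "cytosol-default")
    } else if ("U" %in% locs$compartment) {
      net$reactions[[rid]]$locations <-
        locs[locs$compartment != "U", , drop = FALSE]
    }
  }
  net
}

#' @keywords internal
metabolite_compartments <- function(net, m) {
  ccs <- character()
  for (r in net$reactions) {
    if (m %in% c(r$substrates$metabolite, r$products$metabolite)) {
      ccs <- c(ccs, setdiff(r$locations$compartment, "U"))
    }
  }
  sort(unique(ccs))
}

#' Import transport reactions from a scored reference list
#'
#' Acceptance depends on the evidence grade: score 3 (direct biochemical or
#' genetic evidence) and transporter-annotation rows are accepted whenever
#' the metabolite exists in the network at all; score 2 (physiological or
#' non-human evidence) only when the metabolite participates in located
#' metabolic reactions in *both* compartments of the pair; scores below 2
#' rest on in-silico simulation only and are ignored.
#'
#' @param net A `metnet` object after [reassign_uncertain()].
#' @param reference Data frame with columns `metabolite`, `from`, `to`,
#'   `score` (0-3, or the string `"annotation"` for transporter-annotation
#'   rows), `proteins` (comma-joined, may be `""`), `reversible` (logical).
#' @return List with `accepted` (list of transport objects) and
#'   `rejections` (data frame `metabolite`, `from`, `to`, `score`,
#'   `reason`).
#' @export
import_reference_transports <- function(net, reference) {
  check_compartment(unique(c(reference$from, reference$to)), allow_u = FALSE)
  accepted <- list()
  rej <- list()
  reject <- function(i, reason) {
    rej[[length(rej) + 1]] <<- data.frame(
      metabolite = reference$metabolite[i], from = reference$from[i],
      to = reference$to[i], score = as.character(reference$score[i]),
      reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reference))) {
    m <- reference$metabolite[i]
    score <- as.character(reference$score[i])
    src <- if (score == "annotation") "transporter-annotation" else
      paste0("reference-score", score)
    if (score %in% c("0", "1")) {
      reject(i, "confidence score below 2")
      next
    }
    if (score %in% c("3", "annotation")) {
      if (!(m %in% net$metabolites$id)) {
        reject(i, "metabolite absent from network")
        next
      }
    } else if (score == "2") {
      present <- metabolite_compartments(net, m)
      missing <- setdiff(c(reference$from[i], reference$to[i]), present)
      if (length(missing) > 0) {
        reject(i, paste("metabolite absent from compartment",
                        paste(missing, collapse = ",")))
        next
      }
    } else {
      stop("unknown confidence score: ", score, call. = FALSE)
    }
    prots <- setdiff(strsplit(as.character(reference$proteins[i]), ",")[[1]],
                     "")
    accepted[[length(accepted) + 1]] <-
      new_transport(m, reference$from[i], reference$to[i],
                    isTRUE(reference$reversible[i]), src, prots)
  }
  rejections <- if (length(rej) > 0) do.call(rbind, rej) else
    data.frame(metabolite = character(), from = character(), to = character(),
               score = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(accepted = accepted, rejections = rejections)
}

#' Find dead-end metabolites per compartment
#'
#' A dead end is a metabolite that, within one compartment, is only
#' produced, only consumed, or (optionally) participates in a single
#' reaction. Reversible reactions count as both producer and consumer.
#' Transport reactions already in the network contribute their roles, but a
#' metabolite whose only appearance in a compartment is a transport
#' endpoint is not a candidate — transports are bridges, not pathway
#' membership. Currency metabolites and reactions belonging solely to the
#' `"isolated"` pathway are excluded.
#'
#' @param net A `metnet` object (after [reassign_uncertain()]).
#' @param currency Currency metabolite ids excluded from the analysis.
#' @param mode `"network"` (default): roles are tallied per compartment
#'   across the whole network; `"pathway"`: tallied within each pathway,
#'   and a metabolite is reported once per compartment if dead-ended in any
#'   pathway.
#' @param sole_participant Also flag metabolites appearing in exactly one
#'   reaction in a compartment (any reversibility); a metabolite in a
#'   single reversible reaction is formally both produced and consumed yet
#'   functionally disconnected. Set `FALSE` for the strict
#'   only-produced/only-consumed definition.
#' @return Data frame (`metabolite`, `compartment`, `mode`) sorted by
#'   (compartment, metabolite); `mode` is one of `only-produced`,
#'   `only-consumed`, `sole-participant`.
#' @export
find_dead_ends <- function(net, currency = default_currency(),
                           mode = c("network", "pathway"),
                           sole_participant = TRUE) {
  mode <- match.arg(mode)
  scopes <- if (mode == "network") list(all = NULL) else
    pathway_index(net, exclude_isolated = TRUE)
  hits <- list()
  for (scope in names(scopes)) {
    rids <- if (mode == "network") {
      Filter(function(rid) {
        pw <- net$reactions[[rid]]$pathways
        length(pw) == 0 || !all(pw == "isolated")
      }, names(net$reactions))
    } else scopes[[scope]]
    # tally per (metabolite, compartment): producer/consumer/participation
    prod <- list(); cons <- list(); part <- list(); metab <- list()
    bump <- function(store, m, cc) {
      key <- paste(m, cc, sep = "@")
      store[[key]] <- (if (is.null(store[[key]])) 0 else store[[key]]) + 1
      store
    }
    for (rid in rids) {
      r <- net$reactions[[rid]]
      subs <- setdiff(unique(r$substrates$metabolite), currency)
      prods <- setdiff(unique(r$products$metabolite), currency)
      for (cc in setdiff(r$locations$compartment, "U")) {
        for (m in subs) {
          cons <- bump(cons, m, cc)
          if (r$reversible) prod <- bump(prod, m, cc)
        }
        for (m in prods) {
          prod <- bump(prod, m, cc)
          if (r$reversible) cons <- bump(cons, m, cc)
        }
        for (m in union(subs, prods)) {
          part <- bump(part, m, cc)
          metab[[paste(m, cc, sep = "@")]] <- TRUE
        }
      }
    }
    # transports contribute roles but do not create candidates
    for (tr in net$transports) {
      if (tr$metabolite %in% currency) next
      ends <- list(c(tr$from, "in"), c(tr$to, "out"))
      for (e in ends) {
        cc <- e[1]
        key <- paste(tr$metabolite, cc, sep = "@")
        if (e[2] == "in") cons <- bump(cons, tr$metabolite, cc)
        else prod <- bump(prod, tr$metabolite, cc)
        if (tr$reversible) {
          if (e[2] == "in") prod <- bump(prod, tr$metabolite, cc)
          else cons <- bump(cons, tr$metabolite, cc)
        }
        part <- bump(part, tr$metabolite, cc)
      }
    }
    for (key in names(metab)) {
      mc <- strsplit(key, "@", fixed = TRUE)[[1]]
      np <- if (is.null(prod[[key]])) 0 else prod[[key]]
      nc <- if (is.null(cons[[key]])) 0 else cons[[key]]
      de_mode <- NULL
      if (np > 0 && nc == 0) de_mode <- "only-produced"
      else if (nc > 0 && np == 0) de_mode <- "only-consumed"
      else if (sole_participant && part[[key]] == 1) de_mode <- "sole-participant"
      if (!is.null(de_mode)) {
        hits[[key]] <- data.frame(metabolite = mc[1], compartment = mc[2],
                                  mode = de_mode, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(metabolite = character(), compartment = character(),
               mode = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$compartment, out$metabolite), , drop = FALSE]
}

#' Infer transport reactions for dead-end metabolites
#'
#' For each dead end (m, L) whose metabolite also occurs in at least one
#' other compartment, a reversible transport is added using the cytosol as
#' the bridging compartment: `m: L <-> C` when L is not the cytosol, and
#' `m: C <-> L'` for every other compartment L' containing m when L is the
#' cytosol. Inferred transports are reversible because dead-end analysis
#' carries no directional evidence and the goal is connectivity. Dead ends
#' whose metabolite exists nowhere else yield nothing (logged).
#'
#' @param net A `metnet` object.
#' @param dead_ends Output of [find_dead_ends()].
#' @return List with `transports` (new transport objects, deduplicated
#'   against each other and against `net$transports`) and `skipped` (data
#'   frame of dead ends with no destination compartment).
#' @export
infer_transports <- function(net, dead_ends) {
  existing <- vapply(net$transports, `[[`, "", "id")
  out <- list()
  skipped <- list()
  for (i in seq_len(nrow(dead_ends))) {
    m <- dead_ends$metabolite[i]; L <- dead_ends$compartment[i]
    others <- setdiff(metabolite_compartments(net, m), L)
    if (length(others) == 0) {
      skipped[[length(skipped) + 1]] <- dead_ends[i, , drop = FALSE]
      next
    }
    pairs <- if (L != "C") list(c(L, "C")) else
      lapply(others, function(o) c("C", o))
    for (p in pairs) {
      tr <- new_transport(m, p[1], p[2], reversible = TRUE,
                          source = "dead-end-inferred")
      if (!(tr$id %in% existing)) {
        out[[tr$id]] <- tr
        existing <- c(existing, tr$id)
      }
    }
  }
  skipped <- if (length(skipped) > 0) do.call(rbind, skipped) else
    dead_ends[0, , drop = FALSE]
  trs <- if (length(out) > 0) unname(out[order(names(out))]) else list()
  list(transports = trs, skipped = skipped)
}

#' Deduplicate transport reactions
#'
#' At most one transport survives per (metabolite, unordered compartment
#' pair); when several sources propose the same pair the better-evidenced
#' one wins (`reference-score3` > `reference-score2` >
#' `transporter-annotation` > `dead-end-inferred`).
#'
#' @param transports List of transport objects.
#' @return List with `transports` (canonical, sorted by id) and
#'   `duplicates` (integer count of dropped entries).
#' @export
dedup_transports <- function(transports) {
  rank <- c("reference-score3" = 1, "reference-score2" = 2,
            "transporter-annotation" = 3, "dead-end-inferred" = 4)
  best <- list()
  dropped <- 0L
  for (tr in transports) {
    cur <- best[[tr$id]]
    if (is.null(cur)) {
      best[[tr$id]] <- tr
    } else {
      dropped <- dropped + 1L
      if (rank[[tr$source]] < rank[[cur$source]]) best[[tr$id]] <- tr
    }
  }
  if (length(best) == 0) return(list(transports = list(), duplicates = 0L))
  list(transports = unname(best[order(names(best))]), duplicates = dropped)
}
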