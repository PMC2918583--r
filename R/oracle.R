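# Brute-force reference implementations, deliberately independent of the
# igraph-backed production code paths. They exist so that the synthetic
# generator can verify its planted structure and the test suite can compare
# the fast implementations against first-principles enumeration. None of
# these are exported.

#' Components by boolean-matrix reachability (repeated squaring)
#' @keywords internal
bf_components <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 0) return(list())
  A <- diag(TRUE, n)
  rownames(A) <- colnames(A) <- nodes
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- TRUE
    A[edges$to[i], edges$from[i]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  seen <- character()
  comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    comp <- sort(nodes[A[v, ] > 0])
    comps[[length(comps) + 1]] <- comp
    seen <- c(seen, comp)
  }
  comps[order(vapply(comps, `[`, "", 1))]
}

#' Exhaustive gap enumeration over (reaction, compartment, component pair)
#' @keywords internal
bf_gaps <- function(net, currency = default_currency()) {
  idx <- pathway_index(net, exclude_isolated = TRUE)
  recs <- list()
  for (pw in names(idx)) {
    for (cc in compartment_codes(real_only = TRUE)) {
      located <- Filter(function(r) cc %in% reaction_location_codes(net, r),
                        idx[[pw]])
      if (length(located) < 2) next
      # rebuild edges from first principles
      e <- list()
      for (a in located) for (b in located) {
        if (a >= b) next
        r1 <- net$reactions[[a]]; r2 <- net$reactions[[b]]
        ok <- FALSE
        for (m in setdiff(intersect(reaction_mets(r1), reaction_mets(r2)),
                          currency)) {
          if ((can_produce(r1, m) && can_consume(r2, m)) ||
              (can_produce(r2, m) && can_consume(r1, m))) ok <- TRUE
        }
        if (ok) e[[length(e) + 1]] <- data.frame(from = a, to = b,
                                                 stringsAsFactors = FALSE)
      }
      e <- if (length(e) > 0) do.call(rbind, e) else
        data.frame(from = character(), to = character(),
                   stringsAsFactors = FALSE)
      comps <- bf_components(located, e)
      if (length(comps) < 2) next
      cm <- lapply(comps, function(comp) {
        sort(unique(unlist(lapply(comp, function(r) {
          reaction_mets(net$reactions[[r]], currency)
        }))))
      })
      for (rid in setdiff(idx[[pw]], located)) {
        mets <- reaction_mets(net$reactions[[rid]], currency)
        hit <- which(vapply(cm, function(x) length(intersect(x, mets)) > 0,
                            logical(1)))
        if (length(hit) >= 2) {
          for (i in seq_along(hit)) for (j in seq_len(i - 1)) {
            recs[[length(recs) + 1]] <- data.frame(
              reaction = rid, pathway = pw, compartment = cc,
              component_a = min(comps[[hit[j]]][1], comps[[hit[i]]][1]),
              component_b = max(comps[[hit[j]]][1], comps[[hit[i]]][1]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(reaction = character(), pathway = character(),
               compartment = character(), component_a = character(),
               component_b = character(), stringsAsFactors = FALSE)
  out[order(out$pathway, out$compartment, out$reaction,
            out$component_a, out$component_b), , drop = FALSE]
}

#' Singleton-component scan for IRLRs
#' @keywords internal
bf_irlrs <- function(net, currency = default_currency(), scope = "all") {
  idx <- pathway_index(net, exclude_isolated = TRUE)
  single <- list(); connected <- list()
  for (pw in names(idx)) {
    for (cc in compartment_codes(real_only = TRUE)) {
      located <- Filter(function(r) cc %in% reaction_location_codes(net, r),
                        idx[[pw]])
      if (length(located) == 0) next
      e <- list()
      for (a in located) for (b in located) {
        if (a >= b) next
        r1 <- net$reactions[[a]]; r2 <- net$reactions[[b]]
        for (m in setdiff(intersect(reaction_mets(r1), reaction_mets(r2)),
                          currency)) {
          if ((can_produce(r1, m) && can_consume(r2, m)) ||
              (can_produce(r2, m) && can_consume(r1, m))) {
            e[[length(e) + 1]] <- data.frame(from = a, to = b,
                                             stringsAsFactors = FALSE)
          }
        }
      }
      e <- if (length(e) > 0) do.call(rbind, e) else
        data.frame(from = character(), to = character(),
                   stringsAsFactors = FALSE)
      for (comp in bf_components(located, e)) {
        for (rid in comp) {
          key <- paste(rid, cc, sep = "@")
          if (length(comp) == 1) single[[key]] <- TRUE
          else connected[[key]] <- TRUE
        }
      }
    }
  }
  keys <- names(single)
  if (scope == "all") keys <- setdiff(keys, names(connected))
  out <- do.call(rbind, c(list(data.frame(reaction = character(),
                                          compartment = character(),
                                          stringsAsFactors = FALSE)),
                          lapply(keys, function(k) {
                            p <- strsplit(k, "@", fixed = TRUE)[[1]]
                            data.frame(reaction = p[1], compartment = p[2],
                                       stringsAsFactors = FALSE)
                          })))
  out[order(out$compartment, out$reaction), , drop = FALSE]
}

#' Direct per-compartment role tally for dead ends
#' @keywords internal
bf_dead_ends <- function(net, currency = default_currency(),
                         sole_participant = TRUE) {
  rows <- list()
  for (cc in compartment_codes(real_only = TRUE)) {
    mets <- character()
    for (r in net$reactions) {
      pw <- r$pathways
      if (length(pw) > 0 && all(pw == "isolated")) next
      if (cc %in% r$locations$compartment) {
        mets <- c(mets, setdiff(c(r$substrates$metabolite,
                                  r$products$metabolite), currency))
      }
    }
    for (m in sort(unique(mets))) {
      np <- 0; nc <- 0; npart <- 0
      for (r in net$reactions) {
        pw <- r$pathways
        if (length(pw) > 0 && all(pw == "isolated")) next
        if (!(cc %in% r$locations$compartment)) next
        is_s <- m %in% r$substrates$metabolite
        is_p <- m %in% r$products$metabolite
        if (!is_s && !is_p) next
        npart <- npart + 1
        if (is_p || (r$reversible && is_s)) np <- np + 1
        if (is_s || (r$reversible && is_p)) nc <- nc + 1
      }
      for (tr in net$transports) {
        if (tr$metabolite != m) next
        if (tr$to == cc || (tr$reversible && tr$from == cc)) np <- np + 1
        if (tr$from == cc || (tr$reversible && tr$to == cc)) nc <- nc + 1
        if (tr$from == cc || tr$to == cc) npart <- npart + 1
      }
      md <- NULL
      if (np > 0 && nc == 0) md <- "only-produced"
      else if (nc > 0 && np == 0) md <- "only-consumed"
      else if (sole_participant && npart == 1) md <- "sole-participant"
      if (!is.null(md)) {
        rows[[length(rows) + 1]] <- data.frame(
          metabolite = m, compartment = cc, mode = md,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(metabolite = character(), compartment = character(),
               mode = character(), stringsAsFactors = FALSE)
  out[order(out$compartment, out$metabolite), , drop = FALSE]
}

#' Transitive-closure ancestor set of an ontology term
#' @keywords internal
bf_ancestors <- function(term_id, ontology) {
  out <- character()
  frontier <- term_id
  while (length(frontier) > 0) {
    nxt <- character()
    for (t in frontier) {
      node <- ontology[[t]]
      if (is.null(node) || isTRUE(node$obsolete)) next
      if (!(t %in% out)) {
        out <- c(out, t)
        nxt <- c(nxt, node$parents$parent)
      }
    }
    frontier <- setdiff(unique(nxt), out)
  }
  sort(out)
}
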