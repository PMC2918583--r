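#' Configuration for the synthetic network generator
#'
#' The generator emulates the inputs of a compartmentalization run:
#' pathway-structured reaction chains with one enzyme per reaction, partial
#' and uncertain protein annotation, currency cofactors, and structure
#' planted for each analysis — auto-fillable gaps, isolated
#' reaction-location relationships, and dead-end metabolites shared
#' between two compartments.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_pathways Number of pathways.
#' @param reactions_per_pathway Length-2 integer range for chain length.
#' @param compartment_probs Named sampling weights over the eight real
#'   compartments for per-pathway location.
#' @param unannotated_fraction Fraction of reactions whose enzyme has no
#'   resolvable annotation; realized as the planted-gap enzymes plus extra
#'   reactions in the literal `"isolated"` pathway, which is excluded from
#'   structural analyses, so planted counts stay exact.
#' @param n_gaps,n_irlrs,n_dead_ends Planted structure counts.
#' @param n_currency Number of currency metabolites used as cofactors and
#'   chain boundaries.
#' @param reversibility_prob Probability that a chain reaction is
#'   reversible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_pathways = 6,
                       reactions_per_pathway = c(6, 9),
                       compartment_probs = c(E = 0.08, N = 0.10, C = 0.30,
                                             ER = 0.12, GA = 0.08, X = 0.10,
                                             L = 0.05, M = 0.17),
                       unannotated_fraction = 0.08,
                       n_gaps = 2, n_irlrs = 2, n_dead_ends = 2,
                       n_currency = 5, reversibility_prob = 0.25) {
  cfg <- list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
              reactions_per_pathway = as.integer(reactions_per_pathway),
              compartment_probs = compartment_probs,
              unannotated_fraction = unannotated_fraction,
              n_gaps = as.integer(n_gaps), n_irlrs = as.integer(n_irlrs),
              n_dead_ends = as.integer(n_dead_ends),
              n_currency = as.integer(n_currency),
              reversibility_prob = reversibility_prob)
  if (cfg$n_gaps > cfg$n_pathways) {
    stop("unsatisfiable config: n_gaps exceeds n_pathways", call. = FALSE)
  }
  if (cfg$n_irlrs > cfg$n_pathways) {
    stop("unsatisfiable config: n_irlrs exceeds n_pathways", call. = FALSE)
  }
  if (cfg$n_dead_ends > cfg$n_pathways) {
    stop("unsatisfiable config: n_dead_ends exceeds n_pathways", call. = FALSE)
  }
  if (cfg$n_dead_ends > 0 && cfg$n_pathways < 2) {
    stop("unsatisfiable config: dead ends need two pathways in different compartments",
         call. = FALSE)
  }
  if (cfg$n_currency < 2 || cfg$n_currency > length(default_currency())) {
    stop("unsatisfiable config: n_currency out of range", call. = FALSE)
  }
  if (cfg$reactions_per_pathway[1] < 2 ||
      (cfg$n_irlrs > 0 && cfg$reactions_per_pathway[1] < 3)) {
    stop("unsatisfiable config: chains too short for the planted structure",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Three-level mini ontology for localization tests
#'
#' Root, the eight compartment target terms (children of the root), two
#' leaf children per target (one `is_a`, one `part_of`), a plasma-membrane
#' term mapped to the cytosol with its own leaf, and an off-branch term
#' whose descendants reach no target (they backtrack to `U`).
#'
#' @return An `ontology` object as returned by [read_obo()].
#' @export
mini_ontology <- function() {
  lines <- c("format-version: 1.2")
  stanza <- function(id, name, parents = character(), rel = character(),
                     obsolete = FALSE) {
    c("", "[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: cellular_component",
      vapply(parents, function(p) paste0("is_a: ", p, " ! parent"), ""),
      vapply(rel, function(p) paste0("relationship: part_of ", p, " ! part"), ""),
      if (obsolete) "is_obsolete: true" else character())
  }
  lines <- c(lines, stanza("GO:ROOT", "cellular_component"))
  comp <- compartments()
  for (i in which(comp$code != "U")) {
    tid <- comp$go_id[i]
    lines <- c(lines, stanza(tid, comp$name[i], parents = "GO:ROOT"))
    lines <- c(lines,
               stanza(paste0(tid, ":leafA"), paste(comp$name[i], "lumen"),
                      parents = tid),
               stanza(paste0(tid, ":leafB"), paste(comp$name[i], "membrane"),
                      rel = tid))
  }
  lines <- c(lines, stanza("GO:0005886", "plasma membrane",
                           parents = "GO:ROOT"))
  lines <- c(lines, stanza("GO:0005886:leafA", "plasma membrane raft",
                           parents = "GO:0005886"))
  lines <- c(lines, stanza("GO:OFFB", "cytoskeleton", parents = "GO:ROOT"))
  lines <- c(lines, stanza("GO:OFFB:leafA", "microtubule",
                           parents = "GO:OFFB"))
  read_obo(unlist(lines), namespace = "cellular_component")
}

#' @keywords internal
leaf_term_for <- function(code, which = "A") {
  comp <- compartments()
  paste0(comp$go_id[comp$code == code], ":leaf", which)
}

#' Generate a synthetic compartmentalized-network input set
#'
#' Pathways are chains of irreversible or reversible reactions whose
#' boundary metabolites are currency cofactors (so chain ends are not
#' spurious dead ends) and whose interior metabolites are unique per
#' pathway. Each reaction has one enzyme annotated — via ontology leaf
#' terms or keyword rows — to the pathway's compartment. Planted
#' structure:
#' \itemize{
#'   \item a *gap*: the middle reaction of a chain loses its enzyme
#'     annotation (protein resolves to `{U}`), so the reaction drops out of
#'     the compartment graph, splits the chain in two, and is auto-fillable;
#'   \item an *IRLR*: an extra reaction branching off the chain whose
#'     enzyme carries a second compartment, where the reaction is a
#'     one-node component;
#'   \item a *dead end*: an extra terminal reaction producing a metabolite
#'     that is only produced in this compartment but circulates (produced
#'     and consumed) inside a second pathway located elsewhere.
#' }
#' Planted structure is verified post hoc with the package's brute-force
#' oracles at the pipeline stage where each analysis runs — never with the
#' production detectors — and generation errors if any incidental finding
#' appears.
#'
#' @param config A [sim_config()].
#' @param verify Run the post-hoc oracle verification (default `TRUE`).
#' @return List with `network` (proteins still unlocated), `assoc` and
#'   `keywords` annotation tables, `ontology`, `target_map`, `currency`,
#'   `truth` (planted gaps/irlrs/dead ends and per-protein true locations)
#'   and `config`.
#' @export
simulate_network <- function(config = sim_config(), verify = TRUE) {
  set.seed(config$seed)
  currency <- default_currency()[seq_len(config$n_currency)]
  comps_avail <- names(config$compartment_probs)
  pw_comp <- sample(comps_avail, config$n_pathways, replace = TRUE,
                    prob = config$compartment_probs)
  if (config$n_dead_ends > 0 && length(unique(pw_comp)) < 2) {
    # dead ends need a second compartment to circulate in
    pw_comp[config$n_pathways] <-
      sample(setdiff(comps_avail, pw_comp[1]), 1)
  }
  lo <- config$reactions_per_pathway[1]
  hi <- config$reactions_per_pathway[2]
  lens <- lo - 1L + sample.int(hi - lo + 1L, config$n_pathways,
                               replace = TRUE)
  gap_pw <- seq_len(config$n_gaps)
  lens[gap_pw] <- pmax(lens[gap_pw], 5L)
  irlr_pw <- seq_len(config$n_irlrs)
  de_pw <- integer(0)
  if (config$n_dead_ends > 0) {
    # pair each dead-end pathway with a partner in another compartment
    de_pw <- vapply(seq_len(config$n_dead_ends), function(k) {
      cands <- which(vapply(seq_len(config$n_pathways), function(p) {
        any(pw_comp != pw_comp[p])
      }, logical(1)))
      cands[(k - 1) %% length(cands) + 1]
    }, integer(1))
  }
  reactions <- list(); proteins <- list()
  links <- list(); assoc <- list(); keywords <- list()
  truth_gaps <- list(); truth_irlrs <- list(); truth_des <- list()
  truth_prot <- list()
  kw_codes <- c("N", "ER", "GA", "X", "L", "M")  # keyword-capable locations
  add_link <- function(p, r) {
    links[[length(links) + 1]] <<- data.frame(protein = p, reaction = r,
                                              active = TRUE,
                                              stringsAsFactors = FALSE)
  }
  annotate <- function(pid, code) {
    truth_prot[[pid]] <<- code
    use_kw <- code %in% kw_codes && stats::runif(1) < 0.2
    if (use_kw) {
      keywords[[length(keywords) + 1]] <<-
        data.frame(protein = pid, compartment = code, stringsAsFactors = FALSE)
    } else {
      assoc[[length(assoc) + 1]] <<-
        data.frame(protein = pid,
                   term = leaf_term_for(code, sample(c("A", "B"), 1)),
                   stringsAsFactors = FALSE)
    }
  }
  met <- function(p, i) sprintf("P%02d_m%02d", p, i)
  passengers <- list()  # per pathway: planted dead-end metabolite circulating
  for (p in seq_len(config$n_pathways)) {
    pw_name <- sprintf("pathway_%02d", p)
    cc <- pw_comp[p]
    L <- lens[p]
    boundary <- sample(currency, 2)
    gap_j <- if (p %in% gap_pw) floor(L / 2) + 1L else NA_integer_
    for (j in seq_len(L)) {
      rid <- sprintf("P%02d_R%02d", p, j)
      pid <- paste0("PR_", rid)
      sub_m <- if (j == 1) boundary[1] else met(p, j - 1)
      prod_m <- if (j == L) boundary[2] else met(p, j)
      subs <- stats::setNames(1, sub_m)
      prods <- stats::setNames(1, prod_m)
      # occasional currency cofactor pair
      if (stats::runif(1) < 0.4) {
        cof <- sample(currency, 2)
        if (!(cof[1] %in% names(subs))) subs <- c(subs, stats::setNames(1, cof[1]))
        if (!(cof[2] %in% names(prods))) prods <- c(prods, stats::setNames(1, cof[2]))
      }
      rev <- stats::runif(1) < config$reversibility_prob
      reactions[[rid]] <- reaction(rid, subs, prods, reversible = rev,
                                   pathways = pw_name)
      proteins[[pid]] <- protein(pid)
      add_link(pid, rid)
      if (!is.na(gap_j) && j == gap_j) {
        truth_gaps[[length(truth_gaps) + 1]] <-
          data.frame(reaction = rid, compartment = cc,
                     stringsAsFactors = FALSE)
        # enzyme left unannotated: the reaction resolves to {U}
      } else {
        annotate(pid, cc)
      }
    }
    if (p %in% irlr_pw) {
      rid <- sprintf("P%02d_RX", p)
      pid <- paste0("PR_", rid)
      other <- sample(setdiff(comps_avail, cc), 1)
      attach_at <- 2L  # consumes m2, produced by reaction 2
      reactions[[rid]] <- reaction(rid,
                                   stats::setNames(1, met(p, attach_at)),
                                   stats::setNames(1, sample(currency, 1)),
                                   reversible = FALSE, pathways = pw_name)
      proteins[[pid]] <- protein(pid)
      add_link(pid, rid)
      annotate(pid, cc)
      # second location: separate annotation row for the same protein
      truth_prot[[pid]] <- sort(c(cc, other))
      assoc[[length(assoc) + 1]] <-
        data.frame(protein = pid, term = leaf_term_for(other, "A"),
                   stringsAsFactors = FALSE)
      truth_irlrs[[length(truth_irlrs) + 1]] <-
        data.frame(reaction = rid, compartment = other,
                   stringsAsFactors = FALSE)
    }
  }
  # planted dead ends: producer in pathway p, circulation in a partner
  # pathway located in a different compartment
  for (k in seq_along(de_pw)) {
    p <- de_pw[k]
    cc <- pw_comp[p]
    partner <- which(pw_comp != cc)[ (k - 1) %% sum(pw_comp != cc) + 1 ]
    m_dead <- sprintf("DEAD_m%02d", k)
    rid <- sprintf("P%02d_RD%02d", p, k)
    pid <- paste0("PR_", rid)
    reactions[[rid]] <- reaction(rid, stats::setNames(1, met(p, 1)),
                                 stats::setNames(1, m_dead),
                                 reversible = FALSE,
                                 pathways = sprintf("pathway_%02d", p))
    proteins[[pid]] <- protein(pid)
    add_link(pid, rid)
    annotate(pid, cc)
    # circulate m_dead through two adjacent partner-chain reactions
    q <- partner; Lq <- lens[q]
    jq <- min(3L, Lq - 1L)
    rid_a <- sprintf("P%02d_R%02d", q, jq)
    rid_b <- sprintf("P%02d_R%02d", q, jq + 1L)
    reactions[[rid_a]]$products <- rbind(reactions[[rid_a]]$products,
                                         data.frame(metabolite = m_dead,
                                                    coef = 1))
    reactions[[rid_b]]$substrates <- rbind(reactions[[rid_b]]$substrates,
                                           data.frame(metabolite = m_dead,
                                                      coef = 1))
    truth_des[[length(truth_des) + 1]] <-
      data.frame(metabolite = m_dead, compartment = cc,
                 mode = "only-produced", stringsAsFactors = FALSE)
  }
  # extra unannotated enzymes beyond the planted gaps live in the
  # "isolated" pathway, excluded from every structural analysis
  n_rxn <- length(reactions)
  n_extra <- max(0L, round(config$unannotated_fraction * n_rxn) -
                   config$n_gaps)
  for (k in seq_len(n_extra)) {
    rid <- sprintf("ISO_R%02d", k)
    pid <- paste0("PR_", rid)
    reactions[[rid]] <- reaction(rid,
                                 stats::setNames(1, sprintf("ISO_m%02da", k)),
                                 stats::setNames(1, sprintf("ISO_m%02db", k)),
                                 reversible = FALSE, pathways = "isolated")
    proteins[[pid]] <- protein(pid)
    add_link(pid, rid)
  }
  net <- new_network(reactions, proteins, do.call(rbind, links))
  assoc <- if (length(assoc) > 0) do.call(rbind, assoc) else
    data.frame(protein = character(), term = character(),
               stringsAsFactors = FALSE)
  keywords <- if (length(keywords) > 0) do.call(rbind, keywords) else
    data.frame(protein = character(), compartment = character(),
               stringsAsFactors = FALSE)
  bindrec <- function(x, template) {
    if (length(x) > 0) do.call(rbind, x) else template
  }
  truth <- list(
    gaps = bindrec(truth_gaps, data.frame(reaction = character(),
                                          compartment = character(),
                                          stringsAsFactors = FALSE)),
    irlrs = bindrec(truth_irlrs, data.frame(reaction = character(),
                                            compartment = character(),
                                            stringsAsFactors = FALSE)),
    dead_ends = bindrec(truth_des, data.frame(metabolite = character(),
                                              compartment = character(),
                                              mode = character(),
                                              stringsAsFactors = FALSE)),
    protein_locations = truth_prot)
  sim <- list(network = net, assoc = assoc, keywords = keywords,
              ontology = mini_ontology(), target_map = default_target_map(),
              currency = currency, truth = truth, config = config)
  if (verify) verify_planted(sim)
  sim
}

#' Verify a simulated input set against the brute-force oracles
#'
#' Localizes the simulated network, then checks — at the pipeline stage
#' where each analysis runs — that the brute-force gap, IRLR and dead-end
#' scans recover exactly the planted structure, nothing more. Errors on
#' any incidental finding.
#' @keywords internal
verify_planted <- function(sim) {
  net <- localize_simulation(sim)
  got_gaps <- bf_gaps(net, sim$currency)
  want <- sim$truth$gaps
  if (!identical(
    sort(paste(got_gaps$reaction, got_gaps$compartment)),
    sort(paste(want$reaction, want$compartment)))) {
    stop("simulate_network: planted gaps not recovered exactly (",
         nrow(got_gaps), " found, ", nrow(want), " planted)", call. = FALSE)
  }
  # fill planted gaps directly from the truth table (not via fill_gaps)
  for (i in seq_len(nrow(want))) {
    net <- set_reaction_locations(net, want$reaction[i], want$compartment[i],
                                  "gap-filled")
  }
  got_irlrs <- bf_irlrs(net, sim$currency)
  want_i <- sim$truth$irlrs
  if (!identical(
    sort(paste(got_irlrs$reaction, got_irlrs$compartment)),
    sort(paste(want_i$reaction, want_i$compartment)))) {
    stop("simulate_network: planted IRLRs not recovered exactly (",
         nrow(got_irlrs), " found, ", nrow(want_i), " planted)",
         call. = FALSE)
  }
  for (i in seq_len(nrow(want_i))) {
    keep <- net$reactions[[want_i$reaction[i]]]$locations
    keep <- keep[keep$compartment != want_i$compartment[i], , drop = FALSE]
    net$reactions[[want_i$reaction[i]]]$locations <- keep
  }
  net <- reassign_uncertain(net)
  got_de <- bf_dead_ends(net, sim$currency)
  want_d <- sim$truth$dead_ends
  if (!identical(
    sort(paste(got_de$metabolite, got_de$compartment, got_de$mode)),
    sort(paste(want_d$metabolite, want_d$compartment, want_d$mode)))) {
    stop("simulate_network: planted dead ends not recovered exactly (",
         nrow(got_de), " found, ", nrow(want_d), " planted)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Localize a simulated input set
#'
#' Convenience wrapper running protein localization and reaction location
#' assignment on the output of [simulate_network()].
#'
#' @param sim Output of [simulate_network()].
#' @return A located `metnet` object.
#' @export
localize_simulation <- function(sim) {
  loc <- localize_proteins(sim$assoc, sim$keywords, sim$ontology,
                           sim$target_map)
  net <- set_protein_locations(sim$network, loc$assignments)
  assign_reaction_locations(net)
}
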