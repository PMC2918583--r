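# Shared fixture builders. Everything is generated in code; no data files.

# A well-formed three-reaction toy network: linear chain in one pathway,
# each reaction with one mitochondrial enzyme.
toy_network <- function() {
  rxns <- list(
    reaction("ra", c(A = 1), c(B = 1), pathways = "toy"),
    reaction("rb", c(B = 1), c(C = 1), pathways = "toy"),
    reaction("rc", c(C = 1), c(D = 1), pathways = "toy"))
  prots <- list(protein("p1", "M"), protein("p2", "M"), protein("p3", "M"))
  links <- data.frame(protein = c("p1", "p2", "p3"),
                      reaction = c("ra", "rb", "rc"), active = TRUE,
                      stringsAsFactors = FALSE)
  assign_reaction_locations(new_network(rxns, prots, links))
}

# Random undirected graph in the pathway_graph shape, for component oracles.
rand_component_graph <- function(n, p_edge = 0.06) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      metabolites = rep("", sum(keep)),
                      stringsAsFactors = FALSE)
  structure(list(pathway = "rand", compartment = "C", nodes = nodes,
                 edges = edges, currency = character()),
            class = "pathway_graph")
}

# Random ontology DAG: edges always point from higher to lower index, so
# term t_i can only have parents among t_1..t_{i-1}; a random subset of the
# shallow terms is designated as compartment targets.
rand_ontology <- function(n_terms = 30, p_edge = 0.15, n_targets = 4) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  lines <- "format-version: 1.2"
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i))
    if (i > 1) {
      parents <- which(stats::runif(i - 1) < p_edge)
      if (length(parents) == 0 && stats::runif(1) < 0.8) {
        parents <- sample(seq_len(i - 1), 1)
      }
      for (p in parents) {
        rel <- sample(c("is_a", "part_of"), 1)
        lines <- c(lines, if (rel == "is_a") paste0("is_a: ", ids[p]) else
          paste0("relationship: part_of ", ids[p]))
      }
    }
  }
  onto <- read_obo(lines, namespace = NULL)
  target_ids <- sample(ids[seq_len(min(10, n_terms))], n_targets)
  target_map <- stats::setNames(
    sample(setdiff(compartments()$code, "U"), n_targets), target_ids)
  list(ontology = onto, target_map = target_map)
}

# Independent backtracking oracle: exhaustive ancestor closure intersected
# with the target map.
oracle_backtrack <- function(term_id, ontology, target_map) {
  anc <- compartnet:::bf_ancestors(term_id, ontology)
  hits <- sort(unique(unname(target_map[intersect(anc, names(target_map))])))
  if (length(hits) == 0) "U" else hits
}

canon_pairs <- function(df, cols) {
  sort(do.call(paste, df[cols]))
}
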