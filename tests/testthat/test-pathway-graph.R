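test_that("chain topology links consecutive reactions through main metabolites", {
  net <- toy_network()
  g <- build_pathway_graph(net, "toy", "M", currency = character())
  expect_identical(nrow(g$edges), 2L)
  expect_length(g$components, 1)
  # declaring the shared metabolite B as currency cuts the chain
  g2 <- build_pathway_graph(net, "toy", "M", currency = "B")
  expect_identical(nrow(g2$edges), 1L)
  expect_length(g2$components, 2)
  expect_error(build_pathway_graph(net, "nope", "M"), "unknown pathway")
})

test_that("the flow edge rule does not join parallel consumers", {
  # two irreversible reactions consuming the same substrate share A but
  # neither produces it: no edge under the flow rule, one under
  # co-occurrence
  rxns <- list(reaction("c1", c(A = 1), c(B = 1), pathways = "p"),
               reaction("c2", c(A = 1), c(D = 1), pathways = "p"))
  prots <- list(protein("p1", "C"), protein("p2", "C"))
  links <- data.frame(protein = c("p1", "p2"), reaction = c("c1", "c2"),
                      active = TRUE)
  net <- assign_reaction_locations(new_network(rxns, prots, links))
  flow <- build_pathway_graph(net, "p", "C", currency = character())
  expect_identical(nrow(flow$edges), 0L)
  cooc <- build_pathway_graph(net, "p", "C", currency = character(),
                              edge_rule = "cooccurrence")
  expect_identical(nrow(cooc$edges), 1L)
  # making one reaction reversible restores flow
  net$reactions[["c1"]]$reversible <- TRUE
  flow2 <- build_pathway_graph(net, "p", "C", currency = character())
  expect_identical(nrow(flow2$edges), 1L)
})

test_that("components match reachability on random graphs and edge-free graphs", {
  edgeless <- structure(list(pathway = "p", compartment = "C",
                             nodes = c("a", "b", "c", "d"),
                             edges = data.frame(from = character(),
                                                to = character(),
                                                metabolites = character()),
                             currency = character()),
                        class = "pathway_graph")
  expect_length(graph_components(edgeless), 4)
  set.seed(99)
  for (i in 1:50) {
    g <- rand_component_graph(sample(5:50, 1))
    expect_identical(graph_components(g),
                     compartnet:::bf_components(g$nodes, g$edges),
                     info = paste("graph", i))
  }
})

test_that("graph construction is invariant to reaction input order and edges only merge components", {
  sim <- simulate_network(sim_config(seed = 5, n_pathways = 4, n_gaps = 1,
                                     n_irlrs = 1, n_dead_ends = 1))
  net <- localize_simulation(sim)
  pw <- names(pathway_index(net, exclude_isolated = TRUE))[1]
  cc <- net$reactions[[pathway_index(net)[[pw]][1]]]$locations$compartment[1]
  g <- build_pathway_graph(net, pw, cc, sim$currency)
  net2 <- net
  net2$reactions <- rev(net2$reactions)
  g2 <- build_pathway_graph(net2, pw, cc, sim$currency)
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$components, g2$components)
  # node count equals the sum of component sizes
  expect_identical(length(g$nodes), sum(lengths(g$components)))
  # adding any edge never increases the component count
  if (length(g$nodes) >= 2) {
    extra <- g
    pick <- sample(g$nodes, 2)
    extra$edges <- rbind(extra$edges,
                         data.frame(from = pick[1], to = pick[2],
                                    metabolites = "x"))
    expect_lte(length(graph_components(extra)), length(g$components))
  }
})

test_that("component metabolite lists are the union over member reactions", {
  rxns <- list(reaction("r1", c(A = 1, ATP = 1), c(B = 1), pathways = "p"),
               reaction("r2", c(B = 1), c(D = 1), pathways = "p"))
  prots <- list(protein("p1", "M"), protein("p2", "M"))
  links <- data.frame(protein = c("p1", "p2"), reaction = c("r1", "r2"),
                      active = TRUE)
  net <- assign_reaction_locations(new_network(rxns, prots, links))
  g <- build_pathway_graph(net, "p", "M")
  expect_length(g$components, 1)
  expect_identical(component_metabolites(net, g, 1), c("A", "B", "D"))
  g2 <- build_pathway_graph(net, "p", "M", currency = c("ATP", "B"))
  # B currency: two singleton components
  expect_identical(component_metabolites(net, g2, 1), "A")
})

test_that("path search crosses compartments only through transports", {
  net <- demo_path_network()
  # forced two-step route: transport then conversion
  p <- find_path(net, c("L-Serine", "C"), c("Glycine", "M"))
  expect_identical(p$reaction, c("T_L-Serine_C_M", "S2"))
  expect_identical(p$compartment, c("M", "M"))
  # heme-shaped route alternates C, M, C, M
  full <- find_path(net, c("glycolytic-precursor", "C"), c("Heme", "M"))
  expect_false(is.null(full))
  visited <- rle(full$compartment)$values
  expect_identical(visited, c("C", "M", "C", "M"))
  expect_identical(full$metabolite[nrow(full)], "Heme")
  # unreachable without a transport for the metabolite
  net2 <- net
  net2$transports <- list()
  expect_null(find_path(net2, c("L-Serine", "C"), c("Glycine", "M")))
  # endpoints must exist in the stated compartment
  expect_error(find_path(net, c("Heme", "C"), c("Glycine", "M")),
               "does not occur")
})
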