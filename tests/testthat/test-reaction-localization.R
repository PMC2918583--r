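test_that("reaction locations are the union of enzyme locations with U dropped", {
  net <- demo_relationship_network()
  locs <- function(r) sort(net$reactions[[r]]$locations$compartment)
  # cytosolic + mitochondrial isoenzymes
  expect_identical(locs("R00342"), c("C", "M"))
  # one enzyme with two locations
  expect_identical(locs("R03631"), c("ER", "X"))
  # non-enzymatic reaction defaults to uncertain
  rxns <- list(reaction("spont", c(A = 1), c(B = 1), pathways = "p"))
  net2 <- assign_reaction_locations(new_network(rxns))
  expect_identical(net2$reactions[["spont"]]$locations$compartment, "U")
  expect_identical(net2$reactions[["spont"]]$locations$provenance,
                   "default-uncertain")
})

test_that("assigned locations are always a subset of the enzymes' union", {
  sim <- simulate_network(sim_config(seed = 3, n_pathways = 5, n_gaps = 1,
                                     n_irlrs = 2, n_dead_ends = 1))
  net <- localize_simulation(sim)
  for (rid in names(net$reactions)) {
    pids <- compartnet:::reaction_proteins(net, rid)
    if (length(pids) == 0) next
    pool <- unique(unlist(lapply(pids, function(p) {
      net$proteins[[p]]$locations$compartment
    })))
    got <- net$reactions[[rid]]$locations$compartment
    expect_true(all(got %in% pool), info = rid)
    if (!("U" %in% pool) || length(setdiff(pool, "U")) == 0) {
      expect_setequal(got, pool)
    }
  }
})

test_that("relationship types a-d and unknown follow the location-set shapes", {
  net <- demo_relationship_network()
  expect_identical(classify_reaction(net, "R00256"), "b")
  expect_identical(classify_reaction(net, "R00342"), "c")
  expect_identical(classify_reaction(net, "R05987"), "d")
  expect_identical(classify_reaction(net, "RE3139"), "c")
  expect_identical(classify_reaction(net, "R02204"), "a")
  # all-uncertain enzymes cannot be classified
  rxns <- list(reaction("r1", c(A = 1), c(B = 1), pathways = "p"))
  prots <- list(protein("u1"), protein("u2"))
  links <- data.frame(protein = c("u1", "u2"), reaction = "r1", active = TRUE)
  netu <- assign_reaction_locations(new_network(rxns, prots, links))
  expect_identical(classify_reaction(netu, "r1"), "unknown")
  # classification is invariant under protein order
  net2 <- net
  net2$links <- net2$links[rev(seq_len(nrow(net2$links))), ]
  expect_identical(classify_reaction(net2, "R05987"), "d")
  expect_identical(classify_reaction(net2, "R00342"), "c")
})

test_that("type counts match a literal brute-force classifier", {
  # brute force: enumerate informative location sets and apply the
  # definitions directly
  brute <- function(net, rid) {
    pids <- compartnet:::reaction_proteins(net, rid)
    sets <- lapply(pids, function(p) {
      sort(unique(net$proteins[[p]]$locations$compartment))
    })
    sets <- Filter(function(s) !identical(s, "U"), sets)
    if (length(sets) == 0) return("unknown")
    if (length(sets) == 1) return("a")
    uniq <- unique(sets)
    if (length(uniq) == 1) return("b")
    all_disjoint <- TRUE
    for (i in seq_along(uniq)) for (j in seq_len(i - 1)) {
      if (length(intersect(uniq[[i]], uniq[[j]])) > 0) all_disjoint <- FALSE
    }
    if (all_disjoint) "c" else "d"
  }
  net <- demo_relationship_network()
  cls <- classify_reactions(net)
  for (i in seq_len(nrow(cls))) {
    expect_identical(cls$type[i], brute(net, cls$reaction[i]),
                     info = cls$reaction[i])
  }
})

test_that("complementary groups aggregate reactions sharing a partition", {
  net <- demo_relationship_network()
  groups <- find_complementary_groups(net)
  expect_length(groups, 2)
  g3139 <- Filter(function(g) "RE3139" %in% g$reactions, groups)[[1]]
  sizes <- sort(vapply(g3139$parts, length, 0L))
  expect_identical(sizes, c(1L, 3L))
  # two reactions catalyzed by the same C-vs-M pair collapse to one group
  rxns <- list(reaction("q1", c(A = 1), c(B = 1), pathways = "p"),
               reaction("q2", c(B = 1), c(D = 1), pathways = "p"))
  prots <- list(protein("pc", "C"), protein("pm", "M"))
  links <- data.frame(protein = c("pc", "pm", "pc", "pm"),
                      reaction = c("q1", "q1", "q2", "q2"), active = TRUE)
  net2 <- assign_reaction_locations(new_network(rxns, prots, links))
  g2 <- find_complementary_groups(net2)
  expect_length(g2, 1)
  expect_setequal(g2[[1]]$reactions, c("q1", "q2"))
  # no type-c reactions, no groups
  expect_length(find_complementary_groups(toy_network()), 0)
})

test_that("type-c resolution deactivates the wrong part's links", {
  net <- demo_relationship_network()
  g <- Filter(function(g) "RE3139" %in% g$reactions,
              find_complementary_groups(net))[[1]]
  res <- resolve_type_c(net, g, "X", citation = "peroxisomal VLCFA oxidation")
  expect_identical(nrow(res$deletions), 3L)
  expect_setequal(res$deletions$protein, c("ACAA2", "HADHA", "HADHB"))
  expect_identical(
    res$network$reactions[["RE3139"]]$locations$compartment, "X")
  expect_identical(
    res$network$reactions[["RE3139"]]$locations$provenance, "curated")
  # re-running classification yields a (single informative protein left)
  expect_identical(classify_reaction(res$network, "RE3139"), "a")
  # a verdict outside every part is rejected
  expect_error(resolve_type_c(net, g, "N"), "not among any part")
  # deletions scale with group size: 2 reactions x 1 wrong protein
  net2 <- assign_reaction_locations(new_network(
    list(reaction("q1", c(A = 1), c(B = 1), pathways = "p"),
         reaction("q2", c(B = 1), c(D = 1), pathways = "p")),
    list(protein("pc", "C"), protein("pm", "M")),
    data.frame(protein = c("pc", "pm", "pc", "pm"),
               reaction = c("q1", "q1", "q2", "q2"), active = TRUE)))
  g2 <- find_complementary_groups(net2)[[1]]
  res2 <- resolve_type_c(net2, g2, "M")
  expect_identical(nrow(res2$deletions), 2L)
})
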