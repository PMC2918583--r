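# small fixture: metabolites spread over C, M, X with known roles
transport_fixture <- function() {
  rxns <- list(
    reaction("m1", c(A = 1), c(B = 1), pathways = "p1"),     # M
    reaction("m2", c(B = 1), c(A = 1), pathways = "p1"),     # M (cycle)
    reaction("c1", c(A = 1), c(E = 1), pathways = "p2"),     # C
    reaction("c2", c(E = 1), c(A = 1), pathways = "p2"),     # C (cycle)
    reaction("x1", c(F = 1), c(G = 1), pathways = "p3"),     # X
    reaction("x2", c(G = 1), c(F = 1), pathways = "p3"))     # X (cycle)
  prots <- list(protein("pm", "M"), protein("pm2", "M"), protein("pc", "C"),
                protein("pc2", "C"), protein("px", "X"), protein("px2", "X"))
  links <- data.frame(protein = c("pm", "pm2", "pc", "pc2", "px", "px2"),
                      reaction = c("m1", "m2", "c1", "c2", "x1", "x2"),
                      active = TRUE)
  assign_reaction_locations(new_network(rxns, prots, links))
}

test_that("uncertain-only reactions move to the cytosol, co-occurring U is dropped", {
  rxns <- list(reaction("u1", c(A = 1), c(B = 1), pathways = "p"),
               reaction("u2", c(B = 1), c(D = 1), pathways = "p"))
  net <- assign_reaction_locations(new_network(rxns))
  net$reactions[["u2"]]$locations <- rbind(
    net$reactions[["u2"]]$locations,
    data.frame(compartment = "M", provenance = "curated"))
  out <- reassign_uncertain(net)
  l1 <- out$reactions[["u1"]]$locations
  expect_identical(l1$compartment, "C")
  expect_identical(l1$provenance, "cytosol-default")
  expect_identical(out$reactions[["u2"]]$locations$compartment, "M")
  # a network without U reactions is unchanged
  net2 <- transport_fixture()
  expect_identical(reassign_uncertain(net2), net2)
})

test_that("reference import applies the score rules row by row", {
  net <- transport_fixture()  # A in C and M; E in C; F,G in X only
  ref <- data.frame(
    metabolite = c("A", "ZZ", "A", "E", "QQ", "A", "B", "F", "WW",
                   "A", "G", "E"),
    from       = c("C", "C", "C", "C", "C", "C", "C", "C", "C",
                   "C", "X", "C"),
    to         = c("M", "M", "M", "M", "M", "M", "M", "X", "M",
                   "M", "C", "M"),
    score      = c("3", "3", "2", "2", "2", "1", "0", "annotation",
                   "annotation", "3", "2", "1"),
    proteins   = "",
    reversible = TRUE,
    stringsAsFactors = FALSE)
  res <- import_reference_transports(net, ref)
  # expectations per rule: score 3 needs mere existence; score 2 needs
  # presence in both compartments; <2 always rejected; annotation behaves
  # like score 3
  expect_length(res$accepted, 4)     # rows 1, 3, 8, 10
  expect_identical(nrow(res$rejections), 8L)
  expect_identical(res$rejections$reason[res$rejections$metabolite == "ZZ"],
                   "metabolite absent from network")
  expect_identical(res$rejections$reason[res$rejections$metabolite == "E"],
                   c("metabolite absent from compartment M",
                     "confidence score below 2"))
  expect_true(all(c("1", "0") %in%
                    res$rejections$score[res$rejections$reason ==
                                           "confidence score below 2"]))
  # G exists only in X: the score-2 X->C row is rejected
  expect_true("G" %in% res$rejections$metabolite)
  # monotone in score: everything accepted at score 2 would pass at 3
  srcs <- vapply(res$accepted, `[[`, "", "source")
  expect_setequal(unique(srcs), c("reference-score3", "reference-score2",
                                  "transporter-annotation"))
  expect_error(import_reference_transports(
    net, data.frame(metabolite = "A", from = "C", to = "ZZ", score = "3",
                    proteins = "", reversible = TRUE)),
    "unknown compartment")
})

test_that("dead ends are only-produced, only-consumed or sole participants", {
  net <- transport_fixture()
  # closed cycles: no dead ends at all
  expect_identical(nrow(find_dead_ends(net, currency = character())), 0L)
  # attach a producer of D in M: D only-produced; A stays balanced
  net$reactions[["m3"]] <- reaction("m3", c(B = 1), c(D = 1),
                                    pathways = "p1")
  net$proteins[["pm3"]] <- protein("pm3", "M")
  net$links <- rbind(net$links, data.frame(protein = "pm3", reaction = "m3",
                                           active = TRUE))
  net <- assign_reaction_locations(net)
  de <- find_dead_ends(net, currency = character())
  expect_identical(de$metabolite, "D")
  expect_identical(de$mode, "only-produced")
  # a reversible sole reaction marks its metabolite as sole-participant
  net$reactions[["m3"]]$reversible <- TRUE
  de2 <- find_dead_ends(net, currency = character())
  expect_identical(de2$mode, "sole-participant")
  expect_identical(nrow(find_dead_ends(net, currency = character(),
                                       sole_participant = FALSE)), 0L)
  # currency metabolites are exempt
  expect_identical(nrow(find_dead_ends(net, currency = "D")), 0L)
  # agreement with the direct tally
  sim <- simulate_network(sim_config(seed = 31, n_pathways = 5, n_gaps = 0,
                                     n_irlrs = 0, n_dead_ends = 2))
  lnet <- reassign_uncertain(localize_simulation(sim))
  expect_identical(find_dead_ends(lnet, sim$currency),
                   compartnet:::bf_dead_ends(lnet, sim$currency),
                   ignore_attr = TRUE)
})

test_that("inferred transports bridge through the cytosol and clear the dead ends", {
  net <- transport_fixture()
  # D produced in M, also circulating in C
  net$reactions[["m3"]] <- reaction("m3", c(B = 1), c(D = 1), pathways = "p1")
  net$proteins[["pm3"]] <- protein("pm3", "M")
  net$reactions[["c3"]] <- reaction("c3", c(E = 1), c(D = 1), pathways = "p2")
  net$reactions[["c4"]] <- reaction("c4", c(D = 1), c(E = 1), pathways = "p2")
  net$proteins[["pc3"]] <- protein("pc3", "C")
  net$proteins[["pc4"]] <- protein("pc4", "C")
  net$links <- rbind(net$links,
                     data.frame(protein = c("pm3", "pc3", "pc4"),
                                reaction = c("m3", "c3", "c4"),
                                active = TRUE))
  net <- assign_reaction_locations(net)
  de <- find_dead_ends(net, currency = character())
  expect_identical(paste(de$metabolite, de$compartment), "D M")
  inf <- infer_transports(net, de)
  expect_length(inf$transports, 1)
  tr <- inf$transports[[1]]
  expect_identical(tr$metabolite, "D")
  expect_setequal(c(tr$from, tr$to), c("C", "M"))
  expect_true(tr$reversible)
  expect_identical(tr$source, "dead-end-inferred")
  net$transports <- inf$transports
  # contract: no metabolite present in two compartments stays dead-ended
  after <- find_dead_ends(net, currency = character())
  expect_identical(nrow(after), 0L)
  # a dead end with no second compartment yields nothing but is logged
  net2 <- transport_fixture()
  net2$reactions[["x3"]] <- reaction("x3", c(G = 1), c(H = 1),
                                     pathways = "p3")
  net2$proteins[["px3"]] <- protein("px3", "X")
  net2$links <- rbind(net2$links, data.frame(protein = "px3",
                                             reaction = "x3", active = TRUE))
  net2 <- assign_reaction_locations(net2)
  de2 <- find_dead_ends(net2, currency = character())
  inf2 <- infer_transports(net2, de2)
  expect_length(inf2$transports, 0)
  expect_identical(inf2$skipped$metabolite, "H")
  # a cytosolic dead end connects to every compartment holding the
  # metabolite
  net3 <- transport_fixture()
  net3$reactions[["c5"]] <- reaction("c5", c(E = 1), c(F = 1),
                                     pathways = "p2")
  net3$reactions[["m4"]] <- reaction("m4", c(F = 1), c(B = 1),
                                     pathways = "p1")
  net3$reactions[["m5"]] <- reaction("m5", c(B = 1), c(F = 1),
                                     pathways = "p1")
  net3$proteins[["pc5"]] <- protein("pc5", "C")
  net3$proteins[["pm4"]] <- protein("pm4", "M")
  net3$proteins[["pm5"]] <- protein("pm5", "M")
  net3$links <- rbind(net3$links,
                      data.frame(protein = c("pc5", "pm4", "pm5"),
                                 reaction = c("c5", "m4", "m5"),
                                 active = TRUE))
  net3 <- assign_reaction_locations(net3)
  de3 <- find_dead_ends(net3, currency = character())
  # F is only-produced in C, present in X (cycle) and M (cycle)
  expect_true("F C" %in% paste(de3$metabolite, de3$compartment))
  inf3 <- infer_transports(net3, de3)
  pairs <- vapply(inf3$transports, function(t) paste(t$metabolite,
                                                     t$from, t$to), "")
  expect_true(all(c("F C M", "F C X") %in% pairs))
})

test_that("deduplication keeps one transport per pair with source precedence", {
  t1 <- compartnet:::new_transport("A", "C", "M", TRUE, "dead-end-inferred")
  t2 <- compartnet:::new_transport("A", "M", "C", TRUE, "reference-score3")
  t3 <- compartnet:::new_transport("B", "C", "M", TRUE, "reference-score2")
  res <- dedup_transports(list(t1, t2, t3))
  expect_length(res$transports, 2)
  expect_identical(res$duplicates, 1L)
  srcs <- stats::setNames(vapply(res$transports, `[[`, "", "source"),
                          vapply(res$transports, `[[`, "", "metabolite"))
  expect_identical(unname(srcs["A"]), "reference-score3")
  expect_identical(dedup_transports(list())$transports, list())
  # ids are deterministic in the unordered pair
  expect_identical(t1$id, t2$id)
})
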