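#' Reaction-location distribution of a network
#'
#' Counts reaction-location relationships per compartment (a reaction
#' located in k compartments contributes k counts).
#'
#' @param net A `metnet` object.
#' @return Named integer vector over the nine compartment codes.
#' @export
location_distribution <- function(net) {
  codes <- unlist(lapply(net$reactions, function(r) r$locations$compartment),
                  use.names = FALSE)
  tab <- table(factor(codes, levels = compartment_codes()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Pathway-by-compartment location matrix
#'
#' For each pathway, the number of member reactions located in each
#' compartment together with the fraction of the pathway it represents —
#' the patchiness view of a localized network.
#'
#' @param net A `metnet` object.
#' @return Data frame (`pathway`, `compartment`, `n`, `fraction`).
#' @export
pathway_location_matrix <- function(net) {
  idx <- pathway_index(net)
  rows <- list()
  for (pw in names(idx)) {
    total <- length(idx[[pw]])
    for (cc in compartment_codes()) {
      n <- sum(vapply(idx[[pw]], function(r) {
        cc %in% reaction_location_codes(net, r)
      }, logical(1)))
      rows[[length(rows) + 1]] <- data.frame(
        pathway = pw, compartment = cc, n = n, fraction = n / total,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full compartmentalization pipeline
#'
#' Stages execute in a fixed order: protein and reaction localization,
#' complementary-group (type-c) resolution, gap identification and
#' filling, IRLR identification and revision, curation edits, uncertain-to-
#' cytosol reassignment, reference-transport import, and dead-end-driven
#' transport inference. A location-distribution snapshot is retained after
#' each revision stage, forming the stage-by-compartment matrix.
#'
#' @param net A `metnet` object (proteins may be unlocated).
#' @param assoc,keywords,ontology,target_map Protein annotation inputs; if
#'   `assoc` is `NULL`, proteins are assumed to carry locations already.
#' @param currency Currency metabolite ids.
#' @param typec_verdicts Optional data frame (`reaction`, `compartment`,
#'   `citation`): a verdict applies to the complementary group containing
#'   the named reaction.
#' @param gap_evidence,irlr_evidence,edits Optional evidence/edit tables
#'   (see [fill_gaps()], [decide_irlrs()], [apply_edits()]).
#' @param reference_transports Optional reference transport table (see
#'   [import_reference_transports()]).
#' @param irlr_scope,edge_rule,dead_end_mode,sole_participant Analysis
#'   variants, passed through.
#' @param stop_after Optional stage name (`"localize"`, `"typec"`,
#'   `"gaps"`, `"irlr"`, `"curation"`, `"transport"`): halt the pipeline
#'   early; later snapshots are absent from the stage matrix.
#' @return List with `network`, `stage_matrix` (compartment x stage),
#'   `classification`, `complementary_groups`, `typec_deletions`, `gaps`,
#'   `gap_counts`, `irlrs`, `irlr_counts`, `curation_log`, `dead_ends`,
#'   `transport_rejections`, `transports_duplicates` and `summary` (named
#'   numeric vector of headline counts).
#' @export
run_pipeline <- function(net, assoc = NULL, keywords = NULL, ontology = NULL,
                         target_map = default_target_map(),
                         currency = default_currency(),
                         typec_verdicts = NULL, gap_evidence = NULL,
                         irlr_evidence = NULL, edits = NULL,
                         reference_transports = NULL,
                         irlr_scope = "all", edge_rule = "flow",
                         dead_end_mode = "network", sole_participant = TRUE,
                         stop_after = NULL) {
  out <- list()
  halted <- function(stage) {
    !is.null(stop_after) && stop_after == stage
  }
  # -- localization ----------------------------------------------------
  if (!is.null(assoc)) {
    if (is.null(keywords)) {
      keywords <- data.frame(protein = character(), compartment = character(),
                             stringsAsFactors = FALSE)
    }
    loc <- localize_proteins(assoc, keywords, ontology, target_map)
    net <- set_protein_locations(net, loc$assignments)
    out$protein_summary <- loc$summary
  }
  net <- assign_reaction_locations(net)
  stages <- list(original = location_distribution(net))
  out$classification <- classify_reactions(net)
  if (halted("localize")) {
    return(finish_pipeline(out, net, stages))
  }
  # -- type-c resolution ----------------------------------------------
  groups <- find_complementary_groups(net)
  out$complementary_groups <- groups
  deletions <- list()
  if (!is.null(typec_verdicts)) {
    for (i in seq_len(nrow(typec_verdicts))) {
      hit <- Filter(function(g) typec_verdicts$reaction[i] %in% g$reactions,
                    groups)
      for (g in hit) {
        res <- resolve_type_c(net, g, typec_verdicts$compartment[i],
                              typec_verdicts$citation[i])
        net <- res$network
        deletions[[length(deletions) + 1]] <- res$deletions
      }
    }
  }
  out$typec_deletions <- if (length(deletions) > 0) {
    do.call(rbind, deletions)
  } else {
    data.frame(protein = character(), reaction = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  stages$`type-c` <- location_distribution(net)
  if (halted("typec")) return(finish_pipeline(out, net, stages))
  # -- gap filling -----------------------------------------------------
  gaps <- identify_gaps(net, currency, edge_rule)
  gf <- fill_gaps(net, gaps, gap_evidence)
  net <- gf$network
  out$gaps <- gf$gaps
  out$gap_counts <- gf$counts
  stages$`gap-filling` <- location_distribution(net)
  if (halted("gaps")) return(finish_pipeline(out, net, stages))
  # -- IRLR revision (graphs re-derived after filling) -----------------
  irlrs <- identify_irlrs(net, currency, irlr_scope, edge_rule)
  ir <- decide_irlrs(net, irlrs, irlr_evidence)
  net <- ir$network
  out$irlrs <- ir$irlrs
  out$irlr_counts <- ir$counts
  stages$irlr <- location_distribution(net)
  if (halted("irlr")) return(finish_pipeline(out, net, stages))
  # -- literature-based curation --------------------------------------
  if (!is.null(edits)) {
    cu <- apply_edits(net, edits)
    net <- cu$network
    out$curation_log <- cu$log
  } else {
    out$curation_log <- data.frame()
  }
  stages$curated <- location_distribution(net)
  if (halted("curation")) return(finish_pipeline(out, net, stages))
  # -- transport -------------------------------------------------------
  net <- reassign_uncertain(net)
  accepted <- list()
  if (!is.null(reference_transports)) {
    imp <- import_reference_transports(net, reference_transports)
    accepted <- imp$accepted
    out$transport_rejections <- imp$rejections
  } else {
    out$transport_rejections <- data.frame()
  }
  net$transports <- dedup_transports(accepted)$transports
  de <- find_dead_ends(net, currency, dead_end_mode, sole_participant)
  out$dead_ends <- de
  inf <- infer_transports(net, de)
  all_tr <- dedup_transports(c(net$transports, inf$transports))
  net$transports <- all_tr$transports
  out$transports_duplicates <- all_tr$duplicates
  out$dead_ends_skipped <- inf$skipped
  stages$transport <- location_distribution(net)
  finish_pipeline(out, net, stages)
}

#' @keywords internal
finish_pipeline <- function(out, net, stages) {
  out$network <- net
  mat <- do.call(cbind, stages)
  colnames(mat) <- names(stages)
  out$stage_matrix <- mat
  counts <- c(
    reactions = length(net$reactions),
    located_relationships = sum(location_distribution(net)[
      setdiff(compartment_codes(), "U")]),
    uncertain = unname(location_distribution(net)["U"]),
    gaps = if (is.null(out$gaps)) NA_real_ else nrow(out$gaps),
    gaps_filled = if (is.null(out$gap_counts)) NA_real_ else
      sum(out$gap_counts[c("auto-filled", "evidence-filled")]),
    irlrs = if (is.null(out$irlrs)) NA_real_ else nrow(out$irlrs),
    irlrs_removed = if (is.null(out$irlr_counts)) NA_real_ else
      sum(out$irlr_counts[c("remove", "remove-bad-link")]),
    dead_ends = if (is.null(out$dead_ends)) NA_real_ else
      nrow(out$dead_ends),
    transports = length(net$transports))
  out$summary <- counts
  out
}

#' Write the full output file set of a pipeline run
#'
#' Network tables, finding reports (gaps, IRLRs, dead ends, deletions,
#' curation log), the stage-by-compartment matrix, the
#' pathway-by-compartment matrix, and an SBML Level 3 export.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_network_tables(result$network, outdir)
  w <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$gaps, "gaps.tsv")
  w(result$irlrs, "irlrs.tsv")
  w(result$dead_ends, "dead_ends.tsv")
  w(result$typec_deletions, "typec_deletions.tsv")
  w(result$curation_log, "curation_log.tsv")
  w(result$classification, "classification.tsv")
  sm <- as.data.frame(result$stage_matrix)
  sm <- cbind(compartment = rownames(sm), sm)
  w(sm, "stage_matrix.tsv")
  w(pathway_location_matrix(result$network), "pathway_matrix.tsv")
  write_sbml(result$network, file.path(outdir, "network.sbml.xml"))
  summary <- data.frame(quantity = names(result$summary),
                        value = unname(result$summary),
                        stringsAsFactors = FALSE)
  w(summary, "summary.tsv")
  invisible(outdir)
}
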