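#' Sub-cellular compartments
#'
#' The network model uses eight real sub-cellular locations plus the
#' placeholder `U` ("uncertain") for proteins and reactions whose location
#' cannot be resolved. Each real compartment corresponds to one top-level
#' cellular-component ontology term; `U` is a fallback, never a target of
#' structural analysis.
#'
#' @return A data frame with columns `code`, `name` and `go_id` (empty for
#'   `U`), one row per compartment.
#' @examples
#' compartments()
#' @export
compartments <- function() {
  data.frame(
    code = c("E", "U", "N", "C", "ER", "GA", "X", "L", "M"),
    name = c("extracellular", "uncertain", "nucleus", "cytosol",
             "endoplasmic reticulum", "Golgi apparatus", "peroxisome",
             "lysosome", "mitochondrion"),
    go_id = c("GO:0005576", "", "GO:0005634", "GO:0005829", "GO:0005783",
              "GO:0005794", "GO:0005777", "GO:0005764", "GO:0005739"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
compartment_codes <- function(real_only = FALSE) {
  codes <- compartments()$code
  if (real_only) setdiff(codes, "U") else codes
}

#' Default map from ontology terms to compartments
#'
#' Maps the top-level cellular-component terms to compartment codes. The
#' plasma-membrane term is an additional entry mapped to the cytosol, so
#' membrane-annotated enzymes are treated as cytosolic; this is an entry in
#' the map rather than a special case of the backtracking algorithm, which
#' keeps backtracking generic for synthetic ontologies.
#'
#' @return Named character vector: names are ontology term ids, values are
#'   compartment codes.
#' @export
default_target_map <- function() {
  comp <- compartments()
  comp <- comp[comp$code != "U", ]
  m <- comp$code
  names(m) <- comp$go_id
  c(m, "GO:0005886" = "C") # plasma membrane -> cytosol
}

#' @keywords internal
check_compartment <- function(code, allow_u = TRUE) {
  ok <- compartment_codes(real_only = !allow_u)
  bad <- setdiff(code, ok)
  if (length(bad) > 0) {
    stop("unknown compartment code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(code)
}
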