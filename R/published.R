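#' The published strongest decision rules and the printed excerpt table
#'
#' `publishedRules()` returns the 20 strongest published rules for the
#' requested class as [Rule-class] objects, with the printed support,
#' strength and confirmation attached in a `printed` attribute data.frame.
#' `exampleTable()` loads the bundled 20-formulation excerpt of the
#' information system (raw f2 decision, not yet discretized).
#'
#' @param class 1 (profile preserved) or 2 (profile changed).
#' @return `publishedRules()`: list of [Rule-class]; `exampleTable()`: a
#'   [DecisionTable-class].
#' @export
publishedRules <- function(class = 1) {
  cond <- utils::read.csv(system.file("extdata", "published_rules_conditions.csv",
                                      package = "drsarules"))
  met <- utils::read.csv(system.file("extdata", "published_rules_metrics.csv",
                                     package = "drsarules"),
                         colClasses = c(strength = "character"))
  cond <- cond[cond$class == class, ]
  met <- met[met$class == class, ]
  type <- if (class == 1) "atleast" else "atmost"
  out <- lapply(met$rule, function(i) {
    cd <- cond[cond$rule == i, ]
    decisionRule(cd$attribute, cd$relation, cd$threshold, type, as.integer(class))
  })
  attr(out, "printed") <- met[, c("rule", "support", "strength", "confirmation")]
  out
}

#' @rdname publishedRules
#' @export
exampleTable <- function() {
  loadDecisionTable(
    system.file("extdata", "table2_formulations.csv", package = "drsarules"),
    readSchema(system.file("extdata", "table1_schema.csv", package = "drsarules")),
    decision = "f2", id = "formulation")
}
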