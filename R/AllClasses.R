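#' @import methods
NULL

#' DecisionTable: an ordinal information system
#'
#' An information system in the rough-set sense: a set of objects
#' (formulations) described by condition attributes, optionally labelled with
#' an ordinal decision class. Class 1 is by convention the best class and
#' larger labels are worse, so the upward union "at least class t" collects
#' the classes \eqn{1, \dots, t} and the downward union "at most class t"
#' collects \eqn{t, \dots, k}.
#'
#' The attribute metadata (`attrInfo`) records, per column of `values`:
#' * `name` — column name;
#' * `kind` — `"nominal"` or `"numeric"`; binary 0/1 indicators are numeric;
#' * `preference` — `"gain"` (larger is better), `"cost"` (smaller is
#'   better) or `"none"` (unknown; see [cloneGainCost()]);
#' * `source` — the original attribute a derived column descends from
#'   (binarization and gain/cost copies both keep track of their source);
#' * `domainType`/`domain` — `"set"` with an explicit value set, `"range"`
#'   with `c(min, max)` bounds, or `"free"`.
#'
#' @slot values data.frame of condition-attribute values, one row per object.
#' @slot decision integer vector of class labels (1 = best), or `integer(0)`
#'   when the decision has not yet been discretized.
#' @slot attrInfo data.frame of per-attribute metadata (see Details).
#' @slot metadata list; holds e.g. the raw decision column (`decisionRaw`,
#'   `decisionName`) before discretization, or generator ground truth.
#' @seealso [decisionTable()], [loadDecisionTable()], [discretizeDecision()]
#' @export
setClass("DecisionTable",
  slots = c(
    values = "data.frame",
    decision = "integer",
    attrInfo = "data.frame",
    metadata = "list"
  )
)

setValidity("DecisionTable", function(object) {
  msg <- character()
  v <- object@values
  ai <- object@attrInfo
  needed <- c("name", "kind", "preference", "source", "domainType", "domain")
  if (!all(needed %in% names(ai))) {
    return(paste("attrInfo must have columns", paste(needed, collapse = ", ")))
  }
  if (!identical(as.character(ai$name), colnames(v))) {
    msg <- c(msg, "attrInfo$name must match the columns of values, in order")
  }
  if (!all(ai$kind %in% c("nominal", "numeric"))) {
    msg <- c(msg, "attribute kind must be 'nominal' or 'numeric'")
  }
  if (!all(ai$preference %in% c("gain", "cost", "none"))) {
    msg <- c(msg, "attribute preference must be 'gain', 'cost' or 'none'")
  }
  if (length(object@decision)) {
    if (length(object@decision) != nrow(v)) {
      msg <- c(msg, "decision length must equal the number of objects")
    }
    if (anyNA(object@decision)) {
      msg <- c(msg, "missing decision labels are not allowed")
    } else if (any(object@decision < 1L)) {
      msg <- c(msg, "decision labels must be positive integers (1 = best)")
    }
  }
  if (anyDuplicated(rownames(v))) {
    msg <- c(msg, "duplicate object identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' DissolutionProfile: a cumulative dissolution curve
#'
#' Percent of label claim dissolved at each sampling time, the operand of the
#' f2 similarity factor. Times must be strictly increasing; a small overage
#' above 100% is tolerated (assays can exceed label claim slightly).
#'
#' @slot times numeric, strictly increasing sampling times (hours).
#' @slot dissolved numeric, percent dissolved at each time.
#' @seealso [dissolutionProfile()], [similarityFactorF2()]
#' @export
setClass("DissolutionProfile",
  slots = c(times = "numeric", dissolved = "numeric")
)

setValidity("DissolutionProfile", function(object) {
  msg <- character()
  if (length(object@times) < 1L) msg <- c(msg, "profile needs at least one sampling point")
  if (length(object@times) != length(object@dissolved)) {
    msg <- c(msg, "times and dissolved must have equal length")
  }
  if (length(object@times) > 1L && any(diff(object@times) <= 0)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (anyNA(object@dissolved) || any(object@dissolved < 0) ||
      any(object@dissolved > 110)) {
    msg <- c(msg, "dissolved values must lie in [0, 110] percent")
  }
  if (length(msg)) msg else TRUE
})

#' Rule: a monotonic decision rule E -> H
#'
#' A conjunction of elementary conditions over ordered condition attributes,
#' concluding membership in a union of decision classes. Relations are
#' restricted by attribute preference: `>=` on gain copies, `<=` on cost
#' copies, `=` on nominal/binary attributes.
#'
#' @slot conditions data.frame with columns `attribute`, `relation`
#'   (one of `">="`, `"<="`, `"="`), `threshold`.
#' @slot conclusionType `"atleast"` or `"atmost"` (upward/downward union).
#' @slot conclusionClass integer class index t of the union.
#' @slot support integer; objects matching the premise and in the union.
#' @slot strength numeric; support / number of objects.
#' @slot confidence numeric; support / number of premise matches.
#' @slot confirmation numeric; Bayesian confirmation of the rule.
#' @seealso [decisionRule()], [induceRules()], [ruleSupport()]
#' @export
setClass("Rule",
  slots = c(
    conditions = "data.frame",
    conclusionType = "character",
    conclusionClass = "integer",
    support = "integer",
    strength = "numeric",
    confidence = "numeric",
    confirmation = "numeric"
  ),
  prototype = prototype(
    support = NA_integer_, strength = NA_real_,
    confidence = NA_real_, confirmation = NA_real_
  )
)

setValidity("Rule", function(object) {
  msg <- character()
  cd <- object@conditions
  if (!all(c("attribute", "relation", "threshold") %in% names(cd))) {
    msg <- c(msg, "conditions must have columns attribute, relation, threshold")
  } else if (nrow(cd) && !all(cd$relation %in% c(">=", "<=", "=", ">", "<"))) {
    msg <- c(msg, "relations must be one of '>=', '<=', '=', '>', '<'")
  }
  if (!object@conclusionType %in% c("atleast", "atmost")) {
    msg <- c(msg, "conclusionType must be 'atleast' or 'atmost'")
  }
  if (length(msg)) msg else TRUE
})

#' RuleSet: rules induced for the unions of one decision table
#'
#' @slot rules list of [Rule-class] objects.
#' @slot nObjects integer; size of the inducing table (denominator of
#'   rule strength).
#' @slot info list; induction settings (consistency threshold, unions,
#'   confirmation measure).
#' @seealso [induceRules()]
#' @export
setClass("RuleSet",
  slots = c(rules = "list", nObjects = "integer", info = "list"),
  prototype = prototype(rules = list(), nObjects = 0L, info = list())
)

setValidity("RuleSet", function(object) {
  if (!all(vapply(object@rules, is, logical(1), "Rule"))) {
    "all elements of rules must be Rule objects"
  } else TRUE
})

#' RuleEnsemble: bagged rule sets for voting classification
#'
#' Produced by [vcBaggingTrain()]. Each bag holds the rules induced from one
#' (consistency-weighted) bootstrap sample; classification sums the strengths
#' of all satisfied rules per class union.
#'
#' @slot bags list of [RuleSet-class] objects.
#' @slot sampleIds list of integer vectors, the bootstrap sample behind each
#'   bag.
#' @slot majorityClass integer; training majority class, the default vote
#'   when no rule fires.
#' @slot classes integer vector of class labels seen in training.
#' @slot nTrain integer; training-set size.
#' @seealso [vcBaggingTrain()], [classify()]
#' @export
setClass("RuleEnsemble",
  slots = c(
    bags = "list", sampleIds = "list", majorityClass = "integer",
    classes = "integer", nTrain = "integer"
  )
)

setValidity("RuleEnsemble", function(object) {
  msg <- character()
  if (length(object@bags) < 1L) msg <- c(msg, "ensemble needs at least one bag")
  if (!all(vapply(object@bags, is, logical(1), "RuleSet"))) {
    msg <- c(msg, "bags must be RuleSet objects")
  }
  if (length(msg)) msg else TRUE
})

#' CVReport: repeated stratified cross-validation results
#'
#' @slot perFold data.frame with one row per (repeat, fold): test-set size,
#'   correctly and incorrectly classified counts.
#' @slot perRepeat data.frame with one row per repeat: total correct,
#'   incorrect, accuracy (%), macro- and micro-averaged precision (%).
#' @slot settings list of the CV configuration (k, repeats, bags, seed, ...).
#' @seealso [crossValidate()]
#' @export
setClass("CVReport",
  slots = c(perFold = "data.frame", perRepeat = "data.frame", settings = "list")
)

setValidity("CVReport", function(object) {
  pf <- object@perFold
  if (!all(c("repeatIdx", "fold", "n", "correct", "incorrect") %in% names(pf))) {
    return("perFold must have columns repeatIdx, fold, n, correct, incorrect")
  }
  if (nrow(pf) && any(pf$correct + pf$incorrect != pf$n)) {
    return("correct + incorrect must equal the fold size")
  }
  TRUE
})
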