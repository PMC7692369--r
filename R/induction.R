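#' Construct a decision rule
#'
#' @param attributes character vector of attribute names (two-copy column
#'   names, or original names which are resolved through the attribute
#'   `source` map when matched against a table).
#' @param relations character vector of `">="`, `"<="` or `"="`.
#' @param thresholds numeric vector of condition thresholds.
#' @param type conclusion union direction, `"atleast"` or `"atmost"`.
#' @param class conclusion class index t.
#' @return a [Rule-class] (metrics unset; see [scoreRule()]).
#' @examples
#' r <- decisionRule("hardness", ">=", 42.4, "atleast", 1)
#' @export
decisionRule <- function(attributes = character(0), relations = character(0),
                         thresholds = numeric(0),
                         type = c("atleast", "atmost"), class = 1L) {
  type <- match.arg(type)
  new("Rule",
      conditions = data.frame(attribute = as.character(attributes),
                              relation = as.character(relations),
                              threshold = as.numeric(thresholds),
                              stringsAsFactors = FALSE),
      conclusionType = type, conclusionClass = as.integer(class))
}

# map a condition attribute to a column of the table: exact column name
# first, then source lookup (gain/cost copies and binarized indicators
# share values with their source, so the first match is sufficient)
resolveColumn <- function(attr, table) {
  cn <- colnames(table@values)
  j <- match(attr, cn)
  if (!is.na(j)) return(j)
  j <- which(table@attrInfo$source == attr)
  if (length(j)) return(j[1])
  stop("attribute '", attr, "' not found in the table")
}

#' Which objects satisfy a rule's premise
#'
#' @param rule a [Rule-class].
#' @param table a [DecisionTable-class].
#' @return logical vector over the table's objects.
#' @export
premiseMatches <- function(rule, table) {
  out <- rep(TRUE, nrow(table@values))
  cd <- rule@conditions
  for (i in seq_len(nrow(cd))) {
    v <- table@values[[resolveColumn(cd$attribute[i], table)]]
    out <- out & switch(cd$relation[i],
      ">=" = v >= cd$threshold[i],
      "<=" = v <= cd$threshold[i],
      "="  = v == cd$threshold[i],
      ">"  = v > cd$threshold[i],
      "<"  = v < cd$threshold[i],
      stop("unknown relation ", cd$relation[i]))
  }
  out
}

ruleMembership <- function(rule, table) {
  unionMembership(table@decision, rule@conclusionType, rule@conclusionClass)
}

#' Rule support, strength and confidence
#'
#' Support is the number of objects matching every elementary condition of
#' the premise *and* belonging to the conclusion union; strength is support
#' divided by the number of objects in the table; confidence is support
#' divided by the number of premise matches.
#'
#' @param rule a [Rule-class].
#' @param table a [DecisionTable-class] with a discretized decision.
#' @return `ruleSupport()`: integer count; `ruleStrength()`,
#'   `ruleConfidence()`: fractions.
#' @export
ruleSupport <- function(rule, table) {
  sum(premiseMatches(rule, table) & ruleMembership(rule, table))
}

#' @rdname ruleSupport
#' @export
ruleStrength <- function(rule, table) {
  if (nrow(table@values) == 0L) stop("empty table")
  ruleSupport(rule, table) / nrow(table@values)
}

#' @rdname ruleSupport
#' @export
ruleConfidence <- function(rule, table) {
  m <- premiseMatches(rule, table)
  if (!sum(m)) return(NA_real_)
  sum(m & ruleMembership(rule, table)) / sum(m)
}

#' Truncate rule strength for display
#'
#' Strengths are printed truncated (not rounded) to four decimals, the
#' convention of the published rule tables: support 32 of 180 displays as
#' 0.1777. A small epsilon guards against binary representation error for
#' exact decimals.
#'
#' @param x numeric strengths.
#' @param digits decimals kept (default 4).
#' @return truncated numeric values.
#' @examples
#' truncateStrength(32 / 180)  # 0.1777
#' @export
truncateStrength <- function(x, digits = 4) {
  p <- 10^digits
  floor(x * p + 1e-7) / p
}

# 2x2 contingency of premise match (E) against union membership (H)
contingency <- function(rule, table) {
  e <- premiseMatches(rule, table)
  h <- ruleMembership(rule, table)
  c(a = sum(e & h), b = sum(e & !h), c = sum(!e & h), d = sum(!e & !h))
}

confirmFromCounts <- function(a, b, cc, d, measure) {
  n <- a + b + cc + d
  if (a + b == 0L || cc + d == 0L) {
    warning("premise matches no object or all objects: confirmation undefined")
    return(NA_real_)
  }
  pHgE <- a / (a + b)
  pHgnE <- cc / (cc + d)
  switch(measure,
    s = pHgE - pHgnE,
    c = a / n - (a + b) / n * (a + cc) / n,
    f = {
      if (a + cc == 0L || b + d == 0L) return(NA_real_)
      pEgH <- a / (a + cc)
      pEgnH <- b / (b + d)
      if (pEgH + pEgnH == 0) return(NA_real_)
      (pEgH - pEgnH) / (pEgH + pEgnH)
    },
    l = {
      if (a + cc == 0L || b + d == 0L) return(NA_real_)
      pEgH <- a / (a + cc)
      pEgnH <- b / (b + d)
      if (pEgH == 0 && pEgnH == 0) return(NA_real_)
      log(pEgH / pEgnH)
    },
    stop("unknown confirmation measure '", measure, "'"))
}

#' Bayesian confirmation of a rule
#'
#' Quantifies how much satisfying the premise E raises the probability of
#' the conclusion H relative to not satisfying it, from the 2x2 contingency
#' of premise match against union membership. All four measures are
#' positive when E and H are positively associated, zero when statistically
#' independent, and negative when anti-associated:
#' * `s`: \eqn{P(H|E) - P(H|\neg E)} (default);
#' * `c`: \eqn{P(E \wedge H) - P(E)P(H)};
#' * `f`: Kemeny–Oppenheim, \eqn{(P(E|H) - P(E|\neg H)) / (P(E|H) + P(E|\neg H))};
#' * `l`: log-likelihood ratio \eqn{\log(P(E|H) / P(E|\neg H))}
#'   (infinite for perfectly one-sided premises).
#' A premise matching all objects or none leaves the measures undefined:
#' `NA` is returned with a warning.
#'
#' @param rule a [Rule-class].
#' @param table a [DecisionTable-class] with a discretized decision.
#' @param measure one of `"s"`, `"c"`, `"f"`, `"l"`.
#' @return the confirmation value.
#' @export
confirmationMeasure <- function(rule, table, measure = c("s", "c", "f", "l")) {
  measure <- match.arg(measure)
  ct <- contingency(rule, table)
  unname(confirmFromCounts(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]], measure))
}

#' Score a rule against a table
#'
#' Fills the support, strength, confidence and confirmation slots.
#'
#' @inheritParams confirmationMeasure
#' @return the [Rule-class] with metrics set.
#' @export
scoreRule <- function(rule, table, measure = "s") {
  e <- premiseMatches(rule, table)
  h <- ruleMembership(rule, table)
  n <- length(e)
  a <- sum(e & h)
  rule@support <- as.integer(a)
  rule@strength <- a / n
  rule@confidence <- if (sum(e)) a / sum(e) else NA_real_
  rule@confirmation <- suppressWarnings(
    confirmFromCounts(a, sum(e) - a, sum(h) - a, n - sum(e) - sum(h) + a, measure))
  rule
}

# relation a condition on column j takes for a rule concluding the given
# union: at-least rules keep the favourable side (>= on gain, <= on cost),
# at-most rules the unfavourable side
conditionRelation <- function(preference, type) {
  if (type == "atleast") {
    ifelse(preference == "gain", ">=", "<=")
  } else {
    ifelse(preference == "gain", "<=", ">=")
  }
}

applyCondition <- function(v, relation, threshold) {
  if (relation == ">=") v >= threshold else v <= threshold
}

#' Induce minimal monotonic decision rules for a class union
#'
#' Sequential covering in the DomLEM style. The coverage goal is the
#' union's lower approximation at the given consistency threshold; a rule
#' is grown by greedily adding the elementary condition that maximises rule
#' confidence (then coverage of the remaining goal, then attributes with
#' fewer distinct thresholds) until every matched object lies in the
#' union's admissible region, i.e. has cone-membership consistency at least
#' the threshold. Grown rules are pruned to minimal premises (no condition
#' can be dropped without the matched set leaving the admissible region),
#' redundant rules are removed, and the set is ranked by confirmation, then
#' support, descending.
#'
#' Conditions are generated at observed attribute values as weak
#' inequalities: `>=` on gain copies and `<=` on cost copies for upward
#' unions, dually for downward unions; binary indicators yield
#' presence/absence conditions. See [formatRule()] for the strict
#' (open-bound) display dialect.
#'
#' @param table a [DecisionTable-class], binarized and gain/cost-typed.
#' @param type conclusion union direction, `"atleast"` or `"atmost"`.
#' @param class conclusion class index t.
#' @param consistencyThreshold minimum cone-membership consistency of
#'   matched objects; 1 (default) is the classical rough-set requirement
#'   that rules match only the lower approximation.
#' @param measure confirmation measure used for scoring and ranking.
#' @return a [RuleSet-class].
#' @examples
#' tbl <- decisionTable(data.frame(x = 1:6), decision = c(2, 2, 2, 1, 1, 1))
#' tbl <- cloneGainCost(tbl)
#' induceRules(tbl, "atleast", 1)
#' @export
induceRules <- function(table, type = c("atleast", "atmost"), class,
                        consistencyThreshold = 1, measure = "s") {
  type <- match.arg(type)
  class <- as.integer(class)
  stopIfUnordered(table)
  dec <- table@decision
  n <- nrow(table@values)
  D <- dominanceMatrix(table)
  memb <- unionMembership(dec, type, class)
  cons <- consistencyFromD(D, dec, type, class)
  adm <- cons >= consistencyThreshold - 1e-12
  goal <- memb & adm
  info <- list(type = type, class = class,
               consistencyThreshold = consistencyThreshold, measure = measure)
  if (!any(goal)) {
    warning("empty lower approximation: no rules induced for ", type,
            " class ", class)
    return(new("RuleSet", rules = list(), nObjects = n, info = info))
  }
  ai <- table@attrInfo
  M <- as.matrix(table@values)
  rel <- conditionRelation(ai$preference, type)
  nuniq <- apply(M, 2, function(v) length(unique(v)))
  inGoal <- goal
  ruleCovers <- list()
  ruleConds <- list()
  while (any(inGoal)) {
    covered <- rep(TRUE, n)
    conds <- data.frame(attribute = character(0), relation = character(0),
                        threshold = numeric(0), stringsAsFactors = FALSE)
    repeat {
      if (!any(covered & !adm)) break
      covG <- covered & inGoal
      best <- NULL
      bestKey <- c(-Inf, -Inf, Inf)
      for (j in seq_len(ncol(M))) {
        cand <- unique(M[covG, j])
        for (v in cand) {
          newcov <- covered & applyCondition(M[, j], rel[j], v)
          nc <- sum(newcov)
          if (nc == sum(covered) || !any(newcov & covG)) next
          key <- c(sum(newcov & memb) / nc, sum(newcov & covG), -nuniq[j])
          if (key[1] > bestKey[1] ||
              (key[1] == bestKey[1] && key[2] > bestKey[2]) ||
              (key[1] == bestKey[1] && key[2] == bestKey[2] && key[3] > bestKey[3])) {
            best <- list(j = j, v = v, cov = newcov)
            bestKey <- key
          }
        }
      }
      if (is.null(best)) {
        # cannot separate the remaining goal objects admissibly; drop them
        inGoal[covG] <- FALSE
        conds <- NULL
        break
      }
      covered <- best$cov
      prev <- which(conds$attribute == colnames(M)[best$j])
      if (length(prev)) {
        conds$threshold[prev] <- best$v
      } else {
        conds <- rbind(conds, data.frame(attribute = colnames(M)[best$j],
                                         relation = rel[best$j],
                                         threshold = best$v,
                                         stringsAsFactors = FALSE))
      }
    }
    if (is.null(conds)) next
    # prune to a minimal premise
    if (nrow(conds) > 1L) {
      i <- nrow(conds)
      while (i >= 1L && nrow(conds) > 1L) {
        sub <- conds[-i, , drop = FALSE]
        cov <- rep(TRUE, n)
        for (s in seq_len(nrow(sub))) {
          jj <- match(sub$attribute[s], colnames(M))
          cov <- cov & applyCondition(M[, jj], sub$relation[s], sub$threshold[s])
        }
        if (!any(cov & !adm)) {
          conds <- sub
          covered <- cov
        }
        i <- i - 1L
      }
    }
    ruleConds <- c(ruleConds, list(conds))
    ruleCovers <- c(ruleCovers, list(covered))
    inGoal <- inGoal & !covered
  }
  # drop rules whose goal coverage is contained in the union of the others
  if (length(ruleConds) > 1L) {
    keep <- rep(TRUE, length(ruleConds))
    covB <- lapply(ruleCovers, function(cv) cv & goal)
    ord <- order(vapply(covB, sum, numeric(1)))
    for (i in ord) {
      others <- Reduce(`|`, covB[keep & seq_along(keep) != i],
                       accumulate = FALSE) %||% rep(FALSE, n)
      if (sum(keep) > 1L && all(!covB[[i]] | others)) keep[i] <- FALSE
    }
    ruleConds <- ruleConds[keep]
  }
  ruleList <- lapply(ruleConds, function(cd) {
    scoreRule(new("Rule", conditions = cd, conclusionType = type,
                  conclusionClass = class), table, measure = measure)
  })
  ord <- order(-vapply(ruleList, function(r) r@confirmation, numeric(1)),
               -vapply(ruleList, function(r) r@support, numeric(1)))
  new("RuleSet", rules = ruleList[ord], nObjects = n, info = info)
}

#' Is a rule's premise minimal?
#'
#' `TRUE` iff no single elementary condition can be dropped without the
#' rule's matched set leaving the admissible region of its conclusion union
#' at the given consistency threshold.
#'
#' @param rule a [Rule-class].
#' @param table a [DecisionTable-class].
#' @param consistencyThreshold admissibility threshold, as in
#'   [induceRules()].
#' @return logical.
#' @export
checkMinimality <- function(rule, table, consistencyThreshold = 1) {
  D <- dominanceMatrix(table)
  cons <- consistencyFromD(D, table@decision, rule@conclusionType,
                           rule@conclusionClass)
  adm <- cons >= consistencyThreshold - 1e-12
  cd <- rule@conditions
  if (nrow(cd) == 0L) return(TRUE)
  for (i in seq_len(nrow(cd))) {
    sub <- rule
    sub@conditions <- cd[-i, , drop = FALSE]
    if (!any(premiseMatches(sub, table) & !adm)) return(FALSE)
  }
  TRUE
}

#' @rdname rules-accessors
#' @export
setMethod("rules", "RuleSet", function(x) x@rules)

#' Accessors for rule sets
#'
#' @name rules-accessors
#' @param x a [RuleSet-class].
#' @rdname rules-accessors
#' @aliases nObjects,RuleSet-method
#' @export
setMethod("nObjects", "RuleSet", function(x) x@nObjects)

setMethod("show", "Rule", function(object) {
  cat(formatRule(object), "\n")
  if (!is.na(object@support)) {
    cat(sprintf("  support %d, strength %.4f, confidence %.3f, confirmation %.3f\n",
                object@support, truncateStrength(object@strength),
                object@confidence, object@confirmation))
  }
})

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet with", length(object@rules), "rules over",
      object@nObjects, "objects\n")
  for (r in object@rules) show(r)
})

#' Render a rule as readable text
#'
#' Binary presence/absence conditions are rendered as "presence of X" /
#' "absence of X"; ordered conditions as weak inequalities at observed
#' thresholds (`hardness >= 42.4`). With `strict = TRUE` and a reference
#' table, gain-direction conditions are rendered in the open-bound dialect
#' at the next lower observed value (`force > 6` instead of `force >= 12`
#' when the observed grid is 6, 12, 18), and dually for cost conditions.
#'
#' @param rule a [Rule-class].
#' @param table optional [DecisionTable-class] supplying attribute metadata
#'   and the observed value grid.
#' @param strict logical; use the open-bound display dialect.
#' @return a character string.
#' @export
formatRule <- function(rule, table = NULL, strict = FALSE) {
  cd <- rule@conditions
  parts <- character(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    attr <- cd$attribute[i]
    relStr <- cd$relation[i]
    thr <- cd$threshold[i]
    disp <- attr
    isBinary <- FALSE
    if (!is.null(table)) {
      j <- tryCatch(resolveColumn(attr, table), error = function(e) NA_integer_)
      if (!is.na(j)) {
        ai <- table@attrInfo[j, ]
        disp <- ai$source
        dom <- ai$domain[[1]]
        # two-level 0/x attributes read as presence/absence of the component
        isBinary <- identical(ai$domainType, "set") && !is.null(dom) &&
          length(dom) == 2L && min(dom) == 0
        if (strict && !isBinary && relStr %in% c(">=", "<=")) {
          grid <- sort(unique(table@values[[j]]))
          if (relStr == ">=") {
            lower <- grid[grid < thr]
            if (length(lower)) { thr <- max(lower); relStr <- ">" }
          } else {
            higher <- grid[grid > thr]
            if (length(higher)) { thr <- min(higher); relStr <- "<" }
          }
        }
      }
    }
    if (isBinary) {
      absent <- (relStr %in% c("<=", "=", "<") && thr <= 0) ||
        (relStr == "<" && thr > 0)
      present <- (relStr %in% c(">=", "=", ">") && thr > 0) ||
        (relStr == ">" && thr == 0)
      parts[i] <- if (absent) paste("absence of", disp)
        else if (present) paste("presence of", disp)
        else paste(disp, relStr, format(thr, trim = TRUE))
    } else {
      parts[i] <- paste(disp, relStr, format(thr, trim = TRUE))
    }
  }
  lhs <- if (length(parts)) paste(parts, collapse = " and ") else "(always)"
  concl <- sprintf("class %s %d",
                   if (rule@conclusionType == "atleast") "at least" else "at most",
                   rule@conclusionClass)
  paste("if", lhs, "then", concl)
}

#' Tabulate a rule set
#'
#' @param x a [RuleSet-class].
#' @param row.names,optional ignored (S3 signature).
#' @param table optional [DecisionTable-class] for readable premises.
#' @param strict logical; open-bound rendering (see [formatRule()]).
#' @param ... ignored.
#' @return data.frame with premise, conclusion and rule metrics; the
#'   `strengthDisplay` column carries the four-decimal truncated strength.
#' @export
as.data.frame.RuleSet <- function(x, row.names = NULL, optional = FALSE,
                                  table = NULL, strict = FALSE, ...) {
  if (!length(x@rules)) {
    return(data.frame(premise = character(0), conclusion = character(0),
                      support = integer(0), strength = numeric(0),
                      strengthDisplay = character(0), confidence = numeric(0),
                      confirmation = numeric(0)))
  }
  data.frame(
    premise = vapply(x@rules, formatRule, "", table = table, strict = strict),
    conclusion = vapply(x@rules, function(r) {
      sprintf("%s %d", r@conclusionType, r@conclusionClass)
    }, ""),
    support = vapply(x@rules, function(r) r@support, integer(1)),
    strength = vapply(x@rules, function(r) r@strength, numeric(1)),
    strengthDisplay = sprintf("%.4f", truncateStrength(
      vapply(x@rules, function(r) r@strength, numeric(1)))),
    confidence = vapply(x@rules, function(r) r@confidence, numeric(1)),
    confirmation = vapply(x@rules, function(r) r@confirmation, numeric(1)),
    stringsAsFactors = FALSE
  )
}
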