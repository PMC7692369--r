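# one root seed; per-repeat / per-bag streams derived deterministically
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Stratified k-fold plans, repeated
#'
#' Partitions the objects into k folds preserving class proportions within
#' one object per class, independently for each repeat. Deterministic given
#' the root seed: per-repeat seeds are derived by counter.
#'
#' @param table a [DecisionTable-class] with a discretized decision (or an
#'   integer vector of class labels).
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 100).
#' @param seed root seed.
#' @return list of length `repeats`; each element an integer vector of fold
#'   assignments (1..k) per object.
#' @export
stratifiedFolds <- function(table, k = 5, repeats = 100, seed = 1) {
  dec <- if (is(table, "DecisionTable")) decisions(table) else as.integer(table)
  if (!length(dec)) stop("table has no discretized decision")
  small <- table(dec) < k
  if (any(small)) {
    stop("class smaller than k: ", paste(names(small)[small], collapse = ", "))
  }
  seeds <- deriveSeeds(seed, repeats)
  lapply(seq_len(repeats), function(r) {
    set.seed(seeds[r])
    fold <- integer(length(dec))
    for (cl in sort(unique(dec))) {
      idx <- sample(which(dec == cl))
      off <- sample.int(k, 1L)
      fold[idx] <- (seq_along(idx) + off - 2L) %% k + 1L
    }
    fold
  })
}

# per-object consistency with respect to its own class union(s); used as
# VC sampling weights so that consistent objects are drawn more often
selfConsistency <- function(table) {
  D <- dominanceMatrix(table)
  dec <- table@decision
  k <- max(dec)
  w <- rep(1, length(dec))
  for (cl in seq_len(k)) {
    sel <- dec == cl
    if (!any(sel)) next
    ws <- rep(1, sum(sel))
    if (cl < k) {
      ws <- pmin(ws, consistencyFromD(D, dec, "atleast", cl)[sel])
    }
    if (cl > 1L) {
      ws <- pmin(ws, consistencyFromD(D, dec, "atmost", cl)[sel])
    }
    w[sel] <- ws
  }
  w
}

# rules for every meaningful union of the table, as one combined RuleSet
induceClassifierRules <- function(table, consistencyThreshold = 1, measure = "s") {
  k <- max(table@decision)
  rl <- list()
  for (t in seq_len(max(k - 1L, 1L))) {
    rs <- suppressWarnings(
      induceRules(table, "atleast", t, consistencyThreshold, measure))
    rl <- c(rl, rs@rules)
  }
  if (k > 1L) {
    for (t in 2:k) {
      rs <- suppressWarnings(
        induceRules(table, "atmost", t, consistencyThreshold, measure))
      rl <- c(rl, rs@rules)
    }
  }
  new("RuleSet", rules = rl, nObjects = nrow(table@values),
      info = list(consistencyThreshold = consistencyThreshold,
                  measure = measure, unions = "all"))
}

#' Train a variable-consistency bagging rule ensemble
#'
#' Draws `nBags` bootstrap samples of the training table (size n, with
#' replacement) with sampling weights proportional to each object's
#' cone-membership consistency for its own class union, so dominance-
#' inconsistent objects enter bags less often. Rules are induced per bag
#' for both class unions. Bootstrap samples degenerating to a single class
#' are skipped with a warning.
#'
#' @param table a [DecisionTable-class], binarized, gain/cost-typed, with a
#'   discretized decision.
#' @param nBags number of bags (default 30).
#' @param consistencyThreshold rule admissibility threshold, see
#'   [induceRules()].
#' @param seed root seed; per-bag seeds derived by counter.
#' @param weighting `"consistency"` (VC sampling) or `"uniform"` (plain
#'   bagging).
#' @param resample if `FALSE`, every bag is the full training table (so
#'   `nBags = 1, resample = FALSE` reduces to plain induction).
#' @param measure confirmation measure for rule scoring.
#' @return a [RuleEnsemble-class].
#' @export
vcBaggingTrain <- function(table, nBags = 30, consistencyThreshold = 1,
                           seed = 1, weighting = c("consistency", "uniform"),
                           resample = TRUE, measure = "s") {
  weighting <- match.arg(weighting)
  n <- nrow(table@values)
  if (!length(table@decision)) stop("table has no discretized decision")
  w <- if (weighting == "consistency") selfConsistency(table) else rep(1, n)
  if (all(w <= 0)) w <- rep(1, n)
  seeds <- deriveSeeds(seed, nBags)
  bags <- list()
  ids <- list()
  for (b in seq_len(nBags)) {
    if (resample) {
      set.seed(seeds[b])
      take <- sample.int(n, n, replace = TRUE, prob = w)
    } else {
      take <- seq_len(n)
    }
    sub <- subsetObjects(table, take)
    if (length(unique(sub@decision)) < 2L) {
      warning("bag ", b, " degenerated to a single class; skipped")
      next
    }
    bags <- c(bags, list(induceClassifierRules(sub, consistencyThreshold, measure)))
    ids <- c(ids, list(take))
  }
  if (!length(bags)) stop("all bootstrap bags degenerated to a single class")
  tab <- table(table@decision)
  maj <- as.integer(names(tab)[which.max(tab)])
  new("RuleEnsemble", bags = bags, sampleIds = ids,
      majorityClass = maj,
      classes = sort(unique(table@decision)), nTrain = n)
}

#' @rdname rules-accessors
#' @export
setMethod("nObjects", "RuleEnsemble", function(x) x@nTrain)

setMethod("show", "RuleEnsemble", function(object) {
  nr <- sum(vapply(object@bags, function(b) length(b@rules), integer(1)))
  cat("RuleEnsemble with", length(object@bags), "bags,", nr,
      "rules in total, trained on", object@nTrain, "objects\n")
})

# premise matching against an arbitrary data.frame of condition values;
# two-copy column names fall back to their base attribute name
matchOnData <- function(rule, df) {
  out <- rep(TRUE, nrow(df))
  cd <- rule@conditions
  for (i in seq_len(nrow(cd))) {
    a <- cd$attribute[i]
    if (!a %in% names(df)) a <- sub("_(gain|cost)$", "", a)
    if (!a %in% names(df)) stop("missing attribute value: ", cd$attribute[i])
    v <- df[[a]]
    out <- out & switch(cd$relation[i],
      ">=" = v >= cd$threshold[i],
      "<=" = v <= cd$threshold[i],
      "="  = v == cd$threshold[i],
      ">"  = v > cd$threshold[i],
      "<"  = v < cd$threshold[i])
  }
  out
}

#' @rdname classify
#' @details Every rule whose premise an object satisfies votes for its
#'   conclusion union, weighted by the rule's strength on its inducing bag;
#'   the class with the larger total wins. Objects matching no rule get the
#'   training majority class; exact vote ties go to the worse class
#'   (conservatively predicting a changed release profile). Classification
#'   is restricted to two-class ensembles.
#' @export
setMethod("classify", "RuleEnsemble", function(object, newdata, ...) {
  df <- if (is(newdata, "DecisionTable")) newdata@values else as.data.frame(newdata)
  if (length(object@classes) != 2L) {
    stop("voting classification is implemented for two-class ensembles")
  }
  best <- object@classes[1]
  worst <- object@classes[2]
  m <- nrow(df)
  vBest <- numeric(m)
  vWorst <- numeric(m)
  for (bag in object@bags) {
    for (r in bag@rules) {
      hit <- matchOnData(r, df)
      if (!any(hit)) next
      wt <- r@strength
      if (is.na(wt)) next
      forBest <- (r@conclusionType == "atleast" && r@conclusionClass == best) ||
        (r@conclusionType == "atmost" && r@conclusionClass == best)
      if (forBest) vBest[hit] <- vBest[hit] + wt else vWorst[hit] <- vWorst[hit] + wt
    }
  }
  pred <- ifelse(vBest > vWorst, best, worst)
  none <- vBest == 0 & vWorst == 0
  pred[none] <- object@majorityClass
  as.integer(pred)
})

#' @rdname classify
#' @param object a [RuleEnsemble-class].
#' @export
setMethod("predict", "RuleEnsemble", function(object, newdata, ...) {
  classify(object, newdata, ...)
})

#' Repeated stratified cross-validation of VC-bagging rule ensembles
#'
#' Trains a [vcBaggingTrain()] ensemble on k-1 folds and classifies the
#' held-out fold, for every fold of every repeat. Reports per-fold counts
#' and per-repeat averages: correctly/incorrectly classified instances,
#' classification accuracy (%), and precision (%) macro-averaged over the
#' classes (micro also recorded).
#'
#' @inheritParams vcBaggingTrain
#' @param k folds (default 5).
#' @param repeats repetitions (default 100).
#' @return a [CVReport-class].
#' @export
crossValidate <- function(table, k = 5, repeats = 100, nBags = 30,
                          consistencyThreshold = 1, seed = 1,
                          weighting = "consistency", measure = "s") {
  dec <- table@decision
  classes <- sort(unique(dec))
  plans <- stratifiedFolds(table, k, repeats, seed)
  seeds <- deriveSeeds(seed + 1L, repeats * k)
  perFold <- list()
  perRepeat <- list()
  s <- 0L
  for (r in seq_len(repeats)) {
    fold <- plans[[r]]
    tp <- fp <- stats::setNames(numeric(length(classes)), classes)
    totalCorrect <- 0L
    for (f in seq_len(k)) {
      s <- s + 1L
      test <- which(fold == f)
      train <- subsetObjects(table, which(fold != f))
      ens <- suppressWarnings(
        vcBaggingTrain(train, nBags = nBags,
                       consistencyThreshold = consistencyThreshold,
                       seed = seeds[s], weighting = weighting,
                       measure = measure))
      pred <- classify(ens, subsetObjects(table, test))
      truth <- dec[test]
      good <- sum(pred == truth)
      totalCorrect <- totalCorrect + good
      for (cl in classes) {
        key <- as.character(cl)
        tp[key] <- tp[key] + sum(pred == cl & truth == cl)
        fp[key] <- fp[key] + sum(pred == cl & truth != cl)
      }
      perFold[[length(perFold) + 1L]] <- data.frame(
        repeatIdx = r, fold = f, n = length(test),
        correct = good, incorrect = length(test) - good)
    }
    n <- length(dec)
    prec <- tp / (tp + fp)
    perRepeat[[r]] <- data.frame(
      repeatIdx = r, correct = totalCorrect, incorrect = n - totalCorrect,
      accuracy = 100 * totalCorrect / n,
      precisionMacro = 100 * mean(prec, na.rm = TRUE),
      precisionMicro = 100 * sum(tp) / (sum(tp) + sum(fp)))
  }
  new("CVReport",
      perFold = do.call(rbind, perFold),
      perRepeat = do.call(rbind, perRepeat),
      settings = list(k = k, repeats = repeats, nBags = nBags,
                      consistencyThreshold = consistencyThreshold,
                      seed = seed, weighting = weighting, measure = measure,
                      nObjects = length(dec)))
}

#' Summarise a cross-validation report
#'
#' @param report a [CVReport-class].
#' @param precision `"macro"` (default) or `"micro"` class averaging.
#' @return list with average correctly/incorrectly classified instance
#'   counts, average classification accuracy (%) and average precision (%).
#' @export
cvSummary <- function(report, precision = c("macro", "micro")) {
  precision <- match.arg(precision)
  pr <- report@perRepeat
  list(
    correctlyClassified = mean(pr$correct),
    incorrectlyClassified = mean(pr$incorrect),
    accuracy = mean(pr$accuracy),
    precision = mean(if (precision == "macro") pr$precisionMacro else pr$precisionMicro)
  )
}

setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  st <- object@settings
  cat(sprintf("Stratified %d-fold CV, %d repeats (VC-bagging, %d bags)\n",
              st$k, st$repeats, st$nBags))
  cat(sprintf("  Correctly classified instances:   %.2f (%.2f%%)\n",
              s$correctlyClassified,
              100 * s$correctlyClassified / st$nObjects))
  cat(sprintf("  Incorrectly classified instances: %.2f (%.2f%%)\n",
              s$incorrectlyClassified,
              100 * s$incorrectlyClassified / st$nObjects))
  cat(sprintf("  Average classification accuracy: %.2f%%\n", s$accuracy))
  cat(sprintf("  Average precision (macro):       %.2f%%\n", s$precision))
})

#' Confirmation-based attribute relevance
#'
#' Scores each condition attribute by how much its presence in the premise
#' of a firing rule raises the probability of a correct suggestion. Over
#' all (object, firing rule) events of the ensembles on the table, the
#' chosen confirmation measure is computed for E = "the rule's premise
#' involves the attribute" against H = "the rule's conclusion is correct
#' for the object". The score therefore increases when more rules involving
#' the attribute suggest a correct decision, or when more rules omitting it
#' suggest an incorrect one. Gain/cost copies are aggregated to their
#' source attribute; attributes appearing in no rule get `NA`.
#'
#' @param ensembles a [RuleEnsemble-class] or list of them.
#' @param table a [DecisionTable-class] with a discretized decision.
#' @param measure confirmation measure, see [confirmationMeasure()].
#' @return data.frame with columns `attribute`, `relevance`, `nRules`,
#'   sorted by decreasing relevance.
#' @export
attributeRelevance <- function(ensembles, table, measure = "s") {
  if (is(ensembles, "RuleEnsemble")) ensembles <- list(ensembles)
  rulesAll <- unlist(lapply(ensembles, function(e) {
    unlist(lapply(e@bags, function(b) b@rules), recursive = FALSE)
  }), recursive = FALSE)
  if (!length(rulesAll)) stop("no rules in the supplied ensembles")
  ai <- table@attrInfo
  sources <- unique(ai$source)
  # per rule: firing counts split by correctness, and the source attributes
  # its premise involves
  f1 <- f0 <- numeric(length(rulesAll))
  inv <- matrix(FALSE, length(rulesAll), length(sources),
                dimnames = list(NULL, sources))
  for (i in seq_along(rulesAll)) {
    r <- rulesAll[[i]]
    hit <- matchOnData(r, table@values)
    ok <- unionMembership(table@decision, r@conclusionType, r@conclusionClass)
    f1[i] <- sum(hit & ok)
    f0[i] <- sum(hit & !ok)
    for (a in r@conditions$attribute) {
      j <- tryCatch(resolveColumn(a, table), error = function(e) NA_integer_)
      src <- if (!is.na(j)) ai$source[j] else sub("_(gain|cost)$", "", a)
      if (src %in% sources) inv[i, src] <- TRUE
    }
  }
  rel <- vapply(sources, function(srcName) {
    w <- inv[, srcName]
    if (!any(w)) return(NA_real_)
    suppressWarnings(confirmFromCounts(sum(f1[w]), sum(f0[w]),
                                       sum(f1[!w]), sum(f0[!w]), measure))
  }, numeric(1))
  out <- data.frame(attribute = sources, relevance = rel,
                    nRules = colSums(inv), row.names = NULL)
  out[order(-ifelse(is.na(out$relevance), -Inf, out$relevance)), , drop = FALSE]
}
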