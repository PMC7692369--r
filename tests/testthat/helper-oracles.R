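# Independent brute-force oracles: naive pairwise loops over the DRSA
# definitions, deliberately kept separate from the package's vectorized
# implementations.

# build a small ordered table directly (no two-copy transform needed)
toyTable <- function(values, decision, preference = NULL) {
  values <- as.data.frame(values)
  if (is.null(preference)) preference <- rep("gain", ncol(values))
  ai <- drsarules:::makeAttrInfo(colnames(values), preference = preference)
  decisionTable(values, decision = as.integer(decision), attrInfo = ai)
}

randomOrderedTable <- function(n, p, nclasses = 2, nlevels = 3) {
  values <- as.data.frame(matrix(sample.int(nlevels, n * p, replace = TRUE),
                                 n, p))
  colnames(values) <- paste0("a", seq_len(p))
  pref <- sample(c("gain", "cost"), p, replace = TRUE)
  # ensure every class occurs so that all unions are well defined
  dec <- sample(c(seq_len(nclasses),
                  sample.int(nclasses, max(n - nclasses, 0), replace = TRUE)))
  toyTable(values, dec[seq_len(n)], pref)
}

# does object i weakly dominate object j? (naive per-attribute loop)
bruteDominates <- function(table, i, j) {
  ai <- attributeInfo(table)
  v <- conditionValues(table)
  for (c in seq_len(ncol(v))) {
    if (ai$preference[c] == "gain") {
      if (v[i, c] < v[j, c]) return(FALSE)
    } else if (ai$preference[c] == "cost") {
      if (v[i, c] > v[j, c]) return(FALSE)
    } else {
      stop("brute oracle needs gain/cost attributes")
    }
  }
  TRUE
}

bruteCone <- function(table, j, direction) {
  n <- nObjects(table)
  ids <- objectIds(table)
  keep <- vapply(seq_len(n), function(i) {
    if (direction == "dominating") bruteDominates(table, i, j)
    else bruteDominates(table, j, i)
  }, logical(1))
  ids[keep]
}

bruteUnionMembers <- function(decision, type, class) {
  if (type == "atleast") which(decision <= class) else which(decision >= class)
}

bruteApprox <- function(table, type, class) {
  n <- nObjects(table)
  ids <- objectIds(table)
  memb <- bruteUnionMembers(decisions(table), type, class)
  coneDir <- if (type == "atleast") "dominating" else "dominated"
  dualDir <- if (type == "atleast") "dominated" else "dominating"
  lower <- upper <- logical(n)
  for (j in seq_len(n)) {
    cone <- match(bruteCone(table, j, coneDir), ids)
    lower[j] <- all(cone %in% memb)
    dual <- match(bruteCone(table, j, dualDir), ids)
    upper[j] <- any(dual %in% memb)
  }
  list(members = ids[memb], lower = ids[lower], upper = ids[upper],
       boundary = ids[upper & !lower])
}

bruteConsistency <- function(table, j, type, class) {
  ids <- objectIds(table)
  memb <- ids[bruteUnionMembers(decisions(table), type, class)]
  dir <- if (type == "atleast") "dominating" else "dominated"
  cone <- bruteCone(table, j, dir)
  mean(cone %in% memb)
}

# naive support count: loop objects, evaluate each condition
bruteSupport <- function(rule, table) {
  v <- conditionValues(table)
  ai <- attributeInfo(table)
  dec <- decisions(table)
  cd <- rule@conditions
  inUnion <- if (rule@conclusionType == "atleast") {
    dec <= rule@conclusionClass
  } else {
    dec >= rule@conclusionClass
  }
  count <- 0L
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (s in seq_len(nrow(cd))) {
      col <- cd$attribute[s]
      if (!col %in% colnames(v)) {
        col <- ai$name[match(cd$attribute[s], ai$source)]
      }
      x <- v[i, col]
      ok <- ok && switch(cd$relation[s],
        ">=" = x >= cd$threshold[s], "<=" = x <= cd$threshold[s],
        ">" = x > cd$threshold[s], "<" = x < cd$threshold[s],
        "=" = x == cd$threshold[s])
      if (!ok) break
    }
    if (ok && inUnion[i]) count <- count + 1L
  }
  count
}

# the fully transformed 20-formulation excerpt, shared across tests
excerptTransformed <- function() {
  tbl <- exampleTable()
  tbl <- binarizeNominal(tbl, "Coating")
  tbl <- cloneGainCost(tbl)
  discretizeDecision(tbl)
}
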