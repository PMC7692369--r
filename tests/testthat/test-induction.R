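test_that("a separable one-attribute table yields the single threshold rule", {
  tbl <- decisionTable(data.frame(attr = 1:6),
                       decision = c(2L, 2L, 2L, 1L, 1L, 1L))
  tbl <- cloneGainCost(tbl)
  rs <- induceRules(tbl, "atleast", 1)
  expect_length(rules(rs), 1L)
  r <- rules(rs)[[1]]
  expect_identical(r@conditions$attribute, "attr_gain")
  expect_identical(r@conditions$relation, ">=")
  expect_equal(r@conditions$threshold, 4)
  expect_equal(r@support, 3L)
  expect_equal(r@confidence, 1)
  # brute-force check over all single-condition rules: >= 4 on the gain
  # copy is the unique most-supported fully-confident rule
  best <- 0L
  for (v in 1:6) {
    cand <- decisionRule("attr_gain", ">=", v, "atleast", 1)
    if (isTRUE(ruleConfidence(cand, tbl) == 1)) {
      best <- max(best, bruteSupport(cand, tbl))
    }
  }
  expect_equal(r@support, best)
  # the dual union gets the mirrored rule
  rs2 <- induceRules(tbl, "atmost", 2)
  r2 <- rules(rs2)[[1]]
  expect_identical(r2@conditions$relation, "<=")
  expect_equal(r2@conditions$threshold, 3)
})

test_that("degenerate unions give an unconditional rule or an empty warning", {
  allOne <- decisionTable(data.frame(a = c(1, 5, 9)), decision = c(1L, 1L, 1L))
  allOne <- cloneGainCost(allOne)
  rs <- induceRules(allOne, "atleast", 1)
  expect_length(rules(rs), 1L)
  expect_equal(nrow(rules(rs)[[1]]@conditions), 0L)
  expect_equal(rules(rs)[[1]]@support, 3L)
  mixed <- decisionTable(data.frame(a = c(2, 2)), decision = c(1L, 2L))
  mixed <- cloneGainCost(mixed)
  expect_warning(rsEmpty <- induceRules(mixed, "atleast", 1),
                 "empty lower approximation")
  expect_length(rules(rsEmpty), 0L)
})

test_that("rule support, strength and confidence follow their definitions", {
  tbl <- excerptTransformed()
  n <- nObjects(tbl)
  # unconditional class-1 rule: support = class-1 count of the excerpt
  un <- decisionRule(type = "atleast", class = 1)
  expect_equal(ruleSupport(un, tbl), 9L)
  expect_equal(ruleSupport(un, tbl), bruteSupport(un, tbl))
  expect_equal(ruleStrength(un, tbl), 9 / 20)
  # published premises recomputed against the printed rows match the oracle
  for (cl in 1:2) {
    for (r in publishedRules(cl)) {
      expect_equal(ruleSupport(r, tbl), bruteSupport(r, tbl))
      s <- scoreRule(r, tbl)
      expect_equal(s@strength * n, s@support)
    }
  }
  # premise matching no object
  none <- decisionRule("Hardness", ">=", 1e6, "atleast", 1)
  expect_equal(ruleSupport(none, tbl), 0L)
  expect_error(ruleStrength(un, decisionTable(data.frame(a = numeric(0)),
                                              integer(0))), "empty table")
})

test_that("strength display truncates to four decimals as in the published tables", {
  expect_equal(truncateStrength(32 / 180), 0.1777)
  expect_equal(truncateStrength(30 / 180), 0.1666)
  expect_equal(truncateStrength(53 / 180), 0.2944)
  expect_equal(truncateStrength(36 / 180), 0.2000)  # exact decimals survive
  expect_equal(truncateStrength(0), 0)
})

test_that("confirmation measures have the confirmation sign/zero semantics", {
  # perfect rule on a half-prevalence class covering half the table: s = 1
  tbl <- decisionTable(data.frame(x = c(1, 1, 2, 2)),
                       decision = c(2L, 2L, 1L, 1L))
  tbl <- cloneGainCost(tbl)
  perfect <- decisionRule("x_gain", ">=", 2, "atleast", 1)
  expect_equal(confirmationMeasure(perfect, tbl, "s"), 1)
  # premise independent of the class: all measures are 0
  ind <- decisionTable(data.frame(x = c(1, 1, 2, 2), y = c(1, 2, 1, 2)),
                       decision = c(1L, 2L, 1L, 2L))
  ind <- cloneGainCost(ind)
  indep <- decisionRule("x_gain", ">=", 2, "atleast", 1)
  for (m in c("s", "c", "f", "l")) {
    expect_equal(confirmationMeasure(indep, ind, m), 0)
  }
  # anti-associated premise: all measures negative
  anti <- decisionRule("x_cost", "<=", 1, "atleast", 1)
  tblAnti <- decisionTable(data.frame(x = c(1, 1, 1, 2, 2, 2)),
                           decision = c(2L, 2L, 1L, 1L, 1L, 2L))
  tblAnti <- cloneGainCost(tblAnti)
  for (m in c("s", "c", "f", "l")) {
    expect_lt(confirmationMeasure(anti, tblAnti, m), 0)
  }
  # degenerate premise (matches everything) is flagged undefined
  expect_warning(v <- confirmationMeasure(decisionRule(type = "atleast", class = 1),
                                          tbl, "s"))
  expect_true(is.na(v))
})

test_that("minimality detection agrees with exhaustive condition dropping", {
  tbl <- decisionTable(data.frame(a = 1:6),
                       decision = c(2L, 2L, 2L, 1L, 1L, 1L))
  tbl <- cloneGainCost(tbl)
  expect_true(checkMinimality(decisionRule("a_gain", ">=", 4, "atleast", 1), tbl))
  # a redundant duplicated condition is not minimal
  red <- decisionRule(c("a_gain", "a_gain"), c(">=", ">="), c(4, 2),
                      "atleast", 1)
  expect_false(checkMinimality(red, tbl))
  # random small tables: compare with an independent subset search
  set.seed(505)
  for (rep in 1:20) {
    tt <- randomOrderedTable(sample(4:8, 1), sample(2:3, 1))
    rs <- suppressWarnings(induceRules(tt, "atleast", 1))
    for (r in rules(rs)) {
      cd <- r@conditions
      lower <- bruteApprox(tt, "atleast", 1)$lower
      droppable <- FALSE
      for (i in seq_len(nrow(cd))) {
        sub <- r
        sub@conditions <- cd[-i, , drop = FALSE]
        hits <- objectIds(tt)[premiseMatches(sub, tt)]
        if (all(hits %in% lower)) droppable <- TRUE
      }
      expect_identical(checkMinimality(r, tt), !droppable && nrow(cd) >= 0)
    }
  }
})

test_that("induced rule sets cover the lower approximation with monotone syntax", {
  set.seed(606)
  for (rep in 1:15) {
    tt <- randomOrderedTable(sample(6:14, 1), sample(2:4, 1))
    ai <- attributeInfo(tt)
    for (spec in list(c("atleast", 1), c("atmost", 2))) {
      rs <- suppressWarnings(induceRules(tt, spec[1], as.integer(spec[2])))
      lower <- bruteApprox(tt, spec[1], as.integer(spec[2]))$lower
      if (!length(rules(rs))) {
        expect_length(lower, 0L)
        next
      }
      coveredIds <- character(0)
      for (r in rules(rs)) {
        coveredIds <- union(coveredIds, objectIds(tt)[premiseMatches(r, tt)])
        # every condition respects preference direction for its union
        for (i in seq_len(nrow(r@conditions))) {
          pref <- ai$preference[match(r@conditions$attribute[i], ai$name)]
          expected <- if (spec[1] == "atleast") {
            if (pref == "gain") ">=" else "<="
          } else {
            if (pref == "gain") "<=" else ">="
          }
          expect_identical(r@conditions$relation[i], expected)
        }
        expect_true(checkMinimality(r, tt))
        # matched objects stay inside the lower approximation (threshold 1)
        hits <- objectIds(tt)[premiseMatches(r, tt)]
        expect_true(all(hits %in% lower))
      }
      expect_true(all(lower %in% coveredIds))
    }
  }
})

test_that("rules are ranked by confirmation then support, and render readably", {
  tbl <- excerptTransformed()
  rs <- induceRules(tbl, "atleast", 1)
  conf <- vapply(rules(rs), function(r) r@confirmation, numeric(1))
  expect_true(all(diff(conf) <= 1e-12))
  txt <- formatRule(rules(rs)[[1]], table = tbl, strict = TRUE)
  expect_match(txt, "^if .* then class at least 1$")
  # binary conditions render as presence/absence with the source name
  rb <- decisionRule(c("Coating_1", "Avicel_101"), c(">=", "<="), c(1, 0),
                     "atleast", 1)
  expect_match(formatRule(rb, table = tbl), "presence of Coating_1")
  expect_match(formatRule(rb, table = tbl), "absence of Avicel_101")
  # strict dialect moves a grid threshold to an open bound: force >= 12 -> > 6
  rf <- decisionRule("Compression_force", ">=", 12, "atleast", 1)
  expect_match(formatRule(rf, table = tbl, strict = TRUE),
               "Compression_force > 6")
  df <- as.data.frame(rs, table = tbl)
  expect_true(all(c("premise", "support", "strengthDisplay") %in% names(df)))
})
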