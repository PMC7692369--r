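test_that("stratified folds preserve class proportions and are seed-deterministic", {
  dec <- rep(c(1L, 2L), each = 90)  # 180 objects, balanced classes
  plans <- stratifiedFolds(dec, k = 5, repeats = 3, seed = 11)
  expect_length(plans, 3L)
  for (fold in plans) {
    expect_equal(as.vector(table(fold)), rep(36L, 5))  # folds of 36
    for (f in 1:5) {
      expect_equal(sum(fold == f & dec == 1L), 18L)  # 18 + 18 per fold
      expect_equal(sum(fold == f & dec == 2L), 18L)
    }
  }
  # unbalanced classes stay within one object of proportionality
  dec2 <- c(rep(1L, 47), rep(2L, 83))
  for (fold in stratifiedFolds(dec2, k = 5, repeats = 2, seed = 4)) {
    for (f in 1:5) {
      expect_lte(abs(sum(fold == f & dec2 == 1L) - 47 / 5), 1)
      expect_lte(abs(sum(fold == f & dec2 == 2L) - 83 / 5), 1)
    }
  }
  expect_identical(stratifiedFolds(dec, 5, 4, seed = 7),
                   stratifiedFolds(dec, 5, 4, seed = 7))
  expect_false(identical(stratifiedFolds(dec, 5, 1, seed = 7),
                         stratifiedFolds(dec, 5, 1, seed = 8)))
  expect_error(stratifiedFolds(c(1L, 1L, 2L), k = 5), "class smaller than k")
})

test_that("a single identity bag reduces VC-bagging to plain induction", {
  tbl <- excerptTransformed()
  ens <- vcBaggingTrain(tbl, nBags = 1, resample = FALSE, seed = 1)
  plain <- c(rules(induceRules(tbl, "atleast", 1)),
             rules(induceRules(tbl, "atmost", 2)))
  got <- rules(ens@bags[[1]])
  expect_equal(length(got), length(plain))
  sig <- function(r) paste(r@conclusionType, r@conclusionClass,
                           paste(r@conditions$attribute, r@conditions$relation,
                                 r@conditions$threshold, collapse = "&"),
                           r@support)
  expect_setequal(vapply(got, sig, ""), vapply(plain, sig, ""))
})

test_that("bagging is reproducible by seed and weights consistent objects more", {
  g <- generateTable(nObjects = 50, inconsistency = 0.1, seed = 21)
  tbl <- cloneGainCost(binarizeNominal(g$table, "Coating"))
  e1 <- suppressWarnings(vcBaggingTrain(tbl, nBags = 3, seed = 5))
  e2 <- suppressWarnings(vcBaggingTrain(tbl, nBags = 3, seed = 5))
  expect_identical(e1@sampleIds, e2@sampleIds)
  # flipped (inconsistent) objects should be sampled less often than their
  # fully consistent peers under consistency weighting
  if (length(g$flipped)) {
    counts <- tabulate(unlist(e1@sampleIds), nbins = 50)
    w <- drsarules:::selfConsistency(tbl)
    expect_lte(mean(counts[w < 1]), mean(counts[w == 1]) + 1)
  }
})

test_that("voting classification follows strength-weighted votes with the stated tie policies", {
  mkrule <- function(type, strength) {
    r <- decisionRule("x", ">=", 2, type, if (type == "atleast") 1L else 2L)
    r@strength <- strength
    r
  }
  bag <- new("RuleSet", rules = list(mkrule("atleast", 0.6),
                                     mkrule("atmost", 0.3)), nObjects = 10L)
  ens <- new("RuleEnsemble", bags = list(bag), sampleIds = list(1:10),
             majorityClass = 1L, classes = c(1L, 2L), nTrain = 10L)
  # conflicting matches: 0.6 for class 1 vs 0.3 for class 2
  expect_equal(classify(ens, data.frame(x = 5)), 1L)
  # no rule fires: training majority class
  expect_equal(classify(ens, data.frame(x = 0)), 1L)
  # exact tie goes to the worse class (profile-changed prediction)
  bagTie <- new("RuleSet", rules = list(mkrule("atleast", 0.4),
                                        mkrule("atmost", 0.4)), nObjects = 10L)
  ensTie <- new("RuleEnsemble", bags = list(bagTie), sampleIds = list(1:10),
                majorityClass = 1L, classes = c(1L, 2L), nTrain = 10L)
  expect_equal(classify(ensTie, data.frame(x = 9)), 2L)
  # rule order within the ensemble is irrelevant
  bagRev <- new("RuleSet", rules = rev(bag@rules), nObjects = 10L)
  ensRev <- new("RuleEnsemble", bags = list(bagRev), sampleIds = list(1:10),
                majorityClass = 1L, classes = c(1L, 2L), nTrain = 10L)
  expect_equal(classify(ensRev, data.frame(x = c(5, 0))),
               classify(ens, data.frame(x = c(5, 0))))
  expect_error(classify(ens, data.frame(y = 1)), "missing attribute")
})

test_that("cross-validation bookkeeping is exact and reproducible", {
  g <- generateTable(nObjects = 60, inconsistency = 0.1, seed = 31)
  tbl <- cloneGainCost(binarizeNominal(g$table, "Coating"))
  cv <- crossValidate(tbl, k = 5, repeats = 2, nBags = 3, seed = 9)
  pf <- cv@perFold
  expect_equal(nrow(pf), 10L)
  expect_true(all(pf$correct + pf$incorrect == pf$n))
  # stratification keeps folds within one object per class of 60/5 = 12
  expect_true(all(abs(pf$n - 12L) <= 2L))
  expect_true(all(tapply(pf$n, pf$repeatIdx, sum) == 60L))
  cv2 <- crossValidate(tbl, k = 5, repeats = 2, nBags = 3, seed = 9)
  expect_identical(cv@perFold, cv2@perFold)
  expect_identical(cv@perRepeat, cv2@perRepeat)
  s <- cvSummary(cv)
  expect_true(s$accuracy >= 0 && s$accuracy <= 100)
  expect_equal(s$correctlyClassified + s$incorrectlyClassified, 60)
})

test_that("noise-free synthetic data is fit perfectly and cross-validates near-perfectly", {
  # concept exactly representable by one monotone rule
  single <- list(decisionRule(c("Coating_1", "Compression_force", "Hardness"),
                              c(">=", ">=", ">="), c(1, 12, 42.4),
                              "atleast", 1L))
  g <- generateTable(nObjects = 150, inconsistency = 0,
                     plantedRules = single, seed = 41)
  tbl <- cloneGainCost(binarizeNominal(g$table, "Coating"))
  ens <- vcBaggingTrain(tbl, nBags = 1, resample = FALSE, seed = 1)
  expect_equal(classify(ens, tbl), decisions(tbl))  # 100% training accuracy
  cv <- crossValidate(tbl, k = 5, repeats = 1, nBags = 5, seed = 2)
  expect_gte(cvSummary(cv)$accuracy, 95)
  # the richer two-rule default concept also fits its training data exactly
  g2 <- generateTable(nObjects = 120, inconsistency = 0, seed = 42)
  tbl2 <- cloneGainCost(binarizeNominal(g2$table, "Coating"))
  ens2 <- vcBaggingTrain(tbl2, nBags = 1, resample = FALSE, seed = 1)
  expect_equal(classify(ens2, tbl2), decisions(tbl2))
})

test_that("an ensemble beats or matches a single rule set on noisy held-out data", {
  accs <- vapply(1:4, function(s) {
    g <- generateTable(nObjects = 120, inconsistency = 0.1, seed = 100 + s)
    tbl <- cloneGainCost(binarizeNominal(g$table, "Coating"))
    train <- subsetObjects(tbl, 1:90)
    test <- subsetObjects(tbl, 91:120)
    truth <- decisions(tbl)[91:120]
    bagged <- suppressWarnings(vcBaggingTrain(train, nBags = 10, seed = s))
    single <- vcBaggingTrain(train, nBags = 1, resample = FALSE, seed = s)
    c(mean(classify(bagged, test) == truth),
      mean(classify(single, test) == truth))
  }, numeric(2))
  expect_gte(mean(accs[1, ]), mean(accs[2, ]) - 0.02)
})

test_that("attribute relevance ranks planted informative attributes above noise", {
  hits <- 0L
  for (s in 1:6) {
    set.seed(700 + s)
    n <- 140
    vals <- as.data.frame(matrix(sample.int(5, n * 8, replace = TRUE), n, 8))
    colnames(vals) <- paste0("x", 1:8)
    dec <- ifelse(vals$x1 >= 4 & vals$x2 >= 3, 1L, 2L)
    if (length(unique(dec)) < 2L) next
    tbl <- cloneGainCost(decisionTable(vals, decision = dec))
    ens <- suppressWarnings(vcBaggingTrain(tbl, nBags = 8, seed = s))
    rel <- attributeRelevance(ens, tbl)
    top2 <- rel$attribute[1:2]
    if (setequal(top2, c("x1", "x2"))) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
  # an attribute entering no rule is reported as not applicable
  tbl <- decisionTable(data.frame(a = c(1, 2, 3, 4), noise = c(1, 1, 1, 1)),
                       decision = c(2L, 2L, 1L, 1L))
  tbl <- cloneGainCost(tbl)
  ens <- vcBaggingTrain(tbl, nBags = 1, resample = FALSE)
  rel <- attributeRelevance(ens, tbl)
  expect_true(is.na(rel$relevance[rel$attribute == "noise"]))
  expect_equal(rel$attribute[1], "a")
})
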