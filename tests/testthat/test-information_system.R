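schemaPath <- system.file("extdata", "table1_schema.csv", package = "drsarules")
csvPath <- system.file("extdata", "table2_formulations.csv", package = "drsarules")

test_that("the printed excerpt loads with 20 objects and 23 condition attributes", {
  sch <- readSchema(schemaPath)
  tbl <- loadDecisionTable(csvPath, sch, decision = "f2", id = "formulation")
  expect_s4_class(tbl, "DecisionTable")
  expect_equal(nObjects(tbl), 20L)
  expect_equal(ncol(conditionValues(tbl)), 23L)
  expect_identical(objectIds(tbl), as.character(1:20))  # row order preserved
  expect_equal(tableMetadata(tbl)$decisionRaw[1:3], c(59.4, 56.3, 35.7))
})

test_that("the loader rejects malformed input", {
  sch <- readSchema(schemaPath)
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines("Coating,f2", tmp)
  expect_error(loadDecisionTable(tmp, sch), "no objects")

  writeLines(c("Coating,Hardness", "1,50"), tmp)
  expect_error(loadDecisionTable(tmp, sch, decision = "f2"),
               "missing decision column")

  # out-of-domain nominal value
  d <- utils::read.csv(csvPath, check.names = FALSE)
  d$Coating[3] <- 4
  utils::write.csv(d, tmp, row.names = FALSE)
  expect_error(loadDecisionTable(tmp, sch, decision = "f2", id = "formulation"),
               "outside declared domain")

  d <- utils::read.csv(csvPath, check.names = FALSE)
  d$formulation[2] <- 1
  utils::write.csv(d, tmp, row.names = FALSE)
  expect_error(loadDecisionTable(tmp, sch, decision = "f2", id = "formulation"),
               "duplicate object identifiers")

  d <- utils::read.csv(csvPath, check.names = FALSE)
  d$extra <- 1
  utils::write.csv(d, tmp, row.names = FALSE)
  expect_error(loadDecisionTable(tmp, sch, decision = "f2", id = "formulation"),
               "unknown columns")
})

test_that("binarization one-hot encodes nominals and round-trips", {
  tbl <- exampleTable()
  bin <- binarizeNominal(tbl, "Coating")
  v <- conditionValues(bin)
  expect_true(all(c("Coating_1", "Coating_2", "Coating_3") %in% colnames(v)))
  expect_false("Coating" %in% colnames(v))
  onehot <- v$Coating_1 + v$Coating_2 + v$Coating_3
  expect_true(all(onehot == 1))  # exactly one indicator per object
  # Eudragit NE (coating = 1) everywhere in the excerpt
  expect_true(all(v$Coating_1 == 1))
  expect_equal(reconstructNominal(bin, "Coating"),
               conditionValues(tbl)$Coating)
  expect_error(binarizeNominal(tbl, "Hardness"), "not nominal")
})

test_that("binarizing a single-valued nominal yields one constant indicator", {
  ai <- drsarules:::makeAttrInfo("x", kind = "nominal", domainType = "set",
                                 domain = list(7))
  tbl <- decisionTable(data.frame(x = c(7, 7, 7)), decision = c(1L, 2L, 1L),
                       attrInfo = ai)
  bin <- binarizeNominal(tbl, "x")
  expect_identical(colnames(conditionValues(bin)), "x_7")
  expect_true(all(conditionValues(bin)$x_7 == 1))
})

test_that("the two-copy transform doubles unknown-preference attributes without touching values", {
  tbl <- exampleTable()
  bin <- binarizeNominal(tbl, "Coating")
  two <- cloneGainCost(bin)
  ai <- attributeInfo(two)
  expect_equal(ncol(conditionValues(two)), 2L * ncol(conditionValues(bin)))
  expect_true(all(ai$preference %in% c("gain", "cost")))
  # values identical in the two copies, and identical to the original grid
  for (src in attributeInfo(bin)$name) {
    cols <- which(ai$source == src)
    expect_length(cols, 2L)
    expect_identical(conditionValues(two)[[cols[1]]],
                     conditionValues(two)[[cols[2]]])
    expect_identical(conditionValues(two)[[cols[1]]],
                     conditionValues(bin)[[src]])
  }
  # attributes already declared gain are left as a single copy
  ai2 <- drsarules:::makeAttrInfo(c("g", "u"), preference = c("gain", "none"))
  t2 <- decisionTable(data.frame(g = 1:3, u = 3:1), decision = c(1L, 1L, 2L),
                      attrInfo = ai2)
  t2c <- cloneGainCost(t2)
  expect_identical(colnames(conditionValues(t2c)), c("g", "u_gain", "u_cost"))
})

test_that("f2 discretization applies the sharp >= 50 cut", {
  tbl <- exampleTable()
  dis <- discretizeDecision(tbl)
  dec <- decisions(dis)
  f2 <- tableMetadata(dis)$f2
  expect_equal(dec[1], 1L)  # f2 = 59.4
  expect_equal(dec[3], 2L)  # f2 = 35.7
  expect_identical(dec, ifelse(f2 >= 50, 1L, 2L))
  # boundary is >= : exactly 50 is class 1
  t0 <- decisionTable(data.frame(x = 1))
  t0@metadata$decisionRaw <- 50
  expect_equal(decisions(discretizeDecision(t0)), 1L)
  # class counts of the printed excerpt (recounted from the f2 column)
  expect_equal(as.vector(table(dec)), c(9L, 11L))
  # monotonicity: raising any object's f2 never moves it out of class 1
  for (i in seq_along(f2)) {
    bumped <- t0
    bumped@metadata$decisionRaw <- f2[i] + 10
    expect_lte(decisions(discretizeDecision(bumped)), dec[i])
  }
})

test_that("the ISF dialect reader reproduces a CSV-loaded table", {
  isf <- withr::local_tempfile(fileext = ".isf")
  writeLines(c(
    "**ATTRIBUTES",
    "+ force: [6, 12, 18]",
    "+ hardness: (continuous)",
    "+ class: [1, 2]",
    "decision: class",
    "**PREFERENCES",
    "force: none",
    "hardness: none",
    "**EXAMPLES",
    "6 40 2",
    "12 91 1",
    "18 229 1",
    "**END"), isf)
  tbl <- loadDecisionTable(isf, format = "isf")
  expect_equal(nObjects(tbl), 3L)
  expect_identical(decisions(tbl), c(2L, 1L, 1L))
  expect_identical(colnames(conditionValues(tbl)), c("force", "hardness"))
  expect_identical(attributeInfo(tbl)$domainType, c("set", "free"))
})

test_that("writeDecisionTable round-trips the normalized grid", {
  tbl <- discretizeDecision(exampleTable())
  out <- withr::local_tempfile(fileext = ".csv")
  writeDecisionTable(tbl, out)
  back <- utils::read.csv(out, check.names = FALSE)
  expect_equal(nrow(back), 20L)
  expect_identical(as.integer(back$class), decisions(tbl))
  expect_equal(back$Hardness, conditionValues(tbl)$Hardness)
})
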