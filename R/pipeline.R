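# simple Markdown table rendering for eyeball-diffable rule reports
writeMarkdownTable <- function(df, path, title = NULL) {
  lines <- character(0)
  if (!is.null(title)) lines <- c(paste("#", title), "")
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 6) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(df)))
  lines <- c(lines,
             paste("|", paste(names(df), collapse = " | "), "|"),
             paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
             apply(fmt, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  writeLines(lines, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full DRSA analysis pipeline
#'
#' Executes load -> binarize -> two-copy transform -> decision
#' discretization -> union approximations -> rule induction -> VC-bagging
#' ensemble (with optional repeated stratified cross-validation) ->
#' attribute relevance, and writes a report bundle: the normalized table,
#' an approximation report, ranked rule tables for both classes (CSV and
#' Markdown, with support, truncated strength and confirmation columns),
#' the CV report, the relevance ranking, and a provenance log echoing the
#' configuration and seed.
#'
#' @param input path to the formulation CSV (alternative to `table`).
#' @param schema attribute metadata from [readSchema()] or
#'   [formulationSchema()]; defaults to the latter.
#' @param table a ready [DecisionTable-class] (alternative to `input`).
#' @param outputDir directory for the report bundle (created if needed).
#' @param decision name of the decision column in the CSV.
#' @param id optional identifier column in the CSV.
#' @param f2Threshold class boundary on the f2 scale (default 50).
#' @param consistencyThreshold rule admissibility threshold.
#' @param k,repeats,nBags cross-validation and bagging settings.
#' @param seed root seed for all stochastic components.
#' @param measure confirmation measure.
#' @param topRules how many strongest rules to keep in the ranked tables.
#' @param doCV run the repeated stratified cross-validation (the slowest
#'   stage); disable for a rules-only report.
#' @return (invisibly) a list with the transformed table, approximation
#'   report, rule sets, ensemble, CV report and relevance ranking.
#' @export
runPipeline <- function(input = NULL, schema = NULL, table = NULL,
                        outputDir = tempfile("drsa-report-"),
                        decision = "f2", id = NULL, f2Threshold = 50,
                        consistencyThreshold = 1, k = 5, repeats = 100,
                        nBags = 30, seed = 1, measure = "s", topRules = 20,
                        doCV = TRUE) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(schema)) schema <- formulationSchema()
  tbl <- stage("load", {
    if (is.null(table)) {
      if (is.null(input)) stop("either 'input' or 'table' is required")
      loadDecisionTable(input, schema, decision = decision, id = id)
    } else table
  })
  tbl <- stage("binarize", {
    for (a in tbl@attrInfo$name[tbl@attrInfo$kind == "nominal"]) {
      tbl <- binarizeNominal(tbl, a)
    }
    tbl
  })
  tbl <- stage("two-copy", cloneGainCost(tbl))
  tbl <- stage("discretize", {
    if (length(tbl@decision)) tbl
    else discretizeDecision(tbl, threshold = f2Threshold)
  })
  writeDecisionTable(tbl, file.path(outputDir, "table_normalized.csv"))
  approx <- stage("approximations", approximationReport(tbl))
  utils::write.csv(approx, file.path(outputDir, "approximations.csv"),
                   row.names = FALSE)
  rulesUp <- stage("induce", induceRules(tbl, "atleast", 1,
                                         consistencyThreshold, measure))
  rulesDown <- stage("induce", induceRules(tbl, "atmost", 2,
                                           consistencyThreshold, measure))
  for (side in list(list(rs = rulesUp, nm = "rules_class1"),
                    list(rs = rulesDown, nm = "rules_class2"))) {
    df <- as.data.frame(side$rs, table = tbl, strict = TRUE)
    df <- utils::head(df, topRules)
    df <- data.frame(rule = seq_len(nrow(df)), premise = df$premise,
                     ruleSupport = df$support,
                     ruleStrength = df$strengthDisplay,
                     confirmationMeasure = round(df$confirmation, 2))
    utils::write.csv(df, file.path(outputDir, paste0(side$nm, ".csv")),
                     row.names = FALSE)
    writeMarkdownTable(df, file.path(outputDir, paste0(side$nm, ".md")),
                       title = gsub("_", " ", side$nm))
  }
  ens <- stage("ensemble", suppressWarnings(
    vcBaggingTrain(tbl, nBags = nBags,
                   consistencyThreshold = consistencyThreshold,
                   seed = seed, measure = measure)))
  cv <- NULL
  if (doCV) {
    cv <- stage("cross-validation",
                crossValidate(tbl, k = k, repeats = repeats, nBags = nBags,
                              consistencyThreshold = consistencyThreshold,
                              seed = seed, measure = measure))
    s <- cvSummary(cv)
    utils::write.csv(cv@perRepeat, file.path(outputDir, "cv_per_repeat.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(settings = cv@settings, summary = s),
      file.path(outputDir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  rel <- stage("relevance", attributeRelevance(ens, tbl, measure = measure))
  utils::write.csv(rel, file.path(outputDir, "relevance.csv"), row.names = FALSE)
  cfg <- list(decision = decision, f2Threshold = f2Threshold,
              consistencyThreshold = consistencyThreshold, k = k,
              repeats = repeats, nBags = nBags, seed = seed,
              measure = measure, topRules = topRules, doCV = doCV,
              nObjects = nObjects(tbl),
              package = as.character(utils::packageVersion("drsarules")),
              rversion = R.version.string)
  jsonlite::write_json(cfg, file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", seed),
    paste("objects:", nObjects(tbl)),
    paste("config:", jsonlite::toJSON(cfg, auto_unbox = TRUE))
  ), file.path(outputDir, "run_log.txt"))
  invisible(list(table = tbl, approximations = approx,
                 rulesClass1 = rulesUp, rulesClass2 = rulesDown,
                 ensemble = ens, cv = cv, relevance = rel,
                 outputDir = outputDir))
}
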