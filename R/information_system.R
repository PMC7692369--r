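#' Construct a decision table
#'
#' @param values data.frame of condition-attribute values (numeric columns;
#'   nominal attributes are integer-coded as in the schema).
#' @param decision integer vector of ordinal class labels (1 = best), or
#'   `integer(0)` when the decision is still a raw measurement (see
#'   [discretizeDecision()]).
#' @param attrInfo optional attribute metadata; defaults to numeric
#'   attributes of unknown preference with free domains.
#' @param metadata optional list of table-level metadata.
#' @return a [DecisionTable-class].
#' @examples
#' tbl <- decisionTable(data.frame(hardness = c(40, 60, 90)),
#'                      decision = c(2L, 2L, 1L))
#' nObjects(tbl)
#' @export
decisionTable <- function(values, decision = integer(0), attrInfo = NULL,
                          metadata = list()) {
  values <- as.data.frame(values)
  if (is.null(rownames(values)) || identical(rownames(values), as.character(seq_len(nrow(values))))) {
    rownames(values) <- as.character(seq_len(nrow(values)))
  }
  bad <- !vapply(values, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric condition attributes: ",
         paste(colnames(values)[bad], collapse = ", "),
         " (encode nominal attributes as integer codes)")
  }
  if (is.null(attrInfo)) {
    attrInfo <- makeAttrInfo(colnames(values))
  }
  attrInfo <- as.data.frame(attrInfo)
  new("DecisionTable", values = values,
      decision = as.integer(decision),
      attrInfo = attrInfo, metadata = metadata)
}

# attribute metadata constructor; domain is a list column
makeAttrInfo <- function(name, kind = "numeric", preference = "none",
                         source = name, domainType = "free",
                         domain = vector("list", length(name))) {
  df <- data.frame(name = name, kind = kind, preference = preference,
                   source = source, domainType = domainType,
                   stringsAsFactors = FALSE)
  df$domain <- domain
  df
}

#' @rdname DecisionTable-accessors
#' @aliases nObjects,DecisionTable-method
#' @param x a [DecisionTable-class], [RuleSet-class] or [RuleEnsemble-class].
#' @export
setMethod("nObjects", "DecisionTable", function(x) nrow(x@values))

#' @rdname DecisionTable-accessors
#' @export
setMethod("objectIds", "DecisionTable", function(x) rownames(x@values))

#' @rdname DecisionTable-accessors
#' @export
setMethod("decisions", "DecisionTable", function(x) x@decision)

#' @rdname DecisionTable-accessors
#' @export
setMethod("conditionValues", "DecisionTable", function(x) x@values)

#' Accessors for DecisionTable and related classes
#'
#' `nObjects()`, `objectIds()`, `decisions()`, `conditionValues()`,
#' `attributeInfo()` and `tableMetadata()` extract the corresponding parts of
#' a [DecisionTable-class].
#'
#' @name DecisionTable-accessors
#' @rdname DecisionTable-accessors
#' @aliases attributeInfo,DecisionTable-method
#' @export
setMethod("attributeInfo", "DecisionTable", function(x) x@attrInfo)

#' @rdname DecisionTable-accessors
#' @export
setMethod("tableMetadata", "DecisionTable", function(x) x@metadata)

setMethod("show", "DecisionTable", function(object) {
  cat("DecisionTable with", nrow(object@values), "objects and",
      ncol(object@values), "condition attributes\n")
  pref <- table(factor(object@attrInfo$preference,
                       levels = c("gain", "cost", "none")))
  cat("  preferences: ", paste(names(pref), pref, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(object@decision)) {
    tab <- table(object@decision)
    cat("  decision classes: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n", sep = "")
  } else {
    cat("  decision: not yet discretized\n")
  }
})

#' Subset the objects of a decision table
#'
#' @param table a [DecisionTable-class].
#' @param idx integer or logical index of objects to keep (duplicates
#'   allowed, e.g. for bootstrap samples).
#' @return a [DecisionTable-class] with the selected rows; per-object
#'   metadata vectors are subset alongside.
#' @export
subsetObjects <- function(table, idx) {
  v <- table@values[idx, , drop = FALSE]
  rownames(v) <- make.unique(rownames(table@values)[idx])
  md <- table@metadata
  n <- nrow(table@values)
  md <- lapply(md, function(m) {
    if (is.atomic(m) && length(m) == n && is.null(dim(m))) m[idx] else m
  })
  dec <- if (length(table@decision)) table@decision[idx] else integer(0)
  new("DecisionTable", values = v, decision = dec,
      attrInfo = table@attrInfo, metadata = md)
}

#' Read an attribute schema
#'
#' Reads attribute declarations from CSV (columns `name`, `kind`,
#' `preference`, `domain_type`, `domain`, the latter semicolon-separated),
#' or from YAML/JSON files with a list of the same fields per attribute.
#'
#' @param path path to the schema file; format chosen by extension.
#' @return attribute metadata suitable for [loadDecisionTable()].
#' @export
readSchema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML schemas")
    }
    entries <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(entries, function(e) {
      data.frame(name = e$name, kind = e$kind %||% "numeric",
                 preference = e$preference %||% "none",
                 domain_type = e$domain_type %||% "free",
                 domain = paste(e$domain, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else if (ext == "json") {
    df <- as.data.frame(jsonlite::fromJSON(path))
    if (is.null(df$domain)) df$domain <- ""
    df$domain <- vapply(df$domain, function(d) paste(unlist(d), collapse = ";"), "")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  dom <- lapply(df$domain, function(d) {
    if (is.na(d) || !nzchar(d)) NULL else as.numeric(strsplit(d, ";")[[1]])
  })
  makeAttrInfo(df$name, kind = df$kind, preference = df$preference,
               domainType = df$domain_type, domain = dom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# domain validation used by the loaders
checkDomains <- function(values, attrInfo, tol = 1e-8) {
  for (j in seq_len(ncol(values))) {
    v <- values[[j]]
    dt <- attrInfo$domainType[j]
    dom <- attrInfo$domain[[j]]
    if (is.null(dom) || dt == "free") next
    if (dt == "set") {
      ok <- vapply(v, function(x) any(abs(x - dom) <= tol), logical(1))
    } else {
      ok <- v >= dom[1] - tol & v <= dom[2] + tol
    }
    if (!all(ok)) {
      stop("value outside declared domain for attribute '",
           attrInfo$name[j], "': ", paste(unique(v[!ok]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Load a decision table from CSV (or jMAF/jRS ISF)
#'
#' The CSV dialect is comma-separated with dot decimals and a header row of
#' attribute names. Columns must match the schema exactly: unknown columns
#' are rejected and missing ones are an error. Row order is preserved;
#' object identifiers default to 1-based row numbers unless `id` names an
#' identifier column. As an alternative dialect, `format = "isf"` reads the
#' attribute-declaration header format used by jMAF/jRS rough-set software.
#'
#' @param path input file path.
#' @param schema attribute metadata from [readSchema()] (ignored for ISF,
#'   which declares its own attributes).
#' @param decision name of the decision column.
#' @param id optional name of an object-identifier column.
#' @param discretized logical; if `TRUE` the decision column already holds
#'   integer class labels, otherwise it is kept raw for
#'   [discretizeDecision()].
#' @param format `"csv"` or `"isf"`.
#' @return a [DecisionTable-class].
#' @examples
#' csv <- system.file("extdata", "table2_formulations.csv", package = "drsarules")
#' sch <- readSchema(system.file("extdata", "table1_schema.csv", package = "drsarules"))
#' tbl <- loadDecisionTable(csv, sch, decision = "f2", id = "formulation")
#' tbl
#' @export
loadDecisionTable <- function(path, schema, decision = "f2", id = NULL,
                              discretized = FALSE, format = c("csv", "isf")) {
  format <- match.arg(format)
  if (format == "isf") return(readIsfTable(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no objects: the CSV body is empty")
  if (!decision %in% names(raw)) {
    stop("missing decision column '", decision, "'")
  }
  if (!is.null(id)) {
    if (!id %in% names(raw)) stop("identifier column '", id, "' not found")
    ids <- as.character(raw[[id]])
    if (anyDuplicated(ids)) stop("duplicate object identifiers in column '", id, "'")
    raw[[id]] <- NULL
  } else {
    ids <- as.character(seq_len(nrow(raw)))
  }
  decRaw <- raw[[decision]]
  raw[[decision]] <- NULL
  unknown <- setdiff(names(raw), schema$name)
  if (length(unknown)) {
    stop("unknown columns not declared in the schema: ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(schema$name, names(raw))
  if (length(missing)) {
    stop("columns declared in the schema but absent: ",
         paste(missing, collapse = ", "))
  }
  values <- raw[, schema$name, drop = FALSE]
  rownames(values) <- ids
  checkDomains(values, schema)
  md <- list(decisionName = decision)
  dec <- integer(0)
  if (discretized) {
    if (!is.numeric(decRaw) || any(decRaw != as.integer(decRaw))) {
      stop("decision column is not integer class labels")
    }
    dec <- as.integer(decRaw)
  } else {
    if (!is.numeric(decRaw)) stop("non-numeric decision value in column '", decision, "'")
    md$decisionRaw <- as.numeric(decRaw)
  }
  decisionTable(values, decision = dec, attrInfo = schema, metadata = md)
}

# minimal reader for the jMAF/jRS ISF dialect:
#   **ATTRIBUTES / + name: [v1, v2] or (continuous) / decision: name
#   **PREFERENCES / name: gain|cost|none
#   **EXAMPLES ... **END
readIsfTable <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  sec <- cumsum(grepl("^\\*\\*", lines))
  headers <- toupper(sub("^\\*\\*", "", lines[grepl("^\\*\\*", lines)]))
  getSection <- function(name) {
    k <- which(headers == name)
    if (!length(k)) return(character(0))
    body <- lines[sec == k]
    body[-1]
  }
  attrLines <- getSection("ATTRIBUTES")
  decName <- NULL
  nm <- character(0); kind <- character(0); dom <- list(); dt <- character(0)
  for (ln in attrLines) {
    if (grepl("^decision\\s*:", ln, ignore.case = TRUE)) {
      decName <- trimws(sub("^decision\\s*:", "", ln, ignore.case = TRUE))
      next
    }
    m <- regmatches(ln, regexec("^\\+\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    a <- trimws(m[2]); spec <- trimws(m[3])
    nm <- c(nm, a)
    if (grepl("continuous", spec)) {
      kind <- c(kind, "numeric"); dt <- c(dt, "free"); dom <- c(dom, list(NULL))
    } else {
      vals <- as.numeric(strsplit(gsub("\\[|\\]", "", spec), ",")[[1]])
      kind <- c(kind, "numeric"); dt <- c(dt, "set"); dom <- c(dom, list(vals))
    }
  }
  if (is.null(decName)) decName <- nm[length(nm)]
  pref <- stats::setNames(rep("none", length(nm)), nm)
  for (ln in getSection("PREFERENCES")) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(pref)) pref[trimws(m[2])] <- tolower(m[3])
  }
  exLines <- getSection("EXAMPLES")
  exLines <- exLines[!grepl("^\\*\\*", exLines)]
  fields <- lapply(exLines, function(ln) strsplit(ln, "[,[:space:]]+")[[1]])
  mat <- do.call(rbind, lapply(fields, as.numeric))
  if (is.null(mat) || nrow(mat) == 0L) stop("no objects: empty ISF EXAMPLES section")
  colnames(mat) <- nm
  values <- as.data.frame(mat)
  decIdx <- match(decName, nm)
  dec <- as.integer(values[[decIdx]])
  values <- values[, -decIdx, drop = FALSE]
  keep <- setdiff(seq_along(nm), decIdx)
  ai <- makeAttrInfo(nm[keep], kind = kind[keep],
                     preference = unname(pref[keep]),
                     domainType = dt[keep], domain = dom[keep])
  checkDomains(values, ai)
  decisionTable(values, decision = dec, attrInfo = ai,
                metadata = list(decisionName = decName))
}

#' Write a decision table back to normalized CSV
#'
#' @param table a [DecisionTable-class].
#' @param path output path.
#' @export
writeDecisionTable <- function(table, path) {
  out <- cbind(id = rownames(table@values), table@values)
  if (length(table@decision)) out$class <- table@decision
  if (!is.null(table@metadata$decisionRaw)) {
    out[[table@metadata$decisionName %||% "decisionRaw"]] <- table@metadata$decisionRaw
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Replace a nominal attribute by one 0/1 indicator per domain value
#'
#' A nominal attribute with m domain values is replaced by m binary
#' attributes named `<name>_<value>`, where 1 means presence of that value
#' and 0 absence; exactly one indicator is 1 for each object. The new
#' columns record the original attribute as their `source`.
#'
#' @param table a [DecisionTable-class].
#' @param attribute name of a nominal attribute.
#' @return the transformed [DecisionTable-class].
#' @seealso [reconstructNominal()] for the inverse mapping.
#' @export
binarizeNominal <- function(table, attribute) {
  ai <- table@attrInfo
  j <- match(attribute, ai$name)
  if (is.na(j)) stop("unknown attribute '", attribute, "'")
  if (ai$kind[j] != "nominal") stop("attribute '", attribute, "' is not nominal")
  v <- table@values[[j]]
  dom <- ai$domain[[j]]
  if (is.null(dom)) dom <- sort(unique(v))
  bin <- as.data.frame(lapply(dom, function(d) as.integer(v == d)))
  names(bin) <- paste0(attribute, "_", format(dom, trim = TRUE))
  newAi <- makeAttrInfo(names(bin), kind = "numeric", preference = "none",
                        source = attribute, domainType = "set",
                        domain = rep(list(c(0, 1)), length(dom)))
  values <- cbind(
    table@values[, seq_len(j - 1L), drop = FALSE], bin,
    table@values[, setdiff(seq_len(ncol(table@values)), seq_len(j)), drop = FALSE]
  )
  rownames(values) <- rownames(table@values)
  attrInfo <- rbind(ai[seq_len(j - 1L), ], newAi,
                    ai[setdiff(seq_len(nrow(ai)), seq_len(j)), ])
  rownames(attrInfo) <- NULL
  new("DecisionTable", values = values, decision = table@decision,
      attrInfo = attrInfo, metadata = table@metadata)
}

#' Reconstruct a binarized nominal attribute
#'
#' Inverse of [binarizeNominal()]: returns the original nominal value per
#' object as the domain value whose indicator column is 1.
#'
#' @param table a [DecisionTable-class] containing the indicator columns.
#' @param source name of the original nominal attribute.
#' @return numeric vector of reconstructed values.
#' @export
reconstructNominal <- function(table, source) {
  ai <- table@attrInfo
  cols <- which(ai$source == source & ai$name != source)
  if (!length(cols)) stop("no binarized columns with source '", source, "'")
  vals <- as.numeric(sub(paste0("^", source, "_"), "", ai$name[cols]))
  sub <- as.matrix(table@values[, cols, drop = FALSE])
  vals[max.col(sub, ties.method = "first")]
}

#' Gain/cost two-copy transformation
#'
#' When it is unknown a priori whether larger values of an attribute favour
#' the better class (gain-type) or the worse class (cost-type), the
#' attribute is considered in two copies: the first assumed gain-type, the
#' second cost-type. Rule induction may then place conditions on one or both
#' copies, so the monotone direction of each relationship is discovered
#' rather than imposed. The transformation is non-invasive: values are
#' identical in both copies, and attributes already declared gain or cost
#' are left as a single copy. Nominal attributes are left untouched
#' (binarize them first; indicators are ordered presence/absence).
#'
#' @param table a [DecisionTable-class].
#' @return the transformed [DecisionTable-class], with `<name>_gain` and
#'   `<name>_cost` columns replacing each unknown-preference numeric
#'   attribute.
#' @export
cloneGainCost <- function(table) {
  ai <- table@attrInfo
  pieces <- list(); infos <- list()
  for (j in seq_len(nrow(ai))) {
    col <- table@values[, j, drop = FALSE]
    if (ai$preference[j] == "none" && ai$kind[j] == "numeric") {
      g <- col; c2 <- col
      names(g) <- paste0(ai$name[j], "_gain")
      names(c2) <- paste0(ai$name[j], "_cost")
      pieces <- c(pieces, list(g, c2))
      infos <- c(infos, list(
        makeAttrInfo(names(g), kind = "numeric", preference = "gain",
                     source = ai$name[j], domainType = ai$domainType[j],
                     domain = ai$domain[j]),
        makeAttrInfo(names(c2), kind = "numeric", preference = "cost",
                     source = ai$name[j], domainType = ai$domainType[j],
                     domain = ai$domain[j])
      ))
    } else {
      pieces <- c(pieces, list(col))
      infos <- c(infos, list(ai[j, , drop = FALSE]))
    }
  }
  values <- do.call(cbind, pieces)
  rownames(values) <- rownames(table@values)
  attrInfo <- do.call(rbind, infos)
  rownames(attrInfo) <- NULL
  new("DecisionTable", values = values, decision = table@decision,
      attrInfo = attrInfo, metadata = table@metadata)
}

#' Discretize the decision attribute by the f2 >= 50 rule
#'
#' Maps the raw f2 similarity factor to ordinal classes: class 1 (release
#' profile similar to uncompressed pellets) where `f2 >= threshold`, class 2
#' (profile changed) otherwise. The comparison is a sharp `>=` with no
#' tolerance band; the raw values are retained as table metadata and are
#' not condition attributes.
#'
#' @param table a [DecisionTable-class].
#' @param column optional name of a condition column holding the raw f2
#'   values; by default the raw decision column stored at load time is used.
#' @param threshold class boundary on the f2 scale (default 50).
#' @return the table with an integer decision (1 or 2).
#' @export
discretizeDecision <- function(table, column = NULL, threshold = 50) {
  if (!is.null(column)) {
    j <- match(column, table@attrInfo$name)
    if (is.na(j)) stop("unknown f2 column '", column, "'")
    raw <- table@values[[j]]
    table@values <- table@values[, -j, drop = FALSE]
    table@attrInfo <- table@attrInfo[-j, , drop = FALSE]
    rownames(table@attrInfo) <- NULL
    table@metadata$decisionName <- column
  } else {
    raw <- table@metadata$decisionRaw
    if (is.null(raw)) stop("no raw decision values: load with discretized = FALSE or give 'column'")
  }
  if (!is.numeric(raw)) stop("non-numeric f2 value")
  table@metadata$f2 <- as.numeric(raw)
  table@metadata$f2Threshold <- threshold
  table@metadata$decisionRaw <- NULL
  table@decision <- ifelse(raw >= threshold, 1L, 2L)
  validObject(table)
  table
}
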