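#' ClassUnionApproximation: rough approximations of a union of classes
#'
#' @slot unionType `"atleast"` or `"atmost"`.
#' @slot unionClass integer class index t.
#' @slot members object ids belonging to the union.
#' @slot lower,upper,boundary object ids of the lower/upper approximation
#'   and the boundary (upper minus lower).
#' @slot gamma numeric; global quality of classification of the table
#'   (fraction of objects outside every union boundary).
#' @seealso [unionApproximations()]
#' @export
setClass("ClassUnionApproximation",
  slots = c(
    unionType = "character", unionClass = "integer",
    members = "character", lower = "character", upper = "character",
    boundary = "character", gamma = "numeric"
  )
)

setValidity("ClassUnionApproximation", function(object) {
  msg <- character()
  if (!all(object@lower %in% object@members)) {
    msg <- c(msg, "lower approximation must be included in the union")
  }
  if (!all(object@members %in% object@upper)) {
    msg <- c(msg, "the union must be included in its upper approximation")
  }
  if (!setequal(object@boundary, setdiff(object@upper, object@lower))) {
    msg <- c(msg, "boundary must equal upper minus lower")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for union approximations
#'
#' @param x a [ClassUnionApproximation-class].
#' @return object-id character vectors (`unionMembers`, `lowerApproximation`,
#'   `upperApproximation`, `boundaryObjects`) or the gamma fraction
#'   (`gammaQuality`).
#' @name approximation-accessors
#' @rdname approximation-accessors
#' @export
unionMembers <- function(x) x@members

#' @rdname approximation-accessors
#' @export
lowerApproximation <- function(x) x@lower

#' @rdname approximation-accessors
#' @export
upperApproximation <- function(x) x@upper

#' @rdname approximation-accessors
#' @export
boundaryObjects <- function(x) x@boundary

#' @rdname approximation-accessors
#' @export
gammaQuality <- function(x) x@gamma

setMethod("show", "ClassUnionApproximation", function(object) {
  cat(sprintf("Union '%s class %d': %d members, lower %d, upper %d, boundary %d (gamma = %.4f)\n",
              object@unionType, object@unionClass, length(object@members),
              length(object@lower), length(object@upper),
              length(object@boundary), object@gamma))
})

# all condition attributes must be ordered (gain or cost) before any
# dominance computation
stopIfUnordered <- function(table) {
  ai <- table@attrInfo
  bad <- ai$preference == "none"
  if (any(bad)) {
    stop("attributes without a gain/cost preference: ",
         paste(ai$name[bad], collapse = ", "),
         " (apply binarizeNominal()/cloneGainCost() first)")
  }
  invisible(TRUE)
}

# Pairwise dominance matrix: D[i, j] is TRUE iff object i weakly dominates
# object j, i.e. i is >= j on every gain attribute and <= j on every cost
# attribute. A gain/cost copy pair sharing values contributes an equality
# constraint on its source attribute; those are evaluated jointly through a
# grouping key, which keeps the two copies from being compared twice.
dominanceMatrix <- function(table) {
  stopIfUnordered(table)
  ai <- table@attrInfo
  M <- as.matrix(table@values)
  n <- nrow(M)
  eqRep <- integer(0)
  rest <- logical(ncol(M))
  for (src in unique(ai$source)) {
    cols <- which(ai$source == src)
    g <- cols[ai$preference[cols] == "gain"]
    c2 <- cols[ai$preference[cols] == "cost"]
    if (length(g) == 1L && length(c2) == 1L &&
        identical(M[, g], M[, c2])) {
      eqRep <- c(eqRep, g)
    } else {
      rest[cols] <- TRUE
    }
  }
  D <- matrix(TRUE, n, n)
  if (length(eqRep)) {
    key <- do.call(paste, c(as.data.frame(M[, eqRep, drop = FALSE]), sep = "\r"))
    gid <- match(key, key)
    D <- outer(gid, gid, "==")
  }
  for (j in which(rest)) {
    v <- M[, j]
    D <- D & if (ai$preference[j] == "gain") outer(v, v, ">=") else outer(v, v, "<=")
  }
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

# logical membership of the union over objects; class 1 is best, so
# "at least class t" collects labels <= t and "at most class t" labels >= t
unionMembership <- function(decision, type, class) {
  if (!length(decision)) stop("table has no discretized decision")
  k <- max(decision)
  if (class < 1L || class > k) {
    stop("union spec references a nonexistent class: ", class)
  }
  if (type == "atleast") decision <= class else decision >= class
}

#' Dominance cone of an object
#'
#' The dominating cone of x collects the objects that weakly dominate x
#' (at least as good on every gain attribute, at most as good on every cost
#' attribute); the dominated cone collects the objects x weakly dominates.
#' Dominance is reflexive, so x belongs to both of its cones. After the
#' two-copy transformation each attribute constrains the cone in both
#' directions, so the cone reduces to the objects indiscernible from x.
#'
#' @param table a [DecisionTable-class] with gain/cost-typed attributes.
#' @param object object id (character) or row index.
#' @param direction `"dominating"` or `"dominated"`.
#' @return character vector of object ids in the cone.
#' @export
dominanceCone <- function(table, object,
                          direction = c("dominating", "dominated")) {
  direction <- match.arg(direction)
  ids <- rownames(table@values)
  j <- if (is.character(object)) match(object, ids) else as.integer(object)
  if (is.na(j) || j < 1L || j > length(ids)) stop("unknown object id: ", object)
  D <- dominanceMatrix(table)
  inCone <- if (direction == "dominating") D[, j] else D[j, ]
  ids[inCone]
}

#' Lower and upper approximations of a union of classes
#'
#' For an upward union ("at least class t") the lower approximation
#' collects the objects whose dominating cone lies entirely inside the
#' union — objects whose class assignment is consistent with the dominance
#' principle — and the upper approximation the objects whose dominated cone
#' intersects the union. The downward case is dual. The boundary (upper
#' minus lower) flags the inconsistent objects: formulations described at
#' least as favourably as some member of the union yet assigned outside it,
#' or vice versa.
#'
#' @param table a [DecisionTable-class] with gain/cost-typed attributes and
#'   a discretized decision.
#' @param type `"atleast"` (upward union) or `"atmost"` (downward union).
#' @param class class index t of the union.
#' @return a [ClassUnionApproximation-class].
#' @export
unionApproximations <- function(table, type = c("atleast", "atmost"), class) {
  type <- match.arg(type)
  class <- as.integer(class)
  D <- dominanceMatrix(table)
  approx <- approximateUnion(D, table@decision, type, class)
  ids <- rownames(table@values)
  new("ClassUnionApproximation",
      unionType = type, unionClass = class,
      members = ids[approx$memb], lower = ids[approx$lower],
      upper = ids[approx$upper],
      boundary = ids[approx$upper & !approx$lower],
      gamma = qualityFromD(D, table@decision))
}

# logical-vector workhorse shared with induction; D from dominanceMatrix()
approximateUnion <- function(D, decision, type, class) {
  memb <- unionMembership(decision, type, class)
  if (type == "atleast") {
    lower <- colSums(D[!memb, , drop = FALSE]) == 0L
    upper <- rowSums(D[, memb, drop = FALSE]) > 0L
  } else {
    lower <- rowSums(D[, !memb, drop = FALSE]) == 0L
    upper <- colSums(D[memb, , drop = FALSE]) > 0L
  }
  list(memb = memb, lower = lower, upper = upper)
}

qualityFromD <- function(D, decision) {
  k <- max(decision)
  inBoundary <- rep(FALSE, length(decision))
  for (t in seq_len(k - 1L)) {
    a <- approximateUnion(D, decision, "atleast", t)
    inBoundary <- inBoundary | (a$upper & !a$lower)
    b <- approximateUnion(D, decision, "atmost", t + 1L)
    inBoundary <- inBoundary | (b$upper & !b$lower)
  }
  mean(!inBoundary)
}

#' Quality of classification (gamma)
#'
#' The fraction of objects that belong to no union boundary, i.e. are
#' consistently classified under the dominance principle. Equals 1 iff the
#' table contains no dominance-inconsistent pair.
#'
#' @param table a [DecisionTable-class] with gain/cost-typed attributes.
#' @return gamma in `[0, 1]`.
#' @export
qualityOfClassification <- function(table) {
  qualityFromD(dominanceMatrix(table), table@decision)
}

#' Consistency of an object with respect to a class union
#'
#' The fraction of the object's dominance cone (dominating cone for upward
#' unions, dominated cone for downward unions) that belongs to the union.
#' A value of 1 means the object is fully consistent; an identical-condition
#' twin with a different class pulls the value below 1. This is the
#' cone-membership measure used to guide variable-consistency sampling and
#' rule admissibility.
#'
#' @param table a [DecisionTable-class].
#' @param object object id (character) or row index; if `NULL`, the vector
#'   for all objects is returned.
#' @param type union direction, `"atleast"` or `"atmost"`.
#' @param class class index t of the union.
#' @return consistency fraction(s) in `[0, 1]`.
#' @export
objectConsistency <- function(table, object = NULL,
                              type = c("atleast", "atmost"), class) {
  type <- match.arg(type)
  D <- dominanceMatrix(table)
  cons <- consistencyFromD(D, table@decision, type, as.integer(class))
  if (is.null(object)) {
    return(stats::setNames(cons, rownames(table@values)))
  }
  ids <- rownames(table@values)
  j <- if (is.character(object)) match(object, ids) else as.integer(object)
  if (is.na(j) || j < 1L || j > length(ids)) stop("unknown object id: ", object)
  cons[j]
}

consistencyFromD <- function(D, decision, type, class) {
  memb <- unionMembership(decision, type, class)
  out <- if (type == "atleast") {
    colSums(D[memb, , drop = FALSE]) / colSums(D)
  } else {
    rowSums(D[, memb, drop = FALSE]) / rowSums(D)
  }
  unname(out)
}

#' Approximation report for every meaningful union of a table
#'
#' @param table a [DecisionTable-class].
#' @return data.frame with one row per union: type, class, sizes of the
#'   union, lower and upper approximations and boundary, and gamma.
#' @export
approximationReport <- function(table) {
  k <- max(table@decision)
  specs <- rbind(
    data.frame(type = "atleast", class = seq_len(max(k - 1L, 1L))),
    data.frame(type = "atmost", class = if (k > 1L) 2:k else 1L)
  )
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    a <- unionApproximations(table, specs$type[i], specs$class[i])
    data.frame(union = a@unionType, class = a@unionClass,
               members = length(a@members), lower = length(a@lower),
               upper = length(a@upper), boundary = length(a@boundary),
               gamma = a@gamma,
               boundaryIds = paste(a@boundary, collapse = ";"))
  })
  do.call(rbind, rows)
}
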