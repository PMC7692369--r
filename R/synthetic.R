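#' Attribute schema of the tableting-process information system
#'
#' The 23 condition attributes describing a tableted-pellet formulation:
#' type of polymer coating (1 Eudragit NE, 2 ethyl cellulose, 3 shellac),
#' tablet press (1 single punch, 2 rotary), compression force (kN), tablet
#' mass (mg), hardness (N), crushing strength (10^4 N/m^2), friability (%)
#' and the excipient percentages with their admissible levels.
#'
#' @return attribute metadata usable with [loadDecisionTable()] and
#'   [generateTable()].
#' @export
formulationSchema <- function() {
  set <- function(...) list(c(...))
  rng <- function(a, b) list(c(a, b))
  rbind(
    makeAttrInfo("Coating", "nominal", domainType = "set", domain = set(1, 2, 3)),
    makeAttrInfo("Tablet_press", domainType = "set", domain = set(1, 2)),
    makeAttrInfo("Compression_force", domainType = "set", domain = set(6, 12, 18)),
    makeAttrInfo("Tablet_mass", domainType = "range", domain = rng(516, 568)),
    makeAttrInfo("Hardness", domainType = "range", domain = rng(11, 297)),
    makeAttrInfo("Crushing_strength", domainType = "range", domain = rng(11, 619)),
    makeAttrInfo("Friability", domainType = "range", domain = rng(0, 10.1)),
    makeAttrInfo("Avicel_102", domainType = "set", domain = set(0, 12.7, 47)),
    makeAttrInfo("Avicel_101", domainType = "set", domain = set(0, 12.7)),
    makeAttrInfo("Mannitol", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Tablettose_80", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Ludipress_LCE", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Arbocel_P290", domainType = "set", domain = set(0, 47)),
    makeAttrInfo("Sorbitol", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Povidone_K30", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("StarLac", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Starch_1500", domainType = "set", domain = set(0, 43.8)),
    makeAttrInfo("CaHPO4xH2O", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("CaHPO4", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Vivapur_200", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Avicel_CE015", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Macrogol_6000", domainType = "set", domain = set(0, 34.3)),
    makeAttrInfo("Kollidon_CL", domainType = "set", domain = set(0, 9.5))
  )
}

#' Default planted rules of the synthetic generator
#'
#' Two monotone class-1 rules in the style of the relationships the method
#' is meant to recover: an elastic Eudragit NE coating compressed above the
#' lowest force into sufficiently hard tablets, or an ethyl-cellulose-free
#' formulation of modest mass with adequate crushing strength and
#' microcrystalline cellulose (Avicel 102) as excipient.
#'
#' @return list of [Rule-class] objects concluding "at least class 1".
#' @export
defaultPlantedRules <- function() {
  list(
    decisionRule(c("Coating_1", "Compression_force", "Hardness"),
                 c(">=", ">=", ">="), c(1, 12, 42.4), "atleast", 1L),
    decisionRule(c("Coating_2", "Tablet_mass", "Crushing_strength", "Avicel_102"),
                 c("<=", "<=", ">=", ">="), c(0, 553.1, 68.8, 12.7),
                 "atleast", 1L)
  )
}

#' Configuration for the synthetic formulation-table generator
#'
#' @param nObjects number of formulations (default 180, the size of the
#'   study the generator emulates).
#' @param inconsistency fraction of class labels flipped after rule-based
#'   assignment, in `[0, 0.5)`; emulates dominance-inconsistent
#'   formulations.
#' @param plantedRules list of monotone [Rule-class] objects; an object is
#'   class 1 iff any planted class-1 rule fires.
#' @param replicates how many formulations share each distinct design point
#'   (default 2). Replicated design families mirror the way tableting
#'   studies repeat a composition across process settings, and they are what
#'   lets label noise surface as dominance inconsistency under the two-copy
#'   transform (a flipped label in a replicated family creates an
#'   identical-description pair with conflicting classes).
#' @param seed root seed.
#' @return validated configuration list.
#' @export
generatorConfig <- function(nObjects = 180, inconsistency = 0.1,
                            plantedRules = defaultPlantedRules(),
                            replicates = 2, seed = 1) {
  stopifnot(nObjects >= 2, inconsistency >= 0, inconsistency < 0.5,
            replicates >= 1)
  known <- c(formulationSchema()$name, paste0("Coating_", 1:3))
  for (r in plantedRules) {
    bad <- setdiff(r@conditions$attribute, known)
    if (length(bad)) {
      stop("planted rule references undeclared attributes: ",
           paste(bad, collapse = ", "))
    }
    if (any(r@conditions$relation == "=")) {
      stop("planted rules must be monotone (>= / <= conditions only)")
    }
  }
  list(nObjects = nObjects, inconsistency = inconsistency,
       plantedRules = plantedRules, replicates = replicates, seed = seed)
}

#' Generate a formulation-like decision table with known ground truth
#'
#' Draws condition attributes within the domains of the tableting-process
#' schema: numeric attributes uniformly within their ranges, compression
#' force from \{6, 12, 18\} kN, and the excipient columns following the
#' one-hot filler pattern of real tablet masses (exactly one bulk
#' filler/diluent per formulation, optionally an Avicel binder, Kollidon CL
#' as disintegrant except in starch formulations). Classes are assigned by
#' the planted monotone rules (class 1 iff any fires), then
#' `round(inconsistency * n)` labels are flipped, allocated across both
#' classes in proportion to their sizes so stratification stays meaningful.
#'
#' @param config from [generatorConfig()]; individual fields can also be
#'   passed directly.
#' @param nObjects,inconsistency,plantedRules,replicates,seed see
#'   [generatorConfig()].
#' @return list with `table` (a [DecisionTable-class] whose metadata also
#'   carries the ground truth), `truth` (labels before flipping) and
#'   `flipped` (indices of flipped objects).
#' @examples
#' g <- generateTable(generatorConfig(nObjects = 60, inconsistency = 0, seed = 7))
#' table(g$table@decision == g$truth)
#' @export
generateTable <- function(config = NULL, nObjects = 180, inconsistency = 0.1,
                          plantedRules = defaultPlantedRules(),
                          replicates = 2, seed = 1) {
  if (is.null(config)) {
    config <- generatorConfig(nObjects, inconsistency, plantedRules,
                              replicates, seed)
  }
  n <- config$nObjects
  set.seed(config$seed %% .Machine$integer.max)
  schema <- formulationSchema()
  # distinct design points, replicated into formulation families
  m <- ceiling(n / config$replicates)
  df <- data.frame(
    Coating = sample(1:3, m, replace = TRUE),
    Tablet_press = sample(1:2, m, replace = TRUE),
    Compression_force = sample(c(6, 12, 18), m, replace = TRUE),
    Tablet_mass = round(stats::runif(m, 516, 568), 1),
    Hardness = round(stats::runif(m, 11, 297)),
    Crushing_strength = round(stats::runif(m, 11, 619)),
    Friability = round(stats::runif(m, 0, 10.1), 2)
  )
  excip <- c("Avicel_102", "Avicel_101", "Mannitol", "Tablettose_80",
             "Ludipress_LCE", "Arbocel_P290", "Sorbitol", "Povidone_K30",
             "StarLac", "Starch_1500", "CaHPO4xH2O", "CaHPO4", "Vivapur_200",
             "Avicel_CE015", "Macrogol_6000", "Kollidon_CL")
  for (e in excip) df[[e]] <- 0
  fillers <- c("Mannitol", "Tablettose_80", "Ludipress_LCE", "Sorbitol",
               "Povidone_K30", "StarLac", "CaHPO4xH2O", "CaHPO4",
               "Vivapur_200", "Avicel_CE015", "Macrogol_6000",
               "Arbocel_P290", "Starch_1500", "Avicel_102_full")
  pick <- sample(fillers, m, replace = TRUE)
  for (i in seq_len(m)) {
    f <- pick[i]
    if (f == "Avicel_102_full") {
      df$Avicel_102[i] <- 47
    } else {
      df[[f]][i] <- if (f == "Arbocel_P290") 47 else if (f == "Starch_1500") 43.8 else 34.3
      # binder: mostly Avicel 102, sometimes Avicel 101
      if (stats::runif(1) < 0.75) df$Avicel_102[i] <- 12.7 else df$Avicel_101[i] <- 12.7
    }
    if (f != "Starch_1500") df$Kollidon_CL[i] <- 9.5
  }
  df <- df[rep(seq_len(m), each = config$replicates)[seq_len(n)], , drop = FALSE]
  rownames(df) <- NULL
  df <- df[, schema$name]
  # evaluate planted rules on the binarized view
  ev <- df
  for (v in 1:3) ev[[paste0("Coating_", v)]] <- as.integer(df$Coating == v)
  fires <- rep(FALSE, n)
  for (r in config$plantedRules) fires <- fires | matchOnData(r, ev)
  truth <- ifelse(fires, 1L, 2L)
  nFlip <- round(config$inconsistency * n)
  flipped <- integer(0)
  decision <- truth
  if (nFlip > 0L) {
    n1 <- sum(truth == 1L)
    f1 <- min(round(nFlip * n1 / n), n1)
    f2 <- min(nFlip - f1, n - n1)
    flipped <- c(if (f1 > 0) sample(which(truth == 1L), f1),
                 if (f2 > 0) sample(which(truth == 2L), f2))
    decision[flipped] <- 3L - decision[flipped]
  }
  tbl <- decisionTable(df, decision = decision, attrInfo = schema,
                       metadata = list(truth = truth, flipped = flipped,
                                       generator = config[c("nObjects", "inconsistency", "seed")]))
  list(table = tbl, truth = truth, flipped = sort(flipped))
}

#' Generate paired dissolution profiles with prescribed f2
#'
#' For each target, builds a reference release curve (first-order kinetics
#' over the sampling times) and a test curve at the constant point-wise
#' offset that solves the f2 equation exactly:
#' \eqn{d = \sqrt{10^{4 - f_2/25} - 1}}. A common bounded jitter is added
#' to both curves, which perturbs their shapes without changing the
#' differences, so the computed f2 stays within 0.5 of the target (a
#' target of 100 yields identical profiles, a target of 50 the offset
#' \eqn{\sqrt{99}}).
#'
#' @param f2Targets numeric targets in (0, 100].
#' @param nPoints sampling points (default 6, hourly from 1 h).
#' @param seed root seed.
#' @param times optional explicit sampling times.
#' @return named list per target with elements `reference`, `test`
#'   ([DissolutionProfile-class]), `target` and achieved `f2`.
#' @export
generateProfiles <- function(f2Targets, nPoints = 6, seed = 1, times = NULL) {
  stopifnot(all(f2Targets > 0), all(f2Targets <= 100))
  if (is.null(times)) times <- seq_len(nPoints)
  set.seed(seed %% .Machine$integer.max)
  out <- list()
  for (tg in f2Targets) {
    d <- sqrt(max(10^(4 - tg / 25) - 1, 0))
    rmax <- stats::runif(1, 88, 97)
    if (d >= rmax * 0.95) stop("unreachable f2 target given dissolution bounds: ", tg)
    # release rate fast enough that the first point stays above the offset
    kmin <- -log(1 - min(d * 1.1 / rmax, 0.95)) / times[1]
    kk <- max(stats::runif(1, 0.4, 0.8), kmin)
    ref <- rmax * (1 - exp(-kk * times))
    jit <- stats::runif(length(times), -1.5, 1.5)
    headroom <- 100 - max(ref)
    jit <- pmin(pmax(jit, -(min(ref) - d)), headroom)
    ref <- ref + jit
    test <- ref - d
    pr <- list(reference = dissolutionProfile(times, ref),
               test = dissolutionProfile(times, test),
               target = tg,
               f2 = similarityFactorF2(ref, test))
    out[[length(out) + 1L]] <- pr
  }
  names(out) <- make.unique(format(f2Targets, trim = TRUE))
  out
}
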