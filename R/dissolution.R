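#' Construct a dissolution profile
#'
#' @param times strictly increasing sampling times (hours).
#' @param dissolved percent of label claim dissolved at each time.
#' @return a [DissolutionProfile-class].
#' @examples
#' ref <- dissolutionProfile(1:6, c(28, 46, 60, 70, 77, 83))
#' @export
dissolutionProfile <- function(times, dissolved) {
  new("DissolutionProfile", times = as.numeric(times),
      dissolved = as.numeric(dissolved))
}

setMethod("show", "DissolutionProfile", function(object) {
  cat("DissolutionProfile with", length(object@times), "sampling points\n")
  print(stats::setNames(object@dissolved, paste0("t=", object@times)))
})

#' f2 similarity factor between two dissolution profiles
#'
#' Computes
#' \deqn{f_2 = 50 \log_{10}\left(100 \Big/ \sqrt{1 + \frac{1}{n}\sum_{t=1}^n (R(t)-T(t))^2}\right)}
#' where R and T are the percent dissolved of the reference and test profile
#' at each of the n shared sampling points. Identical profiles give
#' \eqn{f_2 = 100}; a constant point-wise difference of \eqn{\sqrt{99}}
#' gives exactly 50, the conventional boundary between similar and
#' dissimilar release. Values below 0 (very different profiles) are
#' returned as-is, not clipped.
#'
#' All paired points are used by default. The regulatory convention of
#' truncating the profile one point after 85% dissolved (to avoid plateau
#' inflation) is available via `truncate85` but is off by default.
#'
#' @param reference,test [DissolutionProfile-class] objects (or numeric
#'   vectors of percent dissolved sharing the same implicit time grid).
#' @param truncate85 logical; if `TRUE`, drop points after the first at
#'   which the reference reaches 85% dissolved.
#' @return the f2 value (dimensionless).
#' @examples
#' ref <- dissolutionProfile(1:6, c(28, 46, 60, 70, 77, 83))
#' similarityFactorF2(ref, ref)  # 100
#' @export
similarityFactorF2 <- function(reference, test, truncate85 = FALSE) {
  if (is(reference, "DissolutionProfile") && is(test, "DissolutionProfile")) {
    if (length(reference@times) != length(test@times) ||
        any(reference@times != test@times)) {
      stop("mismatched time points between reference and test profiles")
    }
    r <- reference@dissolved
    t <- test@dissolved
    tm <- reference@times
  } else {
    r <- as.numeric(reference)
    t <- as.numeric(test)
    if (length(r) != length(t)) stop("mismatched time points between reference and test profiles")
    tm <- seq_along(r)
  }
  if (length(r) < 1L) stop("empty profiles")
  if (truncate85) {
    k <- which(r >= 85)[1]
    if (!is.na(k) && k < length(r)) {
      r <- r[seq_len(k)]
      t <- t[seq_len(k)]
    }
  }
  msd <- mean((r - t)^2)
  50 * log10(100 / sqrt(1 + msd))
}

#' Tablet crushing strength
#'
#' The force needed to crush a tablet divided by the product of tablet
#' radius and thickness, reported in units of 10^4 N/m^2.
#'
#' @param force crushing force (N).
#' @param radius tablet radius (m).
#' @param thickness tablet thickness (m).
#' @return crushing strength in 10^4 N/m^2.
#' @examples
#' crushingStrength(100, 0.005, 0.002)  # 1000 (i.e. 1e7 N/m^2)
#' @export
crushingStrength <- function(force, radius, thickness) {
  if (any(force <= 0)) stop("force must be strictly positive")
  if (any(radius <= 0) || any(thickness <= 0)) {
    stop("radius and thickness must be strictly positive")
  }
  force / (radius * thickness) / 1e4
}

#' Read paired dissolution profiles from long-format CSV
#'
#' Expects columns `id`, `time`, `dissolved`, `role` with role either
#' `"reference"` (pellets before compression) or `"test"` (after).
#'
#' @param path CSV path.
#' @return named list (per id) of lists with `reference` and `test`
#'   [DissolutionProfile-class] objects.
#' @export
readProfiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "time", "dissolved", "role")
  if (!all(needed %in% names(df))) {
    stop("profile CSV must have columns ", paste(needed, collapse = ", "))
  }
  if (!all(df$role %in% c("reference", "test"))) {
    stop("role must be 'reference' or 'test'")
  }
  out <- lapply(split(df, df$id), function(d) {
    mk <- function(role) {
      dd <- d[d$role == role, ]
      dd <- dd[order(dd$time), ]
      if (!nrow(dd)) stop("missing ", role, " profile for id ", d$id[1])
      dissolutionProfile(dd$time, dd$dissolved)
    }
    list(reference = mk("reference"), test = mk("test"))
  })
  out[unique(as.character(df$id))]
}

#' f2 and class per formulation for a set of profile pairs
#'
#' @param profiles output of [readProfiles()] or [generateProfiles()].
#' @param threshold f2 class boundary (default 50).
#' @return data.frame with columns `id`, `f2`, `class`.
#' @export
f2Table <- function(profiles, threshold = 50) {
  f2 <- vapply(profiles, function(p) similarityFactorF2(p$reference, p$test),
               numeric(1))
  data.frame(id = names(profiles), f2 = unname(f2),
             class = ifelse(f2 >= threshold, 1L, 2L), row.names = NULL)
}
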