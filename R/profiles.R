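# Domain types for horizon-resolved soil profiles along a degradation gradient.
#
# Depth convention: cm, positive downward, 0 = the current (possibly eroded)
# surface of that profile; horizons are half-open intervals [top, bottom).
# A degraded profile's local depth z corresponds to reference depth
# z + crack_depth.

#' Degradation stage levels
#'
#' The six successive pasture degradation stages, from intact root mat (S0)
#' through widening polygonal surface cracks (S1-S4) to bare soil (S5).
#' S0 is the unique non-degraded reference stage.
#'
#' @return Character vector `c("S0", ..., "S5")` in increasing severity.
#' @export
degradation_stages <- function() {
  c("S0", "S1", "S2", "S3", "S4", "S5")
}

#' Coerce to an ordered degradation stage factor
#'
#' @param x Character or factor of stage codes.
#' @return Ordered factor with levels S0 < S1 < ... < S5.
#' @export
as_stage <- function(x) {
  out <- factor(as.character(x), levels = degradation_stages(), ordered = TRUE)
  if (anyNA(out) && !all(is.na(x))) {
    bad <- unique(as.character(x)[is.na(out) & !is.na(x)])
    stop("unknown degradation stage code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct a soil profile (one stage x replicate pedon)
#'
#' A profile is an ordered, contiguous stack of horizons starting at the
#' current surface (depth 0).  Each horizon carries SOC content (g C kg-1
#' soil), bulk density (g cm-3) and optionally N content (g N kg-1),
#' delta-13C (permil vs PDB), VSC lignin phenols (fraction of SOC), clay
#' (% mass) and root density (mg cm-3).  `crack_depth` is the vertical
#' extent of topsoil removal at the plot (cm); by definition it is 0 for
#' the reference stage S0.
#'
#' @param stage Stage code ("S0".."S5").
#' @param replicate Replicate identifier.
#' @param horizons `data.frame` with columns `label`, `top`, `bottom`,
#'   `soc`, `bd` and optionally `n`, `d13c`, `vsc`, `clay`, `root`.
#'   Depths in cm; rows are sorted by `top`.
#' @param crack_depth Topsoil removal depth in cm (0 for S0).
#' @return An object of class `soil_profile`.
#' @seealso [validate_profile()], [horizon_at()], [stage_ensemble()]
#' @export
#' @examples
#' h <- data.frame(label = c("Ah", "Bw"), top = c(0, 15), bottom = c(15, 35),
#'                 soc = c(60, 25), bd = c(0.85, 1.15))
#' p <- soil_profile("S0", "r1", h)
#' validate_profile(p)
soil_profile <- function(stage, replicate, horizons, crack_depth = 0) {
  stopifnot(is.data.frame(horizons))
  optional <- c("n", "d13c", "vsc", "clay", "root")
  for (col in optional) {
    if (is.null(horizons[[col]])) horizons[[col]] <- NA_real_
  }
  for (col in c("top", "bottom", "soc", "bd", optional)) {
    horizons[[col]] <- as.numeric(horizons[[col]])
  }
  horizons$label <- as.character(horizons$label)
  horizons <- horizons[order(horizons$top),
                       c("label", "top", "bottom", "soc", "bd", optional),
                       drop = FALSE]
  rownames(horizons) <- NULL
  structure(
    list(stage = as.character(stage),
         replicate = as.character(replicate),
         crack_depth = as.numeric(crack_depth),
         horizons = horizons),
    class = "soil_profile"
  )
}

#' Validate a soil profile against its type invariants
#'
#' Checks depth ordering and contiguity from the surface, non-negative SOC,
#' positive bulk density, VSC within [0, 1] where present, a known stage
#' code, non-negative crack depth, and crack depth 0 for the reference
#' stage.  Violations are returned, never raised, so that file readers can
#' report all problems at once.
#'
#' @param profile A [soil_profile()].
#' @return Character vector of violations; empty when the profile is valid.
#'   Each entry names the field and the rule broken.
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  h <- profile$horizons
  if (!profile$stage %in% degradation_stages()) {
    v <- c(v, sprintf("stage: unknown code '%s'", profile$stage))
  }
  if (nrow(h) == 0L) {
    return(c(v, "horizons: profile has no horizons"))
  }
  bad <- which(!(h$top >= 0 & h$top < h$bottom))
  for (i in bad) {
    v <- c(v, sprintf("horizon '%s': depth order violated (top %g, bottom %g)",
                      h$label[i], h$top[i], h$bottom[i]))
  }
  if (is.na(h$top[1]) || h$top[1] != 0) {
    v <- c(v, sprintf("horizon '%s': profile must start at depth 0 (top %g)",
                      h$label[1], h$top[1]))
  }
  if (nrow(h) > 1L) {
    gaps <- which(abs(h$top[-1] - h$bottom[-nrow(h)]) > 1e-9)
    for (i in gaps) {
      v <- c(v, sprintf(
        "horizons '%s'/'%s': contiguity violated (bottom %g vs top %g)",
        h$label[i], h$label[i + 1], h$bottom[i], h$top[i + 1]))
    }
  }
  bad <- which(!is.na(h$soc) & h$soc < 0)
  for (i in bad) v <- c(v, sprintf("horizon '%s': soc_content < 0", h$label[i]))
  if (anyNA(h$soc)) v <- c(v, "soc_content: missing value")
  bad <- which(is.na(h$bd) | h$bd <= 0)
  for (i in bad) {
    v <- c(v, sprintf("horizon '%s': bulk_density must be > 0", h$label[i]))
  }
  bad <- which(!is.na(h$vsc) & (h$vsc < 0 | h$vsc > 1))
  for (i in bad) {
    v <- c(v, sprintf("horizon '%s': vsc_content outside [0, 1]", h$label[i]))
  }
  if (is.na(profile$crack_depth) || profile$crack_depth < 0) {
    v <- c(v, "crack_depth: must be >= 0")
  } else if (profile$stage == "S0" && profile$crack_depth != 0) {
    v <- c(v, "crack_depth: reference crack (S0 must have crack_depth 0)")
  }
  v
}

#' Look up the horizon containing a given depth
#'
#' Horizons are half-open `[top, bottom)`, so a depth exactly on a boundary
#' belongs to the horizon below it.
#'
#' @param profile A [soil_profile()].
#' @param depth Depth in cm; must satisfy `0 <= depth < max(bottom)`.
#' @return One-row `data.frame`: the containing horizon.
#' @export
horizon_at <- function(profile, depth) {
  h <- profile$horizons
  if (length(depth) != 1L || is.na(depth) || depth < 0 ||
      depth >= max(h$bottom)) {
    stop(sprintf("depth out of range: %s (profile covers [0, %g))",
                 format(depth), max(h$bottom)))
  }
  i <- which(h$top <= depth & depth < h$bottom)[1]
  h[i, , drop = FALSE]
}

#' Total depth of a profile (cm below its own surface)
#' @param profile A [soil_profile()].
#' @return Numeric depth in cm.
#' @export
profile_depth <- function(profile) {
  max(profile$horizons$bottom)
}

#' Bundle replicate profiles of one degradation stage
#'
#' @param profiles List of [soil_profile()] objects sharing one stage, with
#'   unique replicate ids.
#' @return An object of class `stage_ensemble` with elements `stage` and
#'   `profiles` (named by replicate).
#' @export
stage_ensemble <- function(profiles) {
  if (length(profiles) < 1L) stop("stage_ensemble needs at least one profile")
  stages <- vapply(profiles, function(p) p$stage, character(1))
  if (length(unique(stages)) != 1L) {
    stop("all profiles in an ensemble must share one stage; got: ",
         paste(unique(stages), collapse = ", "))
  }
  reps <- vapply(profiles, function(p) p$replicate, character(1))
  if (anyDuplicated(reps)) {
    stop("replicate ids must be unique within a stage: ",
         paste(reps[duplicated(reps)], collapse = ", "))
  }
  names(profiles) <- reps
  structure(list(stage = stages[1], profiles = profiles),
            class = "stage_ensemble")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> stage %s, replicate %s, crack %g cm, %d horizons to %g cm\n",
              x$stage, x$replicate, x$crack_depth, nrow(x$horizons),
              profile_depth(x)))
  print(x$horizons)
  invisible(x)
}

#' @export
print.stage_ensemble <- function(x, ...) {
  cat(sprintf("<stage_ensemble> stage %s, %d replicate profile(s): %s\n",
              x$stage, length(x$profiles),
              paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}
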