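# Mass-balance partitioning of stage-wise SOC losses into an
# erosion-attributed part (topsoil removal, priced at reference content and
# bulk density) and a combined reduced-input/mineralization part, with a
# per-stage statistical closure check.
#
# Frames: each degraded profile's local depth z corresponds to reference
# depth z + crack_depth.  The headline total loss compares each profile's
# own [0, depth_limit] window; inside the partition the degraded stock is
# integrated in the REFERENCE frame (from the degraded surface down to
# reference depth depth_limit), which makes total = erosion + mineralization
# an algebraic identity on noiseless data.

# integral of content x BD (kg C m-2) over [from, to] of a profile's own axis
integrate_cb <- function(profile, from, to) {
  h <- profile$horizons
  thick <- pmax(0, pmin(h$bottom, to) - pmax(h$top, from))
  sum(h$soc * h$bd * thick) * 1e-2
}

# integral of BD (kg soil m-2) over [from, to]
integrate_bd <- function(profile, from, to) {
  h <- profile$horizons
  thick <- pmax(0, pmin(h$bottom, to) - pmax(h$top, from))
  sum(h$bd * thick) * 10
}

se_of <- function(x) {
  if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
}

# mean reference horizon layout across replicates: requires one common
# horizon sequence (labels checked; counts must agree)
reference_layout <- function(reference) {
  hs <- lapply(reference$profiles, function(p) p$horizons)
  n_h <- vapply(hs, nrow, integer(1))
  if (length(unique(n_h)) != 1L) {
    data_error("data error: reference replicates have differing horizon counts (%s)",
               paste(n_h, collapse = ", "))
  }
  labels <- hs[[1]]$label
  for (h in hs[-1]) {
    if (!identical(h$label, labels)) {
      warning("reference horizon labels differ across replicates; matching by position")
      break
    }
  }
  col_mean <- function(field) {
    colMeans(do.call(rbind, lapply(hs, function(h) h[[field]])))
  }
  data.frame(label = labels, top = col_mean("top"),
             bottom = col_mean("bottom"), soc = col_mean("soc"),
             bd = col_mean("bd"))
}

#' Mean crack depth of a stage ensemble
#' @param ensemble A [stage_ensemble()].
#' @return Mean of the replicate crack depths, cm.
#' @export
stage_crack_depth <- function(ensemble) {
  mean(vapply(ensemble$profiles, function(p) p$crack_depth, numeric(1)))
}

#' Total SOC stock loss of a degraded stage relative to the reference
#'
#' Mean reference cumulative stock minus mean degraded cumulative stock.
#' With `frame = "own"` both stocks use each profile's own
#' `[0, depth_limit]` window (the headline number).  With
#' `frame = "reference"` the degraded stock is integrated from the degraded
#' surface down to reference depth `depth_limit`, i.e. over local depths
#' `[0, depth_limit - crack_depth]`; this is the window under which the
#' partition closes exactly.  The SE is propagated as
#' `sqrt(SE_ref^2 + SE_deg^2)`.  Losses are signed: a degraded stock above
#' the reference yields a negative loss.
#'
#' @param reference Reference (S0) [stage_ensemble()].
#' @param degraded Degraded [stage_ensemble()].
#' @param depth_limit Integration depth, cm.
#' @param frame `"own"` or `"reference"` (see above).
#' @param crack_depth Topsoil removal depth used in the reference frame;
#'   defaults to the degraded ensemble's mean crack depth.
#' @return List: `mean`, `se`, `per_replicate` (loss of each degraded
#'   replicate vs the reference mean), `frame`.
#' @export
total_loss <- function(reference, degraded, depth_limit = 30,
                       frame = c("own", "reference"),
                       crack_depth = stage_crack_depth(degraded)) {
  frame <- match.arg(frame)
  if (length(reference$profiles) == 0L || length(degraded$profiles) == 0L) {
    data_error("data error: empty ensemble in total_loss")
  }
  ref_stocks <- vapply(reference$profiles,
                       function(p) integrate_cb(p, 0, depth_limit), numeric(1))
  deg_to <- if (frame == "own") depth_limit else depth_limit - crack_depth
  if (deg_to < 0) {
    data_error("data error: crack_depth %g exceeds depth_limit %g", crack_depth,
               depth_limit)
  }
  deg_stocks <- vapply(degraded$profiles,
                       function(p) integrate_cb(p, 0, deg_to), numeric(1))
  list(mean = mean(ref_stocks) - mean(deg_stocks),
       se = sqrt(sum(c(se_of(ref_stocks), se_of(deg_stocks))^2)),
       per_replicate = mean(ref_stocks) - deg_stocks,
       frame = frame)
}

#' Erosion-attributed SOC loss from topsoil removal
#'
#' Prices the removed topsoil column `[0, crack_depth]` (reference frame) at
#' the reference stage's SOC content and bulk density: for each reference
#' replicate the integral of content x BD over that interval, reported as
#' mean +/- SE across reference replicates.  Also returns the eroded soil
#' mass (integral of BD alone, kg m-2).
#'
#' @param reference Reference (S0) [stage_ensemble()].
#' @param crack_depth Topsoil removal depth, cm (>= 0); must not exceed the
#'   shallowest reference profile.
#' @return List: `mean`, `se` (kg C m-2), `soil_mass_mean`, `soil_mass_se`
#'   (kg m-2), `per_replicate`.
#' @export
erosion_loss <- function(reference, crack_depth) {
  if (crack_depth < 0) data_error("data error: crack_depth must be >= 0")
  depths <- vapply(reference$profiles, profile_depth, numeric(1))
  if (crack_depth > min(depths)) {
    data_error("data error: crack_depth %g cm exceeds reference profile depth %g cm",
               crack_depth, min(depths))
  }
  c_loss <- vapply(reference$profiles,
                   function(p) integrate_cb(p, 0, crack_depth), numeric(1))
  mass <- vapply(reference$profiles,
                 function(p) integrate_bd(p, 0, crack_depth), numeric(1))
  list(mean = mean(c_loss), se = se_of(c_loss),
       soil_mass_mean = mean(mass), soil_mass_se = se_of(mass),
       per_replicate = c_loss)
}

#' Mineralization/reduced-input SOC loss of the non-eroded horizons
#'
#' For every reference horizon (or part of one) lying below the erosion
#' depth and above `depth_limit` in the reference frame, the loss is the
#' mean reference stock of that slab minus the stock obtained from the
#' matched degraded horizon's content and bulk density over the reference
#' mean thickness:
#' `loss_h = (soc_S0,h * bd_S0,h - soc_s,h * bd_s,h) * T_S0,h * 1e-2`.
#' Degraded horizons are matched to the surviving reference horizons by
#' ordinal position (labels are compared and mismatches warned); a
#' partially eroded reference horizon contributes only its non-eroded
#' remainder here — its eroded fraction is already priced by
#' [erosion_loss()], which is what makes the partition conserve mass.
#'
#' @param reference Reference (S0) [stage_ensemble()].
#' @param degraded Degraded [stage_ensemble()].
#' @param depth_limit Reference-frame integration depth, cm.
#' @param crack_depth Erosion depth, cm; defaults to the degraded
#'   ensemble's mean crack depth.
#' @return List: `mean`, `se`, `per_replicate` (one value per degraded
#'   replicate, each compared against the reference mean layout).
#' @export
mineralization_loss <- function(reference, degraded, depth_limit = 30,
                                crack_depth = stage_crack_depth(degraded)) {
  layout <- reference_layout(reference)
  # reference horizons (or parts) inside the window [crack_depth, depth_limit]
  eff <- pmax(0, pmin(layout$bottom, depth_limit) - pmax(layout$top, crack_depth))
  surviving <- which(layout$bottom > crack_depth + 1e-9)
  active <- which(eff > 1e-12)
  per_rep <- vapply(degraded$profiles, function(p) {
    h <- p$horizons
    loss <- 0
    for (k in seq_along(active)) {
      i <- active[k]
      j <- match(i, surviving)   # ordinal position among surviving horizons
      if (is.na(j) || j > nrow(h)) {
        data_error("horizon matching error: no degraded horizon in %s/%s for reference horizon '%s'",
                   p$stage, p$replicate, layout$label[i])
      }
      if (!is.na(h$label[j]) && h$label[j] != layout$label[i]) {
        warning(sprintf("horizon label mismatch in %s/%s: degraded '%s' matched to reference '%s'",
                        p$stage, p$replicate, h$label[j], layout$label[i]))
      }
      loss <- loss +
        (layout$soc[i] * layout$bd[i] - h$soc[j] * h$bd[j]) * eff[i] * 1e-2
    }
    loss
  }, numeric(1))
  list(mean = mean(per_rep), se = se_of(per_rep), per_replicate = per_rep)
}

#' Express a loss as percent of the reference mean stock
#'
#' @param loss Loss in kg C m-2 (signed).
#' @param reference Reference (S0) [stage_ensemble()].
#' @param depth_limit Integration depth for the reference stock, cm.
#' @return Percent of the reference mean cumulative stock.
#' @export
percent_loss <- function(loss, reference, depth_limit = 30) {
  ref <- mean(vapply(reference$profiles,
                     function(p) integrate_cb(p, 0, depth_limit), numeric(1)))
  if (ref <= 0) data_error("data error: reference mean stock is not positive")
  100 * loss / ref
}

#' Closure check: do erosion + mineralization account for the total loss?
#'
#' Welch two-sample t-test (two-sided) of the per-replicate total losses
#' against the per-replicate erosion + mineralization sums.  Degenerate
#' inputs (both sides essentially constant, as on noiseless data) are
#' resolved by direct comparison of the means: p = 1 when they agree,
#' p = 0 when they do not.
#'
#' @param total Per-replicate total losses (reference-frame window).
#' @param erosion_plus_min Per-replicate erosion + mineralization sums.
#' @param alpha Significance level (default 0.05).
#' @return List: `stat` (t statistic, NA in the degenerate case), `p`,
#'   `ns` (`TRUE` when `p >= alpha`, i.e. closure holds).
#' @export
closure_check <- function(total, erosion_plus_min, alpha = 0.05) {
  if (length(total) < 2L || length(erosion_plus_min) < 2L) {
    data_error("data error: insufficient replication for closure check (need >= 2 per side)")
  }
  res <- tryCatch(
    stats::t.test(total, erosion_plus_min, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    scale <- max(abs(c(total, erosion_plus_min)), 1e-12)
    same <- abs(mean(total) - mean(erosion_plus_min)) <= 1e-8 * scale
    return(list(stat = NA_real_, p = if (same) 1 else 0, ns = same))
  }
  list(stat = unname(res$statistic), p = res$p.value,
       ns = res$p.value >= alpha)
}

#' Partition SOC losses across a full degradation sequence
#'
#' For every degraded stage (S1..S5, relative to the S0 reference) computes
#' the headline total loss (own [0, depth_limit] windows), the
#' reference-frame total loss, the erosion component at the stage mean
#' crack depth, the mineralization component, the percent losses relative
#' to the reference mean stock, and the closure test of total vs
#' erosion + mineralization.
#'
#' @param ensembles Named list of [stage_ensemble()]s including `"S0"`.
#' @param config A [run_config()].
#' @return `data.frame` of class `partition_result`, one row per degraded
#'   stage, with columns `stage`, `crack_cm`, `total_loss`, `total_loss_se`,
#'   `total_loss_ref_frame`, `total_loss_ref_frame_se`, `erosion_loss`,
#'   `erosion_loss_se`, `eroded_soil_mass`, `mineralization_loss`,
#'   `mineralization_loss_se`, `percent_loss`, `percent_loss_erosion_only`,
#'   `closure_stat`, `closure_p`, `closure_ns` (all stocks kg C m-2, soil
#'   mass kg m-2).
#' @export
partition_sequence <- function(ensembles, config = run_config()) {
  stages <- vapply(ensembles, function(e) e$stage, character(1))
  names(ensembles) <- stages
  if (!"S0" %in% stages) data_error("no reference stage: S0 ensemble missing")
  reference <- ensembles[["S0"]]
  degraded_stages <- intersect(degradation_stages(), setdiff(stages, "S0"))
  D <- config$depth_limit
  rows <- lapply(degraded_stages, function(s) {
    deg <- ensembles[[s]]
    crack <- stage_crack_depth(deg)
    tl_own <- total_loss(reference, deg, D, frame = "own")
    tl_ref <- total_loss(reference, deg, D, frame = "reference",
                         crack_depth = crack)
    er <- erosion_loss(reference, crack)
    mn <- mineralization_loss(reference, deg, D, crack_depth = crack)
    n_deg <- length(tl_ref$per_replicate)
    er_rep <- if (length(er$per_replicate) == n_deg) {
      er$per_replicate
    } else {
      rep(er$mean, n_deg)
    }
    cl <- closure_check(tl_ref$per_replicate, er_rep + mn$per_replicate,
                        alpha = config$alpha)
    data.frame(
      stage = s, crack_cm = crack,
      total_loss = tl_own$mean, total_loss_se = tl_own$se,
      total_loss_ref_frame = tl_ref$mean, total_loss_ref_frame_se = tl_ref$se,
      erosion_loss = er$mean, erosion_loss_se = er$se,
      eroded_soil_mass = er$soil_mass_mean,
      mineralization_loss = mn$mean, mineralization_loss_se = mn$se,
      percent_loss = percent_loss(tl_own$mean, reference, D),
      percent_loss_erosion_only = percent_loss(er$mean, reference, D),
      closure_stat = cl$stat, closure_p = cl$p, closure_ns = cl$ns
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("partition_result", "data.frame")
  out
}
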