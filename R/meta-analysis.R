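# Literature effect-size engine: inclusion filtering, degradation-label
# regrouping, unit harmonization (SOM -> SOC, contents -> stocks) and
# percent-change aggregation across studies.

#' Default degradation-label to stage mapping
#'
#' A conservative, user-editable table covering the labels most common in
#' grassland-degradation surveys.  Matching is exact after case-folding and
#' trimming; unmapped labels are never guessed.
#'
#' @return `data.frame(label, stage)`.
#' @export
default_stage_mapping <- function() {
  data.frame(
    label = c("non-degraded", "nondegraded", "undegraded", "intact",
              "no degradation", "reference", "healthy",
              "very lightly degraded", "very light degradation",
              "initial cracking",
              "lightly degraded", "light degradation", "slightly degraded",
              "slight degradation",
              "moderately degraded", "moderate degradation",
              "heavily degraded", "heavy degradation",
              "severely degraded", "severe degradation",
              "extremely degraded", "extreme degradation", "bare soil",
              "bare patch", "black soil patch"),
    stage = c("S0", "S0", "S0", "S0", "S0", "S0", "S0",
              "S1", "S1", "S1",
              "S2", "S2", "S2", "S2",
              "S3", "S3",
              "S4", "S4",
              "S4", "S4",
              "S5", "S5", "S5", "S5", "S5")
  )
}

#' Map degradation labels onto the S0-S5 stages
#'
#' @param original_label Character vector of study labels.
#' @param mapping `data.frame(label, stage)`; matching is case-folded and
#'   whitespace-trimmed, exact otherwise.
#' @param allow_drop If `TRUE`, unmapped labels become `NA` with a warning
#'   instead of an error.
#' @return Character vector of stage codes (or `NA` where dropped).
#' @export
regroup_stage <- function(original_label, mapping = default_stage_mapping(),
                          allow_drop = FALSE) {
  key <- tolower(trimws(original_label))
  idx <- match(key, tolower(trimws(mapping$label)))
  if (anyNA(idx[!is.na(key) & key != ""])) {
    bad <- unique(original_label[is.na(idx) & !is.na(key) & key != ""])
    if (!allow_drop) {
      data_error("unmapped degradation label(s): %s",
                 paste(bad, collapse = "; "))
    }
    warning("dropping unmapped degradation label(s): ",
            paste(bad, collapse = "; "))
  }
  as.character(mapping$stage[idx])
}

#' Apply the literature inclusion criteria
#'
#' Implements the five screening rules: (i) an interpretable degradation
#' classification (label present and covered by the stage mapping);
#' (ii) at least one of SOC/SOM, N or BD reported; (iii) a non-degraded
#' reference record within the same study; (iv) sampling depth and location
#' reported; (v) sampling in exact 10-cm depth intervals.  Nothing is
#' raised: every record is returned either in `kept` (with its
#' `mapped_stage` filled in) or in `rejected` with a `reject_reason`
#' column listing all rules it failed.
#'
#' @param records Literature records ([read_literature()] output or a
#'   data.frame with the same columns).
#' @param mapping Stage mapping table.
#' @return List with `kept` and `rejected` data.frames.
#' @export
apply_inclusion_criteria <- function(records, mapping = default_stage_mapping()) {
  n <- nrow(records)
  stage <- suppressWarnings(
    regroup_stage(records$degradation_label, mapping, allow_drop = TRUE))
  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], why)
  }
  lab <- trimws(ifelse(is.na(records$degradation_label), "",
                       records$degradation_label))
  add(which(lab == "" | is.na(stage)), "unclassified stage")
  has_data <- !is.na(records$carbon_g_kg) | !is.na(records$n_g_kg) |
    !is.na(records$bd_g_cm3)
  add(which(!has_data), "no SOC/N/BD data")
  ref_by_study <- tapply(!is.na(stage) & stage == "S0", records$study_id, any)
  add(which(!ref_by_study[as.character(records$study_id)]), "no reference")
  add(which(is.na(records$depth_top_cm) | is.na(records$depth_bottom_cm)),
      "depth missing")
  add(which(is.na(records$region)), "location missing")
  width <- records$depth_bottom_cm - records$depth_top_cm
  add(which(!is.na(width) & abs(width - 10) > 1e-9), "interval != 10 cm")
  bad <- !vapply(reasons, is.null, logical(1))
  records$mapped_stage <- stage
  rejected <- records[bad, , drop = FALSE]
  rejected$reject_reason <- vapply(reasons[bad], paste, character(1),
                                   collapse = "; ")
  kept <- records[!bad, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Elemental stock of one literature record (kg per hectare)
#'
#' SOM contents are first converted to SOC with the configured factor; the
#' stock then follows the standard unit chain with the record's depth
#' interval as thickness.  Bulk density is required: without it a stock is
#' undefined and the record can only enter content-basis effect sizes.
#'
#' @param record One-row data.frame (literature record).
#' @param element `"C"` or `"N"`.
#' @param config A [run_config()] (supplies the SOM:SOC factor).
#' @return Stock in kg ha-1.
#' @export
record_stock <- function(record, element = c("C", "N"),
                         config = run_config()) {
  element <- match.arg(element)
  if (is.na(record$bd_g_cm3)) {
    data_error("stock unavailable: missing BD for study %s", record$study_id)
  }
  content <- if (element == "C") {
    if (is.na(record$carbon_g_kg)) {
      data_error("stock unavailable: missing carbon content for study %s",
                 record$study_id)
    }
    if (identical(record$carbon_kind, "SOM")) {
      som_to_soc(record$carbon_g_kg, config$som_to_soc_factor)
    } else {
      record$carbon_g_kg
    }
  } else {
    if (is.na(record$n_g_kg)) {
      data_error("stock unavailable: missing N content for study %s",
                 record$study_id)
    }
    record$n_g_kg
  }
  elemental_stock(content, record$bd_g_cm3,
                  record$depth_bottom_cm - record$depth_top_cm)
}

#' Percent effect size of a degraded value relative to its reference
#'
#' `ES = 100 * (D - R) / R`: positive for an increase, zero for no change,
#' negative for a decrease relative to the non-degraded reference.
#' Vectorized; scale-invariant in (D, R).
#'
#' @param D Value(s) in the degraded stage.
#' @param R Reference value(s); must be nonzero.
#' @return Effect size in percent.
#' @export
effect_size <- function(D, R) {
  if (any(R == 0, na.rm = TRUE)) {
    data_error("undefined effect size: reference value is zero")
  }
  100 * (D - R) / R
}

#' Per-record effect sizes within each study and depth interval
#'
#' For every (study, depth interval) cell the reference value is the mean
#' over that study's S0 records; each degraded record then yields one
#' effect size per available variable.  SOC and N effects are computed on
#' stocks when BD is present on both sides, otherwise on (SOM-harmonized)
#' contents; the basis is recorded per effect.  BD itself is a third
#' variable.  Records must already have passed
#' [apply_inclusion_criteria()] (i.e. carry `mapped_stage`).
#'
#' @param records Kept records with `mapped_stage` filled in.
#' @param config A [run_config()].
#' @return `data.frame`: `study_id`, `variable` (`SOC`, `N`, `BD`),
#'   `basis` (`stock`, `content`, `bd`), `stage`, `depth_top_cm`,
#'   `depth_bottom_cm`, `effect_pct`.
#' @export
compute_effect_sizes <- function(records, config = run_config()) {
  if (anyNA(records$mapped_stage)) {
    data_error("data error: records carry unmapped stages; run apply_inclusion_criteria first")
  }
  soc_content <- ifelse(records$carbon_kind == "SOM" & !is.na(records$carbon_kind),
                        records$carbon_g_kg / config$som_to_soc_factor,
                        records$carbon_g_kg)
  cells <- split(seq_len(nrow(records)),
                 list(study = records$study_id,
                      top = records$depth_top_cm,
                      bottom = records$depth_bottom_cm),
                 drop = TRUE)
  out <- list()
  for (idx in cells) {
    ref <- idx[records$mapped_stage[idx] == "S0"]
    deg <- idx[records$mapped_stage[idx] != "S0"]
    if (length(ref) == 0L || length(deg) == 0L) next
    thick <- records$depth_bottom_cm[idx[1]] - records$depth_top_cm[idx[1]]
    emit <- function(variable, basis, ref_val, deg_vals, deg_idx) {
      if (is.na(ref_val) || ref_val == 0 || length(deg_idx) == 0L) return()
      ok <- !is.na(deg_vals)
      if (!any(ok)) return()
      out[[length(out) + 1L]] <<- data.frame(
        study_id = records$study_id[deg_idx[ok]],
        variable = variable, basis = basis,
        stage = records$mapped_stage[deg_idx[ok]],
        depth_top_cm = records$depth_top_cm[deg_idx[ok]],
        depth_bottom_cm = records$depth_bottom_cm[deg_idx[ok]],
        effect_pct = effect_size(deg_vals[ok], ref_val))
    }
    bd_ok <- !is.na(records$bd_g_cm3)
    # SOC: stock basis where BD available on both sides, else content basis
    ref_c_stock <- mean(100 * soc_content[ref] * records$bd_g_cm3[ref] * thick)
    deg_c_stock <- 100 * soc_content[deg] * records$bd_g_cm3[deg] * thick
    if (all(bd_ok[ref]) && !is.na(ref_c_stock)) {
      emit("SOC", "stock", ref_c_stock, deg_c_stock, deg)
      emit("SOC", "content", mean(soc_content[ref]),
           ifelse(bd_ok[deg], NA_real_, soc_content[deg]), deg)
    } else {
      emit("SOC", "content", mean(soc_content[ref]), soc_content[deg], deg)
    }
    # N analogous
    ref_n_stock <- mean(100 * records$n_g_kg[ref] * records$bd_g_cm3[ref] * thick)
    deg_n_stock <- 100 * records$n_g_kg[deg] * records$bd_g_cm3[deg] * thick
    if (all(bd_ok[ref]) && !is.na(ref_n_stock)) {
      emit("N", "stock", ref_n_stock, deg_n_stock, deg)
      emit("N", "content", mean(records$n_g_kg[ref]),
           ifelse(bd_ok[deg], NA_real_, records$n_g_kg[deg]), deg)
    } else {
      emit("N", "content", mean(records$n_g_kg[ref]), records$n_g_kg[deg], deg)
    }
    emit("BD", "bd", mean(records$bd_g_cm3[ref]), records$bd_g_cm3[deg], deg)
  }
  if (length(out) == 0L) {
    return(data.frame(study_id = character(0), variable = character(0),
                      basis = character(0), stage = character(0),
                      depth_top_cm = numeric(0), depth_bottom_cm = numeric(0),
                      effect_pct = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate effect sizes by variable, stage and depth interval
#'
#' Simple unweighted means across observations (the convention for
#' degradation-gradient syntheses reporting means +/- SE), with
#' `SE = sd / sqrt(n)` (`NA` for a single observation).  With
#' `per_study = TRUE` each study is first collapsed to its mean so that
#' studies, not observations, are weighted equally.
#'
#' @param effects Output of [compute_effect_sizes()].
#' @param per_study Collapse to study means before aggregating?
#' @return `data.frame`: `variable`, `basis`, `stage`, `depth_top_cm`,
#'   `depth_bottom_cm`, `mean_pct`, `se_pct`, `n`.
#' @export
aggregate_effects <- function(effects, per_study = FALSE) {
  if (nrow(effects) == 0L) {
    warning("no effects to aggregate")
    return(data.frame(variable = character(0), basis = character(0),
                      stage = character(0), depth_top_cm = numeric(0),
                      depth_bottom_cm = numeric(0), mean_pct = numeric(0),
                      se_pct = numeric(0), n = integer(0)))
  }
  if (per_study) {
    key <- interaction(effects$study_id, effects$variable, effects$basis,
                       effects$stage, effects$depth_top_cm,
                       effects$depth_bottom_cm, drop = TRUE)
    effects <- do.call(rbind, lapply(split(effects, key), function(g) {
      g$effect_pct[1] <- mean(g$effect_pct)
      g[1, , drop = FALSE]
    }))
  }
  key <- interaction(effects$variable, effects$basis, effects$stage,
                     effects$depth_top_cm, effects$depth_bottom_cm,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(effects, key), function(g) {
    data.frame(variable = g$variable[1], basis = g$basis[1],
               stage = g$stage[1], depth_top_cm = g$depth_top_cm[1],
               depth_bottom_cm = g$depth_bottom_cm[1],
               mean_pct = mean(g$effect_pct),
               se_pct = se_of(g$effect_pct),
               n = nrow(g))
  }))
  out <- out[order(out$variable, out$basis,
                   match(out$stage, degradation_stages()),
                   out$depth_top_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
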