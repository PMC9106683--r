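# Elemental stock computation: per horizon and cumulative to a depth limit.
#
# Stocks follow the standard unit chain: content [g element kg-1 soil] x
# bulk density [g soil cm-3] x thickness [cm] integrates, over 1 ha =
# 1e8 cm2, to 100 * content * BD * thickness kilograms per hectare.

#' Elemental stock of one soil layer (kg per hectare)
#'
#' `stock = 100 * content * BD * thickness`, with content in g kg-1, bulk
#' density in g cm-3 and thickness in cm.  Vectorized over all arguments.
#'
#' @param content Element content, g per kg soil.
#' @param bulk_density Bulk density, g per cm3.
#' @param thickness Layer thickness, cm.
#' @return Stock in kg per hectare.
#' @export
#' @examples
#' elemental_stock(50, 1.0, 10)   # 50,000 kg/ha = 5 kg/m2
elemental_stock <- function(content, bulk_density, thickness) {
  if (any(content < 0, na.rm = TRUE) || any(bulk_density < 0, na.rm = TRUE) ||
      any(thickness < 0, na.rm = TRUE)) {
    stop("domain error: content, bulk_density and thickness must all be >= 0")
  }
  100 * content * bulk_density * thickness
}

#' Convert a stock from kg per hectare to kg per square metre
#' @param stock Stock in kg ha-1.
#' @return Stock in kg m-2 (`stock * 1e-4`).
#' @export
kg_ha_to_kg_m2 <- function(stock) {
  stock * 1e-4
}

#' Convert soil organic matter content to soil organic carbon content
#'
#' Literature records often report SOM rather than SOC; the conventional
#' harmonization divides by a fixed conversion factor (default 2.0, i.e.
#' SOC = SOM / 2).
#'
#' @param som_content SOM content, g per kg.
#' @param factor Positive SOM:SOC conversion factor.
#' @return SOC content, g per kg.
#' @export
som_to_soc <- function(som_content, factor = 2.0) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0) {
    config_error("config error: som_to_soc conversion factor must be > 0")
  }
  if (any(som_content < 0, na.rm = TRUE)) {
    stop("domain error: som_content must be >= 0")
  }
  som_content / factor
}

#' Cumulative and per-horizon stock of a profile down to a depth limit
#'
#' Integrates content x bulk density over the profile's own depth axis from
#' the surface to `depth_limit` cm.  Content and BD are taken as uniform
#' within a horizon, so a horizon crossing the limit contributes pro rata by
#' the thickness above the limit.  Profiles shallower than `depth_limit`
#' contribute their full depth with a warning (not an error): pedons on
#' degraded sites can be genuinely shallow.
#'
#' @param profile A [soil_profile()].
#' @param element `"C"` (SOC, from `soc`) or `"N"` (from `n`).
#' @param depth_limit Lower integration bound, cm (default 30).
#' @return An object of class `stock_result`: list with `stage`,
#'   `replicate`, `depth_limit`, `per_horizon` (data.frame: label,
#'   thickness_cm used, stock_kg_m2) and `cumulative` (kg m-2).
#' @export
#' @examples
#' h <- data.frame(label = c("A", "B"), top = c(0, 20), bottom = c(20, 40),
#'                 soc = c(60, 20), bd = c(0.8, 1.2))
#' profile_stock(soil_profile("S0", "r1", h), "C", 30)$cumulative  # 12 kg/m2
profile_stock <- function(profile, element = c("C", "N"), depth_limit = 30) {
  element <- match.arg(element)
  if (depth_limit < 0) stop("config error: depth_limit must be >= 0")
  h <- profile$horizons
  content <- if (element == "C") h$soc else h$n
  if (all(is.na(content))) {
    stop(sprintf("element unavailable: no %s content in profile %s/%s",
                 element, profile$stage, profile$replicate))
  }
  thick <- pmax(0, pmin(h$bottom, depth_limit) - pmax(h$top, 0))
  used <- thick > 0
  if (any(used & is.na(content))) {
    stop(sprintf("element unavailable: missing %s content within [0, %g] in profile %s/%s",
                 element, depth_limit, profile$stage, profile$replicate))
  }
  if (max(h$bottom) < depth_limit) {
    warning(sprintf(
      "profile %s/%s is shallower (%g cm) than depth_limit (%g cm); stock covers the profile only",
      profile$stage, profile$replicate, max(h$bottom), depth_limit))
  }
  stock_m2 <- kg_ha_to_kg_m2(
    elemental_stock(ifelse(used, content, 0), h$bd, thick))
  structure(
    list(stage = profile$stage,
         replicate = profile$replicate,
         element = element,
         depth_limit = depth_limit,
         per_horizon = data.frame(label = h$label,
                                  thickness_cm = thick,
                                  stock_kg_m2 = stock_m2),
         cumulative = sum(stock_m2)),
    class = "stock_result"
  )
}

#' @export
print.stock_result <- function(x, ...) {
  cat(sprintf("<stock_result> %s stock, %s/%s, 0-%g cm: %.3f kg m-2\n",
              x$element, x$stage, x$replicate, x$depth_limit, x$cumulative))
  invisible(x)
}

#' Stage-wise mean stocks with standard errors
#'
#' Computes per-replicate cumulative stocks, then the stage mean and SE
#' (sd / sqrt(n)) across field replicates.
#'
#' @param ensembles List of [stage_ensemble()] objects (e.g. from
#'   [read_profiles()]).
#' @inheritParams profile_stock
#' @return `data.frame` with columns `stage`, `element`, `depth_limit_cm`,
#'   `mean_kg_m2`, `se_kg_m2`, `n`.
#' @export
stage_stocks <- function(ensembles, element = c("C", "N"), depth_limit = 30) {
  element <- match.arg(element)
  rows <- lapply(ensembles, function(ens) {
    stocks <- vapply(ens$profiles,
                     function(p) profile_stock(p, element, depth_limit)$cumulative,
                     numeric(1))
    data.frame(stage = ens$stage,
               element = element,
               depth_limit_cm = depth_limit,
               mean_kg_m2 = mean(stocks),
               se_kg_m2 = if (length(stocks) > 1L) {
                 stats::sd(stocks) / sqrt(length(stocks))
               } else NA_real_,
               n = length(stocks))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$stage, degradation_stages())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
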