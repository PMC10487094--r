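# Binarization, cross-scale combination, refugia, change accounting,
# protected-area gap analysis and rounded percent-change reporting.

#' Round half away from zero
#'
#' The reporting convention for printed percentages: 0.5 at the last kept
#' digit rounds away from zero (unlike R's banker's rounding).
#'
#' @param x numeric.
#' @param decimals digits to keep.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, decimals = 2) {
  sign(x) * floor(abs(x) * 10^decimals + 0.5) / 10^decimals
}

#' Binarize a suitability map at a threshold
#'
#' A cell is suitable (1) iff its suitability is `>= threshold`; cells
#' exactly at the threshold count as suitable. Nodata is preserved.
#'
#' @param suitability continuous `hs_raster`.
#' @param threshold decision threshold (typically the MTSS).
#' @return Binary `hs_raster`.
#' @export
binarize <- function(suitability, threshold) {
  v <- (suitability$values >= threshold) * 1
  v[suitability$nodata_mask] <- NA
  make_raster(suitability$grid, v, suitability$nodata_mask, kind = "binary")
}

#' Combine coarse climatic and fine local suitability
#'
#' Resamples the coarse climatic binary map to the fine grid (nearest
#' neighbour), binarizes the fine local suitability at
#' `provincial_threshold`, and intersects the two. The final continuous
#' map carries the local suitability inside the overlap and 0 outside it.
#'
#' @param national_binary coarse binary `hs_raster` (climatically
#'   suitable area).
#' @param provincial_suitability fine continuous `hs_raster`.
#' @param provincial_threshold threshold for the fine map (its MTSS).
#' @return List: `final_binary`, `final_continuous`,
#'   `national_on_fine` (the resampled coarse binary),
#'   `provincial_binary`.
#' @export
combine_scales <- function(national_binary, provincial_suitability,
                           provincial_threshold) {
  fine <- provincial_suitability$grid
  nat <- resample_nearest(national_binary, fine)
  prov <- binarize(provincial_suitability, provincial_threshold)
  final <- overlay_and(nat, prov)
  cont <- provincial_suitability$values * final$values
  cont[final$nodata_mask] <- NA
  list(final_binary = final,
       final_continuous = make_raster(fine, cont, final$nodata_mask),
       national_on_fine = nat,
       provincial_binary = prov)
}

#' Climate refugia
#'
#' Cells suitable now and under every supplied future map: the cellwise
#' AND of the current binary map with all futures. Order of the future
#' list is immaterial.
#'
#' @param current_binary binary `hs_raster`.
#' @param future_binaries list of binary `hs_raster`s on the same grid.
#' @return Binary `hs_raster`.
#' @export
refugia <- function(current_binary, future_binaries) {
  Reduce(overlay_and, future_binaries, init = current_binary)
}

#' Stable / gain / lost accounting between two binary maps
#'
#' `stable` is current AND future, `lost` is current AND NOT future,
#' `gain` is NOT current AND future, all in km^2 via [area_km2()]. The
#' identities `stable + lost = current area` and `stable + gain = future
#' area` hold by construction.
#'
#' @param current_binary,future_binary binary `hs_raster`s on one grid.
#' @return List of class `change_report`: `stable_km2`, `gain_km2`,
#'   `lost_km2`, `current_km2`, `future_km2`, `percent_change_vs_current`.
#' @export
change_accounting <- function(current_binary, future_binary) {
  not_ <- function(r) {
    v <- 1 - r$values
    v[r$nodata_mask] <- NA
    make_raster(r$grid, v, r$nodata_mask, kind = "binary")
  }
  stable <- area_km2(overlay_and(current_binary, future_binary))
  lost <- area_km2(overlay_and(current_binary, not_(future_binary)))
  gain <- area_km2(overlay_and(not_(current_binary), future_binary))
  cur <- area_km2(current_binary); fut <- area_km2(future_binary)
  structure(list(stable_km2 = stable, gain_km2 = gain, lost_km2 = lost,
                 current_km2 = cur, future_km2 = fut,
                 percent_change_vs_current =
                   if (cur > 0) percent_change(cur, fut) else NA_real_),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> stable %.1f, gain %.1f, lost %.1f km^2 (%+.2f%%)\n",
              x$stable_km2, x$gain_km2, x$lost_km2, x$percent_change_vs_current))
  invisible(x)
}

#' Rounded percent change
#'
#' `(new - reference) / reference * 100`, rounded half away from zero to
#' `decimals` digits — the convention used for printed change tables.
#'
#' @param reference_area,new_area areas (same units); `reference_area`
#'   must be nonzero.
#' @param decimals digits kept (default 2).
#' @return Signed percentage.
#' @export
percent_change <- function(reference_area, new_area, decimals = 2) {
  if (reference_area == 0) stop("percent change undefined for zero reference area")
  round_half_away((new_area - reference_area) / reference_area * 100, decimals)
}

#' Protected-area coverage of suitable habitat
#'
#' Per mask: the share of the suitable area that falls inside the mask,
#' as a percentage rounded to 1 decimal.
#'
#' @param suitable_binary binary `hs_raster`.
#' @param pa_masks named list of binary `hs_raster`s (e.g. nature
#'   reserves, wetland parks).
#' @return data.frame with columns `mask`, `covered_km2`, `coverage_pct`.
#' @export
protected_gap <- function(suitable_binary, pa_masks) {
  total <- area_km2(suitable_binary)
  if (total == 0) stop("no suitable area; coverage undefined")
  rows <- lapply(names(pa_masks), function(nm) {
    inside <- area_km2(overlay_and(suitable_binary, pa_masks[[nm]]))
    data.frame(mask = nm, covered_km2 = inside,
               coverage_pct = round_half_away(inside / total * 100, 1))
  })
  do.call(rbind, rows)
}

#' Mean importance across algorithms
#'
#' Arithmetic mean of the per-algorithm importance columns, rounded to
#' 2 decimals (half away from zero) — the aggregation used in printed
#' importance tables.
#'
#' @param table data.frame with a `variable` column and one numeric
#'   column per algorithm.
#' @return data.frame with `variable` and `mean`.
#' @export
importance_mean <- function(table) {
  num <- vapply(table, is.numeric, TRUE) & names(table) != "mean"
  data.frame(variable = table$variable,
             mean = round_half_away(rowMeans(table[num]), 2))
}
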