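# Bundled worked-example tables: published area statistics and variable
# importance scores for the black-stork wintering study system, used to
# exercise the reporting operations (percent change, importance
# aggregation) on fixed inputs.

#' Example land-use area table (Shaanxi, km^2)
#'
#' Published per-class land-use areas for 2020 with projections for 2030
#' and 2050, over the six general classes. Input for the
#' [percent_change()] worked examples.
#'
#' @return data.frame with columns `class`, `y2020`, `y2030`, `y2050`.
#' @export
example_lulc_areas <- function() {
  data.frame(
    class = c("cropland", "forest", "grassland", "wetland", "impervious", "bare"),
    y2020 = c(59858.55, 83945.79, 42187.50, 1018.08, 3074.76, 1436.04),
    y2030 = c(58964.04, 84545.82, 41398.74, 1025.28, 4141.26, 1448.19),
    y2050 = c(62569.80, 92049.57, 42259.50, 1160.19, 6588.27, 1400.67))
}

#' Example per-algorithm variable-importance table
#'
#' Published importance scores of the national- and provincial-scale
#' predictors under the six member algorithms. Input for the
#' [importance_mean()] worked examples.
#'
#' @return data.frame with columns `scale`, `variable`, one column per
#'   algorithm (`MXD`, `GLM`, `GAM`, `RDF`, `SVM`, `BRT`).
#' @export
example_importance <- function() {
  data.frame(
    scale = c(rep("national", 5), rep("provincial", 7)),
    variable = c("LULC", "Bio15", "Bio3", "Bio14", "Bio9",
                 "Aspect", "Elevation", "LULC", "Nightlight", "Dist_road",
                 "Slope", "Dist_water"),
    MXD = c(0.13, 0.17, 0.03, 0.27, 0.40, 0.01, 0.07, 0.14, 0.29, 0.11, 0.19, 0.19),
    GLM = c(0.30, 0.16, 0.07, 0.15, 0.33, 0.04, 0.07, 0.26, 0.04, 0.15, 0.14, 0.30),
    GAM = c(0.14, 0.18, 0.09, 0.22, 0.37, 0.01, 0.13, 0.18, 0.04, 0.14, 0.05, 0.47),
    RDF = c(0.15, 0.18, 0.18, 0.20, 0.29, 0.07, 0.14, 0.15, 0.13, 0.13, 0.18, 0.21),
    SVM = c(0.04, 0.16, 0.04, 0.31, 0.46, 0.02, 0.09, 0.14, 0.16, 0.12, 0.20, 0.27),
    BRT = c(0.11, 0.12, 0.14, 0.14, 0.49, 0.03, 0.06, 0.14, 0.08, 0.05, 0.14, 0.50))
}
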