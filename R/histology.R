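#' Aggregated postmortem iron-compound concentrations by brain region
#'
#' Loads the packaged reference table of literature-derived transferrin,
#' ferritin and iron concentrations for 11 brain regions in two age groups
#' (younger / older adults), together with the FreeSurfer label ids of each
#' region and per-measurement sample sizes and assay-source keys. Ferritin
#' values combine L-rich and H-rich ferritin estimates where the source
#' reported them separately; for the substantia nigra the entire midbrain
#' was used, and for the gray/white superior temporal gyrus the entire
#' temporal cortex / white matter, to avoid unreliably small segmentations.
#'
#' Units: transferrin and ferritin in ng per microgram of total protein;
#' iron stored under the label "mg/g protein" as printed by the aggregated
#' source (one source reports a microgram-scale conversion for this column;
#' ratios built within the table are unit-consistent either way, so the
#' value is kept exactly as printed and never rescaled).
#'
#' @return Data frame with 22 rows (11 regions x 2 age groups) and columns
#'   \code{region}, \code{label_ids} (semicolon-separated left-hemisphere
#'   FreeSurfer ids; bilateral ROIs use the matching right-hemisphere ids
#'   too), \code{age_group}, \code{transferrin_ng_ug}, \code{ferritin_ng_ug},
#'   \code{iron_mg_g}, per-measurement \code{n_*} sample sizes and
#'   \code{*_source} keys.
#' @export
brain_iron_histology <- function() {
  path <- system.file("extdata", "brain_iron_histology.csv",
                      package = "relaxiq", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label_ids = "character"))
  df$age_group <- factor(df$age_group, levels = c("younger", "older"))
  df
}

#' Parse the label-id list of a histology record
#'
#' @param label_ids Semicolon-separated id string(s) as stored in the
#'   histology table.
#' @return A list of integer vectors.
#' @export
parse_label_ids <- function(label_ids) {
  lapply(strsplit(label_ids, ";"), function(x) as.integer(trimws(x)))
}

#' Summarise per-subject MRI values by region and age group
#'
#' Produces the group-level MRI summary matched to the histology table:
#' per (region, age group), the mean across subjects and the mean absolute
#' deviation (MAD about the mean). When a \code{hemisphere} column is
#' present, the two hemispheres of each subject are averaged first
#' (bilateral ROIs contribute one value per subject).
#'
#' @param data Data frame with columns \code{subject}, \code{region},
#'   \code{age_group}, \code{value}, and optionally \code{hemisphere}.
#' @return Data frame with one row per (region, age_group): \code{mean},
#'   \code{mad} (mean absolute deviation across subjects) and
#'   \code{n_subjects}.
#' @export
summarize_mri_by_group <- function(data) {
  stopifnot(all(c("subject", "region", "age_group", "value") %in%
                  names(data)))
  if ("hemisphere" %in% names(data)) {
    data <- stats::aggregate(value ~ subject + region + age_group,
                             data = data, FUN = mean)
  }
  agg <- stats::aggregate(value ~ region + age_group, data = data,
                          FUN = function(v)
                            c(mean = mean(v),
                              mad = mean(abs(v - mean(v))),
                              n = length(v)))
  out <- data.frame(region = agg$region, age_group = agg$age_group,
                    mean = agg$value[, "mean"], mad = agg$value[, "mad"],
                    n_subjects = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$region, out$age_group), , drop = FALSE]
}

#' Correlate a group-level MRI summary with histology predictors
#'
#' Aligns an MRI summary (one value per region and age group) with the
#' histology table and regresses the MRI measure on each requested
#' predictor: transferrin, ferritin, iron, or the iron mobilization
#' capacity (transferrin/iron). P-values are one-sided regression F-tests,
#' corrected across the predictor family by Benjamini-Hochberg FDR.
#' Regions can be excluded (both age groups) to probe outlier-driven
#' associations, e.g. the globus pallidus.
#'
#' @param mri_summary Data frame with columns \code{region},
#'   \code{age_group} and \code{mean} (as from
#'   \code{\link{summarize_mri_by_group}}).
#' @param predictors Character subset of \code{c("transferrin", "ferritin",
#'   "iron", "tf_over_iron")}.
#' @param exclude_regions Character vector of region names to drop before
#'   fitting.
#' @param histology Histology table; defaults to the packaged one.
#' @return List of class \code{"group_level_result"}: \code{results}, a
#'   data frame with one row per predictor (\code{r_squared}, \code{f_stat},
#'   \code{p_raw}, \code{p_fdr}, \code{n_points}), and \code{scatter}, the
#'   aligned (MRI, predictor) pairs.
#' @export
group_level_correlation <- function(mri_summary,
                                    predictors = c("transferrin", "ferritin",
                                                   "iron", "tf_over_iron"),
                                    exclude_regions = character(),
                                    histology = brain_iron_histology()) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  stopifnot(all(c("region", "age_group", "mean") %in% names(mri_summary)))
  hist <- histology[!(histology$region %in% exclude_regions), , drop = FALSE]
  hist$tf_over_iron <- mobilization_capacity(hist$transferrin_ng_ug,
                                             hist$iron_mg_g)
  merged <- merge(hist, mri_summary, by = c("region", "age_group"))
  if (nrow(merged) < 3L)
    stop("fewer than 3 aligned (region, age group) records")
  cols <- c(transferrin = "transferrin_ng_ug", ferritin = "ferritin_ng_ug",
            iron = "iron_mg_g", tf_over_iron = "tf_over_iron")
  res <- do.call(rbind, lapply(predictors, function(p) {
    ft <- regression_ftest(merged[[cols[p]]], merged$mean)
    data.frame(predictor = p, r_squared = ft$r_squared, f_stat = ft$f_stat,
               df1 = ft$df1, df2 = ft$df2, p_raw = ft$p_one_sided,
               n_points = nrow(merged), stringsAsFactors = FALSE)
  }))
  res$p_fdr <- fdr_bh(res$p_raw)
  scatter <- merged[, c("region", "age_group", "mean", unname(cols[predictors]))]
  structure(list(results = res, scatter = scatter,
                 excluded = exclude_regions),
            class = "group_level_result")
}

#' @export
print.group_level_result <- function(x, ...) {
  cat("Group-level MRI vs histology regressions",
      if (length(x$excluded))
        sprintf("(excluding: %s)", paste(x$excluded, collapse = ", ")),
      "\n")
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}
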