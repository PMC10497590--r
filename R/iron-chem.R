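#' Iron-binding-protein specification
#'
#' Physical constants needed to convert a protein concentration into an
#' elemental iron concentration: the protein molecular weight, the number
#' of iron ions carried per protein molecule, and the molecular weight of
#' iron (55.847 g/mol by default, stored in mg/mol).
#'
#' @param name Protein name.
#' @param molecular_weight_mg_mol Protein molecular weight, mg/mol; > 0.
#' @param iron_ions_per_protein Iron ions bound per protein molecule;
#'   \eqn{\ge 0} (0 for apo-proteins).
#' @param iron_mw_mg_mol Molecular weight of iron, mg/mol.
#' @return Object of class \code{"iron_protein_spec"}.
#' @seealso \code{\link{iron_protein_specs}} for the shipped reference
#'   table.
#' @export
iron_protein_spec <- function(name, molecular_weight_mg_mol,
                              iron_ions_per_protein,
                              iron_mw_mg_mol = 55.847e3) {
  if (molecular_weight_mg_mol <= 0 || iron_mw_mg_mol <= 0)
    stop("molecular weights must be positive")
  if (iron_ions_per_protein < 0)
    stop("iron ions per protein must be non-negative")
  structure(list(name = name,
                 molecular_weight_mg_mol = molecular_weight_mg_mol,
                 iron_ions_per_protein = iron_ions_per_protein,
                 iron_mw_mg_mol = iron_mw_mg_mol),
            class = "iron_protein_spec")
}

#' Reference iron-binding-protein constants
#'
#' The shipped specifications: ferritin (equine spleen; molecular weight
#' 440e6 mg/mol, iron loading ~2250 ions/protein per manufacturer
#' information), holo-transferrin (76e6 mg/mol, 2 ions), apo-transferrin
#' (same protein, 0 ions) and ferrous sulfate heptahydrate (FeSO4.7H2O,
#' 278.02e3 mg/mol, 1 ion). With these constants 1 mg/ml ferritin carries
#' 0.29 mg/ml iron; 1 mg/ml holo-transferrin carries about 1.47e-3 mg/ml
#' (some sources round this figure to 1.4 ug/ml).
#'
#' @return Named list of \code{\link{iron_protein_spec}} objects.
#' @export
iron_protein_specs <- function() {
  list(
    ferritin = iron_protein_spec("ferritin", 440e6, 2250),
    holo_transferrin = iron_protein_spec("holo-transferrin", 76e6, 2),
    apo_transferrin = iron_protein_spec("apo-transferrin", 76e6, 0),
    ferrous_sulfate = iron_protein_spec("ferrous sulfate heptahydrate",
                                        278.02e3, 1)
  )
}

#' Convert an iron-binding-protein concentration to elemental iron
#'
#' \deqn{iron\ (mg/ml) = \frac{protein\ (mg/ml)}{MW_{protein}\ (mg/mol)}
#'       \cdot \frac{ions}{protein} \cdot MW_{Fe}\ (mg/mol)}
#' The conversion is linear in the concentration and applies to controlled,
#' homogeneous in vitro samples only; it is not meaningful for complex
#' tissue.
#'
#' @param conc_protein Protein concentration(s), mg/ml; non-negative.
#' @param spec An \code{\link{iron_protein_spec}}.
#' @return Elemental iron concentration(s), mg/ml.
#' @examples
#' protein_to_iron(1, iron_protein_specs()$ferritin)  # 0.2856 ~ 0.29
#' @export
protein_to_iron <- function(conc_protein, spec) {
  stopifnot(inherits(spec, "iron_protein_spec"))
  if (any(conc_protein < 0)) stop("concentration must be non-negative")
  conc_protein / spec$molecular_weight_mg_mol *
    spec$iron_ions_per_protein * spec$iron_mw_mg_mol
}

#' Iron mobilization capacity (transferrin / iron ratio)
#'
#' The ratio of the transferrin concentration to the total iron
#' concentration, an iron-homeostasis marker: high values indicate spare
#' transport capacity, low values iron overload relative to transport. The
#' ratio is returned in whatever unit quotient the inputs imply; no unit
#' conversion is performed.
#'
#' @param transferrin_conc Transferrin concentration(s).
#' @param iron_conc Iron concentration(s); must be positive.
#' @return \code{transferrin_conc / iron_conc}.
#' @export
mobilization_capacity <- function(transferrin_conc, iron_conc) {
  if (any(iron_conc <= 0)) stop("iron concentration must be positive")
  transferrin_conc / iron_conc
}

#' Transferrin-to-ferritin ratio and median-split classification
#'
#' Computes Tf/Fer and, optionally, classifies each value as "low" or
#' "high" relative to a threshold (default 1, a cohort-median split). Ties
#' at the threshold go to "high" by default.
#'
#' @param tf Transferrin values.
#' @param fer Ferritin values; must be positive.
#' @param threshold Split point for classification; \code{NULL} skips
#'   classification.
#' @param ties Group receiving values equal to the threshold
#'   (\code{"high"} or \code{"low"}).
#' @return If \code{threshold} is \code{NULL}, the numeric ratios;
#'   otherwise a list with \code{ratio} and factor \code{group}.
#' @export
transferrin_ferritin_ratio <- function(tf, fer, threshold = NULL,
                                       ties = c("high", "low")) {
  ties <- match.arg(ties)
  if (any(fer <= 0)) stop("ferritin concentration must be positive")
  ratio <- tf / fer
  if (is.null(threshold)) return(ratio)
  group <- if (ties == "high") ifelse(ratio >= threshold, "high", "low")
           else ifelse(ratio > threshold, "high", "low")
  list(ratio = ratio,
       group = factor(group, levels = c("low", "high")))
}
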