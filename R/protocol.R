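#' Reagent constants for chemical dehydration stoichiometry
#'
#' 2,2-dimethoxypropane (DMP, C5H12O2) hydrolyses 1:1 with water to
#' methanol and acetone, actively removing tissue water during clearing.
#' Molar masses: DMP 104.15 g/mol, water 18.02 g/mol; DMP density
#' 0.847 g/mL (PubChem CID 6985).
#'
#' @format list with `molar_mass_dmp`, `molar_mass_water`, `density_dmp`.
#' @export
reagent_constants <- list(molar_mass_dmp = 104.15,
                          molar_mass_water = 18.02,
                          density_dmp = 0.847)

#' DMP mass required to remove a given water mass
#'
#' One mole of DMP consumes one mole of water, so removing 1 g of water
#' takes `104.15 / 18.02` = 5.78 g of DMP (about 5.8 g). The function is
#' linear and homogeneous in the water mass.
#'
#' @param water_mass grams of water to remove (>= 0).
#' @return grams of DMP.
#' @seealso [dmp_volume_for_water()]
#' @export
dmp_mass_for_water <- function(water_mass) {
  if (any(water_mass < 0)) stop("water_mass must be >= 0")
  water_mass * reagent_constants$molar_mass_dmp /
    reagent_constants$molar_mass_water
}

#' DMP volume for a given water mass (via density)
#'
#' Note: mass / density gives about 6.8 mL per gram of water; the
#' stoichiometric mass figure is treated as primary.
#'
#' @inheritParams dmp_mass_for_water
#' @return millilitres of DMP.
#' @export
dmp_volume_for_water <- function(water_mass) {
  dmp_mass_for_water(water_mass) / reagent_constants$density_dmp
}

#' Histological undersampling factor of a sectioned tissue block
#'
#' Standard histology examines one to two ~5 um sections per 3-4 mm block,
#' so the fraction of tissue actually inspected is
#' `n_sections * section_thickness / block_thickness`; its reciprocal, the
#' undersampling factor, is about 600-800 for those figures.
#'
#' @param block_thickness_um tissue block thickness, micrometres (> 0).
#' @param section_thickness_um single section thickness, micrometres (> 0).
#' @param n_sections number of sections examined (integer >= 1).
#' @return dimensionless ratio `block / (section * n)`.
#' @export
undersampling_factor <- function(block_thickness_um, section_thickness_um,
                                 n_sections = 1L) {
  if (any(block_thickness_um <= 0) || any(section_thickness_um <= 0))
    stop("thicknesses must be positive")
  if (any(n_sections < 1)) stop("n_sections must be >= 1")
  block_thickness_um / (section_thickness_um * n_sections)
}

#' Per-record and per-treatment volume shrinkage percentages
#'
#' Shrinkage is `(1 - V_post / V_pre) * 100`; negative values (swelling)
#' are permitted and reported. Group means are unweighted arithmetic means
#' over records sharing a treatment label. The result is invariant under a
#' uniform change of volume units.
#'
#' @param records data.frame with columns `id`, `treatment`, `pre`, `post`
#'   (volumes, e.g. mm^3), or a path to a CSV file with those columns.
#'   Alternatively `pre`/`post` may each be a length-3 dimensions triple
#'   encoded as `"a x b x c"`; dimensions are converted to volume by the
#'   rectangular product.
#' @return list with `per_record` (data.frame incl. `shrinkage_pct`) and
#'   `group_means` (data.frame: treatment, n, mean_shrinkage_pct).
#' @export
volume_shrinkage_percent <- function(records) {
  if (is.character(records) && length(records) == 1L)
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  records <- as.data.frame(records)
  need <- c("id", "treatment", "pre", "post")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop("records must be nonempty")
  to_vol <- function(v) {
    if (is.numeric(v)) return(v)
    vapply(as.character(v), function(s) {
      parts <- as.numeric(strsplit(s, "[x*]")[[1L]])
      if (any(is.na(parts))) stop("unparseable volume/dimensions: ", s)
      prod(parts)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  pre <- to_vol(records$pre); post <- to_vol(records$post)
  if (any(pre <= 0)) stop("pre-treatment volumes must be positive")
  records$shrinkage_pct <- (1 - post / pre) * 100
  gm <- stats::aggregate(shrinkage_pct ~ treatment, data = records,
                         FUN = mean)
  gm$n <- as.vector(table(records$treatment)[gm$treatment])
  names(gm)[names(gm) == "shrinkage_pct"] <- "mean_shrinkage_pct"
  list(per_record = records,
       group_means = gm[, c("treatment", "n", "mean_shrinkage_pct")])
}
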