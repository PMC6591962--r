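#' Daily hepatocyte turnover implied by the liver cfDNA fraction
#'
#' Back-of-the-envelope physiology: the steady-state pool of liver-derived
#' genomes in circulation is `ge_per_ml * liver_fraction * volume`, where
#' the distribution volume is `distribution_volume_ml_per_kg * body_mass_kg`.
#' With first-order clearance at half-life `half_life_hours`, replacing the
#' pool requires `pool * ln(2) / half_life * 24` cell deaths per day, a
#' fraction `cells_per_day / total_hepatocytes` of the liver. Interval
#' inputs (length-2 vectors) are propagated: the result reports the
#' low/mid/high parameter combinations.
#'
#' @param body_mass_kg Body mass (default 70).
#' @param distribution_volume_ml_per_kg Distribution volume of DNA, mL per
#'   kg; scalar or interval (default `c(60, 70)`).
#' @param ge_per_ml Total cfDNA content as diploid genome equivalents per
#'   mL plasma (default 1000, i.e. ~6 ng/mL).
#' @param liver_fraction Liver-derived fraction of cfDNA; scalar or
#'   interval (default `c(0.01, 0.02)`).
#' @param half_life_hours cfDNA clearance half-life (default 1).
#' @param total_hepatocytes Hepatocytes in an adult liver (default 2.4e11).
#' @return Tibble with rows `low`, `mid`, `high`: `cells_per_day`,
#'   `fraction_of_liver`, `percent_of_liver`.
#' @export
hepatocyte_turnover <- function(body_mass_kg = 70,
                                distribution_volume_ml_per_kg = c(60, 70),
                                ge_per_ml = 1000,
                                liver_fraction = c(0.01, 0.02),
                                half_life_hours = 1,
                                total_hepatocytes = 2.4e11) {
  vals <- c(body_mass_kg, distribution_volume_ml_per_kg, ge_per_ml,
            liver_fraction, half_life_hours, total_hepatocytes)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all turnover parameters must be positive and finite.",
          class = "cfdecon_domain_error")
  }
  ival <- function(x) {
    if (length(x) == 1) x <- c(x, x)
    if (x[2] < x[1]) abort("interval endpoints must be ordered.",
                           class = "cfdecon_domain_error")
    c(low = x[1], mid = mean(x), high = x[2])
  }
  vol <- ival(distribution_volume_ml_per_kg)
  lf <- ival(liver_fraction)
  pool <- ge_per_ml * lf * vol * body_mass_kg        # liver genomes in plasma
  cells <- pool * log(2) / half_life_hours * 24      # first-order clearance
  tibble(
    bound = names(vol),
    distribution_volume_ml_per_kg = unname(vol),
    liver_fraction = unname(lf),
    cells_per_day = unname(cells),
    fraction_of_liver = unname(cells) / total_hepatocytes,
    percent_of_liver = unname(cells) / total_hepatocytes * 100
  )
}
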