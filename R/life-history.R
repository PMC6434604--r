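#' Growth and length-conversion parameters
#'
#' Coefficients for the von Bertalanffy growth curve
#' `L(t) = Linf * (1 - exp(-K * (t - t0)))` and the linear total-length to
#' standard-length conversion `SL = slope * TL + intercept`. The source
#' study cites published lionfish fits for both but prints no numbers, so
#' these are configuration with field-plausible lionfish defaults, not
#' constants.
#'
#' @param linf asymptotic standard length, mm.
#' @param k growth coefficient, 1/yr.
#' @param t0 theoretical age at length zero, yr.
#' @param tl_sl_slope,tl_sl_intercept TL-to-SL conversion coefficients (mm).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(linf = 425, k = 0.47, t0 = -0.5,
                          tl_sl_slope = 0.78, tl_sl_intercept = 0) {
  if (linf <= 0 || k <= 0) .stopf("Linf and K must be positive")
  structure(list(linf = linf, k = k, t0 = t0,
                 tl_sl_slope = tl_sl_slope, tl_sl_intercept = tl_sl_intercept),
            class = "growth_params")
}

#' Standard length from total length
#' @param tl total length, mm (vectorised).
#' @param params growth_params.
#' @return standard length, mm.
#' @export
standard_length_from_total <- function(tl, params = growth_params()) {
  sl <- params$tl_sl_slope * tl + params$tl_sl_intercept
  if (any(sl < 0)) .stopf("conversion produced a negative standard length")
  sl
}

#' Age from standard length (inverse von Bertalanffy)
#'
#' `age = t0 - (1/K) * log(1 - SL/Linf)`; undefined at `SL >= Linf`.
#'
#' @param sl standard length, mm (vectorised).
#' @param params growth_params.
#' @return age in years.
#' @export
age_from_length <- function(sl, params = growth_params()) {
  if (any(sl >= params$linf))
    .stopf("standard length >= Linf (%g mm): age undefined", params$linf)
  params$t0 - (1 / params$k) * log(1 - sl / params$linf)
}

#' Forward von Bertalanffy length at age
#' @param age age in years (vectorised).
#' @param params growth_params.
#' @return standard length, mm.
#' @export
length_at_age <- function(age, params = growth_params()) {
  params$linf * (1 - exp(-params$k * (age - params$t0)))
}

#' Recruitment year from collection date and age
#'
#' @param collection_date decimal year (e.g. 2013.5) or `Date`.
#' @param age age in years.
#' @return integer calendar year: `floor(collection - age)`.
#' @export
recruitment_year <- function(collection_date, age) {
  if (inherits(collection_date, "Date")) {
    y <- as.integer(format(collection_date, "%Y"))
    collection_date <- y + (as.integer(format(collection_date, "%j")) - 1) / 365.25
  }
  as.integer(floor(collection_date - age))
}

#' Genome-size model parameters (cut-site count to genome size)
#'
#' A log-log linear map `log10(G) = intercept + slope * log10(S)` from the
#' number of restriction cut sites `S` to genome size `G` in bp. Default
#' coefficients are a synthetic stand-in for the published SbfI fit: they
#' are back-derived from the study's own printed anchor estimates
#' (15,000 sites -> 370,725,631 bp; 25,000 -> 680,784,288 bp), since the
#' original regression coefficients are not printed.
#'
#' @param intercept,slope log10-scale coefficients; slope must be positive
#'   (the map must be monotone increasing).
#' @param enzyme label recorded in outputs.
#' @return object of class `genome_model_params`.
#' @export
genome_model_params <- function(intercept = 3.600315351895,
                                slope = 1.189805718537,
                                enzyme = "SbfI") {
  if (slope <= 0) .stopf("slope must be positive (monotone map)")
  structure(list(intercept = intercept, slope = slope, enzyme = enzyme),
            class = "genome_model_params")
}

#' Predict genome size from a restriction cut-site count
#' @param n_cut_sites number of cut sites (vectorised, positive).
#' @param params genome_model_params.
#' @return genome size in bp.
#' @export
predict_genome_size <- function(n_cut_sites, params = genome_model_params()) {
  if (any(n_cut_sites <= 0)) .stopf("cut-site count must be positive")
  10^(params$intercept + params$slope * log10(n_cut_sites))
}

#' Inverse of [predict_genome_size()]
#' @param genome_size genome size in bp.
#' @param params genome_model_params.
#' @return implied cut-site count.
#' @export
cut_sites_from_genome_size <- function(genome_size, params = genome_model_params()) {
  if (any(genome_size <= 0)) .stopf("genome size must be positive")
  10^((log10(genome_size) - params$intercept) / params$slope)
}

#' Fraction of the genome covered by the RAD loci
#'
#' `100 * n_loci * locus_len / genome_size`, rounded to two decimals for
#' reporting. The 90-bp locus length includes the 6-bp restriction site.
#'
#' @param n_loci number of loci.
#' @param locus_len locus length in bp (default 90).
#' @param genome_size genome size in bp.
#' @return percent of genome, rounded to 2 decimals.
#' @export
genome_fraction <- function(n_loci, locus_len = 90, genome_size) {
  if (any(genome_size <= 0)) .stopf("genome size must be positive")
  round(100 * n_loci * locus_len / genome_size, 2)
}

#' Annotation rate as a percentage
#' @param n_annotated number of annotated loci.
#' @param n_total total loci.
#' @return percent, rounded to 1 decimal.
#' @export
annotation_rate <- function(n_annotated, n_total) {
  if (n_total <= 0) .stopf("n_total must be positive")
  round(100 * n_annotated / n_total, 1)
}
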