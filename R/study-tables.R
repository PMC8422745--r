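# Published reference tables from a seven-population mtDNA COI survey of
# the Chinese grass shrimp (Palaemonetes sinensis). These printed values
# are shipped so that the distance/tree and expansion-time stages can be
# exercised on real reported numbers without any sequence download.

#' Between-population K2P distances for seven grass-shrimp populations
#'
#' Average Kimura 2-parameter distances (Ds) among seven wild
#' Palaemonetes sinensis populations (labels PJ, SL, AS, DL, SY, SH, JN)
#' as reported in the published survey. The JN population (Huaihe River
#' drainage) is markedly more distant from the six Liaohe-basin
#' populations than those are from each other.
#'
#' @return Symmetric 7 x 7 matrix with population labels.
#' @export
sinensis_ds_matrix <- function() {
  labs <- c("PJ", "SL", "AS", "DL", "SY", "SH", "JN")
  m <- matrix(0, 7, 7, dimnames = list(labs, labs))
  lower <- c(
    SL_PJ = 0.0021,
    AS_PJ = 0.0011, AS_SL = 0.0019,
    DL_PJ = 0.0009, DL_SL = 0.0017, DL_AS = 0.0007,
    SY_PJ = 0.0012, SY_SL = 0.0019, SY_AS = 0.0010, SY_DL = 0.0008,
    SH_PJ = 0.0014, SH_SL = 0.0021, SH_AS = 0.0012, SH_DL = 0.0010,
    SH_SY = 0.0013,
    JN_PJ = 0.0026, JN_SL = 0.0034, JN_AS = 0.0024, JN_DL = 0.0021,
    JN_SY = 0.0026, JN_SH = 0.0027)
  for (nm in names(lower)) {
    ab <- strsplit(nm, "_")[[1L]]
    m[ab[1L], ab[2L]] <- m[ab[2L], ab[1L]] <- lower[[nm]]
  }
  m
}

#' Reported mismatch-distribution parameters for the same survey
#'
#' Fitted sudden-expansion parameters per population (tau, theta0,
#' theta1), goodness-of-fit statistics and the reported expansion times
#' in millions of years, under the 1.4%/Myr COI clock with a 1.5-year
#' generation time and 674 sites.
#'
#' @return data.frame with columns Population, tau, theta0, theta1, SSD,
#'   HRI, t_Ma.
#' @export
sinensis_mismatch_params <- function() {
  data.frame(
    Population = c("DL", "PJ", "AS", "SL", "SY", "SH", "JN", "mean"),
    tau = c(3.000, 3.000, 3.000, 1.387, 0.768, 0.861, 0.469, 1.783),
    theta0 = rep(0, 8),
    theta1 = c(0.341, 0.571, 0.421, 99999.000, 99999.000, 99999.000,
               9.455, 42858.255),
    SSD = c(0.003, 0.010, 0.018, 0.007, 0.003, 0.013, 0.007, 0.009),
    HRI = c(0.322, 0.240, 0.359, 0.070, 0.098, 0.130, 0.190, 0.201),
    t_Ma = c(0.106, 0.106, 0.106, 0.049, 0.027, 0.030, 0.017, 0.063),
    stringsAsFactors = FALSE)
}

#' Sample sizes of the seven surveyed populations
#'
#' @return Named integer vector (population -> sample size).
#' @export
sinensis_sample_sizes <- function() {
  c(DL = 46L, PJ = 44L, AS = 47L, SL = 47L, SY = 48L, SH = 48L, JN = 46L)
}
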