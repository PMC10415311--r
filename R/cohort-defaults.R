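#' Default brain areas, peripheral tissues, and planted networks
#'
#' The 17 brain areas and 5 peripheral tissues profiled by the assay panel,
#' and the default 3-network membership used by the synthetic cohort
#' generator: network 1 is cortico-striatal (mOFC, mPFC, CPu, NAc, M1, V1),
#' network 2 covers salience/navigation-related areas (Thal, DGd, CA3, VTA,
#' DGv, Cereb, VN), and network 3 is limbic (Hypoth, Amyg, SN, PAG).
#'
#' @return `mito_areas()` and `mito_tissues()` return character vectors;
#'   `default_partition()` returns a named integer vector (area -> network);
#'   `mito_features()` returns the six feature names.
#' @export
mito_areas <- function() {
  c("mOFC", "mPFC", "CPu", "NAc", "M1", "Hypoth", "Thal", "DGd", "Amyg",
    "CA3", "VTA", "V1", "SN", "DGv", "PAG", "Cereb", "VN")
}

#' @rdname mito_areas
#' @export
mito_tissues <- function() {
  c("AG", "Liver", "Heart", "Soleus", "WG")
}

#' @rdname mito_areas
#' @export
mito_features <- function() {
  c("CI", "CII", "CIV", "CS", "mtdna_density", "MHI")
}

#' @rdname mito_areas
#' @export
default_partition <- function() {
  p <- c(
    mOFC = 1L, mPFC = 1L, CPu = 1L, NAc = 1L, M1 = 1L, V1 = 1L,
    Thal = 2L, DGd = 2L, CA3 = 2L, VTA = 2L, DGv = 2L, Cereb = 2L, VN = 2L,
    Hypoth = 3L, Amyg = 3L, SN = 3L, PAG = 3L
  )
  p[mito_areas()]
}

#' Estimated mass of a frozen-tissue biopsy punch
#'
#' Punches are too light to weigh, so mass is estimated from cylinder
#' geometry and brain tissue density: m = pi r^2 h * density. With the
#' defaults (r = 0.5 mm, h = 200 um, 1.04 g/cm^3) one punch is ~0.163 mg
#' and the two pooled punches used per sample ~0.327 mg.
#'
#' @param radius_mm punch radius in millimetres.
#' @param height_um section thickness in micrometres.
#' @param density_g_cm3 tissue density in g/cm^3.
#' @param n_punches number of pooled punches.
#' @return Estimated mass in milligrams.
#' @export
punch_mass <- function(radius_mm = 0.5, height_um = 200,
                       density_g_cm3 = 1.04, n_punches = 1) {
  stopifnot(radius_mm > 0, height_um > 0, density_g_cm3 > 0, n_punches >= 1)
  r_cm <- radius_mm / 10
  h_cm <- height_um / 1e4
  vol_cm3 <- pi * r_cm^2 * h_cm
  vol_cm3 * density_g_cm3 * 1000 * n_punches # mg
}
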