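#' Analysis configuration with the study's threshold defaults
#'
#' Single source of truth for every cutoff used across the pipeline. The
#' defaults are the values used throughout the analysis: pLDDT confidence 70,
#' ortholog identity >= 0.30 with coverage > 0.70 and e-value < 1e-5, SiMax
#' structural-similarity threshold 6 Angstrom, active-site ligand shell 4,
#' disulfide 2.1, salt bridge 4 and polar-contact (hydrogen bond) 3.5
#' Angstrom, elastic q-range 0.27-1.97 1/Angstrom, and the force-constant
#' conversion 0.00276 (N/m per Angstrom^2/K).
#'
#' @param ... named overrides for any default listed above.
#' @return A named list of class `"protomod_config"`.
#' @examples
#' cfg <- run_config(simax_similar = 5)
#' cfg$simax_similar
#' @export
run_config <- function(...) {
  cfg <- list(
    plddt_high       = 70,
    identity_min     = 0.30,
    coverage_min     = 0.70,
    evalue_max       = 1e-5,
    simax_similar    = 6,
    ligand_cutoff    = 4,
    disulfide_max    = 2.1,
    salt_bridge_max  = 4,
    hbond_max        = 3.5,
    q_range          = c(0.27, 1.97),
    force_constant   = 0.00276,
    sasa_probe       = 1.4,
    sasa_points      = 960,
    gap_open         = 20,
    gap_extend       = 4,
    ka_lambda        = 0.267,
    ka_K             = 0.041,
    seed             = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  scalars <- setdiff(names(cfg), c("q_range", "seed"))
  for (nm in scalars)
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0))
      stop("config value out of range (must be positive): ", nm)
  if (length(cfg$q_range) != 2 || cfg$q_range[1] >= cfg$q_range[2])
    stop("config value out of range: q_range must be an increasing pair")
  class(cfg) <- "protomod_config"
  cfg
}
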