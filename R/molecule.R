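#' Define a diffusing species
#'
#' A molecule is described by its molecular weight, its diffusion coefficient
#' in free medium, and the tortuosity \eqn{\lambda} of the tissue it moves
#' through. Tortuosity captures the hindrance of the extracellular space:
#' the effective tissue diffusivity is \eqn{D/\lambda^2}.
#'
#' @param name Character label for the species.
#' @param molecular_weight Molecular weight in daltons.
#' @param d_free Free-medium diffusion coefficient, cm^2/s.
#' @param tortuosity Dimensionless hindrance factor \eqn{\lambda \ge 1}.
#'
#' @return An object of class `ced_molecule` (a named list).
#' @examples
#' gdnf <- molecule("r-metHuGDNF", 30400, 1.3e-6, 2.2)
#' effective_diffusivity(gdnf)
#' @export
molecule <- function(name, molecular_weight, d_free, tortuosity) {
  stopifnot_positive(molecular_weight, "molecular_weight")
  stopifnot_positive(d_free, "d_free")
  if (!is.numeric(tortuosity) || length(tortuosity) != 1L ||
      !is.finite(tortuosity) || tortuosity < 1) {
    abort("`tortuosity` must be a single number >= 1.",
          class = "cedflow_invalid_parameter")
  }
  structure(
    list(name = as.character(name)[1],
         molecular_weight = molecular_weight,
         d_free = d_free,
         tortuosity = tortuosity),
    class = "ced_molecule"
  )
}

#' @export
print.ced_molecule <- function(x, ...) {
  cat(sprintf("<ced_molecule> %s\n  MW %.4g Da | D_free %.3g cm^2/s | lambda %.3g | D_eff %.3g cm^2/s\n",
              x$name, x$molecular_weight, x$d_free, x$tortuosity,
              effective_diffusivity(x)))
  invisible(x)
}

#' Built-in molecule presets
#'
#' Two species used throughout the package: the ~30.4 kDa neurotrophic
#' factor r-metHuGDNF (free diffusivity 1.3e-6 cm^2/s, tortuosity 2.2,
#' extrapolated from an NGF-conjugate diffusion study) and the ~938 Da MRI
#' contrast agent Gd-DTPA (4.1e-6 cm^2/s from cube-root molecular-weight
#' scaling, rounded to two significant figures; tortuosity 1.6, the small-
#' molecule value for brain interstitium).
#'
#' @param name One of `"r-metHuGDNF"` or `"Gd-DTPA"`.
#' @return A [molecule()] object.
#' @examples
#' molecule_preset("Gd-DTPA")
#' @export
molecule_preset <- function(name = c("r-metHuGDNF", "Gd-DTPA")) {
  name <- match.arg(name)
  switch(name,
    "r-metHuGDNF" = molecule("r-metHuGDNF", 30400, 1.3e-6, 2.2),
    "Gd-DTPA"     = molecule("Gd-DTPA", 938, 4.1e-6, 1.6)
  )
}

#' Effective diffusivity in tissue
#'
#' Tissue-level diffusivity of a species, reduced from its free-medium value
#' by tortuosity: \eqn{D_t = D / \lambda^2}.
#'
#' @param molecule A [molecule()].
#' @return Effective diffusivity in cm^2/s.
#' @examples
#' effective_diffusivity(molecule_preset("r-metHuGDNF"))  # 2.69e-7
#' @export
effective_diffusivity <- function(molecule) {
  if (!inherits(molecule, "ced_molecule")) {
    abort("`molecule` must be a `ced_molecule`.",
          class = "cedflow_invalid_parameter")
  }
  molecule$d_free / molecule$tortuosity^2
}

#' Scale a diffusion coefficient by molecular weight
#'
#' Stokes-Einstein scaling for spherical molecules implies an inverse
#' one-third power dependence of diffusivity on molecular weight:
#' \eqn{D_{target} = D_{ref} (MW_{ref}/MW_{target})^{1/3}}.
#'
#' @param d_ref Reference diffusion coefficient, cm^2/s.
#' @param mw_ref Reference molecular weight, Da.
#' @param mw_target Target molecular weight, Da.
#' @return Scaled diffusion coefficient, cm^2/s.
#' @examples
#' # GDNF (30.4 kDa) -> Gd-DTPA (938 Da)
#' scale_diffusivity_by_mw(1.3e-6, 30400, 938)  # ~4.1e-6
#' @export
scale_diffusivity_by_mw <- function(d_ref, mw_ref, mw_target) {
  stopifnot_positive(d_ref, "d_ref")
  stopifnot_positive(mw_ref, "mw_ref")
  stopifnot_positive(mw_target, "mw_target")
  d_ref * (mw_ref / mw_target)^(1 / 3)
}
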