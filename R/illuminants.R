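# Standard illuminants tabulated at grid resolution.
#
# CIE A is *defined* as a Planckian radiator at 2856 K (c2 = 1.4388e-2 m K),
# normalized to 100 at 560 nm, so the Planck route is exact. Illuminant E is
# exactly flat. "tungsten" follows the same law at 3200 K (studio tungsten).
# "D65" here is a smooth solar-simulator surrogate (Planck at 6504 K, the
# correlated colour temperature of D65): the CIE D65 table stops at 830 nm
# and cannot describe the NIR anyway, and no pre-installed package ships it;
# the surrogate is documented as such.

planck_spd <- function(wl_nm, temp_k, c2 = 1.4388e-2) {
  lam <- wl_nm * 1e-9
  # relative spectral radiance; normalization applied by the caller
  lam^-5 / (exp(c2 / (lam * temp_k)) - 1)
}

#' Standard illuminants
#'
#' Returns one of the shipped illuminants tabulated on `grid`:
#' \describe{
#'   \item{`"A"`}{CIE standard illuminant A: Planckian radiator at 2856 K,
#'     normalized to 100 at 560 nm (exact by definition). The reflectance
#'     dataset this toolkit emulates was measured under illuminant A.}
#'   \item{`"E"`}{Equal-energy illuminant, constant 100.}
#'   \item{`"D65"`}{Smooth solar-simulator surrogate for D65: Planckian
#'     radiator at 6504 K normalized to 100 at 560 nm. The CIE D65 table is
#'     undefined past 830 nm, so a full-range smooth surrogate is used.}
#'   \item{`"tungsten"`}{Planckian radiator at 3200 K, normalized to 100 at
#'     560 nm.}
#' }
#'
#' @param name One of `"A"`, `"E"`, `"D65"`, `"tungsten"`.
#' @param grid A [wl_grid()]; default full modeling grid 380-1000 nm, 1 nm.
#' @return An [illuminant()].
#' @export
standard_illuminant <- function(name = c("A", "E", "D65", "tungsten"),
                                grid = wl_grid()) {
  name <- match.arg(name)
  wl <- wavelengths(grid)
  v <- switch(name,
    A = planck_spd(wl, 2856) / planck_spd(560, 2856) * 100,
    E = rep(100, length(wl)),
    D65 = planck_spd(wl, 6504) / planck_spd(560, 6504) * 100,
    tungsten = planck_spd(wl, 3200) / planck_spd(560, 3200) * 100
  )
  illuminant(name, spectrum_curve(grid, v, kind = "spd"))
}
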