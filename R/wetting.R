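#' Wetting classification of a hydrogel particle at the dextran-PEG interface
#'
#' A particle straddles the liquid-liquid interface when replacing a patch
#' of dextran-PEG interface with particle surface lowers the total surface
#' energy, which happens iff
#' `|gamma_p_peg - gamma_p_dex| < gamma_dex_peg`.
#' Otherwise the particle is fully engulfed by whichever phase it wets more
#' cheaply: dextran when `gamma_p_peg - gamma_p_dex >= gamma_dex_peg`, PEG
#' in the mirror case. Equality at the boundary classifies as engulfed
#' (the interface condition is a strict inequality).
#'
#' @param gamma_p_peg Particle-PEG interfacial tension, N/m (>= 0).
#' @param gamma_p_dex Particle-dextran interfacial tension, N/m (>= 0).
#' @param gamma_dex_peg Dextran-PEG interfacial tension, N/m (>= 0).
#' @return One of `"interface"`, `"engulfed_in_dextran"`,
#'   `"engulfed_in_peg"`.
#' @examples
#' particle_location(1.0, 1.0, 0.5)  # "interface"
#' particle_location(2.0, 0.5, 1.0)  # "engulfed_in_dextran"
#' @export
particle_location <- function(gamma_p_peg, gamma_p_dex, gamma_dex_peg) {
  g <- c(gamma_p_peg, gamma_p_dex, gamma_dex_peg)
  if (!is.numeric(g) || length(g) != 3 || any(!is.finite(g)) || any(g < 0))
    stop("all three interfacial tensions must be finite and >= 0 (N/m)")
  if (abs(gamma_p_peg - gamma_p_dex) < gamma_dex_peg) {
    "interface"
  } else if (gamma_p_peg >= gamma_p_dex) {
    "engulfed_in_dextran"
  } else {
    "engulfed_in_peg"
  }
}
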