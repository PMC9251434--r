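# Hindered-diffusion model of peptide release through narrow wall pores,
# compared with the translocation speed of the degradation machinery.
# Internally everything is computed in nm and ns; reported units mirror
# common usage (ns for free diffusion, us for pore transit, s for product
# generation).

#' Hindrance slowdown factor for a peptide of length L
#'
#' Transit through a narrow inert pore is slower than free diffusion over
#' the same distance by a factor of `L^2`, where `L` is the peptide length
#' in residues: a dipeptide crosses four times slower, a 10-mer a hundred
#' times slower.
#'
#' @param L peptide length in residues (integer >= 1).
#' @return dimensionless slowdown factor `L^2`.
#' @export
slowdown_factor <- function(L) {
  check_positive(L, "L")
  if (any(L < 1)) stop("`L` must be >= 1", call. = FALSE)
  L^2
}

#' Free one-dimensional diffusion time over the pore thickness
#'
#' `tau_free = x^2 / (2 D)` with unit-safe conversion: `x` in nm, `D` in
#' um^2/s, result in ns. A typical proteasome product (`D` about 3 um^2/s)
#' crosses 1 nm -- the thickness of a wall pore -- in about 167 ns.
#'
#' @param x pore thickness in nm.
#' @param D diffusivity in um^2/s.
#' @return diffusion time in ns.
#' @export
free_diffusion_time <- function(x, D) {
  check_positive(x, "x"); check_positive(D, "D")
  D_nm2_ns <- D * 1e6 / 1e9   # um^2/s -> nm^2/ns
  x^2 / (2 * D_nm2_ns)
}

#' Pore transit time of a peptide
#'
#' Hindered-diffusion transit time `tau_pore = L^2 * x^2 / (2 D)`,
#' returned in microseconds. For a 10-mer with `D = 3 um^2/s` and a 1 nm
#' pore this is about 16.7 us.
#'
#' @inheritParams free_diffusion_time
#' @inheritParams slowdown_factor
#' @return transit time in us.
#' @export
pore_release_time <- function(L, x, D) {
  slowdown_factor(L) * free_diffusion_time(x, D) * 1e-3  # ns -> us
}

#' Compare product release with substrate translocation
#'
#' The machine threads substrate at `v` residues per second, so one
#' product of length `L` is generated every `L / v` seconds; the ratio of
#' that generation time to the pore transit time says how much headroom
#' passive release has over the production rate. `orders_of_magnitude` is
#' `floor(log10(ratio))`.
#'
#' @inheritParams slowdown_factor
#' @param v translocation speed in residues per second.
#' @param tau_pore_us pore transit time in us (e.g. from
#'   [pore_release_time()]).
#' @return one-row tibble: `product_generation_s`, `ratio`,
#'   `orders_of_magnitude`.
#' @export
translocation_comparison <- function(L, v, tau_pore_us) {
  check_positive(L, "L"); check_positive(v, "v"); check_positive(tau_pore_us, "tau_pore_us")
  gen <- L / v
  ratio <- gen / (tau_pore_us * 1e-6)
  tibble::tibble(
    product_generation_s = gen,
    ratio = ratio,
    orders_of_magnitude = floor(log10(ratio))
  )
}

#' Full release-kinetics report
#'
#' Chains the hindered-diffusion model end to end for one parameter set
#' and returns a tidy one-row report. When `mean_hydropathy` is supplied
#' and exceeds `attraction_threshold` the pore may not be inert -- an
#' attractive lining would slow release massively -- and
#' `attraction_warning` is set; no quantitative adsorption model is
#' applied.
#'
#' @param L peptide length, residues.
#' @param x pore thickness, nm.
#' @param D diffusivity, um^2/s.
#' @param v translocation speed, residues/s.
#' @param mean_hydropathy optional Kyte-Doolittle mean of the pore lining.
#' @param attraction_threshold hydropathy above which the inert-pore
#'   assumption is flagged (default 0).
#' @return one-row tibble with `tau_free_ns`, `slowdown`, `tau_pore_us`,
#'   `product_generation_s`, `ratio`, `orders_of_magnitude`,
#'   `attraction_warning`.
#' @export
#' @examples
#' release_kinetics(L = 10, x = 1, D = 3, v = 40)
release_kinetics <- function(L = 10, x = 1, D = 3, v = 40,
                             mean_hydropathy = NULL,
                             attraction_threshold = 0) {
  tau_free <- free_diffusion_time(x, D)
  sl <- slowdown_factor(L)
  tau_pore <- pore_release_time(L, x, D)
  cmp <- translocation_comparison(L, v, tau_pore)
  tibble::tibble(
    L = L, x_nm = x, D_um2_s = D, v_aa_s = v,
    tau_free_ns = tau_free, slowdown = sl, tau_pore_us = tau_pore,
    product_generation_s = cmp$product_generation_s,
    ratio = cmp$ratio, orders_of_magnitude = cmp$orders_of_magnitude,
    attraction_warning = !is.null(mean_hydropathy) &&
      isTRUE(mean_hydropathy > attraction_threshold)
  )
}

check_positive <- function(v, name) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(v)
}
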