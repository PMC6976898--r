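#' Optical property database
#'
#' The package ships a small database of tissue optical properties — absorption
#' coefficient \eqn{\mu_a} (1/mm), scattering coefficient \eqn{\mu_s} (1/mm),
#' scattering anisotropy \eqn{g} (mean cosine of the single-scattering
#' deflection) and refractive index \eqn{n} — for skin, fatty and fibrous soft
#' tissue at the four wavelengths commonly used for photoacoustic excitation
#' (700, 800, 900 and 1064 nm), plus milk and gelatin at 1064 nm for the
#' phantom study. All tissue entries carry g = 0.9 and n = 1.4; milk and
#' gelatin keep their own anisotropy and index.
#'
#' @return A data frame with columns `tissue`, `wavelength_nm`, `mu_a_per_mm`,
#'   `mu_s_per_mm`, `g`, `n`.
#' @export
#' @examples
#' head(optical_property_table())
optical_property_table <- function() {
  path <- system.file("extdata", "optical_properties.tsv", package = "palight",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

new_optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(mu_a >= 0, mu_s >= 0, g >= -1, g <= 1, n >= 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g /mm, mu_s = %g /mm, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Tissue specification
#'
#' A lightweight descriptor naming a tissue class and wavelength, resolvable to
#' an [optical property quadruple][get_properties]. `kind = "mixed"` describes
#' a bulk tissue that is a volume-fraction blend of fatty and fibrous tissue
#' and requires `fatty_fraction`.
#'
#' @param kind One of `"skin"`, `"fatty"`, `"fibrous"`, `"mixed"`, `"milk"`,
#'   `"gelatin"`.
#' @param wavelength_nm Excitation wavelength in nm; one of 700, 800, 900,
#'   1064. Milk and gelatin are defined only at 1064 nm.
#' @param fatty_fraction Fatty volume fraction in \[0, 1\]; only for `"mixed"`.
#' @return An object of class `tissue_spec`.
#' @export
#' @examples
#' tissue_spec("fibrous", 700)
#' tissue_spec("mixed", 800, fatty_fraction = 0.4)
tissue_spec <- function(kind, wavelength_nm, fatty_fraction = NULL) {
  kind <- match.arg(kind, c("skin", "fatty", "fibrous", "mixed", "milk", "gelatin"))
  if (!wavelength_nm %in% c(700, 800, 900, 1064))
    stop("wavelength must be one of 700, 800, 900, 1064 nm; got ", wavelength_nm)
  if (kind == "mixed") {
    if (is.null(fatty_fraction))
      stop("mixed tissue requires `fatty_fraction`")
    if (fatty_fraction < 0 || fatty_fraction > 1)
      stop("fatty_fraction must lie in [0, 1]; got ", fatty_fraction)
  }
  structure(list(kind = kind, wavelength_nm = wavelength_nm,
                 fatty_fraction = fatty_fraction),
            class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  frac <- if (!is.null(x$fatty_fraction))
    sprintf(" (%.0f%% fatty)", 100 * x$fatty_fraction) else ""
  cat(sprintf("tissue: %s%s @ %d nm\n", x$kind, frac, x$wavelength_nm))
  invisible(x)
}

#' Look up optical properties for a tissue
#'
#' Resolves a [tissue_spec()] against the bundled database. Mixed tissues are
#' computed with [mix_properties()], never looked up.
#'
#' @param spec A [tissue_spec()].
#' @return An `optical_properties` object (fields `mu_a`, `mu_s`, `g`, `n`).
#' @export
#' @examples
#' get_properties(tissue_spec("skin", 800))
get_properties <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (spec$kind == "mixed")
    return(mix_properties(spec$fatty_fraction, spec$wavelength_nm))
  tab <- optical_property_table()
  row <- tab[tab$tissue == spec$kind & tab$wavelength_nm == spec$wavelength_nm, ]
  if (nrow(row) != 1L)
    stop(sprintf("no optical properties tabulated for tissue '%s' at %d nm",
                 spec$kind, spec$wavelength_nm))
  new_optical_properties(row$mu_a_per_mm, row$mu_s_per_mm, row$g, row$n)
}

#' Fatty/fibrous tissue mixture
#'
#' Bulk soft tissue intermediate between the fibrous (weakly scattering) and
#' fatty (strongly scattering) extremes is modelled as a convex combination of
#' the two database rows: \eqn{\mu = f\,\mu_{fatty} + (1-f)\,\mu_{fibrous}}
#' applied to both \eqn{\mu_a} and \eqn{\mu_s}. Anisotropy and refractive
#' index are common to all soft tissues (0.9 and 1.4) and are unchanged.
#'
#' @param fatty_fraction Fatty volume fraction \eqn{f} in \[0, 1\].
#' @param wavelength_nm Wavelength with both fatty and fibrous entries.
#' @return An `optical_properties` object.
#' @export
#' @examples
#' mix_properties(0.4, 800)
mix_properties <- function(fatty_fraction, wavelength_nm) {
  if (fatty_fraction < 0 || fatty_fraction > 1)
    stop("fatty_fraction must lie in [0, 1]; got ", fatty_fraction)
  fat <- get_properties(tissue_spec("fatty", wavelength_nm))
  fib <- get_properties(tissue_spec("fibrous", wavelength_nm))
  f <- fatty_fraction
  new_optical_properties(f * fat$mu_a + (1 - f) * fib$mu_a,
                         f * fat$mu_s + (1 - f) * fib$mu_s,
                         0.9, 1.4)
}
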