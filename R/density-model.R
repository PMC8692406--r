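#' Constants of the DNA buoyant-density / isotope model
#'
#' The qSIP model links a taxon's GC content, the molecular weight of its
#' DNA, and the CsCl buoyant density of that DNA. The constants are the
#' standard calibration used throughout quantitative SIP work:
#' \describe{
#'   \item{slope_gc_density, intercept_density}{linear map from GC fraction
#'     to light (unlabeled) buoyant density, g/ml:
#'     `W_light = 0.083506 G + 1.646057`.}
#'   \item{mw_slope, mw_intercept}{average nucleotide molecular weight of
#'     unlabeled DNA, g/mol: `M_light = 0.496 G + 307.691`.}
#'   \item{heavy_slope, heavy_intercept}{maximum mass gain under complete
#'     13C substitution: `M_heavymax - M_light = -0.4987282 G + 9.974564`.}
#'   \item{nat_13c}{natural 13C atom fraction, 0.01111233.}
#' }
#'
#' @param ... Named overrides of individual constants (requires
#'   `allow_override = TRUE`; the calibration is fixed by design).
#' @param allow_override Set `TRUE` to permit overriding constants.
#' @return A named list of model constants, class `isotope_params`.
#' @export
isotope_params <- function(..., allow_override = FALSE) {
  p <- list(
    slope_gc_density = 0.083506,
    intercept_density = 1.646057,
    mw_slope = 0.496,
    mw_intercept = 307.691,
    heavy_slope = -0.4987282,
    heavy_intercept = 9.974564,
    nat_13c = 0.01111233
  )
  dots <- list(...)
  if (length(dots) > 0L) {
    if (!allow_override) {
      stop("isotope model constants are fixed; use allow_override = TRUE ",
           "to change them deliberately", call. = FALSE)
    }
    bad <- setdiff(names(dots), names(p))
    if (length(bad) > 0L) stop("unknown constant: ", bad[1L], call. = FALSE)
    p[names(dots)] <- dots
  }
  structure(p, class = "isotope_params")
}

#' Infer GC content from light buoyant density
#'
#' Inverts the linear density--GC relation:
#' `G = (W_light - 1.646057) / 0.083506`. Noisy weighted-average densities
#' can land outside the physical range; such values are clamped to \[0, 1\]
#' with a warning, and the unclamped value is attached as attribute
#' `"unclamped"` for diagnostics.
#'
#' @param w_light Light (unlabeled) weighted average density, g/ml.
#' @param params Model constants, see [isotope_params()].
#' @return GC fraction in \[0, 1\] (vectorized).
#' @export
gc_from_density <- function(w_light, params = isotope_params()) {
  stopifnot(all(w_light > 0))
  g <- (w_light - params$intercept_density) / params$slope_gc_density
  tiny <- abs(g) < 1e-8 | abs(g - 1) < 1e-8
  g[tiny] <- pmin(pmax(g[tiny], 0), 1)  # numerical overshoot, not bad data
  if (any(g < 0 | g > 1)) {
    warning("GC content outside [0, 1] inferred from density; clamped",
            call. = FALSE)
    gc <- pmin(pmax(g, 0), 1)
    attr(gc, "unclamped") <- g
    return(gc)
  }
  g
}

#' Molecular weights of unlabeled and maximally 13C-labeled DNA
#'
#' @param gc GC fraction in \[0, 1\] (vectorized).
#' @param params Model constants, see [isotope_params()].
#' @return A list with `m_light` (average nucleotide molecular weight of
#'   unlabeled DNA, g/mol) and `m_heavymax` (at complete 13C substitution).
#' @export
molecular_weights <- function(gc, params = isotope_params()) {
  stopifnot(all(gc >= 0), all(gc <= 1))
  m_light <- params$mw_slope * gc + params$mw_intercept
  m_heavymax <- m_light + params$heavy_slope * gc + params$heavy_intercept
  list(m_light = m_light, m_heavymax = m_heavymax)
}

#' Excess atom fraction 13C from a buoyant-density shift
#'
#' The core qSIP estimator. Given a taxon's light weighted average density
#' `w_light` (from unlabeled controls) and its density `w_lab` in a labeled
#' incubation, the density shift is converted to a molecular-weight gain and
#' expressed as the fraction of carbon atoms that are 13C in excess of
#' natural abundance:
#' \deqn{M_{lab} = (\Delta W / W_{light} + 1) M_{light}, \quad
#'       A = \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}
#'           (1 - 0.01111233)}
#' Negative shifts give negative A; no truncation at zero is applied.
#'
#' @param w_light Light weighted average density, g/ml.
#' @param w_lab Weighted average density in the labeled incubation, g/ml.
#' @param params Model constants, see [isotope_params()].
#' @param gc Optional externally supplied GC fraction; by default inferred
#'   from `w_light` via [gc_from_density()].
#' @return Excess atom fraction 13C (unitless; 0 when `w_lab == w_light`,
#'   `1 - nat_13c` at complete labeling). Vectorized.
#' @examples
#' eaf_point(1.70, 1.70)            # exactly 0
#' eaf_point(1.687810, 1.697810)    # ~0.1855 for a +0.010 g/ml shift
#' @export
eaf_point <- function(w_light, w_lab, params = isotope_params(), gc = NULL) {
  stopifnot(all(w_light > 0))
  if (is.null(gc)) gc <- suppressWarnings(gc_from_density(w_light, params))
  gc <- pmin(pmax(as.numeric(gc), 0), 1)
  mw <- molecular_weights(gc, params)
  m_lab <- ((w_lab - w_light) / w_light + 1) * mw$m_light
  (m_lab - mw$m_light) / (mw$m_heavymax - mw$m_light) * (1 - params$nat_13c)
}

#' Expected buoyant-density band center for a given true labeling level
#'
#' Exact inverse of [eaf_point()]: for a taxon of GC content `gc` with true
#' excess atom fraction `a_true`, returns the buoyant density at which its
#' DNA bands,
#' `W_light + W_light * (M_heavymax - M_light) / M_light * a_true / (1 - nat_13c)`.
#' Used by the gradient simulator to place taxon bands.
#'
#' @param gc GC fraction in \[0, 1\].
#' @param a_true True excess atom fraction 13C in \[0, 1 - nat_13c\].
#' @param params Model constants, see [isotope_params()].
#' @return Band-center density, g/ml (vectorized).
#' @export
expected_band_center <- function(gc, a_true, params = isotope_params()) {
  stopifnot(all(gc >= 0), all(gc <= 1),
            all(a_true >= 0), all(a_true <= 1 - params$nat_13c + 1e-12))
  w_light <- params$slope_gc_density * gc + params$intercept_density
  mw <- molecular_weights(gc, params)
  shift <- w_light * (mw$m_heavymax - mw$m_light) / mw$m_light *
    a_true / (1 - params$nat_13c)
  w_light + shift
}
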