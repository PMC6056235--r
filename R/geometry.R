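#' Coiled-coil geometry parameters
#'
#' An alpha-helical coiled coil rises 0.146 nm per residue along its axis;
#' contour lengths measured on EM class averages can therefore be converted
#' to residue positions and back.
#'
#' @param rise_per_residue Axial rise per residue (nm); default 0.146.
#' @return An object of class `coiled_coil_params`.
#' @export
coiled_coil_params <- function(rise_per_residue = 0.146) {
  check_positive(rise_per_residue, "rise_per_residue")
  structure(list(rise_per_residue = rise_per_residue),
            class = "coiled_coil_params")
}

#' Contour length of a coiled-coil segment
#'
#' @param n_residues Number of residues (>= 0).
#' @param params A [coiled_coil_params()].
#' @param signif_digits Reporting precision in significant figures (default
#'   3, matching how contour lengths are quoted); `NULL` for full precision.
#' @return Length in nm.
#' @examples
#' coil_length(258)   # 37.7 nm
#' @export
coil_length <- function(n_residues, params = coiled_coil_params(),
                        signif_digits = 3) {
  check_count(n_residues, "n_residues")
  len <- n_residues * params$rise_per_residue
  if (is.null(signif_digits)) len else signif(len, signif_digits)
}

#' Residue position at a contour length
#'
#' @param length Contour length (nm, >= 0).
#' @param params A [coiled_coil_params()].
#' @return Nearest residue index (integer).
#' @examples
#' residue_at(16.5)   # residue 113
#' @export
residue_at <- function(length, params = coiled_coil_params()) {
  check_number(length, "length")
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  as.integer(round(length / params$rise_per_residue))
}

#' Sum contour-length segments with error propagation
#'
#' @param lengths Segment lengths (nm).
#' @param sds Optional per-segment SDs (nm) for quadrature propagation.
#' @return A list with `total` (nm, 3 significant figures) and `sd`
#'   (propagated as the root sum of squares, or NA).
#' @examples
#' sum_segments(c(16.5, 19.1))                    # total 35.6
#' sum_segments(c(16.5, 19.1), c(2.3, 2.0))$sd    # ~3.05
#' @export
sum_segments <- function(lengths, sds = NULL) {
  if (length(lengths) < 1) stop("no segments supplied", call. = FALSE)
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("segment lengths must be positive finite numbers", call. = FALSE)
  }
  sd_out <- NA_real_
  if (!is.null(sds)) {
    if (length(sds) != length(lengths) || any(sds < 0)) {
      stop("sds must match lengths and be >= 0", call. = FALSE)
    }
    sd_out <- signif(sqrt(sum(sds^2)), 3)
  }
  list(total = signif(sum(lengths), 3), sd = sd_out)
}
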