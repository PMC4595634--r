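# CHNOPS molecular-formula assignment from accurate neutral mass and,
# when available, the observed relative abundance of the M+1 isotopologue.

#' Default element-count bounds for formula enumeration
#'
#' @return Named integer vector of per-element maxima.
#' @export
default_element_bounds <- function() {
  c(C = 40L, H = 80L, N = 20L, O = 25L, P = 5L, S = 5L)
}

#' Assign molecular formulas to a neutral mass
#'
#' Exhaustively enumerates CHNOPS elemental compositions whose monoisotopic
#' mass lies within `mass_tol_ppm` of `neutral_mass`, and ranks them by a
#' score combining the absolute mass error (ppm) with, when an observed
#' M+1/M intensity ratio is supplied, the relative deviation between the
#' predicted and observed isotopologue ratio. Lower scores are better; the
#' planted/true composition scores 0 on exact inputs.
#'
#' Candidates with negative or non-integer ring-and-double-bond
#' equivalents (RDBE = C + 1 + (N + P)/2 - H/2) are excluded when
#' `rdbe_filter` is on: no neutral even-electron molecule has RDBE below
#' zero, and a half-integer RDBE implies a radical (the nitrogen rule). The element-ratio
#' filter applies the empirical plausibility ranges of natural products
#' (H/C <= 6, N/C <= 1.3, O/C <= 1.2, P/C <= 0.3, S/C <= 0.8, for
#' carbon-containing candidates); it resolves near-degenerate compositions
#' (e.g. the ~0.4 mDa CH2 vs N substitution family) in favour of
#' chemically sensible formulas when no isotope measurement is available.
#'
#' @param neutral_mass Target neutral monoisotopic mass in Da (> 0,
#'   < 1200 Da by default bounds).
#' @param m1_ratio Observed M+1/M intensity ratio, or `NULL`/`NA` when no
#'   isotope measurement is available.
#' @param bounds Named vector of per-element count maxima (CHNOPS).
#' @param mass_tol_ppm Mass tolerance in parts per million.
#' @param rdbe_filter Drop candidates with RDBE < 0 (default TRUE).
#' @param ratio_filter Drop candidates outside the empirical element
#'   ratio ranges (default TRUE).
#' @param iso_weight Weight of the isotope-fit term in the score.
#' @return data.frame of candidates sorted by ascending score, with columns
#'   formula, C, H, N, O, P, S, mass, mass_error_ppm, rdbe,
#'   predicted_m1_ratio, isotope_fit_error, score. Zero rows when no
#'   composition fits.
#' @examples
#' assign_formula(147.0532, m1_ratio = 0.056)[1, "formula"] # "C5H9NO4"
#' @export
assign_formula <- function(neutral_mass, m1_ratio = NULL,
                           bounds = default_element_bounds(),
                           mass_tol_ppm = 5, rdbe_filter = TRUE,
                           ratio_filter = TRUE, iso_weight = 100) {
  stopifnot(is.numeric(neutral_mass), length(neutral_mass) == 1L,
            neutral_mass > 0, mass_tol_ppm > 0)
  if (!is.null(m1_ratio) && (length(m1_ratio) != 1L || is.na(m1_ratio))) {
    m1_ratio <- NULL
  }
  tol <- neutral_mass * mass_tol_ppm * 1e-6
  mA <- .ATOMIC_MASS
  bd <- default_element_bounds()
  bd[names(bounds)] <- bounds
  # cap bounds by what fits under the target mass
  for (el in .ELEMENTS) {
    bd[el] <- min(bd[el], floor((neutral_mass + tol) / mA[el]))
  }
  if (any(bd < 0)) bd[bd < 0] <- 0L

  # enumerate the heavy heteroatoms on a grid, then solve C and H
  grid <- expand.grid(N = 0:bd[["N"]], O = 0:bd[["O"]],
                      P = 0:bd[["P"]], S = 0:bd[["S"]],
                      KEEP.OUT.ATTRS = FALSE)
  base <- grid$N * mA[["N"]] + grid$O * mA[["O"]] +
    grid$P * mA[["P"]] + grid$S * mA[["S"]]
  grid <- grid[base <= neutral_mass + tol, , drop = FALSE]
  base <- base[base <= neutral_mass + tol]

  out <- vector("list", bd[["C"]] + 1L)
  for (cc in 0:bd[["C"]]) {
    rem <- neutral_mass - base - cc * mA[["C"]]
    h <- round(rem / mA[["H"]])
    err <- rem - h * mA[["H"]]
    ok <- which(h >= 0 & h <= bd[["H"]] & abs(err) <= tol)
    if (length(ok)) {
      out[[cc + 1L]] <- data.frame(
        C = cc, H = h[ok], N = grid$N[ok], O = grid$O[ok],
        P = grid$P[ok], S = grid$S[ok]
      )
    }
  }
  cand <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(cand) || nrow(cand) == 0L) {
    return(.empty_formula_candidates())
  }
  cand$mass <- cand$C * mA[["C"]] + cand$H * mA[["H"]] +
    cand$N * mA[["N"]] + cand$O * mA[["O"]] +
    cand$P * mA[["P"]] + cand$S * mA[["S"]]
  cand$mass_error_ppm <- (cand$mass - neutral_mass) / neutral_mass * 1e6
  cand$rdbe <- cand$C + 1 + (cand$N + cand$P) / 2 - cand$H / 2
  if (rdbe_filter) {
    cand <- cand[cand$rdbe >= 0 & cand$rdbe %% 1 == 0, , drop = FALSE]
  }
  if (ratio_filter) {
    hasC <- cand$C > 0
    ok <- !hasC | (cand$H <= 6 * cand$C & cand$N <= 1.3 * cand$C &
                     cand$O <= 1.2 * cand$C & cand$P <= 0.3 * cand$C &
                     cand$S <= 0.8 * cand$C)
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(.empty_formula_candidates())
  }
  cand$predicted_m1_ratio <- cand$C * .M1_RATIO[["C"]] +
    cand$H * .M1_RATIO[["H"]] + cand$N * .M1_RATIO[["N"]] +
    cand$O * .M1_RATIO[["O"]] + cand$S * .M1_RATIO[["S"]]
  if (is.null(m1_ratio)) {
    cand$isotope_fit_error <- NA_real_
    cand$score <- abs(cand$mass_error_ppm)
  } else {
    cand$isotope_fit_error <-
      abs(cand$predicted_m1_ratio - m1_ratio) /
      pmax(cand$predicted_m1_ratio, 1e-6)
    cand$score <- abs(cand$mass_error_ppm) +
      iso_weight * cand$isotope_fit_error
  }
  cand$formula <- apply(cand[, c("C", "H", "N", "O", "P", "S")], 1L,
                        function(x) format_formula(x))
  ord <- order(cand$score, cand$C, cand$H, cand$N, cand$O, cand$P, cand$S)
  cand <- cand[ord, c("formula", "C", "H", "N", "O", "P", "S", "mass",
                      "mass_error_ppm", "rdbe", "predicted_m1_ratio",
                      "isotope_fit_error", "score")]
  rownames(cand) <- NULL
  cand
}

.empty_formula_candidates <- function() {
  data.frame(formula = character(0), C = integer(0), H = integer(0),
             N = integer(0), O = integer(0), P = integer(0), S = integer(0),
             mass = numeric(0), mass_error_ppm = numeric(0),
             rdbe = numeric(0), predicted_m1_ratio = numeric(0),
             isotope_fit_error = numeric(0), score = numeric(0))
}
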