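#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue composition (extracellular and intracellular water,
#' neutral lipid, neutral phospholipid, acidic phospholipid content in mg/g,
#' and compartment pH) for the tissues whose partition coefficients are
#' predicted mechanistically, plus blood cells and plasma.  The bundled table
#' is compiled from the published composition tables that accompany the
#' Rodgers-Rowland method; the table edition in use is recorded in the
#' `edition` attribute.
#'
#' @param file Optional CSV path with columns
#'   `tissue, f_ew, f_iw, f_nl, f_np, ap_mg_g, ph`; defaults to the bundled
#'   table.
#' @return A data.frame, one row per tissue, with attribute `edition`.
#' @export
tissue_composition <- function(file = NULL) {
  if (is.null(file)) file <- tetrodose_file("tissue_composition.csv")
  comp <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g", "ph")
  if (!all(need %in% names(comp))) {
    stop("composition table must have columns: ", paste(need, collapse = ", "))
  }
  frac <- as.matrix(comp[, c("f_ew", "f_iw", "f_nl", "f_np")])
  if (any(frac < 0 | frac > 1)) stop("composition fractions must lie in [0, 1]")
  if (!all(c("blood_cells", "plasma") %in% comp$tissue)) {
    stop("composition table must include 'blood_cells' and 'plasma' rows")
  }
  attr(comp, "edition") <- basename(file)
  comp
}

#' Predict a tissue-to-plasma partition coefficient (Rodgers-Rowland)
#'
#' Mechanistic prediction of the partition coefficient used for tissues with
#' no usable imaging data (muscle, adipose, GI, spleen, pancreas).  For a
#' monoprotic base with pKa above the intracellular pH the
#' moderate-to-strong-base equations are used: partitioning into tissue
#' water (with pH-dependent ionization), into neutral lipid and neutral
#' phospholipid, and electrostatic association of the ionized species with
#' acidic phospholipids.  The association constant is derived from blood
#' cell partitioning, which is obtained from the blood:plasma ratio, the
#' haematocrit and the fraction unbound; when the data imply a non-positive
#' association constant it is floored at zero (no acidic-phospholipid
#' binding) with a warning-free note in the result attributes.
#'
#' The returned value is on the tissue:plasma scale, `Kp = Kpu * fu`.
#'
#' @param drug A `drug_params` object (needs `physchem` and
#'   `blood_plasma_ratio`).
#' @param tissue Tissue name present in the composition table.
#' @param comp Composition table from [tissue_composition()].
#' @param hematocrit Haematocrit used to unpack blood-cell partitioning.
#' @return Partition coefficient (dimensionless, tissue:plasma), with
#'   attributes `kpu` and `ka_ap` (the blood-cell-derived association
#'   constant before flooring).
#' @export
rodgers_rowland_kp <- function(drug, tissue,
                               comp = tissue_composition(),
                               hematocrit = 0.45) {
  pc <- drug$physchem
  if (is.null(pc)) stop("drug parameters carry no physicochemical block")
  type <- tolower(pc$compound_type)
  if (!identical(type, "monoprotic base")) {
    stop("unsupported compound_type: ", pc$compound_type,
         " (only 'monoprotic base' is implemented)")
  }
  row <- comp[comp$tissue == tissue, ]
  if (nrow(row) != 1L) stop("tissue not in composition table: ", tissue)
  bc <- comp[comp$tissue == "blood_cells", ]
  pl <- comp[comp$tissue == "plasma", ]

  P <- 10^pc$logp
  fu <- pc$fu
  R <- drug$blood_plasma_ratio
  ion <- function(ph) 1 + 10^(pc$pka - ph)
  Yp <- ion(pl$ph)

  lip <- function(z) (P * z$f_nl + (0.3 * P + 0.7) * z$f_np) / Yp
  # association constant for acidic phospholipids from blood-cell data
  kpu_bc <- (R - (1 - hematocrit)) / (hematocrit * fu)
  ka_ap <- (kpu_bc - ion(bc$ph) / Yp * bc$f_iw - lip(bc)) *
    Yp / (10^(pc$pka - bc$ph) * bc$ap_mg_g)
  ka <- max(ka_ap, 0)

  kpu <- row$f_ew + ion(row$ph) / Yp * row$f_iw +
    ka * row$ap_mg_g * 10^(pc$pka - row$ph) / Yp + lip(row)
  structure(kpu * fu, kpu = kpu, ka_ap = ka_ap)
}

#' Predict all mechanistically derived partition coefficients
#'
#' Convenience wrapper applying [rodgers_rowland_kp()] to every tissue row
#' of the composition table (excluding blood cells and plasma).
#'
#' @inheritParams rodgers_rowland_kp
#' @return Named numeric vector of partition coefficients.
#' @export
predict_kp_table <- function(drug, comp = tissue_composition(),
                             hematocrit = 0.45) {
  tissues <- setdiff(comp$tissue, c("blood_cells", "plasma"))
  vapply(tissues, function(t) {
    as.numeric(rodgers_rowland_kp(drug, t, comp, hematocrit))
  }, numeric(1))
}
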