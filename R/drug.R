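#' Drug-specific model parameters
#'
#' Constructs the drug parameter set of the PBPK model: partition
#' coefficients per tissue, permeability-surface products for the
#' permeability-limited organs (heart, kidney), renal and hepatic
#' clearances, the gallbladder emptying constant and the blood:plasma
#' ratio.  `default_drug_params()` loads the bundled Tc99m-tetrofosmin set:
#' the adult maximum-likelihood estimates for the eleven fitted parameters
#' together with the mechanistically predicted partition coefficients for
#' the unobserved tissues.
#'
#' @param kp Named numeric vector of partition coefficients; must contain
#'   `lung, heart, kidney, liver, thyroid, other, muscle, adipose, gi,
#'   spleen, pancreas`.
#' @param ps Named vector with `heart` and `kidney` (L/min).
#' @param cl Named vector with `renal` and `liver` (L/min).
#' @param k_gb Gallbladder emptying constant (1/min).
#' @param blood_plasma_ratio Whole-blood to plasma concentration ratio.
#' @param physchem Optional list with `logp`, `pka`, `fu`, `compound_type`
#'   (needed for partition-coefficient prediction).
#' @param name Optional label.
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(kp, ps, cl, k_gb, blood_plasma_ratio = 0.8,
                        physchem = NULL, name = "drug") {
  need_kp <- c("lung", "heart", "kidney", "liver", "thyroid", "other",
               "muscle", "adipose", "gi", "spleen", "pancreas")
  kp <- unlist(kp); ps <- unlist(ps); cl <- unlist(cl)
  miss <- setdiff(need_kp, names(kp))
  if (length(miss)) stop("missing Kp for: ", paste(miss, collapse = ", "))
  if (any(kp[need_kp] <= 0)) stop("all Kp must be > 0")
  if (!all(c("heart", "kidney") %in% names(ps))) {
    stop("ps must name 'heart' and 'kidney'")
  }
  if (!all(c("renal", "liver") %in% names(cl))) {
    stop("cl must name 'renal' and 'liver'")
  }
  if (any(c(ps, cl, k_gb) < 0)) stop("PS, CL and K_gb must be >= 0")
  if (blood_plasma_ratio <= 0) stop("blood:plasma ratio must be > 0")
  if (!is.null(physchem)) {
    stopifnot(physchem$fu > 0, physchem$fu <= 1)
  }
  structure(list(name = name, kp = kp[need_kp],
                 ps = ps[c("heart", "kidney")],
                 cl = cl[c("renal", "liver")],
                 k_gb = as.numeric(k_gb),
                 blood_plasma_ratio = blood_plasma_ratio,
                 physchem = physchem),
            class = "drug_params")
}

#' @rdname drug_params
#' @param file Optional JSON file mirroring the `drug_params` fields.
#' @export
default_drug_params <- function(file = NULL) {
  if (is.null(file)) file <- tetrodose_file("drug_tetrofosmin.json")
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  drug_params(kp = x$kp, ps = x$ps, cl = x$cl, k_gb = x$k_gb,
              blood_plasma_ratio = x$blood_plasma_ratio,
              physchem = x$physchem, name = x$name)
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s\n", x$name))
  cat("  Kp:", paste(sprintf("%s=%.3g", names(x$kp), x$kp), collapse = " "), "\n")
  cat(sprintf("  PS: heart=%.4g kidney=%.4g L/min | CL: renal=%.4g liver=%.4g L/min\n",
              x$ps[["heart"]], x$ps[["kidney"]], x$cl[["renal"]], x$cl[["liver"]]))
  cat(sprintf("  K_gb=%.4g 1/min, blood:plasma R=%.3g\n",
              x$k_gb, x$blood_plasma_ratio))
  invisible(x)
}

#' Scale drug parameters from adult to a paediatric physiology
#'
#' Partition coefficients and the gallbladder emptying constant are kept at
#' their adult values; permeability-surface products scale with the
#' corresponding total organ volume ratio to the power `a_ps` (surface-like,
#' default 2/3) and clearances with the kidney or liver volume ratio to the
#' power `a_cl` (metabolic, default 3/4).
#'
#' @param adult_drug Adult `drug_params`.
#' @param adult_phys,child_phys `pbpk_physiology` objects.
#' @param a_ps,a_cl Allometric exponents in (0, 1].
#' @return A `drug_params` object for the child.
#' @export
scale_drug_params <- function(adult_drug, adult_phys, child_phys,
                              a_ps = 2 / 3, a_cl = 3 / 4) {
  stopifnot(inherits(adult_drug, "drug_params"),
            inherits(adult_phys, "pbpk_physiology"),
            inherits(child_phys, "pbpk_physiology"))
  if (a_ps <= 0 || a_ps > 1 || a_cl <= 0 || a_cl > 1) {
    stop("allometric exponents must lie in (0, 1]")
  }
  vol_ratio <- function(organ_parts) {
    va <- sum(adult_phys$V[organ_parts])
    vc <- sum(child_phys$V[organ_parts])
    if (va <= 0) stop("zero adult volume for: ",
                      paste(organ_parts, collapse = "+"))
    vc / va
  }
  r_heart  <- vol_ratio(c("heart_vascular", "heart_extravascular"))
  r_kidney <- vol_ratio(c("kidney_vascular", "kidney_extravascular"))
  r_liver  <- vol_ratio("liver")
  out <- adult_drug
  out$ps[["heart"]]  <- adult_drug$ps[["heart"]]  * r_heart^a_ps
  out$ps[["kidney"]] <- adult_drug$ps[["kidney"]] * r_kidney^a_ps
  out$cl[["renal"]]  <- adult_drug$cl[["renal"]]  * r_kidney^a_cl
  out$cl[["liver"]]  <- adult_drug$cl[["liver"]]  * r_liver^a_cl
  out$name <- paste0(adult_drug$name, " (", child_phys$age_label, ")")
  out
}
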