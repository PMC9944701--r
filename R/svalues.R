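# S-value matrices (absorbed dose per unit cumulated activity), ICRP-103
# tissue weighting factors, and synthetic per-age S-value fixtures.

#' Construct an S-value matrix
#'
#' @param S Numeric matrix, targets in rows, source regions in columns,
#'   in mGy/(MBq h).
#' @param age_label Age label the matrix belongs to.
#' @return An object of class `svalue_matrix`.
#' @export
svalue_matrix <- function(S, age_label = "adult") {
  stopifnot(is.matrix(S), !is.null(rownames(S)), !is.null(colnames(S)))
  if (any(S < 0)) stop("S values must be non-negative")
  shared <- intersect(rownames(S), colnames(S))
  for (s in shared) {
    if (S[s, s] < max(S[, s])) {
      warning("self-dose not dominant for source: ", s)
      break
    }
  }
  structure(list(S = S, age_label = age_label,
                 targets = rownames(S), sources = colnames(S)),
            class = "svalue_matrix")
}

#' @export
print.svalue_matrix <- function(x, ...) {
  cat(sprintf("<svalue_matrix> %s: %d targets x %d sources [mGy/(MBq h)]\n",
              x$age_label, length(x$targets), length(x$sources)))
  invisible(x)
}

#' Read an S-value matrix from CSV
#'
#' Long format with columns `target, source, svalue, unit`.  Units are
#' normalized to mGy/(MBq h) on ingest; `mGy/MBq/h` and `mGy/MBq/s` are
#' recognised.
#'
#' @param file CSV path; the bundled synthetic tables are selected with
#'   [bundled_svalues()].
#' @param age_label Age label to record.
#' @return An `svalue_matrix`.
#' @export
read_svalue_matrix <- function(file, age_label = "adult") {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("target", "source", "svalue", "unit")
  if (!all(need %in% names(d))) {
    stop("S-value file must have columns: ", paste(need, collapse = ", "))
  }
  fac <- c("mGy/MBq/h" = 1, "mGy/MBq/s" = 3600)
  if (any(!d$unit %in% names(fac))) {
    stop("unknown S-value unit: ",
         paste(unique(setdiff(d$unit, names(fac))), collapse = ", "))
  }
  d$svalue <- d$svalue * fac[d$unit]
  tg <- sort(unique(d$target)); sr <- sort(unique(d$source))
  S <- matrix(0, length(tg), length(sr), dimnames = list(tg, sr))
  S[cbind(match(d$target, tg), match(d$source, sr))] <- d$svalue
  svalue_matrix(S, age_label)
}

#' Bundled synthetic S-value table for one age
#'
#' Loads the packaged per-age Tc99m S-value tables.  These are synthetic
#' stand-ins constructed with [make_svalue_table()] from the bundled
#' physiologies and an energy-budget photon/electron model, not phantom
#' Monte-Carlo values; study-specific tables should be supplied via
#' [read_svalue_matrix()].
#'
#' @param age_label One of the supported ages.
#' @return An `svalue_matrix`.
#' @export
bundled_svalues <- function(age_label = "adult") {
  age_label <- match.arg(age_label, supported_ages())
  read_svalue_matrix(
    tetrodose_file(sprintf("svalues_tc99m_%s_synthetic.csv", age_label)),
    age_label)
}

#' Read ICRP-103 tissue weighting factors
#'
#' @param file CSV with columns `target, weight`; defaults to the bundled
#'   ICRP-103 set (including a `remainder` row).
#' @return A `tissue_weights` object (named numeric vector, summing to 1).
#' @export
read_tissue_weights <- function(file = NULL) {
  if (is.null(file)) file <- tetrodose_file("icrp103_weights.csv")
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  w <- stats::setNames(d$weight, d$target)
  if (abs(sum(w) - 1) > 1e-8) stop("tissue weights must sum to 1")
  structure(w, class = "tissue_weights")
}

# --- synthetic S-value construction -------------------------------------

# Tc99m energy budget per decay: ~16.2 keV in conversion/Auger electrons
# (non-penetrating, absorbed locally) and ~126.9 keV in photons.  The
# constant 576.7 converts MeV/decay to mGy g / (MBq h).
TC99M_DELTA_NP <- 576.7 * 0.0162
TC99M_DELTA_PH <- 576.7 * 0.1269
# effective photon absorption coefficient (1/cm) of the one-parameter
# sphere model, anchored so that the adult whole body self-absorbs ~33%
# of 140 keV photon energy
PHOTON_KEFF <- 0.0155

phi_photon <- function(mass_g) {
  r <- (3 * mass_g / (4 * pi))^(1 / 3)  # unit-density sphere radius, cm
  1 - exp(-PHOTON_KEFF * r)
}

svalue_registry <- function(phys) {
  bw_g <- phys$body_weight * 1000
  scale <- phys$body_weight / 73
  brain_g <- phys$V[["brain_vascular"]] * 1450 / 0.06
  targets <- c(
    gonads = 35 * scale, red_marrow = 1170 * scale,
    colon_wall = 670 * scale, lung = phys$V[["lung"]] * 1050,
    stomach_wall = 150 * scale, breast = 360 * scale,
    bladder_wall = 50 * scale, liver = phys$V[["liver"]] * 1050,
    oesophagus = 40 * scale, thyroid = phys$V[["thyroid"]] * 1050,
    skin = 3300 * scale, bone_surface = 120 * scale, brain = brain_g,
    salivary_glands = 85 * scale, adrenals = 14 * scale,
    gallbladder_wall = 10 * scale,
    heart_wall = sum(phys$V[c("heart_vascular", "heart_extravascular")]) * 1050,
    kidneys = sum(phys$V[c("kidney_vascular", "kidney_extravascular")]) * 1050,
    muscle = phys$V[["muscle"]] * 1040,
    pancreas = phys$V[["pancreas"]] * 1050,
    small_intestine_wall = 650 * scale,
    spleen = phys$V[["spleen"]] * 1050, thymus = 25 * scale)
  sources <- c(
    heart_wall = unname(targets["heart_wall"]),
    lungs = unname(targets["lung"]), liver = unname(targets["liver"]),
    gallbladder_contents = phys$V[["gallbladder"]] * 1030,
    intestine_wall = phys$V[["gi_tissue"]] * 1040,
    intestine_contents = 1000 * scale,
    kidneys = unname(targets["kidneys"]),
    spleen = unname(targets["spleen"]),
    pancreas = unname(targets["pancreas"]),
    thyroid = unname(targets["thyroid"]),
    bladder_contents = 200 * scale)
  in_rest <- c("gonads", "red_marrow", "breast", "bladder_wall",
               "oesophagus", "skin", "bone_surface", "brain",
               "salivary_glands", "adrenals", "gallbladder_wall",
               "muscle", "thymus")
  list(targets = targets, sources = sources, body_g = bw_g,
       in_rest = in_rest)
}

#' Build a synthetic Tc99m S-value table from a physiology
#'
#' Deterministic energy-budget stand-in for phantom-derived S values:
#' conversion/Auger electron energy is absorbed in the source region,
#' photon energy is partly self-absorbed (one-parameter sphere model for
#' the absorbed fraction) and the escaping remainder is spread uniformly
#' over the whole body; hollow-organ contents irradiate their walls with
#' half the surface electron/photon term.  A distributed `rest_of_body`
#' source covers the blood pools, muscle, adipose and the remainder
#' compartment.  Intended for structural and approximate quantitative
#' work; not a substitute for phantom Monte-Carlo tables.
#'
#' @param phys A `pbpk_physiology`.
#' @return An `svalue_matrix` in mGy/(MBq h).
#' @export
make_svalue_table <- function(phys) {
  reg <- svalue_registry(phys)
  tg <- names(reg$targets); src <- c(names(reg$sources), "rest_of_body")
  m_rest <- reg$body_g - sum(reg$sources)
  phiWB <- phi_photon(reg$body_g)
  S <- matrix(0, length(tg), length(src), dimnames = list(tg, src))
  wall_of <- list(bladder_contents = c(bladder_wall = 1),
                  gallbladder_contents = c(gallbladder_wall = 1),
                  intestine_contents = c(small_intestine_wall = 0.5,
                                         colon_wall = 0.5),
                  intestine_wall = c(stomach_wall = 1,
                                     small_intestine_wall = 1,
                                     colon_wall = 1),
                  heart_wall = c(heart_wall = 1),
                  lungs = c(lung = 1), liver = c(liver = 1),
                  kidneys = c(kidneys = 1), spleen = c(spleen = 1),
                  pancreas = c(pancreas = 1), thyroid = c(thyroid = 1))
  contents <- c("bladder_contents", "gallbladder_contents",
                "intestine_contents")
  for (s in names(reg$sources)) {
    ms <- reg$sources[[s]]
    phi_s <- phi_photon(ms)
    # photon energy escaping the source, spread over the whole body
    S[, s] <- TC99M_DELTA_PH * max(phiWB - phi_s, 0) / reg$body_g
    self <- (TC99M_DELTA_NP + phi_s * TC99M_DELTA_PH) / ms
    w <- wall_of[[s]]
    fac <- if (s %in% contents) 0.5 else 1
    S[names(w), s] <- S[names(w), s] + fac * self * w
  }
  # distributed remainder source
  phi_r <- phiWB
  S[, "rest_of_body"] <- TC99M_DELTA_PH * phi_r / reg$body_g
  S[reg$in_rest, "rest_of_body"] <-
    S[reg$in_rest, "rest_of_body"] + TC99M_DELTA_NP / m_rest
  svalue_matrix(S, phys$age_label)
}

#' Write an S-value matrix to CSV
#' @param sv An `svalue_matrix`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_svalue_matrix <- function(sv, file) {
  long <- data.frame(target = rep(sv$targets, times = length(sv$sources)),
                     source = rep(sv$sources, each = length(sv$targets)),
                     svalue = signif(as.vector(sv$S), 6),
                     unit = "mGy/MBq/h")
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
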