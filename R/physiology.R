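#' Organ registries used by the model
#'
#' `physiology_organs()` returns the organ names that must carry a volume in a
#' physiology table; `physiology_flows()` the organ names that must carry a
#' blood flow.
#'
#' @return Character vector of organ labels.
#' @export
physiology_organs <- function() {
  c("arterial_blood", "venous_blood", "lung", "heart_vascular",
    "heart_extravascular", "heart_chambers", "brain_vascular", "muscle",
    "liver", "gallbladder", "gi_tissue", "spleen", "pancreas",
    "kidney_vascular", "kidney_extravascular", "adipose", "thyroid")
}

#' @rdname physiology_organs
#' @export
physiology_flows <- function() {
  c("lung", "heart_vascular", "brain_vascular", "muscle", "liver",
    "hepatic_artery", "gi_tissue", "spleen", "pancreas", "kidney_vascular",
    "adipose", "thyroid")
}

supported_ages <- function() c("adult", "15y", "10y", "5y", "1y")

#' Load a physiology table
#'
#' Reads organ volumes (L) and blood flows (L/min) for one age from a CSV
#' table with columns `organ`, `volume_L`, `flow_L_per_min`, validates them,
#' and closes the mass and flow balances: the volume of the unresolved
#' remainder compartment (`other`) is the whole-body volume minus all named
#' organs, and its flow is the cardiac output minus all named venous returns.
#'
#' The bundled tables (used when `file` is `NULL`) are compiled
#' approximations from standard reference anatomy and physiology sources;
#' they can be overridden with study-specific tables via `file`.
#'
#' @param age_label One of `"adult"`, `"15y"`, `"10y"`, `"5y"`, `"1y"`.
#' @param file Optional path to a physiology CSV; defaults to the bundled
#'   table for `age_label`.
#' @return An object of class `pbpk_physiology`: a list with `age_label`,
#'   `body_weight` (kg), named vectors `V` (L) and `Q` (L/min) including the
#'   closed `other` entries, and `cardiac_output`.
#' @export
load_physiology <- function(age_label = "adult", file = NULL) {
  age_label <- match.arg(age_label, supported_ages())
  if (is.null(file)) {
    file <- tetrodose_file(sprintf("physiology_%s.csv", age_label))
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("organ", "volume_L", "flow_L_per_min")
  if (!all(need %in% names(tab))) {
    stop("physiology table must have columns: ", paste(need, collapse = ", "))
  }
  vol <- stats::setNames(tab$volume_L, tab$organ)
  flo <- stats::setNames(tab$flow_L_per_min, tab$organ)

  miss_v <- setdiff(c("whole_body", physiology_organs()), names(vol)[!is.na(vol)])
  if (length(miss_v)) {
    stop("missing organ volume(s): V_", paste(miss_v, collapse = ", V_"))
  }
  fl_have <- names(flo)[!is.na(flo)]
  miss_q <- setdiff(physiology_flows(), fl_have)
  if (length(miss_q)) {
    stop("missing organ flow(s): Q_", paste(miss_q, collapse = ", Q_"))
  }
  V <- vol[physiology_organs()]
  Q <- flo[physiology_flows()]
  names(Q) <- sub("_vascular$", "", names(Q))
  names(Q)[names(Q) == "gi_tissue"] <- "gi"
  if (any(V <= 0)) {
    stop("non-positive volume for: ", paste(names(V)[V <= 0], collapse = ", "))
  }
  if (any(Q <= 0)) {
    stop("non-positive flow for: ", paste(names(Q)[Q <= 0], collapse = ", "))
  }

  v_body <- vol[["whole_body"]]
  co <- flo[["lung"]]
  V[["other"]] <- v_body - sum(V[physiology_organs()])
  if (V[["other"]] <= 0) stop("whole-body volume smaller than named organs")
  # venous return balance: Q_lung = sum of flows returning to venous blood
  Q[["other"]] <- co - sum(Q[c("muscle", "heart", "brain", "liver",
                               "thyroid", "adipose", "kidney")])
  if (Q[["other"]] <= 0) stop("cardiac output smaller than named venous returns")
  hep <- sum(Q[c("hepatic_artery", "gi", "spleen", "pancreas")])
  if (abs(hep - Q[["liver"]]) > 1e-6 * Q[["liver"]]) {
    stop(sprintf(paste0("hepatic flow balance violated: Q_liver = %.5f but ",
                        "Q_hepatic + Q_gi + Q_spleen + Q_pancreas = %.5f"),
                 Q[["liver"]], hep))
  }
  structure(list(age_label = age_label,
                 body_weight = v_body * 1.05,
                 V = V, Q = Q, cardiac_output = co),
            class = "pbpk_physiology")
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat(sprintf("<pbpk_physiology> %s, body weight %.1f kg, CO %.2f L/min\n",
              x$age_label, x$body_weight, x$cardiac_output))
  cat(sprintf("  %d organ volumes (total %.1f L), %d flows\n",
              length(x$V), sum(x$V), length(x$Q)))
  invisible(x)
}

#' Validate the flow balances of a physiology object
#'
#' Checks that the venous return flows sum to the cardiac output and the
#' splanchnic flows to the liver outflow.
#'
#' @param phys A `pbpk_physiology` object.
#' @return Invisibly, a named list of absolute balance residuals.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  ven <- sum(phys$Q[c("muscle", "heart", "brain", "liver", "thyroid",
                      "adipose", "kidney", "other")]) - phys$Q[["lung"]]
  hep <- sum(phys$Q[c("hepatic_artery", "gi", "spleen", "pancreas")]) -
    phys$Q[["liver"]]
  if (abs(ven) > 1e-8 || abs(hep) > 1e-8) {
    stop("flow balance violated (venous ", signif(ven, 3),
         ", hepatic ", signif(hep, 3), ")")
  }
  invisible(list(venous = ven, hepatic = hep))
}
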