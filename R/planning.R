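#' Dose thresholds for activity planning
#'
#' Planning limits: a maximum mean lung dose, a maximum mean normal-liver
#' dose, and a minimum desired tumor dose (checked and reported, never a
#' constraint). Two published presets are provided: `"T1"` (lung 25 Gy,
#' normal liver 70 Gy, tumor > 100 Gy, the resin-microsphere package
#' insert) and `"T2"` (lung 25 Gy, normal liver 40 Gy, tumor > 100 Gy, the
#' more conservative literature values).
#'
#' @param name `"T1"`, `"T2"` or `"custom"`.
#' @param lung_Gy,normal_liver_Gy,tumor_min_Gy custom limits (all > 0),
#'   required when `name = "custom"`.
#' @return object of class `sirt_thresholds`.
#' @export
thresholds <- function(name = c("T1", "T2", "custom"), lung_Gy = NULL,
                       normal_liver_Gy = NULL, tumor_min_Gy = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    T1 = list(lung_Gy = 25, normal_liver_Gy = 70, tumor_min_Gy = 100),
    T2 = list(lung_Gy = 25, normal_liver_Gy = 40, tumor_min_Gy = 100),
    custom = list(lung_Gy = lung_Gy, normal_liver_Gy = normal_liver_Gy,
                  tumor_min_Gy = tumor_min_Gy))
  if (any(vapply(preset, is.null, logical(1))))
    stop("custom thresholds need lung_Gy, normal_liver_Gy and tumor_min_Gy",
         call. = FALSE)
  if (any(unlist(preset) <= 0)) stop("thresholds must be > 0", call. = FALSE)
  structure(c(preset, list(tag = name)), class = "sirt_thresholds")
}

#' Patient body data for the BSA method
#'
#' @param height_m body height in metres (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param tumor_mL total tumor volume in mL.
#' @param total_mL total liver-plus-tumor volume in mL (>= `tumor_mL`).
#' @return object of class `patient_body`.
#' @export
patient_body <- function(height_m, weight_kg, tumor_mL, total_mL) {
  if (height_m <= 0 || weight_kg <= 0)
    stop("height and weight must be > 0", call. = FALSE)
  if (total_mL <= 0) stop("total volume must be > 0", call. = FALSE)
  if (tumor_mL < 0 || tumor_mL > total_mL)
    stop("tumor volume must lie in [0, total volume]", call. = FALSE)
  structure(list(height_m = height_m, weight_kg = weight_kg,
                 tumor_mL = tumor_mL, total_mL = total_mL),
            class = "patient_body")
}

#' Empirical body-surface-area activity
#'
#' The DuBois body surface area
#' `BSA = 0.20247 * height^0.725 * weight^0.425` (m^2) and the empirical
#' prescription `A = BSA - 0.2 + V_T / V_total` (GBq). Depends only on
#' patient size and tumor volume fraction, never on image counts.
#'
#' @param body a [patient_body()].
#' @return prescribed activity in GBq.
#' @export
bsa_activity <- function(body) {
  stopifnot(inherits(body, "patient_body"))
  bsa <- 0.20247 * body$height_m^0.725 * body$weight_kg^0.425
  bsa - 0.2 + body$tumor_mL / body$total_mL
}

#' Threshold-constrained prescribed activity
#'
#' Every dose in both models is linear in the total activity `A0`, so each
#' constraint inverts in closed form. The prescription is
#' `A0 = min(A0_NL, A0_lung)` where `A0_NL` puts the mean normal-liver dose
#' exactly at its limit and `A0_lung` puts the lung dose at its limit (the
#' lung constraint is inactive when the shunt fraction is 0). Under
#' `model = "PM"` the classical three-compartment equations are inverted
#' (any margin partition is merged back into normal liver, as the classical
#' model knows no margin); under `model = "TM"` the mass-weighted mean of
#' the territorial normal-liver doses is inverted. The tumor minimum is
#' checked and flagged, never enforced; an optional `tumor_max_Gy` cap can
#' additionally restrict `A0`.
#'
#' @param table a [partition_counts()] table.
#' @param model `"PM"` or `"TM"`.
#' @param limits a [thresholds()] object.
#' @param tumor_max_Gy optional maximum mean tumor dose; `NULL` (default)
#'   disables the cap.
#' @param constants a [dose_constants()] list.
#' @return object of class `plan_result`: `A0_GBq`, `limiting` (the binding
#'   constraint), `model`, `doses` (PM: list; TM: the dosed table),
#'   `tumor_target_met`, `summary` (A0, D_lung, mean D_NL, mean D_T).
#' @export
plan_activity <- function(table, model = c("PM", "TM"), limits = thresholds("T1"),
                          tumor_max_Gy = NULL, constants = dose_constants()) {
  model <- match.arg(model)
  stopifnot(inherits(limits, "sirt_thresholds"))
  k <- constants$dose_factor_Gy_kg_per_GBq
  L <- lung_shunt_fraction(table)
  if (L >= 1) stop("all activity shunts to the lung; no feasible plan", call. = FALSE)
  m_lung <- sum(table$mass_kg[table$role == "lung"])

  if (model == "PM") {
    agg <- pm_aggregate(table)
    # invert D_NL = k A0 (1-L) / (m_NL + TN m_T) for A0
    A0_nl <- limits$normal_liver_Gy * (agg$m_nl + agg$TN * agg$m_tumor) /
      (k * (1 - L))
  } else {
    nl <- table$role == "normal_liver_territory"
    liver <- table$role %in% liver_side_roles
    c_liver <- sum(table$counts[liver])
    if (sum(table$counts[nl]) <= 0)
      stop("no normal-liver counts; territorial plan undefined", call. = FALSE)
    f_nl <- sum(table$counts[nl]) / c_liver
    m_nl <- sum(table$mass_kg[nl])
    # invert mass-weighted mean NL dose = k A0 (1-L) f_NL / m_NL
    A0_nl <- limits$normal_liver_Gy * m_nl / (k * (1 - L) * f_nl)
  }
  A0_lung <- if (L > 0 && m_lung > 0) limits$lung_Gy * m_lung / (k * L) else Inf

  cands <- c(normal_liver = A0_nl, lung = A0_lung)
  if (!is.null(tumor_max_Gy)) {
    A0_tum <- a0_at_tumor_dose(table, model, tumor_max_Gy, k, L)
    cands <- c(cands, tumor_max = A0_tum)
  }
  A0 <- min(cands)
  limiting <- names(cands)[which.min(cands)]
  if (!is.finite(A0) || A0 <= 0)
    stop("no finite positive activity satisfies the constraints", call. = FALSE)

  if (model == "PM") {
    agg <- pm_aggregate(table)
    d <- pm_doses(A0, L, agg$TN, m_lung, agg$m_nl, agg$m_tumor, constants)
    summary <- c(A0_GBq = A0, D_lung_Gy = d$D_lung_Gy, D_nl_Gy = d$D_nl_Gy,
                 D_tumor_Gy = d$D_tumor_Gy)
    tumor_met <- d$D_tumor_Gy > limits$tumor_min_Gy
    doses <- d
  } else {
    dosed <- tm_doses(A0, table, L = L, constants = constants)
    mean_nl <- mean_normal_liver_dose(dosed)
    tum <- dosed[dosed$role == "tumor" & !dosed$empty, ]
    mean_t <- if (nrow(tum)) sum(tum$dose_Gy * tum$mass_kg) / sum(tum$mass_kg) else NA_real_
    summary <- c(A0_GBq = A0,
                 D_lung_Gy = dosed$dose_Gy[dosed$role == "lung"][1],
                 D_nl_Gy = mean_nl, D_tumor_Gy = mean_t)
    tumor_met <- if (nrow(tum)) tum$dose_Gy > limits$tumor_min_Gy else logical(0)
    doses <- dosed
  }
  structure(list(A0_GBq = A0, limiting = limiting, model = model,
                 thresholds = limits, L = L, doses = doses,
                 tumor_target_met = tumor_met, summary = summary),
            class = "plan_result")
}

# classical-model aggregates from a partition table; the margin partition
# is folded back into normal liver (the PM has no margin concept)
pm_aggregate <- function(table) {
  nl <- table$role %in% c("normal_liver_territory", "excluded_margin")
  tum <- table$role == "tumor"
  m_nl <- sum(table$mass_kg[nl]); m_tumor <- sum(table$mass_kg[tum])
  c_nl <- sum(table$counts[nl]); c_tumor <- sum(table$counts[tum])
  if (m_nl <= 0 || c_nl <= 0)
    stop("classical model needs normal-liver mass and counts", call. = FALSE)
  TN <- if (m_tumor > 0) (c_tumor / m_tumor) / (c_nl / m_nl) else 1
  list(m_nl = m_nl, m_tumor = m_tumor, c_nl = c_nl, c_tumor = c_tumor, TN = TN)
}

a0_at_tumor_dose <- function(table, model, dose_Gy, k, L) {
  if (model == "PM") {
    agg <- pm_aggregate(table)
    if (agg$m_tumor <= 0) return(Inf)
    # D_T = TN * k A0 (1-L) / (m_NL + TN m_T)
    dose_Gy * (agg$m_nl + agg$TN * agg$m_tumor) / (k * (1 - L) * agg$TN)
  } else {
    tum <- table$role == "tumor" & table$counts > 0
    if (!any(tum)) return(Inf)
    liver <- table$role %in% liver_side_roles
    f <- table$counts[tum] / sum(table$counts[liver])
    # mass-weighted mean tumor dose = k A0 (1-L) sum(f) / sum(m)
    dose_Gy * sum(table$mass_kg[table$role == "tumor"]) /
      (k * (1 - L) * sum(f))
  }
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %s, A0 = %.2f GBq (limited by %s, thresholds %s)\n",
              x$model, x$A0_GBq, x$limiting, x$thresholds$tag))
  s <- x$summary
  cat(sprintf("  D_lung %.2f Gy | mean D_NL %.2f Gy | mean D_T %s Gy | tumor target %s\n",
              s["D_lung_Gy"], s["D_nl_Gy"],
              ifelse(is.na(s["D_tumor_Gy"]), "-", sprintf("%.2f", s["D_tumor_Gy"])),
              if (length(x$tumor_target_met) && all(x$tumor_target_met)) "met"
              else if (!length(x$tumor_target_met)) "n/a" else "NOT met"))
  invisible(x)
}

#' Side-by-side model comparison
#'
#' Plans the activity with the classical partition model, the territorial
#' model and (when body data is given) the BSA method on the same inputs,
#' reporting prescribed activity, limiting constraint, lung dose, mean
#' normal-liver dose, mean tumor dose and the tumor-target flag per model.
#'
#' @param table a [partition_counts()] table.
#' @param limits a [thresholds()] object.
#' @param body optional [patient_body()] for the BSA row.
#' @param constants a [dose_constants()] list.
#' @return data.frame, one row per model.
#' @export
compare_models <- function(table, limits = thresholds("T1"), body = NULL,
                           constants = dose_constants()) {
  rows <- list()
  for (model in c("PM", "TM")) {
    p <- plan_activity(table, model, limits, constants = constants)
    rows[[model]] <- data.frame(
      model = model, A0_GBq = p$A0_GBq, limiting = p$limiting,
      D_lung_Gy = unname(p$summary["D_lung_Gy"]),
      D_nl_Gy = unname(p$summary["D_nl_Gy"]),
      D_tumor_Gy = unname(p$summary["D_tumor_Gy"]),
      tumor_target_met = length(p$tumor_target_met) > 0 && all(p$tumor_target_met))
  }
  if (!is.null(body)) {
    rows$BSA <- data.frame(model = "BSA", A0_GBq = bsa_activity(body),
                           limiting = "empirical", D_lung_Gy = NA_real_,
                           D_nl_Gy = NA_real_, D_tumor_Gy = NA_real_,
                           tumor_target_met = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
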