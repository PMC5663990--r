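#' Y-90 dose constants
#'
#' The MIRD single-compartment dose factor for Y-90 under the local
#' energy-deposition assumption: mean energy per nuclear transition times
#' the time-integrated decays per unit initial activity,
#' `factor = <E> * T_half / ln 2`, converted to Gy.kg/GBq. With
#' `<E> = 0.9267` MeV and `T_half = 64.04` h this evaluates to 49.38
#' Gy.kg/GBq (full precision is kept internally; 49.38 is the conventional
#' rounded display value).
#'
#' @param mean_energy_MeV mean beta energy per transition.
#' @param half_life_h physical half-life in hours.
#' @return list with the inputs and `dose_factor_Gy_kg_per_GBq`.
#' @export
dose_constants <- function(mean_energy_MeV = 0.9267, half_life_h = 64.04) {
  joule_per_MeV <- 1.602176634e-13
  decays_per_s_per_GBq <- 1e9
  factor <- mean_energy_MeV * joule_per_MeV * decays_per_s_per_GBq *
    (half_life_h * 3600) / log(2)
  list(mean_energy_MeV = mean_energy_MeV, half_life_h = half_life_h,
       dose_factor_Gy_kg_per_GBq = factor)
}

#' Mean absorbed dose of a single compartment
#'
#' `D = factor * A / m` for activity `A` (GBq) fully decaying in mass `m`
#' (kg).
#'
#' @param activity_GBq activity in GBq (>= 0).
#' @param mass_kg compartment mass in kg (> 0).
#' @param constants a [dose_constants()] list.
#' @return absorbed dose in Gy.
#' @export
dose_simple <- function(activity_GBq, mass_kg, constants = dose_constants()) {
  if (any(mass_kg <= 0)) stop("mass must be > 0", call. = FALSE)
  if (any(activity_GBq < 0)) stop("activity must be >= 0", call. = FALSE)
  constants$dose_factor_Gy_kg_per_GBq * activity_GBq / mass_kg
}

#' Classical partition-model doses
#'
#' The MIRD three-compartment model. With total activity `A0`, lung shunt
#' fraction `L` and tumor-to-normal ratio `TN`:
#' \deqn{D_L = k A_0 L / m_L}
#' \deqn{D_{NL} = k A_0 (1-L) / (m_{NL} + TN\, m_T)}
#' \deqn{D_T = TN \cdot D_{NL}}
#' with `k` the Y-90 dose factor (49.38 Gy.kg/GBq).
#'
#' @param A0_GBq total delivered activity.
#' @param L lung shunt fraction in `[0, 1]`.
#' @param TN tumor-to-normal concentration ratio (> 0).
#' @param m_lung_kg,m_nl_kg,m_tumor_kg compartment masses in kg.
#' @param constants a [dose_constants()] list.
#' @return list with `D_lung_Gy`, `D_nl_Gy`, `D_tumor_Gy`.
#' @export
pm_doses <- function(A0_GBq, L, TN, m_lung_kg, m_nl_kg, m_tumor_kg,
                     constants = dose_constants()) {
  if (L < 0 || L > 1) stop("lung shunt fraction must lie in [0, 1]", call. = FALSE)
  if (TN <= 0) stop("T/N must be > 0", call. = FALSE)
  if (any(c(m_lung_kg, m_nl_kg) <= 0) || m_tumor_kg < 0)
    stop("masses must be positive", call. = FALSE)
  k <- constants$dose_factor_Gy_kg_per_GBq
  d_nl <- k * A0_GBq * (1 - L) / (m_nl_kg + TN * m_tumor_kg)
  list(D_lung_Gy = k * A0_GBq * L / m_lung_kg,
       D_nl_Gy = d_nl,
       D_tumor_Gy = TN * d_nl)
}

#' Fractional uptake of each partition
#'
#' A partition's share of the total liver-side activity:
#' `f_i = A_i / sum_j A_j = 1 / (1 + A_{rest} / A_i)`. A partition with no
#' activity gets `f = 0` (the limit; no division is performed).
#'
#' @param activities non-negative activities (or counts, as activity
#'   surrogates) over the partition set.
#' @return vector of fractional uptakes summing to 1.
#' @export
fractional_uptake <- function(activities) {
  if (any(activities < 0)) stop("activities must be >= 0", call. = FALSE)
  total <- sum(activities)
  if (total <= 0) stop("total activity must be > 0", call. = FALSE)
  activities / total
}

#' Territorial-model doses for every partition
#'
#' The generalized partition dose: for each liver-side partition `i` in the
#' set `Sigma` (normal-liver territories, tumors, and any margin
#' partition),
#' \deqn{D_i = k A_0 (1-L) f_i / m_i}
#' with fractional uptake `f_i` estimated from the partition counts, and
#' the lung dose from the lung shunt fraction as in the classical model.
#' For `Sigma = {NL, T}` this reduces exactly to [pm_doses()].
#'
#' @param A0_GBq total delivered activity.
#' @param table a [partition_counts()] table.
#' @param L lung shunt fraction; computed from the table when `NULL`.
#' @param constants a [dose_constants()] list.
#' @return the table with `f`, `activity_GBq` and `dose_Gy` filled in.
#' @export
tm_doses <- function(A0_GBq, table, L = NULL, constants = dose_constants()) {
  if (is.null(L)) L <- lung_shunt_fraction(table)
  k <- constants$dose_factor_Gy_kg_per_GBq
  liver <- table$role %in% liver_side_roles
  if (sum(table$counts[liver]) <= 0)
    stop("no liver-side counts; fractional uptake undefined", call. = FALSE)
  f <- numeric(nrow(table))
  f[liver] <- fractional_uptake(table$counts[liver])
  if (any(liver & f > 0 & table$mass_kg <= 0))
    stop("a partition with counts has zero mass", call. = FALSE)

  table$f[liver] <- f[liver]
  table$activity_GBq[liver] <- A0_GBq * (1 - L) * f[liver]
  table$dose_Gy[liver] <- ifelse(f[liver] > 0,
                                 k * A0_GBq * (1 - L) * f[liver] / table$mass_kg[liver],
                                 0)
  lung <- table$role == "lung"
  table$f[lung] <- NA_real_
  table$activity_GBq[lung] <- A0_GBq * L
  table$dose_Gy[lung] <- if (any(table$mass_kg[lung] > 0))
    k * A0_GBq * L / sum(table$mass_kg[lung]) else NA_real_
  attr(table, "A0_GBq") <- A0_GBq
  attr(table, "L") <- L
  table
}

#' Mean normal-liver dose
#'
#' Aggregated over the normal-liver territories only (tumors and the
#' excluded margin contribute nothing). The default mass weighting makes
#' the mean equal to the pooled normal-liver dose
#' `k A0 (1-L) f_NL,total / m_NL,total`; an unweighted mean of the
#' territory doses is available for comparison.
#'
#' @param table a table with doses filled in by [tm_doses()].
#' @param weighted mass-weighted (default) or plain mean over territories.
#' @return mean normal-liver dose in Gy.
#' @export
mean_normal_liver_dose <- function(table, weighted = TRUE) {
  nl <- table[table$role == "normal_liver_territory" & !table$empty, ]
  if (nrow(nl) == 0) stop("no normal-liver territories", call. = FALSE)
  if (any(is.na(nl$dose_Gy))) stop("doses not yet computed", call. = FALSE)
  if (weighted) sum(nl$dose_Gy * nl$mass_kg) / sum(nl$mass_kg)
  else mean(nl$dose_Gy)
}

#' Piecewise-constant dose map
#'
#' Renders the per-partition doses back onto the voxel grid: every labeled
#' voxel takes its partition's dose, background stays 0, and the excluded
#' margin is painted with a sentinel value so it is distinguishable from
#' both background and any real dose.
#'
#' @param table a table with doses filled in (its `label_map` attribute
#'   supplies the partition geometry).
#' @param margin_sentinel value painted over the excluded margin
#'   (default -1).
#' @return numeric dose [as_volume()] in Gy.
#' @export
render_dose_map <- function(table, margin_sentinel = -1) {
  labels <- attr(table, "label_map")
  if (is.null(labels)) stop("table carries no label map", call. = FALSE)
  if (any(is.na(table$dose_Gy[!table$empty])))
    stop("doses not yet computed", call. = FALSE)
  lab <- vol_data(labels)
  dose_of <- numeric(max(table$partition))
  dose_of[table$partition] <- table$dose_Gy
  margin_ids <- table$partition[table$role == "excluded_margin"]
  dose_of[margin_ids] <- margin_sentinel
  out <- array(0, dim(lab))
  nz <- lab > 0L
  out[nz] <- dose_of[lab[nz]]
  as_volume(out, vol_spacing(labels))
}
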