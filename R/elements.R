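#' Supported micronutrient elements
#'
#' The five trace metals tracked by the model, in canonical order. Carbon is
#' the reference currency of all stoichiometric ratios and is never an element
#' of this set.
#'
#' @format Character vector of length 5: `"Fe"`, `"Zn"`, `"Cu"`, `"Co"`, `"Mn"`.
#' @export
MN_ELEMENTS <- c("Fe", "Zn", "Cu", "Co", "Mn")

#' Phytoplankton functional groups
#' @format Character vector: `"nano"`, `"diatom"`.
#' @export
MN_GROUPS <- c("nano", "diatom")

.mn_check_element <- function(element) {
  if (!is.character(element) || length(element) != 1L ||
      !(element %in% MN_ELEMENTS)) {
    stop("'element' must be one of: ", paste(MN_ELEMENTS, collapse = ", "),
         call. = FALSE)
  }
  element
}

#' Per-element stoichiometric parameters
#'
#' Builds the table of stoichiometric constants for the five micronutrients:
#' maximum phytoplankton quotas per group (Droop caps), the fixed zooplankton
#' quota, dissolved-uptake half-saturations, and the assimilation-efficiency
#' parameters. Defaults are the model's standard values: maximum
#' micronutrient:C quotas of 80e-6 (Fe), 40e-6/123e-6 (Zn in
#' nanophytoplankton/diatoms), 16e-6 (Cu), 1.2e-6 (Co) and 8e-6 (Mn), and
#' fixed zooplankton quotas of 10e-6 (Fe, Zn, Cu), 0.16e-6 (Co) and 1e-6 (Mn).
#' All quotas are absolute mol metal per mol C; concentrations are mol m^-3.
#'
#' @param overrides optional named list; each entry is itself a named list (or
#'   vector) of column values for one element, e.g.
#'   `list(Fe = list(q_max_nano = 60e-6))`.
#' @return A data.frame with one row per element and columns `element`,
#'   `q_max_nano`, `q_max_diatom`, `q_zoo`, `k_uptake`, `ae_max`, `ae_shape`.
#' @examples
#' element_params()
#' element_params(list(Mn = list(ae_shape = 2)))
#' @export
element_params <- function(overrides = NULL) {
  tab <- data.frame(
    element      = MN_ELEMENTS,
    q_max_nano   = c(80e-6, 40e-6, 16e-6, 1.2e-6, 8e-6),
    q_max_diatom = c(80e-6, 123e-6, 16e-6, 1.2e-6, 8e-6),
    q_zoo        = c(10e-6, 10e-6, 10e-6, 0.16e-6, 1e-6),
    k_uptake     = c(0.5e-6, 1e-6, 1e-6, 0.03e-6, 0.5e-6),
    ae_max       = rep(0.8, 5),
    ae_shape     = rep(2, 5),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$element
  if (!is.null(overrides)) {
    if (!is.list(overrides) || is.null(names(overrides))) {
      stop("'overrides' must be a named list keyed by element", call. = FALSE)
    }
    for (el in names(overrides)) {
      .mn_check_element(el)
      ov <- overrides[[el]]
      bad <- setdiff(names(ov), setdiff(names(tab), "element"))
      if (length(bad)) {
        stop("unknown element parameter(s) for ", el, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      for (nm in names(ov)) tab[el, nm] <- ov[[nm]]
    }
  }
  validate_element_params(tab)
  tab
}

#' @rdname element_params
#' @param tab an element-parameter table as returned by [element_params()].
#' @export
validate_element_params <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("element", "q_max_nano", "q_max_diatom", "q_zoo", "k_uptake",
            "ae_max", "ae_shape")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("element table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(tab$element, MN_ELEMENTS)) {
    stop("element table must have exactly the rows ",
         paste(MN_ELEMENTS, collapse = ", "), " in that order", call. = FALSE)
  }
  num <- tab[, setdiff(need, "element")]
  if (any(!vapply(num, is.numeric, logical(1)))) {
    stop("element parameter columns must be numeric", call. = FALSE)
  }
  # ae_shape may be 0 (assimilation efficiency flat in food quality)
  if (any(tab$q_max_nano <= 0) || any(tab$q_max_diatom <= 0) ||
      any(tab$q_zoo <= 0) || any(tab$k_uptake <= 0)) {
    stop("element quotas and half-saturations must be positive", call. = FALSE)
  }
  if (any(tab$ae_max <= 0) || any(tab$ae_max > 1)) {
    stop("ae_max must lie in (0, 1]", call. = FALSE)
  }
  if (any(tab$ae_shape < 0)) stop("ae_shape must be >= 0", call. = FALSE)
  invisible(tab)
}

#' Zooplankton food quality
#'
#' Food quality for a metal is the zooplankton micronutrient:C quota divided
#' by the micronutrient:C stoichiometry of the ingested prey. A value of 1
#' means zooplankton feed on stoichiometrically matched prey; values above 1
#' mean the zooplankton metal demand exceeds the prey content (metal-poor
#' diet), values below 1 a metal-rich diet.
#'
#' @param q_zoo zooplankton quota, mol metal per mol C (> 0).
#' @param mc_prey prey (diet) stoichiometry, mol metal per mol C (> 0).
#' @return Dimensionless food quality `q_zoo / mc_prey` (vectorized).
#' @examples
#' food_quality(10e-6, 40e-6)  # 0.25
#' @export
food_quality <- function(q_zoo, mc_prey) {
  if (any(!is.finite(q_zoo)) || any(q_zoo <= 0)) {
    stop("q_zoo must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(mc_prey)) || any(mc_prey <= 0)) {
    stop("mc_prey must be finite and > 0 (empty or metal-free prey field)",
         call. = FALSE)
  }
  q_zoo / mc_prey
}

#' Construct a prey pool
#'
#' A prey pool couples a carbon concentration with its metal content and the
#' grazer's preference for it. Prey are nanophytoplankton, diatoms or organic
#' particles.
#'
#' @param carbon mol C m^-3 (>= 0).
#' @param metal_content named numeric vector, mol metal m^-3 per element
#'   (>= 0); names must be a subset of [MN_ELEMENTS].
#' @param preference dimensionless grazing preference (>= 0).
#' @return A list of class `mn_prey_pool`.
#' @export
prey_pool <- function(carbon, metal_content, preference = 1) {
  stopifnot(is.numeric(carbon), length(carbon) == 1L, carbon >= 0,
            is.numeric(preference), length(preference) == 1L, preference >= 0)
  if (is.null(names(metal_content)) ||
      !all(names(metal_content) %in% MN_ELEMENTS)) {
    stop("metal_content must be named by elements in MN_ELEMENTS",
         call. = FALSE)
  }
  if (any(metal_content < 0)) stop("metal_content must be >= 0", call. = FALSE)
  structure(list(carbon = carbon, metal_content = metal_content,
                 preference = preference),
            class = "mn_prey_pool")
}

#' Preference-weighted prey quantity
#'
#' Prey quantity for a metal is the sum over prey types of the metal
#' concentration in each prey weighted by the grazer's preference for that
#' prey. It measures the metal available to the grazer through its diet.
#'
#' @param pools non-empty list of [prey_pool()] objects.
#' @param element one of [MN_ELEMENTS].
#' @return mol metal m^-3.
#' @examples
#' pools <- list(prey_pool(1e-3, c(Fe = 4e-6), 1.0),
#'               prey_pool(1e-3, c(Fe = 2e-6), 0.5))
#' prey_quantity(pools, "Fe")  # 5e-6
#' @export
prey_quantity <- function(pools, element) {
  .mn_check_element(element)
  if (!is.list(pools) || length(pools) == 0L) {
    stop("'pools' must be a non-empty list of prey pools", call. = FALSE)
  }
  contents <- vapply(pools, function(p) {
    stopifnot(inherits(p, "mn_prey_pool"))
    mc <- p$metal_content[element]
    if (is.na(mc)) 0 else unname(mc)
  }, numeric(1))
  prefs <- vapply(pools, function(p) p$preference, numeric(1))
  if (any(prefs < 0)) stop("preferences must be >= 0", call. = FALSE)
  sum(contents * prefs)
}

#' Bulk stoichiometry of the ingested diet
#'
#' The grazing-weighted mean metal:C quota across prey, i.e. the metal:C
#' ratio of the mixed diet actually ingested. Always bounded by the minimum
#' and maximum prey quota.
#'
#' @param grazing_c per-prey carbon grazing fluxes, mol C m^-3 d^-1 (>= 0,
#'   positive total).
#' @param prey_quotas per-prey metal:C quotas, mol:mol.
#' @return mol metal per mol C.
#' @examples
#' ingested_stoichiometry(c(3, 1), c(10e-6, 50e-6))  # 20e-6
#' @export
ingested_stoichiometry <- function(grazing_c, prey_quotas) {
  stopifnot(length(grazing_c) == length(prey_quotas))
  if (any(grazing_c < 0)) stop("grazing fluxes must be >= 0", call. = FALSE)
  tot <- sum(grazing_c)
  if (!is.finite(tot) || tot <= 0) {
    stop("total grazing must be > 0 (no diet defined)", call. = FALSE)
  }
  sum(grazing_c * prey_quotas) / tot
}

#' Food-quality dependent assimilation efficiency
#'
#' Assimilation efficiency is maximal (`ae_max`) for a stoichiometrically
#' balanced diet (food quality 1) and declines symmetrically as food quality
#' moves away from 1 in either direction:
#' `AE = ae_max * min(fq, 1/fq)^ae_shape`. The decline is symmetric under
#' `fq -> 1/fq` (i.e. in `|log fq|`), and `ae_shape = 0` makes AE independent
#' of food quality. The default `ae_shape = 2` makes the decline steep enough
#' that the AE limit on metal assimilation stays active on both sides of
#' `fq = 1` once the fixed-quota demand cap of [zoo_budget()] is applied (see
#' the methods vignette).
#'
#' @param fq dimensionless food quality (> 0, vectorized).
#' @param ae_max maximum assimilation efficiency in (0, 1].
#' @param ae_shape dimensionless exponent >= 0 controlling the steepness of
#'   the decline.
#' @return Dimensionless assimilation efficiency in (0, ae_max].
#' @examples
#' assimilation_efficiency(2, ae_max = 0.8, ae_shape = 1)    # 0.4
#' assimilation_efficiency(0.5, ae_max = 0.8, ae_shape = 1)  # 0.4
#' @export
assimilation_efficiency <- function(fq, ae_max = 0.8, ae_shape = 2) {
  if (any(!is.finite(fq)) || any(fq <= 0)) {
    stop("fq must be finite and > 0", call. = FALSE)
  }
  stopifnot(ae_max > 0, ae_max <= 1, ae_shape >= 0)
  ae_max * pmin(fq, 1 / fq)^ae_shape
}

#' Recycling stoichiometry
#'
#' Metal:C ratio of the recycled (dissolved excretion) flux. When the carbon
#' recycling flux is zero the ratio is undefined; a `NaN` sentinel is returned
#' (not an error) so that time series keep their alignment.
#'
#' @param flux_metal metal recycling flux, mol m^-3 d^-1 (>= 0, vectorized).
#' @param flux_c carbon recycling flux, mol m^-3 d^-1 (>= 0).
#' @return mol metal per mol C; `NaN` where `flux_c == 0`.
#' @export
recycling_stoichiometry <- function(flux_metal, flux_c) {
  if (any(flux_metal < 0, na.rm = TRUE)) {
    stop("flux_metal must be >= 0", call. = FALSE)
  }
  if (any(flux_c < 0, na.rm = TRUE)) stop("flux_c must be >= 0", call. = FALSE)
  out <- flux_metal / flux_c
  out[flux_c == 0] <- NaN
  out
}
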