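#' Driver columns of an attribution panel
#'
#' The four regressors of the recycling models: food quality (`fq`), prey
#' quantity (`prey_q`), sea surface temperature (`sst`) and zooplankton
#' biomass (`zoo_b`).
#' @export
MN_PREDICTORS <- c("fq", "prey_q", "sst", "zoo_b")

.check_panel <- function(panel, response = "response",
                         predictors = MN_PREDICTORS) {
  stopifnot(is.data.frame(panel))
  miss <- setdiff(c(response, predictors), names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- panel[, c(response, predictors)]
  if (any(!vapply(cols, is.numeric, logical(1)))) {
    stop("fitted columns must be numeric", call. = FALSE)
  }
  if (anyNA(cols)) {
    stop("fitted columns must not contain missing values", call. = FALSE)
  }
  if (nrow(panel) < length(predictors) + 2) {
    stop("panel needs at least p + 2 rows per fitted group", call. = FALSE)
  }
  invisible(panel)
}

#' Standardize the fitted columns of a panel
#'
#' Centers and scales (sd with denominator n - 1) the response and predictor
#' columns. Importance shares are invariant to this affine rescaling; the
#' transform mainly stabilizes coefficient magnitudes. The transform record
#' is attached as attribute `"transform"` and the operation is idempotent.
#'
#' @param panel a driver panel data.frame.
#' @param response name of the response column.
#' @param predictors names of the predictor columns.
#' @return The panel with standardized columns.
#' @export
standardize <- function(panel, response = "response",
                        predictors = MN_PREDICTORS) {
  .check_panel(panel, response, predictors)
  cols <- c(response, predictors)
  center <- vapply(panel[cols], mean, numeric(1))
  scale <- vapply(panel[cols], stats::sd, numeric(1))
  zero <- names(scale)[scale == 0 | !is.finite(scale)]
  if (length(zero)) {
    stop("zero-variance column: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  for (cl in cols) panel[[cl]] <- (panel[[cl]] - center[[cl]]) / scale[[cl]]
  attr(panel, "transform") <- list(center = center, scale = scale)
  panel
}

#' Ordinary least-squares fit of the recycling model
#'
#' Fits the linear Gaussian model
#' `response = alpha * fq + beta * prey_q + gamma * sst + delta * zoo_b +
#' intercept + error` by ordinary least squares (identity link). The error
#' variance estimate and the coefficient of determination are returned; a
#' large error term signals drivers omitted from the model.
#'
#' @inheritParams standardize
#' @return List of class `mn_glm_fit` with `coefficients` (named by
#'   predictor), `intercept`, `sigma2` (residual variance), `std_errors`,
#'   `r_squared` and `n`.
#' @export
fit_glm <- function(panel, response = "response",
                    predictors = MN_PREDICTORS) {
  .check_panel(panel, response, predictors)
  X <- as.matrix(panel[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
    stop("rank-deficient design; collinear predictor(s): ",
         paste(predictors[dropped[dropped > 0]], collapse = ", "),
         call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = panel)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  structure(list(coefficients = cf[predictors],
                 intercept = unname(cf[1]),
                 sigma2 = sm$sigma^2,
                 std_errors = sm$coefficients[predictors, "Std. Error"],
                 r_squared = sm$r.squared,
                 n = nrow(panel),
                 response = response, predictors = predictors),
            class = "mn_glm_fit")
}

#' @export
print.mn_glm_fit <- function(x, ...) {
  cat("<mn_glm_fit> n =", x$n, " R^2 =", signif(x$r_squared, 4), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

# R^2 of the regression of y (last row/col of C) on the predictor subset
.r2_from_cov <- function(C, subset) {
  p <- ncol(C) - 1L
  if (length(subset) == 0L) return(0)
  syy <- C[p + 1L, p + 1L]
  Sxx <- C[subset, subset, drop = FALSE]
  sxy <- C[subset, p + 1L]
  as.numeric(crossprod(sxy, solve(Sxx, sxy))) / syy
}

# all-subset R^2 values indexed by bitmask + 1
.r2_all_subsets <- function(C) {
  p <- ncol(C) - 1L
  r2 <- numeric(2^p)
  for (m in 0:(2^p - 1L)) {
    r2[m + 1L] <- .r2_from_cov(C, which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) > 0L))
  }
  r2
}

# LMG by the subset-weighted formula:
# share_j = sum over subsets S of the other predictors of
#   w(|S|) * (R^2(S + j) - R^2(S)),  w(k) = k! (p-1-k)! / p!
.lmg_from_cov <- function(C) {
  p <- ncol(C) - 1L
  r2 <- .r2_all_subsets(C)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (m in 0:(2^p - 1L)) {
      if (bitwAnd(m, bit_j) > 0L) next
      k <- sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) > 0L)
      w <- factorial(k) * factorial(p - 1L - k) / factorial(p)
      shares[j] <- shares[j] + w * (r2[m + bit_j + 1L] - r2[m + 1L])
    }
  }
  list(shares = shares, r_squared = r2[2^p])
}

# LMG by explicit enumeration of all p! predictor orderings
.lmg_brute_from_cov <- function(C) {
  p <- ncol(C) - 1L
  if (p > 6L) stop("brute-force enumeration limited to p <= 6", call. = FALSE)
  r2 <- .r2_all_subsets(C)
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]), deparse.level = 0)
    }))
  }
  orderings <- perms(seq_len(p))
  shares <- numeric(p)
  for (r in seq_len(nrow(orderings))) {
    mask <- 0L
    for (pos in seq_len(p)) {
      j <- orderings[r, pos]
      newmask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
      shares[j] <- shares[j] + (r2[newmask + 1L] - r2[mask + 1L])
      mask <- newmask
    }
  }
  list(shares = shares / nrow(orderings), r_squared = r2[2^p])
}

.panel_cov <- function(panel, response, predictors) {
  X <- as.matrix(panel[, c(predictors, response)])
  C <- stats::cov(X)
  v <- diag(C)
  if (any(v == 0 | !is.finite(v))) {
    stop("zero-variance column: ",
         paste(colnames(C)[v == 0 | !is.finite(v)], collapse = ", "),
         call. = FALSE)
  }
  C
}

.importance <- function(res, predictors, n) {
  structure(list(shares = stats::setNames(res$shares, predictors),
                 r_squared = res$r_squared, n = n),
            class = "mn_importance")
}

#' LMG relative-importance shares
#'
#' Decomposes the model R-squared into non-negative per-driver shares by
#' averaging each predictor's sequential contribution to R-squared over all
#' orderings in which it can enter the model (the LMG metric), computed via
#' the equivalent subset-weighted formula. Shares sum exactly to the full
#' model R-squared, i.e. they are fractions of total response variance.
#'
#' @inheritParams standardize
#' @return List of class `mn_importance`: `shares` (named, summing to
#'   `r_squared`), `r_squared`, `n`.
#' @seealso [lmg_shares_bruteforce()] for the enumeration oracle.
#' @export
lmg_shares <- function(panel, response = "response",
                       predictors = MN_PREDICTORS) {
  .check_panel(panel, response, predictors)
  C <- .panel_cov(panel, response, predictors)
  .importance(.lmg_from_cov(C), predictors, nrow(panel))
}

#' LMG shares by explicit enumeration of orderings
#'
#' Independent oracle for [lmg_shares()]: averages sequential R-squared
#' increments over all `p!` predictor orderings explicitly (24 orderings for
#' the four standard drivers). Limited to `p <= 6`.
#'
#' @inheritParams standardize
#' @return Same structure as [lmg_shares()].
#' @export
lmg_shares_bruteforce <- function(panel, response = "response",
                                  predictors = MN_PREDICTORS) {
  .check_panel(panel, response, predictors)
  C <- .panel_cov(panel, response, predictors)
  .importance(.lmg_brute_from_cov(C), predictors, nrow(panel))
}

#' @export
print.mn_importance <- function(x, ...) {
  cat("<mn_importance> R^2 =", signif(x$r_squared, 4), "\n")
  print(signif(x$shares, 4))
  invisible(x)
}

#' Classify driver dominance and build ternary coordinates
#'
#' Renormalizes the three biotic shares (food quality, prey quantity,
#' zooplankton biomass) to sum to one - the ternary coordinates - while the
#' temperature share is kept separate as an absolute fraction of response
#' variance. A group is `included` in ternary output only when the model
#' explains more than `threshold` (default 50%) of the response variance.
#' The dominant driver is the largest biotic coordinate; exact ties are
#' broken in the fixed order quality > quantity > biomass and flagged.
#'
#' @param shares an `mn_importance` from [lmg_shares()].
#' @param threshold minimum R-squared for inclusion (fraction, default 0.5).
#' @return List of class `mn_ternary_point` with `qual`, `quant`, `zoo`
#'   (summing to 1), `sst_share`, `r_squared`, `included`, `dominant`,
#'   `tie`.
#' @export
classify_dominance <- function(shares, threshold = 0.5) {
  stopifnot(inherits(shares, "mn_importance"),
            threshold >= 0, threshold <= 1)
  s <- shares$shares
  biotic <- c(qual = unname(s[["fq"]]), quant = unname(s[["prey_q"]]),
              zoo = unname(s[["zoo_b"]]))
  tot <- sum(biotic)
  if (tot <= 0) {
    return(structure(list(qual = NA_real_, quant = NA_real_, zoo = NA_real_,
                          sst_share = unname(s[["sst"]]),
                          r_squared = shares$r_squared, included = FALSE,
                          dominant = NA_character_, tie = FALSE),
                     class = "mn_ternary_point"))
  }
  coords <- biotic / tot
  dominant <- names(coords)[which.max(coords)]
  tie <- sum(coords == max(coords)) > 1L
  structure(list(qual = coords[["qual"]], quant = coords[["quant"]],
                 zoo = coords[["zoo"]], sst_share = unname(s[["sst"]]),
                 r_squared = shares$r_squared,
                 included = shares$r_squared > threshold,
                 dominant = dominant, tie = tie),
            class = "mn_ternary_point")
}

#' Planar embedding of ternary coordinates
#'
#' Standard equilateral-triangle embedding with the quality corner at
#' `(0, 0)`, the quantity corner at `(1, 0)` and the biomass apex at
#' `(0.5, sqrt(3)/2)`:
#' `x = (2 * quant + zoo) / (2 * (qual + quant + zoo))`,
#' `y = sqrt(3)/2 * zoo / (qual + quant + zoo)`.
#'
#' @param point an `mn_ternary_point`, or a numeric triple
#'   `(qual, quant, zoo)`.
#' @return Named numeric `c(x, y)`.
#' @export
ternary_coordinates <- function(point) {
  if (inherits(point, "mn_ternary_point")) {
    abc <- c(point$qual, point$quant, point$zoo)
  } else {
    stopifnot(is.numeric(point), length(point) == 3)
    abc <- as.numeric(point)
  }
  tot <- sum(abc)
  c(x = 0.5 * (2 * abc[2] + abc[3]) / tot,
    y = sqrt(3) / 2 * abc[3] / tot)
}

#' Grouped attribution pipeline
#'
#' Runs the fit / importance / dominance pipeline independently for each
#' group of the panel (by default region x element x response kind x
#' period, using whichever of those columns are present). Groups whose fit
#' fails (e.g. a zero-variance column in a degenerate region) are reported
#' with their failure reason, never silently dropped; groups with R-squared
#' at or below the threshold are retained in the table but flagged
#' `included = FALSE`.
#'
#' @inheritParams standardize
#' @param by grouping columns (present ones are used).
#' @param threshold R-squared inclusion threshold for the ternary output.
#' @return data.frame with one row per group: grouping keys, `n`, `status`
#'   (`"ok"` or the error message), `r_squared`, coefficients, shares,
#'   ternary coordinates (`qual`, `quant`, `zoo`, `x`, `y`), `sst_share`,
#'   `dominant`, `tie`, `included`. The full fit objects are attached as
#'   attribute `"fits"`.
#' @export
attribute_by_group <- function(panel, by = c("region", "element",
                                             "response_kind", "period"),
                               response = "response",
                               predictors = MN_PREDICTORS,
                               threshold = 0.5) {
  by <- intersect(by, names(panel))
  if (length(by) == 0L) {
    panel$.group <- "all"
    by <- ".group"
  }
  keys <- unique(panel[, by, drop = FALSE])
  rownames(keys) <- NULL
  fits <- vector("list", nrow(keys))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(panel))
    for (cl in by) sel <- sel & panel[[cl]] == keys[i, cl]
    sub <- panel[sel, , drop = FALSE]
    base <- keys[i, , drop = FALSE]
    base$n <- nrow(sub)
    row <- tryCatch({
      sub_s <- standardize(sub, response, predictors)
      fit <- fit_glm(sub_s, response, predictors)
      imp <- lmg_shares(sub_s, response, predictors)
      pt <- classify_dominance(imp, threshold)
      xy <- if (is.na(pt$qual)) c(x = NA_real_, y = NA_real_) else
        ternary_coordinates(pt)
      fits[[i]] <- list(fit = fit, importance = imp, point = pt)
      cbind(base, data.frame(
        status = "ok", r_squared = fit$r_squared,
        alpha = unname(fit$coefficients[["fq"]]),
        beta = unname(fit$coefficients[["prey_q"]]),
        gamma = unname(fit$coefficients[["sst"]]),
        delta = unname(fit$coefficients[["zoo_b"]]),
        share_fq = unname(imp$shares[["fq"]]),
        share_prey_q = unname(imp$shares[["prey_q"]]),
        share_sst = unname(imp$shares[["sst"]]),
        share_zoo_b = unname(imp$shares[["zoo_b"]]),
        qual = pt$qual, quant = pt$quant, zoo = pt$zoo,
        x = unname(xy["x"]), y = unname(xy["y"]),
        sst_share = pt$sst_share, dominant = pt$dominant, tie = pt$tie,
        included = pt$included, stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base, data.frame(
        status = conditionMessage(e), r_squared = NA_real_,
        alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
        delta = NA_real_, share_fq = NA_real_, share_prey_q = NA_real_,
        share_sst = NA_real_, share_zoo_b = NA_real_, qual = NA_real_,
        quant = NA_real_, zoo = NA_real_, x = NA_real_, y = NA_real_,
        sst_share = NA_real_, dominant = NA_character_, tie = NA,
        included = FALSE, stringsAsFactors = FALSE))
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
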