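# Isolation by distance / environment: Haversine geographic distances,
# elevational distances, and multiple regression on distance matrices (MRM)
# with matrix-permutation inference.

#' Great-circle (Haversine) distance
#'
#' Uses the mean Earth radius R = 6371.0 km. Vectorised.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Site-by-site geographic and elevational distance matrices
#'
#' @param samples Metadata tibble; site coordinates are taken from the first
#'   row per site (they must be constant within a site).
#' @return List with `geo_km` and `elev_m`, symmetric site-labelled matrices.
#' @export
pairwise_distance_matrices <- function(samples) {
  sites <- dplyr::distinct(tibble::as_tibble(samples), .data$site_id,
                           .data$latitude, .data$longitude, .data$elevation_m)
  if (anyDuplicated(sites$site_id) > 0L) {
    stop("a site has more than one set of coordinates")
  }
  sites <- dplyr::arrange(sites, .data$site_id)
  k <- nrow(sites)
  geo <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(k)) {
    geo[i, ] <- haversine_km(sites$latitude[i], sites$longitude[i],
                             sites$latitude, sites$longitude)
  }
  elev <- abs(outer(sites$elevation_m, sites$elevation_m, "-"))
  dimnames(elev) <- dimnames(geo)
  list(geo_km = geo, elev_m = elev)
}

unfold_lower <- function(m) m[lower.tri(m)]

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded lower triangle of the response
#' distance matrix on the unfolded predictors, with significance from jointly
#' permuting rows and columns of the response matrix (Mantel-type inference:
#' labels are permuted, never individual pairs). The overall p compares
#' permuted to observed R-squared; per-coefficient p-values are two-sided
#' (absolute-value comparison). The observed statistic is included in the
#' null set.
#'
#' @param response Symmetric distance matrix (shared labels with predictors).
#' @param predictors Named list of symmetric predictor matrices.
#' @param n_perm Number of matrix permutations.
#' @param seed Integer seed.
#' @return One-row tibble of class `mrm_result` with intercept, one
#'   coefficient and p per predictor, `r2`, `p_overall`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999L, seed = 1L) {
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  k <- nrow(response)
  stopifnot(k >= 4L, all(vapply(predictors, nrow, integer(1)) == k))
  lab <- rownames(response)
  if (!is.null(lab)) {
    for (pm in predictors) {
      if (!identical(rownames(pm), lab)) stop("matrix labels do not match")
    }
  }
  X <- cbind(intercept = 1,
             do.call(cbind, lapply(predictors, unfold_lower)))
  if (kappa(X, exact = TRUE) > 1e10) stop("collinear predictors")
  y <- unfold_lower(response)
  xtx_inv <- solve(crossprod(X))
  hat <- xtx_inv %*% t(X)
  fit_stats <- function(y) {
    b <- hat %*% y
    res <- y - X %*% b
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    list(b = as.vector(b), r2 = r2)
  }
  obs <- fit_stats(y)
  set.seed(seed)
  exceed_r2 <- 0L
  exceed_b <- rep(0L, length(obs$b) - 1L)
  for (it in seq_len(n_perm)) {
    perm <- sample.int(k)
    yp <- unfold_lower(response[perm, perm])
    st <- fit_stats(yp)
    if (st$r2 >= obs$r2) exceed_r2 <- exceed_r2 + 1L
    exceed_b <- exceed_b + (abs(st$b[-1]) >= abs(obs$b[-1]))
  }
  coefs <- setNames(obs$b, c("intercept", names(predictors)))
  out <- tibble::tibble(
    term = names(coefs),
    estimate = unname(coefs),
    p = c(NA_real_, (1 + exceed_b) / (1 + n_perm)))
  out <- tidyr::pivot_wider(
    dplyr::mutate(out, dummy = 1), names_from = "term",
    values_from = c("estimate", "p"), id_cols = "dummy")
  out$dummy <- NULL
  out$r2 <- obs$r2
  out$p_overall <- (1 + exceed_r2) / (1 + n_perm)
  out$n_perm <- as.integer(n_perm)
  attr(out, "coefficients") <- coefs
  class(out) <- c("mrm_result", class(out))
  out
}

#' Tidy an MRM result
#'
#' @param x An `mrm_result`.
#' @param ... Unused.
#' @return Tibble with one row per term (`estimate`, two-sided permutation
#'   `p`; intercept has no p).
#' @export
tidy.mrm_result <- function(x, ...) {
  coefs <- attr(x, "coefficients")
  pcols <- x[paste0("p_", names(coefs)[-1])]
  tibble::tibble(term = names(coefs), estimate = unname(coefs),
                 p = c(NA_real_, unname(unlist(pcols[1, ]))))
}

#' One-row MRM summary
#'
#' @param x An `mrm_result`.
#' @param ... Unused.
#' @return Tibble with `r2`, `p_overall`, `n_perm`.
#' @export
glance.mrm_result <- function(x, ...) {
  tibble::tibble(r2 = x$r2, p_overall = x$p_overall, n_perm = x$n_perm)
}

#' Isolation by distance / elevation for a fitted dataset
#'
#' Convenience wrapper: builds the geographic and elevational site distance
#' matrices and regresses the chosen genetic distance (Nei's D by default,
#' optionally genome-wide F_ST) on them — together (MRM) and separately
#' (single-predictor Mantel regressions).
#'
#' @param gm A `genotype_fit`.
#' @param samples Metadata tibble.
#' @param response `"nei"` or `"fst"`.
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return List with `mrm` (two-predictor fit), `mantel_geo`, `mantel_elev`.
#' @export
ibd_regression <- function(gm, samples, response = c("nei", "fst"),
                           n_perm = 999L, seed = 1L) {
  response <- match.arg(response)
  dm <- pairwise_distance_matrices(samples)
  gen <- genetic_distance_matrix(gm, samples, kind = response)
  gen <- gen[rownames(dm$geo_km), rownames(dm$geo_km)]
  list(
    mrm = mrm(gen, list(geo_km = dm$geo_km, elev_m = dm$elev_m),
              n_perm = n_perm, seed = seed),
    mantel_geo = mrm(gen, list(geo_km = dm$geo_km),
                     n_perm = n_perm, seed = seed + 1L),
    mantel_elev = mrm(gen, list(elev_m = dm$elev_m),
                      n_perm = n_perm, seed = seed + 2L))
}
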