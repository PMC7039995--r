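# Diversity-vs-geography analysis: waypoint-constrained great-circle
# distances from an East African origin, logit-transformed PIC response,
# two-predictor ordinary least squares with confidence intervals, a
# +/- 2 SD outlier exclusion rule, and Bonferroni correction across the
# family of fitted models.

#' Construct a geographic point
#' @param name Point name.
#' @param lat,lon Latitude and longitude in decimal degrees.
#' @return A list of class `geo_point`.
#' @export
geo_point <- function(name, lat, lon) {
  if (abs(lat) > 90 || abs(lon) > 180) {
    stop("invalid coordinates for ", name, ": lat must be in [-90, 90], ",
         "lon in [-180, 180]", call. = FALSE)
  }
  structure(list(name = name, lat = lat, lon = lon), class = "geo_point")
}

#' Great-circle (haversine) distance in km
#' @param a,b `geo_point` objects.
#' @param radius_km Mean Earth radius (default 6371 km).
#' @return Distance in km.
#' @export
haversine_km <- function(a, b, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (b$lat - a$lat) * to_rad
  dlon <- (b$lon - a$lon) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a$lat * to_rad) * cos(b$lat * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(h)))
}

#' Default migration waypoints by destination continent
#'
#' Human-migration distance models route the path from East Africa
#' through a small set of fixed waypoints rather than the direct geodesic.
#' The exact five points used by prior compilations are not published;
#' these defaults follow their intent -- an Africa exit (Cairo), an
#' Anatolian land bridge (Istanbul), a Beringian crossing (Anadyr), and
#' two American relays (Anchorage; Panama City) -- and are explicitly
#' replaceable via the `waypoints` argument of [waypoint_distance()].
#'
#' @return Named list of continent -> list of `geo_point` routes.
#' @export
default_waypoints <- function() {
  cairo <- geo_point("Cairo", 30.06, 31.25)
  istanbul <- geo_point("Istanbul", 41.01, 28.98)
  anadyr <- geo_point("Anadyr", 64.73, 177.51)
  anchorage <- geo_point("Anchorage", 61.22, -149.90)
  panama <- geo_point("PanamaCity", 8.98, -79.52)
  list(
    Africa = list(),
    Europe = list(cairo, istanbul),
    Asia = list(cairo, istanbul),
    Oceania = list(cairo, istanbul),
    NorthAmerica = list(cairo, istanbul, anadyr, anchorage),
    SouthAmerica = list(cairo, istanbul, anadyr, anchorage, panama)
  )
}

#' Waypoint-constrained distance from an origin to a destination
#'
#' Sum of great-circle legs `origin -> waypoint_1 -> ... -> destination`.
#' With an empty waypoint list this is the direct geodesic. Routes per
#' destination continent are available from [default_waypoints()].
#'
#' @param origin,dest `geo_point` objects.
#' @param waypoints Ordered list of `geo_point` objects (possibly empty).
#' @return Distance in km.
#' @examples
#' addis <- geo_point("AddisAbaba", 9.03, 38.74)
#' waypoint_distance(addis, addis)  # 0
#' @export
waypoint_distance <- function(origin, dest, waypoints = list()) {
  pts <- c(list(origin), waypoints, list(dest))
  sum(vapply(seq_len(length(pts) - 1L), function(i) {
    haversine_km(pts[[i]], pts[[i + 1L]])
  }, numeric(1L)))
}

#' Logit transform and its inverse
#'
#' `logit(p) = log(p / (1 - p))` for `p` strictly inside (0, 1); the
#' inverse round-trips to 1e-12.
#'
#' @param p Probability-scale value(s) in (0, 1).
#' @return Logit-scale value(s).
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("logit is defined on (0, 1) only", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @param eta Logit-scale value(s).
#' @export
inv_logit <- function(eta) 1 / (1 + exp(-eta))

#' Outlier exclusion on logit(PIC) values
#'
#' A population is excluded when its logit(PIC) at ANY of the supplied
#' loci lies beyond `mean +/- k * SD` for that locus. Single pass: means
#' and SDs are computed once on the full data and the rule is not
#' re-iterated after exclusion.
#'
#' @param logit_pic Numeric matrix or data.frame: populations x loci of
#'   logit-transformed PIC values (>= 3 rows).
#' @param k SD multiplier (default 2).
#' @return List: `kept`, `excluded` (integer row indices).
#' @export
exclude_outliers <- function(logit_pic, k = 2) {
  m <- as.matrix(logit_pic)
  if (nrow(m) < 3L) stop("need >= 3 populations", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  out <- rep(FALSE, nrow(m))
  for (j in seq_len(ncol(m))) {
    if (sdv[j] > 0) {
      out <- out | abs(m[, j] - mu[j]) > k * sdv[j]
    }
  }
  list(kept = which(!out), excluded = which(out))
}

#' Ordinary-least-squares fit with confidence intervals
#'
#' Fits `response ~ predictors` by OLS (through `stats::lm`), returning
#' coefficient estimates, t-based 95% confidence intervals, two-sided
#' p-values, and R^2. Bonferroni-adjusted p-values across a family of
#' models are added by [bonferroni_family()].
#'
#' @param table `data.frame` holding the variables.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return List of class `glm_fit`: `response`, `predictors`,
#'   `coefficients` (`data.frame`: `term`, `estimate`, `ci_lower`,
#'   `ci_upper`, `p_value`), `r_squared`, `n`.
#' @export
fit_glm <- function(table, response, predictors) {
  n <- nrow(table)
  if (n <= length(predictors) + 1L) {
    stop("need more observations than predictors + 1", call. = FALSE)
  }
  X <- as.matrix(table[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1L) {
    # name the offending columns: those whose removal restores full rank
    bad <- predictors[vapply(seq_along(predictors), function(j) {
      qr(cbind(1, X[, -j, drop = FALSE]))$rank == ncol(X)
    }, logical(1L))]
    stop("collinear design; offending column(s): ",
         paste(if (length(bad)) bad else predictors, collapse = ", "),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = table)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1L],
                      ci_lower = ci[, 1L], ci_upper = ci[, 2L],
                      p_value = sm$coefficients[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(response = response, predictors = predictors,
                 coefficients = coefs, r_squared = sm$r.squared, n = n),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("OLS fit: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "),
      "  (n = ", x$n, ", R^2 = ", round(x$r_squared, 4), ")\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Bonferroni correction across a family of fitted models
#'
#' The family size is the number of models fitted in a run (locus x
#' predictor-set x dataset); each model's raw p-values are multiplied by
#' the family size and capped at 1, reported alongside the raw values.
#'
#' @param fits List of `glm_fit` objects.
#' @return The list with a `p_bonferroni` column added to each fit's
#'   coefficient table and a `family_size` attribute.
#' @export
bonferroni_family <- function(fits) {
  m <- length(fits)
  fits <- lapply(fits, function(f) {
    f$coefficients$p_bonferroni <- pmin(1, f$coefficients$p_value * m)
    f
  })
  attr(fits, "family_size") <- m
  fits
}

#' Diversity-vs-geography/pathogen regression over a population table
#'
#' The end-to-end analysis: logit-transform the per-locus PIC columns,
#' optionally exclude populations whose logit(PIC) is beyond 2 SD at any
#' locus, fit `logit(PIC) ~ distance + richness` per locus and richness
#' measure, and Bonferroni-correct across the fitted family.
#'
#' @param table `data.frame` with columns `distance_km`,
#'   `pathogen_richness`, `viral_richness` and `PIC_<locus>` per locus.
#' @param loci Loci to analyze (default A, B, DRB1).
#' @param richness Richness columns to pair with distance.
#' @param exclude Apply the outlier rule first (default TRUE).
#' @return List of `glm_fit` objects (named `<locus>.<richness>`), with
#'   Bonferroni-adjusted p-values and attributes `excluded` (row indices)
#'   and `family_size`.
#' @export
geo_glm_analysis <- function(table, loci = c("A", "B", "DRB1"),
                             richness = c("pathogen_richness",
                                          "viral_richness"),
                             exclude = TRUE) {
  pic_cols <- paste0("PIC_", loci)
  lp <- as.data.frame(lapply(table[pic_cols], logit))
  names(lp) <- paste0("logit_", pic_cols)
  excluded <- integer()
  if (exclude) {
    part <- exclude_outliers(lp)
    excluded <- part$excluded
    keep <- part$kept
  } else {
    keep <- seq_len(nrow(table))
  }
  dat <- cbind(table[keep, , drop = FALSE], lp[keep, , drop = FALSE])
  fits <- list()
  for (loc in loci) {
    for (rich in richness) {
      fits[[paste(loc, rich, sep = ".")]] <-
        fit_glm(dat, paste0("logit_PIC_", loc),
                c("distance_km", rich))
    }
  }
  fits <- bonferroni_family(fits)
  attr(fits, "excluded") <- excluded
  fits
}
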