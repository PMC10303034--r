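# Reduction of voxel deposits to central-axis depth-dose curves and the
# dose enhancement ratio (DER).

#' Central-axis depth-dose curve from a dose grid
#'
#' Per depth bin, dose per history = (summed deposits in voxels whose
#' lateral centers lie within `scoring_radius` of the beam axis) /
#' (mass of those voxels) / n_histories. The spread over statistical
#' batches gives the standard error.
#'
#' @param grid A `dose_grid` from [simulate_run()].
#' @param scoring_radius Radius (cm) of the central-axis scoring region;
#'   must not exceed the field radius.
#' @return A `depth_dose_curve` data frame with columns `depth_cm`,
#'   `dose_per_history` (keV/g), `rel_se`.
#' @export
depth_dose <- function(grid, scoring_radius = 0.5) {
  stopifnot(inherits(grid, "dose_grid"))
  if (scoring_radius > grid$source$field_diameter_cm / 2)
    stop("scoring_radius exceeds the field radius", call. = FALSE)
  ex <- grid$edges$x; ey <- grid$edges$y; ez <- grid$edges$z
  cx <- (ex[-1] + ex[-length(ex)]) / 2
  cy <- (ey[-1] + ey[-length(ey)]) / 2
  cz <- (ez[-1] + ez[-length(ez)]) / 2
  inside <- outer(cx^2, cy^2, "+") <= scoring_radius^2
  if (!any(inside))
    stop("no voxel centers inside scoring_radius; enlarge it", call. = FALSE)
  vol <- prod(grid$geometry$voxel_cm)
  mass <- sum(inside) * vol * grid$material$density    # g per depth bin
  nb <- grid$config$n_batches
  per_hist_b <- grid$config$n_histories / nb
  # batch x depth matrix of dose per history
  dmat <- vapply(seq_len(nb), function(b) {
    sl <- grid$deposit[, , , b, drop = FALSE]
    vapply(seq_along(cz), function(k)
      sum(sl[, , k, 1][inside]), numeric(1)) / mass / per_hist_b
  }, numeric(length(cz)))
  dose <- rowMeans(dmat)
  se <- apply(dmat, 1, stats::sd) / sqrt(nb)
  out <- data.frame(depth_cm = cz, dose_per_history = dose,
                    rel_se = ifelse(dose > 0, se / dose, 0))
  class(out) <- c("depth_dose_curve", "data.frame")
  attr(out, "material") <- grid$material$name
  attr(out, "kvp") <- grid$kvp
  attr(out, "n_histories") <- grid$config$n_histories
  out
}

#' Dose enhancement ratio versus depth
#'
#' DER(d) = dose with nanoparticles / dose in plain water at the same
#' depth. Relative uncertainties of the two curves are combined in
#' quadrature. Depth bins with zero water dose are flagged undefined
#' (NA with a reason code), never silently dropped.
#'
#' @param curve_np `depth_dose_curve` for the nanoparticle-loaded
#'   phantom.
#' @param curve_water `depth_dose_curve` for the matching water
#'   baseline (identical depth binning).
#' @param material,concentration,kvp Optional metadata stored on the
#'   result.
#' @return A `der_curve` data frame with columns `depth_cm`, `der`,
#'   `rel_unc`, `status` ("ok" or "zero_water_dose").
#' @export
compute_der <- function(curve_np, curve_water, material = NULL,
                        concentration = NULL, kvp = NULL) {
  stopifnot(inherits(curve_np, "depth_dose_curve"),
            inherits(curve_water, "depth_dose_curve"))
  if (length(curve_np$depth_cm) != length(curve_water$depth_cm) ||
      any(abs(curve_np$depth_cm - curve_water$depth_cm) > 1e-9))
    stop("depth binning of the two curves differs", call. = FALSE)
  zero <- curve_water$dose_per_history <= 0
  der <- ifelse(zero, NA_real_,
                curve_np$dose_per_history / curve_water$dose_per_history)
  out <- data.frame(
    depth_cm = curve_np$depth_cm, der = der,
    rel_unc = ifelse(zero, NA_real_,
                     sqrt(curve_np$rel_se^2 + curve_water$rel_se^2)),
    status = ifelse(zero, "zero_water_dose", "ok"))
  class(out) <- c("der_curve", "data.frame")
  attr(out, "material") <- material %||% attr(curve_np, "material")
  attr(out, "concentration") <- concentration
  attr(out, "kvp") <- kvp %||% attr(curve_np, "kvp")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent contrast between two DER values
#'
#' Two conventions are reported: `ratio_pct` = 100 * new/old (the
#' convention matching printed "(342%)"-style figures in the
#' orthovoltage literature) and `increase_pct` = 100 * (new/old - 1),
#' the plain relative increase.
#'
#' @param old,new DER values.
#' @return List with `ratio_pct` and `increase_pct`.
#' @export
der_contrast <- function(old, new) {
  list(ratio_pct = 100 * new / old, increase_pct = 100 * (new / old - 1))
}

#' Summary table over a set of DER curves
#'
#' Per curve: maximum and minimum DER within the reported 0-10 cm depth
#' range and the DER at 0.5 and 5.5 cm depth. When several
#' concentrations of the same material/beam are present, percent
#' contrasts between the lowest and highest concentration at 0.5 and
#' 5.5 cm are appended as attribute `"contrasts"` (both conventions of
#' [der_contrast()]).
#'
#' @param curves A `der_curve` or list of them.
#' @param depth_max Depth range upper limit for max/min (cm).
#' @return Data frame with one row per curve; attribute `"contrasts"`.
#' @export
der_summary <- function(curves, depth_max = 10) {
  if (inherits(curves, "der_curve")) curves <- list(curves)
  if (length(curves) == 0) stop("empty set of DER curves", call. = FALSE)
  at_depth <- function(cv, d) {
    i <- which(abs(cv$depth_cm - d) < 1e-9)
    if (length(i) == 1) cv$der[i] else NA_real_
  }
  rows <- lapply(curves, function(cv) {
    rng <- cv$depth_cm <= depth_max & cv$status == "ok"
    data.frame(material = attr(cv, "material") %||% NA_character_,
               concentration_mg_per_ml = attr(cv, "concentration") %||% NA_real_,
               kvp = attr(cv, "kvp") %||% NA_real_,
               max_der = max(cv$der[rng]), min_der = min(cv$der[rng]),
               der_0.5cm = at_depth(cv, 0.5), der_5.5cm = at_depth(cv, 5.5))
  })
  out <- do.call(rbind, rows)
  contrasts <- NULL
  grp <- split(seq_len(nrow(out)),
               paste(out$material, out$kvp))
  for (g in grp) {
    if (length(g) < 2 || anyNA(out$concentration_mg_per_ml[g])) next
    o <- g[order(out$concentration_mg_per_ml[g])]
    lo <- o[1]; hi <- o[length(o)]
    for (d in c("der_0.5cm", "der_5.5cm")) {
      ct <- der_contrast(out[[d]][lo], out[[d]][hi])
      contrasts <- rbind(contrasts, data.frame(
        material = out$material[lo], kvp = out$kvp[lo], depth = d,
        c_low = out$concentration_mg_per_ml[lo],
        c_high = out$concentration_mg_per_ml[hi],
        ratio_pct = ct$ratio_pct, increase_pct = ct$increase_pct))
    }
  }
  attr(out, "contrasts") <- contrasts
  out
}
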