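# Treatment-plan containers: shots, plug sectors, prescriptions. A plan is
# purely geometric; the dose model lives in synthetic_dose.R.

#' Specify a single Gamma Knife shot
#'
#' @param isocenter Length-3 mm position (Leksell X, Y, Z).
#' @param collimator Collimator size in mm; one of 4, 8, 14, 18.
#' @param weight Non-negative relative weight.
#' @param plug_sectors List of plug sectors, each a list or length-3 numeric
#'   `(azimuth_start_deg, azimuth_end_deg, transmission)`. Azimuths are
#'   measured in the axial (X-Y) plane about the shot axis, in `[0, 360)`,
#'   with `start < end`; transmission is the residual dose fraction inside
#'   the blocked wedge (0 = fully blocked).
#' @return An object of class `shot_spec`.
#' @export
shot_spec <- function(isocenter, collimator, weight = 1, plug_sectors = list()) {
  isocenter <- as.numeric(isocenter)
  stopifnot(length(isocenter) == 3L, all(is.finite(isocenter)))
  collimator <- as.numeric(collimator)
  if (!collimator %in% c(4, 8, 14, 18)) {
    stop("collimator must be one of 4, 8, 14, 18 mm")
  }
  if (!is.finite(weight) || weight < 0) stop("weight must be >= 0")
  plug_sectors <- lapply(plug_sectors, function(s) {
    s <- unlist(s, use.names = FALSE)
    if (length(s) != 3L) stop("each plug sector needs (start, end, transmission)")
    names(s) <- c("start", "end", "transmission")
    if (s["start"] < 0 || s["start"] >= 360 || s["end"] <= s["start"] ||
        s["end"] > 360) {
      stop("plug sector azimuths must satisfy 0 <= start < end <= 360")
    }
    if (s["transmission"] < 0 || s["transmission"] > 1) {
      stop("plug transmission must be in [0, 1]")
    }
    s
  })
  structure(list(isocenter = isocenter, collimator = collimator,
                 weight = weight, plug_sectors = plug_sectors),
            class = "shot_spec")
}

#' Specify a multi-shot plan with a prescription
#'
#' The maximum plan dose follows from the prescription:
#' `max = prescription_dose / prescription_isodose` (8 Gy to the 50%
#' isodose gives a 16 Gy maximum).
#'
#' @param shots List of [shot_spec()] objects (at least one).
#' @param prescription_dose Prescription dose in Gy.
#' @param prescription_isodose Prescription isodose as a fraction in (0, 1].
#' @param phantom_radius Phantom radius in mm.
#' @param phantom_center Length-3 mm position of the phantom center.
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(shots, prescription_dose = 8, prescription_isodose = 0.5,
                      phantom_radius = 80, phantom_center = c(100, 100, 100)) {
  if (length(shots) == 0L) stop("a plan needs at least one shot")
  if (!all(vapply(shots, inherits, TRUE, "shot_spec"))) {
    stop("shots must be a list of shot_spec objects")
  }
  if (!is.finite(prescription_dose) || prescription_dose <= 0) {
    stop("prescription_dose must be positive")
  }
  if (prescription_isodose <= 0 || prescription_isodose > 1) {
    stop("prescription_isodose must be in (0, 1]")
  }
  phantom_center <- as.numeric(phantom_center)
  for (i in seq_along(shots)) {
    d <- sqrt(sum((shots[[i]]$isocenter - phantom_center)^2))
    if (d > phantom_radius) {
      stop(sprintf("shot %d isocenter lies outside the phantom", i))
    }
  }
  structure(list(shots = shots, prescription_dose = prescription_dose,
                 prescription_isodose = prescription_isodose,
                 phantom_radius = phantom_radius,
                 phantom_center = phantom_center),
            class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat("<plan_spec> ", length(x$shots), " shot(s), ",
      x$prescription_dose, " Gy to the ", 100 * x$prescription_isodose,
      "% isodose (max ", x$prescription_dose / x$prescription_isodose,
      " Gy)\n", sep = "")
  for (i in seq_along(x$shots)) {
    s <- x$shots[[i]]
    cat(sprintf("  shot %d: %g mm collimator at (%g, %g, %g), weight %g, %d plug sector(s)\n",
                i, s$collimator, s$isocenter[1], s$isocenter[2],
                s$isocenter[3], s$weight, length(s$plug_sectors)))
  }
  invisible(x)
}

#' The bundled three-shot plugged plan
#'
#' A three-shot plan (18, 14 and 8 mm collimators) prescribed 8 Gy to the
#' 50% isodose inside a 16 cm spherical phantom, with one plug sector per
#' shot whose angular width is proportional to the number of plugged
#' source channels (45, 21 and 46 of 201). Shipped as a YAML fixture and
#' parsed through [read_plan_yaml()].
#'
#' @return A [plan_spec()].
#' @export
table1_plan <- function() {
  read_plan_yaml(system.file("extdata", "three_shot_plug_plan.yaml",
                             package = "plugdose", mustWork = TRUE))
}

#' Read a plan from YAML
#'
#' @param path Path to a plan YAML file (see the bundled
#'   `three_shot_plug_plan.yaml` for the layout).
#' @return A [plan_spec()].
#' @export
read_plan_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  shots <- lapply(y$shots, function(s) {
    plugs <- lapply(s$plugs, function(p) {
      c(p$azimuth_start_deg, p$azimuth_end_deg, p$transmission)
    })
    shot_spec(unlist(s$isocenter_mm), s$collimator_mm,
              weight = if (is.null(s$weight)) 1 else s$weight,
              plug_sectors = plugs)
  })
  plan_spec(shots,
            prescription_dose = y$prescription_dose_gy,
            prescription_isodose = y$prescription_isodose,
            phantom_radius = y$phantom_radius_mm,
            phantom_center = unlist(y$phantom_center_mm))
}

#' Write a plan to YAML
#'
#' @param plan A [plan_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan_yaml <- function(plan, path) {
  stopifnot(inherits(plan, "plan_spec"))
  y <- list(
    prescription_dose_gy = plan$prescription_dose,
    prescription_isodose = plan$prescription_isodose,
    phantom_radius_mm = plan$phantom_radius,
    phantom_center_mm = plan$phantom_center,
    shots = lapply(plan$shots, function(s) {
      list(isocenter_mm = s$isocenter,
           collimator_mm = s$collimator,
           weight = s$weight,
           plugs = lapply(s$plug_sectors, function(p) {
             list(azimuth_start_deg = unname(p["start"]),
                  azimuth_end_deg = unname(p["end"]),
                  transmission = unname(p["transmission"]))
           }))
    }))
  yaml::write_yaml(y, path)
  invisible(path)
}
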