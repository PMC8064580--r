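# The two acceleration protocols as pure decision functions. Both act on a
# single designated ligand bead (the force-target "CA" bead) relative to a
# fixed reference atom in the binding site. Distances here are unwrapped:
# the protocols are only defined on the extracellular side of the membrane
# and are switched off rather than wrapped across the periodic boundary.

#' Bias reason codes
#'
#' Integer codes recorded per frame per particle explaining the controller
#' decision. Codes 1 (steering force on) and 5 (harmonic restoring force on)
#' are the only states with a nonzero bias force.
#' @format Named integer vector.
#' @export
bias_reason_codes <- c(
  none = 0L,
  beyond_cutoff_in_region = 1L,
  within_cutoff = 2L,
  outside_region = 3L,
  inside_flat_region = 4L,
  in_harmonic_region = 5L,
  degenerate_zero = 6L
)

reason_active <- function(code) code %in% c(1L, 5L)

#' Conical selection region for force application
#'
#' The steering force is only applied inside an extracellular cone around
#' the pore axis (+z), defined by `z > 0` and `x^2 + y^2 < (z + a)^2` with
#' apex offset `a` (default 15 A): a 45-degree half-opening cone whose apex
#' sits at z = -a on the axis. Membership is strict on both inequalities.
#'
#' @param apex_offset apex offset a in Angstrom (> 0).
#' @param exponent exponent applied to `(z + a)`; 2 gives the quadratic
#'   (dimensionally consistent) cone and is the default.
#' @return An object of class `cone_region`.
#' @export
cone_region <- function(apex_offset = 15, exponent = 2) {
  if (!is.finite(apex_offset) || apex_offset <= 0) {
    stop("cone apex offset must be positive", call. = FALSE)
  }
  structure(list(apex_offset = apex_offset, exponent = exponent),
            class = "cone_region")
}

#' Test cone membership
#'
#' @param p numeric(3) point, or an n x 3 matrix of points.
#' @param region a [cone_region()].
#' @return Logical (vector for matrix input): inside the selection region?
#' @export
cone_contains <- function(p, region = cone_region()) {
  stopifnot(inherits(region, "cone_region"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(p[, 3] > 0 &
             p[, 1]^2 + p[, 2]^2 < (p[, 3] + region$apex_offset)^region$exponent)
  }
  p <- check_vec3(p)
  p[3] > 0 && p[1]^2 + p[2]^2 < (p[3] + region$apex_offset)^region$exponent
}

#' Configuration of the gated constant-force steering protocol
#'
#' A constant-magnitude force `f0` pushes the target bead towards the
#' reference atom, recomputed from the instantaneous inter-atom vector, but
#' only while the bead is (a) inside the extracellular selection cone and
#' (b) farther than `cutoff` from the reference. Within the cut-off the
#' force is switched off entirely, so the final approach and binding are
#' unbiased.
#'
#' @param f0 force magnitude, kcal/mol/A (> 0; default 5).
#' @param cutoff switch-off distance in Angstrom (default 7; 10 is the
#'   documented alternative).
#' @param reference selector string or [atom_selector()] for the reference
#'   atom (default `"ARG:397:CZ"`).
#' @param target_label label of the ligand bead the force acts on.
#' @param update_period apply/refresh the force every 1 or 2 integration
#'   steps (default 1).
#' @param region the [cone_region()] gating application.
#' @return An object of class `steering_config` (also `bias_config`).
#' @export
steering_config <- function(f0 = 5, cutoff = 7, reference = "ARG:397:CZ",
                            target_label = "CA", update_period = 1L,
                            region = cone_region()) {
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (!update_period %in% c(1L, 2L)) {
    stop("update_period must be 1 or 2", call. = FALSE)
  }
  stopifnot(inherits(region, "cone_region"))
  structure(list(kind = "steer", f0 = f0, cutoff = cutoff,
                 reference = reference, target_label = target_label,
                 update_period = as.integer(update_period), region = region),
            class = c("steering_config", "bias_config"))
}

#' Configuration of the flat-bottom harmonic containment restraint
#'
#' The restraint energy is zero while the target bead is within `cutoff` of
#' the reference atom and harmonic beyond it:
#' `U(d) = 0` for `d <= dc`, `U(d) = k/2 (d - dc)^2` for `d > dc`,
#' continuous and once-differentiable at the cut-off. It contains the
#' ligand near the site without biasing it once inside.
#'
#' @param k stiffness in kcal/mol/A^2 (default 0.1). With `wall = "linear"`
#'   a constant restoring force of magnitude `k` (kcal/mol/A) is used
#'   beyond the cut-off instead.
#' @param cutoff flat-region radius dc in Angstrom; 7, 10 and 12 are the
#'   documented choices (default 12).
#' @inheritParams steering_config
#' @param wall `"harmonic"` (default) or `"linear"`.
#' @return An object of class `flatbottom_config` (also `bias_config`).
#' @export
flatbottom_config <- function(k = 0.1, cutoff = 12, reference = "ARG:397:CZ",
                              target_label = "CA", wall = c("harmonic", "linear")) {
  wall <- match.arg(wall)
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(kind = "flatbottom", k = k, cutoff = cutoff,
                 reference = reference, target_label = target_label, wall = wall),
            class = c("flatbottom_config", "bias_config"))
}

new_bias_decision <- function(active, force, reason) {
  structure(list(active = active, force = force, reason = reason,
                 reason_code = bias_reason_codes[[reason]]),
            class = "bias_decision")
}

#' Steering controller decision for one ligand bead
#'
#' Implements the flow control of the gated constant-force protocol:
#' outside the selection cone, or within the cut-off distance of the
#' reference, no force is applied; otherwise a force of magnitude `f0`
#' along the instantaneous unit vector from the bead to the reference is
#' returned. Distances are unwrapped (no minimum image).
#'
#' @param ligand_pos,ref_pos numeric(3) positions (Angstrom).
#' @param cfg a [steering_config()].
#' @return A `bias_decision`: list with `active`, `force` (numeric(3),
#'   exactly zero when inactive), `reason` and `reason_code`.
#' @export
steering_decision <- function(ligand_pos, ref_pos, cfg = steering_config()) {
  stopifnot(inherits(cfg, "steering_config"))
  p <- check_vec3(ligand_pos, "ligand_pos")
  r <- check_vec3(ref_pos, "ref_pos")
  if (!cone_contains(p, cfg$region)) {
    return(new_bias_decision(FALSE, c(0, 0, 0), "outside_region"))
  }
  dvec <- r - p
  d <- sqrt(sum(dvec^2))
  if (d <= cfg$cutoff) {
    return(new_bias_decision(FALSE, c(0, 0, 0), "within_cutoff"))
  }
  if (d < 1e-12) {
    return(new_bias_decision(FALSE, c(0, 0, 0), "degenerate_zero"))
  }
  new_bias_decision(TRUE, cfg$f0 * dvec / d, "beyond_cutoff_in_region")
}

#' Flat-bottom restraint energy and force magnitude
#'
#' @param d distance(s) from the reference atom, Angstrom (>= 0); vectorised.
#' @param cfg a [flatbottom_config()].
#' @return List with `energy` (kcal/mol) and `force` (restoring-force
#'   magnitude, kcal/mol/A, directed towards the reference), each the same
#'   length as `d`.
#' @export
flat_bottom <- function(d, cfg = flatbottom_config()) {
  stopifnot(inherits(cfg, "flatbottom_config"))
  d <- as.numeric(d)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distance", call. = FALSE)
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  x <- pmax(d - cfg$cutoff, 0)
  if (cfg$wall == "harmonic") {
    list(energy = 0.5 * cfg$k * x^2, force = cfg$k * x)
  } else {
    list(energy = cfg$k * x, force = ifelse(x > 0, cfg$k, 0))
  }
}

#' Flat-bottom controller decision for one ligand bead
#'
#' Vector form of [flat_bottom()]: zero force in the flat region, restoring
#' force `k (d - dc)` towards the reference beyond it.
#'
#' @inheritParams steering_decision
#' @param cfg a [flatbottom_config()].
#' @return A `bias_decision`.
#' @export
flatbottom_decision <- function(ligand_pos, ref_pos, cfg = flatbottom_config()) {
  stopifnot(inherits(cfg, "flatbottom_config"))
  p <- check_vec3(ligand_pos, "ligand_pos")
  r <- check_vec3(ref_pos, "ref_pos")
  dvec <- r - p
  d <- sqrt(sum(dvec^2))
  if (d <= cfg$cutoff) {
    return(new_bias_decision(FALSE, c(0, 0, 0), "inside_flat_region"))
  }
  fb <- flat_bottom(d, cfg)
  new_bias_decision(TRUE, fb$force * dvec / d, "in_harmonic_region")
}

#' Build a bias configuration from flat config keys
#'
#' Accepts the key set used in YAML run configurations:
#' `bias.kind` (none/steer/flatbottom), `bias.f0`, `bias.k`, `bias.cutoff`,
#' `bias.update_period`, `bias.cone_apex_offset`, `bias.reference`,
#' `bias.target_label`. Either dotted names in a flat list or a nested
#' `bias:` block are accepted.
#'
#' @param lst a named list (for example from [yaml::read_yaml()]).
#' @return A `bias_config` or `NULL` for kind "none".
#' @export
bias_config_from_list <- function(lst) {
  b <- if (!is.null(lst$bias)) lst$bias else {
    keys <- grep("^bias\\.", names(lst), value = TRUE)
    stats::setNames(lst[keys], sub("^bias\\.", "", keys))
  }
  kind <- b$kind %||% "none"
  if (kind == "none") return(NULL)
  ref <- b$reference %||% "ARG:397:CZ"
  tgt <- b$target_label %||% "CA"
  if (kind == "steer") {
    steering_config(
      f0 = b$f0 %||% 5, cutoff = b$cutoff %||% 7,
      reference = ref, target_label = tgt,
      update_period = as.integer(b$update_period %||% 1L),
      region = cone_region(apex_offset = b$cone_apex_offset %||% 15)
    )
  } else if (kind == "flatbottom") {
    flatbottom_config(k = b$k %||% 0.1, cutoff = b$cutoff %||% 12,
                      reference = ref, target_label = tgt)
  } else {
    stop(sprintf("unknown bias kind '%s'", kind), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
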