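# Trajectory observables: reference-pair distance series, RDF and
# cumulative RDF around a reference atom, syn/anti conformer occupancy,
# binding-event detection with hysteresis, and the bias-time fraction.

resolve_endpoint <- function(traj, sel, struct = NULL) {
  # returns either a fixed numeric(3) (static atom) or a particle index
  if (is.character(sel) && length(sel) == 1L && sel %in% traj$labels) {
    idx <- which(traj$labels == sel)
    if (length(idx) > 1L) {
      stop(sprintf("label '%s' matches %d particles; labels must be unique for a series",
                   sel, length(idx)), call. = FALSE)
    }
    return(list(kind = "particle", index = idx))
  }
  if (is.null(struct)) {
    stop(sprintf("'%s' is not a trajectory particle label and no structure was supplied",
                 if (is.character(sel)) sel else format_selector(parse_selector(sel))),
         call. = FALSE)
  }
  list(kind = "static", pos = atom_coords(struct, sel))
}

endpoint_coords <- function(traj, ep) {
  nf <- length(traj$times)
  if (ep$kind == "static") {
    matrix(ep$pos, nf, 3, byrow = TRUE)
  } else {
    traj$coords[, ep$index, , drop = TRUE]
  }
}

#' Distance time series between two atoms
#'
#' Per-frame minimum-image distance between two endpoints, each either a
#' static receptor atom (selector resolved in `struct`, e.g. the Ser-277
#' CA to Pro-356 CA gate distance) or a mobile particle label from the
#' trajectory (e.g. the ligand "CA" bead against "ARG:397:CZ").
#'
#' @param traj a [trajectory()].
#' @param a,b selector strings, [atom_selector()]s or particle labels.
#' @param struct a `structure` for static endpoints (optional otherwise).
#' @return A data frame (class `distance_series`) with columns `time` and
#'   `distance`; the endpoints used are kept in attributes.
#' @export
distance_series <- function(traj, a, b, struct = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ea <- resolve_endpoint(traj, a, struct)
  eb <- resolve_endpoint(traj, b, struct)
  pa <- endpoint_coords(traj, ea)
  pb <- endpoint_coords(traj, eb)
  d <- pa - pb
  if (!is.null(traj$box)) {
    L <- traj$box$lengths; per <- traj$box$periodic
    for (k in 1:3) if (per[k]) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  }
  out <- data.frame(time = traj$times, distance = sqrt(rowSums(d^2)))
  attr(out, "endpoint_a") <- if (is.character(a)) a else format_selector(a)
  attr(out, "endpoint_b") <- if (is.character(b)) b else format_selector(b)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Radial distribution function around a reference atom
#'
#' Histograms the reference-to-ligand distances of every frame within
#' `r_max` of the reference. `g(r)` is the count density per spherical
#' shell, normalised by the mean particle density within the `r_max`
#' sphere (not a bulk density: the analysis volume is the near-reference
#' region itself, and the normalisation is recorded in the attributes).
#' `N(r)` is the mean cumulative particle count within `r` per frame.
#'
#' @param traj a [trajectory()].
#' @param reference selector for the reference atom (resolved in `struct`)
#'   or a fixed numeric(3) position.
#' @param struct a `structure` (needed when `reference` is a selector).
#' @param labels optional subset of particle labels to include.
#' @param r_max analysis radius, Angstrom (default 10).
#' @param bin_width histogram bin width, Angstrom (default 0.1).
#' @return Data frame (class `rdf_result`) with columns `r` (bin centre),
#'   `g` and `N`.
#' @export
rdf <- function(traj, reference, struct = NULL, labels = NULL,
                r_max = 10, bin_width = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  if (bin_width <= 0 || bin_width >= r_max) {
    stop("bin width must be in (0, r_max)", call. = FALSE)
  }
  ref <- if (is.numeric(reference)) check_vec3(reference) else {
    atom_coords(struct, reference)
  }
  nf <- length(traj$times)
  sel <- if (is.null(labels)) seq_along(traj$labels) else which(traj$labels %in% labels)
  if (!length(sel)) stop("no particles match the requested labels", call. = FALSE)
  L <- if (!is.null(traj$box)) traj$box$lengths else NULL
  per <- if (!is.null(traj$box)) traj$box$periodic else c(FALSE, FALSE, FALSE)

  dx <- traj$coords[, sel, 1, drop = FALSE] - ref[1]
  dy <- traj$coords[, sel, 2, drop = FALSE] - ref[2]
  dz <- traj$coords[, sel, 3, drop = FALSE] - ref[3]
  if (!is.null(L)) {
    if (per[1]) dx <- dx - L[1] * round(dx / L[1])
    if (per[2]) dy <- dy - L[2] * round(dy / L[2])
    if (per[3]) dz <- dz - L[3] * round(dz / L[3])
  }
  dist <- sqrt(dx^2 + dy^2 + dz^2)

  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- tabulate(findInterval(dist[dist < r_max], edges,
                                  rightmost.closed = TRUE), nbins = nb)
  mean_counts <- counts / nf                    # mean count per frame per shell
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  sphere_vol <- 4 / 3 * pi * r_max^3
  mean_total <- sum(mean_counts)                # mean count within r_max per frame
  dens <- mean_total / sphere_vol
  g <- if (mean_total > 0) (mean_counts / shell_vol) / dens else rep(0, nb)
  N <- cumsum(mean_counts)
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = g, N = N)
  attr(out, "r_max") <- r_max
  attr(out, "bin_width") <- bin_width
  attr(out, "normalisation") <- "mean density within the r_max sphere"
  attr(out, "mean_count_rmax") <- mean_total
  class(out) <- c("rdf_result", "data.frame")
  out
}

#' Classify ligand side-chain conformers from a dihedral series
#'
#' Computes the C-CA-CB-CG dihedral per frame and labels frames syn when
#' `|angle| <= boundary` and anti otherwise. The default boundary of 120
#' degrees is the midpoint between the two observed modes (~70 degrees syn,
#' ~180 degrees anti). With `three_state = TRUE`, frames are labelled syn /
#' anti only within +-30 degrees of those modes and "other" elsewhere.
#' Frames with degenerate geometry are labelled "undefined" and excluded
#' from the occupancy fractions.
#'
#' @param traj a [trajectory()] containing the four beads.
#' @param labels the four bead labels, in dihedral order
#'   (default `c("C", "CA", "CB", "CG")`).
#' @param boundary syn/anti boundary on `|angle|`, degrees (default 120).
#' @param three_state use the windowed three-state labelling instead.
#' @return List of class `conformer_series`: `series` (data frame time,
#'   angle, state) and `occupancy` (named fractions over labelled frames).
#' @export
conformer_classify <- function(traj, labels = c("C", "CA", "CB", "CG"),
                               boundary = 120, three_state = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(labels) != 4L) stop("exactly four bead labels required", call. = FALSE)
  idx <- match(labels, traj$labels)
  if (anyNA(idx)) {
    stop(sprintf("labels not in trajectory: %s",
                 paste(labels[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  nf <- length(traj$times)
  ang <- rep(NA_real_, nf)
  state <- rep("undefined", nf)
  n_degenerate <- 0L
  for (f in seq_len(nf)) {
    a <- tryCatch(
      dihedral_angle(traj$coords[f, idx[1], ], traj$coords[f, idx[2], ],
                     traj$coords[f, idx[3], ], traj$coords[f, idx[4], ]),
      error = function(e) NA_real_)
    ang[f] <- a
    if (is.na(a)) { n_degenerate <- n_degenerate + 1L; next }
    state[f] <- if (three_state) {
      if (abs(abs(a) - 70) <= 30) "syn"
      else if (abs(abs(a) - 180) <= 30) "anti"
      else "other"
    } else {
      if (abs(a) <= boundary) "syn" else "anti"
    }
  }
  if (n_degenerate > 0L) {
    message(sprintf("%d frame(s) with degenerate dihedral geometry excluded", n_degenerate))
  }
  labelled <- state != "undefined"
  occ <- if (any(labelled)) {
    tab <- table(state[labelled])
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else stats::setNames(numeric(0), character(0))
  structure(list(series = data.frame(time = traj$times, angle = ang,
                                     state = state),
                 occupancy = occ,
                 boundary = boundary, three_state = three_state),
            class = "conformer_series")
}

#' @export
print.conformer_series <- function(x, ...) {
  occ <- paste(sprintf("%s %.1f%%", names(x$occupancy), 100 * x$occupancy),
               collapse = ", ")
  cat(sprintf("<conformer_series: %d frames; %s>\n", nrow(x$series), occ))
  invisible(x)
}

#' Detect binding events with hysteresis
#'
#' An event opens once the distance has been below `bind` for `dwell`
#' consecutive frames (the event start is the first of those frames) and
#' closes at the first frame with distance above `unbind`; an event still
#' open at the last frame closes there. The two thresholds give hysteresis
#' so boundary noise does not fragment events.
#'
#' @param ds a [distance_series()] (or data frame with time, distance).
#' @param bind binding threshold, Angstrom (default 7).
#' @param unbind unbinding threshold, Angstrom (default 9; must be
#'   `>= bind`).
#' @param dwell consecutive frames below `bind` required to open an event
#'   (default 10).
#' @param ligand label stored with the events (default "CA").
#' @return Data frame with columns ligand, start, end, residency (ps);
#'   zero rows when no event occurs.
#' @export
detect_binding_events <- function(ds, bind = 7, unbind = 9, dwell = 10L,
                                  ligand = "CA") {
  if (unbind < bind) stop("unbind threshold must be >= bind threshold", call. = FALSE)
  if (dwell < 1L) stop("dwell must be >= 1", call. = FALSE)
  d <- ds$distance
  tms <- ds$time
  events <- list()
  open <- FALSE
  run <- 0L
  start <- NA_real_
  for (i in seq_along(d)) {
    if (!open) {
      run <- if (d[i] < bind) run + 1L else 0L
      if (run >= dwell) {
        open <- TRUE
        start <- tms[i - dwell + 1L]
      }
    } else if (d[i] > unbind) {
      events[[length(events) + 1L]] <- c(start, tms[i])
      open <- FALSE
      run <- 0L
    }
  }
  if (open) events[[length(events) + 1L]] <- c(start, tms[length(tms)])
  if (!length(events)) {
    return(data.frame(ligand = character(0), start = numeric(0),
                      end = numeric(0), residency = numeric(0)))
  }
  m <- do.call(rbind, events)
  data.frame(ligand = ligand, start = m[, 1], end = m[, 2],
             residency = m[, 2] - m[, 1])
}

#' Fraction of simulation time spent under bias
#'
#' @param x a `simulation_result`, a [trajectory()] with flags, or a
#'   logical vector/matrix of per-frame bias-active flags.
#' @return Fraction in `[0, 1]` of frame-particle records with the bias
#'   force active.
#' @export
bias_fraction <- function(x) {
  flags <- if (inherits(x, "simulation_result")) x$trajectory$flags
  else if (inherits(x, "trajectory")) x$flags
  else x
  if (length(flags) == 0L) stop("no frames: bias fraction undefined", call. = FALSE)
  mean(as.logical(flags))
}

#' Run the standard analysis bundle and write its outputs
#'
#' Convenience wrapper producing the four standard artifacts for a
#' trajectory: `<prefix>_distance.csv`, `<prefix>_rdf.csv`,
#' `<prefix>_dihedral.csv` (when the four beads are present) and
#' `<prefix>_events.jsonl`.
#'
#' @param traj a [trajectory()].
#' @param struct the receptor `structure`.
#' @param pair character(2): the two endpoints of the distance series.
#' @param prefix output path prefix.
#' @param dihedral_labels four bead labels or `NULL` to skip.
#' @param r_max,bin_width RDF parameters.
#' @param bind,unbind,dwell event-detection parameters.
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
analyze_trajectory <- function(traj, struct, pair, prefix,
                               dihedral_labels = NULL,
                               r_max = 10, bin_width = 0.1,
                               bind = 7, unbind = 9, dwell = 10L) {
  ds <- distance_series(traj, pair[1], pair[2], struct)
  files <- list(distance = paste0(prefix, "_distance.csv"))
  write_analysis_csv(ds, files$distance)
  g <- rdf(traj, pair[1], struct,
           labels = if (pair[2] %in% traj$labels) pair[2] else NULL,
           r_max = r_max, bin_width = bin_width)
  files$rdf <- paste0(prefix, "_rdf.csv")
  write_analysis_csv(g, files$rdf)
  conf <- NULL
  if (!is.null(dihedral_labels) && all(dihedral_labels %in% traj$labels)) {
    conf <- conformer_classify(traj, dihedral_labels)
    files$dihedral <- paste0(prefix, "_dihedral.csv")
    write_analysis_csv(conf$series, files$dihedral)
  }
  ev <- detect_binding_events(ds, bind, unbind, dwell,
                              ligand = pair[2])
  files$events <- paste0(prefix, "_events.jsonl")
  write_events_jsonl(ev, files$events)
  invisible(list(distance = ds, rdf = g, conformers = conf, events = ev,
                 files = files))
}
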