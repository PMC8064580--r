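# Synthetic-system generator: a minimal aspartate-transporter-like binding
# site with named anchor atoms near the membrane surface, plus a 4-bead
# ligand template, so the whole pipeline is testable with no downloads.
# All fixture coordinates are synthetic: they emulate the occluded-state
# geometry (gate and binding distances of 5.6 A) but are not copied from
# any deposited structure. import_reference_anchors() can pull the same
# anchor set out of a locally supplied real structure instead.

#' Fixture specification
#'
#' Describes the synthetic receptor + ligand system: the anchor atoms to
#' emit (always including ARG397 CZ and CG, SER277 CA, PRO356 CA and the
#' ASP390/ASP394 carboxylate anchors, all within 5 A of the membrane
#' surface), the ligand bead template (four beads C/CA/CB/CG, or a single
#' CA bead) with a prescribed initial side-chain dihedral, and the initial
#' ligand distance from the reference atom.
#'
#' @param initial_distance starting distance of the free ligand from the
#'   ARG397 CZ reference along +z, Angstrom. 18, 23 and 27 are the
#'   documented starting distances; default 18.
#' @param box a [periodic_box()].
#' @param ligand_template `"four"` (C/CA/CB/CG beads) or `"one"`.
#' @param ligand_dihedral prescribed C-CA-CB-CG dihedral of the bound
#'   ligand copy, degrees (default 180, the anti conformation seen in the
#'   occluded crystal state).
#' @param include_bound_ligand also place a bound ligand copy with its CA
#'   bead at the crystal-like 5.6 A from the reference (default TRUE; this
#'   is what the crystal-geometry checks measure).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(initial_distance = 18, box = periodic_box(),
                         ligand_template = c("four", "one"),
                         ligand_dihedral = 180,
                         include_bound_ligand = TRUE) {
  ligand_template <- match.arg(ligand_template)
  stopifnot(inherits(box, "periodic_box"))
  if (initial_distance <= 0) stop("initial distance must be positive", call. = FALSE)
  structure(list(initial_distance = initial_distance, box = box,
                 ligand_template = ligand_template,
                 ligand_dihedral = ligand_dihedral,
                 include_bound_ligand = include_bound_ligand),
            class = "fixture_spec")
}

# synthetic anchor coordinates: binding site on the pore axis just above
# the membrane plane (all anchors at z <= 5), with the two crystal-like
# 5.6 A distances built in (SER277 CA <-> PRO356 CA, ARG397 CZ <-> bound CA)
fixture_anchor_table <- function() {
  data.frame(
    name    = c("CZ",     "CG",     "CA",     "CA",     "CG",     "CG"),
    resname = c("ARG",    "ARG",    "SER",    "PRO",    "ASP",    "ASP"),
    resno   = c(397L,     397L,     277L,     356L,     390L,     394L),
    chain   = "A",
    x = c(0.0,  0.0, -2.8,  2.8, -2.0,  2.0),
    y = c(0.0, -3.3,  1.5,  1.5, -2.5, -2.5),
    z = c(2.0,  0.0,  3.0,  3.0,  1.0,  1.2),
    stringsAsFactors = FALSE
  )
}

#' Build a four-bead ligand with a prescribed side-chain dihedral
#'
#' Constructs C, CA, CB, CG bead coordinates with 1.52-1.53 A bond lengths
#' and 111-degree bond angles such that the C-CA-CB-CG dihedral equals
#' `chi` exactly, then translates the unit so the CA bead lands at
#' `ca_position`. The fourth bead is generated by rotating the planar-cis
#' arrangement about the CA-CB axis, which is also how scheduled dihedral
#' trajectories are produced.
#'
#' @param ca_position numeric(3) target position of the CA bead.
#' @param chi dihedral in degrees (normalised into `(-180, 180]`).
#' @return 4 x 3 matrix with rows C, CA, CB, CG.
#' @export
build_ligand_beads <- function(ca_position = c(0, 0, 0), chi = 180) {
  ca_position <- check_vec3(ca_position, "ca_position")
  chi <- normalize_angle(chi)
  ca <- c(0, 0, 0)
  cb <- c(1.53, 0, 0)
  th <- 111 * pi / 180
  cc <- 1.52 * c(cos(th), sin(th), 0)          # the carbonyl-side bead
  # cis CG (dihedral 0): in plane, same side as C
  phi <- (180 - 111) * pi / 180
  cg0 <- cb + 1.52 * c(cos(phi), sin(phi), 0)
  cg <- rotate_about_axis(cg0, axis = cb - ca, angle = chi, origin = cb)
  m <- rbind(C = cc, CA = ca, CB = cb, CG = cg)
  sweep(m, 2, ca_position, `+`)
}

normalize_angle <- function(a) {
  a <- ((a + 180) %% 360) - 180
  if (a == -180) a <- 180
  a
}

#' Build the synthetic receptor-ligand system
#'
#' Emits a `structure` containing the required anchor atoms and (by
#' default) a bound four-bead ligand copy (HETATM, residue ASP 500, chain
#' L) whose CA bead sits exactly 5.6 A from the ARG397 CZ reference,
#' together with a draft [engine_config()] whose initial free-ligand
#' distance is taken from the spec. The structure round-trips through
#' [write_fixture_pdb()] / [read_pdb_subset()].
#'
#' @param spec a [fixture_spec()].
#' @return List with `structure`, `config` (engine draft) and
#'   `ligand_start` (numeric(3): free-ligand start position).
#' @export
build_synthetic_system <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  anchors <- fixture_anchor_table()
  ref <- as.numeric(anchors[anchors$resno == 397 & anchors$name == "CZ",
                            c("x", "y", "z")])
  Lz <- spec$box$lengths[3]
  start <- ref + c(0, 0, spec$initial_distance)
  if (start[3] >= Lz || start[3] <= 0) {
    stop(sprintf("initial distance %g A places the ligand at z = %g, outside the box (0, %g)",
                 spec$initial_distance, start[3], Lz), call. = FALSE)
  }
  atoms <- data.frame(serial = seq_len(nrow(anchors)),
                      name = anchors$name, resname = anchors$resname,
                      chain = anchors$chain, resno = anchors$resno,
                      x = anchors$x, y = anchors$y, z = anchors$z,
                      element = substr(anchors$name, 1, 1), het = FALSE,
                      stringsAsFactors = FALSE)
  if (spec$include_bound_ligand) {
    # bound CA bead 5.6 A from the reference (3-4-5-like offset scaled)
    ca_bound <- ref + 5.6 * c(0, 0.6, 0.8)
    lig <- if (spec$ligand_template == "four") {
      build_ligand_beads(ca_bound, spec$ligand_dihedral)
    } else {
      matrix(ca_bound, 1, 3, dimnames = list("CA", NULL))
    }
    lig_atoms <- data.frame(serial = nrow(atoms) + seq_len(nrow(lig)),
                            name = rownames(lig), resname = "ASP",
                            chain = "L", resno = 500L,
                            x = lig[, 1], y = lig[, 2], z = lig[, 3],
                            element = "C", het = TRUE,
                            stringsAsFactors = FALSE)
    atoms <- rbind(atoms, lig_atoms)
  }
  rownames(atoms) <- NULL
  struct <- new_structure(atoms, spec$box)
  cfg <- engine_config(n_steps = 100000L, box = spec$box,
                       initial_distance = spec$initial_distance)
  list(structure = struct, config = cfg, ligand_start = start)
}

#' Write a structure to a fixed-column PDB file
#'
#' Uses the standard PDB writer; ATOM/HETATM record types follow the
#' structure's `het` flags. Intended for fixtures generated by
#' [build_synthetic_system()]; name synthetic files accordingly (for
#' example `synthetic_gltph_like.pdb`).
#'
#' @param struct a `structure`.
#' @param file output path.
#' @export
write_fixture_pdb <- function(struct, file) {
  stopifnot(inherits(struct, "structure"))
  a <- struct$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(isTRUE(a$het) | a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(file)
}

#' Extract the standard anchor set from a supplied structure file
#'
#' For use with a locally available real structure (for example the
#' aspartate-bound occluded transporter structure): pulls out the ARG397
#' CZ/CG, SER277 CA and PRO356 CA anchors plus, when present, the CA atom
#' of the bound free-aspartate HETATM nearest to the reference. When the
#' file holds several chains, the first chain containing the ARG397 CZ
#' anchor is used.
#'
#' @param file path to a PDB file.
#' @return A `structure` holding the anchors (and the bound ligand CA, if
#'   found) suitable for the crystal-geometry distance checks.
#' @export
import_reference_anchors <- function(file) {
  full <- read_pdb_subset(file)
  a <- full$atoms
  cz <- a[a$resname == "ARG" & a$resno == 397 & a$name == "CZ" & !a$het, , drop = FALSE]
  if (nrow(cz) == 0L) stop("no ARG397 CZ anchor found in the supplied file", call. = FALSE)
  ch <- cz$chain[1]
  want <- list(c("ARG", 397, "CZ"), c("ARG", 397, "CG"),
               c("SER", 277, "CA"), c("PRO", 356, "CA"),
               c("ASP", 390, "CG"), c("ASP", 394, "CG"))
  rows <- do.call(rbind, lapply(want, function(w) {
    hit <- a[a$chain == ch & a$resname == w[1] & a$resno == as.integer(w[2]) &
               a$name == w[3] & !a$het, , drop = FALSE]
    if (nrow(hit)) hit[1, , drop = FALSE] else NULL
  }))
  refp <- as.numeric(rows[rows$resno == 397 & rows$name == "CZ", c("x", "y", "z")])
  lig <- a[a$het & a$resname == "ASP" & a$name == "CA", , drop = FALSE]
  if (nrow(lig)) {
    dd <- sqrt((lig$x - refp[1])^2 + (lig$y - refp[2])^2 + (lig$z - refp[3])^2)
    rows <- rbind(rows, lig[which.min(dd), , drop = FALSE])
  }
  rownames(rows) <- NULL
  new_structure(rows, full$box)
}

#' Synthetic dihedral trajectory from a schedule
#'
#' Builds a four-bead (C, CA, CB, CG) trajectory whose per-frame dihedral
#' follows a schedule of (frames, angle) segments exactly, by rotating the
#' fourth bead about the CA-CB axis. The designed feed for conformer
#' analyses: composing this with [conformer_classify()] recovers the
#' scheduled state fractions.
#'
#' @param schedule a list of `c(frames, angle_deg)` pairs, or a two-column
#'   matrix / data frame (frames, angle).
#' @param ca_position CA bead position used for every frame.
#' @param dt frame spacing, ps.
#' @return A [trajectory()] with labels C, CA, CB, CG.
#' @export
synth_dihedral_trajectory <- function(schedule, ca_position = c(0, 0, 10), dt = 1) {
  if (is.data.frame(schedule) || is.matrix(schedule)) {
    schedule <- lapply(seq_len(nrow(schedule)), function(i) as.numeric(schedule[i, 1:2]))
  }
  if (!length(schedule)) stop("schedule must be nonempty", call. = FALSE)
  angles <- unlist(lapply(schedule, function(seg) {
    nfr <- as.integer(seg[1])
    if (nfr < 1L) stop("schedule segment with no frames", call. = FALSE)
    a <- seg[2]
    an <- normalize_angle(a)
    if (an != a) message(sprintf("angle %g normalised to %g", a, an))
    rep(an, nfr)
  }))
  nf <- length(angles)
  coords <- array(0, dim = c(nf, 4, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- build_ligand_beads(ca_position, angles[f])
  }
  trajectory(times = (seq_len(nf) - 1) * dt, coords = coords,
             labels = c("C", "CA", "CB", "CG"))
}

#' Molar concentration of n particles in a volume
#'
#' @param n particle count.
#' @param volume volume in cubic Angstrom (> 0).
#' @return Concentration in mol/L. 76 ligands in the default
#'   120 x 120 x 100 A box give 0.0876 M, the "about 0.1 M"
#'   high-concentration regime (the quoted 0.1 M refers to the aqueous
#'   sub-volume; the full-box value is the analytic check).
#' @export
molarity <- function(n, volume) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive", call. = FALSE)
  if (n < 0) stop("particle count must be non-negative", call. = FALSE)
  n / (6.02214076e23 * volume * 1e-27)
}
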