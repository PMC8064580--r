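# Structure and trajectory I/O. PDB reading/writing is delegated to bio3d
# (fixed-column dialect only); the trajectory format is a package-specific
# extended XYZ carrying a time stamp and per-particle bias flags on the
# comment line, chosen over binary formats so runs are diffable.

#' Read a receptor structure from a fixed-column PDB file
#'
#' Parses ATOM and HETATM records (all other record types are ignored) into
#' a `structure` object: a data frame of atoms plus an optional periodic
#' box. HETATM ligand records (for example a free aspartate) are retained.
#' Alternate-location indicators other than blank or "A" are skipped with a
#' message. Author residue numbering is kept exactly as read.
#'
#' @param file path to a PDB file.
#' @param box optional [periodic_box()] to attach.
#' @return An object of class `structure` with elements `atoms` (data frame
#'   with columns serial, name, resname, chain, resno, x, y, z, element,
#'   het) and `box`.
#' @export
read_pdb_subset <- function(file, box = NULL) {
  if (!file.exists(file)) stop(sprintf("PDB file not found: %s", file), call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse PDB '%s': %s",
                                     file, conditionMessage(e)), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in PDB input", call. = FALSE)
  alt <- at$alt
  keep <- is.na(alt) | alt %in% c("", "A")
  if (any(!keep)) {
    message(sprintf("skipping %d alternate-location record(s) (altLoc not blank/'A')",
                    sum(!keep)))
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no atoms in PDB input after altLoc filtering", call. = FALSE)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad)) {
    stop(sprintf("malformed coordinate columns at atom serial %s",
                 paste(at$eleno[bad], collapse = ", ")), call. = FALSE)
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    resname = as.character(at$resid),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(sprintf("duplicate (chain, resno, atom name) records: %s",
                 paste(dups, collapse = "; ")), call. = FALSE)
  }
  new_structure(atoms, box)
}

new_structure <- function(atoms, box = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (!is.null(box)) stopifnot(inherits(box, "periodic_box"))
  structure(list(atoms = atoms, box = box), class = "structure")
}

#' @export
print.structure <- function(x, ...) {
  cat(sprintf("<structure: %d atoms, %d residues%s>\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              if (is.null(x$box)) "" else ", with box"))
  invisible(x)
}

#' Atom selector
#'
#' A selector matches atoms by exact equality on whichever of the four
#' fields are provided. `parse_selector()` accepts the compact string forms
#' `"ARG:397:CZ"` (resname:resno:atom), `"397:CZ"` (resno:atom) or `"CZ"`
#' (atom name only), with an optional leading `chain/` prefix.
#'
#' @param chain,resno,resname,name selection fields; `NULL` = unconstrained.
#' @return An object of class `atom_selector`.
#' @export
atom_selector <- function(resname = NULL, resno = NULL, name = NULL, chain = NULL) {
  if (!is.null(resno)) resno <- as.integer(resno)
  structure(list(chain = chain, resno = resno, resname = resname, name = name),
            class = "atom_selector")
}

#' @rdname atom_selector
#' @param x a selector string such as `"ARG:397:CZ"`.
#' @export
parse_selector <- function(x) {
  if (inherits(x, "atom_selector")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  chain <- NULL
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    chain <- parts[1]
    x <- parts[2]
  }
  f <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(f) == 3L) {
    atom_selector(resname = f[1], resno = as.integer(f[2]), name = f[3], chain = chain)
  } else if (length(f) == 2L) {
    atom_selector(resno = as.integer(f[1]), name = f[2], chain = chain)
  } else if (length(f) == 1L) {
    atom_selector(name = f[1], chain = chain)
  } else {
    stop(sprintf("cannot parse selector '%s'", x), call. = FALSE)
  }
}

#' Resolve an atom selection against a structure
#'
#' @param s a `structure`.
#' @param sel an `atom_selector` or selector string (see [parse_selector()]).
#' @param mode `"unique"` (error unless exactly one atom matches) or
#'   `"all"` (return every match).
#' @return The matching row(s) of `s$atoms` as a data frame.
#' @export
select_atom <- function(s, sel, mode = c("unique", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "structure"))
  sel <- parse_selector(sel)
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain == sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno == sel$resno
  if (!is.null(sel$resname)) keep <- keep & a$resname == sel$resname
  if (!is.null(sel$name)) keep <- keep & a$name == sel$name
  hits <- a[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    near <- if (!is.null(sel$resno)) {
      ord <- order(abs(unique(a$resno) - sel$resno))
      paste(utils::head(unique(a$resno)[ord], 5), collapse = ", ")
    } else paste(utils::head(unique(a$resno), 5), collapse = ", ")
    stop(sprintf("no atom matches selector %s; closest residue numbers: %s",
                 format_selector(sel), near), call. = FALSE)
  }
  if (mode == "unique" && nrow(hits) > 1L) {
    stop(sprintf("selector %s matches %d atoms (expected 1): %s",
                 format_selector(sel), nrow(hits),
                 paste(sprintf("%s:%d:%s", hits$resname, hits$resno, hits$name),
                       collapse = ", ")), call. = FALSE)
  }
  hits
}

format_selector <- function(sel) {
  paste(c(if (!is.null(sel$chain)) paste0("chain=", sel$chain),
          if (!is.null(sel$resname)) paste0("resname=", sel$resname),
          if (!is.null(sel$resno)) paste0("resno=", sel$resno),
          if (!is.null(sel$name)) paste0("atom=", sel$name)),
        collapse = " ")
}

#' Coordinates of a uniquely selected atom
#' @inheritParams select_atom
#' @return numeric(3).
#' @export
atom_coords <- function(s, sel) {
  hit <- select_atom(s, sel, mode = "unique")
  c(hit$x, hit$y, hit$z)
}

#' Particle trajectory
#'
#' Time-ordered frames of labelled mobile-particle coordinates with a
#' per-frame, per-particle bias-active flag.
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param coords numeric array `frames x particles x 3` (Angstrom).
#' @param labels character vector of particle labels.
#' @param flags logical matrix `frames x particles`; `TRUE` where the bias
#'   force on that particle was nonzero at that frame. Defaults to all off.
#' @param box optional [periodic_box()].
#' @param reasons optional integer matrix of bias reason codes (see
#'   [bias_reason_codes]).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, coords, labels, flags = NULL, box = NULL,
                       reasons = NULL) {
  times <- as.numeric(times)
  if (length(times) == 0L) stop("trajectory must have at least one frame", call. = FALSE)
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a frames x particles x 3 array", call. = FALSE)
  }
  nf <- dim(coords)[1]; np <- dim(coords)[2]
  if (nf != length(times)) stop("coords frame count does not match times", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != np) stop("one label per particle required", call. = FALSE)
  if (is.null(flags)) flags <- matrix(FALSE, nf, np)
  flags <- matrix(as.logical(flags), nf, np)
  if (!is.null(box)) stopifnot(inherits(box, "periodic_box"))
  structure(list(times = times, coords = coords, labels = labels,
                 flags = flags, box = box, reasons = reasons),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d particle(s) [%s], t = %g .. %g ps>\n",
              length(x$times), length(x$labels),
              paste(utils::head(x$labels, 4), collapse = ","),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

#' Write / read a trajectory in extended XYZ format
#'
#' One block per frame: an atom-count line; a comment line
#' `time=<ps> flags=<bitstring>` (one bit per particle, 1 = bias active);
#' then one `label x y z` line per particle. Coordinates are written with
#' enough digits for a lossless round trip at the 1e-6 A level.
#'
#' @param traj a [trajectory()].
#' @param file output (input) path.
#' @return `write_trajectory` returns `file` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); np <- length(traj$labels)
  if (nf == 0L) stop("refusing to write an empty trajectory", call. = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(np), con)
    writeLines(sprintf("time=%.9g flags=%s", traj$times[f],
                       paste(as.integer(traj$flags[f, ]), collapse = "")), con)
    xyz <- traj$coords[f, , , drop = FALSE]
    writeLines(sprintf("%s %.9g %.9g %.9g", traj$labels,
                       xyz[1, , 1], xyz[1, , 2], xyz[1, , 3]), con)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @param box optional [periodic_box()] to attach on read.
#' @export
read_trajectory <- function(file, box = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty trajectory file", call. = FALSE)
  i <- 1L; frame <- 0L
  times <- numeric(0)
  frames <- list()
  flags <- list()
  labels <- NULL
  np0 <- NA_integer_
  while (i <= length(lines)) {
    frame <- frame + 1L
    np <- suppressWarnings(as.integer(lines[i]))
    if (is.na(np) || np < 1L) {
      stop(sprintf("frame %d: expected an atom count, got '%s'", frame, lines[i]),
           call. = FALSE)
    }
    if (is.na(np0)) np0 <- np
    if (np != np0) {
      stop(sprintf("frame %d: atom count %d differs from first frame (%d)",
                   frame, np, np0), call. = FALSE)
    }
    if (i + 1L + np > length(lines)) {
      stop(sprintf("frame %d: truncated file", frame), call. = FALSE)
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) < 2L) stop(sprintf("frame %d: comment line lacks time=", frame),
                              call. = FALSE)
    times[frame] <- as.numeric(tm[2])
    fm <- regmatches(comment, regexec("flags=([01]+)", comment))[[1]]
    fl <- if (length(fm) >= 2L) {
      as.integer(strsplit(fm[2], "")[[1]]) == 1L
    } else rep(FALSE, np)
    body <- lines[(i + 2L):(i + 1L + np)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    lab <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop(sprintf("frame %d: malformed coordinate line", frame),
                         call. = FALSE)
    if (is.null(labels)) labels <- lab
    frames[[frame]] <- xyz
    flags[[frame]] <- fl
    i <- i + 2L + np
  }
  coords <- array(0, dim = c(frame, np0, 3))
  flg <- matrix(FALSE, frame, np0)
  for (f in seq_len(frame)) {
    coords[f, , ] <- frames[[f]]
    flg[f, ] <- flags[[f]]
  }
  trajectory(times, coords, labels, flg, box)
}

#' Write an analysis table as CSV
#'
#' Plain CSV with a header row; the standard sink for distance series, RDF
#' tables and conformer series.
#'
#' @param df data frame.
#' @param file output path.
#' @export
write_analysis_csv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write / read binding events as JSON lines
#'
#' One JSON object per line per event, with fields ligand, start, end,
#' residency (times in ps).
#'
#' @param events data frame as returned by [detect_binding_events()].
#' @param file path.
#' @export
write_events_jsonl <- function(events, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      writeLines(as.character(jsonlite::toJSON(as.list(events[i, ]),
                                               auto_unbox = TRUE, digits = NA)), con)
    }
  }
  invisible(file)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(ligand = character(0), start = numeric(0),
                      end = numeric(0), residency = numeric(0)))
  }
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
}
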