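# Trajectory and structure I/O.
#
# Coordinates are in Angstrom throughout. A "structure" is a list with a
# topology table and a coords array [frames x atoms x 3]; a trajectory
# ensemble keeps one coords array per trajectory so that time-lagged
# statistics never cross a trajectory boundary.

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  # Strip leading digits (e.g. "1HB"), then greek/remoteness suffixes.
  nm <- sub("^[0-9]+", "", nm)
  if (nm == "") return("")
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE") && nchar(nm) == 2) return(two)
  substr(nm, 1, 1)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns); multiple MODEL blocks become
#' frames. Only one topology is kept: all models must have the same atoms.
#'
#' @param path Path to a PDB file.
#' @return A list with `topology` (data.frame: serial, name, resname, chain,
#'   resid, element, serial_resid) and `coords` (array frames x atoms x 3, in
#'   Angstrom). `serial_resid` numbers residues contiguously across chains in
#'   order of appearance, the convention used for loop selections when no
#'   chain qualifier is given.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), "format_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) abort(paste0("no ATOM records in ", path), "format_error")
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  model_id[model_id == 0L] <- 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  models <- split(atom_lines, atom_model)
  n_atoms <- length(models[[1]])
  if (any(vapply(models, length, integer(1)) != n_atoms)) {
    abort("MODEL blocks have differing atom counts", "format_error")
  }
  parse_block <- function(bl) {
    cbind(as.numeric(substr(bl, 31, 38)),
          as.numeric(substr(bl, 39, 46)),
          as.numeric(substr(bl, 47, 54)))
  }
  first <- models[[1]]
  elem_col <- trimws(substr(first, 77, 78))
  name <- trimws(substr(first, 13, 16))
  element <- ifelse(elem_col == "", vapply(name, guess_element, character(1)), toupper(elem_col))
  topology <- data.frame(
    serial = as.integer(substr(first, 7, 11)),
    name = name,
    resname = trimws(substr(first, 18, 20)),
    chain = substr(first, 22, 22),
    resid = as.integer(substr(first, 23, 26)),
    element = unname(element),
    stringsAsFactors = FALSE
  )
  key <- paste(topology$chain, topology$resid, sep = "|")
  topology$serial_resid <- as.integer(factor(key, levels = unique(key)))
  coords <- array(NA_real_, dim = c(length(models), n_atoms, 3))
  for (i in seq_along(models)) coords[i, , ] <- parse_block(models[[i]])
  if (!all(is.finite(coords))) abort(paste0("non-finite coordinates in ", path), "format_error")
  list(topology = topology, coords = coords)
}

#' Write a structure or multi-frame trajectory as PDB
#'
#' @param topology Topology data.frame as returned by [read_pdb()].
#' @param coords Array frames x atoms x 3 (or a single atoms x 3 matrix).
#' @param path Output path.
#' @export
write_pdb <- function(topology, coords, path) {
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(1, dim(coords)))
  n_frames <- dim(coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  fmt_name <- function(nm) {
    # PDB convention: atom names of <4 chars start in column 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  for (f in seq_len(n_frames)) {
    if (n_frames > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     topology$serial %% 100000, fmt_name(topology$name),
                     substr(topology$resname, 1, 3), topology$chain, topology$resid,
                     coords[f, , 1], coords[f, , 2], coords[f, , 3], topology$element)
    writeLines(lines, con)
    if (n_frames > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- DCD (X-PLOR style, float32, Fortran unformatted records) ---------------

read_record <- function(con, what, size, endian) {
  n1 <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(n1) == 0) return(NULL)
  nv <- n1 / size
  dat <- readBin(con, what, nv, size = size, endian = endian)
  n2 <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(n2) == 0 || n2 != n1) abort("corrupt DCD record", "format_error")
  dat
}

#' Read a DCD trajectory file
#'
#' Supports the CHARMM/X-PLOR DCD layout with single-precision coordinates;
#' unit-cell blocks (CHARMM extra block flag) are skipped. Endianness is
#' auto-detected.
#'
#' @param path Path to a DCD file.
#' @return Array frames x atoms x 3 (Angstrom).
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- if (identical(first, 84L)) "little" else "big"
  seek(con, 0)
  hdr_len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_len != 84) abort("not a DCD file (bad header length)", "format_error")
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") abort("not a DCD file (missing CORD magic)", "format_error")
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  n_frames_hdr <- icntrl[1]
  has_cell <- icntrl[11] == 1
  invisible(read_record(con, "integer", 4, endian))        # title block
  natom <- read_record(con, "integer", 4, endian)
  if (length(natom) != 1) abort("corrupt DCD natom record", "format_error")
  frames <- list()
  repeat {
    if (has_cell) {
      cell <- read_record(con, "double", 8, endian)
      if (is.null(cell)) break
    }
    x <- read_record(con, "double", 4, endian)
    if (is.null(x)) break
    y <- read_record(con, "double", 4, endian)
    z <- read_record(con, "double", 4, endian)
    if (length(x) != natom || length(y) != natom || length(z) != natom) {
      abort("corrupt DCD coordinate record", "format_error")
    }
    frames[[length(frames) + 1]] <- cbind(x, y, z)
  }
  if (length(frames) == 0) abort("DCD contains no frames", "format_error")
  if (n_frames_hdr > 0 && length(frames) != n_frames_hdr) {
    warning(sprintf("DCD header declares %d frames but %d were read", n_frames_hdr, length(frames)))
  }
  coords <- array(NA_real_, dim = c(length(frames), natom, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  coords
}

#' Write a DCD trajectory file (X-PLOR style, float32)
#'
#' @param coords Array frames x atoms x 3.
#' @param path Output path.
#' @export
write_dcd <- function(coords, path) {
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(1, dim(coords)))
  n_frames <- dim(coords)[1]; natom <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  put_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  put_int(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n_frames
  put_int(icntrl)
  put_int(84)
  title <- format("Created by loopmsm", width = 80)
  put_int(4 + 80); put_int(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  put_int(4 + 80)
  put_int(4); put_int(natom); put_int(4)
  nb <- 4 * natom
  for (f in seq_len(n_frames)) {
    for (ax in 1:3) {
      put_int(nb)
      writeBin(as.numeric(coords[f, , ax]), con, size = 4, endian = "little")
      put_int(nb)
    }
  }
  invisible(path)
}

#' Load a trajectory ensemble
#'
#' Reads one or more trajectory files (DCD, or multi-MODEL PDB) against a
#' common PDB topology. Trajectory boundaries are preserved: downstream
#' time-lagged statistics never pair frames across trajectories.
#'
#' @param paths Character vector of trajectory file paths.
#' @param topology Path to the PDB topology (its first model supplies the
#'   atom table).
#' @param frame_interval Time between saved frames in nanoseconds (> 0).
#'   Must be supplied by the user; it is not stored in DCD/PDB files.
#' @param labels Optional per-trajectory names (default: file basenames).
#' @return A `trajectory_ensemble`: list(coords = list of frames x atoms x 3
#'   arrays, topology, frame_interval, labels).
#' @export
load_ensemble <- function(paths, topology, frame_interval, labels = NULL) {
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be a positive number of nanoseconds", "argument_error")
  }
  top <- read_pdb(topology)$topology
  n_atoms <- nrow(top)
  coords <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    ext <- tolower(tools::file_ext(p))
    tr <- switch(ext,
      dcd = read_dcd(p),
      pdb = read_pdb(p)$coords,
      abort(paste0("unsupported trajectory format: ", p), "format_error")
    )
    if (dim(tr)[2] != n_atoms) {
      abort(sprintf("atom count mismatch: topology has %d atoms, %s has %d",
                    n_atoms, p, dim(tr)[2]), "topology_error")
    }
    if (!all(is.finite(tr))) abort(paste0("non-finite coordinates in ", p), "format_error")
    coords[[i]] <- tr
  }
  if (is.null(labels)) labels <- basename(unlist(paths))
  structure(list(coords = coords, topology = top,
                 frame_interval = frame_interval, labels = labels),
            class = "trajectory_ensemble")
}

#' Build a trajectory ensemble from in-memory coordinates
#'
#' @param coords List of frames x atoms x 3 arrays.
#' @param topology Topology data.frame (see [read_pdb()]).
#' @param frame_interval Frame spacing in ns.
#' @param labels Optional names.
#' @export
ensemble_from_arrays <- function(coords, topology, frame_interval, labels = NULL) {
  if (length(dim(coords[[1]])) != 3) abort("coords must be frames x atoms x 3 arrays", "argument_error")
  if (is.null(topology$serial_resid)) {
    key <- paste(topology$chain, topology$resid, sep = "|")
    topology$serial_resid <- as.integer(factor(key, levels = unique(key)))
  }
  if (is.null(labels)) labels <- paste0("traj", seq_along(coords))
  structure(list(coords = coords, topology = topology,
                 frame_interval = frame_interval, labels = labels),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  n <- vapply(x$coords, function(a) dim(a)[1], integer(1))
  cat(sprintf("<trajectory_ensemble> %d trajectories, %d atoms, frame interval %g ns\n",
              length(n), nrow(x$topology), x$frame_interval))
  cat("  frames per trajectory:", paste(n, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames per trajectory
#' @param ensemble A `trajectory_ensemble`.
#' @export
n_frames <- function(ensemble) {
  vapply(ensemble$coords, function(a) dim(a)[1], integer(1))
}

#' Select loop residues and their atoms
#'
#' Parses inclusive residue ranges such as `"92-97,205-210"` (contiguous
#' serial numbering across chains, alpha then beta, as crystallographic
#' tables for paired-chain receptors often use) or `"A:92-97,B:205-210"`
#' (author numbering within the named chain).
#'
#' @param x A `trajectory_ensemble` or a topology data.frame.
#' @param spec Residue-range text.
#' @return A `loop_selection`: residues table plus atom index vectors
#'   `atoms` (all), `backbone` (N, CA, C, O), `heavy` (non-hydrogen).
#' @export
select_loop <- function(x, spec) {
  top <- if (inherits(x, "trajectory_ensemble")) x$topology else x
  if (!is.character(spec) || length(spec) != 1 || !nzchar(trimws(spec))) {
    abort("empty residue-range specification", "selection_error")
  }
  parts <- trimws(strsplit(spec, ",")[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) abort("empty residue-range specification", "selection_error")
  keep <- logical(nrow(top))
  for (p in parts) {
    m <- regmatches(p, regexec("^(?:([A-Za-z0-9]):)?(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse residue range: '", p, "'"), "selection_error")
    chain <- m[2]; lo <- as.integer(m[3])
    hi <- if (m[4] == "") lo else as.integer(m[4])
    if (hi < lo) abort(paste0("descending residue range: '", p, "'"), "selection_error")
    for (r in lo:hi) {
      hit <- if (chain == "") top$serial_resid == r else top$chain == chain & top$resid == r
      if (!any(hit)) {
        abort(sprintf("residue %s%d not present in topology",
                      if (chain == "") "" else paste0(chain, ":"), r), "selection_error")
      }
      keep <- keep | hit
    }
  }
  idx <- which(keep)
  res <- unique(top[idx, c("chain", "resid", "resname", "serial_resid")])
  rownames(res) <- NULL
  structure(list(
    residues = res,
    atoms = idx,
    backbone = idx[top$name[idx] %in% c("N", "CA", "C", "O")],
    heavy = idx[top$element[idx] != "H"],
    spec = spec
  ), class = "loop_selection")
}

#' @export
print.loop_selection <- function(x, ...) {
  cat(sprintf("<loop_selection> '%s': %d residues, %d atoms (%d backbone)\n",
              x$spec, nrow(x$residues), length(x$atoms), length(x$backbone)))
  invisible(x)
}
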