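#' @title Structure and trajectory I/O
#' @description Readers and writers for PDB and GRO structures and for
#'   multi-frame GRO and DCD trajectories. PDB coordinates (Angstrom) are
#'   converted to nm on input; GRO files are already in nm. PDB parsing and
#'   DCD reading are delegated to bio3d; GRO parsing and DCD writing are
#'   implemented here. XTC and TRR are rejected with a clear error.
#' @name trajectory-io
NULL

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  if (ext == "dcd") return("dcd")
  if (ext %in% c("xtc", "trr")) return(ext)
  stop("cannot infer file format from extension '.", ext, "'")
}

infer_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  ifelse(nchar(stripped) > 0, toupper(substr(stripped, 1L, 1L)), "X")
}

#' Load a structure file (PDB or GRO)
#'
#' @param path file path
#' @param format `"pdb"`, `"gro"` or `"auto"` (extension-based)
#' @return list with elements `topology` (`vw_topology`) and `frame`
#'   (`vw_frame`, coordinates in nm). For PDB files without a CRYST1 record
#'   the frame box is the coordinate bounding box plus a 2 nm margin.
#' @export
load_structure <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("file is empty: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    pdb = load_pdb(path),
    gro = load_gro_structure(path),
    stop("unsupported structure format '", format, "'")
  )
}

load_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("PDB file contains no atoms: ", path)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- infer_element(at$elety[bad])
  atoms <- data.frame(name = at$elety, element = toupper(trimws(elem)),
                      resname = at$resid, resid = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  topology <- vw_topology(atoms)
  xyz <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  box <- read_cryst1(path)
  if (is.null(box)) box <- apply(xyz, 2, function(v) diff(range(v))) + 2
  list(topology = topology, frame = vw_frame(xyz, box))
}

read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(NULL)
  a <- as.numeric(substr(cl[1L], 7, 15))
  b <- as.numeric(substr(cl[1L], 16, 24))
  c_ <- as.numeric(substr(cl[1L], 25, 33))
  angles <- c(as.numeric(substr(cl[1L], 34, 40)),
              as.numeric(substr(cl[1L], 41, 47)),
              as.numeric(substr(cl[1L], 48, 54)))
  if (any(is.na(c(a, b, c_))) || any(a <= 0)) return(NULL)
  if (any(abs(angles - 90) > 1e-3)) {
    stop("triclinic unit cell in PDB is not supported")
  }
  c(a, b, c_) / 10
}

parse_gro_block <- function(lines, start) {
  title <- lines[start]
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms) || natoms < 1L) {
    stop("malformed GRO atom count at line ", start + 1L)
  }
  atom_lines <- lines[(start + 2L):(start + 1L + natoms)]
  box_line <- lines[start + 2L + natoms]
  resid <- as.integer(substr(atom_lines, 1, 5))
  resname <- trimws(substr(atom_lines, 6, 10))
  name <- trimws(substr(atom_lines, 11, 15))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  if (any(is.na(c(x, y, z))) || any(is.na(resid))) {
    stop("malformed GRO atom record near line ", start + 2L)
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1L]]))
  if (length(box) >= 9L) {
    if (any(abs(box[4:9]) > 1e-9)) stop("triclinic GRO box not supported")
    box <- box[1:3]
  }
  if (length(box) != 3L || any(is.na(box))) {
    stop("malformed GRO box line near line ", start + 2L + natoms)
  }
  tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1L]]
  time <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
  list(natoms = natoms, resid = resid, resname = resname, name = name,
       xyz = cbind(x, y, z), box = box, time = time,
       next_start = start + 3L + natoms)
}

load_gro_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  blk <- parse_gro_block(lines, 1L)
  atoms <- data.frame(name = blk$name, element = infer_element(blk$name),
                      resname = blk$resname, resid = blk$resid,
                      chain = "A", stringsAsFactors = FALSE)
  time <- if (is.na(blk$time)) 0 else blk$time
  list(topology = vw_topology(atoms),
       frame = vw_frame(blk$xyz, blk$box, time))
}

#' Load a trajectory (multi-frame GRO or DCD)
#'
#' @param topology `vw_topology` the frames belong to; the file's atom count
#'   must match.
#' @param path trajectory file
#' @param format `"gro"`, `"dcd"` or `"auto"`
#' @param spacing_ps frame spacing in ps. Required for DCD (the format does
#'   not carry reliable per-frame times); for GRO it is only used when the
#'   frame titles carry no `t=` stamps.
#' @param t0_ps time of the first frame when times must be synthesized.
#' @return a `vw_trajectory`
#' @export
load_trajectory <- function(topology, path, format = "auto",
                            spacing_ps = NULL, t0_ps = 0) {
  stopifnot(inherits(topology, "vw_topology"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format %in% c("xtc", "trr")) {
    stop("XTC/TRR trajectories are not supported; convert to DCD or ",
         "multi-frame GRO")
  }
  traj <- switch(format,
    gro = load_gro_trajectory(topology, path, spacing_ps, t0_ps),
    dcd = load_dcd_trajectory(topology, path, spacing_ps, t0_ps),
    stop("unsupported trajectory format '", format, "'")
  )
  traj
}

load_gro_trajectory <- function(topology, path, spacing_ps, t0_ps) {
  lines <- readLines(path, warn = FALSE)
  start <- 1L
  coords <- list(); boxes <- list(); times <- numeric(0)
  while (start <= length(lines) && nzchar(trimws(lines[start]))) {
    blk <- parse_gro_block(lines, start)
    if (blk$natoms != topology$n_atoms) {
      stop("trajectory frame has ", blk$natoms, " atoms but topology has ",
           topology$n_atoms)
    }
    coords[[length(coords) + 1L]] <- blk$xyz
    boxes[[length(boxes) + 1L]] <- blk$box
    times <- c(times, blk$time)
    start <- blk$next_start
  }
  if (length(coords) == 0L) stop("no frames found in ", path)
  if (any(is.na(times))) {
    if (is.null(spacing_ps)) {
      stop("GRO frames carry no 't=' time stamps; supply spacing_ps")
    }
    times <- t0_ps + (seq_along(coords) - 1L) * spacing_ps
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times in ", path, " are not strictly increasing")
  }
  vw_trajectory(topology,
                array(unlist(coords),
                      dim = c(topology$n_atoms, 3L, length(coords))),
                do.call(rbind, boxes), times)
}

load_dcd_trajectory <- function(topology, path, spacing_ps, t0_ps) {
  if (is.null(spacing_ps)) {
    stop("DCD files carry no per-frame times; supply spacing_ps")
  }
  xyz <- bio3d::read.dcd(path, verbose = FALSE, cell = FALSE)
  cell <- bio3d::read.dcd(path, verbose = FALSE, cell = TRUE)
  nfr <- nrow(xyz)
  natoms <- ncol(xyz) / 3L
  if (natoms != topology$n_atoms) {
    stop("trajectory has ", natoms, " atoms but topology has ",
         topology$n_atoms)
  }
  coords <- array(NA_real_, dim = c(natoms, 3L, nfr))
  for (i in seq_len(nfr)) {
    coords[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10
  }
  if (any(abs(cell[, 4:6] - 90) > 1e-3)) {
    stop("triclinic DCD unit cell not supported")
  }
  boxes <- cell[, 1:3, drop = FALSE] / 10
  times <- t0_ps + (seq_len(nfr) - 1L) * spacing_ps
  vw_trajectory(topology, coords, boxes, times)
}

#' Write a trajectory to disk
#'
#' @param traj a `vw_trajectory`
#' @param path output path (`.gro` or `.dcd`)
#' @param format `"gro"`, `"dcd"` or `"auto"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = "auto") {
  stopifnot(inherits(traj, "vw_trajectory"))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    gro = write_gro_trajectory(traj, path),
    dcd = write_dcd(traj$coords, traj$box, path),
    stop("unsupported trajectory output format '", format, "'")
  )
  invisible(path)
}

format_gro_frame <- function(topology, xyz, box, time) {
  at <- topology$atoms
  n <- nrow(at)
  header <- sprintf("synthetic frame t= %.4f", time)
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  at$resid %% 100000L, substr(at$resname, 1, 5),
                  substr(at$name, 1, 5), seq_len(n) %% 100000L,
                  xyz[, 1L], xyz[, 2L], xyz[, 3L])
  c(header, sprintf("%5d", n), recs,
    sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
}

write_gro_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(traj$n_frames)) {
    writeLines(format_gro_frame(traj$topology, traj$coords[, , i],
                                traj$box[i, ], traj$times[i]), con)
  }
}

#' Write a structure (topology + frame) as GRO
#' @param topology a `vw_topology`
#' @param frame a `vw_frame`
#' @param path output `.gro` path
#' @return `path`, invisibly
#' @export
write_gro_structure <- function(topology, frame, path) {
  writeLines(format_gro_frame(topology, frame$xyz, frame$box, frame$time),
             path)
  invisible(path)
}

#' Write a structure (topology + frame) as PDB
#'
#' Optionally stores a per-atom scalar (e.g. RMSF in nm, scaled by 10 to
#' match the Angstrom convention) in the B-factor column for thickness or
#' putty rendering.
#'
#' @param topology a `vw_topology`
#' @param frame a `vw_frame`
#' @param path output `.pdb` path
#' @param bfactor optional per-atom numeric vector for the B-factor column
#' @return `path`, invisibly
#' @export
write_pdb_structure <- function(topology, frame, path, bfactor = NULL) {
  at <- topology$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(at))
  if (length(bfactor) != nrow(at)) {
    stop("bfactor must have one value per atom")
  }
  xyz_ang <- as.vector(t(frame$xyz * 10))
  bio3d::write.pdb(file = path, xyz = xyz_ang, resno = at$resid,
                   resid = at$resname, eleno = seq_len(nrow(at)),
                   elety = at$name, chain = at$chain, o = rep(1, nrow(at)),
                   b = bfactor)
  # prepend a CRYST1 record so the box survives the round trip
  lines <- readLines(path, warn = FALSE)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   frame$box[1L] * 10, frame$box[2L] * 10,
                   frame$box[3L] * 10, 90, 90, 90)
  writeLines(c(cryst, lines), path)
  invisible(path)
}

# CHARMM-style DCD writer. Coordinates in the file are Angstrom; the unit
# cell block stores (a, cos(gamma), b, cos(beta), cos(alpha), c).
write_dcd <- function(coords_nm, box_nm, path) {
  n_atoms <- dim(coords_nm)[1L]
  nfr <- dim(coords_nm)[3L]
  if (is.null(dim(box_nm))) box_nm <- matrix(box_nm, nfr, 3L, byrow = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # writer fills a raw connection; wrap with Fortran record markers
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1L] <- nfr; icntrl[2L] <- 1L; icntrl[3L] <- 1L; icntrl[4L] <- nfr
  icntrl[11L] <- 1L  # unit-cell block present
  icntrl[20L] <- 24L # CHARMM version tag
  wrec(function(c_) {
    writeChar("CORD", c_, nchars = 4L, eos = NULL)
    writeBin(icntrl, c_, size = 4L)
  })
  wrec(function(c_) {
    writeBin(1L, c_, size = 4L)
    writeChar(formatC("synthetic trajectory", width = -80), c_,
              nchars = 80L, eos = NULL)
  })
  wrec(function(c_) writeBin(as.integer(n_atoms), c_, size = 4L))
  for (i in seq_len(nfr)) {
    b <- box_nm[i, ] * 10
    wrec(function(c_) writeBin(c(b[1L], 0, b[2L], 0, 0, b[3L]), c_,
                               size = 8L))
    xyz <- coords_nm[, , i] * 10
    for (k in 1:3) {
      wrec(function(c_) writeBin(as.numeric(xyz[, k]), c_, size = 4L))
    }
  }
  invisible(path)
}
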