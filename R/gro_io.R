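#' Read coarse-grained frames from a GRO coordinate file
#'
#' Reads single- or multi-frame fixed-column GRO files (GROMACS coordinate
#' format, positions in nm) and returns frames with coordinates in Angstrom.
#' The frame time is taken from a `t=` tag in the title line (ps, converted
#' to ns) when present, otherwise set to the 0-based frame index.
#'
#' @param path readable GRO file.
#' @param stride keep every `stride`-th frame, starting from the first.
#' @return list of [cg_frame()] objects in file order.
#' @export
read_gro_frames <- function(path, stride = 1L) {
  stopifnot(length(stride) == 1L, stride >= 1L, stride == as.integer(stride))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file: missing atom count after line ", i)
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 0L)
      stop("malformed atom-count line at line ", i + 1L)
    if (i + 1L + natoms + 1L > length(lines))
      stop("truncated GRO file: missing box line for frame starting at line ", i)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    frame <- parse_gro_block(title, atom_lines, box_line, i + 1L, idx)
    if (idx %% stride == 0L) frames[[length(frames) + 1L]] <- frame
    idx <- idx + 1L
    i <- i + natoms + 3L
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

parse_gro_block <- function(title, atom_lines, box_line, offset, idx) {
  f <- function(line, from, to) substr(line, from, to)
  resid <- suppressWarnings(as.integer(f(atom_lines, 1, 5)))
  resname <- trimws(f(atom_lines, 6, 10))
  bead <- trimws(f(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(f(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(f(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(f(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z) | !nzchar(bead))
  if (length(bad))
    stop("malformed GRO record at line ", offset + bad[1])
  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop("malformed or missing box line at line ", offset + length(atom_lines) + 1L)
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) / 1000 else idx
  cg_frame(
    beads = data.frame(bead = bead, resname = resname, resid = resid,
                       x = x * 10, y = y * 10, z = z * 10),
    box = box[1:3] * 10, time = time)
}

#' Write frames to a GRO coordinate file
#'
#' Inverse of [read_gro_frames()]: Angstrom coordinates are written in nm at
#' the format's fixed precision (0.001 nm = 0.01 Angstrom). Frame times are
#' written as `t=` tags in ps.
#'
#' @param frames a [cg_frame()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gro_frames <- function(frames, path) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    b <- fr$beads
    n <- nrow(b)
    writeLines(sprintf("synthetic bilayer t= %.4f", fr$time * 1000), con)
    writeLines(sprintf("%5d", n), con)
    atomno <- (seq_len(n) - 1L) %% 99999L + 1L
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$resid %% 100000L, b$resname, b$bead, atomno,
                       b$x / 10, b$y / 10, b$z / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10), con)
  }
  invisible(path)
}
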