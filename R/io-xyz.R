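#' Read an XYZ file
#'
#' Standard XYZ dialect: count line, free-form comment line, then
#' `element x y z` rows in angstrom. Multi-frame files are allowed; each frame
#' becomes one list element with fields `comment` and `atoms`.
#'
#' @param path File path.
#' @return List of frames, each `list(comment =, atoms = tibble)`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      abort(sprintf("%s: malformed atom count at line %d", path, i),
            class = "saptfit_parse_error")
    }
    if (i + 1 + n > length(lines)) {
      abort(sprintf("%s: frame starting at line %d declares %d atoms but file ends early",
                    path, i, n), class = "saptfit_parse_error")
    }
    comment <- lines[i + 1]
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad) > 0) {
      abort(sprintf("%s: malformed atom row at line %d", path, i + 1 + bad[1]),
            class = "saptfit_parse_error")
    }
    el <- vapply(parts, `[[`, "", 1)
    if (!all(el %in% ELEMENTS)) {
      j <- which(!el %in% ELEMENTS)[1]
      abort(sprintf("%s: unknown element '%s' at line %d", path, el[j],
                    i + 1 + j), class = "saptfit_parse_error")
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) {
      abort(sprintf("%s: non-numeric coordinate in frame starting at line %d",
                    path, i), class = "saptfit_parse_error")
    }
    frames[[length(frames) + 1]] <- list(
      comment = comment,
      atoms = tibble::tibble(element = el, x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3])
    )
    i <- i + 2 + n
  }
  frames
}

#' Write monomers or atom tables to an XYZ file
#'
#' @param frames List of frames (`list(comment =, atoms =)`), or a single
#'   [sapt_monomer()] / [sapt_dimer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "sapt_monomer")) {
    frames <- list(list(comment = paste0("name=", frames$name),
                        atoms = frames$atoms))
  } else if (inherits(frames, "sapt_dimer")) {
    frames <- list(dimer_frame(frames))
  }
  out <- character(0)
  for (fr in frames) {
    at <- fr$atoms
    out <- c(out, as.character(nrow(at)), fr$comment,
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     at$element, at$x, at$y, at$z))
  }
  writeLines(out, path)
  invisible(path)
}

dimer_frame <- function(dimer) {
  list(
    comment = sprintf("name=%s natoms_a=%d", dimer$name, nrow(dimer$a$atoms)),
    atoms = dplyr::bind_rows(dimer$a$atoms[, c("element", "x", "y", "z")],
                             dimer$b$atoms[, c("element", "x", "y", "z")])
  )
}

comment_field <- function(comment, key) {
  m <- regmatches(comment,
                  regexec(paste0(key, "=([^[:space:]]+)"), comment))[[1]]
  if (length(m) < 2) NULL else m[2]
}

#' Read a dimer geometry from an XYZ file
#'
#' The comment line must carry a `natoms_a=<k>` marker splitting the frame
#' into monomer A (first k atoms) and monomer B; a `name=` field is used when
#' present.
#'
#' @param path File path.
#' @param frame Frame index for multi-frame files (default 1).
#' @return A [sapt_dimer()] (untyped, no properties).
#' @export
read_dimer_xyz <- function(path, frame = 1) {
  fr <- read_xyz(path)[[frame]]
  ka <- comment_field(fr$comment, "natoms_a")
  if (is.null(ka)) {
    abort(sprintf("%s: dimer file lacks natoms_a marker in comment line", path),
          class = "saptfit_parse_error")
  }
  ka <- as.integer(ka)
  n <- nrow(fr$atoms)
  if (is.na(ka) || ka < 1 || ka >= n) {
    abort(sprintf("%s: invalid natoms_a marker", path),
          class = "saptfit_parse_error")
  }
  name <- comment_field(fr$comment, "name")
  if (is.null(name)) name <- "dimer"
  sapt_dimer(
    sapt_monomer(fr$atoms[seq_len(ka), ], name = paste0(name, "_a")),
    sapt_monomer(fr$atoms[(ka + 1):n, ], name = paste0(name, "_b")),
    name = name
  )
}
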