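#' Write a dataset manifest to disk
#'
#' Serializes a dataset tibble as a directory tree: dimer geometries as
#' multi-atom XYZ files with the monomer split marked in the comment line,
#' per-monomer property sidecars, reference component energies as delimited
#' text, and a YAML manifest listing every entry with its subgroup tags and
#' file paths.
#'
#' @param manifest Dataset tibble with a `dimer` list-column.
#' @param dir Output directory (created if needed).
#' @param name Dataset identifier stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir, name = "dataset") {
  if (anyDuplicated(manifest$name)) {
    abort("manifest entry names must be unique",
          class = "saptfit_manifest_error")
  }
  dir.create(file.path(dir, "xyz"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "props"), showWarnings = FALSE)
  entries <- list()
  energies <- list()
  for (i in seq_len(nrow(manifest))) {
    d <- manifest$dimer[[i]]
    nm <- manifest$name[i]
    write_xyz(d, file.path(dir, "xyz", paste0(nm, ".xyz")))
    write_properties(d$a$properties, file.path(dir, "props",
                                               paste0(nm, "_a.yaml")),
                     name = d$a$name)
    write_properties(d$b$properties, file.path(dir, "props",
                                               paste0(nm, "_b.yaml")),
                     name = d$b$name)
    entries[[i]] <- list(
      name = nm,
      xyz = file.path("xyz", paste0(nm, ".xyz")),
      props_a = file.path("props", paste0(nm, "_a.yaml")),
      props_b = file.path("props", paste0(nm, "_b.yaml")),
      group_a = d$a$group_class, group_b = d$b$group_class,
      subgroup = manifest$subgroup[i], hbond = manifest$hbond[i]
    )
    if (!is.null(d$reference)) {
      energies[[length(energies) + 1]] <-
        dplyr::bind_cols(tibble::tibble(name = nm), d$reference)
    }
  }
  yaml::write_yaml(list(name = name, entries = entries),
                   file.path(dir, "manifest.yaml"))
  if (length(energies) > 0) {
    en <- dplyr::bind_rows(energies)
    en[-1] <- lapply(en[-1], function(x) sprintf("%.17g", x))
    write.table(en, file.path(dir, "energies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset manifest from disk
#'
#' Inverse of [write_manifest()]: reloads geometries, property sidecars and
#' reference energies, re-perceives bonds and atom types, and rebuilds the
#' dataset tibble. Every referenced file must resolve.
#'
#' @param dir Directory containing `manifest.yaml`.
#' @return Dataset tibble with a `dimer` list-column.
#' @export
read_manifest <- function(dir) {
  doc <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  energies <- NULL
  en_path <- file.path(dir, "energies.tsv")
  if (file.exists(en_path)) {
    energies <- read.delim(en_path, sep = "\t", stringsAsFactors = FALSE)
  }
  rows <- purrr::map(doc$entries, function(e) {
    for (f in c(e$xyz, e$props_a, e$props_b)) {
      if (!file.exists(file.path(dir, f))) {
        abort(sprintf("manifest entry '%s' references missing file %s",
                      e$name, f), class = "saptfit_manifest_error")
      }
    }
    d <- read_dimer_xyz(file.path(dir, e$xyz))
    d$name <- e$name
    d$a$group_class <- e$group_a
    d$b$group_class <- e$group_b
    d$a$properties <- read_properties(file.path(dir, e$props_a),
                                      n_atoms = nrow(d$a$atoms))
    d$b$properties <- read_properties(file.path(dir, e$props_b),
                                      n_atoms = nrow(d$b$atoms))
    d$a <- assign_atom_types(d$a)
    d$b <- assign_atom_types(d$b)
    if (!is.null(energies) && e$name %in% energies$name) {
      d$reference <- as_components(energies[energies$name == e$name,
                                            c(COMPONENTS, "total")])
    }
    dimer_manifest_row(d)
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    abort("manifest entry names must be unique",
          class = "saptfit_manifest_error")
  }
  out
}
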