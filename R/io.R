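#' Load a PDB structure as a one-bead-per-residue model
#'
#' Reads a standard PDB file (ATOM records; HETATM is ignored) and reduces it
#' to one bead per residue. The bead sits at the centroid of the side-chain
#' heavy atoms; for glycine (or any residue with no side-chain heavy atoms)
#' the C-alpha position is used. Charges and classes follow the pH 7.4 scheme
#' of [classify_residue()].
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier; defaults to all chains.
#' @param radii Optional named numeric vector of per-residue bead radii in
#'   Angstrom (names are 3-letter codes); residues not named fall back to the
#'   generic default of 2.64 A.
#' @param label Model label; defaults to the file name.
#' @return A [bead_model()].
#' @export
load_structure <- function(path, chain = NULL, radii = NULL, label = NULL) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ", conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # drop hydrogens
  at <- at[is.na(at$elesy) | trimws(at$elesy) != "H", , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0) abort(paste0("chain '", chain, "' not present or empty in ", path))
  }
  if (nrow(at) == 0) abort(paste0("no ATOM records in ", path))
  bad <- setdiff(unique(at$resid), .standard_aa)
  if (length(bad) > 0) {
    abort(paste0("unknown residue name(s) in ", path, ": ", paste(bad, collapse = ", ")))
  }

  backbone <- c("N", "CA", "C", "O", "OXT")
  at$key <- paste(at$chain, at$resno, sep = "|")
  keys <- unique(at$key)
  rows <- lapply(keys, function(k) {
    sub <- at[at$key == k, , drop = FALSE]
    side <- sub[!(trimws(sub$elety) %in% backbone), , drop = FALSE]
    if (nrow(side) == 0) side <- sub[trimws(sub$elety) == "CA", , drop = FALSE]
    if (nrow(side) == 0) side <- sub
    tibble(
      residue_index = sub$resno[1],
      residue_name = toupper(sub$resid[1]),
      chain_id = sub$chain[1],
      x = mean(side$x), y = mean(side$y), z = mean(side$z)
    )
  })
  beads <- dplyr::bind_rows(rows)
  beads <- beads[order(beads$chain_id, beads$residue_index), ]
  r <- rep(.default_bead_radius, nrow(beads))
  if (!is.null(radii)) {
    hit <- match(beads$residue_name, names(radii))
    r[!is.na(hit)] <- radii[hit[!is.na(hit)]]
  }
  beads$radius <- r
  bead_model(beads, label = label %||% basename(path))
}

#' Write a bead model as a pseudo-atom PDB file
#'
#' Each bead becomes one ATOM record (atom name CA, element C, occupancy
#' 1.00), so the model can be inspected in any molecular viewer and
#' round-trips through [load_structure()].
#'
#' @param model A `bead_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  xyz <- as.numeric(t(bead_coords(model)))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = model$residue_index,
    resid = model$residue_name,
    chain = model$chain_id,
    elety = rep("CA", nrow(model)),
    o = rep(1, nrow(model)),
    b = rep(0, nrow(model)),
    elesy = rep("C", nrow(model))
  )
  invisible(path)
}

#' Write / read the flat CSV form of a bead model
#'
#' Columns: residue_index, name, chain, x, y, z, radius, charge, class,
#' segment.
#'
#' @param model A `bead_model`.
#' @param path CSV file path.
#' @return `write_bead_csv()` returns `path` invisibly; `read_bead_csv()`
#'   returns a [bead_model()].
#' @export
write_bead_csv <- function(model, path) {
  out <- data.frame(
    residue_index = model$residue_index, name = model$residue_name,
    chain = model$chain_id, x = model$x, y = model$y, z = model$z,
    radius = model$radius, charge = model$charge, class = model$charge_class,
    segment = model$segment
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_csv
#' @param label Model label for the re-read model.
#' @export
read_bead_csv <- function(path, label = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  bead_model(
    tibble(
      residue_index = df$residue_index, residue_name = df$name,
      chain_id = as.character(df$chain), x = df$x, y = df$y, z = df$z,
      radius = df$radius, charge = df$charge, charge_class = df$class,
      segment = if ("segment" %in% names(df)) as.character(df$segment) else NA_character_
    ),
    label = label
  )
}
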