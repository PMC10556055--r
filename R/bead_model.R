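#' Residue charge and polarity classification
#'
#' Classifies a standard 3-letter amino-acid code into one of four classes at
#' pH 7.4: `positive` (LYS, ARG, charge +1), `negative` (ASP, GLU, charge -1),
#' `polar` (ASN, GLN, SER, THR, TYR, charge 0) or `apolar` (everything else,
#' charge 0). Histidine is treated as neutral and apolar at this pH.
#'
#' @param residue_name Character vector of 3-letter residue codes
#'   (case-insensitive).
#' @return Character vector of classes, one per input code.
#' @examples
#' classify_residue(c("ARG", "ASP", "SER", "GLY"))
#' @export
classify_residue <- function(residue_name) {
  code <- toupper(residue_name)
  unknown <- setdiff(unique(code), .standard_aa)
  if (length(unknown) > 0) {
    abort(paste0("unknown residue name(s): ", paste(unknown, collapse = ", ")))
  }
  dplyr::case_when(
    code %in% c("LYS", "ARG") ~ "positive",
    code %in% c("ASP", "GLU") ~ "negative",
    code %in% c("ASN", "GLN", "SER", "THR", "TYR") ~ "polar",
    TRUE ~ "apolar"
  )
}

#' Formal charge of a residue at pH 7.4
#'
#' @inheritParams classify_residue
#' @return Numeric vector of formal charges in elementary units
#'   (+1, -1 or 0).
#' @export
residue_charge <- function(residue_name) {
  cls <- classify_residue(residue_name)
  dplyr::case_when(cls == "positive" ~ 1, cls == "negative" ~ -1, TRUE ~ 0)
}

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# default bead radius, Angstrom (half of a MARTINI-like 5.28 A bead diameter)
.default_bead_radius <- 2.64

#' Construct a bead model
#'
#' A bead model is the package's unit of geometry and energetics: a tibble
#' with one row per residue carrying the bead position (the side-chain
#' heavy-atom centroid), radius, formal charge, charge class and an optional
#' segment label (`TM1`..`TM4`, `ECS1`, `ECS2`, `loop`, `cterm`).
#'
#' @param beads Data frame with columns `residue_index`, `residue_name`,
#'   `chain_id`, `x`, `y`, `z`, `radius` and optionally `segment`, `charge`,
#'   `charge_class` (the latter two are derived from `residue_name` when
#'   absent).
#' @param label Text label for the model (e.g. `"CLDN23"`).
#' @return A `bead_model` tibble with attributes `label` and
#'   `principal_axis` (unit membrane normal, `+z` by convention).
#' @export
bead_model <- function(beads, label = "model") {
  beads <- as_tibble(beads)
  required <- c("residue_index", "residue_name", "chain_id", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0) {
    abort(paste0("bead model is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(beads) < 1) abort("bead model must contain at least one bead")
  if (any(beads$radius <= 0)) abort("bead radii must be positive")
  if (!"segment" %in% names(beads)) beads$segment <- NA_character_
  if (!"charge" %in% names(beads)) beads$charge <- NA_real_
  if (!"charge_class" %in% names(beads)) beads$charge_class <- NA_character_
  fill <- is.na(beads$charge) | is.na(beads$charge_class)
  beads$charge[fill] <- residue_charge(beads$residue_name[fill])
  beads$charge_class[fill] <- classify_residue(beads$residue_name[fill])
  beads <- beads[, c(
    "residue_index", "residue_name", "chain_id", "x", "y", "z",
    "radius", "charge", "charge_class", "segment"
  )]
  structure(
    beads,
    label = label,
    principal_axis = c(0, 0, 1),
    class = c("bead_model", class(tibble()))
  )
}

is_bead_model <- function(x) inherits(x, "bead_model")

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf(
    "<bead_model '%s': %d beads, net charge %+d>\n",
    attr(x, "label") %||% "?", nrow(x), as.integer(net_charge(x))
  ))
  NextMethod()
}

#' Net formal charge of a bead model
#'
#' @param model A `bead_model`.
#' @return Sum of bead charges (elementary units).
#' @export
net_charge <- function(model) sum(model$charge)

# coordinate matrix (n x 3)
bead_coords <- function(model) {
  cbind(model$x, model$y, model$z)
}

# drop beads flagged as cytosolic C-terminal tail before any energetics
drop_cterm <- function(model) {
  keep <- is.na(model$segment) | model$segment != "cterm"
  model[keep, , drop = FALSE]
}

# the in-plane point the model rotates about: TM centroid when segments are
# annotated, otherwise the all-bead centroid
axis_center_xy <- function(model) {
  tm <- !is.na(model$segment) & grepl("^TM", model$segment)
  sub <- if (any(tm)) model[tm, ] else model
  c(mean(sub$x), mean(sub$y))
}

#' Assign topology segments to a bead model
#'
#' @param model A `bead_model`.
#' @param segments Data frame with columns `residue_index` and `segment`;
#'   segment values must be one of `TM1`..`TM4`, `ECS1`, `ECS2`, `loop`,
#'   `cterm`.
#' @return The model with its `segment` column updated.
#' @export
set_segments <- function(model, segments) {
  valid <- c(paste0("TM", 1:4), "ECS1", "ECS2", "loop", "cterm")
  bad <- setdiff(unique(segments$segment), valid)
  if (length(bad) > 0) {
    abort(paste0("invalid segment label(s): ", paste(bad, collapse = ", ")))
  }
  idx <- match(model$residue_index, segments$residue_index)
  model$segment <- ifelse(is.na(idx), model$segment, segments$segment[idx])
  model
}
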