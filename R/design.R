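#' Build the plate layout of a phenotypic reversion screen
#'
#' Constructs the deterministic 384-well layout used throughout the pipeline:
#' one plate per (knock-out sub-clone, concentration) pair, each plate carrying
#' every compound once alongside wild-type vehicle, knock-out vehicle and
#' knock-out untreated control wells. Control wells are interleaved across the
#' occupied plate area rather than clustered at the edges. The defaults
#' reproduce the screen geometry of a 330-compound anti-cancer library tested
#' at 100/300/1000 nM against three knock-out sub-clones: nine plates with 24
#' wild-type vehicle and 16 knock-out vehicle wells each, four image fields
#' per well.
#'
#' @param n_subclones Number of knock-out sub-clones (one plate set each).
#' @param concentrations Compound doses in nM; one plate per dose per sub-clone.
#' @param n_compounds Number of library compounds (one well per compound per plate).
#' @param wt_vehicle_wells_per_plate Wild-type vehicle (positive control) wells.
#' @param ko_vehicle_wells_per_plate Knock-out vehicle (negative control) wells.
#' @param ko_untreated_wells_per_plate Knock-out wells with no treatment at all.
#' @param fields_per_well Image fields acquired per well.
#'
#' @return A `screen_design` object: a list with the design parameters, a
#'   `plates` data.frame (`plate_id`, `subclone_id`, `concentration_nM`) and a
#'   `layout` data.frame (`well`, `row`, `col`, `role`, `compound_id`) shared
#'   by all plates.
#' @export
#' @examples
#' d <- screen_design()
#' nrow(d$plates)  # 9 plates
screen_design <- function(n_subclones = 3,
                          concentrations = c(100, 300, 1000),
                          n_compounds = 330,
                          wt_vehicle_wells_per_plate = 24,
                          ko_vehicle_wells_per_plate = 16,
                          ko_untreated_wells_per_plate = 6,
                          fields_per_well = 4) {
  n_subclones <- stopifnot_scalar_count(n_subclones, "n_subclones")
  n_compounds <- stopifnot_scalar_count(n_compounds, "n_compounds")
  wt <- stopifnot_scalar_count(wt_vehicle_wells_per_plate, "wt_vehicle_wells_per_plate")
  ko <- stopifnot_scalar_count(ko_vehicle_wells_per_plate, "ko_vehicle_wells_per_plate")
  unt <- stopifnot_scalar_count(ko_untreated_wells_per_plate, "ko_untreated_wells_per_plate")
  fields_per_well <- stopifnot_scalar_count(fields_per_well, "fields_per_well")
  if (!is.numeric(concentrations) || !length(concentrations) ||
      any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("`concentrations` must be positive doses in nM")

  n_occ <- n_compounds + wt + ko + unt
  if (n_occ > 384)
    stop(sprintf(paste0("plate capacity exceeded: %d compound + %d WT-vehicle + ",
                        "%d KO-vehicle + %d KO-untreated wells = %d > 384"),
                 n_compounds, wt, ko, unt, n_occ))

  # Interleave all roles across the occupied row-major well sequence: each
  # role's i-th member sits at fraction (i - 0.5) / count, then roles are
  # merged by fraction. Deterministic and spreads controls over the plate.
  roles <- c(rep("WT_VEHICLE", wt), rep("KO_VEHICLE", ko),
             rep("KO_UNTREATED", unt), rep("COMPOUND", n_compounds))
  counts <- c(WT_VEHICLE = wt, KO_VEHICLE = ko, KO_UNTREATED = unt,
              COMPOUND = n_compounds)
  idx_within <- unlist(lapply(counts, seq_len), use.names = FALSE)
  frac <- (idx_within - 0.5) / rep(counts, counts)
  ord <- order(frac, match(roles, names(counts)))
  role_seq <- roles[ord]

  pos <- seq_len(n_occ)  # row-major over the 16 x 24 grid
  row <- ((pos - 1L) %/% 24L) + 1L
  col <- ((pos - 1L) %% 24L) + 1L
  well <- sprintf("%s%02d", LETTERS[row], col)

  compound_id <- rep(NA_character_, n_occ)
  compound_id[role_seq == "COMPOUND"] <-
    sprintf("CPD%03d", seq_len(n_compounds))
  layout <- data.frame(well = well, row = row, col = col, role = role_seq,
                       compound_id = compound_id, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(layout$well))

  plates <- expand.grid(subclone_id = sprintf("SC%d", seq_len(n_subclones)),
                        concentration_nM = sort(concentrations),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plates <- plates[order(plates$subclone_id, plates$concentration_nM), ]
  plates$plate_id <- sprintf("P%02d", seq_len(nrow(plates)))
  plates <- plates[, c("plate_id", "subclone_id", "concentration_nM")]
  rownames(plates) <- NULL

  structure(list(n_subclones = n_subclones,
                 concentrations = sort(concentrations),
                 n_compounds = n_compounds,
                 wt_vehicle_wells_per_plate = wt,
                 ko_vehicle_wells_per_plate = ko,
                 ko_untreated_wells_per_plate = unt,
                 fields_per_well = fields_per_well,
                 plates = plates, layout = layout),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %d plates (%d sub-clones x %d concentrations)\n",
              nrow(x$plates), x$n_subclones, length(x$concentrations)))
  cat(sprintf("  per plate: %d compound, %d WT-vehicle, %d KO-vehicle, %d KO-untreated wells; %d fields/well\n",
              x$n_compounds, x$wt_vehicle_wells_per_plate,
              x$ko_vehicle_wells_per_plate, x$ko_untreated_wells_per_plate,
              x$fields_per_well))
  invisible(x)
}

#' Default annotated compound-library manifest
#'
#' A synthetic stand-in for a 330-compound annotated anti-cancer screening
#' library. Two drugs are deliberately present as two formulations each
#' (a free base plus a salt form), so that compound-level hits can collapse to
#' fewer unique drug treatments, and every entry carries a mechanism-of-action
#' class.
#'
#' @param n_compounds Library size (default 330).
#' @return data.frame with columns `compound_id`, `parent_drug`,
#'   `mechanism_class`, `is_salt_form`.
#' @export
default_library_manifest <- function(n_compounds = 330) {
  n_compounds <- stopifnot_scalar_count(n_compounds, "n_compounds")
  if (n_compounds < 6)
    stop("manifest needs at least 6 compounds to host two salt-form pairs")
  classes <- c("metabolism", "protease_proteasome_inhibitor",
               "DNA_synthesis_repair_inhibitor", "kinase_inhibitor",
               "epigenetic_modulator", "microtubule_agent")
  compound_id <- sprintf("CPD%03d", seq_len(n_compounds))
  parent <- sprintf("drug_%03d", seq_len(n_compounds))
  is_salt <- rep(FALSE, n_compounds)
  # two salt-form pairs: entries 2/3 share parent drug_002, 5/6 share drug_005
  parent[3] <- parent[2]; is_salt[3] <- TRUE
  parent[6] <- parent[5]; is_salt[6] <- TRUE
  mech <- classes[((seq_len(n_compounds) - 1L) %% length(classes)) + 1L]
  mech[3] <- mech[2]; mech[6] <- mech[5]  # salt forms share the parent's class
  out <- data.frame(compound_id = compound_id, parent_drug = parent,
                    mechanism_class = mech, is_salt_form = is_salt,
                    stringsAsFactors = FALSE)
  validate_manifest(out)
  out
}

validate_manifest <- function(manifest) {
  need <- c("compound_id", "parent_drug", "mechanism_class", "is_salt_form")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$compound_id))
    stop("manifest compound_id values must be unique")
  salts <- manifest$parent_drug[manifest$is_salt_form]
  shared <- manifest$parent_drug[!manifest$is_salt_form]
  orphan <- setdiff(salts, shared)
  if (length(orphan))
    stop("salt-form entries without a non-salt parent entry: ",
         paste(orphan, collapse = ", "))
  invisible(manifest)
}

#' Write / read a library manifest as CSV
#' @param manifest data.frame as from [default_library_manifest()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  data.table::fwrite(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  out$is_salt_form <- as.logical(out$is_salt_form)
  validate_manifest(out)
  out
}
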