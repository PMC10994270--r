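#' Simulation parameters for a synthetic morphological screen
#'
#' Parametrises the generative model behind [simulate_screen()]. Feature
#' vectors are standardised units: the wild-type vehicle population has mean 0,
#' the knock-out population is shifted by `genotype_effect` on an affected
#' feature subset, and a compound with reversion strength `rho` moves the
#' treated knock-out mean the fraction `rho` of the way back towards wild-type
#' on those features. Correlated noise comes from latent feature blocks plus
#' plate-, well- and field-level Gaussian components.
#'
#' @param n_features Number of morphological features (default 1100).
#' @param affected_fraction Fraction of features carrying the genotype effect.
#' @param genotype_effect Standardised shift per affected feature (delta).
#' @param n_reverters Number of planted true reverter compounds.
#' @param reverter_rho_min Minimum reversion strength of a planted reverter.
#' @param null_rho_max Maximum reversion strength of a non-reverter.
#' @param rho_star Ground-truth hit threshold on rho.
#' @param offtarget_max Upper bound of the per-compound off-target magnitude
#'   `eta` (uniform on `[0, offtarget_max]`, direction fixed per compound).
#' @param n_latent Number of latent correlation blocks among features.
#' @param block_r Within-block feature correlation of the field-level noise.
#' @param sigma_plate,sigma_well,sigma_field SDs of the plate x feature,
#'   well x feature and field-level noise components.
#' @param toxic_fraction Fraction of compound wells lost to simulated toxicity
#'   (their records are dropped, emulating cell loss).
#' @param dose_scaling If `TRUE` (default), the effective reversion at dose d
#'   is `rho * d / max(dose)` (monotone dose-response); if `FALSE`, `rho` acts
#'   at every dose.
#' @param seed Integer seed controlling every random draw.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_features = 1100,
                       affected_fraction = 0.2,
                       genotype_effect = 1.0,
                       n_reverters = 10,
                       reverter_rho_min = 0.8,
                       null_rho_max = 0.15,
                       rho_star = 0.8,
                       offtarget_max = 0.2,
                       n_latent = 20,
                       block_r = 0.3,
                       sigma_plate = 0.1,
                       sigma_well = 0.1,
                       sigma_field = 1.0,
                       toxic_fraction = 0,
                       dose_scaling = TRUE,
                       seed = 1) {
  p <- list(n_features = stopifnot_scalar_count(n_features, "n_features"),
            affected_fraction = affected_fraction,
            genotype_effect = genotype_effect,
            n_reverters = as.integer(n_reverters),
            reverter_rho_min = reverter_rho_min,
            null_rho_max = null_rho_max,
            rho_star = rho_star,
            offtarget_max = offtarget_max,
            n_latent = stopifnot_scalar_count(n_latent, "n_latent"),
            block_r = block_r,
            sigma_plate = sigma_plate, sigma_well = sigma_well,
            sigma_field = sigma_field,
            toxic_fraction = toxic_fraction,
            dose_scaling = isTRUE(dose_scaling),
            seed = as.integer(seed))
  num <- unlist(p[c("affected_fraction", "genotype_effect", "reverter_rho_min",
                    "null_rho_max", "rho_star", "offtarget_max", "block_r",
                    "sigma_plate", "sigma_well", "sigma_field",
                    "toxic_fraction")])
  if (any(!is.finite(num))) stop("non-finite simulation parameter")
  if (p$affected_fraction < 0 || p$affected_fraction > 1)
    stop("affected_fraction must be in [0, 1]")
  if (any(unlist(p[c("sigma_plate", "sigma_well", "sigma_field")]) < 0))
    stop("variance components must be >= 0")
  if (p$reverter_rho_min < 0 || p$reverter_rho_min > 1 ||
      p$null_rho_max < 0 || p$null_rho_max > 1)
    stop("reversion strengths rho must lie in [0, 1]")
  if (p$block_r < 0 || p$block_r >= 1) stop("block_r must be in [0, 1)")
  class(p) <- "sim_params"
  p
}

# Feature names follow Compartment_Class_Index over the classic Cell Painting
# compartments and the nine extracted feature classes.
make_feature_names <- function(n_features) {
  compartments <- c("Nuc", "ER", "RNA", "Mem", "Actin", "Mito")
  classes <- c("Coloc", "Adjacency", "Size", "Shape", "Area", "Texture",
               "RadialDist", "Granularity", "Intensity")
  combo <- expand.grid(class = classes, compartment = compartments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- ((seq_len(n_features) - 1L) %% nrow(combo)) + 1L
  idx <- ave(seq_len(n_features), i, FUN = seq_along)
  sprintf("%s_%s_%03d", combo$compartment[i], combo$class[i], idx)
}

#' Simulate a full screen with known ground truth
#'
#' Generates image-level feature records for every (plate, well, field) in a
#' [screen_design()], under the generative model described in
#' [sim_params()], and returns the ground truth (per-compound reversion
#' strength, off-target magnitude, true-hit labels, affected-feature mask)
#' alongside.
#'
#' @param design A `screen_design`.
#' @param params A `sim_params`.
#' @return list with `table` (data.frame: metadata columns then feature
#'   columns) and `truth` (list; see [write_ground_truth()]).
#' @export
simulate_screen <- function(design, params = sim_params()) {
  stopifnot(inherits(design, "screen_design"), inherits(params, "sim_params"))
  with_seed(params$seed, simulate_screen_impl(design, params))
}

simulate_screen_impl <- function(design, params) {
  p <- params$n_features
  feat_names <- make_feature_names(p)
  n_aff <- round(params$affected_fraction * p)
  mask <- rep(FALSE, p)
  mask[sample.int(p, n_aff)] <- TRUE
  delta_vec <- ifelse(mask, params$genotype_effect, 0)

  # per-compound ground truth
  nc <- design$n_compounds
  compound_ids <- sprintf("CPD%03d", seq_len(nc))
  n_rev <- min(params$n_reverters, nc)
  rev_idx <- sort(sample.int(nc, n_rev))
  rho <- runif(nc, 0, params$null_rho_max)
  rho[rev_idx] <- runif(n_rev, params$reverter_rho_min, 1)
  eta <- runif(nc, 0, params$offtarget_max)
  # off-target direction: unit vector per compound, fixed across wells/doses
  U <- matrix(rnorm(nc * p), nc, p)
  U <- U / sqrt(rowSums(U^2))

  block <- ((seq_len(p) - 1L) %% params$n_latent) + 1L

  plates <- design$plates
  layout <- design$layout
  n_wells <- nrow(layout)
  fpw <- design$fields_per_well
  max_dose <- max(design$concentrations)

  tabs <- vector("list", nrow(plates))
  for (pi in seq_len(nrow(plates))) {
    pl <- plates[pi, ]
    # well-level metadata for this plate
    genotype <- ifelse(layout$role == "WT_VEHICLE", "WT", "KO")
    treatment <- ifelse(layout$role == "COMPOUND", layout$compound_id,
                        ifelse(layout$role == "KO_UNTREATED", "UNTREATED",
                               "VEHICLE"))
    conc <- ifelse(layout$role == "COMPOUND", pl$concentration_nM, 0)
    subclone <- ifelse(layout$role == "WT_VEHICLE", "WT", pl$subclone_id)

    # well mean vectors (n_wells x p)
    means <- matrix(0, n_wells, p)
    is_ko <- genotype == "KO"
    means[is_ko, ] <- rep(delta_vec, each = sum(is_ko))
    trt_idx <- match(layout$compound_id, compound_ids)
    has_cpd <- !is.na(trt_idx)
    if (any(has_cpd)) {
      ci <- trt_idx[has_cpd]
      rho_eff <- if (params$dose_scaling)
        rho[ci] * pl$concentration_nM / max_dose else rho[ci]
      means[has_cpd, ] <- (1 - rho_eff) %o% delta_vec + (eta[ci] * U[ci, , drop = FALSE])
    }

    # noise components
    plate_eff <- rnorm(p, 0, params$sigma_plate)          # plate x feature
    well_eff <- matrix(rnorm(n_wells * p, 0, params$sigma_well), n_wells, p)
    n_rec <- n_wells * fpw
    zb <- matrix(rnorm(n_rec * params$n_latent), n_rec, params$n_latent)
    field_noise <- sqrt(params$block_r) * zb[, block, drop = FALSE] +
      sqrt(1 - params$block_r) * matrix(rnorm(n_rec * p), n_rec, p)
    widx <- rep(seq_len(n_wells), each = fpw)
    X <- means[widx, , drop = FALSE] + well_eff[widx, , drop = FALSE] +
      rep(plate_eff, each = n_rec) + params$sigma_field * field_noise
    colnames(X) <- feat_names

    meta <- data.frame(plate_id = pl$plate_id,
                       well = layout$well[widx],
                       subclone_id = subclone[widx],
                       genotype = genotype[widx],
                       treatment = treatment[widx],
                       concentration_nM = conc[widx],
                       field = rep(seq_len(fpw), times = n_wells),
                       stringsAsFactors = FALSE)
    tabs[[pi]] <- cbind(meta, as.data.frame(X))
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL

  toxic_wells <- character(0)
  if (params$toxic_fraction > 0) {
    cw <- unique(tab[tab$treatment %in% compound_ids,
                     c("plate_id", "well")])
    n_tox <- round(params$toxic_fraction * nrow(cw))
    if (n_tox > 0) {
      tox <- cw[sample.int(nrow(cw), n_tox), ]
      key <- paste(tab$plate_id, tab$well)
      toxic_wells <- paste(tox$plate_id, tox$well)
      tab <- tab[!(key %in% toxic_wells), ]
      rownames(tab) <- NULL
    }
  }

  truth <- list(compound_id = compound_ids, rho = rho, eta = eta,
                true_hit = rho >= params$rho_star,
                rho_star = params$rho_star,
                affected_features = feat_names[mask],
                toxic_wells = toxic_wells,
                seed = params$seed)
  list(table = tab, truth = truth)
}

#' Write / read a feature table as CSV with exact numeric round-trip
#'
#' The external schema keeps the metadata columns first, in a fixed order
#' (`plate_id, well, subclone_id, genotype, treatment, concentration_nM,
#' field`), followed by feature columns. Numeric feature values are written
#' with 17 significant digits so that read(write(x)) reproduces the doubles
#' bit for bit. Unknown extra columns in a file are preserved and passed
#' through after the feature columns.
#'
#' @param tab Feature table (data.frame).
#' @param path CSV path.
#' @export
write_feature_table <- function(tab, path) {
  assert_feature_table(tab)
  fc <- feature_cols(tab)
  out <- as.data.frame(tab)[, c(META_COLS, fc), drop = FALSE]
  for (cn in fc) if (is.double(out[[cn]]))
    out[[cn]] <- sprintf("%.17g", out[[cn]])
  data.table::fwrite(out, path, quote = "auto")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  missing <- setdiff(META_COLS, names(tab))
  if (length(missing))
    stop("feature table at ", path, " is missing metadata columns: ",
         paste(missing, collapse = ", "))
  tab <- tab[, c(META_COLS, setdiff(names(tab), META_COLS)), drop = FALSE]
  for (cn in c("plate_id", "well", "subclone_id", "genotype", "treatment"))
    tab[[cn]] <- as.character(tab[[cn]])
  tab$concentration_nM <- as.numeric(tab$concentration_nM)
  tab$field <- as.integer(tab$field)
  tab
}

#' Serialise / restore screen ground truth as JSON
#' @param truth Ground-truth list as emitted by [simulate_screen()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$rho <- as.numeric(x$rho); x$eta <- as.numeric(x$eta)
  x$true_hit <- as.logical(x$true_hit)
  x$rho_star <- as.numeric(x$rho_star)
  x$seed <- as.integer(x$seed)
  x$compound_id <- as.character(x$compound_id)
  x$affected_features <- as.character(x$affected_features)
  x$toxic_wells <- as.character(x$toxic_wells)
  x
}
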