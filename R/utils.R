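# internal helpers shared across modules

#' @importFrom stats median mad rnorm runif cor pf phyper p.adjust sd hclust
#'   dist as.dist predict quantile setNames model.matrix var ave
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "subclone_id", "genotype", "treatment",
  "concentration_nM", "prob", "score", "exc", "max_score", "sc_exc",
  "sc_max", "all_sc", "mechanism_class", "compound_id", "n_meta"))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a root seed; stays below 2^31.
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.finite(root_seed))
  offsets <- c(design = 11L, simulate = 23L, qc = 37L, reduce = 41L,
               separate = 53L, split = 61L, train = 71L, score = 83L,
               hits = 97L, enrich = 101L)
  if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
  (as.integer(root_seed) %% 1000003L) * 2011L + offsets[[stage]]
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop("`", name, "` must be a single positive integer, got: ",
         paste(format(x), collapse = ", "), call. = FALSE)
  as.integer(x)
}

# metadata schema of feature tables, in the fixed external column order
META_COLS <- c("plate_id", "well", "subclone_id", "genotype", "treatment",
               "concentration_nM", "field")

feature_cols <- function(tab) setdiff(names(tab), META_COLS)

# Split a feature table into metadata data.frame and numeric feature matrix.
feature_matrix <- function(tab) {
  fc <- feature_cols(tab)
  m <- as.matrix(as.data.frame(tab)[, fc, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

assert_feature_table <- function(tab) {
  missing <- setdiff(META_COLS, names(tab))
  if (length(missing))
    stop("not a feature table; missing metadata columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(tab)
}
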