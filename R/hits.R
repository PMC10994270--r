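#' Call replicated compound hits from per-well similarity scores
#'
#' A compound is a hit when every knock-out sub-clone shows a wild-type
#' similarity score strictly above the threshold `tau` at one or more
#' concentrations. `mode = "any_conc"` (default) allows each sub-clone to
#' exceed at a different concentration; `mode = "same_conc"` requires a
#' single concentration exceeding in all sub-clones. Missing cells (e.g.
#' wells lost to toxicity) count as non-exceeding.
#'
#' @param scores data.frame from [score_treated()] with columns
#'   `compound_id`, `subclone_id`, `concentration_nM`, `score`.
#' @param tau Similarity threshold (strict `>`; default 0.505).
#' @param mode `"any_conc"` or `"same_conc"`.
#' @param subclones Sub-clones required to replicate; defaults to all
#'   sub-clones present in `scores`.
#' @return A `hit_table` data.frame: one row per compound with `max_score`,
#'   per-sub-clone max scores, and logical `hit`.
#' @export
call_hits <- function(scores, tau = 0.505, mode = c("any_conc", "same_conc"),
                      subclones = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must lie strictly inside (0, 1)")
  need <- c("compound_id", "subclone_id", "concentration_nM", "score")
  missing <- setdiff(need, names(scores))
  if (length(missing))
    stop("score table missing columns: ", paste(missing, collapse = ", "))
  if (is.null(subclones)) subclones <- sort(unique(scores$subclone_id))
  dt <- data.table::as.data.table(scores)
  concs <- sort(unique(dt$concentration_nM))

  exceeds <- dt[, .(exc = any(score > tau), max_score = max(score)),
                by = c("compound_id", "subclone_id", "concentration_nM")]
  per_sc <- exceeds[, .(sc_exc = any(exc), sc_max = max(max_score)),
                    by = c("compound_id", "subclone_id")]
  if (mode == "any_conc") {
    hit_dt <- per_sc[, .(hit = all(subclones %in% subclone_id[sc_exc])),
                     by = "compound_id"]
  } else {
    per_conc <- exceeds[, .(all_sc = all(subclones %in% subclone_id[exc])),
                        by = c("compound_id", "concentration_nM")]
    hit_dt <- per_conc[, .(hit = any(all_sc)), by = "compound_id"]
  }
  maxes <- per_sc[, .(max_score = max(sc_max)), by = "compound_id"]
  wide <- data.table::dcast(per_sc, compound_id ~ subclone_id,
                            value.var = "sc_max")
  data.table::setnames(wide, setdiff(names(wide), "compound_id"),
                       paste0("max_", setdiff(names(wide), "compound_id")))
  out <- Reduce(function(a, b) merge(a, b, by = "compound_id"),
                list(maxes, wide, hit_dt))
  out <- as.data.frame(out[order(-out$max_score)])
  attr(out, "tau") <- tau
  attr(out, "mode") <- mode
  attr(out, "subclones") <- subclones
  attr(out, "concentrations") <- concs
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Collapse salt-form hits to unique parent drugs
#'
#' Hit compounds that are alternative formulations of the same parent drug
#' are merged; the best compound-level score is retained per drug.
#'
#' @param hits A `hit_table` from [call_hits()].
#' @param manifest Library manifest covering every hit compound.
#' @return list with `drugs` (per-drug table for hit drugs: `parent_drug`,
#'   `mechanism_class`, `n_forms`, `best_score`), `n_compound_hits`,
#'   `n_drug_hits`.
#' @export
collapse_salt_forms <- function(hits, manifest) {
  validate_manifest(manifest)
  hit_rows <- hits[hits$hit, , drop = FALSE]
  absent <- setdiff(hit_rows$compound_id, manifest$compound_id)
  if (length(absent))
    stop("hit compound(s) absent from manifest: ",
         paste(absent, collapse = ", "))
  mi <- match(hit_rows$compound_id, manifest$compound_id)
  hit_rows$parent_drug <- manifest$parent_drug[mi]
  hit_rows$mechanism_class <- manifest$mechanism_class[mi]
  dt <- data.table::as.data.table(hit_rows)
  drugs <- dt[, .(mechanism_class = mechanism_class[1],
                  n_forms = .N,
                  forms = paste(sort(compound_id), collapse = ";"),
                  best_score = max(max_score)),
              by = "parent_drug"]
  drugs <- as.data.frame(drugs[order(-drugs$best_score)])
  list(drugs = drugs,
       n_compound_hits = nrow(hit_rows),
       n_drug_hits = nrow(drugs))
}

#' Summarise hit drugs by mechanism class
#'
#' @param drugs Per-drug table from [collapse_salt_forms()].
#' @return data.frame: `mechanism_class`, `n_drugs`, `mean_score`,
#'   `max_score`; drugs with missing/empty annotation appear under
#'   `"unannotated"`.
#' @export
summarize_by_mechanism <- function(drugs) {
  if (!nrow(drugs))
    return(data.frame(mechanism_class = character(0), n_drugs = integer(0),
                      mean_score = numeric(0), max_score = numeric(0)))
  mech <- drugs$mechanism_class
  mech[is.na(mech) | !nzchar(mech)] <- "unannotated"
  dt <- data.table::data.table(mechanism_class = mech,
                               score = drugs$best_score)
  out <- dt[, .(n_drugs = .N, mean_score = mean(score),
                max_score = max(score)), by = "mechanism_class"]
  as.data.frame(out[order(-out$n_drugs)])
}

#' Compare called hits with simulation ground truth
#'
#' @param hits A `hit_table`.
#' @param truth Ground truth from [simulate_screen()].
#' @return list with counts: true reverters recovered, missed, false
#'   positives, plus sensitivity and specificity of hit calling.
#' @export
hit_recovery <- function(hits, truth) {
  called <- hits$compound_id[hits$hit]
  true_hits <- truth$compound_id[truth$true_hit]
  non_hits <- setdiff(truth$compound_id, true_hits)
  tp <- length(intersect(called, true_hits))
  fp <- length(intersect(called, non_hits))
  list(n_true_reverters = length(true_hits),
       recovered = tp,
       missed = length(setdiff(true_hits, called)),
       false_positives = fp,
       sensitivity = tp / max(length(true_hits), 1),
       specificity = (length(non_hits) - fp) / max(length(non_hits), 1))
}
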