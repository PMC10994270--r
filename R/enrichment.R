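#' Read a gene-set collection from a GMT file
#'
#' GMT lines are tab-separated: set identifier, description, then member gene
#' symbols. Symbols are uppercased and de-duplicated within a set; set
#' identifiers must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(parts))
    ids[i] <- parts[1]
    desc[i] <- parts[2]
    genes <- unique(toupper(trimws(parts[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set at line ", i, ": ", parts[1])
    sets[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stop("duplicate gene-set identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  names(desc) <- ids
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets Named list of gene vectors (or `gene_set_collection`).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect genes with an expressed-gene list
#'
#' Case-insensitive intersection; used both to prune network nodes not
#' expressed in the assayed cell lines and to define the enrichment
#' background.
#'
#' @param genes Character vector of gene symbols (or network node names).
#' @param expressed Expressed-gene list.
#' @export
filter_by_expression <- function(genes, expressed) {
  if (!length(expressed)) stop("expressed-gene list is empty")
  g <- toupper(genes)
  keep <- g %in% toupper(expressed)
  unique(g[keep])
}

#' Hypergeometric over-representation test against an expressed background
#'
#' For each gene set: with background size `N` (the expressed genes), set
#' overlap with the background `K`, query size `n` and observed overlap `x`,
#' computes the upper-tail hypergeometric p-value `P(X >= x)`, the expected
#' overlap `E = n K / N`, the enrichment strength `log10(x / E)` (defined
#' when `x > 0`), and Benjamini-Hochberg q-values across all tested sets.
#' Query genes outside the background are dropped with a warning; sets with
#' no background member are skipped.
#'
#' @param query Character vector of query gene symbols.
#' @param collection A `gene_set_collection` (or named list of gene vectors).
#' @param background Expressed-gene background (character vector).
#' @return data.frame with one row per tested set: `set_id`, `N`, `K`, `n`,
#'   `x`, `expected`, `strength`, `p`, `q`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(query, collection, background) {
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background")
  q0 <- unique(toupper(query))
  query <- q0[q0 %in% background]
  dropped <- setdiff(q0, query)
  if (length(dropped))
    warning(length(dropped), " query gene(s) outside the background dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ...")
  if (!length(query)) stop("query empty after background intersection")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(toupper(collection[[id]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    x <- length(intersect(query, members))
    E <- n * K / N
    data.frame(set_id = id, N = N, K = K, n = n, x = x, expected = E,
               strength = if (x > 0) log10(x / E) else NA_real_,
               p = phyper(x - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the background")
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), ]
  rownames(out) <- NULL
  out
}

#' Write enrichment rows as TSV
#' @param rows data.frame from [hypergeometric_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(rows, path) {
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
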