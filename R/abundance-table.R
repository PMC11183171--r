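#' Sample-by-taxon abundance table with kingdom labels and slope metadata
#'
#' Container for a non-negative samples x taxa abundance matrix (counts or
#' absolute gene-copy abundances), a kingdom label per taxon, and per-sample
#' slope metadata (position on the slope and plot id).
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   unique row (sample) and column (taxon) names; no negative entries.
#' @param kingdom character vector, one of `"bacteria"`, `"rhizobia"`,
#'   `"am_fungi"` per taxon; either named by taxon id or in column order.
#' @param metadata data.frame with columns `sample_id`, `position`
#'   (`"top"`, `"middle"`, `"bottom"`) and `plot`, one row per sample.
#' @return An object of class `abund_table`: a list with elements
#'   `counts`, `kingdom`, `metadata`.
#' @export
abund_table <- function(counts, kingdom, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("abundances must be finite and non-negative")
  if (is.null(names(kingdom))) {
    if (length(kingdom) != ncol(counts))
      stop("kingdom labels must cover every taxon")
    names(kingdom) <- colnames(counts)
  }
  if (!all(colnames(counts) %in% names(kingdom)))
    stop("kingdom labels must cover every taxon")
  kingdom <- kingdom[colnames(counts)]
  bad <- setdiff(unique(kingdom), c("bacteria", "rhizobia", "am_fungi"))
  if (length(bad)) stop("unknown kingdom label(s): ", paste(bad, collapse = ", "))
  metadata <- as.data.frame(metadata)
  need <- c("sample_id", "position", "plot")
  if (!all(need %in% names(metadata)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (!setequal(metadata$sample_id, rownames(counts)))
    stop("metadata sample ids do not match the count matrix")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$position %in% c("top", "middle", "bottom")))
    stop("position must be one of top/middle/bottom")
  structure(list(counts = counts, kingdom = kingdom, metadata = metadata),
            class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat("<abund_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa (", paste(sprintf("%s: %d", names(table(x$kingdom)),
                               as.integer(table(x$kingdom))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Merge per-kingdom abundance tables into one cross-kingdom table
#'
#' Column-binds tables that share an identical sample set (aligned by sample
#' id) and have disjoint taxon ids, preserving kingdom labels.  Used to build
#' cross-kingdom networks from per-kingdom filtered tables.
#'
#' @param tables list of [abund_table] objects.
#' @return A single [abund_table].
#' @export
merge_kingdom_tables <- function(tables) {
  if (inherits(tables, "abund_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1L) return(tables[[1]])
  ids <- rownames(tables[[1]]$counts)
  for (t in tables[-1]) {
    if (!setequal(rownames(t$counts), ids))
      stop("tables do not share an identical sample set")
  }
  taxa <- unlist(lapply(tables, function(t) colnames(t$counts)))
  if (anyDuplicated(taxa))
    stop("duplicate taxon id(s) across tables: ",
         paste(unique(taxa[duplicated(taxa)])[1:3], collapse = ", "))
  counts <- do.call(cbind, lapply(tables, function(t) t$counts[ids, , drop = FALSE]))
  kingdom <- setNames(unlist(unname(lapply(tables, function(t) unname(t$kingdom)))), taxa)
  abund_table(counts, kingdom, tables[[1]]$metadata)
}

#' Samples-by-functions ecosystem function table
#'
#' Validates a samples x 12 matrix of ecosystem function measurements.  The
#' 12 functions and their grouping into four services are fixed by the study
#' design: microbially driven C pools (DOC, MBC), nutrient cycling (TDN,
#' OlsenP, MBN, MBP), organic matter decomposition (BG, NAG, LAP, AP) and
#' plant production (leafC, litterC).
#'
#' @param mat numeric matrix or data.frame, samples in rows, the 12 functions
#'   in columns (any column order; names must match).
#' @return A numeric matrix of class `function_table` with a
#'   `service_groups` attribute mapping function to service.
#' @export
function_table <- function(mat) {
  mat <- as.matrix(mat)
  fn <- names(service_groups())
  if (!setequal(colnames(mat), fn))
    stop("function table must contain exactly the 12 functions: ",
         paste(fn, collapse = ", "))
  mat <- mat[, fn, drop = FALSE]
  if (any(!is.finite(mat))) stop("function table has missing or non-finite values")
  structure(mat, class = c("function_table", class(mat)),
            service_groups = service_groups())
}

#' The fixed map from ecosystem function to service group
#' @return Named character vector: function id -> service.
#' @export
service_groups <- function() {
  c(DOC = "C_pools", MBC = "C_pools",
    TDN = "nutrient_cycling", OlsenP = "nutrient_cycling",
    MBN = "nutrient_cycling", MBP = "nutrient_cycling",
    BG = "decomposition", NAG = "decomposition",
    LAP = "decomposition", AP = "decomposition",
    leafC = "plant_production", litterC = "plant_production")
}
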