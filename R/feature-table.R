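#' Taxonomic ranks used throughout the package
#'
#' The seven-rank Greengenes-style hierarchy, kingdom through species.
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Construct a feature-by-sample count table
#'
#' The central container for microbial abundance data: a samples-by-features
#' matrix of non-negative integer counts, with an optional Greengenes-style
#' taxonomy lineage string per feature (e.g. `"k__Bacteria; p__Firmicutes; ..."`).
#'
#' @param counts numeric matrix, samples in rows, features in columns, with
#'   unique `rownames` (sample ids) and `colnames` (feature ids). Values must
#'   be non-negative integers (integer-valued doubles are accepted).
#' @param taxonomy optional named character vector of lineage strings; names
#'   must cover all feature ids.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and feature colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by feature id")
    missing_tax <- setdiff(colnames(counts), names(taxonomy))
    if (length(missing_tax))
      stop("taxonomy missing for features: ", paste(missing_tax, collapse = ", "))
    taxonomy <- taxonomy[colnames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Sample and feature accessors
#' @param table a `feature_table`
#' @return character vector of ids, or named numeric vector of per-sample
#'   read totals for `sample_depths()`.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
feature_ids <- function(table) colnames(table$counts)

#' @rdname sample_ids
#' @export
sample_depths <- function(table) rowSums(table$counts)

#' Subset a feature table by sample and/or feature ids
#' @param table a `feature_table`
#' @param samples,features character vectors of ids to keep (default all)
#' @return a `feature_table`
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  counts <- table$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(counts))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    counts <- counts[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(counts))
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
    counts <- counts[, features, drop = FALSE]
  }
  tax <- if (is.null(table$taxonomy)) NULL else table$taxonomy[colnames(counts)]
  feature_table(counts, tax)
}

#' Read a feature table from TSV or BIOM-JSON
#'
#' The TSV dialect is the common ASV-table convention: features as rows,
#' samples as columns, first column the feature id, and an optional final
#' `taxonomy` column holding lineage strings. BIOM support covers the JSON
#' (v1) flavor via the `biomformat` package.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom-json"`
#' @return a `feature_table`
#' @export
read_feature_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    tax <- tryCatch({
      obs <- biomformat::observation_metadata(b)
      if (is.null(obs)) NULL else {
        lin <- apply(as.matrix(obs), 1L, paste, collapse = "; ")
        stats::setNames(as.character(lin), rownames(m))
      }
    }, error = function(e) NULL)
    return(feature_table(t(m), tax))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (anyDuplicated(colnames(df)))
    stop("duplicate sample ids in header: ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  fids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  tax <- NULL
  if (ncol(df) && tolower(colnames(df)[ncol(df)]) == "taxonomy") {
    tax <- stats::setNames(as.character(df[[ncol(df)]]), fids)
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- fids
  feature_table(t(m), tax)
}

#' Write a feature table as TSV
#'
#' Features as rows, samples as columns, trailing `taxonomy` column when
#' lineages are present. UTF-8, tab-delimited, `NA` for missing.
#'
#' @param table a `feature_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  m <- t(table$counts)  # features x samples
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy))
    df$taxonomy <- unname(table$taxonomy[rownames(m)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse Greengenes-style lineage strings
#'
#' Splits semicolon-separated lineages with optional `k__`..`s__` rank
#' prefixes into the seven canonical ranks. Missing, empty, or malformed
#' segments become `NA` (unclassified). Segments without a recognized prefix
#' are assigned by position.
#'
#' @param lineage character vector of lineage strings
#' @return a character matrix, one row per input, columns
#'   `kingdom`..`species`; `NA` marks unclassified ranks.
#' @export
parse_lineage <- function(lineage) {
  lineage <- as.character(lineage)
  out <- matrix(NA_character_, nrow = length(lineage),
                ncol = length(TAXONOMIC_RANKS),
                dimnames = list(NULL, TAXONOMIC_RANKS))
  for (i in seq_along(lineage)) {
    s <- lineage[i]
    if (is.na(s) || !nzchar(trimws(s))) next
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    for (j in seq_along(parts)) {
      seg <- parts[j]
      if (!nzchar(seg)) next
      pref <- substr(seg, 1L, 3L)
      hit <- match(pref, RANK_PREFIXES)
      if (!is.na(hit)) {
        val <- trimws(substring(seg, 4L))
        rank <- hit
      } else if (j <= length(TAXONOMIC_RANKS)) {
        val <- seg
        rank <- j
      } else next
      if (nzchar(val)) out[i, rank] <- val
    }
  }
  rownames(out) <- names(lineage)
  out
}

#' Build a lineage string from parsed ranks
#' @param ranks character matrix as returned by [parse_lineage()], or a single
#'   named character vector
#' @param upto last rank to include (default species)
#' @return character vector of lineage strings with rank prefixes
#' @export
make_lineage <- function(ranks, upto = "species") {
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L,
                                           dimnames = list(NULL, names(ranks)))
  upto_i <- match(upto, TAXONOMIC_RANKS)
  if (is.na(upto_i)) stop("unknown rank: ", upto)
  apply(ranks[, seq_len(upto_i), drop = FALSE], 1L, function(r) {
    r[is.na(r)] <- ""
    paste0(RANK_PREFIXES[seq_len(upto_i)], r, collapse = "; ")
  })
}

#' Remove samples with low sequencing depth
#'
#' Drops samples whose read total falls below `min_reads`, the quality-control
#' rule used to exclude specimens indistinguishable from negative controls
#' (threshold 6000 reads in the study design this package follows).
#'
#' @param table a `feature_table`
#' @param min_reads minimum total reads a sample must have to be retained
#' @return a `feature_table` with the same features and the surviving samples
#' @export
filter_low_depth <- function(table, min_reads = 6000) {
  stopifnot(min_reads >= 0)
  depths <- sample_depths(table)
  keep <- depths >= min_reads
  if (!any(keep))
    stop("all samples fall below the minimum depth of ", min_reads, " reads")
  subset_table(table, samples = sample_ids(table)[keep])
}

#' Validate sample metadata against a feature table
#'
#' @param table a `feature_table`
#' @param metadata data frame with columns `sample_id`, `patient_id`,
#'   `tissue` (values `"tumor"`/`"normal"`), and optionally `batch`
#' @return the metadata rows for `table`'s samples, in table order
#' @export
validate_metadata <- function(table, metadata) {
  req <- c("sample_id", "patient_id", "tissue")
  missing_cols <- setdiff(req, colnames(metadata))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(metadata$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  absent <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(absent))
    stop("samples without metadata: ", paste(absent, collapse = ", "))
  md <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  dup <- duplicated(md[, c("patient_id", "tissue")])
  if (any(dup))
    stop("a patient may have at most one tumor and one normal sample")
  rownames(md) <- NULL
  md
}

#' Tumor/normal sample pairs present in metadata
#' @param metadata validated metadata data frame
#' @return data frame with columns `patient_id`, `tumor`, `normal` (sample
#'   ids), one row per patient having both tissues
#' @export
sample_pairs <- function(metadata) {
  tum <- metadata[metadata$tissue == "tumor", c("patient_id", "sample_id")]
  nor <- metadata[metadata$tissue == "normal", c("patient_id", "sample_id")]
  m <- merge(tum, nor, by = "patient_id", suffixes = c("_t", "_n"))
  data.frame(patient_id = m$patient_id, tumor = m$sample_id_t,
             normal = m$sample_id_n, stringsAsFactors = FALSE)
}
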