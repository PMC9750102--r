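#' Read a quantification table from TSV
#'
#' Expects a tab-separated file whose first column holds feature IDs
#' (header `ID` by convention) and whose remaining columns hold one sample
#' each. Empty cells and the tokens `NA`/`NaN` (case-insensitive) are
#' treated as missing; `0` is a value, not missing -- quantification
#' pipelines routinely distinguish a measured zero from an unobserved
#' feature. Any other non-numeric cell is an error reported with its
#' coordinates; nothing is silently coerced.
#'
#' @param path TSV file path.
#' @param name table identifier; defaults to the file name without
#'   extension.
#' @inheritParams omics_data_table
#' @return an [omics_data_table()].
#' @export
read_data_table <- function(path, name = NULL, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
               check.names = FALSE, quote = "", comment.char = "",
               na.strings = NULL),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  if (ncol(raw) < 2L) {
    stop("'", path, "': need a feature-ID column plus at least one sample column")
  }
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("'", path, "': duplicated feature IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing_tok <- cells == "" | tolower(cells) %in% c("na", "nan")
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop("'", path, "': non-numeric cell '", cells[bad[1L, , drop = FALSE]],
         "' at feature '", ids[i[1L]], "', sample '",
         colnames(raw)[-1L][i[2L]], "'")
  }
  num[missing_tok] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  omics_data_table(num, name = name, scale = scale)
}

#' Write a quantification table to TSV
#'
#' Inverse of [read_data_table()]: values round-trip exactly (up to 15
#' significant digits) and missing entries are written as `NA`.
#'
#' @param table an [omics_data_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_data_table <- function(table, path) {
  df <- data.frame(ID = rownames(table$values),
                   format_num(table$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# Deterministic numeric formatting for all TSV output (15 significant
# digits, no scientific-notation drift across platforms).
format_num <- function(x) {
  out <- ifelse(is.na(x), NA_character_,
                formatC(x, digits = 15, format = "g"))
  if (is.matrix(x)) {
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  out
}

#' Read a sample annotation file
#'
#' Tab-separated with a header; columns `sample` and `class` are required,
#' `batch`, `order` and `is_qc` optional. A missing `batch` column assigns
#' every sample to batch `"B1"`; a missing `is_qc` column marks no sample
#' as a QC replicate.
#'
#' @param path annotation TSV path.
#' @return a `data.frame` with columns `sample`, `class`, `batch`,
#'   `order`, `is_qc`.
#' @export
read_sample_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  req <- c("sample", "class")
  if (!all(req %in% names(df))) {
    stop("'", path, "': annotation needs columns ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$sample)) {
    stop("'", path, "': duplicated sample IDs: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  ann <- data.frame(sample = df$sample, class = df$class,
                    stringsAsFactors = FALSE)
  ann$batch <- if ("batch" %in% names(df)) df$batch else "B1"
  if ("order" %in% names(df)) {
    ord <- suppressWarnings(as.numeric(df$order))
    if (any(is.na(ord) | ord != round(ord))) {
      stop("'", path, "': run order must be integer")
    }
    ann$order <- as.integer(ord)
  } else {
    ann$order <- seq_len(nrow(ann))
  }
  for (b in unique(ann$batch)) {
    o <- ann$order[ann$batch == b]
    if (anyDuplicated(o)) {
      stop("'", path, "': duplicated run order within batch '", b, "'")
    }
  }
  ann$is_qc <- if ("is_qc" %in% names(df)) {
    tolower(df$is_qc) %in% c("true", "t", "1", "yes")
  } else FALSE
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("sample", "class", "batch", "order", "is_qc") %in% names(ann)))
  if (anyDuplicated(ann$sample)) stop("annotation: duplicated sample IDs")
  invisible(ann)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' member TAB member ...`. The description is discarded; duplicate
#' members within a set are removed with a warning. An empty file yields
#' an empty collection.
#'
#' @param path GMT file path.
#' @param kind `"complex"` (CORUM-style protein complexes) or
#'   `"pathway"` (KEGG-style pathways).
#' @return a `gene_set_collection`: list with `kind` and named list
#'   `sets`.
#' @export
read_gmt <- function(path, kind = c("complex", "pathway")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("'", path, "' line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, members)")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("'", path, "' set '", fields[1L],
              "': duplicate members removed")
      members <- unique(members)
    }
    if (length(members) == 0L) {
      stop("'", path, "' line ", i, ": set '", fields[1L], "' is empty")
    }
    sets[[fields[1L]]] <- members
  }
  gene_set_collection(sets, kind)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (set name -> member IDs).
#' @export
gene_set_collection <- function(sets, kind = c("complex", "pathway")) {
  kind <- match.arg(kind)
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  }
  structure(list(kind = kind, sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets, sizes %s\n", x$kind,
              length(x$sets),
              if (length(x$sets)) paste0(min(lengths(x$sets)), "-",
                                         max(lengths(x$sets))) else "-"))
  invisible(x)
}

#' Align data tables and annotation onto a common sample set
#'
#' Restricts every table to the intersection of all tables' sample sets,
#' column-reordered to annotation order, and checks each table's samples
#' are annotated. Feature sets are deliberately not intersected -- the
#' depth metrics need each table's own features. Correlation-based
#' metrics are meaningless below 3 samples, so a smaller intersection is
#' an error.
#'
#' @param tables list of [omics_data_table()] (at least one).
#' @param annotation annotation `data.frame` from
#'   [read_sample_annotation()].
#' @return list with `tables` (aligned, in input order) and `annotation`
#'   (rows restricted to the common samples, original order).
#' @export
align_tables <- function(tables, annotation) {
  stopifnot(length(tables) >= 1L)
  validate_annotation(annotation)
  nm <- vapply(tables, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop("table names must be unique")
  for (t in tables) {
    extra <- setdiff(sample_ids(t), annotation$sample)
    if (length(extra)) {
      stop("table '", t$name, "': samples absent from annotation: ",
           paste(extra, collapse = ", "))
    }
  }
  common <- Reduce(intersect, lapply(tables, sample_ids))
  common <- annotation$sample[annotation$sample %in% common]
  if (length(common) < 3L) {
    counts <- vapply(tables, function(t) length(sample_ids(t)), integer(1))
    stop("sample intersection across tables has ", length(common),
         " samples (< 3); per-table sample counts: ",
         paste(sprintf("%s=%d", nm, counts), collapse = ", "))
  }
  aligned <- lapply(tables, function(t) {
    omics_data_table(t$values[, common, drop = FALSE], t$name, t$scale)
  })
  names(aligned) <- nm
  list(tables = aligned,
       annotation = annotation[match(common, annotation$sample), ,
                               drop = FALSE])
}
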