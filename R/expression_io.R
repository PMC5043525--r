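#' Read a gene-by-sample expression matrix from a delimited text file
#'
#' Expects a header row of sample identifiers and one row per gene (or
#' probeset), with the identifier in `id_column` and numeric expression
#' values (log-scale intensities) in the remaining columns. Gzip-compressed
#' files are read transparently. Rows containing unparseable or missing
#' values are rejected, not imputed: the algorithm downstream assumes a
#' complete matrix, so incomplete rows are dropped and reported.
#'
#' @param path Path to a tab-delimited (or `delim`-delimited) text file,
#'   optionally gzip-compressed.
#' @param delim Field delimiter. Default tab.
#' @param id_column Name or position of the gene identifier column.
#'   Default: the first column.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names. Rejected rows (if any) are reported in a
#'   warning and recorded in the `"rejected"` attribute as a character
#'   vector of gene identifiers.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_expression_matrix(simulate_null(3, 4, seed = 1), f)
#' x <- read_expression_matrix(f)
#' dim(x)
#' @export
read_expression_matrix <- function(path, delim = "\t", id_column = 1) {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (is.character(id_column)) {
    id_idx <- match(id_column, colnames(raw))
    if (is.na(id_idx)) {
      stop("identifier column '", id_column, "' not found in header",
           call. = FALSE)
    }
  } else {
    id_idx <- as.integer(id_column)
  }
  gene_ids <- raw[[id_idx]]
  sample_ids <- colnames(raw)[-id_idx]
  if (length(sample_ids) < 2) {
    stop("fewer than 2 sample columns in ", path, call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifier(s) in header: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifier(s): ",
         paste(utils::head(dup_g, 5), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(raw[-id_idx], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(gene_ids, sample_ids))
  bad <- rowSums(is.na(vals)) > 0
  if (all(bad)) {
    stop("no row of ", path, " parses as numeric; offending rows: ",
         paste(utils::head(gene_ids[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable or missing values ",
            "rejected: ", paste(utils::head(gene_ids[bad], 10), collapse = ", "),
            call. = FALSE)
  }
  out <- vals[!bad, , drop = FALSE]
  attr(out, "rejected") <- gene_ids[bad]
  out
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: header row of sample identifiers,
#' first column `gene_id`, one row per gene.
#'
#' @param matrix Numeric matrix with gene row names and sample column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert between expression matrices and tibbles
#'
#' `expression_tbl()` turns a gene-by-sample matrix into a tibble with a
#' `gene_id` column; `as_expression_matrix()` does the reverse. These are
#' the bridges between the matrix substrate the SVD filter operates on and
#' the tabular interfaces of the rest of the package.
#'
#' @param matrix Numeric matrix with gene row names and sample column names.
#' @param data A data frame with one identifier column and numeric sample
#'   columns.
#' @param id_column Name of the identifier column in `data`.
#' @return A tibble, or a numeric matrix, respectively.
#' @export
expression_tbl <- function(matrix) {
  tibble::as_tibble(matrix, rownames = "gene_id")
}

#' @rdname expression_tbl
#' @export
as_expression_matrix <- function(data, id_column = "gene_id") {
  stopifnot(is.data.frame(data), id_column %in% colnames(data))
  ids <- as.character(data[[id_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifiers in '", id_column, "'", call. = FALSE)
  }
  m <- as.matrix(data[setdiff(colnames(data), id_column)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Construct or read a two-column identifier mapping table
#'
#' A mapping table relates source identifiers (probesets, or genes in
#' another species) to target identifiers, many-to-one toward targets. A
#' source that maps to two different targets makes the table ambiguous and
#' is rejected as malformed.
#'
#' @param source_id,target_id Character vectors of equal length.
#' @param name Provenance label for the table.
#' @param path For `read_mapping_table()`: a headerless two-column
#'   tab-delimited file, source identifier first.
#' @return A tibble with columns `source_id`, `target_id` and a `"name"`
#'   attribute.
#' @examples
#' mapping_table(c("p1", "p2"), c("G1", "G1"), name = "probes")
#' @export
mapping_table <- function(source_id, target_id, name = "mapping") {
  tbl <- tibble::tibble(source_id = as.character(source_id),
                        target_id = as.character(target_id))
  tbl <- dplyr::distinct(tbl)
  amb <- unique(tbl$source_id[duplicated(tbl$source_id)])
  if (length(amb) > 0) {
    stop("malformed mapping table '", name, "': source id(s) with ",
         "multiple targets: ", paste(utils::head(amb, 5), collapse = ", "),
         call. = FALSE)
  }
  attr(tbl, "name") <- name
  tbl
}

#' @rdname mapping_table
#' @export
read_mapping_table <- function(path, name = basename(path)) {
  if (!file.exists(path)) {
    stop("mapping table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("mapping table must have two columns", call. = FALSE)
  mapping_table(raw[[1]], raw[[2]], name = name)
}

#' Collapse probeset rows to gene rows by averaging
#'
#' Rows of `matrix` are probeset identifiers; `probe_map` relates probesets
#' to genes. All probesets mapping to the same gene are replaced by their
#' arithmetic mean on the stored (log) scale. Probesets absent from the map
#' are dropped and counted. Output rows are ordered by gene identifier, so
#' the operation is invariant to the input row order.
#'
#' @param matrix Numeric probeset-by-sample matrix with row names.
#' @param probe_map A [mapping_table()] from probeset to gene identifiers.
#' @return A gene-by-sample matrix with attributes `n_unmapped` (count of
#'   dropped probesets) and `unmapped` (their identifiers).
#' @examples
#' m <- rbind(p1 = c(1, 3), p2 = c(3, 5))
#' colnames(m) <- c("s1", "s2")
#' collapse_probesets(m, mapping_table(c("p1", "p2"), c("G", "G")))
#' @export
collapse_probesets <- function(matrix, probe_map) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  probe_map <- mapping_table(probe_map$source_id, probe_map$target_id,
                             name = attr(probe_map, "name") %||% "mapping")
  hit <- probe_map[probe_map$source_id %in% rownames(matrix), ]
  unmapped <- setdiff(rownames(matrix), hit$source_id)
  if (nrow(hit) == 0) {
    stop("no probeset in the matrix maps to any gene", call. = FALSE)
  }
  sums <- rowsum(matrix[hit$source_id, , drop = FALSE],
                 group = hit$target_id, reorder = TRUE)
  counts <- as.vector(table(hit$target_id)[rownames(sums)])
  out <- sums / counts
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "unmapped") <- unmapped
  out
}

#' Map identifiers through an ordered hierarchy of tables
#'
#' Each identifier is mapped by the first (highest-priority, most trusted)
#' table in which it appears; lower-priority tables are consulted only for
#' identifiers the earlier tables miss. This keeps the most specific
#' mapping source in control while still covering the long tail.
#'
#' @param ids Character vector of source identifiers.
#' @param tables List of [mapping_table()]s ordered from most to least
#'   trusted. List names (or table `"name"` attributes) label the source of
#'   each mapping in the output.
#' @return A tibble with one row per input identifier: `source_id`,
#'   `target_id` (`NA` if unmapped), `table_name` (`NA` if unmapped) and
#'   `priority` (1-based index of the supplying table).
#' @examples
#' t1 <- mapping_table("A", "a", name = "curated")
#' t2 <- mapping_table(c("A", "B"), c("x", "b"), name = "predicted")
#' map_identifiers_hierarchical(c("A", "B", "C"), list(t1, t2))
#' @export
map_identifiers_hierarchical <- function(ids, tables) {
  if (length(tables) == 0) {
    stop("at least one mapping table is required", call. = FALSE)
  }
  ids <- as.character(ids)
  nm <- names(tables)
  labels <- vapply(seq_along(tables), function(i) {
    if (!is.null(nm) && nzchar(nm[i])) nm[i]
    else attr(tables[[i]], "name") %||% paste0("table_", i)
  }, character(1))
  target <- rep(NA_character_, length(ids))
  table_name <- rep(NA_character_, length(ids))
  priority <- rep(NA_integer_, length(ids))
  for (i in seq_along(tables)) {
    tbl <- tables[[i]]
    open <- is.na(target)
    hit <- match(ids, tbl$source_id)
    take <- open & !is.na(hit)
    target[take] <- tbl$target_id[hit[take]]
    table_name[take] <- labels[i]
    priority[take] <- i
  }
  tibble::tibble(source_id = ids, target_id = target,
                 table_name = table_name, priority = priority)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
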