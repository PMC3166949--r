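#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids, gene ids in column 1, and non-negative
#' numeric signal values in the body. This is also the shape of the data block
#' inside a GEO Series Matrix file, so one internal representation serves both
#' dialects.
#'
#' @param path Path to a tab-delimited file.
#' @param scaled Logical; whether the stored values are already globally
#'   scaled. Defaults to `FALSE` for plain matrices.
#' @return An [expr_matrix()].
#' @export
read_expression_tsv <- function(path, scaled = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file needs a header row and at least one gene row",
         call. = FALSE)
  }
  parse_matrix_lines(lines, source = path, scaled = scaled)
}

# shared body parser for the TSV and Series Matrix dialects
parse_matrix_lines <- function(lines, source, scaled) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- strip_quotes(fields[[1]])
  sample_ids <- header[-1]
  if (length(sample_ids) == 0L) {
    stop(sprintf("%s: header row carries no sample ids", source), call. = FALSE)
  }
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop(sprintf("%s: ragged row (line %d has %d fields, header has %d)",
                 source, which(widths != length(header))[1] + 1L,
                 widths[widths != length(header)][1], length(header)),
         call. = FALSE)
  }
  gene_ids <- strip_quotes(vapply(body, `[[`, character(1), 1L))
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("%s: duplicate gene id '%s'",
                 source, gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("%s: invalid cell '%s' at gene '%s', sample '%s' (must be a non-negative number)",
                   source, body[[i]][-1][bad[1]], gene_ids[i], sample_ids[bad[1]]),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), source))
  expr_matrix(vals, scaled = scaled)
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

#' Write an expression matrix to tab-delimited text
#'
#' Values are written with full precision (17 significant digits); rounding is
#' a presentation concern only and round-trips must be exact.
#'
#' @param matrix An [expr_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(unclass(matrix), 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Extracts the data block between the standard
#' `!series_matrix_table_begin` / `!series_matrix_table_end` sentinels.
#' Metadata lines outside the block are ignored (their count is logged).
#' Quoted identifiers are unquoted. Deposited values are post-processing, so
#' the result is flagged `scaled = TRUE` by convention.
#'
#' @param path Path to a Series Matrix file.
#' @return An [expr_matrix()] with `scaled = TRUE`.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop(sprintf("%s: missing or malformed series-matrix table sentinels", path),
         call. = FALSE)
  }
  message(sprintf("ignored %d metadata lines outside the data block",
                  length(lines) - (end - begin + 1L)))
  block <- lines[(begin + 1L):(end - 1L)]
  block <- block[nzchar(block)]
  parse_matrix_lines(block, source = path, scaled = TRUE)
}

#' Read a sample sheet
#'
#' Tab-delimited with columns `sample_id`, `strain`, `condition`, `replicate`.
#' Strain and condition tokens are case-folded against [pka_strains()] and
#' [pka_conditions()]; anything else is a hard error, never a silent coercion.
#'
#' @param path Path to a tab-delimited sample sheet.
#' @return A data.frame with one validated descriptor per row.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data.frame
#'
#' @param df Data.frame with columns `sample_id`, `strain`, `condition`,
#'   `replicate`.
#' @return The validated data.frame with canonical upper-case tokens.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "strain", "condition", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("sample sheet lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$strain <- toupper(trimws(as.character(df$strain)))
  df$condition <- toupper(trimws(as.character(df$condition)))
  bad <- setdiff(unique(df$strain), pka_strains())
  if (length(bad)) {
    stop(sprintf("unknown strain token(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$condition), pka_conditions())
  if (length(bad)) {
    stop(sprintf("unknown condition token(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (any(is.na(rep_num) | rep_num < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  df$replicate <- rep_num
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample_id '%s'",
                 df$sample_id[duplicated(df$sample_id)][1]), call. = FALSE)
  }
  key <- paste(df$strain, df$condition, df$replicate, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (strain, condition, replicate) triple: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  df[need]
}

#' @rdname read_sample_sheet
#' @param samples Sample-sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# check every matrix column has a descriptor; returns descriptors in matrix order
match_samples <- function(matrix, samples) {
  idx <- match(colnames(matrix), samples$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("sample(s) in matrix without descriptor: %s",
                 paste(colnames(matrix)[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  samples[idx, , drop = FALSE]
}

#' Write and re-read a classification report
#'
#' `write_classification_report()` emits one tab-delimited row per gene
#' (factors per strain, response calls, PKA class, transience, gluconeogenic
#' category) plus a JSON sidecar (`<path>.summary.json`) with machine-readable
#' category counts. `read_classification_report()` reads the table back.
#'
#' @param profiles A `pka_profiles` data.frame from [build_profiles()].
#' @param path Output path for the tab-delimited report.
#' @return `write_classification_report()` returns the sidecar counts,
#'   invisibly; `read_classification_report()` returns the report data.frame.
#' @export
write_classification_report <- function(profiles, path) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- list(
    n_genes = nrow(profiles),
    pka_class = as.list(table(profiles$pka_class)),
    direction = as.list(table(profiles$direction)),
    transience_ref = as.list(table(profiles$transience_ref)),
    gluconeogenic = as.list(table(profiles$gluconeogenic))
  )
  jsonlite::write_json(counts, paste0(path, ".summary.json"), auto_unbox = TRUE)
  invisible(counts)
}

#' @rdname write_classification_report
#' @export
read_classification_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
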