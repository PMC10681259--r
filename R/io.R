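# Readers and writers. TSV dialect throughout: tab-separated, UTF-8,
# "." decimal, NA token "NA". Gene identifiers are case-sensitive.

#' Read a gene-by-sample count matrix
#'
#' `format = "plain"` expects a header row with the gene-id column first
#' and one column per sample. `format = "featurecounts"` accepts the
#' native featureCounts layout (optional `#`-comment first line, then
#' Geneid, Chr, Start, End, Strand, Length and the sample columns) and
#' keeps column 1 plus columns 7 onward.
#'
#' @param path TSV file path.
#' @param format `"plain"` or `"featurecounts"`.
#' @return Validated count tibble (`gene_id` + sample columns).
#' @export
read_count_matrix <- function(path, format = c("plain", "featurecounts")) {
  format <- match.arg(format)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (format == "featurecounts") {
    if (ncol(tbl) < 7) {
      abort("featureCounts tables need at least 7 columns.")
    }
    tbl <- tbl[, c(1, 7:ncol(tbl))]
  }
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  validate_count_matrix(tbl)
  tbl
}

#' Write a count matrix
#' @param counts Count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample`, `condition` (or `group`) and
#'   optionally `replicate`.
#' @return Design tibble.
#' @export
read_design <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample" %in% names(tbl)) {
    abort("Design file must have a `sample` column.")
  }
  tbl$sample <- as.character(tbl$sample)
  tbl
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Selects the LFQ intensity columns by prefix and maps the standard
#' evidence/flag columns; "+" flags are parsed to logicals. Column names
#' are configurable for non-default exports.
#'
#' @param path TSV file path (a `proteinGroups.txt`-style export).
#' @param lfq_prefix Prefix of the per-sample intensity columns
#'   (default `"LFQ intensity "`); the sample name is the remainder.
#' @param id_col,razor_col,reverse_col,contaminant_col Source column
#'   names.
#' @return Raw-stage protein-group tibble: `group_id`,
#'   `razor_unique_peptides`, `reverse`, `contaminant`, plus one intensity
#'   column per sample.
#' @export
read_protein_groups <- function(path, lfq_prefix = "LFQ intensity ",
                                id_col = "Protein IDs",
                                razor_col = "Razor + unique peptides",
                                reverse_col = "Reverse",
                                contaminant_col = "Potential contaminant") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  for (cl in c(id_col, razor_col, reverse_col, contaminant_col)) {
    if (!cl %in% names(tbl)) {
      abort(paste0("Column `", cl, "` not found in ", path, "."))
    }
  }
  lfq_cols <- names(tbl)[startsWith(names(tbl), lfq_prefix)]
  if (length(lfq_cols) == 0) {
    abort(paste0("No columns match the LFQ prefix `", lfq_prefix, "`."))
  }
  out <- tibble(
    group_id = as.character(tbl[[id_col]]),
    razor_unique_peptides = as.integer(tbl[[razor_col]]),
    reverse = parse_plus_flag(tbl[[reverse_col]]),
    contaminant = parse_plus_flag(tbl[[contaminant_col]])
  )
  for (cl in lfq_cols) {
    out[[substring(cl, nchar(lfq_prefix) + 1)]] <- as.numeric(tbl[[cl]])
  }
  set_stage(out, "raw")
}

parse_plus_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- as.character(x)
  !is.na(x) & x == "+"
}

#' Read a gene set (one id per line)
#' @param path Text file, one gene id per line; blank lines ignored.
#' @return Character vector of unique ids, input order preserved.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Write a gene set (one id per line)
#' @param ids Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a GMT-style multi-set file
#'
#' Each line: set name, description, then the member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort("GMT lines need at least a name, a description and one id.")
    }
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Read a two-column gene-to-category annotation
#' @param path TSV with columns `gene_id`, `category` (header required).
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "category") %in% names(tbl))) {
    abort("Annotation file must have `gene_id` and `category` columns.")
  }
  tbl
}

#' Import a worksheet from an Excel workbook
#'
#' Thin wrapper over `readxl::read_excel()` with optional column
#' renaming, for ingesting supplementary-material workbooks (e.g. an
#' enrichment table whose fold-change and p-value columns carry
#' journal-specific names).
#'
#' @param path Workbook path (`.xlsx` / `.xls`).
#' @param sheet Sheet name or index (default first sheet).
#' @param column_map Optional named character vector
#'   `c(new_name = "Source Column")`; mapped columns must exist.
#' @return Tibble of the (renamed) sheet.
#' @export
import_xlsx_table <- function(path, sheet = 1, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.character(sheet) &&
      !sheet %in% readxl::excel_sheets(path)) {
    abort(paste0("Sheet `", sheet, "` not found in ", path, "."))
  }
  tbl <- readxl::read_excel(path, sheet = sheet)
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(tbl))
    if (length(missing)) {
      abort(paste0("Mapped column(s) not found: ",
                   paste(missing, collapse = ", ")))
    }
    for (i in seq_along(column_map)) {
      names(tbl)[names(tbl) == column_map[i]] <- names(column_map)[i]
    }
  }
  as_tibble(tbl)
}

#' Score and select targets from an imported enrichment table
#'
#' Applies the Vfactor to a table that already carries log2 fold changes
#' and p-values (e.g. an imported differential-enrichment export) and
#' selects targets by the strict threshold. Column names are configurable
#' to match the source table.
#'
#' @param tbl Data frame with fold-change and p-value columns.
#' @param log2fc_col,p_col Source column names (defaults
#'   `"log2FoldChange"`, `"pvalue"`).
#' @param id_col Gene-id column (default `"gene_id"`).
#' @param threshold Strict selection threshold (default 50).
#' @param p_floor Floor applied to p (default `1e-300`).
#' @return Tibble `gene_id`, `log2fc`, `p`, `vfactor`, `selected`.
#' @export
score_enrichment_table <- function(tbl, log2fc_col = "log2FoldChange",
                                   p_col = "pvalue", id_col = "gene_id",
                                   threshold = 50, p_floor = 1e-300) {
  for (cl in c(id_col, log2fc_col, p_col)) {
    if (!cl %in% names(tbl)) {
      abort(paste0("Column `", cl, "` not found."))
    }
  }
  out <- tibble(
    gene_id = as.character(tbl[[id_col]]),
    log2fc = as.numeric(tbl[[log2fc_col]]),
    p = as.numeric(tbl[[p_col]])
  )
  out$vfactor <- vfactor(out$log2fc, out$p, p_floor = p_floor)
  out$selected <- !is.na(out$vfactor) & out$vfactor > threshold
  out
}

#' Write an enrichment or interactor result table
#' @param res Result tibble ([rip_enrichment()] / [call_interactors()] /
#'   [enrichment_report()] output).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(res, path) {
  readr::write_tsv(as_tibble(res), path)
  invisible(path)
}

#' Write a YAML run manifest
#'
#' Records the command name, the full parameter set, input file digests,
#' the seed and the package version, so a run can be reproduced exactly.
#'
#' @param path Output YAML path.
#' @param command Name of the pipeline stage.
#' @param params Named list of parameters (must include any seed used).
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, params = list(),
                               inputs = character()) {
  digest_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    con <- file(f, "rb")
    on.exit(close(con))
    bytes <- readBin(con, "raw", n = file.info(f)$size)
    # small stable checksum: sum of bytes and length (no digest dep)
    sprintf("sum%08x-len%d", sum(as.integer(bytes)) %% .Machine$integer.max,
            length(bytes))
  }
  manifest <- list(
    command = command,
    params = params,
    inputs = lapply(setNames(as.list(inputs), inputs), digest_file),
    tool_version = as.character(utils::packageVersion("ripscore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
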