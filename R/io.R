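# Reading and writing peptide quantification tables, sample metadata,
# FASTA, PSSM files and YAML run configuration.

#' Table dialect for MaxQuant-style peptide tables
#'
#' Describes the column layout of a tab-separated peptide quantification
#' table. Defaults follow the MaxQuant `peptides.txt` conventions: a
#' `Sequence` column, a `Proteins` column of semicolon-separated identifiers,
#' one `Intensity <sample>` column per sample, and marker columns flagging
#' reversed-decoy and contaminant hits with `"+"`.
#'
#' @param sequence_col name of the peptide-sequence column.
#' @param proteins_col name of the protein-identifier column.
#' @param intensity_prefix prefix of per-sample intensity columns; the sample
#'   id is the remainder of the column name.
#' @param reverse_col,contaminant_col marker columns whose flagged rows are
#'   dropped; set to `NULL` to disable.
#' @param marker string marking a flagged row.
#' @return A list of class `table_dialect`.
#' @export
table_dialect <- function(sequence_col = "Sequence",
                          proteins_col = "Proteins",
                          intensity_prefix = "Intensity ",
                          reverse_col = "Reverse",
                          contaminant_col = "Potential contaminant",
                          marker = "+") {
  structure(list(sequence_col = sequence_col, proteins_col = proteins_col,
                 intensity_prefix = intensity_prefix, reverse_col = reverse_col,
                 contaminant_col = contaminant_col, marker = marker),
            class = "table_dialect")
}

#' Construct a peptide record
#'
#' @param sequence uppercase amino-acid string.
#' @param proteins character vector of source-protein identifiers.
#' @param volumes named numeric vector of raw ion peak volumes keyed by
#'   sample id; zero or missing means not detected and is not stored.
#' @return A list of class `peptide_record`.
#' @export
peptide_record <- function(sequence, proteins = character(), volumes = numeric()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  if (any(volumes < 0)) stop("ion peak volumes must be non-negative")
  volumes <- volumes[volumes > 0]
  structure(list(sequence = sequence,
                 proteins = as.character(proteins),
                 volumes = volumes),
            class = "peptide_record")
}

#' Read a peptide quantification table
#'
#' Reads a tab-separated MaxQuant-style peptide table into a list of
#' [peptide_record()]s. Rows flagged in the reverse-decoy or contaminant
#' columns are dropped, as are sequences containing non-canonical residues
#' (B, Z, X, U, ...), with a warning. Rows sharing a sequence are merged by
#' summing per-sample volumes, so the result has one record per unique
#' sequence. Zero and missing intensities both mean "not detected".
#'
#' @param path file path.
#' @param dialect a [table_dialect()].
#' @return List of `peptide_record` objects, in first-appearance order.
#' @export
read_peptide_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  for (col in c(dialect$sequence_col, dialect$proteins_col)) {
    if (!col %in% names(df)) {
      stop("peptide table format error: missing mandatory column '", col, "'")
    }
  }
  int_cols <- names(df)[startsWith(names(df), dialect$intensity_prefix)]
  if (length(int_cols) == 0L) {
    stop("peptide table format error: no columns with intensity prefix '",
         dialect$intensity_prefix, "'")
  }
  sample_ids <- substring(int_cols, nchar(dialect$intensity_prefix) + 1L)

  keep <- rep(TRUE, nrow(df))
  for (mcol in c(dialect$reverse_col, dialect$contaminant_col)) {
    if (!is.null(mcol) && mcol %in% names(df)) {
      keep <- keep & !(as.character(df[[mcol]]) %in% dialect$marker)
    }
  }
  df <- df[keep, , drop = FALSE]

  seqs <- toupper(as.character(df[[dialect$sequence_col]]))
  ok <- is_canonical_sequence(seqs) & nchar(seqs) >= 1L
  if (any(!ok)) {
    warning(sum(!ok), " sequence(s) with non-canonical residues dropped")
    df <- df[ok, , drop = FALSE]
    seqs <- seqs[ok]
  }

  vol <- matrix(0, nrow = nrow(df), ncol = length(int_cols),
                dimnames = list(NULL, sample_ids))
  for (j in seq_along(int_cols)) {
    raw <- df[[int_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric intensity in column '", int_cols[j],
           "', row ", bad[1])
    }
    num[is.na(num)] <- 0
    vol[, j] <- num
  }
  if (any(vol < 0)) stop("parse error: negative intensity value")

  prot <- strsplit(as.character(df[[dialect$proteins_col]]), ";", fixed = TRUE)
  uniq <- unique(seqs)
  idx <- split(seq_along(seqs), factor(seqs, levels = uniq))
  lapply(uniq, function(s) {
    rows <- idx[[s]]
    v <- if (length(rows) == 1L) vol[rows, ] else colSums(vol[rows, , drop = FALSE])
    peptide_record(s,
                   proteins = unique(unlist(prot[rows])),
                   volumes = v)
  })
}

#' Write peptide records back to a MaxQuant-style table
#'
#' Inverse of [read_peptide_table()]: one row per record, one intensity
#' column per sample. Volumes are written with 17 significant digits so the
#' read/write round trip is exact.
#'
#' @param records list of [peptide_record()]s.
#' @param path output file path.
#' @param dialect a [table_dialect()].
#' @export
write_peptide_table <- function(records, path, dialect = table_dialect()) {
  samples <- sort(unique(unlist(lapply(records, function(r) names(r$volumes)))))
  header <- c(dialect$sequence_col, dialect$proteins_col,
              paste0(dialect$intensity_prefix, samples))
  lines <- vapply(records, function(r) {
    v <- setNames(rep(0, length(samples)), samples)
    v[names(r$volumes)] <- r$volumes
    paste(c(r$sequence, paste(r$proteins, collapse = ";"),
            sprintf("%.17g", v)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `cell_line`, `allotype`,
#' `bio_replicate`, `tech_replicate`.
#'
#' @param path file path.
#' @param allotypes optional character vector of allowed allotype labels.
#' @return data.frame with one row per sample.
#' @export
read_sample_meta <- function(path, allotypes = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample_id", "cell_line", "allotype", "bio_replicate", "tech_replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample metadata format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(allotypes) && !all(df$allotype %in% allotypes)) {
    stop("allotype outside the configured set: ",
         paste(setdiff(df$allotype, allotypes), collapse = ", "))
  }
  df$bio_replicate <- as.integer(df$bio_replicate)
  df$tech_replicate <- as.integer(df$tech_replicate)
  df
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [read_sample_meta()].
#' @param path output file path.
#' @export
write_sample_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Construct a position-specific scoring matrix object
#'
#' @param values numeric matrix, positions x 20 residues (columns in the
#'   classic BLOSUM residue order `AA_ORDER`).
#' @param kind one of `"frequency"`, `"log_odds"`, `"shannon_height"`.
#' @return A matrix of class `pssm` with a `kind` attribute.
#' @export
pssm_matrix <- function(values, kind = c("frequency", "log_odds", "shannon_height")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (ncol(values) != 20L) stop("a PSSM needs 20 residue columns")
  colnames(values) <- AA_ORDER
  rownames(values) <- seq_len(nrow(values))
  if (kind == "frequency") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("frequency PSSM validation error: row sums deviate from 1 (max |dev| = ",
           format(max(abs(rs - 1))), ")")
    }
  }
  structure(values, kind = kind, class = c("pssm", "matrix", "array"))
}

#' Write a PSSM to a tab-separated text file
#'
#' One row per motif position, 20 named residue columns, a leading `pos`
#' column, and a `# kind:` comment line. Values carry 17 significant digits so
#' [read_pssm()] restores them bit-exactly.
#'
#' @param matrix a [pssm_matrix()].
#' @param path output file path.
#' @export
write_pssm <- function(matrix, path) {
  if (!inherits(matrix, "pssm")) matrix <- pssm_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", attr(matrix, "kind")), con)
  writeLines(paste(c("pos", AA_ORDER), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(i, sprintf("%.17g", matrix[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#' @param path file path.
#' @return A [pssm_matrix()].
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  kind <- sub("^# kind: *", "", lines[1])
  df <- read.delim(text = lines[-1], sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, AA_ORDER, drop = FALSE])
  storage.mode(m) <- "double"
  pssm_matrix(m, kind = kind)
}

#' Read a YAML run-configuration file
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Read a published abundance-share table as a one-column repertoire
#'
#' Loads a TSV of peptides with already-normalized abundances given in
#' percent (columns `sequence`, `protein`, `percent_normalized_volume`), such
#' as the shipped reference top-20 tables for the DQ2.5 / DQ2.2 / DQ7.5
#' eluted repertoires (see `system.file("extdata", package = "motifquant")`).
#' The values are stored as fractions in a single-sample
#' [repertoire_matrix()], so [abundance_share()] reproduces the printed
#' percentages directly.
#'
#' @param path TSV file path.
#' @param group label used as sample id and allotype.
#' @return A [repertoire_matrix()] with one column.
#' @export
read_share_table <- function(path, group) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("sequence", "percent_normalized_volume")
  if (!all(needed %in% names(df))) {
    stop("share table format error: need columns ",
         paste(needed, collapse = ", "))
  }
  meta <- data.frame(sample_id = group, cell_line = NA_character_,
                     allotype = group, bio_replicate = NA_integer_,
                     tech_replicate = NA_integer_, stringsAsFactors = FALSE)
  repertoire_matrix(cbind(df$percent_normalized_volume / 100),
                    df$sequence, meta)
}
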