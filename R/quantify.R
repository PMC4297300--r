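# Scale-ratio normalization of ion peak volumes, replicate averaging,
# abundance shares, length distributions, nested sets and CLIP annotation.

#' Construct a repertoire matrix
#'
#' A peptides x samples matrix of normalized abundances on the 0-1 scale
#' (0 = not detected) together with sample metadata.
#'
#' @param values numeric matrix, peptides in rows, samples in columns.
#' @param peptides character vector of peptide sequences (row names).
#' @param samples data.frame of sample metadata; `samples$sample_id` must
#'   match the column order of `values`.
#' @return A list of class `repertoire_matrix` with elements `values`,
#'   `peptides`, `samples`.
#' @export
repertoire_matrix <- function(values, peptides, samples) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(peptides),
            ncol(values) == nrow(samples))
  if (any(values < 0) || any(values > 1 + 1e-12)) {
    stop("repertoire matrix entries must lie in [0, 1]")
  }
  dimnames(values) <- list(peptides, samples$sample_id)
  structure(list(values = values, peptides = peptides, samples = samples),
            class = "repertoire_matrix")
}

#' @export
print.repertoire_matrix <- function(x, ...) {
  cat("repertoire_matrix:", nrow(x$values), "peptides x",
      ncol(x$values), "samples\n")
  if ("allotype" %in% names(x$samples)) {
    cat("allotypes:", paste(unique(x$samples$allotype), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scale-ratio normalization of ion peak volumes
#'
#' Divides each peptide's raw ion peak volume by the summed volume of all
#' peptides identified in the same sample, so each sample column sums to 1 and
#' every value lies on a 0-1 scale. Peptides not detected in a sample stay 0.
#' A sample with no detected peptides is left all-zero with a warning.
#'
#' @param records list of [peptide_record()]s.
#' @param meta sample metadata data.frame ([read_sample_meta()] layout); every
#'   sample referenced by a record must appear here.
#' @return A [repertoire_matrix()].
#' @export
normalize_scale_ratio <- function(records, meta) {
  seqs <- vapply(records, `[[`, character(1), "sequence")
  if (anyDuplicated(seqs)) stop("duplicate peptide sequences in records; merge first")
  referenced <- unique(unlist(lapply(records, function(r) names(r$volumes))))
  unknown <- setdiff(referenced, meta$sample_id)
  if (length(unknown) > 0L) {
    stop("sample(s) in records missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  raw <- matrix(0, nrow = length(records), ncol = nrow(meta),
                dimnames = list(seqs, meta$sample_id))
  for (i in seq_along(records)) {
    v <- records[[i]]$volumes
    if (length(v) > 0L) raw[i, names(v)] <- v
  }
  totals <- colSums(raw)
  empty <- totals == 0
  if (any(empty)) {
    warning("sample(s) with no detected peptides left all-zero: ",
            paste(meta$sample_id[empty], collapse = ", "))
    totals[empty] <- 1
  }
  repertoire_matrix(sweep(raw, 2, totals, "/"), seqs, meta)
}

#' Average repertoire columns by a metadata grouping
#'
#' Collapses the sample columns to one column per level of a metadata field,
#' each entry the unweighted arithmetic mean over the group's columns
#' (absent peptides contribute 0). Grouping by `sample_id` returns the matrix
#' unchanged.
#'
#' @param matrix a [repertoire_matrix()].
#' @param group_by name of a metadata column, e.g. `"allotype"`.
#' @return A [repertoire_matrix()] with one column per group; metadata fields
#'   that are not constant within a group become `NA`.
#' @export
mean_by_group <- function(matrix, group_by = "allotype") {
  if (!group_by %in% names(matrix$samples)) {
    stop("unknown metadata key: ", group_by)
  }
  g <- as.character(matrix$samples[[group_by]])
  levels <- unique(g)
  vals <- vapply(levels, function(lev) {
    rowMeans(matrix$values[, g == lev, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (!is.matrix(vals)) vals <- rbind(vals) # single-peptide edge case
  dimnames(vals) <- list(matrix$peptides, levels)
  meta <- data.frame(sample_id = levels, stringsAsFactors = FALSE)
  for (col in setdiff(names(matrix$samples), "sample_id")) {
    u <- vapply(levels, function(lev) {
      v <- unique(matrix$samples[[col]][g == lev])
      if (length(v) == 1L) as.character(v) else NA_character_
    }, character(1))
    meta[[col]] <- u
  }
  if (group_by != "sample_id") meta[[group_by]] <- levels
  repertoire_matrix(vals, matrix$peptides, meta)
}

#' Group-mean abundance column for one group
#' @noRd
group_mean_column <- function(matrix, group, group_by = "allotype") {
  if (group %in% matrix$samples$sample_id) {
    return(matrix$values[, match(group, matrix$samples$sample_id)])
  }
  if (!group_by %in% names(matrix$samples) ||
      !group %in% matrix$samples[[group_by]]) {
    stop("group not present: ", group)
  }
  rowMeans(matrix$values[, matrix$samples[[group_by]] == group, drop = FALSE])
}

#' Abundance share of a peptide selection
#'
#' Sum of the group-mean normalized abundances of a set of peptides, as a
#' percentage of the group total. The selection rule is top-N by group-mean
#' abundance (`top_n`), an explicit sequence list (`sequences`), or a
#' predicate over sequences (`predicate`, e.g. a CLIP flag lookup).
#'
#' @param matrix a [repertoire_matrix()].
#' @param group allotype label (or sample id) whose mean column to use.
#' @param top_n integer, select the N most abundant peptides.
#' @param sequences explicit peptide sequences to select.
#' @param predicate function mapping a character vector of sequences to a
#'   logical vector.
#' @param group_by metadata field defining groups (default `"allotype"`).
#' @return Share in percent (0-100).
#' @export
abundance_share <- function(matrix, group, top_n = NULL, sequences = NULL,
                            predicate = NULL, group_by = "allotype") {
  col <- group_mean_column(matrix, group, group_by)
  sel <- if (!is.null(top_n)) {
    rank(-col, ties.method = "first") <= top_n
  } else if (!is.null(sequences)) {
    matrix$peptides %in% sequences
  } else if (!is.null(predicate)) {
    predicate(matrix$peptides)
  } else {
    rep(TRUE, length(col))
  }
  if (!any(sel)) {
    warning("empty peptide selection; share is 0")
    return(0)
  }
  100 * sum(col[sel])
}

#' Length distribution of detected peptides
#'
#' Counts unique detected peptide sequences per length for one group (or all
#' samples) and reports the modal length (ties broken toward the smaller
#' length).
#'
#' @param matrix a [repertoire_matrix()].
#' @param group allotype label, or `NULL` for all samples.
#' @param group_by metadata field defining groups.
#' @return List with `counts` (named integer vector keyed by length) and
#'   `mode` (integer, `NA` for an empty repertoire).
#' @export
length_distribution <- function(matrix, group = NULL, group_by = "allotype") {
  col <- if (is.null(group)) rowSums(matrix$values) else {
    group_mean_column(matrix, group, group_by)
  }
  detected <- unique(matrix$peptides[col > 0])
  if (length(detected) == 0L) {
    return(list(counts = setNames(integer(0), character(0)), mode = NA_integer_))
  }
  tab <- table(nchar(detected))
  counts <- setNames(as.integer(tab), names(tab))
  lens <- as.integer(names(counts))
  mode <- lens[which.max(counts)] # which.max takes the first maximum; lens ascending
  list(counts = counts, mode = mode)
}

#' Assign peptides to nested sets
#'
#' Two peptides belong to the same nested set iff they are connected under
#' the relation "one sequence contains the other as a contiguous substring"
#' (transitive closure). Singletons receive their own set id; membership in a
#' nested set means set size >= 2.
#'
#' @param sequences character vector of unique peptide sequences (a list of
#'   [peptide_record()]s is also accepted).
#' @return Named integer vector mapping each sequence to a set id.
#' @export
assign_nested_sets <- function(sequences) {
  if (is.list(sequences)) {
    sequences <- vapply(sequences, `[[`, character(1), "sequence")
  }
  if (anyDuplicated(sequences)) stop("sequences must be unique")
  n <- length(sequences)
  if (n == 0L) return(setNames(integer(0), character(0)))
  uf <- make_union_find(n)
  id_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(sequences[i], i, envir = id_of)
  lens <- sort(unique(nchar(sequences)))
  for (i in seq_len(n)) {
    s <- sequences[i]
    L <- nchar(s)
    for (l in lens) {
      if (l >= L) break
      for (start in 1:(L - l + 1)) {
        sub <- substr(s, start, start + l - 1L)
        j <- get0(sub, envir = id_of, inherits = FALSE)
        if (!is.null(j)) uf$union(i, j)
      }
    }
  }
  comp <- uf$components()
  setNames(match(comp, unique(comp)), sequences)
}

#' Which peptides are part of a nested set (set size >= 2)?
#' @param set_ids output of [assign_nested_sets()].
#' @return Named logical vector.
#' @export
in_nested_set <- function(set_ids) {
  sizes <- table(set_ids)
  setNames(as.integer(sizes[as.character(set_ids)]) >= 2L, names(set_ids))
}

#' Filter a repertoire the way the motif analyses filter theirs
#'
#' Drops peptides shorter than `min_length` and peptides that are not part of
#' a nested set.
#'
#' @param matrix a [repertoire_matrix()].
#' @param min_length minimum retained peptide length (default 11).
#' @return A [repertoire_matrix()] restricted to the retained peptides.
#' @export
filter_repertoire <- function(matrix, min_length = 11L) {
  nested <- in_nested_set(assign_nested_sets(matrix$peptides))
  keep <- nchar(matrix$peptides) >= min_length & nested[matrix$peptides]
  repertoire_matrix(matrix$values[keep, , drop = FALSE],
                    matrix$peptides[keep], matrix$samples)
}

#' CLIP annotation configuration
#'
#' Defaults target the canonical CLIP span of the invariant chain (CD74):
#' peptides mapping into the configured CD74 region, or containing one of the
#' CLIP1/CLIP2 binding-register cores, are flagged. Both rules are active by
#' default; core sequences and the region are configurable because published
#' CLIP registers vary.
#'
#' @param source_protein_ids identifiers of the invariant chain entry in the
#'   protein FASTA.
#' @param clip_region inclusive residue interval (start, end) on CD74.
#' @param core_motifs CLIP core sequences matched as substrings.
#' @param min_overlap minimum residues of overlap with `clip_region`.
#' @param rules subset of `c("region", "core")`.
#' @return List of class `clip_config`.
#' @export
clip_config <- function(source_protein_ids = "CD74",
                        clip_region = c(81L, 104L),
                        core_motifs = c(CLIP1 = "MRMATPLLM", CLIP2 = "ATPLLMQAL"),
                        min_overlap = 9L,
                        rules = c("region", "core")) {
  stopifnot(length(clip_region) == 2L, clip_region[1] <= clip_region[2],
            all(nchar(core_motifs) > 0L), all(rules %in% c("region", "core")))
  structure(list(source_protein_ids = source_protein_ids,
                 clip_region = as.integer(clip_region),
                 core_motifs = core_motifs,
                 min_overlap = as.integer(min_overlap),
                 rules = rules),
            class = "clip_config")
}

#' Flag CLIP peptides
#'
#' A peptide is flagged as CLIP if (a) it maps exactly within the invariant
#' chain (CD74) sequence and its span overlaps the configured CLIP region by
#' at least `min_overlap` residues, or (b) it contains any configured CLIP
#' core as a substring. Which of the two rules apply is set in the config.
#'
#' @param sequences character vector of peptide sequences (or a list of
#'   [peptide_record()]s).
#' @param clip a [clip_config()].
#' @param proteins named character vector of protein sequences (e.g. from
#'   [read_protein_fasta()]); required when the `"region"` rule is active.
#' @return Named logical vector.
#' @export
annotate_clip <- function(sequences, clip = clip_config(), proteins = NULL) {
  if (is.list(sequences)) {
    sequences <- vapply(sequences, `[[`, character(1), "sequence")
  }
  flag <- rep(FALSE, length(sequences))
  if ("region" %in% clip$rules) {
    present <- clip$source_protein_ids %in% names(proteins)
    if (!any(present)) {
      stop("CLIP configuration error: none of the source protein id(s) (",
           paste(clip$source_protein_ids, collapse = ", "),
           ") found in the protein FASTA")
    }
    for (pid in clip$source_protein_ids[present]) {
      prot <- proteins[[pid]]
      pos <- vapply(sequences, function(s) {
        as.integer(regexpr(s, prot, fixed = TRUE))
      }, integer(1))
      hit <- pos > 0L
      if (any(hit)) {
        start <- pos[hit]
        end <- start + nchar(sequences[hit]) - 1L
        overlap <- pmin(end, clip$clip_region[2]) - pmax(start, clip$clip_region[1]) + 1L
        flag[hit] <- flag[hit] | (overlap >= clip$min_overlap)
      }
    }
  }
  if ("core" %in% clip$rules) {
    for (core in clip$core_motifs) {
      flag <- flag | grepl(core, sequences, fixed = TRUE)
    }
  }
  setNames(flag, sequences)
}
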