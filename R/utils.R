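# Internal helpers shared across modules.

#' Run code with a locally seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Union-find over n items; returns a function environment.
#' @noRd
make_union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # attach the larger root under the smaller so component ids are deterministic
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) return(invisible(NULL))
    lo <- min(ri, rj); hi <- max(ri, rj)
    parent[hi] <<- lo
    invisible(NULL)
  }
  components <- function() {
    vapply(seq_len(n), find, integer(1))
  }
  list(find = find, union = union, components = components)
}

#' Validate that sequences use only the 20 canonical residues.
#' @noRd
is_canonical_sequence <- function(x) {
  !grepl(paste0("[^", paste(AA_ORDER, collapse = ""), "]"), x)
}

#' Map residue characters to 0-based integer codes in `AA_ORDER`; NA for unknown.
#' @noRd
aa_codes <- function(sequences) {
  lookup <- setNames(seq_along(AA_ORDER) - 1L, AA_ORDER)
  lapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    unname(lookup[ch])
  })
}

#' Pad 0-based code lists into an n x Lmax integer matrix (-1 beyond length).
#' @noRd
codes_matrix <- function(code_list) {
  lens <- lengths(code_list)
  m <- matrix(-1L, nrow = length(code_list), ncol = max(lens, 1L))
  for (i in seq_along(code_list)) {
    if (lens[i] > 0) m[i, seq_len(lens[i])] <- code_list[[i]]
  }
  list(codes = m, lengths = as.integer(lens))
}
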