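# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by the most literal method
# available, independent of the package's implementation paths.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptides <- function(n, length, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(aa20, length, replace = TRUE), collapse = "")
  }, character(1))
}

# connected components under "one contains the other" via all-pairs checks
bf_nested_components <- function(seqs) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      adj[i, j] <- grepl(seqs[i], seqs[j], fixed = TRUE) ||
        grepl(seqs[j], seqs[i], fixed = TRUE)
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      comp[i] <- cid
      while (length(queue) > 0L) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# connected components under "shares any identical k-mer"
bf_shared_kmer_components <- function(seqs, k = 9L) {
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    starts <- 1:(nchar(s) - k + 1L)
    unique(substring(s, starts, starts + k - 1L))
  })
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) adj[i, j] <- length(intersect(kmers[[i]], kmers[[j]])) > 0L
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      comp[i] <- cid
      while (length(queue) > 0L) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# literal greedy average-linkage agglomeration; returns merge heights
bf_average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in 1:(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# independent forward pass of one network over every core window
r_score_cores <- function(net, peptide, enc, L = 9L) {
  chars <- strsplit(peptide, "")[[1]]
  codes <- match(chars, aa20)
  n_off <- length(codes) - L + 1L
  vapply(seq_len(n_off), function(o) {
    win <- codes[o:(o + L - 1L)]
    x <- as.vector(t(enc[win, , drop = FALSE])) # position-major encoding
    h <- 1 / (1 + exp(-(net$b1 + as.numeric(crossprod(net$w1, x)))))
    1 / (1 + exp(-(net$b2 + sum(net$w2 * h))))
  }, numeric(1))
}

zero_network <- function(motif_length = 9L, hidden = 3L) {
  list(w1 = matrix(0, motif_length * 20L, hidden), b1 = numeric(hidden),
       w2 = numeric(hidden), b2 = 0, seed = 1L, fold = 1L)
}

# minimal repertoire matrix from a plain value matrix
toy_matrix <- function(values, allotypes = NULL, peptides = NULL) {
  values <- as.matrix(values)
  if (is.null(peptides)) {
    peptides <- random_peptides(nrow(values), 12, seed = 99)
  }
  ids <- paste0("s", seq_len(ncol(values)))
  meta <- data.frame(
    sample_id = ids,
    cell_line = ids,
    allotype = if (is.null(allotypes)) ids else allotypes,
    bio_replicate = 1L, tech_replicate = seq_len(ncol(values)),
    stringsAsFactors = FALSE)
  repertoire_matrix(values, peptides, meta)
}

toy_records <- function(volumes_matrix, sequences, sample_ids) {
  lapply(seq_along(sequences), function(i) {
    v <- volumes_matrix[i, ]
    names(v) <- sample_ids
    peptide_record(sequences[i], proteins = "P1", volumes = v)
  })
}

extdata <- function(...) system.file("extdata", ..., package = "motifquant")
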