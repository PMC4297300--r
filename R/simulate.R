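# Synthetic peptide-elution datasets with the statistical structure the
# analysis assumes: planted 9-mer binding motifs, nested sets with ragged
# ends, length mode near 14, log-normal abundances spanning orders of
# magnitude, replicate structure (3 cell lines x 2 biological x 3 technical
# per allotype), detection dropout, and CLIP spike-ins from a toy invariant
# chain.

#' Build a position weight matrix with specified anchor preferences
#'
#' Non-anchor positions follow the background composition; at an anchor
#' position the named residues take the stated frequencies and the remaining
#' mass is spread over the other residues proportionally to background.
#'
#' @param anchors named list: position (as character or integer) ->
#'   named numeric vector of residue frequencies (summing to < 1).
#' @param length motif length.
#' @param background residue background frequencies.
#' @return A frequency [pssm_matrix()].
#' @export
make_pwm <- function(anchors = list(), length = 9L,
                     background = BACKGROUND_FREQS) {
  pwm <- matrix(rep(background[AA_ORDER], each = length), nrow = length,
                dimnames = list(NULL, AA_ORDER))
  for (pos in names(anchors)) {
    spec <- anchors[[pos]]
    p <- as.integer(pos)
    rest <- setdiff(AA_ORDER, names(spec))
    remaining <- 1 - sum(spec)
    if (remaining < 0) stop("anchor frequencies at position ", pos, " exceed 1")
    row <- setNames(numeric(20), AA_ORDER)
    row[names(spec)] <- spec
    row[rest] <- remaining * background[rest] / sum(background[rest])
    pwm[p, ] <- row
  }
  pssm_matrix(pwm, "frequency")
}

#' Default planted binding motifs
#'
#' Three qualitative motif shapes used as simulation fixtures: a
#' "DQ2.5-like" motif (hydrophobic P1, acidic P4/P6, aromatic P7, no P9
#' anchor), a "DQ2.2-like" motif adding a strong serine/threonine anchor at
#' P3 and a hydrophobic P9 anchor, and a "DQ7.5-like" motif with uncharged
#' anchors throughout. They are test fixtures emulating reported motif
#' differences, not claims about the true allotype motifs.
#'
#' @return Named list of frequency [pssm_matrix()]s.
#' @export
default_pwms <- function() {
  list(
    DQ2.5 = make_pwm(list(
      `1` = c(F = 0.45, Y = 0.30, W = 0.10),
      `4` = c(D = 0.45, E = 0.40),
      `6` = c(E = 0.45, D = 0.35),
      `7` = c(Y = 0.40, F = 0.35)
    )),
    DQ2.2 = make_pwm(list(
      `1` = c(Y = 0.35, F = 0.25, W = 0.10),
      `3` = c(S = 0.45, T = 0.35, D = 0.08),
      `4` = c(D = 0.45, E = 0.35),
      `6` = c(E = 0.45, D = 0.35),
      `9` = c(L = 0.40, F = 0.35)
    )),
    DQ7.5 = make_pwm(list(
      `1` = c(L = 0.45, I = 0.35),
      `4` = c(A = 0.45, S = 0.35),
      `6` = c(P = 0.45, G = 0.30),
      `9` = c(V = 0.45, A = 0.35)
    ))
  )
}

# CLIP span of the toy invariant chain; the canonical human CD74 CLIP-region
# sequence, so the shipped CLIP1/CLIP2 core defaults match the spike-ins.
CLIP_REGION_SEQ <- "LPKPPKPVSKMRMATPLLMQALPMGALPQGPM"

#' Simulation configuration
#'
#' Defaults mirror the design of the emulated elution study: three allotypes
#' with planted motifs, 3 cell lines x 2 biological x 3 technical replicates
#' per allotype (54 samples), peptide lengths 8-25 with mode 14, log-normal
#' abundances, multiplicative replicate noise, detection dropout, and CLIP
#' spike-ins carrying a configured share of each allotype's total signal
#' (0.53 / 0.05 / 0.12, matching the dominance of CLIP on DQ2.5-like
#' molecules).
#'
#' @param allotypes named list of planted frequency PWMs.
#' @param n_ligands primary ligands per allotype.
#' @param length_weights named numeric vector: length -> probability.
#' @param nested_set_rate probability a ligand spawns trimmed variants.
#' @param variant_mean mean extra variants per spawning ligand
#'   (count is `1 + Poisson(variant_mean - 1)`).
#' @param abundance_mu,abundance_sigma log-scale location and spread of true
#'   abundances.
#' @param motif_gain coupling of log abundance to the core's
#'   log-likelihood-ratio score under the planted PWM (motif-matching
#'   peptides accumulate more).
#' @param replicate_noise_cv multiplicative coefficient of variation across
#'   technical replicates.
#' @param detection_dropout probability a peptide goes undetected in a sample.
#' @param loading_sd log-scale spread of per-sample loading factors (removed
#'   again by scale-ratio normalization).
#' @param clip_fraction named share of total signal assigned to CLIP
#'   spike-ins per allotype.
#' @param clip_sigma log-scale spread of abundance across CLIP length
#'   variants.
#' @param n_clip_variants CLIP length variants spiked per allotype.
#' @param background_freqs residue background for flanks and random cores.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(allotypes = default_pwms(),
                       n_ligands = 400L,
                       length_weights = NULL,
                       nested_set_rate = 0.35,
                       variant_mean = 1.5,
                       abundance_mu = 0,
                       abundance_sigma = 1,
                       motif_gain = 1,
                       replicate_noise_cv = 0.3,
                       detection_dropout = 0.1,
                       loading_sd = 0.5,
                       clip_fraction = c(DQ2.5 = 0.53, DQ2.2 = 0.05, DQ7.5 = 0.12),
                       clip_sigma = 0.7,
                       n_clip_variants = 20L,
                       background_freqs = BACKGROUND_FREQS,
                       seed = 1L) {
  if (is.null(length_weights)) {
    # peaked unimodal profile over 8-25 with a clear mode at 14
    lens <- 8:25
    w <- exp(-((lens - 14) / 2)^2 / 2) * (1 - 0.25 * (lens < 14))
    length_weights <- setNames(w / sum(w), lens)
  }
  stopifnot(abs(sum(length_weights) - 1) < 1e-9,
            !is.null(names(allotypes)))
  structure(list(allotypes = allotypes, n_ligands = as.integer(n_ligands),
                 length_weights = length_weights,
                 nested_set_rate = nested_set_rate, variant_mean = variant_mean,
                 abundance_mu = abundance_mu, abundance_sigma = abundance_sigma,
                 motif_gain = motif_gain,
                 replicate_noise_cv = replicate_noise_cv,
                 detection_dropout = detection_dropout,
                 loading_sd = loading_sd,
                 clip_fraction = clip_fraction,
                 clip_sigma = clip_sigma,
                 n_clip_variants = as.integer(n_clip_variants),
                 background_freqs = background_freqs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @noRd
sample_background <- function(n, background) {
  paste(sample(AA_ORDER, n, replace = TRUE, prob = background), collapse = "")
}

#' @noRd
sample_core <- function(pwm) {
  paste(vapply(seq_len(nrow(pwm)), function(p) {
    sample(AA_ORDER, 1L, prob = pwm[p, ])
  }, character(1)), collapse = "")
}

#' @noRd
core_llr <- function(core, pwm, background) {
  aa <- strsplit(core, "")[[1]]
  sum(log(pwm[cbind(seq_along(aa), match(aa, AA_ORDER))] /
            background[aa]))
}

#' Generate a synthetic peptide-elution dataset
#'
#' Per allotype: 9-mer cores are sampled from the planted PWM, flanked with
#' background residues to lengths drawn from the length distribution (lengths
#' below the core length are redrawn, so an 8-weight contributes nothing);
#' a fraction of ligands spawns end-trimmed nested variants that never cut
#' into the core; true abundances are log-normal with a motif-score coupling;
#' CLIP variants from a toy invariant chain (CD74) are spiked in at the
#' configured share of total signal; the signal is then distributed over
#' 3 cell lines x 2 biological x 3 technical replicates with per-sample
#' loading factors, multiplicative noise, and detection dropout.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_data`: `records` (list of [peptide_record()]s),
#'   `meta` (sample metadata data.frame), `truth` (data.frame with one row
#'   per generated peptide per allotype: sequence, allotype, core,
#'   core_offset, true_abundance, is_clip, family), `cd74` (the toy CD74
#'   sequence), `config`.
#' @export
generate_repertoire <- function(config = sim_config()) {
  motif_len <- nrow(config$allotypes[[1]])
  lens_ok <- as.integer(names(config$length_weights)) >= motif_len
  if (!any(lens_ok)) stop("length_weights incompatible with the motif length")
  lw <- config$length_weights[lens_ok]
  lw <- lw / sum(lw)
  lens_avail <- as.integer(names(lw))

  with_seed(config$seed, {
    cd74 <- paste0(sample_background(20L, config$background_freqs),
                   CLIP_REGION_SEQ,
                   sample_background(8L, config$background_freqs))
    clip_region_start <- 21L
    region_len <- nchar(CLIP_REGION_SEQ)

    truth_list <- list()
    long <- list()
    meta_list <- list()

    for (a in names(config$allotypes)) {
      pwm <- config$allotypes[[a]]
      n <- config$n_ligands
      seqs <- character(0); cores <- character(0); offs <- integer(0)
      lnA <- numeric(0); fam <- integer(0)
      for (i in seq_len(n)) {
        core <- sample_core(pwm)
        len <- sample(lens_avail, 1L, prob = lw)
        off <- sample.int(len - motif_len + 1L, 1L)
        left <- sample_background(off - 1L, config$background_freqs)
        right <- sample_background(len - motif_len - off + 1L,
                                   config$background_freqs)
        pep <- paste0(left, core, right)
        score <- core_llr(core, pwm, config$background_freqs)
        base_lnA <- config$abundance_mu +
          config$abundance_sigma * rnorm(1) + config$motif_gain * score
        seqs <- c(seqs, pep); cores <- c(cores, core); offs <- c(offs, off)
        lnA <- c(lnA, base_lnA); fam <- c(fam, i)
        if (runif(1) < config$nested_set_rate) {
          n_var <- 1L + rpois(1L, max(config$variant_mean - 1, 0))
          core_end <- off + motif_len - 1L
          for (v in seq_len(n_var)) {
            # ragged ends: short geometric trims that never cut into the core
            t_l <- min(stats::rgeom(1L, 0.75), off - 1L)
            t_r <- min(stats::rgeom(1L, 0.75), len - core_end)
            if (t_l + t_r == 0L) {
              if (len - core_end > 0L) t_r <- 1L else if (off > 1L) t_l <- 1L
            }
            new_start <- 1L + t_l
            new_end <- len - t_r
            var_pep <- substr(pep, new_start, new_end)
            seqs <- c(seqs, var_pep)
            cores <- c(cores, core)
            offs <- c(offs, off - new_start + 1L)
            lnA <- c(lnA, base_lnA + rnorm(1, sd = 0.5))
            fam <- c(fam, i)
          }
        }
      }
      is_clip <- rep(FALSE, length(seqs))

      # CLIP spike-ins: ragged windows of the toy CD74 CLIP region that all
      # retain the CLIP1 core (region positions 11-19)
      starts <- sample.int(8L, config$n_clip_variants, replace = TRUE)
      ends <- sample(20:region_len, config$n_clip_variants, replace = TRUE)
      clip_seqs <- unique(substr(rep(CLIP_REGION_SEQ, config$n_clip_variants),
                                 starts, ends))
      clip_lnA <- config$abundance_mu + rnorm(length(clip_seqs),
                                              sd = config$clip_sigma)
      clip_A <- exp(clip_lnA)
      A <- exp(lnA)
      cf <- config$clip_fraction[[a]]
      if (cf > 0 && cf < 1) {
        clip_A <- clip_A * (cf / (1 - cf)) * sum(A) / sum(clip_A)
      } else if (cf == 0) {
        clip_A <- numeric(0)
        clip_seqs <- character(0)
      }
      all_seqs <- c(seqs, clip_seqs)
      all_A <- c(A, clip_A)
      all_cores <- c(cores, rep(NA_character_, length(clip_seqs)))
      all_offs <- c(offs, rep(NA_integer_, length(clip_seqs)))
      all_fam <- c(fam, seq_along(clip_seqs) + max(fam))
      all_clip <- c(is_clip, rep(TRUE, length(clip_seqs)))

      truth_list[[a]] <- data.frame(
        sequence = all_seqs, allotype = a, core = all_cores,
        core_offset = all_offs, true_abundance = all_A,
        is_clip = all_clip, family = paste0(a, "_", all_fam),
        stringsAsFactors = FALSE)

      sd_ln <- sqrt(log(1 + config$replicate_noise_cv^2))
      for (cl in 1:3) for (b in 1:2) for (t in 1:3) {
        sid <- sprintf("%s_CL%d_B%d_T%d", a, cl, b, t)
        meta_list[[sid]] <- data.frame(
          sample_id = sid, cell_line = sprintf("%s_CL%d", a, cl),
          allotype = a, bio_replicate = b, tech_replicate = t,
          stringsAsFactors = FALSE)
        loading <- exp(rnorm(1, sd = config$loading_sd))
        vol <- all_A * loading * exp(rnorm(length(all_A), sd = sd_ln))
        vol[runif(length(vol)) < config$detection_dropout] <- 0
        detected <- vol > 0
        if (any(detected)) {
          long[[length(long) + 1L]] <- data.frame(
            sequence = all_seqs[detected], sample = sid,
            volume = vol[detected],
            protein = ifelse(all_clip[detected], "CD74", paste0("SIM_", a)),
            stringsAsFactors = FALSE)
        }
      }
    }

    truth <- do.call(rbind, truth_list)
    rownames(truth) <- NULL
    meta <- do.call(rbind, meta_list)
    rownames(meta) <- NULL
    df <- do.call(rbind, long)

    uniq <- unique(df$sequence)
    rec_idx <- split(seq_len(nrow(df)), factor(df$sequence, levels = uniq))
    records <- lapply(uniq, function(s) {
      rows <- rec_idx[[s]]
      vols <- tapply(df$volume[rows], df$sample[rows], sum)
      peptide_record(s, proteins = sort(unique(df$protein[rows])),
                     volumes = setNames(as.numeric(vols), names(vols)))
    })

    structure(list(records = records, meta = meta, truth = truth,
                   cd74 = cd74, clip_region = c(clip_region_start,
                                                clip_region_start + region_len - 1L),
                   config = config),
              class = "sim_data")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the peptide quantification table and sample metadata as TSV and the
#' truth bundle as JSON; outputs are byte-identical across runs with the same
#' config.
#'
#' @param sim a [generate_repertoire()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peptides = file.path(dir, "peptides.tsv"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"),
             fasta = file.path(dir, "proteins.fasta"))
  write_peptide_table(sim$records, paths["peptides"])
  write_sample_meta(sim$meta, paths["meta"])
  jsonlite::write_json(list(truth = sim$truth, clip_region = sim$clip_region,
                            seed = sim$config$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  writeLines(c(">CD74 toy invariant chain", sim$cd74), paths["fasta"])
  invisible(paths)
}

#' Compare a recovered motif with the planted PWM
#'
#' @param planted frequency [pssm_matrix()] (the planted PWM).
#' @param logo a `motif_logo` (or a frequency matrix) recovered by the model.
#' @param anchors integer positions regarded as anchors.
#' @param top_k how many top residues per anchor to compare.
#' @return List: `correlation` (per-position Pearson between planted and
#'   recovered frequencies), `anchor_report` (data.frame: position, planted
#'   and recovered top residues, hit = recovered top-k contains the planted
#'   top-k).
#' @export
planted_vs_recovered <- function(planted, logo, anchors = integer(0),
                                 top_k = 2L) {
  rec <- if (inherits(logo, "motif_logo")) logo$freq else logo
  if (nrow(planted) != nrow(rec)) stop("motif length mismatch")
  correlation <- vapply(seq_len(nrow(planted)), function(p) {
    # a flat recovered row has zero variance; its correlation is undefined
    suppressWarnings(cor(as.numeric(planted[p, ]), as.numeric(rec[p, ])))
  }, numeric(1))
  report <- NULL
  if (length(anchors) > 0L) {
    rows <- lapply(anchors, function(p) {
      top_planted <- AA_ORDER[order(-planted[p, ])[seq_len(top_k)]]
      top_rec <- AA_ORDER[order(-rec[p, ])[seq_len(top_k)]]
      data.frame(position = p,
                 planted = paste(top_planted, collapse = ""),
                 recovered = paste(top_rec, collapse = ""),
                 hit = setequal(top_planted, top_rec),
                 stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
  }
  list(correlation = correlation, anchor_report = report)
}
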