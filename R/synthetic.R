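# Seed-deterministic synthetic repertoire generator.
#
# Emulates the statistical shape of a curated TCR-epitope reference set:
# epitope popularity follows a truncated power law (a few heavily studied
# epitopes dominate the calls), a configurable fraction of epitopes are
# singletons (recognized by exactly one receptor), most receptor groups are
# mono-specific, and same-epitope CDR3beta sequences form point-mutation
# neighborhoods of one per-epitope motif sequence.
#
# Motifs are CDR3-like rather than uniform random: each starts with a
# V-segment-derived prefix and ends with a J-segment-derived suffix drawn
# from small shared pools (the trimmed junction's germline-encoded flanks),
# with a random hypervariable core in between.  Shared flanks are what make
# short CDR3s align well into longer unrelated ones in real repertoires.

# germline-like flank pools for trimmed CDR3beta (no leading C, no final F/W)
.CDR3_PREFIXES <- c("ASS", "ASR", "AIS", "AWS", "ASG", "SAR")
.CDR3_SUFFIXES <- c("EQY", "EAF", "GYT", "ETQY", "NEQF", "QPQH", "YGYT",
                    "TDTQY")

#' Generate a synthetic reference database
#'
#' Every non-singleton epitope is guaranteed at least two receptor groups;
#' the remaining group budget is allocated across non-singleton epitopes
#' with probability proportional to `rank^-abundance_exponent`.  Each
#' epitope gets one random motif CDR3beta (length drawn from
#' `motif_length_range`); its receptors are derived by applying a Poisson
#' (`mutation_lambda`) number of random substitutions, with rejection
#' sampling to keep all CDR3beta unique.  A `1 - mono_specific_fraction`
#' share of groups receives extra epitopes drawn from the non-singleton
#' popularity distribution, so planted singleton counts are preserved.
#'
#' @param n_groups total receptor groups (default 2500).
#' @param n_epitopes number of epitopes (>= 2; default 500).
#' @param abundance_exponent positive power-law exponent for epitope
#'   popularity (default 1.3, giving a top-heavy call distribution).
#' @param motif_length_range integer pair, motif CDR3 length bounds
#'   (default c(6, 18), spanning the short-to-long range of trimmed
#'   CDR3beta loops seen in curated repertoires).
#' @param mutation_lambda Poisson mean of substitutions per receptor
#'   (default 1.5).
#' @param mono_specific_fraction target fraction of single-epitope groups
#'   (default 0.885).
#' @param singleton_fraction fraction of epitopes planted with exactly one
#'   receptor (default 0.5).
#' @param with_alpha also generate CDR3alpha sequences (per-epitope alpha
#'   motifs, same mutation model; default `FALSE`).
#' @param seed integer seed; the same seed yields an identical database.
#' @return a [ReferenceDatabase-class].
#' @examples
#' db <- generateSynthetic(n_groups = 60, n_epitopes = 12, seed = 7)
#' nGroups(db)
#' @export
generateSynthetic <- function(n_groups = 2500L, n_epitopes = 500L,
                              abundance_exponent = 1.3,
                              motif_length_range = c(6L, 18L),
                              mutation_lambda = 1.5,
                              mono_specific_fraction = 0.885,
                              singleton_fraction = 0.5,
                              with_alpha = FALSE, seed = 1L) {
  if (n_epitopes < 2L) stop("need n_epitopes >= 2")
  if (abundance_exponent <= 0) stop("abundance_exponent must be positive")
  if (mono_specific_fraction < 0 || mono_specific_fraction > 1 ||
      singleton_fraction < 0 || singleton_fraction > 1)
    stop("fractions must lie in [0, 1]")
  lo <- as.integer(motif_length_range[1]); hi <- as.integer(motif_length_range[2])
  if (lo < 3L || hi < lo) stop("invalid motif_length_range")
  n_singleton <- round(singleton_fraction * n_epitopes)
  n_multi <- n_epitopes - n_singleton
  need <- n_singleton + 2L * n_multi
  if (n_groups < need)
    stop("infeasible spec: ", n_groups, " groups cannot cover ",
         n_singleton, " singleton epitopes plus 2 receptors for each of ",
         n_multi, " non-singleton epitopes (need >= ", need, ")")
  if (n_multi == 0L && mono_specific_fraction < 1)
    stop("infeasible spec: cross-reactive groups need non-singleton epitopes")
  set.seed(as.integer(seed))

  randomPeptide <- function(len) paste(sample(AA_ALPHABET, len, replace = TRUE),
                                       collapse = "")
  uniqueSet <- function(n, len) {
    out <- character(0)
    while (length(out) < n) {
      out <- unique(c(out, vapply(rep(len, n - length(out)),
                                  randomPeptide, "")))
    }
    out
  }
  epitope_names <- uniqueSet(n_epitopes, 9L)
  multi_epi <- epitope_names[seq_len(n_multi)]
  singleton_epi <- epitope_names[n_multi + seq_len(n_singleton)]

  # group budget per epitope
  pop <- if (n_multi > 0) seq_len(n_multi)^(-abundance_exponent) else numeric(0)
  counts <- c(rep(2L, n_multi), rep(1L, n_singleton))
  spare <- n_groups - need
  if (spare > 0 && n_multi > 0) {
    extra <- tabulate(sample.int(n_multi, spare, replace = TRUE,
                                 prob = pop / sum(pop)), nbins = n_multi)
    counts[seq_len(n_multi)] <- counts[seq_len(n_multi)] + extra
  }

  randomMotif <- function(len) {
    pre <- sample(.CDR3_PREFIXES, 1L)
    sufs <- .CDR3_SUFFIXES[nchar(.CDR3_SUFFIXES) <= len - nchar(pre)]
    suf <- if (length(sufs)) sample(sufs, 1L) else ""
    core <- len - nchar(pre) - nchar(suf)
    if (core < 0) return(substr(paste0(pre, suf), 1L, len))
    paste0(pre, if (core > 0) randomPeptide(core) else "", suf)
  }
  motif_len <- sample(seq(lo, hi), n_epitopes, replace = TRUE)
  motif_b <- vapply(motif_len, randomMotif, "")
  motif_a <- if (with_alpha) vapply(motif_len, randomMotif, "") else NULL

  mutate <- function(motif, m) {
    ch <- strsplit(motif, "", fixed = TRUE)[[1]]
    m <- min(m, length(ch))
    if (m > 0) {
      pos <- sample(seq_along(ch), m)
      for (p in pos) ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }
  deriveUnique <- function(motif, n, seen) {
    out <- character(n)
    for (i in seq_len(n)) {
      m <- stats::rpois(1L, mutation_lambda)
      attempt <- 0L
      repeat {
        cand <- mutate(motif, m)
        # reject flank-ambiguous sequences (leading C with trailing F/W would
        # look untrimmed to the reader and not survive a TSV round trip)
        if (!(cand %in% seen) && !grepl("^C.*[FW]$", cand)) break
        attempt <- attempt + 1L
        if (attempt %% 10L == 0L) m <- m + 1L     # widen the neighborhood
        if (attempt > 500L)
          stop("infeasible spec: could not sample enough unique sequences")
      }
      out[i] <- cand
      seen[length(seen) + 1L] <- cand
    }
    list(seqs = out, seen = seen)
  }

  cdr3b_all <- character(0)
  cdr3a_all <- character(0)
  primary <- character(0)
  seen_b <- character(0)
  seen_a <- character(0)
  for (k in seq_len(n_epitopes)) {
    db <- deriveUnique(motif_b[k], counts[k], seen_b)
    seen_b <- db$seen
    cdr3b_all <- c(cdr3b_all, db$seqs)
    if (with_alpha) {
      da <- deriveUnique(motif_a[k], counts[k], seen_a)
      seen_a <- da$seen
      cdr3a_all <- c(cdr3a_all, da$seqs)
    }
    primary <- c(primary, rep(epitope_names[k], counts[k]))
  }

  epitopes <- as.list(primary)
  n_cross <- round((1 - mono_specific_fraction) * n_groups)
  if (n_cross > 0 && n_multi > 0) {
    cross <- sample.int(n_groups, n_cross)
    for (g in cross) {
      avail <- setdiff(multi_epi, epitopes[[g]])
      if (length(avail) == 0L) next
      n_extra <- min(1L + stats::rpois(1L, 0.3), length(avail))
      w <- pop[match(avail, multi_epi)]
      epitopes[[g]] <- c(epitopes[[g]],
                         sample(avail, n_extra, prob = w / sum(w)))
    }
  }

  db <- referenceDatabase(
    cdr3b = cdr3b_all, epitopes = epitopes,
    cdr3a = if (with_alpha) cdr3a_all else NA_character_,
    antigen = paste0("antigen_", match(primary, epitope_names)),
    organism = "synthetic", merge = FALSE)
  .logStep(db, "generate_synthetic",
           sprintf("seed %d, %d singleton epitopes planted", as.integer(seed),
                   n_singleton))
}
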