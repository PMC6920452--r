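#' Configuration for the synthetic haplotype-distribution generator
#'
#' Bundles the parameters of the simulator: the number of haplotypes and
#' locations, the total sample size, the global haplotype frequency
#' spectrum, the sampling effort per location, and a single segregation
#' parameter controlling spatial structure. `segregation_strength = 0`
#' gives the independence null (every location shares the global
#' spectrum); for positive values each location's spectrum is drawn from
#' `Dirichlet(global_spectrum / segregation_strength)`, so larger values
#' produce stronger location-specific distortion of haplotype frequencies
#' (emulating multiple independent incursions seeding different regions).
#'
#' The default spectrum mimics an invasive mtDNA COI survey: a few dominant
#' haplotypes (the top two carrying 68% and the top five 80% of
#' individuals) plus many rare ones sharing the remainder equally.
#'
#' @param n_haplotypes,n_locations positive integers (study scale: 25, 11).
#' @param total_observations positive integer grand total (default 226).
#' @param haplotype_frequency_spectrum probability vector of length
#'   `n_haplotypes` summing to 1; default [dominant_spectrum()].
#' @param segregation_strength non-negative real; 0 = null.
#' @param location_weights sampling-effort probabilities per location
#'   (default uniform), summing to 1.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_haplotypes
#' @export
sim_config <- function(n_haplotypes = 25L, n_locations = 11L,
                       total_observations = 226L,
                       haplotype_frequency_spectrum =
                         dominant_spectrum(n_haplotypes),
                       segregation_strength = 0,
                       location_weights = rep(1 / n_locations, n_locations),
                       seed = NULL) {
  stopifnot(n_haplotypes >= 1L, n_locations >= 1L, total_observations >= 1L,
            segregation_strength >= 0,
            length(haplotype_frequency_spectrum) == n_haplotypes,
            all(haplotype_frequency_spectrum >= 0),
            length(location_weights) == n_locations,
            all(location_weights >= 0))
  if (abs(sum(haplotype_frequency_spectrum) - 1) > 1e-12)
    stop("haplotype frequency spectrum must sum to 1")
  if (abs(sum(location_weights) - 1) > 1e-12)
    stop("location weights must sum to 1")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_locations = as.integer(n_locations),
                 total_observations = as.integer(total_observations),
                 haplotype_frequency_spectrum = haplotype_frequency_spectrum,
                 segregation_strength = segregation_strength,
                 location_weights = location_weights,
                 seed = seed),
            class = "sim_config")
}

#' Dominant-plus-rare haplotype frequency spectrum
#'
#' Frequency vector with `n_dominant` common haplotypes carrying
#' `dominant_mass` of the probability (in fixed decreasing proportions
#' 0.40 : 0.28 : 0.05 : 0.04 : 0.03 when `n_dominant = 5`, i.e. top two =
#' 68%, top five = 80%) and the remaining mass spread equally over the
#' rare haplotypes.
#'
#' @param n total number of haplotypes.
#' @param n_dominant number of dominant haplotypes (capped at `n`).
#' @param dominant_mass total probability carried by the dominant set.
#' @return numeric probability vector of length `n`.
#' @export
dominant_spectrum <- function(n, n_dominant = 5L, dominant_mass = 0.80) {
  stopifnot(n >= 1L, dominant_mass > 0, dominant_mass <= 1)
  n_dominant <- min(n_dominant, n)
  base <- c(0.40, 0.28, 0.05, 0.04, 0.03)
  w <- if (n_dominant <= 5L) base[seq_len(n_dominant)] else
    c(base, rep(base[5], n_dominant - 5L))
  p <- numeric(n)
  p[seq_len(n_dominant)] <- w / sum(w) * dominant_mass
  if (n > n_dominant)
    p[(n_dominant + 1L):n] <- (1 - dominant_mass) / (n - n_dominant)
  p / sum(p)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate-alpha guard
  g / sum(g)
}

#' Simulate a haplotype-by-location count matrix
#'
#' Each of the `total_observations` individuals is assigned a location
#' (multinomially, by `location_weights`) and then a haplotype from that
#' location's spectrum: the global spectrum when
#' `segregation_strength = 0`, otherwise a per-location
#' `Dirichlet(global / strength)` draw. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param require_full if `TRUE`, redraw until the realized matrix has no
#'   empty row or column, so the full `n_haplotypes x n_locations` shape
#'   is preserved (useful for building validation templates).
#' @param max_tries redraw limit for `require_full`.
#' @return a [contingency_matrix()] whose grand total equals
#'   `config$total_observations`.
#' @examples
#' m <- simulate_matrix(sim_config(4, 3, 60, seed = 7))
#' sum(m)
#' @export
simulate_matrix <- function(config, require_full = FALSE, max_tries = 5000L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$haplotype_frequency_spectrum
  q <- config$location_weights
  N <- config$total_observations
  R <- config$n_haplotypes; C <- config$n_locations

  draw <- function() {
    n_loc <- as.vector(stats::rmultinom(1L, N, q))
    m <- matrix(0L, R, C)
    for (j in seq_len(C)) {
      if (n_loc[j] == 0L) next
      pj <- if (config$segregation_strength > 0)
        rdirichlet1(p / config$segregation_strength) else p
      m[, j] <- as.vector(stats::rmultinom(1L, n_loc[j], pj))
    }
    m
  }

  m <- draw()
  if (require_full) {
    tries <- 1L
    while ((any(rowSums(m) == 0L) || any(colSums(m) == 0L)) &&
           tries < max_tries) {
      m <- draw(); tries <- tries + 1L
    }
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
      stop("could not realize a full matrix in ", max_tries, " draws; ",
           "the spectrum makes empty margins too likely")
  }
  suppressWarnings(contingency_matrix(
    m, row_labels = sprintf("Hap_%02d", seq_len(R)),
    col_labels = sprintf("Loc_%02d", seq_len(C))))
}

## ---- COI-like sequence simulation -------------------------------------

# invertebrate mitochondrial code as a plain codon -> AA lookup
invert_mito_code <- function() {
  Biostrings::getGeneticCode("SGC4")
}

#' Simulate a COI-like haplotype sequence dataset
#'
#' Builds an ancestral open reading frame free of in-frame stop codons
#' under the invertebrate mitochondrial code, derives the configured
#' number of haplotypes by transition substitutions placed preferentially
#' at third codon positions (so most changes are synonymous), assigns each
#' individual a haplotype and location according to [simulate_matrix()],
#' and optionally injects decoy NUMT-like sequences carrying a premature
#' stop codon so pseudogene QC can be measured against known truth.
#'
#' @param config a [sim_config()].
#' @param seq_length sequence length in bp (default 548, a typical partial
#'   COI amplicon).
#' @param frame reading-frame offset in `0:2` (bases to skip before the
#'   first complete codon).
#' @param decoy_rate per-individual probability of being emitted as a
#'   decoy NUMT-like sequence instead of a clean haplotype copy.
#' @param third_pos_bias probability that a substitution lands on a third
#'   codon position (default 0.9).
#' @return a list with `sequences` (named character vector),
#'   `metadata` (data.frame: id, location, haplotype_truth, is_decoy),
#'   `haplotype_sequences` (named character vector of true haplotypes) and
#'   `matrix` (the simulated [contingency_matrix()], decoys excluded).
#' @export
simulate_coi_dataset <- function(config, seq_length = 548L, frame = 0L,
                                 decoy_rate = 0, third_pos_bias = 0.9) {
  stopifnot(inherits(config, "sim_config"), seq_length >= 30L,
            decoy_rate >= 0, decoy_rate <= 1)
  if (!(frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  m <- simulate_matrix(config, require_full = FALSE)
  # simulate_matrix seeded the RNG; everything below continues the stream

  code <- invert_mito_code()
  sense_codons <- names(code)[code != "*"]
  n_codons <- ceiling((seq_length - frame) / 3) + 1L
  ancestor <- paste0(
    paste(rep("A", frame), collapse = ""),
    paste(sample(sense_codons, n_codons, replace = TRUE), collapse = ""))
  ancestor <- substr(ancestor, 1L, seq_length)

  R <- nrow(m)
  haps <- character(R)
  haps[1] <- ancestor
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  third_pos <- seq(frame + 3L, seq_length, by = 3L)
  other_pos <- setdiff(seq_len(seq_length), third_pos)
  for (i in seq_len(R)[-1]) {
    repeat {
      s <- ancestor
      n_sub <- 1L + stats::rpois(1L, 1)
      for (k in seq_len(n_sub)) {
        pos <- if (stats::runif(1) < third_pos_bias || !length(other_pos))
          sample(third_pos, 1L) else sample(other_pos, 1L)
        substr(s, pos, pos) <- transit[[substr(s, pos, pos)]]
      }
      if (!check_premature_stops(s, frame) && !(s %in% haps[seq_len(i - 1L)]))
        break
    }
    haps[i] <- s
  }
  names(haps) <- rownames(m)

  # one individual per observation, in cell order
  idx <- which(unclass(m) > 0, arr.ind = TRUE)
  hap_id <- rep(rownames(m)[idx[, 1]], unclass(m)[idx])
  loc_id <- rep(colnames(m)[idx[, 2]], unclass(m)[idx])
  n <- length(hap_id)
  is_decoy <- stats::runif(n) < decoy_rate

  seqs <- haps[hap_id]
  if (any(is_decoy)) {
    # decoys copy their haplotype but acquire an internal stop codon
    stop_codons <- c("TAA", "TAG")
    for (k in which(is_decoy)) {
      codon_start <- frame + 3L * (sample.int(
        (seq_length - frame) %/% 3L - 1L, 1L) - 1L) + 1L
      s <- seqs[[k]]
      substr(s, codon_start, codon_start + 2L) <- sample(stop_codons, 1L)
      seqs[[k]] <- s
    }
  }
  ids <- sprintf("ind_%04d", seq_len(n))
  names(seqs) <- ids
  meta <- data.frame(id = ids, location = loc_id,
                     haplotype_truth = ifelse(is_decoy, NA, hap_id),
                     is_decoy = is_decoy, stringsAsFactors = FALSE)

  # the truth matrix excludes decoys
  keep <- !is_decoy
  truth <- table(factor(hap_id[keep], levels = rownames(m)),
                 factor(loc_id[keep], levels = colnames(m)))
  truth_m <- suppressWarnings(contingency_matrix(
    matrix(as.integer(truth), nrow(m), ncol(m),
           dimnames = dimnames(m))))
  list(sequences = seqs, metadata = meta, haplotype_sequences = haps,
       matrix = truth_m)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA sequences, TSV metadata (`id`, `location`,
#' `haplotype_truth`, `is_decoy`) and the CSV truth count matrix.
#'
#' @param dataset result of [simulate_coi_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_coi_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "sequences.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$sequences), fa)
  tsv <- file.path(dir, "metadata.tsv")
  utils::write.table(dataset$metadata, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  csv <- file.path(dir, "counts.csv")
  write_count_matrix(dataset$matrix, csv)
  invisible(c(fasta = fa, metadata = tsv, counts = csv))
}
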