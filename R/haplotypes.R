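#' Read COI sequences with their collection metadata
#'
#' Joins a FASTA file of same-locus amplicon sequences with a tab-separated
#' metadata table (columns `id`, `location`, optionally `date` and others).
#' Every FASTA id must have exactly one metadata row.
#'
#' @param fasta_path FASTA file of DNA sequences (A/C/G/T/N).
#' @param metadata_path TSV with at least columns `id` and `location`.
#' @return a data.frame with one row per sequence: `id`, `location`,
#'   `date` (NA if absent), `sequence`, plus any further metadata columns.
#' @export
read_fasta_with_metadata <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("id", "location") %in% names(meta)))
    stop("metadata must contain columns 'id' and 'location'")
  if (anyDuplicated(meta$id))
    stop("duplicate ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  missing <- setdiff(ids, meta$id)
  if (length(missing))
    stop("sequence id(s) absent from metadata: ",
         paste(missing, collapse = ", "))

  s <- toupper(as.character(seqs))
  if (any(!grepl("^[ACGTN]+$", s)))
    stop("sequences must use only A, C, G, T, N")
  out <- meta[match(ids, meta$id), , drop = FALSE]
  if (is.null(out$date)) out$date <- NA_character_
  out$sequence <- unname(s)
  rownames(out) <- NULL
  out
}

#' Collapse sequences into haplotypes
#'
#' Identical sequences share a haplotype; any difference (including an N,
#' which is deliberately treated as a mismatch so uncertain reads are not
#' merged) separates them. Labels are assigned deterministically as
#' `Hap_01, Hap_02, ...` by decreasing count, ties broken by order of
#' first appearance; a named `labels` map (representative sequence id ->
#' label) can override.
#'
#' @param records data.frame from [read_fasta_with_metadata()] (needs
#'   columns `id`, `location`, `sequence`).
#' @param trim_to_common_region if sequences differ in length, trim all to
#'   the shortest (amplicons are assumed aligned by position from a shared
#'   start); otherwise unequal lengths are an error.
#' @param labels optional character vector of replacement haplotype labels
#'   in rank order.
#' @return an object of class `haplotype_catalog`: list with
#'   `haplotypes` (label -> representative sequence), `members` (id ->
#'   label), `counts` (haplotype x location [contingency_matrix()]),
#'   `n` (number of sequences), `seq_length`.
#' @export
call_haplotypes <- function(records, trim_to_common_region = FALSE,
                            labels = NULL) {
  stopifnot(is.data.frame(records),
            all(c("id", "location", "sequence") %in% names(records)))
  s <- records$sequence
  len <- nchar(s)
  if (length(unique(len)) > 1L) {
    if (!trim_to_common_region)
      stop("sequences have unequal lengths (", paste(sort(unique(len)),
           collapse = ", "), "); set trim_to_common_region = TRUE")
    s <- substr(s, 1L, min(len))
  }

  first_seen <- !duplicated(s)
  uniq <- s[first_seen]
  counts <- as.integer(table(factor(s, levels = uniq)))
  ord <- order(-counts, seq_along(uniq))
  uniq <- uniq[ord]; counts <- counts[ord]
  lab <- sprintf("Hap_%02d", seq_along(uniq))
  if (!is.null(labels)) {
    stopifnot(length(labels) >= length(uniq))
    lab <- labels[seq_along(uniq)]
  }
  members <- stats::setNames(lab[match(s, uniq)], records$id)
  cm <- table(factor(members, levels = lab),
              factor(records$location, levels = unique(records$location)))
  cm <- suppressWarnings(contingency_matrix(
    matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))))
  structure(list(haplotypes = stats::setNames(uniq, lab),
                 members = members, counts = cm, n = length(s),
                 seq_length = min(len)),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat(sprintf("Haplotype catalog: %d haplotypes from %d sequences (%d bp)\n",
              length(x$haplotypes), x$n, x$seq_length))
  tot <- rowSums(x$counts)
  show <- utils::head(tot, 10L)
  cat("  counts:", paste(sprintf("%s=%d", names(show), show),
                         collapse = " "),
      if (length(tot) > 10L) "...\n" else "\n")
  invisible(x)
}

## ---- translation & pseudogene QC --------------------------------------

translate_mito <- function(sequence, frame = 0L) {
  code <- invert_mito_code()
  n <- nchar(sequence)
  starts <- seq(frame + 1L, n - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Screen a sequence for premature stop codons
#'
#' Translates in the given frame under the invertebrate mitochondrial
#' genetic code (TAA/TAG are stops; TGA encodes tryptophan) and reports
#' whether a stop occurs before the final complete codon — the classic
#' signature of a nuclear mitochondrial pseudogene (NUMT) contaminating a
#' COI dataset. A trailing partial codon is ignored.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param frame reading-frame offset in `0:2`.
#' @return `TRUE` if a premature stop is present.
#' @examples
#' check_premature_stops("ATTTAAGGC", 0)  # TAA at codon 2 -> TRUE
#' check_premature_stops("ATTTGAGGC", 0)  # TGA = Trp here -> FALSE
#' @export
check_premature_stops <- function(sequence, frame = 0L) {
  if (!(frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  aa <- translate_mito(sequence, frame)
  n <- nchar(aa)
  if (n <= 1L) return(FALSE)
  grepl("\\*", substr(aa, 1L, n - 1L))
}

# fixed published side-chain classification (Taylor-style sets)
aa_categories <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y", "C"),
       small = c("G", "A", "S", "T", "C", "P", "N", "D", "V"),
       polar = c("S", "T", "N", "Q", "Y", "C", "H", "K", "R", "D", "E", "W"),
       charged = c("D", "E", "K", "R", "H"))
}

#' Classify amino-acid substitutions between two haplotypes
#'
#' Translates both sequences and reports every amino-acid difference with
#' the side-chain categories (hydrophobic, small, polar, charged) shared
#' by the two residues. A change is conservative if the residues share at
#' least one category — e.g. L/V or I/M (hydrophobic), A/G (small).
#'
#' @param haplotype,reference equal-length DNA strings.
#' @param frame reading-frame offset in `0:2`.
#' @return data.frame with columns `position` (codon index), `from`, `to`,
#'   `shared_categories` (comma-separated, "" if none) and `conservative`;
#'   zero rows if the proteins are identical.
#' @export
classify_aa_substitutions <- function(haplotype, reference, frame = 0L) {
  stopifnot(nchar(haplotype) == nchar(reference))
  a <- strsplit(translate_mito(reference, frame), "")[[1]]
  b <- strsplit(translate_mito(haplotype, frame), "")[[1]]
  diff <- which(a != b & a != "X" & b != "X")
  cats <- aa_categories()
  if (!length(diff))
    return(data.frame(position = integer(), from = character(),
                      to = character(), shared_categories = character(),
                      conservative = logical(), stringsAsFactors = FALSE))
  shared <- vapply(diff, function(i) {
    paste(names(cats)[vapply(cats, function(set)
      a[i] %in% set && b[i] %in% set, logical(1))], collapse = ",")
  }, character(1))
  data.frame(position = diff, from = a[diff], to = b[diff],
             shared_categories = shared, conservative = nzchar(shared),
             stringsAsFactors = FALSE)
}

#' Pseudogene / sequencing-error QC report for a haplotype catalog
#'
#' Applies the three NUMT screens to every haplotype: (1) premature stop
#' codons under the invertebrate mitochondrial code, (2) classification of
#' amino-acid changes relative to a reference haplotype (the most common
#' by default) for conservation of side-chain chemistry, and (3) support
#' metrics — whether each variant site is shared with other haplotypes and
#' how many independent sequences confirm the haplotype.
#'
#' @param catalog a [call_haplotypes()] result.
#' @param frame reading-frame offset in `0:2`.
#' @param reference label of the reference haplotype (default the first,
#'   i.e. most common).
#' @return data.frame with one row per haplotype: `haplotype`,
#'   `has_premature_stop`, `n_aa_changes`, `aa_conservative` (all changes
#'   conservative), `snp_shared_with_other_haplotypes`,
#'   `n_independent_confirmations`; the per-change detail is attached as
#'   attribute `"aa_changes"` (named list of data.frames).
#' @export
qc_report <- function(catalog, frame = 0L,
                      reference = names(catalog$haplotypes)[1]) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  haps <- catalog$haplotypes
  ref <- haps[[reference]]
  counts <- rowSums(catalog$counts)[names(haps)]
  counts[is.na(counts)] <- 0L

  split_cache <- lapply(haps, function(s) strsplit(s, "")[[1]])
  aa_detail <- stats::setNames(vector("list", length(haps)), names(haps))
  res <- lapply(names(haps), function(h) {
    s <- haps[[h]]
    stops <- check_premature_stops(s, frame)
    ch <- classify_aa_substitutions(s, ref, frame)
    aa_detail[[h]] <<- ch
    # variant sites relative to the reference, shared by any other haplotype?
    sv <- which(split_cache[[h]] != split_cache[[reference]])
    shared <- if (length(sv) && length(haps) > 2L) {
      others <- setdiff(names(haps), c(h, reference))
      all(vapply(sv, function(pos) any(vapply(others, function(o)
        split_cache[[o]][pos] == split_cache[[h]][pos], logical(1))),
        logical(1)))
    } else FALSE
    data.frame(haplotype = h, has_premature_stop = stops,
               n_aa_changes = nrow(ch),
               aa_conservative = nrow(ch) == 0L || all(ch$conservative),
               snp_shared_with_other_haplotypes = shared,
               n_independent_confirmations = unname(counts[h]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "aa_changes") <- aa_detail
  out
}
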