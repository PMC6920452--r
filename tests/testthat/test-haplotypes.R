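base_orf <- paste(rep(c("ATT", "GGC", "CTT", "ACA", "GCT"), 8), collapse = "")

test_that("reading FASTA with metadata joins and validates records", {
  d <- local_dir()
  seqs <- make_seqs(base_orf, list(s2 = matrix(3, 1, 1, dimnames = list("C")),
                                   s3 = matrix(6, 1, 1, dimnames = list("A"))))
  names(seqs) <- c("a1", "a2", "a3")
  writeLines(paste0(">", names(seqs), "\n", seqs), file.path(d, "in.fasta"))
  meta <- data.frame(id = c("a1", "a2", "a3"),
                     location = c("X", "X", "Y"),
                     date = "2014-04-01")
  write.table(meta, file.path(d, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  rec <- read_fasta_with_metadata(file.path(d, "in.fasta"),
                                  file.path(d, "meta.tsv"))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$location, c("X", "X", "Y"))
  expect_equal(rec$sequence[1], base_orf)

  # id missing from the metadata is named in the error
  write.table(meta[-2, ], file.path(d, "meta2.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_fasta_with_metadata(file.path(d, "in.fasta"),
                                        file.path(d, "meta2.tsv")), "a2")
  # duplicate metadata ids rejected
  write.table(meta[c(1, 1, 2, 3), ], file.path(d, "meta3.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_fasta_with_metadata(file.path(d, "in.fasta"),
                                        file.path(d, "meta3.tsv")),
               "duplicate")
})

test_that("haplotype calling collapses identical sequences deterministically", {
  rec <- data.frame(
    id = c("i1", "i2", "i3", "i4", "i5"),
    location = c("X", "X", "Y", "Y", "Y"),
    sequence = c(base_orf, base_orf, base_orf,
                 sub("ATT", "ATC", base_orf), sub("ATT", "ATC", base_orf)),
    stringsAsFactors = FALSE)
  cat1 <- call_haplotypes(rec)
  expect_equal(length(cat1$haplotypes), 2)
  expect_equal(unname(rowSums(cat1$counts)), c(3, 2))
  expect_equal(names(cat1$haplotypes), c("Hap_01", "Hap_02"))
  # two identical sequences -> one haplotype of count 2
  cat2 <- call_haplotypes(rec[1:2, ])
  expect_equal(length(cat2$haplotypes), 1)
  expect_equal(sum(cat2$counts), 2)
  # members partition the inputs; counts sum to n
  expect_setequal(names(cat1$members), rec$id)
  expect_equal(sum(cat1$counts), nrow(rec))
})

test_that("unequal lengths error unless trimming to the common region", {
  rec <- data.frame(id = c("i1", "i2"), location = "X",
                    sequence = c(base_orf, substr(base_orf, 1, 100)),
                    stringsAsFactors = FALSE)
  expect_error(call_haplotypes(rec), "unequal lengths")
  ct <- call_haplotypes(rec, trim_to_common_region = TRUE)
  expect_equal(ct$seq_length, 100)
  expect_equal(length(ct$haplotypes), 1)
})

test_that("haplotype calling recovers the simulated partition and counts", {
  ds <- simulate_coi_dataset(sim_config(8, 5, 120, seed = 17),
                             decoy_rate = 0.1)
  keep <- !ds$metadata$is_decoy
  rec <- data.frame(id = ds$metadata$id[keep],
                    location = ds$metadata$location[keep],
                    sequence = unname(ds$sequences[keep]),
                    stringsAsFactors = FALSE)
  cat1 <- call_haplotypes(rec)
  # partition equality: sequences group exactly as simulated
  truth <- split(ds$metadata$id[keep], ds$metadata$haplotype_truth[keep])
  called <- split(names(cat1$members), cat1$members)
  expect_setequal(unname(lapply(truth, sort)), unname(lapply(called, sort)))
  # count matrix equality after matching rows by representative sequence
  called_by_seq <- stats::setNames(names(cat1$haplotypes),
                                   unname(cat1$haplotypes))
  for (r in rownames(ds$matrix)) {
    lab <- called_by_seq[[ds$haplotype_sequences[[r]]]]
    expect_equal(unname(unclass(cat1$counts)[lab, colnames(ds$matrix)]),
                 unname(unclass(ds$matrix)[r, ]))
  }
})

test_that("premature stop screening follows the invertebrate mitochondrial code", {
  expect_true(check_premature_stops("ATTTAAGGC", 0))   # TAA at codon 2
  expect_false(check_premature_stops("ATTTGAGGC", 0))  # TGA is Trp here
  expect_true(check_premature_stops("ATTTAGGGC", 0))   # TAG is a stop
  # stop only in the final complete codon is not premature
  expect_false(check_premature_stops("ATTGGCTAA", 0))
  # frame shifts move the codon boundaries
  expect_false(check_premature_stops("ATAATTGGC", 0))
  expect_true(check_premature_stops("TTAAATTGG", 1))   # frame 1: TAA first
  expect_error(check_premature_stops("ATT", 3), "frame")
})

test_that("amino-acid substitutions are classified by shared side-chain category", {
  # CTT (L) -> GTT (V): conservative, hydrophobic
  a <- paste0("CTT", substr(base_orf, 4, nchar(base_orf)))
  b <- paste0("GTT", substr(base_orf, 4, nchar(base_orf)))
  ch <- classify_aa_substitutions(b, a, 0)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$from, "L"); expect_equal(ch$to, "V")
  expect_true(ch$conservative)
  expect_match(ch$shared_categories, "hydrophobic")
  # GCT (A) -> GGT (G): conservative via the 'small' category
  b2 <- paste0(substr(base_orf, 1, 12), "GGT",
               substr(base_orf, 16, nchar(base_orf)))
  ch2 <- classify_aa_substitutions(b2, base_orf, 0)
  expect_equal(ch2$from, "A"); expect_equal(ch2$to, "G")
  expect_true(ch2$conservative)
  expect_match(ch2$shared_categories, "small")
  # ATT (I) -> ATG (M): hydrophobic pair, matches the published QC calls
  b3 <- paste0("ATG", substr(base_orf, 4, nchar(base_orf)))
  ch3 <- classify_aa_substitutions(b3, base_orf, 0)
  expect_true(ch3$conservative)
  expect_match(ch3$shared_categories, "hydrophobic")
  # identical proteins -> empty classification
  expect_equal(nrow(classify_aa_substitutions(base_orf, base_orf, 0)), 0)
})

test_that("QC report flags stop-codon haplotypes and is internally consistent", {
  ds <- simulate_coi_dataset(sim_config(5, 3, 60, seed = 19),
                             decoy_rate = 0.15)
  rec <- data.frame(id = ds$metadata$id, location = ds$metadata$location,
                    sequence = unname(ds$sequences),
                    stringsAsFactors = FALSE)
  cat1 <- call_haplotypes(rec)
  qc <- qc_report(cat1)
  # flags recomputable from the sequences themselves
  recheck <- vapply(cat1$haplotypes[qc$haplotype], check_premature_stops,
                    logical(1), frame = 0)
  expect_identical(unname(recheck), qc$has_premature_stop)
  # the decoy-bearing haplotypes are exactly the flagged ones
  decoy_seqs <- unique(ds$sequences[ds$metadata$is_decoy])
  flagged_seqs <- unname(cat1$haplotypes[qc$haplotype[qc$has_premature_stop]])
  expect_setequal(flagged_seqs, decoy_seqs)
  expect_equal(qc$n_independent_confirmations,
               unname(rowSums(cat1$counts)[qc$haplotype]))
})
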