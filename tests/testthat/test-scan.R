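make_genome <- function(seq, replicon_id = "r1", strain = "s1",
                        class = "chromosome") {
  data.frame(strain_id = strain, replicon_id = replicon_id, sequence = seq,
             length = nchar(seq), replicon_class = class,
             stringsAsFactors = FALSE)
}

test_that("scanning finds paired occurrences of a palindromic motif", {
  gantc <- motif_spec("GANTC", "6mA", 2)
  occ <- scan_motif(make_genome("GGAATCG"), gantc)
  expect_equal(occ$start, c(2L, 2L))
  expect_setequal(occ$strand, c("+", "-"))
  expect_equal(occ$modified_genome_position[occ$strand == "+"], 3L)
  expect_equal(occ$modified_genome_position[occ$strand == "-"], 5L)
  expect_false(any(occ$methylated))
})

test_that("motifs longer than the sequence yield no occurrences", {
  m <- motif_spec("CCCGGG", "4mC", 2)
  expect_equal(nrow(scan_motif(make_genome("AAAA"), m)), 0L)
})

test_that("scanning agrees exactly with the brute-force expansion oracle", {
  set.seed(91)
  motifs <- sm_motifs()
  for (i in 1:20) {
    seq <- random_dna(sample(300:2000, 1), p_n = 0.01)
    g <- make_genome(seq)
    for (m in motifs[sample(length(motifs), 4)]) {
      got <- scan_motif(g, m)
      exp <- oracle_scan(seq, m$iupac, m$modified_index)
      expect_identical(got$start, exp$start)
      expect_identical(got$strand, exp$strand)
      expect_identical(got$modified_genome_position, exp$modified)
    }
  }
})

test_that("N in the genome never matches, even N in the motif", {
  g <- make_genome("GGANTCG")
  occ <- scan_motif(g, motif_spec("GANTC", "6mA", 2))
  expect_equal(nrow(occ), 0L)
})

test_that("scanning the reverse complement swaps and reflects strands", {
  set.seed(17)
  m <- motif_spec("GCRDB", "4mC", 2)
  for (i in 1:10) {
    seq <- random_dna(500)
    n <- nchar(seq)
    rc <- reverse_complement_iupac(seq)
    f <- scan_motif(make_genome(seq), m)
    r <- scan_motif(make_genome(rc), m)
    L <- nchar(m$iupac)
    reflect <- function(starts) sort(n - (starts + L - 1L) + 1L)
    expect_identical(sort(r$start[r$strand == "-"]),
                     reflect(f$start[f$strand == "+"]))
    expect_identical(sort(r$start[r$strand == "+"]),
                     reflect(f$start[f$strand == "-"]))
  }
})

test_that("palindromic motifs have equal counts on both strands", {
  set.seed(3)
  for (m in list(motif_spec("GANTC", "6mA", 2),
                 motif_spec("CTCGAG", "6mA", 5))) {
    seq <- random_dna(4000)
    occ <- scan_motif(make_genome(seq), m)
    expect_equal(sum(occ$strand == "+"), sum(occ$strand == "-"))
  }
})

test_that("methylation assignment matches calls by position, strand, type", {
  gantc <- motif_spec("GANTC", "6mA", 2)
  occ <- data.frame(
    motif_label = "GANTC", strain_id = "s1", replicon_id = "r1",
    replicon_class = "chromosome", start = c(10L, 10L),
    strand = c("+", "-"), modified_genome_position = c(11L, 13L),
    methylated = FALSE, stringsAsFactors = FALSE
  )
  call <- function(pos, strand, type) {
    data.frame(replicon_id = "r1", position = pos, strand = strand,
               modification_type = type, score = NA_real_,
               coverage = NA_integer_, stringsAsFactors = FALSE)
  }
  res <- assign_methylation(occ, call(11L, "+", "6mA"), list(gantc))
  expect_identical(res$methylated, c(TRUE, FALSE))
  res <- assign_methylation(occ, call(13L, "-", "6mA"), list(gantc))
  expect_identical(res$methylated, c(FALSE, TRUE))
  ## wrong type never matches under strict typing
  res <- assign_methylation(occ, call(11L, "+", "4mC"), list(gantc))
  expect_false(any(res$methylated))
  expect_equal(attr(res, "unmatched_calls"), 1L)
  ## generic modified_base calls are compatible with any type when allowed
  res <- assign_methylation(occ, call(11L, "+", "modified_base"),
                            list(gantc), allow_generic = TRUE)
  expect_identical(res$methylated, c(TRUE, FALSE))
  res <- assign_methylation(occ, call(11L, "+", "modified_base"),
                            list(gantc), allow_generic = FALSE)
  expect_false(any(res$methylated))
  ## wrong strand never matches
  res <- assign_methylation(occ, call(11L, "-", "6mA"), list(gantc))
  expect_false(any(res$methylated))
})

test_that("one call can flag several overlapping occurrences", {
  ## ACGGAGTC carries both ACGGAG (A5) and GANTC (A2) on + with the same
  ## modified adenine at position 5
  g <- make_genome("TACGGAGTCT")
  motifs <- list(motif_spec("ACGGAG", "6mA", 5),
                 motif_spec("GANTC", "6mA", 2))
  occ <- scan_genome(g, motifs)
  plus <- occ[occ$strand == "+", ]
  expect_equal(sort(unique(plus$modified_genome_position)), 6L)
  calls <- data.frame(replicon_id = "r1", position = 6L, strand = "+",
                      modification_type = "6mA", score = NA_real_,
                      coverage = NA_integer_, stringsAsFactors = FALSE)
  res <- assign_methylation(occ, calls, motifs)
  expect_equal(sum(res$methylated), 2L)
  expect_equal(attr(res, "unmatched_calls"), 0L)
})
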