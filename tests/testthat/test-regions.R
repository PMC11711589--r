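gene <- function(start, end, strand, id = "g1", replicon = "r1") {
  data.frame(replicon_id = replicon, start = start, end = end,
             strand = strand, feature_type = "CDS", gene_id = id,
             stringsAsFactors = FALSE)
}

segment_categories <- function(idx, strand, len) {
  region_category(idx, seq_len(len), rep(strand, len))
}

test_that("a single plus-strand gene partitions both strands as expected", {
  idx <- build_region_index(gene(11, 40, "+"), 60, us_length = 5)
  plus <- segment_categories(idx, "+", 60)
  expect_true(all(plus[6:10] == "US"))
  expect_true(all(plus[11:40] == "CDS"))
  expect_true(all(plus[c(1:5, 41:60)] == "tIG"))
  minus <- segment_categories(idx, "-", 60)
  expect_true(all(minus[11:40] == "nCDS"))
  expect_true(all(minus[c(1:10, 41:60)] == "tIG"))
})

test_that("an empty annotation leaves the whole replicon intergenic", {
  idx <- build_region_index(gene(1, 1, "+")[0, ], 100, us_length = 300)
  expect_true(all(segment_categories(idx, "+", 100) == "tIG"))
  expect_true(all(segment_categories(idx, "-", 100) == "tIG"))
})

test_that("upstream windows truncate at gaps and replicon boundaries", {
  ## two adjacent + genes, 3 bp gap: the gap is entirely US of the
  ## downstream gene (truncated from 5 to 3 bp by the upstream gene's CDS)
  genes <- rbind(gene(1, 20, "+", "g1"), gene(24, 40, "+", "g2"))
  idx <- build_region_index(genes, 50, us_length = 5)
  plus <- segment_categories(idx, "+", 50)
  expect_true(all(plus[21:23] == "US"))
  expect_true(all(plus[1:20] == "CDS"))
  ## a gene starting at 3 on a linear replicon has only 2 bp of US
  idx2 <- build_region_index(gene(3, 10, "+"), 20, us_length = 5)
  plus2 <- segment_categories(idx2, "+", 20)
  expect_identical(plus2[1:2], c("US", "US"))
  ## circular mode wraps the window across the origin
  idx3 <- build_region_index(gene(3, 10, "+"), 20, us_length = 5,
                             circular = TRUE)
  plus3 <- segment_categories(idx3, "+", 20)
  expect_identical(plus3[c(18, 19, 20, 1, 2)], rep("US", 5))
})

test_that("the partition matches a per-position oracle on random layouts", {
  set.seed(33)
  for (rep in 1:40) {
    len <- sample(80:800, 1)
    n_genes <- sample(0:8, 1)
    genes <- if (n_genes == 0) gene(1, 1, "+")[0, ] else do.call(rbind, {
      lapply(seq_len(n_genes), function(i) {
        s <- sample(seq_len(len), 1)
        e <- min(len, s + sample(5:120, 1))
        gene(s, e, sample(c("+", "-"), 1), sprintf("g%d", i))
      })
    })
    us <- sample(c(0, 5, 30, 300), 1)
    idx <- build_region_index(genes, len, us_length = us)
    for (s in c("+", "-")) {
      expect_identical(segment_categories(idx, s, len),
                       oracle_regions(genes, len, us, s))
    }
    ## partition: per strand, segment lengths sum to the replicon length
    for (s in c("+", "-")) {
      seg <- idx$segments[idx$segments$strand == s, ]
      expect_equal(sum(seg$end - seg$start + 1L), len)
    }
  }
})

test_that("classification is independent of gene input order", {
  set.seed(8)
  genes <- rbind(gene(10, 50, "+", "a"), gene(30, 90, "-", "b"),
                 gene(60, 75, "+", "c"), gene(100, 140, "-", "d"))
  idx1 <- build_region_index(genes, 200, us_length = 20)
  idx2 <- build_region_index(genes[sample(4), ], 200, us_length = 20)
  expect_identical(idx1$segments, idx2$segments)
})

test_that("degenerate gene layouts behave sensibly", {
  ## overlapping same-strand genes merge into one CDS block
  genes <- rbind(gene(10, 30, "+", "a"), gene(20, 45, "+", "b"))
  idx <- build_region_index(genes, 60, us_length = 0)
  seg <- idx$segments[idx$segments$strand == "+" &
                        idx$segments$category == "CDS", ]
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(10L, 45L))
  ## a gene covering the whole replicon leaves zero tIG on its strand
  idx2 <- build_region_index(gene(1, 60, "+"), 60, us_length = 10)
  expect_false("tIG" %in%
                 idx2$segments$category[idx2$segments$strand == "+"])
  ## gene coordinates beyond the replicon are rejected
  expect_error(build_region_index(gene(50, 80, "+"), 60), "exceed")
})

test_that("occurrence classification looks up the modified base per strand", {
  idx <- build_region_index(gene(11, 40, "+"), 60, us_length = 5)
  expect_identical(region_category(idx, 20, "+"), "CDS")
  expect_identical(region_category(idx, 20, "-"), "nCDS")
  expect_identical(region_category(idx, 50, "+"), "tIG")
  expect_identical(region_category(idx, 50, "-"), "tIG")
  expect_identical(region_category(idx, 8, "+"), "US")
  expect_error(region_category(idx, 61, "+"), "outside")
  occ <- data.frame(modified_genome_position = c(20L, 8L),
                    strand = c("-", "+"))
  expect_identical(classify_occurrences(idx, occ)$region, c("nCDS", "US"))
})

test_that("region BED export uses 0-based half-open coordinates", {
  idx <- build_region_index(gene(11, 40, "+"), 60, us_length = 5)
  f <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(idx, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(sum(bed$V3 - bed$V2), 2L * 60L)
  cds <- bed[bed$V4 == "CDS" & bed$V6 == "+", ]
  expect_equal(c(cds$V2, cds$V3), c(10L, 40L))
})
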