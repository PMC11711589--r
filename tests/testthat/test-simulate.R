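test_that("the generator is deterministic given the seed", {
  cfg <- panel_config(n_strains = 2, seed = 99, n_min = 2,
                      replicon_plan = data.frame(
                        replicon_class = c("chromosome", "pSymA"),
                        length = c(8000L, 5000L), stringsAsFactors = FALSE))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_panel(cfg, out_dir = d1)
  p2 <- generate_panel(cfg, out_dir = d2)
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(p1$calls, p2$calls)
  expect_identical(p1$truth, p2$truth)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planting guarantees minimum occurrences per motif and region", {
  p <- small_panel()
  n_min <- p$config$n_min
  tr <- p$truth
  ## for every strain x motif x region that can hold the motif, at least
  ## n_min occurrences exist (chromosome replicons are large enough for all)
  chr <- tr[tr$replicon_class == "chromosome", ]
  counts <- table(chr$strain_id, chr$motif_label, chr$region)
  expect_true(all(counts >= n_min))
})

test_that("strains outside a motif's presence subset emit no calls", {
  p <- small_panel()
  pres <- p$config$presence
  types <- vapply(p$config$motifs, `[[`, "", "modification_type")
  names(types) <- vapply(p$config$motifs, `[[`, "", "label")
  for (motif in names(pres)) {
    absent <- setdiff(p$config$strains, pres[[motif]])
    if (length(absent) == 0) next
    tr <- p$truth[p$truth$motif_label == motif &
                    p$truth$strain_id %in% absent, ]
    expect_true(all(!tr$methylated), label = motif)
    expect_true(all(tr$design_p == 0), label = motif)
  }
})

test_that("emitted files validate through the readers with no warnings", {
  cfg <- panel_config(n_strains = 2, seed = 5, n_min = 2,
                      replicon_plan = data.frame(
                        replicon_class = c("chromosome", "pSymB"),
                        length = c(10000L, 6000L), stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  p <- generate_panel(cfg, out_dir = d)
  expect_no_warning({
    g <- read_fasta(file.path(d, "S01.fna"), strain_id = "S01")
    genes <- read_annotation_gff3(file.path(d, "S01.genes.gff3"))
    calls <- read_methylation_gff3(file.path(d, "S01.meth.gff3"), genome = g)
    manifest <- read_manifest(file.path(d, "manifest.tsv"))
  })
  expect_identical(g$sequence,
                   p$genomes$sequence[p$genomes$strain_id == "S01"])
  expect_equal(nrow(calls), sum(p$calls$strain_id == "S01"))
  expect_equal(nrow(genes), sum(p$genes$strain_id == "S01"))
})

test_that("every emitted call sits at a planted occurrence's modified base", {
  p <- small_panel()
  occ_key <- paste(p$truth$replicon_id, p$truth$strand,
                   p$truth$modified_genome_position)
  call_key <- paste(p$calls$replicon_id, p$calls$strand, p$calls$position)
  expect_true(all(call_key %in% occ_key))
  ## and the truth flags mirror the call set exactly
  flagged <- p$truth[p$truth$methylated, ]
  expect_true(all(paste(flagged$replicon_id, flagged$strand,
                        flagged$modified_genome_position) %in% call_key))
})

test_that("observed frequencies track the design probabilities", {
  p <- small_panel()
  exp_tab <- expected_frequency(p, by = c("motif_label", "region"))
  obs <- methylation_frequency(p$truth, by = c("motif_label", "region"))
  key <- paste(obs$motif_label, obs$region)
  ekey <- paste(exp_tab$motif_label, exp_tab$region)
  m <- match(key, ekey)
  dev <- abs(obs$frequency - exp_tab$expected[m])
  bound <- 2.576 * exp_tab$sd[m] + 1e-9
  ## a 99% interval leaves each of the ~64 groups a 1% miss rate, so allow
  ## the number of misses a correct generator produces with high probability
  expect_lte(sum(dev > bound), 2L)
  expect_true(all(dev <= 4 * exp_tab$sd[m] + 1e-9))
})

test_that("a gene-free configuration classifies everything as intergenic", {
  cfg <- panel_config(n_strains = 2, seed = 3, n_min = 2,
                      gene_length = c(9000L, 9500L),
                      replicon_plan = data.frame(
                        replicon_class = "chromosome", length = 5000L,
                        stringsAsFactors = FALSE),
                      plasmid_every = 0L)
  p <- generate_panel(cfg)
  expect_equal(nrow(p$genes), 0L)
  expect_true(all(p$truth$region == "tIG"))
})

test_that("shell presence designs span 2 to n-2 strains at full size", {
  cfg <- panel_config(n_strains = 21, seed = 1)
  sizes <- lengths(cfg$presence)
  tab <- attr(cfg$motifs, "table")
  shell <- tab$label[tab$distribution == "shell"]
  expect_equal(sum(sizes == 21), 10L)
  expect_setequal(names(sizes[sizes < 21]), shell)
  expect_true(all(sizes[shell] >= 2 & sizes[shell] <= 19))
})
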