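# Alignment container, file formats and the curation filters.

test_that("FASTA parsing, round trips and error paths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">A\nACGT\n>B\nACGA", f)
  aln <- read_alignment(f, "fasta")
  expect_equal(aln_taxa(aln), c("A", "B"))
  expect_equal(ncol(aln$mat), 4L)
  expect_equal(paste(aln$mat["B", ], collapse = ""), "ACGA")

  for (fmt in c("fasta", "phylip", "nexus")) {
    g <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignment(aln, g, fmt)
    back <- read_alignment(g, fmt)
    expect_equal(back$mat, aln$mat, info = fmt)
  }

  writeLines(">A\nACGT\n>B\nACGTA", f)
  expect_error(read_alignment(f, "fasta"), "ragged")
  writeLines(">A\nACJT\n>B\nACGT", f)
  expect_error(read_alignment(f, "fasta"), "symbol 'J'.*taxon A.*column 3")
})

test_that("relaxed PHYLIP handles sequential and interleaved layouts", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 8", "taxon_one  ACGTACGT", "taxon_two  ACGAACGA"), f)
  aln <- read_alignment(f, "phylip")
  expect_equal(aln_taxa(aln), c("taxon_one", "taxon_two"))
  expect_equal(ncol(aln$mat), 8L)
  writeLines(c("2 8", "taxon_one  ACGT", "taxon_two  ACGA",
               "ACGT", "ACGA"), f)
  aln2 <- read_alignment(f, "phylip")
  expect_equal(aln2$mat, aln$mat)
  writeLines(c("2 9", "taxon_one  ACGTACGT", "taxon_two  ACGAACGA"), f)
  expect_error(read_alignment(f, "phylip"), "declares 9")
})

test_that("alignment invariants are enforced", {
  m <- matrix("A", 2, 6, dimnames = list(c("x", "y"), NULL))
  expect_s3_class(alignment(m, codon = TRUE), "dp_alignment")
  expect_error(alignment(m[, 1:5], codon = TRUE), "divisible by 3")
  gb <- data.frame(gene = c("g1", "g2"), start = c(0L, 2L), end = c(3L, 6L))
  expect_error(alignment(m, gene_bounds = gb), "partition")
  m2 <- m; rownames(m2) <- c("x", "x")
  expect_error(alignment(m2), "duplicate taxon")
})

test_that("occupancy filter keeps the >= boundary and preserves frame", {
  m <- rbind(a = c("A", "A"), b = c("C", "-"), c = c("-", "G"), d = c("-", "T"))
  colnames(m) <- NULL
  aln <- alignment(m)
  # column 1: a,b have states -> occupancy 0.5, kept at the boundary;
  # column 2: a,c,d -> 0.75, kept
  kept <- filter_low_occupancy_columns(aln, 0.5)
  expect_equal(ncol(kept$mat), 2L)
  kept6 <- filter_low_occupancy_columns(aln, 0.6)
  expect_equal(ncol(kept6$mat), 1L)

  # no gaps: identity
  full <- random_nuc_alignment(letters[1:4], 30, gap_prob = 0)
  expect_equal(filter_low_occupancy_columns(full, 0.5)$mat, full$mat)

  # codon triple with 14 of 26 rows missing: occupancy 12/26 < 0.5, dropped
  m3 <- matrix("A", 26, 6, dimnames = list(paste0("t", 1:26), NULL))
  m3[1:14, 1:3] <- "?"
  aln3 <- alignment(m3, codon = TRUE)
  kept3 <- filter_low_occupancy_columns(aln3, 0.5)
  expect_equal(ncol(kept3$mat), 3L)

  # idempotence on random gappy fixtures
  for (s in 1:5) {
    a <- random_nuc_alignment(letters[1:6], 60, gap_prob = 0.4, seed = s)
    once <- filter_low_occupancy_columns(a, 0.5)
    expect_equal(filter_low_occupancy_columns(once, 0.5)$mat, once$mat)
  }
  all_gap <- alignment(matrix("-", 2, 3, dimnames = list(c("a", "b"), NULL)))
  expect_error(filter_low_occupancy_columns(all_gap, 0.5), "all columns")
})

test_that("gene filter applies length boundary and required groups", {
  mk <- function(len, taxa = c("in1", "in2", "out1")) {
    alignment(matrix("A", length(taxa), len, dimnames = list(taxa, NULL)))
  }
  tab <- gene_table(list(g199 = mk(199), g200 = mk(200),
                         g_noout = {
                           a <- mk(300)
                           a$mat["out1", ] <- "?"
                           a
                         }))
  out <- filter_genes(tab, min_len_bp = 200,
                      required_groups = list(outgroup = "out1"))
  expect_equal(names(out$genes), "g200")
  out2 <- filter_genes(tab, min_len_bp = 0)
  expect_equal(length(out2$genes), 3L)
  expect_warning(filter_genes(tab, min_len_bp = 1000), "all genes")
})

test_that("concatenation fills absences and reports the missing fraction", {
  g1 <- alignment(matrix("A", 2, 6, dimnames = list(c("t1", "t2"), NULL)))
  g2 <- alignment(matrix("C", 2, 6, dimnames = list(c("t2", "t3"), NULL)))
  tab <- gene_table(list(g1 = g1, g2 = g2))
  cat1 <- concatenate(tab)
  expect_equal(ncol(cat1$mat), 12L)
  expect_equal(attr(cat1, "missing_fraction"), 2 / 6)
  expect_true(all(cat1$mat["t3", 1:6] == "?"))
  expect_equal(cat1$gene_bounds$end, c(6L, 12L))

  single <- concatenate(gene_table(list(g1 = g1)))
  expect_equal(single$mat, g1$mat)

  aa <- alignment(matrix("M", 2, 4, dimnames = list(c("t1", "t2"), NULL)),
                  alphabet = "amino_acid")
  expect_error(gene_table(list(g1 = g1, aa = aa)), "mixed alphabets")

  # missing fraction equals brute-force cell count on random fixtures
  set.seed(2)
  for (r in 1:3) {
    taxa <- paste0("t", 1:5)
    genes <- lapply(1:4, function(g) {
      a <- random_nuc_alignment(taxa, 9, gap_prob = 0)
      drop <- runif(5) < 0.3
      a$mat[drop, ] <- "?"
      a
    })
    names(genes) <- paste0("g", 1:4)
    tabr <- gene_table(genes, taxa = taxa)
    manual <- mean(sapply(genes, function(a) rowSums(a$mat != "?") == 0))
    expect_equal(attr(concatenate(tabr), "missing_fraction"), manual)
  }
})

test_that("translation follows the genetic code and flags stops", {
  m <- rbind(s1 = strsplit("ATGGCT", "")[[1]])
  aln <- alignment(m, codon = TRUE)
  expect_equal(paste(translate_alignment(aln)$mat[1, ], collapse = ""), "MA")

  m2 <- rbind(s1 = strsplit("ATGTGACCT", "")[[1]])
  expect_error(translate_alignment(alignment(m2, codon = TRUE)),
               "stop codon TGA at codon 2")

  # gap codon -> gap, partial/missing -> missing, multi-aa ambiguity -> X,
  # synonymous ambiguity (GCN) -> amino acid
  m3 <- rbind(s1 = strsplit("---A-GGCNRAT", "")[[1]])
  tr <- translate_alignment(alignment(m3, codon = TRUE))
  expect_equal(unname(tr$mat[1, ]), c("-", "?", "A", "X"))

  # translate(concatenate(T)) == concatenate(translate per gene)
  set.seed(4)
  codons <- names(Biostrings::getGeneticCode("1"))
  sense <- codons[Biostrings::getGeneticCode("1") != "*"]
  genes <- lapply(1:3, function(g) {
    taxa <- paste0("t", 1:4)
    m <- t(sapply(taxa, function(tx)
      unlist(strsplit(paste(sample(sense, 5, TRUE), collapse = ""), ""))))
    alignment(m, codon = TRUE)
  })
  names(genes) <- paste0("g", 1:3)
  tab <- gene_table(genes)
  a <- translate_alignment(concatenate(tab))
  b <- concatenate(translate_alignment(tab))
  expect_equal(a$mat, b$mat)
  expect_equal(a$gene_bounds, b$gene_bounds)
})
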