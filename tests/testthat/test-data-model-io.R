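test_that("expression matrix and design round-trip unchanged", {
  x <- tinyDataset()
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(x, mp, dp)
  y <- readExpression(mp, dp)
  expect_identical(rownames(y), rownames(x))
  expect_equal(intensities(y), intensities(x))
  expect_equal(sampleDesign(y), sampleDesign(x))
})

test_that("random small datasets round-trip through the writers", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:20, 1)
    reps <- sample(2:4, 1)
    d <- randomDesign(n_cond = 3, reps = reps)
    m <- matrix(round(exp(rnorm(n * nrow(d), 6, 1)), 4), nrow = n,
                dimnames = list(sprintf("g%03d", seq_len(n)), NULL))
    x <- ExpressionDataset(m, d)
    mp <- withr::local_tempfile(); dp <- withr::local_tempfile()
    writeExpression(x, mp, dp)
    y <- readExpression(mp, dp)
    expect_equal(intensities(y), intensities(x))
    expect_equal(sampleDesign(y), sampleDesign(x))
  }
})

test_that("malformed expression input is rejected with located errors", {
  x <- tinyDataset()
  mp <- withr::local_tempfile(); dp <- withr::local_tempfile()
  writeExpression(x, mp, dp)

  # design listing a sample absent from the matrix names that sample
  d <- sampleDesign(x)
  d$sample_id[3] <- "ghost_sample"
  dp2 <- withr::local_tempfile()
  write.table(d, dp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpression(mp, dp2), "ghost_sample")

  # negative intensity reported with its coordinates
  lines <- readLines(mp)
  lines[2] <- sub("^gA\t[0-9.]+", "gA\t-5", lines[2])
  mp2 <- withr::local_tempfile()
  writeLines(lines, mp2)
  expect_error(readExpression(mp2, dp), "-5.*gA|gA.*-5")

  # duplicated gene id
  lines <- readLines(mp)
  lines[3] <- sub("^gB", "gA", lines[3])
  mp3 <- withr::local_tempfile()
  writeLines(lines, mp3)
  expect_error(readExpression(mp3, dp), "duplicate.*gA")
})

test_that("dataset validity enforces design invariants", {
  m <- matrix(1:8, nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  d <- randomDesign(n_cond = 2, reps = 2)
  expect_s4_class(ExpressionDataset(m, d), "ExpressionDataset")
  # single replicate for a condition
  expect_error(ExpressionDataset(m[, 1:3], d[1:3, ]), "2 replicates")
  # negative intensity
  m2 <- m; m2[1, 1] <- -1
  expect_error(ExpressionDataset(m2, d), "non-negative")
  # duplicated (tissue, hpe, replicate) triple
  d2 <- d; d2$replicate <- c(1, 1, 1, 2)
  expect_error(ExpressionDataset(m, d2), "duplicate")
})

test_that("annotation reader validates and deduplicates", {
  ann <- data.frame(gene_id = sprintf("g%d", 1:5),
                    category_code = c("Ib", "Ib", "VIa", "VIa", "VIa"),
                    category_name = c("Storage", "Storage", "Secondary",
                                      "Secondary", "Secondary"),
                    hormone_category = c("none", "auxin", "none", "none",
                                         "ethylene"))
  p <- withr::local_tempfile()
  write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readAnnotation(p)
  expect_equal(nrow(got), 5)
  expect_equal(got$gene_id, ann$gene_id)

  # exact duplicate rows collapse silently
  write.table(rbind(ann, ann[3, ]), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(nrow(readAnnotation(p)), 5)

  # conflicting categories for one gene are an error
  ann2 <- rbind(ann, data.frame(gene_id = "g1", category_code = "XV",
                                category_name = "Other",
                                hormone_category = "none"))
  write.table(ann2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotation(p), "g1")

  # unknown hormone label is an error
  ann3 <- ann; ann3$hormone_category[2] <- "auxinn"
  write.table(ann3, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotation(p), "auxinn")
})

test_that("gene sets round-trip with provenance, including tabs", {
  p <- withr::local_tempfile()
  s <- geneSet("stem_base_identity", c("gA", "gB", "gC"),
               provenance = list(comparison = "sb_0_vs_root",
                                 note = "cut\toff=500",
                                 m_cut = "1"))
  writeGeneSet(s, p)
  got <- readGeneSet(p)
  expect_identical(got@name, s@name)
  expect_identical(got@genes, s@genes)
  expect_identical(got@provenance, list(comparison = "sb_0_vs_root",
                                        note = "cut\toff=500", m_cut = "1"))

  writeGeneSet(geneSet("empty"), p)
  empty <- readGeneSet(p)
  expect_identical(empty@genes, character(0))
  expect_identical(empty@name, "empty")
})
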