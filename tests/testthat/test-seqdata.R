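test_that("one-hot encoding follows the A,T,C,G column convention", {
  M <- encodeSequence("NGACAN")
  expected <- rbind(c(0, 0, 0, 0),
                    c(0, 0, 0, 1),
                    c(1, 0, 0, 0),
                    c(0, 0, 1, 0),
                    c(1, 0, 0, 0),
                    c(0, 0, 0, 0))
  expect_equal(unname(M), expected, ignore_attr = TRUE)
  expect_equal(unname(encodeSequence("A")), matrix(c(1, 0, 0, 0), 1),
               ignore_attr = TRUE)
  # U normalises to T
  expect_identical(encodeSequence("ACGU"), encodeSequence("ACGT"))
  expect_identical(encodeSequence("acgu"), encodeSequence("ACGT"))
  # row sums are 0 only for N
  rs <- rowSums(M)
  expect_identical(rs == 0, strsplit("NGACAN", "")[[1]] == "N")
})

test_that("unknown characters are rejected with their position", {
  expect_error(encodeSequence("ACGXA"), "position 4")
  expect_error(encodeSequence(""), "non-empty")
})

test_that("decode inverts encode on random A/C/G/T/N strings", {
  set.seed(11)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(decodeSequence(encodeSequence(s)), s)
  }
})

test_that("boxplot threshold equals the hand-computed Tukey fence", {
  expect_identical(lengthThreshold(c(30, 30, 30, 30)), 30L)
  for (lens in list(1:100,
                    c(10, 10, 12, 14, 50),
                    sample(20:120, 37, replace = TRUE))) {
    expect_identical(lengthThreshold(lens),
                     as.integer(floor(oracleUpperFence(lens) + 0.5)))
  }
  # 50 lies above the fence of the small example and would be discarded
  thr <- lengthThreshold(c(10, 10, 12, 14, 50))
  expect_true(50 > thr)
  expect_error(lengthThreshold(integer(0)))
})

test_that("centre padding puts the odd remainder on the 3' side", {
  pol <- lengthPolicy(7L)
  expect_identical(padOrDiscard("ACGTA", pol), "NACGTAN")
  expect_identical(padOrDiscard("ACGT", pol), "NACGTNN")
  expect_identical(padOrDiscard("ACGTACG", pol), "ACGTACG")
  # longer than the threshold: discard signal
  expect_null(padOrDiscard(strrep("A", 80), lengthPolicy(72L)))
})

test_that("buildDataset balances, deduplicates and is seed-deterministic", {
  set.seed(5)
  pos <- vapply(1:10, function(i) randomSeq(30), character(1))
  names(pos) <- paste0("s", 1:10)
  ds <- buildDataset(pos, policy = lengthPolicy(40L), seed = 3)
  expect_identical(as.integer(table(siteLabels(ds))), c(10L, 10L))
  # negatives point back at their positive
  neg <- siteLabels(ds) == "negative"
  expect_true(all(ds@pairedWith[neg] %in% names(pos)))

  # exact duplicates are removed before shuffling
  dup <- c(pos, s11 = unname(pos[1]))
  ds2 <- buildDataset(dup, policy = lengthPolicy(40L), seed = 3)
  expect_identical(length(ds2), 20L)

  # bit-identical under a fixed seed
  dsA <- buildDataset(pos, policy = lengthPolicy(40L), seed = 9)
  dsB <- buildDataset(pos, policy = lengthPolicy(40L), seed = 9)
  expect_identical(as.character(siteSequences(dsA)),
                   as.character(siteSequences(dsB)))
  expect_error(buildDataset(character(0)))
})

test_that("negative pool conserves the positive pool's dinucleotide counts", {
  set.seed(7)
  pos <- vapply(1:15, function(i) randomSeq(40), character(1))
  ds <- buildDataset(pos, policy = lengthPolicy(40L), seed = 2)
  posSeq <- as.character(siteSequences(ds))[siteLabels(ds) == "positive"]
  negSeq <- as.character(siteSequences(ds))[siteLabels(ds) == "negative"]
  cntP <- table(unlist(lapply(posSeq, oracleDinucCounts)))
  cntN <- table(unlist(lapply(negSeq, oracleDinucCounts)))
  expect_identical(cntP[sort(names(cntP))], cntN[sort(names(cntN))])
})

test_that("length outliers are discarded and all encoded rows equal the threshold", {
  set.seed(8)
  pos <- c(vapply(1:12, function(i) randomSeq(sample(20:30, 1)), character(1)),
           long = randomSeq(90))
  names(pos) <- paste0("p", seq_along(pos))
  ds <- buildDataset(pos, seed = 1)
  thr <- sitePolicy(ds)@thresholdL
  expect_true(all(Biostrings::width(siteSequences(ds)) <= thr))
  enc <- capsRBP:::.encodeSet(ds)
  expect_true(all(nchar(enc$padded) == thr))
  expect_identical(ncol(enc$codes), as.integer(thr))
})

test_that("the coordinate filter drops sites with high Jaccard overlap", {
  r <- IRanges::IRanges(start = c(1, 5, 100, 102, 300),
                        end = c(50, 54, 130, 132, 320))
  # 2 vs 1: 46/54 = 0.85; 4 vs 3: 29/33 = 0.88; both above the cutoff
  expect_identical(capsRBP:::.jaccardKeep(r, 0.8),
                   c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # with a permissive cutoff everything survives
  expect_true(all(capsRBP:::.jaccardKeep(r, 0.95)))
  set.seed(1)
  pos <- vapply(1:5, function(i) randomSeq(30), character(1))
  ds <- buildDataset(pos, policy = lengthPolicy(30L), seed = 1,
                     ranges = r, maxJaccard = 0.8)
  expect_identical(length(ds), 6L)
})

test_that("FASTA round trip preserves ids and sequences, normalising U", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">a desc", "ACGUACGU", ">b", "GGGTTT"), tmp)
  x <- readFastaSites(tmp)
  expect_identical(names(x), c("a", "b"))
  expect_identical(as.character(x), c(a = "ACGTACGT", b = "GGGTTT"))
  out <- tempfile(fileext = ".fa")
  writeFastaSites(x, out)
  expect_identical(as.character(readFastaSites(out)), as.character(x))
})

test_that("manifest records id, label, length and source", {
  set.seed(9)
  pos <- vapply(1:5, function(i) randomSeq(25), character(1))
  ds <- buildDataset(pos, policy = lengthPolicy(30L), seed = 1)
  tmp <- tempfile(fileext = ".tsv")
  writeManifest(ds, tmp)
  man <- read.delim(tmp)
  expect_identical(nrow(man), 10L)
  expect_identical(sort(unique(man$label)), c("negative", "positive"))
  expect_true(all(man$length == 25L))
})
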