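# stub scorer: counts A's in each window (window width attached)
aCountScorer <- function(W) {
  f <- function(windows) vapply(strsplit(windows, ""), function(ch)
    sum(ch == "A"), numeric(1))
  attr(f, "window") <- W
  f
}

test_that("window arithmetic matches the sequence geometry", {
  m <- capsModel(10L, kernelSize = 3L, nFilters = 4L, capsDim = 2L, seed = 1)
  s <- paste(rep("ACGTT", 2), collapse = "")
  # L_seq = W: one window in linear mode
  h1 <- scanCircRNA(s, m, circular = FALSE)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$start, 1L)
  expect_identical(h1$end, 10L)
  # circular: one window per start position
  set.seed(2)
  s100 <- randomSeq(100)
  h2 <- scanCircRNA(s100, NULL, circular = TRUE, scoreFun = aCountScorer(40L))
  expect_identical(nrow(h2), 100L)
  expect_identical(sort(h2$start), 1:100)
  # unwrapped hits span exactly W; wrapped hits are flagged
  unw <- h2[!h2$wrapped, ]
  expect_true(all(unw$end - unw$start + 1L == 40L))
  expect_identical(sum(h2$wrapped), 39L)
  expect_true(all(h2$start >= 1L & h2$start <= 100L))
  # stride thins the start positions
  h3 <- scanCircRNA(s100, NULL, circular = TRUE, scoreFun = aCountScorer(40L),
                    stride = 5L)
  expect_identical(h3$start[order(h3$start)], seq(1L, 100L, by = 5L))
  expect_error(scanCircRNA(randomSeq(20), m, circular = FALSE,
                           scoreFun = aCountScorer(40L)))
  # circular windows may wrap more than once on a short circle
  h4 <- scanCircRNA("ACGTACGTAC", NULL, circular = TRUE,
                    scoreFun = aCountScorer(25L))
  expect_identical(nrow(h4), 10L)
  expect_true(all(h4$wrapped))
  # every window of width 25 on a 10-mer circle sees each base >= 2 times
  expect_true(all(h4$score >= 2 * 3))
})

test_that("the top window matches exhaustive enumeration with a stub scorer", {
  set.seed(33)
  for (i in 1:10) {
    s <- randomSeq(60)
    W <- 15L
    h <- scanCircRNA(s, NULL, circular = TRUE, scoreFun = aCountScorer(W))
    # brute force: enumerate every rotation window and count A's
    ext <- paste0(s, substr(s, 1, W - 1))
    cnt <- vapply(1:60, function(st)
      sum(strsplit(substr(ext, st, st + W - 1), "")[[1]] == "A"), numeric(1))
    best <- max(cnt)
    expect_equal(h$score[1], best)
    # ranked by score desc, ties by start asc
    expect_identical(h$start[1], which(cnt == best)[1])
    expect_true(all(diff(h$score) <= 0))
  }
})

test_that("rotating a circular sequence rotates hit coordinates", {
  set.seed(44)
  s <- randomSeq(80)
  W <- 20L
  rot <- 17L
  srot <- paste0(substr(s, rot + 1, 80), substr(s, 1, rot))
  h0 <- scanCircRNA(s, NULL, scoreFun = aCountScorer(W))
  h1 <- scanCircRNA(srot, NULL, scoreFun = aCountScorer(W))
  # same multiset of scores
  expect_equal(sort(h0$score), sort(h1$score))
  # the window starting at position p on the original starts at
  # ((p - rot - 1) mod 80) + 1 on the rotation
  o0 <- h0[order(h0$start), ]
  o1 <- h1[order(h1$start), ]
  mapped <- ((o0$start - rot - 1) %% 80) + 1
  expect_equal(o0$score, o1$score[match(mapped, o1$start)])
})

test_that("scan scores equal independent per-window forward passes", {
  m <- capsModel(12L, kernelSize = 3L, nFilters = 8L, capsDim = 4L, seed = 6)
  set.seed(7)
  s <- randomSeq(30)
  h <- scanCircRNA(s, m, circular = TRUE)
  ext <- paste0(s, substr(s, 1, 11))
  for (row in c(1L, 5L, 30L)) {
    win <- substr(ext, h$start[row], h$start[row] + 11L)
    expect_equal(h$score[row],
                 unname(predictScores(m, win)[1, "scorePos"]),
                 tolerance = 1e-12)
  }
})

test_that("top-hit reporting is greedy, non-overlapping and tie-stable", {
  hits <- data.frame(start = c(10L, 3L, 40L, 12L),
                     end = c(24L, 17L, 54L, 26L),
                     wrapped = FALSE,
                     score = c(0.9, 0.9, 0.5, 0.8))
  hits <- hits[order(-hits$score, hits$start), ]
  attr(hits, "seqLength") <- 60L
  attr(hits, "window") <- 15L
  top1 <- reportTopHits(hits, 1)
  # equal scores: earlier start wins
  expect_identical(top1$start, 3L)
  top2 <- reportTopHits(hits, 3)
  # overlapping hit at 10/12 skipped, next non-overlapping kept
  expect_identical(top2$start, c(3L, 40L, NULL))
  expect_true(all(top2$end - top2$start + 1L == 15L))
  expect_error(reportTopHits(hits, 0))
})

test_that("BED export converts to 0-based half-open and splits wrapped hits", {
  hits <- data.frame(start = c(5L, 58L), end = c(14L, 7L),
                     wrapped = c(FALSE, TRUE), score = c(0.8, 0.6))
  attr(hits, "seqLength") <- 60L
  attr(hits, "window") <- 10L
  tmp <- tempfile(fileext = ".bed")
  writeHitsBED(hits, tmp, id = "circX")
  bed <- read.delim(tmp, header = FALSE)
  expect_identical(nrow(bed), 3L)
  expect_identical(bed$V2[1], 4L)
  expect_identical(bed$V3[1], 14L)
  # wrapped: [58, 60] and [1, 7] arcs
  expect_identical(bed$V2[2:3], c(57L, 0L))
  expect_identical(bed$V3[2:3], c(60L, 7L))
})
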