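test_that("confusion counts match hand-computed and degenerate cases", {
  g <- genome(chr1 = strrep("A", 100))
  cur <- ann("chr1", 11, 30, class = "LTR")
  tst <- ann("chr1", 21, 40, class = "LTR")
  cc <- confusionCounts(cur, tst, "LTR", g)
  expect_equal(as.data.frame(cc),
               data.frame(tp = 10, fp = 10, fn = 10, tn = 70))
  ## exact agreement
  cc2 <- confusionCounts(cur, cur, "LTR", g)
  expect_equal(as.data.frame(cc2),
               data.frame(tp = 20, fp = 0, fn = 0, tn = 80))
  ## empty test annotation
  cc3 <- confusionCounts(cur, TEAnnotation(GenomicRanges::GRanges()),
                         "LTR", g)
  expect_equal(as.data.frame(cc3),
               data.frame(tp = 0, fp = 0, fn = 20, tn = 80))
  ## out-of-bounds record is an error naming the record
  expect_error(confusionCounts(ann("chr1", 90, 120), tst, "LTR", g),
               "chr1:90-120")
})

test_that("interval arithmetic equals per-base labeling on random cases", {
  set.seed(51)
  classes <- c("LTR", "TIR", "Helitron", "nonLTR", "nonTE")
  for (case in 1:200) {
    L <- sample(100:10000, 1)
    nc <- sample(1:50, 1); nt <- sample(1:50, 1)
    cs <- sample(L, nc, replace = TRUE)
    ce <- pmin(L, cs + sample(0:200, nc, replace = TRUE))
    ccl <- sample(classes, nc, replace = TRUE)
    ts <- sample(L, nt, replace = TRUE)
    te <- pmin(L, ts + sample(0:200, nt, replace = TRUE))
    target <- sample(classes, sample(1:4, 1))
    g <- genome(chr1 = strrep("A", L))
    cc <- confusionCounts(ann("chr1", cs, ce, class = ccl),
                          ann("chr1", ts, te), target, g)
    want <- c(bruteConfusion(L, cs, ce, ccl %in% target, ts, te))
    storage.mode(want) <- "double"
    expect_identical(unlist(as.data.frame(cc)), want,
                     info = paste("case", case))
    expect_equal(sum(as.data.frame(cc)), L)
  }
})

test_that("growing the test annotation never decreases tp or fp", {
  set.seed(52)
  g <- genome(chr1 = strrep("A", 5000))
  cur <- ann("chr1", st <- sample(1:4500, 20), pmin(5000, st + 150),
             class = "LTR")
  prevTp <- 0; prevFp <- 0
  sts <- sample(1:4500, 30)
  for (k in seq(5, 30, by = 5)) {
    tst <- ann("chr1", sts[1:k], pmin(5000, sts[1:k] + 100))
    cc <- confusionCounts(cur, tst, "LTR", g)
    expect_gte(cc@tp, prevTp)
    expect_gte(cc@fp, prevFp)
    prevTp <- cc@tp; prevFp <- cc@fp
  }
  ## swapping curated and test swaps fn and fp when all classes are targets
  tst <- ann("chr1", sts, pmin(5000, sts + 100))
  a <- confusionCounts(cur, tst, "LTR", g)
  b <- confusionCounts(tst, cur, "LTR", g)
  expect_equal(a@fp, b@fn)
  expect_equal(a@fn, b@fp)
  expect_equal(a@tp, b@tp)
})

test_that("the six metrics follow their defining formulas, 0/0 is NA", {
  m <- as.data.frame(computeMetrics(ConfusionCounts(10, 10, 10, 70)))
  expect_equal(m, data.frame(sensitivity = 0.5, specificity = 0.875,
                             accuracy = 0.8, precision = 0.5, fdr = 0.5,
                             f1 = 0.5))
  ## empty-target degenerate: sensitivity and precision undefined
  m2 <- as.data.frame(computeMetrics(ConfusionCounts(0, 0, 0, 100)))
  expect_true(is.na(m2$sensitivity) && is.na(m2$precision) &&
                is.na(m2$fdr) && is.na(m2$f1))
  expect_equal(m2$specificity, 1.0)
  expect_equal(m2$accuracy, 1.0)
  ## perfect annotation
  m3 <- as.data.frame(computeMetrics(ConfusionCounts(40, 0, 0, 60)))
  expect_equal(unlist(m3[c("sensitivity", "specificity", "accuracy",
                           "precision", "f1")], use.names = FALSE),
               rep(1, 5))
  expect_equal(m3$fdr, 0)
  ## fdr is the complement of precision whenever defined
  set.seed(53)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE)
    mm <- as.data.frame(computeMetrics(do.call(ConfusionCounts,
                                               as.list(v))))
    if (!is.na(mm$precision)) expect_equal(mm$fdr, 1 - mm$precision)
  }
})

test_that("copies are complete only above 80% coverage (strict)", {
  set.seed(54)
  l0 <- lib(`fam1#LTR/Gypsy` = rndSeq(1000))
  mk <- function(widths, gaps = 0) {
    st <- 101
    out <- NULL
    for (i in seq_along(widths)) {
      out <- rbind(out, c(st, st + widths[i] - 1))
      st <- st + widths[i] + gaps
    }
    ann("chr1", out[, 1], out[, 2], class = "LTR", name = "fam1")
  }
  expect_equal(classifyCopies(l0, mk(810))$complete, 1)
  expect_equal(classifyCopies(l0, mk(810))$fragmented, 0)
  expect_equal(classifyCopies(l0, mk(790))$fragmented, 1)
  ## exactly 800 of 1000 is fragmented: "more than 80%" is strict
  expect_equal(classifyCopies(l0, mk(800))$complete, 0)
  expect_equal(classifyCopies(l0, mk(801))$complete, 1)
  ## fragments within 50 bp merge into one region; farther apart they are
  ## separate fragmented copies
  expect_equal(classifyCopies(l0, mk(c(500, 310), gaps = 50))$complete, 1)
  expect_equal(classifyCopies(l0, mk(c(500, 310), gaps = 51))$fragmented, 2)
  expect_error(classifyCopies(l0, ann("chr1", 1, 100, name = "ghost")),
               "unknown entries")
})

test_that("misclassification rates are zero on agreement, definitional otherwise", {
  ref <- ann("chr1", c(1, 2001), c(1000, 3000),
             class = c("LTR", "TIR"), name = c("a", "b"))
  ## test annotation calls the curated LTR region a TIR element
  tst <- ann("chr1", c(1, 2001), c(1000, 3000),
             class = c("TIR", "TIR"), name = c("x", "b"))
  m <- misclassificationRate(tst, ref)
  expect_equal(unname(m$perClass["LTR"]), 1.0)
  expect_equal(unname(m$perClass["TIR"]), 0.0)
  expect_equal(m$overall, 1000 / 2000)
  ## identical annotations: all rates zero
  m2 <- misclassificationRate(ref, ref)
  expect_equal(m2$overall, 0)
  expect_true(all(m2$perClass[c("LTR", "TIR")] == 0))
  ## self mode: overlapping records of different classes are inconsistent
  un <- TEAnnotation(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 501), c(1000, 1500)),
    Name = c("a", "b"), teClass = c("LTR", "Helitron")), resolved = FALSE)
  m3 <- misclassificationRate(un)
  expect_equal(m3$mode, "self")
  expect_equal(m3$overall, 500 / 1500)
})
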