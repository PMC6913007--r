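test_that("basic cleaning enforces class-specific length minima exactly", {
  set.seed(41)
  l0 <- lib(`t79#DNA/hAT` = rndSeq(79), `t80#DNA/hAT` = rndSeq(80),
            `l99#LTR/Gypsy` = rndSeq(99), `l100#LTR/Gypsy` = rndSeq(100),
            `h99#DNA/Helitron` = rndSeq(99),
            `tand#LTR/Gypsy` = strrep("TA", 200),
            `ok#LTR/Gypsy` = rndSeq(500))
  out <- basicClean(l0)
  expect_setequal(names(out), c("t80", "l100", "ok"))
  rem <- attr(out, "removals")
  expect_equal(rem$rule[rem$entry == "t79"], "min_length")
  expect_equal(rem$rule[rem$entry == "tand"], "tandem")
})

test_that("entries dominated by Ns are dropped", {
  l0 <- lib(`nn#LTR/Gypsy` = paste0(strrep("N", 60001), rndSeq(100)),
            `ok#LTR/Gypsy` = rndSeq(200))
  out <- basicClean(l0, filterConfig(maxMissing = 60000L))
  expect_setequal(names(out), "ok")
})

test_that("MITE reclassification is inclusive at 600 bp", {
  set.seed(42)
  l0 <- lib(`a600#DNA/hAT` = rndSeq(600), `a601#DNA/hAT` = rndSeq(601),
            `a80#DNA/hAT` = rndSeq(80), `ltr#LTR/Gypsy` = rndSeq(300))
  out <- reclassifyMites(l0)
  expect_equal(length(out), 4)
  info <- libInfo(out)
  expect_equal(info$isMITE[match(c("a600", "a601", "a80", "ltr"),
                                 info$name)],
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("Helitron structural filter checks motif, target site and score", {
  set.seed(43)
  mk <- function(name, seq, left = paste0(rndSeq(59), "A"),
                 right = paste0("T", rndSeq(59)), score = 14) {
    CandidateSet(
      TELibrary(stats::setNames(Biostrings::DNAStringSet(seq), name),
                info = S4Vectors::DataFrame(
                  name = sub("#.*", "", name), class = "Helitron",
                  subclass = NA_character_, superfamily = NA_character_,
                  isMITE = FALSE, stage = "raw", tsdLength = NA_integer_,
                  score = score)),
      S4Vectors::DataFrame(seqId = "chr1", start = 100L,
                           end = 100L + nchar(seq) - 1L,
                           leftFlank = left, rightFlank = right,
                           corruption = NA_character_,
                           sourceEntry = NA_character_,
                           verdict = NA_character_))
  }
  core <- rndSeq(300)
  good <- paste0("TC", core, "CTAG")
  expect_length(helitronStructuralFilter(mk("h1", good)), 1)
  expect_length(helitronStructuralFilter(mk("h2", paste0("GC", core, "CTAG"))), 0)
  expect_length(helitronStructuralFilter(mk("h3", paste0("TC", core, "CTTG"))), 0)
  expect_length(helitronStructuralFilter(mk("h4", good, left = paste0(rndSeq(59), "G"))), 0)
  expect_length(helitronStructuralFilter(mk("h5", good, right = paste0("A", rndSeq(59)))), 0)
  ## score boundary: 11 rejected, 12 kept, absent score kept
  expect_length(helitronStructuralFilter(mk("h6", good, score = 11)), 0)
  expect_length(helitronStructuralFilter(mk("h7", good, score = 12)), 1)
  expect_length(helitronStructuralFilter(mk("h8", good, score = NA_real_)), 1)
  ## no flank (contig edge): rejected with logged reason
  out <- helitronStructuralFilter(mk("h9", good, left = ""))
  expect_length(out, 0)
  expect_equal(attr(out, "removals")$rule, "no_flank")
})

test_that("terminal copy-number verdicts follow the 20-copy rule", {
  set.seed(44)
  ## windows: A = abundant start terminal (25 genomic copies), paired with
  ## either a rare end (-> false positive) or an abundant end whose joined
  ## flank window is also abundant (-> nested true candidate)
  winA <- rndSeq(60); winB <- rndSeq(60)
  elem <- paste0(substr(winA, 31, 60), rndSeq(340),
                 substr(winB, 1, 30))
  ## plant: 25 copies of winA, 25 of winB, and the real occurrence where
  ## the element sits between the two outside half-windows
  occ <- paste0(substr(winA, 1, 30), elem, substr(winB, 31, 60))
  g <- genome(chr1 = paste0(
    rndSeq(200), paste0(replicate(24, paste0(winA, rndSeq(40))), collapse = ""),
    rndSeq(100), paste0(replicate(24, paste0(winB, rndSeq(40))), collapse = ""),
    rndSeq(100), occ, rndSeq(200)))
  gs <- as.character(g[[1]])
  st <- as.integer(regexpr(elem, gs, fixed = TRUE))
  en <- st + nchar(elem) - 1L
  mkCand <- function(name, st, en) CandidateSet(
    TELibrary(stats::setNames(
      Biostrings::DNAStringSet(substr(gs, st, en)), paste0(name, "#DNA/hAT"))),
    S4Vectors::DataFrame(seqId = "chr1", start = st, end = en,
                         leftFlank = substr(gs, st - 60, st - 1),
                         rightFlank = substr(gs, en + 1, en + 60),
                         corruption = NA_character_,
                         sourceEntry = NA_character_,
                         verdict = NA_character_))
  ## both termini abundant, unique target site -> nested true candidate
  out <- terminalCopyFilter(mkCand("nested", st, en), g)
  expect_equal(anchors(out)$verdict, "nested_true_candidate")
  ## one terminus abundant (start in winA, end in unique sequence) -> false
  out2 <- terminalCopyFilter(mkCand("half", st, en - 25L), g)
  expect_length(out2, 0)
  expect_equal(attr(out2, "removals")$detail, "false_positive")
  ## both termini unique -> true candidate
  out3 <- terminalCopyFilter(mkCand("uniq", st + 35L, en - 25L), g)
  expect_equal(anchors(out3)$verdict, "true_candidate")
  ## window beyond the contig -> kept as unevaluated, with a warning
  expect_warning(out4 <- terminalCopyFilter(mkCand("edge", 10L, 200L), g),
                 "window beyond contig")
  expect_equal(anchors(out4)$verdict, "unevaluated")
})

test_that("terminal SSR filter drops, trims and re-checks length", {
  set.seed(45)
  body <- paste0("G", rndSeq(289))
  l0 <- lib(`full#DNA/hAT` = paste0(strrep("AT", 10), rndSeq(300)),
            `trim#DNA/hAT` = paste0(strrep("A", 10), body),
            `inner#DNA/hAT` = paste0(rndSeq(100), strrep("AG", 12),
                                     rndSeq(100)),
            `tiny#DNA/hAT` = paste0(strrep("A", 10), rndSeq(75)))
  out <- ssrTerminalFilter(l0)
  expect_setequal(names(out), c("trim", "inner"))
  ## 20/20 SSR terminus dropped; 10-bp poly-A trimmed (290 bp left)
  expect_equal(unname(nchar(as.character(seqs(out)["trim"]))), 290)
  expect_equal(as.character(seqs(out)[["trim"]]), body)
  ## internal SSR only: untouched
  expect_equal(unname(nchar(as.character(seqs(out)["inner"]))), 224)
  rem <- attr(out, "removals")
  expect_equal(rem$rule[rem$entry == "full"], "ssr_terminal")
  expect_equal(rem$rule[rem$entry == "tiny"], "ssr_trim_short")
  ## boundary: exactly 15 of 20 bp SSR is tolerated, 16 is not
  w15 <- paste0(strrep("A", 15), "GCGTC")   # 15/20 SSR
  w16 <- paste0(strrep("A", 16), "GCGT")    # 16/20 SSR
  expect_equal(ssrSpan(w15), 15)
  expect_equal(ssrSpan(w16), 16)
  l15 <- lib(`k#DNA/hAT` = paste0(w15, rndSeq(200)))
  l16 <- lib(`d#DNA/hAT` = paste0(w16, rndSeq(200)))
  expect_length(ssrTerminalFilter(l15), 1)
  expect_length(ssrTerminalFilter(l16), 0)
})

test_that("richness purification removes cross-library contaminants reciprocally", {
  set.seed(46)
  fam <- rndSeq(400)
  relatives <- vapply(1:3, function(i) mutateSeq(fam, 0.05), "")
  tirs <- vapply(1:3, function(i) rndSeq(300), "")
  sublibs <- list(
    LTR = lib(`ltr0#LTR/Gypsy` = fam, `ltr1#LTR/Gypsy` = relatives[1],
              `ltr2#LTR/Gypsy` = relatives[2],
              `ltr3#LTR/Gypsy` = relatives[3]),
    TIR = lib(`dup#DNA/hAT` = fam, `t1#DNA/hAT` = tirs[1],
              `t2#DNA/hAT` = tirs[2], `t3#DNA/hAT` = tirs[3]))
  out <- richnessPurify(sublibs)
  ## the LTR exemplar duplicated into the TIR sublibrary is a contaminant
  expect_false("dup" %in% names(out$TIR))
  ## unrelated TIR entries and the true LTR family survive
  expect_setequal(names(out$TIR), c("t1", "t2", "t3"))
  expect_setequal(names(out$LTR), c("ltr0", "ltr1", "ltr2", "ltr3"))
  rem <- attr(out, "removals")
  expect_equal(rem$entry, "dup")
  expect_equal(rem$rule, "richness")

  ## equal richness in both sublibraries: removed from the target
  ## (1 < ratio * 1 with the default ratio 2)
  twin <- rndSeq(400)
  s2 <- list(LTR = lib(`c#LTR/Gypsy` = twin, `c2#LTR/Gypsy` = twin),
             TIR = lib(`d#DNA/hAT` = twin, `t#DNA/hAT` = rndSeq(300)))
  out2 <- richnessPurify(s2)
  expect_false("c" %in% names(out2$LTR))
  expect_false("d" %in% names(out2$TIR))
  ## zero cross-library homology: retained
  expect_true("t" %in% names(out2$TIR))
})

test_that("nested insertions are excised and redundancy removed within 5 rounds", {
  set.seed(47)
  X <- rndSeq(150); Y <- rndSeq(150); Z <- rndSeq(100); A <- rndSeq(120)
  l1 <- lib(`B#DNA/hAT` = paste0(X, A, Y), `A#DNA/hAT` = A)
  out1 <- removeNestedRedundancy(l1)
  expect_setequal(names(out1), c("A", "B"))
  expect_equal(as.character(seqs(out1)[["B"]]), paste0(X, Y))
  expect_lte(attr(out1, "iterations"), 5)

  ## doubly nested: both spans excised, converging in <= 2 iterations
  l2 <- lib(`B#DNA/hAT` = paste0(X, A, Z, A, Y), `A#DNA/hAT` = A)
  out2 <- removeNestedRedundancy(l2)
  expect_equal(as.character(seqs(out2)[["B"]]), paste0(X, Z, Y))
  expect_lte(attr(out2, "iterations"), 2)

  ## duplicate entries: one survivor, smaller name on ties
  q <- rndSeq(200)
  out3 <- removeNestedRedundancy(lib(`q2#LTR/Gypsy` = q,
                                     `q1#LTR/Gypsy` = q))
  expect_equal(names(out3), "q1")

  ## output is non-redundant under the 80-80-80 rule
  for (nm in names(out1))
    expect_false(matches808080(out1[nm], out1[setdiff(names(out1), nm)]))
})

test_that("CDS homology is excised and gene-only entries dropped", {
  set.seed(48)
  cdsSeq <- rndSeq(300)
  te1 <- rndSeq(200); te2 <- rndSeq(200)
  l0 <- lib(`mix#LTR/Gypsy` = paste0(te1, cdsSeq, te2),
            `gene#LTR/Gypsy` = cdsSeq,
            `clean#LTR/Gypsy` = rndSeq(400))
  cds <- Biostrings::DNAStringSet(c(cds1 = cdsSeq))
  out <- cdsFilter(l0, cds)
  expect_setequal(names(out), c("mix", "clean"))
  expect_equal(as.character(seqs(out)[["mix"]]), paste0(te1, te2))
  expect_equal(unname(nchar(as.character(seqs(out)["mix"]))), 400)
  ## no CDS supplied: identity
  out2 <- cdsFilter(l0, NULL)
  expect_identical(as.character(seqs(out2)), as.character(seqs(l0)))
})

test_that("the LTR sublibrary passes the stage-1 class filters unchanged", {
  sim <- corruptedSim()
  info0 <- libInfo(entries(sim$stage0$candidates))
  ltrIn <- sort(info0$name[info0$class == "LTR"])
  ## LTR entries are exempt from terminal-copy and SSR filtering; any LTR
  ## loss may come only from the aggregation filters (richness and
  ## redundancy), so the purified candidate set's LTR entries must be
  ## sequence-identical to their stage-0 versions
  cands1 <- entries(sim$stage1$candidates)
  info1 <- libInfo(cands1)
  ltrOut <- sort(info1$name[info1$class == "LTR"])
  expect_true(all(ltrOut %in% ltrIn))
  expect_identical(
    as.character(seqs(cands1)[ltrOut]),
    as.character(seqs(entries(sim$stage0$candidates))[ltrOut]))
})
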