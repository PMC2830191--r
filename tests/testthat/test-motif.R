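# Site windows, anchored motif matching and positional enrichment.

test_that("windows re-derive from full-length sequences and clip at
           termini", {
    # embed a published window in a longer sequence: the site sits at
    # position 11 + 4 of the padded sequence
    core <- "MVRVAINGFGRIGRLVMRIAL"
    seqFull <- paste0("AAAA", core, "AAAA")
    w <- extractWindow(seqFull, 15, residue = "R")
    expect_identical(paste(w, collapse = ""), core)
    expect_identical(names(w)[1], "-10")

    short <- "ABCDKFGHIJKL"
    w2 <- extractWindow(gsub("[BJ]", "A", short), 5)
    expect_identical(names(w2), as.character(-4:7))
    w3 <- extractWindow("KAAA", 1)
    expect_identical(names(w3), as.character(0:3))
    expect_error(extractWindow("KAAA", 1, residue = "R"), "mismatch")
})

test_that("anchored motif matching honours offsets and X wildcards", {
    tdh3 <- windowFromString("MVRVAINGFGRIGRLVMRIAL")
    expect_true(matchMotif(tdh3, "GXXRXG", center = 4))
    expect_true(matchMotif(tdh3, "RXG", center = 1))
    expect_false(matchMotif(tdh3, "RG", center = 1))
    ecm29 <- windowFromString("ARLFNIWGTVRTNRFDIIEES")
    expect_true(matchMotif(ecm29, "WXXXR", center = 5))
    allA <- windowFromString(paste0(strrep("A", 10), "K", strrep("A", 10)))
    expect_false(matchMotif(allA, "MK", center = 2))
    # offsets absent from a clipped window never match
    clipped <- extractWindow("KAAA", 1)
    expect_false(matchMotif(clipped, "MK", center = 2))
    expect_error(matchMotif(tdh3, paste0(strrep("X", 15), "R"),
                            center = 16), "beyond")
    expect_error(windowFromString("ABCD"), "odd")
})

test_that("exact binomial enrichment agrees with a direct-summation
           oracle", {
    # 5 of 7 windows with M at -1, background 0.021: tail probability
    # computed by explicit summation of the binomial pmf
    wins <- c(rep(list(windowFromString(paste0(strrep("A", 9), "MK",
                                               strrep("A", 10)))), 5),
              rep(list(windowFromString(paste0(strrep("A", 10), "K",
                                               strrep("A", 10)))), 2))
    bg <- stats::setNames(rep(0.05, 20),
                          strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]])
    bg["M"] <- 0.021
    bg <- bg / sum(bg)
    bgM <- 0.021
    oracle <- sum(choose(7, 5:7) * bgM^(5:7) * (1 - bgM)^(7 - (5:7)))
    expect_equal(oracle, 8.279132309312e-08, tolerance = 1e-10)
    bg2 <- bg; bg2["M"] <- bgM   # exact background for the tested letter
    enr <- positionalEnrichment(wins, bg2)
    got <- enr[enr$offset == -1 & enr$residue == "M", ]
    expect_equal(got$observed, 5L)
    expect_equal(got$nCovering, 7L)
    expect_equal(got$p, oracle, tolerance = 1e-12)
})

test_that("Bonferroni correction multiplies and caps at one", {
    wins <- rep(list(windowFromString(paste0(strrep("G", 10), "R",
                                             strrep("G", 10)))), 4)
    bg <- stats::setNames(rep(0.05, 20),
                          strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]])
    enr <- positionalEnrichment(wins, bg, nTests = 420)
    expect_true(all(enr$pBonferroni >= enr$p))
    expect_true(all(enr$pBonferroni <= 1))
    expect_equal(enr$pBonferroni,
                 pmin(1, enr$p * 420))
})

test_that("the null case is not significant and p is monotone in the
           observed count", {
    # observed proportion equal to background: tail p at least 0.5
    wins <- c(rep(list(windowFromString(paste0("A", strrep("G", 9), "R",
                                               strrep("G", 10)))), 5),
              rep(list(windowFromString(paste0("C", strrep("G", 9), "R",
                                               strrep("G", 10)))), 5))
    bg <- stats::setNames(rep(0.05, 20),
                          strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]])
    bg["A"] <- 0.5; bg["C"] <- 0.5
    bg <- bg / sum(bg)
    # use exact 0.5 background for A at the tested offset
    bgA <- stats::setNames(rep(0.001, 20), names(bg)); bgA["A"] <- 0.5
    enr <- positionalEnrichment(wins, bgA)
    expect_gte(enr$p[enr$offset == -10 & enr$residue == "A"], 0.5)
    # monotone in observed count at fixed n
    ps <- vapply(0:10, function(k)
        stats::pbinom(k - 1, 10, 0.3, lower.tail = FALSE), numeric(1))
    expect_true(all(diff(ps) <= 0))
})

test_that("family-wise error of corrected enrichment stays controlled
           on background windows", {
    set.seed(515)
    bg <- yeastResidueFrequencies()
    hits <- 0L
    nrep <- 60
    for (r in seq_len(nrep)) {
        wins <- lapply(1:8, function(i) {
            aa <- sample(names(bg), 21, replace = TRUE, prob = bg)
            aa[11] <- "K"
            stats::setNames(aa, as.character(-10:10))
        })
        enr <- positionalEnrichment(wins, bg)
        if (any(enr$pBonferroni < 0.05)) hits <- hits + 1L
    }
    expect_lte(hits / nrep, 0.05)
})

test_that("the packaged motif windows validate and every published
           window centre is its site residue", {
    tab <- motifWindowFixture()
    expect_true(all(nchar(tab$window) == 21L))
    expect_identical(substr(tab$window, 11, 11), tab$residue)
    expect_true(all(tab$degree %in% 1:2))
})
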