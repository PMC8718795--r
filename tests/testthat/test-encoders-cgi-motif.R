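test_that("CpG-island detection finds a planted CG run and computes OE", {
  set.seed(2)
  polyA <- strrep("A", 1000)
  run <- strrep("CG", 150)             # 300 bp of alternating CG
  s <- paste0(polyA, run, polyA)
  isl <- detect_cgis(s)
  expect_equal(nrow(isl), 1)
  expect_gte(isl$length, 300)
  # island must cover the run
  expect_lte(isl$start, 1001)
  expect_gte(isl$end, 1300)
  # direct formula on the pure run: 150 C, 150 G, 150 CG starts ->
  # OE = 150 * 300 / (150 * 150) = 2
  pure <- detect_cgis(run)
  expect_equal(nrow(pure), 1)
  expect_equal(pure$oe, 150 * 300 / (150 * 150))
  expect_equal(pure$gc_percent, 100)

  expect_equal(nrow(detect_cgis(strrep("A", 500))), 0)   # GC% = 0
  expect_equal(nrow(detect_cgis("ACGT")), 0)             # shorter than window
})

test_that("island coordinates are translation invariant", {
  set.seed(11)
  core <- paste(sample(c("C", "G", "A"), 400, TRUE,
                       prob = c(.45, .45, .1)), collapse = "")
  # identical flanking content, pads differing by exactly 1000 bp
  s1 <- paste0(strrep("A", 500), core, strrep("A", 500))
  s2 <- paste0(strrep("A", 1500), core, strrep("A", 500))
  isl1 <- detect_cgis(s1)
  expect_gt(nrow(isl1), 0)  # the CG-rich core must contain an island
  isl2 <- detect_cgis(s2)
  expect_equal(nrow(isl2), nrow(isl1))
  expect_equal(isl2$start, isl1$start + 1000)
  expect_equal(isl2$end, isl1$end + 1000)
  expect_equal(isl2$gc_percent, isl1$gc_percent)
  expect_equal(isl2$oe, isl1$oe)
})

test_that("CGI feature aggregation follows the report definition", {
  expect_equal(unname(cgi_features(detect_cgis(strrep("A", 500)), 500)),
               rep(0, 5))
  # one island ending at the 3' end -> distance 0
  one <- data.frame(start = 251, end = 500, length = 250,
                    gc_percent = 60, oe = 0.8, cpg_count = 30)
  f <- cgi_features(one, seq_length = 500)
  expect_equal(unname(f), c(1, 250, 0, 60, 0.8))
  # two islands: total length sums, means are arithmetic
  two <- rbind(one, data.frame(start = 1, end = 200, length = 200,
                               gc_percent = 70, oe = 1.0, cpg_count = 40))
  f2 <- cgi_features(two, seq_length = 500)
  expect_equal(unname(f2),
               c(2, 450, mean(c(0, 300)), mean(c(60, 70)),
                 mean(c(0.8, 1.0))))
})

test_that("motif scan finds exact and degenerate matches on both strands", {
  lib <- structure(data.frame(name = c("GBOX", "DEGEN"),
                              consensus = c("CACGTG", "CACGTK"),
                              stringsAsFactors = FALSE),
                   class = c("motif_library", "data.frame"))
  set.seed(21)
  bg <- paste(sample(c("A", "T"), 400, TRUE), collapse = "")  # AT-rich
  s <- paste0(substr(bg, 1, 100), "CACGTG", substr(bg, 107, 250),
              "CACGTT", substr(bg, 257, 400))
  # uniform background; exact p of a perfect 6-mer match is ~2.4e-4, so a
  # scan for short motifs needs a threshold above that
  hits <- motif_scan(c(p1 = s), lib, p_threshold = 1e-3,
                     background = c(A = .25, C = .25, G = .25, T = .25))
  gb <- hits[hits$motif == "GBOX", ]
  expect_gte(nrow(gb), 1)
  expect_true(101 %in% gb$start)
  # palindrome: the site matches its own reverse complement once, not twice
  expect_equal(sum(gb$start == 101), 1)
  expect_equal(gb$strand[gb$start == 101], "+")
  # degenerate K = G|T: both planted words hit
  dg <- hits[hits$motif == "DEGEN" & hits$strand == "+", ]
  expect_true(all(c(101, 251) %in% dg$start))
  # oracle: regex expansion of the IUPAC string agrees on + strand sites
  rx_sites <- gregexpr("CACGT[GT]", s)[[1]]
  expect_true(all(as.integer(rx_sites) %in% dg$start))
})

test_that("motif scan respects sequence bounds and empty input", {
  lib <- structure(data.frame(name = "LONG",
                              consensus = strrep("ACGT", 10)),
                   class = c("motif_library", "data.frame"))
  hits <- motif_scan(c(x = "ACGTACGT"), lib, p_threshold = 0.5)
  expect_equal(nrow(hits), 0)          # motif longer than sequence
})

test_that("motif features follow the 4-per-motif definitions", {
  lib <- structure(data.frame(name = c("M1", "M2"),
                              consensus = c("AAAAAA", "CCCCCC")),
                   class = c("motif_library", "data.frame"))
  hits <- data.frame(
    seq_id = c("s1", "s1"), motif = "M1",
    start = c(1201, 1401), end = c(1206, 1406),
    strand = c("+", "+"), score = c(4, 6), p_value = 1e-5)
  f <- motif_features(hits, lib, "s1", c(s1 = 1500))
  expect_equal(unname(f[1, "M1_number"]), 2)
  expect_equal(unname(f[1, "M1_conserve"]), (4 + 6) / 2)
  expect_equal(unname(f[1, "M1_orientation"]), 1.0)  # both + strand
  # hits at 1201 and 1401 of a 1500-bp promoter: distances 300 and 100
  expect_equal(unname(f[1, "M1_dis"]), 200)
  # absent motif -> all-zero block
  expect_equal(unname(f[1, c("M2_number", "M2_conserve",
                             "M2_orientation", "M2_dis")]), rep(0, 4))
  expect_equal(ncol(f), 4 * nrow(lib))

  # mixed strand: orientation is the + fraction
  hits2 <- hits; hits2$strand <- c("+", "-")
  f2 <- motif_features(hits2, lib, "s1", c(s1 = 1500))
  expect_equal(unname(f2[1, "M1_orientation"]), 0.5)
})

test_that("bundled motif library is valid IUPAC", {
  lib <- read_motif_library()
  expect_s3_class(lib, "motif_library")
  expect_gte(nrow(lib), 30)
  expect_true(all(grepl("^[ACGTRYSWKMBDHVN]+$", lib$consensus)))
})
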