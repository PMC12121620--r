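writeTblout <- function(rows, path = tempfile(fileext = ".tblout")) {
  writeLines(c("# cmscan tblout", rows, "#"), path)
  path
}

tblRow <- function(family, contig, from, to, strand, score = 50.1,
                   evalue = 1e-9) {
  paste(family, "-", contig, "-", "cm", 1, 100, from, to, strand, "no", 1,
        0.45, 0.0, score, evalue, "!", "-")
}

test_that("cmscan tblout hits convert to 0-based half-open loci", {
  path <- writeTblout(c(tblRow("TPP", "c1", 100, 250, "+"),
                        tblRow("FMN", "c1", 250, 100, "-"),
                        tblRow("TPP", "c2", 500, 700, "+")))
  loci <- parseCmscanTblout(path)
  expect_equal(nrow(loci), 3L)
  expect_equal(loci$source_start, c(99, 99, 499))
  expect_equal(loci$source_end, c(250, 250, 700))
  expect_equal(loci$strand, c("+", "-", "+"))
  expect_equal(loci$family, c("TPP", "FMN", "TPP"))
  expect_false(anyDuplicated(loci$locus_id) > 0)
  expect_true(all(loci$source_start < loci$source_end))
})

test_that("malformed tblout lines are reported with their line number", {
  path <- writeTblout(c(tblRow("TPP", "c1", 100, 250, "+"), "TPP broken"))
  expect_error(parseCmscanTblout(path), "line 3")
  path2 <- writeTblout(character(0))
  expect_warning(loci <- parseCmscanTblout(path2), "no hits")
  expect_equal(nrow(loci), 0L)
})

test_that("locus tables round trip through the fixture writer", {
  spec <- simulationSpec(seed = 5)
  dir <- tempfile()
  sim <- simulateDataset(spec, dir)
  reread <- readLocusTable(file.path(dir, "loci.tsv"))
  expect_equal(reread$locus_id, sim$loci$locus_id)
  expect_equal(reread$source_start, sim$loci$source_start)
  expect_equal(reread$strand, sim$loci$strand)
})

test_that("downstream ORF is the first same-strand ORF past the 5' end", {
  locus <- list(locus_id = "l1", contig_id = "c1", source_start = 100,
                source_end = 200, strand = "+")
  orfs <- data.frame(orf_id = c("o1", "o2", "o3"),
                     contig_id = "c1",
                     start = c(150, 500, 20), end = c(400, 800, 90),
                     strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  # overlap with the riboswitch is allowed
  expect_equal(assignDownstreamOrf(locus, orfs)$orf_id, "o1")

  minusLocus <- list(locus_id = "l2", contig_id = "c1", source_start = 100,
                     source_end = 200, strand = "-")
  minusOrfs <- data.frame(orf_id = "m1", contig_id = "c1", start = 20,
                          end = 90, strand = "-", stringsAsFactors = FALSE)
  expect_equal(assignDownstreamOrf(minusLocus, minusOrfs)$orf_id, "m1")

  expect_null(assignDownstreamOrf(locus, minusOrfs))
})

test_that("ORF assignment is invariant under coordinate mirroring", {
  set.seed(42)
  L <- 10000L
  for (rep in 1:25) {
    s <- sample(1000:8000, 1L)
    locus <- list(locus_id = "l", contig_id = "c", source_start = s,
                  source_end = s + 150L, strand = "+")
    orfs <- data.frame(
      orf_id = sprintf("o%d", 1:6), contig_id = "c",
      start = sample(0:(L - 500L), 6L), strand = sample(c("+", "-"), 6L,
                                                        replace = TRUE),
      stringsAsFactors = FALSE)
    orfs$end <- orfs$start + sample(100:400, 6L)
    hit <- assignDownstreamOrf(locus, orfs)

    mirrorLocus <- list(locus_id = "l", contig_id = "c",
                        source_start = L - locus$source_end,
                        source_end = L - locus$source_start, strand = "-")
    mirrorOrfs <- data.frame(
      orf_id = orfs$orf_id, contig_id = "c", start = L - orfs$end,
      end = L - orfs$start,
      strand = ifelse(orfs$strand == "+", "-", "+"),
      stringsAsFactors = FALSE)
    mirrorHit <- assignDownstreamOrf(mirrorLocus, mirrorOrfs)
    if (is.null(hit)) expect_null(mirrorHit)
    else expect_equal(mirrorHit$orf_id, hit$orf_id)
  }
})

test_that("reference windows trim, clip and reverse complement correctly", {
  set.seed(7)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  locus <- list(locus_id = "plus", contig_id = "c", source_start = 1500,
                source_end = 1600, strand = "+", family = "TPP")
  w <- buildReferenceWindow(locus, contig, flank = 1000)
  expect_equal(w@windowStartOnContig, 500L)
  expect_equal(length(w@sequence), 2100L)
  expect_equal(c(w@riboswitchStart, w@riboswitchEnd), c(1000L, 1100L))
  expect_equal(as.character(w@sequence), substr(contig, 501, 2600))

  # upstream flank clipped at the contig start -> asymmetric window
  nearEnd <- list(locus_id = "edge", contig_id = "c", source_start = 300,
                  source_end = 400, strand = "+", family = "TPP")
  we <- buildReferenceWindow(nearEnd, contig, flank = 1000)
  expect_equal(we@windowStartOnContig, 0L)
  expect_equal(we@riboswitchStart, 300L)
  expect_equal(length(we@sequence), 1400L)

  minus <- list(locus_id = "minus", contig_id = "c", source_start = 1500,
                source_end = 1600, strand = "-", family = "TPP")
  wm <- buildReferenceWindow(minus, contig, flank = 1000)
  expect_true(wm@wasReverseComplemented)
  expect_equal(as.character(wm@sequence),
               revCompOracle(substr(contig, 501, 2600)))
  expect_equal(c(wm@riboswitchStart, wm@riboswitchEnd), c(1000L, 1100L))

  outOfBounds <- list(locus_id = "bad", contig_id = "c",
                      source_start = 9900, source_end = 10100, strand = "+",
                      family = "TPP")
  expect_error(buildReferenceWindow(outOfBounds, contig), "bad")
})

test_that("riboswitch subsequence round trips through the window", {
  set.seed(11)
  contig <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                  collapse = "")
  for (strand in c("+", "-")) {
    for (rep in 1:10) {
      s <- sample(0:4800, 1L)
      e <- s + sample(60:180, 1L)
      if (e > 5000) next
      locus <- list(locus_id = paste0("l", strand, rep), contig_id = "c",
                    source_start = s, source_end = e, strand = strand,
                    family = "x")
      w <- buildReferenceWindow(locus, contig, flank = 700)
      got <- as.character(Biostrings::subseq(w@sequence,
                                             w@riboswitchStart + 1L,
                                             w@riboswitchEnd))
      onContig <- substr(contig, s + 1, e)
      want <- if (strand == "-") revCompOracle(onContig) else onContig
      expect_equal(got, want)
      expect_lte(length(w@sequence), (e - s) + 2L * 700L)
    }
  }
})

test_that("reference windows survive a write/read cycle", {
  set.seed(3)
  contig <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = "")
  loci <- data.frame(locus_id = c("a", "b"), contig_id = "c",
                     family = c("TPP", "FMN"),
                     source_start = c(1200, 2500), source_end = c(1350, 2650),
                     strand = c("+", "-"), model_score = NA_real_,
                     e_value = NA_real_, stringsAsFactors = FALSE)
  windows <- buildReferenceWindows(loci, c(c = contig), flank = 500)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeReferenceWindows(windows, fa, tsv)
  back <- readReferenceWindows(fa, tsv)
  expect_equal(names(back), names(windows))
  for (id in names(windows)) {
    expect_equal(as.character(back[[id]]@sequence),
                 as.character(windows[[id]]@sequence))
    expect_equal(back[[id]]@riboswitchStart, windows[[id]]@riboswitchStart)
    expect_equal(back[[id]]@wasReverseComplemented,
                 windows[[id]]@wasReverseComplemented)
  }
})

test_that("Prodigal FASTA headers parse to 0-based ORF records", {
  path <- tempfile(fileext = ".faa")
  writeLines(c(">c1_1 # 3 # 98 # 1 # ID=1_1;partial=00", "MKL",
               ">c1_2 # 120 # 320 # -1 # ID=1_2;partial=00", "MSA"), path)
  orfs <- parseProdigalFastaHeaders(path)
  expect_equal(orfs$start, c(2L, 119L))
  expect_equal(orfs$end, c(98L, 320L))
  expect_equal(orfs$strand, c("+", "-"))
  expect_equal(orfs$contig_id, c("c1", "c1"))
})
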