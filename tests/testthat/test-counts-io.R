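toy_aln <- function() {
  pomo_counts(list(
    popA = rbind(c(3L, 0L, 7L, 0L), c(10L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L)),
    popB = rbind(c(0L, 5L, 0L, 5L), c(9L, 1L, 0L, 0L), c(0L, 0L, 10L, 0L))),
    chrom = c("chr1", "chr1", "chr2"), pos = c(11L, 12L, 3L))
}

test_that("counts files round-trip bit-identically", {
  aln <- toy_aln()
  f <- withr::local_tempfile(fileext = ".cf")
  write_counts(aln, f)
  back <- read_counts(f)
  expect_equal(back$counts, aln$counts)
  expect_equal(back$populations, aln$populations)
  expect_equal(back$chrom, aln$chrom)
  expect_equal(back$pos, aln$pos)
  # a second write of the re-read alignment is byte-identical
  f2 <- withr::local_tempfile(fileext = ".cf")
  write_counts(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("cells parse to observations; all-zero means missing", {
  f <- withr::local_tempfile(fileext = ".cf")
  writeLines(c("COUNTSFILE NPOP 2 NSITES 2",
               "CHROM\tPOS\tx\ty",
               "chr1\t1\t3,0,7,0\t0,0,0,0",
               "chr1\t2\t1,1,1,0\t2,0,0,0"), f)
  aln <- read_counts(f)
  expect_equal(aln$counts$x[1, ], c(A = 3L, C = 0L, G = 7L, T = 0L))
  expect_equal(sum(aln$counts$y[1, ]), 0L)   # missing, not an error
  # the triallelic cell parses; rejection happens at likelihood init
  expect_equal(aln$counts$x[2, ], c(A = 1L, C = 1L, G = 1L, T = 0L))
  expect_error(leaf_likelihood(aln$counts$x[2, ], pomo_states(10)),
               "segregating")
})

test_that("malformed counts files produce located parse errors", {
  f <- withr::local_tempfile(fileext = ".cf")
  writeLines(c("NOTCOUNTS 2 3", "CHROM POS a b"), f)
  expect_error(read_counts(f), "header")
  writeLines(c("COUNTSFILE NPOP 2 NSITES 1",
               "CHROM\tPOS\ta\tb",
               "chr1\t1\t1,0,0,0"), f)
  expect_error(read_counts(f), "line 3")
  writeLines(c("COUNTSFILE NPOP 1 NSITES 1",
               "CHROM\tPOS\ta",
               "chr1\t1\t1,x,0,0"), f)
  expect_error(read_counts(f), "line 3")
  writeLines(c("COUNTSFILE NPOP 1 NSITES 5",
               "CHROM\tPOS\ta",
               "chr1\t1\t1,0,0,0"), f)
  expect_warning(read_counts(f), "NSITES")
})

test_that("large alignments survive a write/read round trip", {
  set.seed(9)
  n <- 1e5
  aln <- pomo_counts(list(
    p1 = cbind(sample(0:10, n, TRUE), sample(0:3, n, TRUE), 0L, 0L),
    p2 = cbind(0L, 0L, sample(0:10, n, TRUE), sample(0:2, n, TRUE))))
  f <- withr::local_tempfile(fileext = ".cf")
  write_counts(aln, f)
  expect_equal(read_counts(f)$counts, aln$counts)
})

test_that("empty alignments write a header-only file", {
  aln <- pomo_counts(list(a = matrix(integer(0), 0, 4)))
  f <- withr::local_tempfile(fileext = ".cf")
  write_counts(aln, f)
  lines <- readLines(f)
  expect_equal(lines[1], "COUNTSFILE NPOP 1 NSITES 0")
  expect_length(lines, 2)
})

test_that("FASTA alignments convert to per-population counts", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ind1", "AACR", ">ind2", "ACC-"), fa)
  fb <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ind1", "GG--", ">ind2", "GT--"), fb)
  aln <- fasta_to_counts(c(p1 = fa, p2 = fb))
  expect_equal(aln$counts$p1[1, ], c(A = 2L, C = 0L, G = 0L, T = 0L))
  expect_equal(aln$counts$p1[2, ], c(A = 1L, C = 1L, G = 0L, T = 0L))
  # IUPAC ambiguity (R) and gaps contribute nothing
  expect_equal(aln$counts$p1[4, ], c(A = 0L, C = 0L, G = 0L, T = 0L))
  expect_equal(aln$counts$p2[2, ], c(A = 0L, C = 0L, G = 1L, T = 1L))
  # all-gap column is a missing observation
  expect_equal(sum(aln$counts$p2[3, ]), 0L)
  # length mismatch across populations errors
  fc <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">i", "AAAAA"), fc)
  expect_error(fasta_to_counts(c(p1 = fa, p3 = fc)), "length")
})

test_that("Newick IO round-trips and flags defects", {
  tr <- read_newick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))
  # fuzz round trip on random trees
  set.seed(21)
  for (rep in 1:10) {
    t0 <- ape::rtree(sample(3:12, 1))
    s <- write_newick(t0)
    t1 <- read_newick(s)
    expect_equal(write_newick(t1), s)
    expect_equal(brute_force_splits(t1), brute_force_splits(t0),
                 tolerance = 1e-10)
  }
  expect_warning(read_newick("(A:1,(B,C):0.5);"), "branch length")
  suppressWarnings(
    expect_error(read_newick(withr::local_tempfile(fileext = ".nwk"))))
})
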