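# fragment model, VCF/SAM extraction, barcode merging, fragment-file IO

test_that("heterozygous SNPs are filtered, renumbered and dosed from a VCF", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
    pos = c(100L, 250L, 300L, 410L, 500L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "T"),
    gt  = c("0/0/1", "1/1/1", "0/1/1", "0/0/0", "0/1/0"))
  v <- load_heterozygous_variants(vcf, ploidy = 3)
  expect_identical(v$index, 1:3)                 # renumbered in position order
  expect_identical(v$pos, c(100L, 300L, 500L))   # hom sites dropped
  expect_identical(v$dosage, c(1L, 2L, 1L))
})

test_that("VCF loader rejects ploidy mismatches and skips indels", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
    pos = 100L, ref = "A", alt = "G", gt = "0/1")
  expect_error(load_heterozygous_variants(vcf, ploidy = 3), "arity")
  vcf2 <- write_test_vcf(tempfile(fileext = ".vcf"),
    pos = c(100L, 200L), ref = c("A", "AT"), alt = c("G", "A"),
    gt = c("0/0/1", "0/0/1"))
  v <- load_heterozygous_variants(vcf2, ploidy = 3)
  expect_identical(v$pos, 100L)                  # indel skipped
})

test_that("read extraction codes alleles, filters and merges mates", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
    pos = c(1000L, 1010L, 1500L, 2000L, 2040L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G"),
    gt  = rep("0/0/1", 5))
  v <- load_heterozygous_variants(vcf, ploidy = 3)
  mk <- function(pos, len, at, base) {           # read with controlled bases
    seq <- rep("C", len)
    for (k in seq_along(at)) seq[at[k] - pos + 1L] <- base[k]
    paste(seq, collapse = "")
  }
  reads <- list(
    # spans SNPs at 1000 (alt G) and 1010 (ref C): calls (1,1),(2,0)
    list(qname = "r1", pos = 990L,
         seq = mk(990L, 40L, c(1000L, 1010L), c("G", "C"))),
    # covers one SNP, unbarcoded: dropped
    list(qname = "r2", pos = 1495L,
         seq = mk(1495L, 20L, 1500L, "G")),
    # mate pair: {1000,1010} and {2000} merged into one 3-call fragment
    list(qname = "r3", pos = 995L,
         seq = mk(995L, 30L, c(1000L, 1010L), c("A", "T"))),
    list(qname = "r3", pos = 1995L,
         seq = mk(1995L, 20L, 2000L, "C")),
    # base matching neither ref nor alt at 2040 is skipped
    list(qname = "r4", pos = 2035L,
         seq = mk(2035L, 20L, c(2040L, 2040L), c("T", "T"))),
    # secondary alignment: ignored with a counter
    list(qname = "r5", pos = 990L, flag = 256L,
         seq = mk(990L, 40L, c(1000L, 1010L), c("G", "C"))))
  sam <- write_test_sam(tempfile(fileext = ".sam"), reads)
  fr <- extract_read_fragments(sam, v)
  expect_identical(attr(fr, "skipped"), 1L)
  ids <- vapply(fr, `[[`, character(1), "id")
  expect_setequal(ids, c("r1", "r3"))
  f1 <- fr[[match("r1", ids)]]
  expect_identical(f1$idx, c(1L, 2L))
  expect_identical(f1$allele, c(1L, 0L))
  f3 <- fr[[match("r3", ids)]]
  expect_identical(f3$idx, c(1L, 2L, 4L))
  expect_identical(f3$allele, c(0L, 1L, 1L))
})

test_that("barcoded single-SNP reads survive until after barcode merging", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
    pos = c(1000L, 5000L), ref = c("A", "C"), alt = c("G", "T"),
    gt = rep("0/0/1", 2))
  v <- load_heterozygous_variants(vcf, ploidy = 3)
  reads <- list(
    list(qname = "a", pos = 995L, seq = strrep("A", 20L), bx = "ACGT"),
    list(qname = "b", pos = 4995L, seq = strrep("T", 20L), bx = "ACGT"))
  sam <- write_test_sam(tempfile(fileext = ".sam"), reads)
  fr <- extract_read_fragments(sam, v)
  expect_length(fr, 2L)                          # kept, each 1 call
  merged <- merge_by_barcode(fr)
  expect_length(merged, 1L)
  expect_identical(merged[[1L]]$idx, c(1L, 2L))
  # strict ordering drops them before the merge instead
  expect_length(extract_read_fragments(sam, v, strict_two_snp = TRUE), 0L)
})

test_that("barcode merging unites calls and resolves conflicts by quality", {
  f1 <- frag("a", c(2L), 0L, 30L, barcode = "B1")
  f2 <- frag("b", c(5L, 6L), c(1L, 0L), 30L, barcode = "B1")
  m <- merge_by_barcode(list(f1, f2))
  expect_length(m, 1L)
  expect_identical(m[[1L]]$idx, c(2L, 5L, 6L))
  expect_identical(m[[1L]]$origin, "barcode")

  # higher quality wins
  g1 <- frag("a", c(4L, 9L), c(0L, 1L), c(20L, 30L), barcode = "B1")
  g2 <- frag("b", c(4L, 8L), c(1L, 0L), c(35L, 30L), barcode = "B1")
  m <- merge_by_barcode(list(g1, g2))[[1L]]
  expect_identical(m$allele[m$idx == 4L], 1L)
  expect_identical(m$qual[m$idx == 4L], 35L)

  # equal-quality conflict drops the site entirely
  h1 <- frag("a", c(4L, 9L), c(0L, 1L), 30L, barcode = "B1")
  h2 <- frag("b", c(4L, 8L), c(1L, 0L), 30L, barcode = "B1")
  m <- merge_by_barcode(list(h1, h2))[[1L]]
  expect_false(4L %in% m$idx)
  expect_identical(m$idx, c(8L, 9L))
})

test_that("barcode merging is idempotent, order-independent, non-inventing", {
  set.seed(42)
  for (rep in 1:20) {
    fl <- lapply(1:6, function(i)
      random_fragment(paste0("f", i), M = 15L,
                      barcode = sample(c("B1", "B2"), 1L)))
    m1 <- merge_by_barcode(fl)
    m2 <- merge_by_barcode(rev(fl))
    key <- function(x) x[order(vapply(x, `[[`, character(1), "id"))]
    expect_identical(key(m1), key(m2))
    expect_identical(key(merge_by_barcode(m1)), key(m1))   # idempotent
    # no invented calls: every merged (idx, allele) pair appears in input
    inp <- unique(do.call(rbind, lapply(fl, function(f)
      cbind(f$idx, f$allele))))
    for (f in m1) {
      out <- cbind(f$idx, f$allele)
      expect_true(all(apply(out, 1L, function(r)
        any(inp[, 1L] == r[1L] & inp[, 2L] == r[2L]))))
    }
    expect_true(all(fragment_sizes(m1) >= 2L))
  }
})

test_that("fragment files round-trip on all four dialects", {
  set.seed(7)
  for (dialect in c("short_read", "barcoded", "barcode_specific",
                    "molecule_specific")) {
    origin <- switch(dialect, short_read = "read", barcoded = "read",
                     barcode_specific = "barcode",
                     molecule_specific = "molecule")
    for (rep in 1:10) {
      fl <- lapply(1:5, function(i)
        random_fragment(paste0("fr", i), M = 40L, origin = origin,
                        barcode = if (dialect == "short_read")
                          NA_character_ else paste0("BC", i),
                        ordinal = if (dialect == "molecule_specific")
                          sample(3L, 1L) else NA_integer_))
      path <- tempfile()
      write_fragment_file(fl, path, dialect)
      back <- read_fragment_file(path, dialect)
      expect_length(back, length(fl))
      for (i in seq_along(fl)) expect_same_fragment(back[[i]], fl[[i]])
      # write(read(.)) is byte-identical
      path2 <- tempfile()
      write_fragment_file(back, path2, dialect)
      expect_identical(readLines(path2), readLines(path))
    }
  }
})

test_that("fragment-file layout groups consecutive indices into parts", {
  f <- frag("x", c(3L, 4L, 9L), c(0L, 1L, 0L), c(30L, 31L, 32L))
  path <- tempfile()
  write_fragment_file(list(f), path, "short_read")
  tok <- strsplit(readLines(path), " ")[[1L]]
  expect_identical(tok[1:6], c("2", "x", "3", "01", "9", "0"))
  expect_identical(utf8ToInt(tok[7L]) - 33L, c(30L, 31L, 32L))

  # molecule naming: barcode and ordinal joined by an underscore
  fm <- frag("m", c(1L, 2L), c(0L, 1L), origin = "molecule",
             barcode = "ACGT", ordinal = 2L)
  write_fragment_file(list(fm), path, "molecule_specific")
  expect_identical(strsplit(readLines(path), " ")[[1L]][3L], "ACGT_2")
  back <- read_fragment_file(path, "molecule_specific")[[1L]]
  expect_identical(back$barcode, "ACGT")
  expect_identical(back$ordinal, 2L)
})

test_that("fragment files: empty list and malformed lines", {
  path <- tempfile()
  write_fragment_file(list(), path, "barcoded")
  expect_length(read_fragment_file(path, "barcoded"), 0L)

  writeLines("2 id BC 3 01 II", path)            # says 2 parts, has 1
  expect_error(read_fragment_file(path, "barcoded"), "line 1")
  writeLines("1 id BC 3 011 II", path)           # 3 alleles, 2 qualities
  expect_error(read_fragment_file(path, "barcoded"), "quality")
})
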