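test_that("read_sumstats derives z, drops invalid rows and counts them", {
  df <- data.frame(
    SNP = c("rs1", "rs2", "rs123", "rs123", "rs4"),
    CHR = "1", BP = c(100L, 200L, 300L, 400L, 500L),
    A1 = c("A", "I", "A", "A", "C"),
    A2 = c("G", "D", "G", "G", "T"),
    BETA = c(0.1, 0.2, 0.05, 0.05, -0.02),
    SE = c(0.05, 0.05, 0.05, 0.05, 0.01),
    N = 10000, stringsAsFactors = FALSE
  )
  path <- write_toy_sumstats(df)
  ss <- read_sumstats(path, verbose = FALSE)
  rep <- munge_report(ss)

  expect_equal(ss$snp_id, c("rs1", "rs4"))
  expect_equal(ss$z[1], 0.1 / 0.05) # z = beta / se
  expect_equal(unname(rep$dropped["non_snp_alleles"]), 1L)
  expect_equal(unname(rep$dropped["duplicate_snp_id"]), 2L)
  expect_equal(rep$read, rep$kept + sum(rep$dropped))
  # p derived from z when absent
  expect_equal(ss$p, 2 * pnorm(-abs(ss$z)))
})

test_that("rows with z inconsistent with beta/se or with p are dropped", {
  df <- toy_sumstats_df(4)
  df$BETA <- df$Z * 0.01
  df$SE <- 0.01
  df$BETA[2] <- df$BETA[2] + 1 # disagrees with Z
  df$P[3] <- df$P[3] + 0.01    # disagrees with Z
  ss <- read_sumstats(write_toy_sumstats(df), verbose = FALSE)
  rep <- munge_report(ss)
  expect_equal(ss$snp_id, df$SNP[c(1, 4)])
  expect_equal(unname(rep$dropped["inconsistent_effect"]), 1L)
  expect_equal(unname(rep$dropped["p_z_mismatch"]), 1L)
})

test_that("underflowed p-values are clipped to the smallest positive double", {
  df <- toy_sumstats_df(2)
  df$Z <- c(50, 1)
  df$P <- c(0, 2 * pnorm(-1))
  ss <- read_sumstats(write_toy_sumstats(df), verbose = FALSE)
  expect_true(all(ss$p > 0))
  expect_equal(nrow(ss), 2L)
})

test_that("unreadable files, missing columns and empty survivors are fatal", {
  expect_error(read_sumstats(tempfile()), "does not exist")
  df <- toy_sumstats_df(3)
  df$A1 <- NULL
  expect_error(read_sumstats(write_toy_sumstats(df), verbose = FALSE),
               "A1")
  df2 <- toy_sumstats_df(2)
  df2$Z <- NULL
  df2$P <- NULL
  expect_error(read_sumstats(write_toy_sumstats(df2), verbose = FALSE),
               "effect")
  df3 <- toy_sumstats_df(2)
  df3$A1 <- "I" # every row invalid
  expect_error(read_sumstats(write_toy_sumstats(df3), verbose = FALSE),
               "no rows")
})

test_that("gzipped summary statistics are read transparently", {
  df <- toy_sumstats_df(10)
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  utils::write.table(df, con, quote = FALSE, sep = "\t", row.names = FALSE)
  close(con)
  ss <- read_sumstats(path, verbose = FALSE)
  expect_equal(nrow(ss), 10L)
  expect_equal(ss$z, df$Z)
})

test_that("filter_to_reference keeps order, handles supersets and fails on disjoint lists", {
  ss <- read_sumstats(write_toy_sumstats(toy_sumstats_df(10)), verbose = FALSE)
  sub <- filter_to_reference(ss, c("rs2", "rs5", "rs7", "rs9"))
  expect_equal(sub$snp_id, c("rs2", "rs5", "rs7", "rs9"))
  expect_equal(filter_to_reference(ss, paste0("rs", 1:50))$snp_id, ss$snp_id)
  expect_error(filter_to_reference(ss, c("rs99", "rs100")), "no overlap")
  expect_error(filter_to_reference(ss, character(0)), "empty")
})

test_that("drop_strand_ambiguous removes exactly the A/T and C/G variants", {
  df <- toy_sumstats_df(6)
  df$A1 <- c("A", "A", "C", "G", "T", "C")
  df$A2 <- c("T", "G", "G", "C", "C", "A")
  ss <- read_sumstats(write_toy_sumstats(df), verbose = FALSE)
  kept <- suppressMessages(drop_strand_ambiguous(ss))
  expect_equal(kept$snp_id, c("rs2", "rs5", "rs6")) # A/T, C/G, G/C removed
})

test_that("align_pair flips swapped alleles, drops mismatches and sorts by position", {
  a <- read_sumstats(write_toy_sumstats(toy_sumstats_df(4)), verbose = FALSE)
  bdf <- toy_sumstats_df(4)
  bdf$A1 <- c("G", "A", "A", "A") # rs1 swapped, rs3 mismatched
  bdf$A2 <- c("A", "G", "C", "G")
  b <- read_sumstats(write_toy_sumstats(bdf), verbose = FALSE)
  pa <- align_pair(a, b)
  expect_equal(pa$snp_id, c("rs1", "rs2", "rs4"))
  expect_equal(pa$z2[pa$snp_id == "rs1"], -b$z[b$snp_id == "rs1"])
  expect_equal(pa$z2[pa$snp_id == "rs2"], b$z[b$snp_id == "rs2"])
  expect_equal(attr(pa, "align_report")$n_allele_mismatch, 1L)
  expect_equal(pa$a1, a$a1[match(pa$snp_id, a$snp_id)])
})

test_that("align_pair is symmetric up to relabelling and idempotent", {
  set.seed(42)
  a <- read_sumstats(write_toy_sumstats(toy_sumstats_df(20, seed = 1)),
                     verbose = FALSE)
  bdf <- toy_sumstats_df(20, seed = 2)
  swap <- seq(1, 20, by = 3)
  bdf$A1[swap] <- "G"; bdf$A2[swap] <- "A"
  b <- read_sumstats(write_toy_sumstats(bdf), verbose = FALSE)

  ab <- align_pair(a, b)
  ba <- align_pair(b, a)
  expect_setequal(ab$snp_id, ba$snp_id)
  m <- match(ab$snp_id, ba$snp_id)
  expect_equal(abs(ab$z1), abs(ba$z2[m]))
  expect_equal(abs(ab$z2), abs(ba$z1[m]))

  # re-aligning an aligned pair is the identity
  to_ss <- function(pa, which) {
    pairgwas:::new_sumstats(data.frame(
      snp_id = pa$snp_id, chrom = pa$chrom, bp = pa$bp,
      a1 = pa$a1, a2 = pa$a2,
      z = if (which == 1) pa$z1 else pa$z2,
      p = if (which == 1) pa$p1 else pa$p2,
      n = if (which == 1) pa$n1 else pa$n2,
      stringsAsFactors = FALSE
    ))
  }
  again <- align_pair(to_ss(ab, 1), to_ss(ab, 2))
  expect_equal(again$z1, ab$z1)
  expect_equal(again$z2, ab$z2)
  expect_equal(again$snp_id, ab$snp_id)
})

test_that("write_sumstats emits the munged z-score layout readable by read_sumstats", {
  ss <- read_sumstats(write_toy_sumstats(toy_sumstats_df(8)), verbose = FALSE)
  out <- tempfile(fileext = ".sumstats")
  write_sumstats(ss, out)
  back <- read_sumstats(out, dialect = "auto", verbose = FALSE)
  expect_equal(back$snp_id, ss$snp_id)
  expect_equal(back$z, ss$z, tolerance = 1e-12)
  header <- strsplit(readLines(out, n = 1), "\t")[[1]]
  expect_true(all(c("SNP", "A1", "A2", "Z", "N") %in% header))
})
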