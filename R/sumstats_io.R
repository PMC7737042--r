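# Reading, validating and harmonising GWAS summary statistics.
#
# The currency of every downstream stage is a validated per-variant table
# ("sumstats"): snp_id, alleles, signed z-score, sample size and (where
# available) chromosome/position, beta/se and p. Rows violating the record
# invariants are dropped and counted in a munge report rather than silently
# repaired.

ACGT <- c("A", "C", "G", "T")

#' Built-in summary-statistics column dialects
#'
#' Column-name mappings from canonical field names to the column headers found
#' in common summary-statistics layouts: `"ldsc"` is the munged
#' `SNP A1 A2 Z N` layout, `"generic"` a typical raw GWAS export with
#' beta/se/p, and `"auto"` accepts any recognised column that is present.
#'
#' @format A named list of named character vectors (field -> column header).
#' @export
sumstats_dialects <- list(
  ldsc = c(snp_id = "SNP", a1 = "A1", a2 = "A2", z = "Z", n = "N"),
  generic = c(
    snp_id = "SNP", chrom = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
    beta = "BETA", se = "SE", p = "P", n = "N"
  ),
  auto = c(
    snp_id = "SNP", chrom = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
    z = "Z", beta = "BETA", se = "SE", p = "P", n = "N"
  )
)

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))) {
    if (!dialect %in% names(sumstats_dialects)) {
      stop("unknown dialect '", dialect, "'; built-ins are: ",
           paste(names(sumstats_dialects), collapse = ", "))
    }
    return(sumstats_dialects[[dialect]])
  }
  if (is.null(names(dialect)) || any(!nzchar(names(dialect)))) {
    stop("a custom dialect must be a named character vector (field -> column)")
  }
  dialect
}

new_sumstats <- function(df, report = NULL) {
  class(df) <- c("sumstats", "data.frame")
  if (!is.null(report)) attr(df, "munge_report") <- report
  df
}

#' Read and validate GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited (optionally gzipped) summary-statistics
#' file, maps its columns through a dialect, derives the signed z-score when
#' only beta/se (or p plus a signed beta) are present, and drops rows that
#' violate the record invariants: alleles must be distinct A/C/G/T codes,
#' sample size positive, z finite and consistent with beta/se, and any
#' supplied p-value consistent with `2*pnorm(-|z|)`. Duplicated variant ids
#' are removed entirely (all copies). p-values of exactly zero are clipped to
#' the smallest positive double. A munge report (rows read / kept / dropped
#' by reason) is attached as an attribute and printed when `verbose`.
#'
#' @param path path to the file; `.gz` suffixes are read through `gzfile()`.
#' @param dialect a built-in dialect name (see [sumstats_dialects]) or a named
#'   character vector mapping canonical fields to column headers.
#' @param p_tolerance maximum allowed absolute discrepancy between a supplied
#'   p-value and the two-sided normal p implied by z.
#' @param verbose print the munge report as a message.
#' @return a `sumstats` data.frame with canonical columns (`snp_id`, `a1`,
#'   `a2`, `z`, `p`, `n`, plus `chrom`, `bp`, `beta`, `se` when available) and
#'   attribute `munge_report`.
#' @export
read_sumstats <- function(path, dialect = "auto", p_tolerance = 1e-4,
                          verbose = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read summary statistics: file '", path, "' does not exist")
  }
  map <- resolve_dialect(dialect)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- tryCatch(
    utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop("unreadable summary statistics file '", path,
                             "': ", conditionMessage(e))
  )
  map <- map[map %in% names(raw)]

  required <- c("snp_id", "a1", "a2", "n")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    stop("summary statistics file '", path, "' is missing required column(s): ",
         paste(unlist(sumstats_dialects$auto[missing]), collapse = ", "))
  }
  has <- function(f) f %in% names(map)
  if (!has("z") && !(has("beta") && has("se")) && !(has("p") && has("beta"))) {
    stop("no usable effect columns in '", path,
         "': need Z, or BETA+SE, or P with a signed BETA")
  }

  col <- function(f) raw[[map[[f]]]]
  n_read <- nrow(raw)
  reason <- rep(NA_character_, n_read)
  mark <- function(reason, bad, why) {
    sel <- is.na(reason) & bad
    reason[sel] <- why
    reason
  }

  snp_id <- as.character(col("snp_id"))
  a1 <- toupper(as.character(col("a1")))
  a2 <- toupper(as.character(col("a2")))
  n <- as.numeric(col("n"))
  z_in <- if (has("z")) as.numeric(col("z")) else NULL
  beta <- if (has("beta")) as.numeric(col("beta")) else NULL
  se <- if (has("se")) as.numeric(col("se")) else NULL
  p_in <- if (has("p")) as.numeric(col("p")) else NULL

  core_na <- is.na(snp_id) | is.na(a1) | is.na(a2) | is.na(n)
  reason <- mark(reason, core_na, "missing_values")
  reason <- mark(reason, !(a1 %in% ACGT) | !(a2 %in% ACGT) | a1 == a2,
                 "non_snp_alleles")
  reason <- mark(reason, n <= 0, "nonpositive_n")
  if (!is.null(se)) reason <- mark(reason, !is.na(se) & se <= 0, "nonpositive_se")

  # derive/validate z
  if (!is.null(z_in)) {
    z <- z_in
    if (!is.null(beta) && !is.null(se)) {
      z0 <- beta / se
      inconsistent <- is.finite(z) & is.finite(z0) &
        abs(z - z0) > 1e-6 * pmax(1, abs(z))
      reason <- mark(reason, inconsistent, "inconsistent_effect")
    }
    p_derived <- FALSE
  } else if (!is.null(beta) && !is.null(se)) {
    z <- beta / se
    p_derived <- FALSE
  } else {
    # p + signed beta: magnitude from p, sign from beta
    z <- sign(beta) * qnorm(pmin(pmax(p_in, .Machine$double.xmin), 1) / 2,
                            lower.tail = FALSE)
    p_derived <- TRUE
  }
  reason <- mark(reason, !is.finite(z), "bad_effect")

  if (!is.null(p_in)) {
    p <- pmax(p_in, .Machine$double.xmin)
    if (!p_derived) {
      mismatch <- is.finite(z) & !is.na(p_in) &
        abs(p - 2 * pnorm(-abs(z))) > p_tolerance
      reason <- mark(reason, mismatch, "p_z_mismatch")
      p[is.na(p_in)] <- (2 * pnorm(-abs(z)))[is.na(p_in)]
    }
  } else {
    p <- 2 * pnorm(-abs(z))
  }

  dup_ids <- unique(snp_id[duplicated(snp_id) & is.na(reason)])
  reason <- mark(reason, snp_id %in% dup_ids, "duplicate_snp_id")

  keep <- is.na(reason)
  if (!any(keep)) {
    stop("no rows of '", path, "' survived validation (", n_read, " read)")
  }

  out <- data.frame(snp_id = snp_id[keep], stringsAsFactors = FALSE)
  if (has("chrom")) out$chrom <- as.character(col("chrom"))[keep]
  if (has("bp")) out$bp <- as.integer(col("bp"))[keep]
  out$a1 <- a1[keep]
  out$a2 <- a2[keep]
  out$z <- z[keep]
  if (!is.null(beta)) out$beta <- beta[keep]
  if (!is.null(se)) out$se <- se[keep]
  out$p <- p[keep]
  out$n <- n[keep]

  dropped <- table(reason[!keep])
  report <- list(
    path = path,
    read = n_read,
    kept = sum(keep),
    dropped = setNames(as.integer(dropped), names(dropped))
  )
  if (verbose) {
    message("read ", report$read, " rows from '", basename(path), "'; kept ",
            report$kept,
            if (length(report$dropped)) paste0(
              "; dropped ", sum(report$dropped), " (",
              paste(names(report$dropped), report$dropped,
                    sep = "=", collapse = ", "), ")"
            ) else "")
  }
  new_sumstats(out, report)
}

#' Retrieve the munge report of a sumstats object
#' @param x a `sumstats` object from [read_sumstats()].
#' @return list with elements `read`, `kept`, `dropped`.
#' @export
munge_report <- function(x) attr(x, "munge_report")

#' Read a one-column SNP-list file
#' @param path file with one variant id per line (no header).
#' @return character vector of ids.
#' @export
read_snplist <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids[nzchar(trimws(ids))])
  if (!length(ids)) stop("empty SNP list: '", path, "'")
  ids
}

#' Filter summary statistics to a reference variant set
#'
#' Keeps only records whose id is in `snp_list` (e.g. HapMap 3 variants),
#' preserving order. An empty intersection is fatal.
#'
#' @param records a `sumstats` data.frame.
#' @param snp_list character vector of variant ids.
#' @param list_name label used in error messages.
#' @export
filter_to_reference <- function(records, snp_list, list_name = "reference SNP list") {
  if (!length(snp_list)) stop("empty reference SNP list")
  keep <- records$snp_id %in% snp_list
  if (!any(keep)) {
    stop("no overlap between the summary statistics (", nrow(records),
         " variants) and the ", list_name, " (", length(snp_list), " ids)")
  }
  new_sumstats(records[keep, , drop = FALSE], munge_report(records))
}

#' Drop strand-ambiguous variants
#'
#' Removes A/T and C/G variants, whose strand cannot be resolved from allele
#' codes alone.
#'
#' @param records a `sumstats` data.frame.
#' @param verbose report the number removed.
#' @export
drop_strand_ambiguous <- function(records, verbose = TRUE) {
  amb <- (records$a1 == "A" & records$a2 == "T") |
    (records$a1 == "T" & records$a2 == "A") |
    (records$a1 == "C" & records$a2 == "G") |
    (records$a1 == "G" & records$a2 == "C")
  if (verbose) message("dropped ", sum(amb), " strand-ambiguous variants")
  new_sumstats(records[!amb, , drop = FALSE], munge_report(records))
}

#' Align two sets of summary statistics on shared variants and alleles
#'
#' Intersects the two collections on variant id and harmonises effect alleles
#' to the first collection: when the second collection's alleles are swapped,
#' its z (and beta) sign is flipped; variants whose alleles cannot be
#' reconciled are dropped and counted. Strand complements are deliberately not
#' attempted. Output is sorted by (chromosome, position) when positions are
#' available.
#'
#' @param records_a,records_b `sumstats` data.frames for trait 1 and trait 2.
#' @return a `paired_variants` data.frame with columns `snp_id`, `chrom`,
#'   `bp`, shared `a1`/`a2`, `z1`, `z2`, `n1`, `n2`, `p1`, `p2` (and
#'   `beta1`/`beta2` when both inputs carry betas), plus attribute
#'   `align_report`.
#' @export
align_pair <- function(records_a, records_b) {
  common <- intersect(records_a$snp_id, records_b$snp_id)
  if (!length(common)) {
    stop("no shared variants between the two summary-statistics sets")
  }
  ia <- match(common, records_a$snp_id)
  ib <- match(common, records_b$snp_id)
  a1a <- records_a$a1[ia]; a2a <- records_a$a2[ia]
  a1b <- records_b$a1[ib]; a2b <- records_b$a2[ib]
  same <- a1a == a1b & a2a == a2b
  flip <- a1a == a2b & a2a == a1b
  keep <- same | flip
  if (!any(keep)) stop("no allele-consistent shared variants")

  sgn <- ifelse(flip, -1, 1)[keep]
  ia <- ia[keep]; ib <- ib[keep]
  out <- data.frame(
    snp_id = records_a$snp_id[ia],
    stringsAsFactors = FALSE
  )
  chrom <- records_a$chrom[ia] %||% records_b$chrom[ib]
  bp <- records_a$bp[ia] %||% records_b$bp[ib]
  out$chrom <- if (is.null(chrom)) NA_character_ else chrom
  out$bp <- if (is.null(bp)) NA_integer_ else bp
  out$a1 <- records_a$a1[ia]
  out$a2 <- records_a$a2[ia]
  out$z1 <- records_a$z[ia]
  out$z2 <- sgn * records_b$z[ib]
  if (!is.null(records_a$beta) && !is.null(records_b$beta)) {
    out$beta1 <- records_a$beta[ia]
    out$beta2 <- sgn * records_b$beta[ib]
  }
  out$n1 <- records_a$n[ia]
  out$n2 <- records_b$n[ib]
  out$p1 <- records_a$p[ia] %||% (2 * pnorm(-abs(out$z1)))
  out$p2 <- records_b$p[ib] %||% (2 * pnorm(-abs(out$z2)))

  if (!all(is.na(out$chrom)) && !all(is.na(out$bp))) {
    out <- out[order(chrom_key(out$chrom), out$bp), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "align_report") <- list(
    n_a = nrow(records_a), n_b = nrow(records_b),
    n_common = length(common), n_aligned = nrow(out),
    n_flipped = sum(flip), n_allele_mismatch = sum(!keep)
  )
  class(out) <- c("paired_variants", "data.frame")
  out
}

#' Write harmonised summary statistics in the munged z-score layout
#'
#' Emits a tab-delimited `SNP A1 A2 Z N` file (gzipped when the path ends in
#' `.gz`), the layout consumed by LD-score-regression tooling. When the input
#' carries positions, `CHR` and `BP` columns are included so the pairwise
#' stage can segment the output.
#'
#' @param x a `sumstats` data.frame.
#' @param path output path.
#' @param positions include CHR/BP columns when available.
#' @export
write_sumstats <- function(x, path, positions = TRUE) {
  out <- data.frame(SNP = x$snp_id, stringsAsFactors = FALSE)
  if (positions && !is.null(x$chrom) && !is.null(x$bp)) {
    out$CHR <- x$chrom
    out$BP <- x$bp
  }
  out$A1 <- x$a1
  out$A2 <- x$a2
  out$Z <- x$z
  if (!is.null(x$p)) out$P <- x$p
  out$N <- x$n
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
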