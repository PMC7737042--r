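# Genome segmentation into approximately independent LD blocks, variant ->
# block assignment, and LD-and-distance clumping.
#
# Coordinate convention: BED blocks are 0-based half-open; summary statistics
# are 1-based. The conversion is bp - 1 at the assignment boundary.

#' Read approximately independent LD blocks from a BED3 file
#'
#' Parses a three-column BED (chrom, start, end; 0-based half-open), assigns
#' each block a stable `block_id` in file order, sorts by (chromosome, start)
#' and refuses overlapping blocks. Malformed lines are fatal with their line
#' number.
#'
#' @param path path to a BED3 file.
#' @return an `ld_blocks` data.frame with columns `chrom`, `start`, `end`,
#'   `block_id`.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("BED file '", path, "' does not exist")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty BED file: '", path, "'")
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  n <- length(parts)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    f <- parts[[i]]
    if (length(f) < 3) {
      stop("malformed BED line ", lineno[i], " in '", path,
           "': expected at least 3 fields")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", lineno[i], " in '", path,
           "': non-numeric coordinates")
    }
    if (s >= e) {
      stop("malformed BED line ", lineno[i], " in '", path,
           "': start (", s, ") must be < end (", e, ")")
    }
    chrom[i] <- sub("^chr", "", f[1], ignore.case = TRUE)
    start[i] <- as.integer(s)
    end[i] <- as.integer(e)
  }
  blocks <- data.frame(chrom = chrom, start = start, end = end,
                       block_id = seq_len(n) - 1L, stringsAsFactors = FALSE)
  blocks <- blocks[order(chrom_key(blocks$chrom), blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping LD blocks on chromosome ", ch, " in '", path, "'")
    }
  }
  class(blocks) <- c("ld_blocks", "data.frame")
  blocks
}

#' Assign variants to LD blocks
#'
#' Maps each variant to the block with matching chromosome and
#' `start <= bp - 1 < end`. Variants outside every block get `NA` and are
#' reported.
#'
#' @param x a data.frame with `chrom` and `bp` columns (e.g. a
#'   `paired_variants` object).
#' @param blocks an `ld_blocks` data.frame from [read_blocks()].
#' @param verbose report the unassigned count.
#' @return integer vector of `block_id`s aligned to the rows of `x` (`NA` for
#'   unassigned variants).
#' @export
assign_segments <- function(x, blocks, verbose = TRUE) {
  stopifnot(!is.null(x$chrom), !is.null(x$bp))
  chrom <- sub("^chr", "", as.character(x$chrom), ignore.case = TRUE)
  bid <- rep(NA_integer_, nrow(x))
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    pos0 <- x$bp[sel] - 1L
    j <- findInterval(pos0, b$start)
    ok <- j >= 1L & pos0 < b$end[pmax(j, 1L)]
    bid[sel[ok]] <- b$block_id[j[ok]]
  }
  if (verbose && anyNA(bid)) {
    message(sum(is.na(bid)), " of ", length(bid),
            " variants fall outside all LD blocks and are excluded")
  }
  bid
}

#' Greedy LD-and-distance clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest p-value as an
#' index SNP and removes all unclaimed variants within `window_bp` of it on
#' the same chromosome with LD `r^2 > r2_threshold`, until no variants
#' remain. Ties on p are broken by smaller (chromosome, position).
#'
#' @param records data.frame with `snp_id`, `chrom`, `bp`, `p`.
#' @param ld either a function `(id_a, id_b) -> r^2` or a square matrix with
#'   variant ids as dimnames; pairs absent from a matrix count as `r^2 = 0`.
#' @param r2_threshold LD threshold above which a variant is claimed.
#' @param window_bp maximum distance (inclusive) for claiming.
#' @return character vector of index variant ids in selection order.
#' @export
clump <- function(records, ld, r2_threshold = 0.1, window_bp = 3e6) {
  stopifnot(!is.null(records$p))
  if (!nrow(records)) return(character(0))
  lookup <- if (is.function(ld)) {
    ld
  } else {
    mat <- as.matrix(ld)
    function(i, j) {
      if (i %in% rownames(mat) && j %in% colnames(mat)) mat[i, j] else 0
    }
  }
  ord <- order(records$p, chrom_key(records$chrom), records$bp)
  rec <- records[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(rec))
  indices <- character(0)
  while (any(remaining)) {
    i <- which(remaining)[1L]
    indices <- c(indices, rec$snp_id[i])
    remaining[i] <- FALSE
    cand <- which(remaining & rec$chrom == rec$chrom[i] &
                    abs(rec$bp - rec$bp[i]) <= window_bp)
    if (length(cand)) {
      r2 <- vapply(rec$snp_id[cand], function(id) lookup(rec$snp_id[i], id),
                   numeric(1))
      remaining[cand[r2 > r2_threshold]] <- FALSE
    }
  }
  indices
}
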