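# End-to-end orchestration: the pairwise segment scan and the
# partial-genetic-correlation analysis, each runnable from in-memory objects
# or from the text files the generators and mungers emit.

as_ld_blocks <- function(blocks) {
  if (is.character(blocks)) return(read_blocks(blocks))
  if (inherits(blocks, "ld_blocks")) return(blocks)
  stopifnot(all(c("chrom", "start", "end") %in% names(blocks)))
  b <- as.data.frame(blocks)[, c("chrom", "start", "end")]
  b$chrom <- sub("^chr", "", as.character(b$chrom), ignore.case = TRUE)
  b$block_id <- seq_len(nrow(b)) - 1L
  b <- b[order(chrom_key(b$chrom), b$start), , drop = FALSE]
  rownames(b) <- NULL
  class(b) <- c("ld_blocks", "data.frame")
  b
}

as_sumstats <- function(x, verbose = TRUE) {
  if (is.character(x)) return(read_sumstats(x, verbose = verbose))
  if (inherits(x, "sumstats")) return(x)
  # a generic-dialect data.frame (e.g. straight from a generator)
  map <- sumstats_dialects$auto
  map <- map[map %in% names(x)]
  out <- setNames(as.data.frame(x)[, unname(map), drop = FALSE], names(map))
  out$a1 <- toupper(out$a1)
  out$a2 <- toupper(out$a2)
  if (is.null(out$z)) out$z <- out$beta / out$se
  if (is.null(out$p)) out$p <- 2 * pnorm(-abs(out$z))
  out$chrom <- if (is.null(out$chrom)) NA_character_ else as.character(out$chrom)
  new_sumstats(out)
}

#' Run the full pairwise-GWAS segment analysis
#'
#' The complete pipeline for two traits: align the summary statistics,
#' assign variants to LD blocks, compute single-trait segment posteriors for
#' both traits, estimate the null z-score correlation from segments
#' unassociated with either trait (unless `null_correlation` is supplied),
#' run the five-model Bayesian test on every segment with empirical-Bayes
#' priors, and classify segments.
#'
#' @param sumstats1,sumstats2 `sumstats` objects, generator data.frames or
#'   file paths for the two traits.
#' @param blocks LD blocks: an `ld_blocks` object, a chrom/start/end
#'   data.frame, or a BED3 path.
#' @param W_grid prior-variance grid for the ABFs.
#' @param null_correlation supply a known overlap correlation C to skip the
#'   estimation pre-step (0 disables the correction).
#' @param ppa_threshold single-trait PPA below which a segment counts as
#'   unassociated in the null-correlation pre-step; also the total-PPA
#'   threshold of the NEITHER classification rule.
#' @param gws_threshold genome-wide significance level on p.
#' @param min_snps segments with fewer variants are excluded from prior
#'   estimation (still scored and classified).
#' @param verbose print progress messages.
#' @return a `pairwise_scan` list: `segments` (per-segment table with
#'   coordinates, k, log10 regional Bayes factors, posteriors, GWS flags,
#'   top SNPs and label), `priors`, `single_trait` (per-trait priors and
#'   PPAs), `null_correlation`, `counts`, `params`.
#' @export
run_pairwise <- function(sumstats1, sumstats2, blocks,
                         W_grid = c(0.01, 0.1, 0.5),
                         null_correlation = NULL,
                         ppa_threshold = 0.2, gws_threshold = 5e-8,
                         min_snps = 10, verbose = TRUE) {
  ss1 <- as_sumstats(sumstats1, verbose = verbose)
  ss2 <- as_sumstats(sumstats2, verbose = verbose)
  blocks <- as_ld_blocks(blocks)
  if (!nrow(blocks)) stop("empty LD block set")
  paired <- align_pair(ss1, ss2)
  seg <- assign_segments(paired, blocks, verbose = verbose)
  keep <- !is.na(seg)
  paired <- paired[keep, , drop = FALSE]
  seg <- seg[keep]
  if (!nrow(paired)) stop("no variants fall inside the LD blocks")

  v1 <- 1 / paired$n1
  v2 <- 1 / paired$n2

  st1 <- single_trait_segment_ppa(paired$z1, v1, seg, W_grid, min_snps)
  st2 <- single_trait_segment_ppa(paired$z2, v2, seg, W_grid, min_snps)

  null_est <- NULL
  if (is.null(null_correlation)) {
    null_est <- estimate_null_correlation(paired, seg, st1$ppa, st2$ppa,
                                          threshold = ppa_threshold)
    null_correlation <- null_est$C
    if (verbose) {
      message(sprintf(
        "null z-score correlation: %.4f (%d variants in %d segments)",
        null_correlation, null_est$n_variants, null_est$n_segments))
    }
  }

  params <- abf_params(W_grid, null_correlation)
  ev <- snp_evidence(paired$z1, paired$z2, v1, v2, params)
  idx <- split(seq_len(nrow(paired)), seg)
  lrbf <- t(vapply(idx, function(i) {
    unname(as.vector(regional_bfs(ev[i, , drop = FALSE])))
  }, numeric(4)))
  k <- lengths(idx)
  usable <- k >= min_snps
  if (verbose && any(!usable)) {
    message(sum(!usable), " segments with fewer than ", min_snps,
            " variants excluded from prior estimation")
  }
  priors <- estimate_priors(lrbf[usable, , drop = FALSE])
  ppa <- segment_posteriors(lrbf, priors)

  top <- function(i, p) i[which.min(p)]
  top1 <- vapply(idx, function(i) top(i, paired$p1[i]), integer(1))
  top2 <- vapply(idx, function(i) top(i, paired$p2[i]), integer(1))
  gws1 <- paired$p1[top1] < gws_threshold
  gws2 <- paired$p2[top2] < gws_threshold

  labels <- classify_segments(ppa, gws1, gws2, ppa_threshold)

  bid <- as.integer(names(idx))
  bi <- match(bid, blocks$block_id)
  segments <- data.frame(
    block_id = bid,
    chrom = blocks$chrom[bi], start = blocks$start[bi], end = blocks$end[bi],
    n_snps = as.integer(k),
    log10_rbf1 = lrbf[, 1] / log(10), log10_rbf2 = lrbf[, 2] / log(10),
    log10_rbf3 = lrbf[, 3] / log(10), log10_rbf4 = lrbf[, 4] / log(10),
    stringsAsFactors = FALSE
  )
  segments <- cbind(segments, as.data.frame(ppa))
  segments$ppa_assoc <- 1 - ppa[, 1]
  segments$gws1 <- gws1
  segments$gws2 <- gws2
  segments$top_snp1 <- paired$snp_id[top1]
  segments$top_p1 <- paired$p1[top1]
  segments$top_snp2 <- paired$snp_id[top2]
  segments$top_p2 <- paired$p2[top2]
  segments$label <- labels
  rownames(segments) <- NULL

  counts <- table(factor(labels, levels = c("TRAIT1_ONLY", "TRAIT2_ONLY",
                                            "BOTH", "SEPARATE", "NEITHER",
                                            "UNCLASSIFIED")))
  out <- structure(
    list(segments = segments, priors = priors,
         single_trait = list(trait1 = st1, trait2 = st2),
         null_correlation = null_correlation, null_correlation_fit = null_est,
         counts = counts,
         params = list(W_grid = W_grid, ppa_threshold = ppa_threshold,
                       gws_threshold = gws_threshold, min_snps = min_snps)),
    class = "pairwise_scan"
  )
  if (verbose) print(out)
  out
}

#' @export
print.pairwise_scan <- function(x, ...) {
  cat("Pairwise GWAS segment scan:", nrow(x$segments), "segments\n")
  cat(sprintf("  null z-score correlation C = %.4f\n", x$null_correlation))
  cat("  model priors:",
      paste(names(x$priors$pi), round(x$priors$pi, 4), sep = "=",
            collapse = " "), "\n")
  cat("  segment labels:\n")
  print(x$counts)
  invisible(x)
}

#' Write the per-segment table of a pairwise scan
#' @param x a `pairwise_scan`.
#' @param path output TSV path.
#' @export
write_pairwise_segments <- function(x, path) {
  utils::write.table(x$segments, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Partial genetic correlations of third traits with two focal traits
#'
#' For every trait Y in `ss_list` other than the two focal traits, builds
#' the 3x3 genetic covariance matrix (Y, MD, Neu) by LDSC on a shared
#' variant set and jackknife partition, fits the genetic multiple regression
#' of Y on both focal traits, tests (i) unadjusted correlations against
#' zero, (ii) adjusted coefficients against zero and (iii) attenuation of
#' each adjusted estimate relative to its unadjusted counterpart, pools all
#' p-values into one Benjamini-Yekutieli family, and labels each trait's
#' pattern.
#'
#' @param ss_list named list of `sumstats` objects (or generator
#'   data.frames / file paths) containing the two focal traits and at least
#'   one further trait.
#' @param md,neu names of the two focal traits within `ss_list`.
#' @param ldscores LD score table (data.frame or path).
#' @param M variant count behind the LD scores (default: attribute).
#' @param n_blocks jackknife blocks.
#' @param alpha significance level applied to q-values for pattern labels.
#' @param verbose print progress.
#' @return a `partial_rg_result` data.frame: one row per trait Y with
#'   unadjusted correlations, adjusted (standardised) coefficients,
#'   classical partial correlations, SEs, p- and q-values, attenuation
#'   differences and the pattern label. The underlying fits are attached as
#'   attribute `fits`.
#' @export
run_partial_rg <- function(ss_list, md = "MD", neu = "NEU", ldscores,
                           M = NULL, n_blocks = 200, alpha = 0.05,
                           verbose = TRUE) {
  if (is.character(ldscores)) ldscores <- read_ldscores(ldscores)
  if (is.null(M)) M <- attr(ldscores, "M")
  stopifnot(is.list(ss_list), !is.null(names(ss_list)))
  if (!all(c(md, neu) %in% names(ss_list))) {
    stop("ss_list must contain the focal traits '", md, "' and '", neu, "'")
  }
  y_traits <- setdiff(names(ss_list), c(md, neu))
  if (!length(y_traits)) {
    stop("need a third trait: ss_list only contains the two focal traits")
  }
  ss_list <- lapply(ss_list, as_sumstats, verbose = verbose)

  rows <- list()
  fits <- list()
  for (y in y_traits) {
    S_fit <- build_genetic_covariance(
      setNames(ss_list[c(y, md, neu)], c(y, md, neu)),
      ldscores, M = M, n_blocks = n_blocks
    )
    reg <- fit_partial_regression(S_fit, y = y, x = c(md, neu))
    att_md <- test_attenuation(reg$r_xy[md], reg$b[md],
                               reg$reps$r[, md], reg$reps$b[, md])
    att_neu <- test_attenuation(reg$r_xy[neu], reg$b[neu],
                                reg$reps$r[, neu], reg$reps$b[, neu])
    rows[[y]] <- data.frame(
      trait = y,
      r_md = unname(reg$r_xy[md]), r_md_se = unname(reg$r_se[md]),
      p_r_md = unname(reg$r_p[md]),
      r_neu = unname(reg$r_xy[neu]), r_neu_se = unname(reg$r_se[neu]),
      p_r_neu = unname(reg$r_p[neu]),
      md_adj_neu = unname(reg$b[md]), md_adj_neu_se = unname(reg$b_se[md]),
      p_md_adj_neu = unname(reg$b_p[md]),
      neu_adj_md = unname(reg$b[neu]), neu_adj_md_se = unname(reg$b_se[neu]),
      p_neu_adj_md = unname(reg$b_p[neu]),
      partial_r_md = unname(reg$partial_r[md]),
      partial_r_neu = unname(reg$partial_r[neu]),
      atten_md = att_md$difference, p_atten_md = att_md$p,
      atten_neu = att_neu$difference, p_atten_neu = att_neu$p,
      sign_flip_md = att_md$sign_flip, sign_flip_neu = att_neu$sign_flip,
      residual_u = reg$u,
      stringsAsFactors = FALSE
    )
    fits[[y]] <- list(S = S_fit, regression = reg)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  # one pooled BY family: all traits x {unadjusted, adjusted, attenuation}
  pcols <- c("p_r_md", "p_r_neu", "p_md_adj_neu", "p_neu_adj_md",
             "p_atten_md", "p_atten_neu")
  pmat <- as.matrix(res[, pcols])
  qmat <- matrix(fdr_correct(as.vector(pmat)), nrow = nrow(res),
                 dimnames = list(NULL, sub("^p_", "q_", pcols)))
  res <- cbind(res, as.data.frame(qmat))

  res$label <- vapply(seq_len(nrow(res)), function(i) {
    classify_pattern(
      res$q_r_md[i], res$q_r_neu[i], res$q_md_adj_neu[i], res$q_neu_adj_md[i],
      res$md_adj_neu[i], res$md_adj_neu_se[i],
      res$neu_adj_md[i], res$neu_adj_md_se[i], alpha = alpha
    )
  }, character(1))

  attr(res, "fits") <- fits
  attr(res, "params") <- list(md = md, neu = neu, n_blocks = n_blocks,
                              alpha = alpha, M = M)
  class(res) <- c("partial_rg_result", "data.frame")
  res
}
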